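# Shared fixtures, built lazily and cached for the whole test run.

.fix <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (is.null(.fix[[name]])) .fix[[name]] <- force(expr)
  .fix[[name]]
}

circle_polygon <- function(n = 64, r = 1) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(r * cos(th), r * sin(th))
}

coarse_disk <- function() cached("coarse_disk", build_mesh(circle_polygon(), 16, 400))
fine_disk <- function() cached("fine_disk", build_mesh(circle_polygon(), 16, 2000))
proto16 <- function() cached("proto16", adjacent_protocol(16))

small_scene <- function() cached("small_scene", make_thorax_scene(64, 64, 1))

# compact study configuration used by non-acceptance study tests
tiny_config <- function() {
  study_config(M = 64, N = 64, fwd_elements = 5000, inv_elements = 1200,
               n_seeds = 2, seed = 1, greit_targets = 200,
               atelectasis_fractions = c(0, 0.25))
}
tiny_setup <- function() cached("tiny_setup", study_setup(tiny_config()))

# full-scale study shared by the acceptance criteria (built once)
accept_config <- function() study_config(seed = 1)
accept_setup <- function() cached("accept_setup", study_setup(accept_config()))
accept_patterns <- function() {
  cached("accept_patterns", run_pattern_study(accept_config(), accept_setup()))
}
accept_atelectasis <- function() {
  cached("accept_atelectasis",
         run_atelectasis_study(accept_config(), accept_setup()))
}
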