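# Simulation study harness: the five-pattern comparison and the graded
# dorsal-atelectasis series, four methods each (GREIT, element-space
# Gauss-Newton with background prior, DCT + contour prior, DCT + detail
# prior), scored by the l2-norm image difference against normalized ground
# truth.

#' Study configuration
#'
#' @param M,N raster size
#' @param n_elec electrode count (adjacent protocol)
#' @param fwd_elements forward-mesh element target (inverse-crime avoidance:
#'   at least 4x the inverse mesh)
#' @param inv_elements inverse-mesh element target
#' @param noise_fraction measurement noise relative to sd(V - V_baseline)
#' @param n_seeds noise realizations averaged per case
#' @param seed master seed (scene generation and noise-seed derivation)
#' @param n_x,n_y cosine frequencies per axis
#' @param target_noise_figure regularization calibration target
#' @param greit_targets GREIT training-target count
#' @param atelectasis_fractions grid for the atelectasis series
#' @return a `study_config`
#' @export
study_config <- function(M = 128L, N = 128L, n_elec = 16L,
                         fwd_elements = 20000L, inv_elements = 3000L,
                         noise_fraction = 0.25, n_seeds = 10L, seed = 1L,
                         n_x = 15L, n_y = 15L, target_noise_figure = 0.5,
                         greit_targets = 1000L,
                         atelectasis_fractions = seq(0, 0.5, by = 0.05)) {
  structure(list(M = as.integer(M), N = as.integer(N),
                 n_elec = as.integer(n_elec),
                 fwd_elements = as.integer(fwd_elements),
                 inv_elements = as.integer(inv_elements),
                 noise_fraction = noise_fraction,
                 n_seeds = as.integer(n_seeds), seed = as.integer(seed),
                 n_x = as.integer(n_x), n_y = as.integer(n_y),
                 target_noise_figure = target_noise_figure,
                 greit_targets = as.integer(greit_targets),
                 atelectasis_fractions = atelectasis_fractions),
            class = "study_config")
}

# shared setup: scene, meshes, baseline solves, Jacobian, operators
study_setup <- function(config) {
  scene <- make_thorax_scene(config$M, config$N, config$seed)
  proto <- adjacent_protocol(config$n_elec)
  mesh_f <- build_mesh(scene$thorax_polygon, config$n_elec, config$fwd_elements)
  mesh_i <- build_mesh(scene$thorax_polygon, config$n_elec, config$inv_elements)
  mesh_f <- set_conductivity(mesh_f, scene$sigma_baseline_fun)
  mesh_i <- set_conductivity(mesh_i, scene$sigma_baseline_fun)
  v_base <- as.numeric(solve_forward(mesh_f, proto))
  # Jacobian at the inhomogeneous background linearization (lung 0.5 / 1),
  # shared by the Gauss-Newton background baseline and the DCT pipeline
  J <- compute_jacobian(mesh_i, protocol = proto, normalized = TRUE)
  # GREIT carries no patient-specific conductivity prior: it trains on the
  # homogeneous (sigma = 1) linearization, as in the consensus algorithm
  J_hom <- compute_jacobian(mesh_i, sigma_baseline = rep(1, nrow(mesh_i$elements)),
                            protocol = proto, normalized = TRUE)
  rcfg <- recon_config(config$target_noise_figure, config$n_x, config$n_y)
  contour <- make_contour_prior(scene$lung_mask, scene$extent)
  # one shared noise-figure reference: small targets at the lung centroids
  y_hom <- lung_reference_signal(J, mesh_i, scene$lung_mask, scene$extent)
  greit <- greit_train(mesh_i, J_hom, scene$extent, config$M, config$N,
                       n_targets = config$greit_targets,
                       noise_fraction = config$noise_fraction, config = rcfg,
                       y_hom = y_hom)
  list(scene = scene, proto = proto, mesh_f = mesh_f, mesh_i = mesh_i,
       v_base = v_base, J = J, rcfg = rcfg, contour = contour, greit = greit,
       y_hom = y_hom)
}

# evaluate one target state under all four methods across noise seeds
run_cases <- function(setup, state_scene, case_label, study_label, config,
                      seed_offset = 0L) {
  mesh_t <- set_conductivity(setup$mesh_f, state_scene$sigma_target_fun)
  v_t <- as.numeric(solve_forward(mesh_t, setup$proto))
  gt_n <- normalize_image(state_scene$ground_truth)
  detail <- make_detail_prior(state_scene$ct_surrogate, state_scene$lung_mask)
  mask <- state_scene$lung_mask
  rows <- vector("list", config$n_seeds)
  for (s in seq_len(config$n_seeds)) {
    sd_i <- config$seed * 10000L + seed_offset * 100L + s
    y <- add_measurement_noise(v_t, setup$v_base, config$noise_fraction, sd_i)
    r_g <- greit_reconstruct(setup$greit, y, mask)
    r_n <- gn_background(setup$J, y, setup$mesh_i, mask, state_scene$extent,
                         setup$rcfg, y_hom = setup$y_hom)
    r_c <- reconstruct_pipeline(setup$mesh_i, setup$contour, setup$J, y,
                                setup$rcfg, y_hom = setup$y_hom)
    r_d <- reconstruct_pipeline(setup$mesh_i, detail, setup$J, y, setup$rcfg,
                                y_hom = setup$y_hom)
    l2 <- c(
      greit = l2_image_difference(normalize_image(r_g$masked_rasterized), gt_n),
      gn = l2_image_difference(normalize_image(r_n$masked_rasterized), gt_n),
      dct_contour = l2_image_difference(normalize_image(r_c$restored_image), gt_n),
      dct_detail = l2_image_difference(normalize_image(r_d$restored_image), gt_n))
    rows[[s]] <- tibble::tibble(study = study_label, case = case_label,
                                seed = sd_i, method = names(l2),
                                l2 = as.numeric(l2))
  }
  dplyr::bind_rows(rows)
}

#' Run the five-pattern comparison study
#'
#' Simulates the five lung conductivity patterns with noisy adjacent-protocol
#' measurements, reconstructs each frame with GREIT, the one-step
#' Gauss-Newton background solver, and the DCT pipeline with contour and
#' detail priors, and scores every reconstruction by the l2-norm image
#' difference against the normalized ground truth.
#'
#' @param config a `study_config`
#' @param setup optional precomputed [study_setup] (reused across studies)
#' @return an `eit_study` with a per-case tibble and the run manifest
#' @export
run_pattern_study <- function(config = study_config(), setup = NULL) {
  if (is.null(setup)) setup <- study_setup(config)
  cases <- dplyr::bind_rows(lapply(seq_along(letters[1:5]), function(i) {
    p <- letters[i]
    sc <- apply_pattern(setup$scene, p)
    run_cases(setup, sc, paste0("pattern_", p), "patterns", config,
              seed_offset = i)
  }))
  new_eit_study(cases, config, setup, "patterns")
}

#' Run the graded dorsal-atelectasis study
#'
#' Same four-method comparison over the atelectasis fraction grid: the
#' dorsal part of each lung holding the given area fraction stays at
#' baseline conductivity (no ventilation signal, 0 HU in the CT surrogate)
#' while the rest of the lung ventilates.
#'
#' @inheritParams run_pattern_study
#' @return an `eit_study`
#' @export
run_atelectasis_study <- function(config = study_config(), setup = NULL) {
  if (is.null(setup)) setup <- study_setup(config)
  fr <- config$atelectasis_fractions
  cases <- dplyr::bind_rows(lapply(seq_along(fr), function(i) {
    sc <- apply_atelectasis(setup$scene, fr[i])
    run_cases(setup, sc, sprintf("atelectasis_%02.0f", 100 * fr[i]),
              "atelectasis", config, seed_offset = 50L + i)
  }))
  st <- new_eit_study(cases, config, setup, "atelectasis")
  st$fractions <- fr
  st
}

new_eit_study <- function(cases, config, setup, label) {
  structure(list(
    cases = cases,
    study = label,
    config = config,
    setup = setup,
    manifest = tibble::tibble(
      study = label, seed = config$seed,
      fwd_elements = nrow(setup$mesh_f$elements),
      inv_elements = nrow(setup$mesh_i$elements),
      n_seeds = config$n_seeds, noise_fraction = config$noise_fraction,
      greit_lambda = setup$greit$lambda, greit_nf = setup$greit$achieved_nf)
  ), class = "eit_study")
}

#' @export
print.eit_study <- function(x, ...) {
  cat(sprintf("<eit_study %s> %d cases x %d seeds x 4 methods\n",
              x$study, length(unique(x$cases$case)), x$config$n_seeds))
  print(summary_table(x))
  invisible(x)
}

#' Per-case mean l2 table of a study
#' @param study an `eit_study` (or a raw case tibble)
#' @return tibble: case x method mean l2 over noise seeds
#' @export
summary_table <- function(study) {
  cases <- if (inherits(study, "eit_study")) study$cases else study
  cases |>
    dplyr::group_by(.data$study, .data$case, .data$method) |>
    dplyr::summarise(l2 = mean(.data$l2), .groups = "drop")
}

#' Case-level results of a study as a tibble
#' @param x an `eit_study`
#' @param ... unused
#' @export
tidy.eit_study <- function(x, ...) x$cases

#' One-row improvement summary of a study
#' @param x an `eit_study`
#' @param ... unused
#' @export
glance.eit_study <- function(x, ...) improvement_summary(x$cases)

#' Mean relative l2 improvements of the DCT priors over the baselines
#'
#' Improvement = (baseline mean l2 - DCT mean l2) / baseline mean l2 * 100,
#' with means taken over all supplied cases (patterns, fractions, seeds).
#'
#' @param cases case tibble (one or several studies bound together, columns
#'   method and l2)
#' @return one-row tibble with the four improvement percentages and the
#'   per-method means
#' @export
improvement_summary <- function(cases) {
  if (inherits(cases, "eit_study")) cases <- cases$cases
  m <- cases |>
    dplyr::group_by(.data$method) |>
    dplyr::summarise(l2 = mean(.data$l2), .groups = "drop")
  g <- function(meth) m$l2[m$method == meth]
  imp <- function(dct, base) 100 * (g(base) - g(dct)) / g(base)
  tibble::tibble(
    n_cases = nrow(cases) / dplyr::n_distinct(cases$method),
    mean_l2_greit = g("greit"), mean_l2_gn = g("gn"),
    mean_l2_dct_contour = g("dct_contour"),
    mean_l2_dct_detail = g("dct_detail"),
    improvement_contour_vs_greit = imp("dct_contour", "greit"),
    improvement_contour_vs_gn = imp("dct_contour", "gn"),
    improvement_detail_vs_greit = imp("dct_detail", "greit"),
    improvement_detail_vs_gn = imp("dct_detail", "gn"))
}
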