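make_test_problem <- function(n_meas = 60, n_par = 25, seed = 2) {
  set.seed(seed)
  J <- matrix(rnorm(n_meas * n_par), n_meas, n_par) %*%
    diag(exp(-seq(0, 4, length.out = n_par)))
  y_hom <- as.numeric(J %*% rnorm(n_par))
  list(J = J, y_hom = y_hom)
}

test_that("noise-figure calibration hits the target and is monotone", {
  pb <- make_test_problem()
  lam <- calibrate_lambda(pb$J, pb$y_hom, target_nf = 0.5)
  expect_gt(as.numeric(lam), 0)
  nf <- attr(lam, "achieved_nf")
  expect_gte(nf, 0.495)
  expect_lte(nf, 0.505)
  # NF computed from the dense reconstruction matrix agrees with the
  # SVD-path value used during calibration
  B <- recon_matrix(pb$J, as.numeric(lam))
  expect_equal(noise_figure(B, pb$y_hom), nf, tolerance = 1e-8)
  # NF(lambda) decreases monotonically over the bracket
  nfs <- vapply(10^seq(-6, 4, length.out = 25), function(l) {
    noise_figure(recon_matrix(pb$J, l), pb$y_hom)
  }, numeric(1))
  expect_true(all(diff(nfs) < 0))
  expect_error(calibrate_lambda(pb$J, pb$y_hom, target_nf = 1e6),
               "calibration error")
})

test_that("closed-form reconstruction equals the augmented LS oracle", {
  pb <- make_test_problem()
  set.seed(3)
  y <- rnorm(nrow(pb$J))
  for (lam in c(1e-3, 0.1, 10)) {
    xh <- reconstruct(pb$J, y, lam)
    xo <- oracle_augmented_ls(pb$J, y, lam)
    expect_equal(xh, unname(xo), tolerance = 1e-8)
    # explicit penalty-matrix path agrees with the push-through identity
    xr <- reconstruct(pb$J, y, lam, R = diag(ncol(pb$J)))
    expect_equal(xr, xh, tolerance = 1e-8)
  }
  expect_equal(reconstruct(pb$J, numeric(nrow(pb$J)), 1), rep(0, ncol(pb$J)))
})

test_that("reconstruction is linear in the data and shrinks with lambda", {
  pb <- make_test_problem()
  set.seed(6)
  y1 <- rnorm(nrow(pb$J)); y2 <- rnorm(nrow(pb$J))
  x1 <- reconstruct(pb$J, y1, 0.5)
  x2 <- reconstruct(pb$J, y2, 0.5)
  x12 <- reconstruct(pb$J, 2 * y1 - 3 * y2, 0.5)
  expect_equal(x12, 2 * x1 - 3 * x2, tolerance = 1e-10)
  norms <- vapply(10^seq(-2, 4, length.out = 15), function(l) {
    sqrt(sum(reconstruct(pb$J, y1, l)^2))
  }, numeric(1))
  expect_true(all(diff(norms) < 0))
  expect_lt(norms[15] / norms[1], 1e-4)
})

test_that("full pipeline confines, caches, and carries a negative lung", {
  setup <- tiny_setup()
  cfg <- tiny_config()
  sc <- apply_pattern(setup$scene, "a")
  mesh_t <- set_conductivity(setup$mesh_f, sc$sigma_target_fun)
  v_t <- as.numeric(solve_forward(mesh_t, setup$proto))
  y <- add_measurement_noise(v_t, setup$v_base, 0, NULL)
  r <- reconstruct_pipeline(setup$mesh_i, setup$contour, setup$J, y,
                            setup$rcfg, y_hom = setup$y_hom)
  expect_s3_class(r, "eit_recon")
  expect_length(r$coefficients, 225L)
  # conductivity decreased: restored image negative in the lung
  expect_lt(mean(r$restored_image$values[sc$lung_mask]), 0)
  # exactly zero outside the prior support
  expect_equal(max(abs(r$restored_image$values[!sc$lung_mask])), 0)
  expect_gte(r$achieved_noise_figure, 0.495)
  expect_lte(r$achieved_noise_figure, 0.505)
  # a second frame with the same prior reuses the cached operator
  y2 <- add_measurement_noise(v_t, setup$v_base, 0.25, 99)
  r2 <- reconstruct_pipeline(setup$mesh_i, setup$contour, setup$J, y2,
                             setup$rcfg, y_hom = setup$y_hom)
  expect_identical(r2$reconstruction_matrix_hash, r$reconstruction_matrix_hash)
  expect_identical(r2$lambda_used, r$lambda_used)
  # glance/tidy surfaces
  expect_equal(nrow(glance(r)), 1L)
  expect_equal(nrow(tidy(r)), 225L)
})

test_that("a detail prior zeroed over the atelectatic slab inhibits it", {
  setup <- tiny_setup()
  sc <- apply_atelectasis(setup$scene, 0.25)
  mesh_t <- set_conductivity(setup$mesh_f, sc$sigma_target_fun)
  v_t <- as.numeric(solve_forward(mesh_t, setup$proto))
  y <- add_measurement_noise(v_t, setup$v_base, 0.25, 21)
  detail <- make_detail_prior(sc$ct_surrogate, sc$lung_mask)
  r <- reconstruct_pipeline(setup$mesh_i, detail, setup$J, y, setup$rcfg,
                            y_hom = setup$y_hom)
  atel <- eitdct:::eval_on_grid(function(x, y) sc$atelectatic_fun(x, y),
                                sc$extent, sc$M, sc$N) > 0
  expect_equal(max(abs(r$restored_image$values[atel])), 0)
  # but the ventilated lung does carry signal
  expect_gt(max(abs(r$restored_image$values[sc$lung_mask & !atel])), 0)
})
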