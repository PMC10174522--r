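test_that("adjacent protocol yields 16 x 13 = 208 measurements", {
  pr <- proto16()
  expect_equal(pr$n_meas, 208L)
  expect_equal(nrow(pr$measurement_pairs), 208L)
  # no measurement pair shares an electrode with its drive pair
  for (r in seq_len(pr$n_meas)) {
    d <- pr$injection_pairs[pr$table[r, "drive"], ]
    mp <- pr$measurement_pairs[r, ]
    expect_length(intersect(d, mp), 0)
  }
  expect_equal(adjacent_protocol(8)$n_meas, 8L * 5L)
})

test_that("forward solution satisfies reciprocity", {
  m <- coarse_disk()
  pr <- proto16()
  v <- as.numeric(solve_forward(m, pr))
  tab <- pr$table
  swapped <- vapply(seq_len(nrow(tab)), function(r) {
    v[which(tab[, "drive"] == tab[r, "meas"] & tab[, "meas"] == tab[r, "drive"])]
  }, numeric(1))
  expect_lt(max(abs(swapped - v)) / max(abs(v)), 1e-10)
})

test_that("voltages scale as 1/c under the continuum conductivity scaling", {
  m <- coarse_disk()
  pr <- proto16()
  v <- as.numeric(solve_forward(m, pr))
  # continuum scaling: sigma -> c sigma with contact impedance z -> z/c
  m2 <- set_conductivity(m, rep(3, nrow(m$elements)))
  m2$contact_impedance <- m$contact_impedance / 3
  v2 <- as.numeric(solve_forward(m2, pr))
  expect_equal(v2, v / 3, tolerance = 1e-12)
  # with fixed contact impedance the scaling holds approximately
  m3 <- set_conductivity(m, rep(3, nrow(m$elements)))
  v3 <- as.numeric(solve_forward(m3, pr))
  expect_equal(v3, v / 3, tolerance = 0.15)
})

test_that("solver agrees with an independent dense CEM assembly", {
  m <- coarse_disk()
  m <- set_conductivity(m, function(x, y) 1 + 0.5 * (x^2 + y^2 < 0.25))
  pr <- proto16()
  v <- as.numeric(solve_forward(m, pr))
  v_oracle <- oracle_cem_forward(m, pr)
  expect_equal(v, v_oracle, tolerance = 1e-9)
})

test_that("measurement magnitude decays away from the injection pair", {
  m <- fine_disk()
  pr <- proto16()
  v <- as.numeric(solve_forward(m, pr))
  # drive 1 injects between electrodes 1 and 2; walk measurement pairs
  # 3..8 moving away and expect monotone decreasing |V|
  d1 <- which(pr$table[, "drive"] == 1 & pr$table[, "meas"] %in% 3:8)
  mags <- abs(v[d1])[order(pr$table[d1, "meas"])]
  expect_true(all(diff(mags) < 0))
})

test_that("injected current is conserved", {
  m <- coarse_disk()
  pr <- proto16()
  sys <- eitdct:::assemble_cem(m)
  for (d in c(1, 7)) {
    rhs <- numeric(sys$N + sys$L + 1)
    rhs[sys$N + pr$injection_pairs[d, 1]] <- 1
    rhs[sys$N + pr$injection_pairs[d, 2]] <- -1
    expect_equal(sum(rhs), 0)
    sol <- as.numeric(Matrix::solve(sys$S, rhs))
    # current through each electrode: (U_l - u) / z integrated over E_l
    u <- sol[seq_len(sys$N)]
    U <- sol[sys$N + seq_len(sys$L)]
    cur <- vapply(seq_len(sys$L), function(l) {
      en <- m$electrodes[[l]]
      z <- m$contact_impedance[l]
      tot <- 0
      for (s in seq_len(length(en) - 1)) {
        h <- sqrt(sum((m$nodes[en[s], ] - m$nodes[en[s + 1], ])^2))
        tot <- tot + (h / z) * (U[l] - (u[en[s]] + u[en[s + 1]]) / 2)
      }
      tot
    }, numeric(1))
    expect_equal(cur[pr$injection_pairs[d, 1]], 1, tolerance = 1e-8)
    expect_equal(cur[pr$injection_pairs[d, 2]], -1, tolerance = 1e-8)
    expect_lt(max(abs(cur[-pr$injection_pairs[d, ]])), 1e-8)
  }
})

test_that("simulated frames are normalized, seeded and zero without change", {
  m <- coarse_disk()
  pr <- proto16()
  y0 <- simulate_measurement(m, m, pr, noise_fraction = 0, seed = 1)
  expect_equal(as.numeric(y0), rep(0, pr$n_meas))
  m2 <- set_conductivity(m, function(x, y) 1 - 0.5 * (x^2 + y^2 < 0.2))
  y1 <- simulate_measurement(m2, m, pr, noise_fraction = 0.25, seed = 7)
  y2 <- simulate_measurement(m2, m, pr, noise_fraction = 0.25, seed = 7)
  expect_identical(as.numeric(y1), as.numeric(y2))
  y3 <- simulate_measurement(m2, m, pr, noise_fraction = 0.25, seed = 8)
  expect_false(identical(as.numeric(y1), as.numeric(y3)))
})

test_that("injected noise std matches the 25% model over many seeds", {
  m <- coarse_disk()
  pr <- proto16()
  m2 <- set_conductivity(m, function(x, y) 1 - 0.5 * (x^2 + y^2 < 0.2))
  v <- as.numeric(solve_forward(m2, pr))
  v0 <- as.numeric(solve_forward(m, pr))
  y_clean <- (v - v0) / v0
  target_sd <- 0.25 * sd(v - v0)
  noise_raw <- vapply(seq_len(10000), function(s) {
    y <- as.numeric(add_measurement_noise(v, v0, 0.25, s))
    (y - y_clean)[37] * v0[37]      # recover the raw-voltage noise sample
  }, numeric(1))
  expect_equal(sd(noise_raw), target_sd, tolerance = 0.02)
})

test_that("voltage frames round-trip through the CSV interface", {
  fr <- matrix(rnorm(2 * 208), 2)
  f <- withr::local_tempfile(fileext = ".csv")
  write_voltage_frames(fr, f, proto16(), seed = 3)
  expect_equal(unname(read_voltage_frames(f)), unname(fr), tolerance = 1e-12)
  expect_match(readLines(f, n = 1), "adjacent16")
})
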