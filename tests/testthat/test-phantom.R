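test_that("baseline scene satisfies its geometric invariants", {
  sc <- small_scene()
  pc <- eitdct:::pixel_centres(sc$extent, sc$M, sc$N)
  xs <- rep(pc$x, each = sc$M)
  ys <- rep(pc$y, times = sc$N)
  inside <- eitdct:::in_polygon(xs, ys, sc$thorax_polygon)
  # every lung pixel lies inside the thorax polygon
  expect_true(all(inside[as.vector(sc$lung_mask)]))
  # lung area fraction of the thorax within the stated band
  frac <- sum(sc$lung_mask) / sum(inside)
  expect_gt(frac, 0.30)
  expect_lt(frac, 0.50)
  # baseline ground truth is the zero image
  expect_equal(max(abs(sc$ground_truth$values)), 0)
  # baseline conductivity: 0.5 in lung, 1 elsewhere
  expect_equal(sort(unique(sc$sigma_baseline_fun(xs, ys))), c(0.5, 1))
  # CT surrogate: -700 HU in ventilated lung, soft tissue elsewhere
  expect_true(all(sc$ct_surrogate$values[sc$lung_mask] == -700))
  expect_true(all(sc$ct_surrogate$values[!sc$lung_mask] >= 20 &
                  sc$ct_surrogate$values[!sc$lung_mask] <= 60))
  # deterministic per seed
  sc2 <- make_thorax_scene(64, 64, 1)
  expect_identical(sc2$thorax_polygon, sc$thorax_polygon)
  expect_identical(sc2$lung_mask, sc$lung_mask)
  sc3 <- make_thorax_scene(64, 64, 2)
  expect_false(identical(sc3$thorax_polygon, sc$thorax_polygon))
  expect_error(make_thorax_scene(32, 32), "64")
})

test_that("detail prior recovers the stated Hounsfield anchors", {
  sc <- small_scene()
  pr <- make_detail_prior(sc$ct_surrogate, sc$lung_mask)
  expect_equal(unique(pr$weights[sc$lung_mask]), 0.7)
  expect_true(all(pr$weights[!sc$lung_mask] == 0))
})

test_that("pattern conductivities match their definitions", {
  sc <- small_scene()
  pc <- eitdct:::pixel_centres(sc$extent, sc$M, sc$N)
  xs <- rep(pc$x, each = sc$M)
  ys <- rep(pc$y, times = sc$N)
  inl <- as.vector(sc$lung_mask)

  a <- apply_pattern(sc, "a")
  expect_true(all(a$sigma_target_fun(xs[inl], ys[inl]) == 0.25))
  expect_equal(unique(a$ground_truth$values[sc$lung_mask]), -0.25)

  b <- apply_pattern(sc, "b")
  sb <- b$sigma_target_fun(xs[inl], ys[inl])
  # sigma = 1 at the most ventral lung pixel, decreasing dorsally
  expect_equal(max(sb[ys[inl] == max(ys[inl])]), 1, tolerance = 0.02)
  expect_lt(mean(sb[ys[inl] < quantile(ys[inl], 0.1)]),
            mean(sb[ys[inl] > quantile(ys[inl], 0.9)]))

  cc <- apply_pattern(sc, "c")
  scc <- cc$sigma_target_fun(xs, ys)
  l <- sc$lungs$left
  expect_equal(scc[which.min((xs - l$cx)^2 + (ys - l$cy)^2)], 1,
               tolerance = 0.05)

  d <- apply_pattern(sc, "d")
  sd_ <- d$sigma_target_fun(xs[inl], ys[inl])
  expect_setequal(round(sort(unique(sd_)), 3), c(0.001, 0.5, 1))

  e <- apply_pattern(sc, "e")
  se <- e$sigma_target_fun(xs[inl], ys[inl])
  expect_setequal(round(sort(unique(se)), 3), c(0.001, 1))
  # chessboard: neighbouring cells along x differ (probe within the left lung)
  bb <- eitdct:::lung_bbox(sc)
  w <- (bb$xmax - bb$xmin) / 8
  l <- sc$lungs$left
  x0 <- bb$xmin + w * (floor((l$cx - 0.5 * l$ax - bb$xmin) / w) + 0.5)
  probe_x <- x0 + w * 0:2
  expect_true(all(sc$in_lung_fun(probe_x, rep(l$cy, 3))))
  probe <- e$sigma_target_fun(probe_x, rep(l$cy, 3))
  expect_true(all(abs(diff(probe)) > 0.9))

  expect_error(apply_pattern(sc, "z"), "unknown pattern")
  expect_error(apply_pattern(a, "a"), "baseline")
})

test_that("atelectasis slabs hold the requested dorsal area fraction", {
  sc <- small_scene()
  for (fr in c(0.25, 0.5)) {
    at <- apply_atelectasis(sc, fr)
    atel <- eitdct:::eval_on_grid(function(x, y) at$atelectatic_fun(x, y),
                                  sc$extent, sc$M, sc$N) > 0
    for (i in 1:2) {
      lung_i <- sc$lung_label == i
      got <- sum(atel & lung_i) / sum(lung_i)
      # the dorsal cut is chosen on pixel-row boundaries: the achievable
      # granularity is one row of that lung
      row_gran <- max(rowSums(lung_i)) / sum(lung_i)
      expect_lt(abs(got - fr), row_gran + 1e-9)
      # atelectatic region is the dorsal-most part
      if (any(atel & lung_i)) {
        ys <- eitdct:::pixel_centres(sc$extent, sc$M, sc$N)$y
        ygrid <- matrix(rep(ys, times = sc$N), sc$M, sc$N)
        expect_lt(max(ygrid[atel & lung_i]), min(ygrid[lung_i & !atel]) + 1e-9)
      }
    }
    # ground truth zero inside the atelectatic slab, negative elsewhere
    expect_true(all(at$ground_truth$values[atel] == 0))
    expect_true(all(at$ground_truth$values[sc$lung_mask & !atel] < 0))
    # CT surrogate: 0 HU in the slab, -700 in ventilated lung
    expect_true(all(at$ct_surrogate$values[atel] == 0))
    expect_true(all(at$ct_surrogate$values[sc$lung_mask & !atel] == -700))
  }
  # fraction 0 reproduces pattern (a) conductivity with the same sigma
  a <- apply_pattern(sc, "a")
  at0 <- apply_atelectasis(sc, 0, ventilation_sigma = 0.25)
  pc <- eitdct:::pixel_centres(sc$extent, sc$M, sc$N)
  xs <- rep(pc$x, each = sc$M); ys <- rep(pc$y, times = sc$N)
  expect_equal(at0$sigma_target_fun(xs, ys), a$sigma_target_fun(xs, ys))
  # non-atelectatic changed area ~ atelectatic area at fraction 0.5
  at5 <- apply_atelectasis(sc, 0.5)
  atel <- eitdct:::eval_on_grid(function(x, y) at5$atelectatic_fun(x, y),
                                sc$extent, sc$M, sc$N) > 0
  expect_equal(sum(atel), sum(sc$lung_mask & !atel),
               tolerance = 2 * sc$N / sum(sc$lung_mask))
  expect_error(apply_atelectasis(sc, 0.6), "fraction")
})

test_that("element conductivities and the ground-truth raster agree", {
  # at the data-generating (forward mesh) resolution, painting the element
  # conductivities back onto the default raster reproduces the ground truth
  # up to boundary-pixel rasterization error
  sc <- make_thorax_scene(128, 128, 1)
  mesh <- build_mesh(sc$thorax_polygon, 16, 20000)
  for (st in list(apply_pattern(sc, "a"), apply_pattern(sc, "e"),
                  apply_atelectasis(sc, 0.25))) {
    change <- st$sigma_target_fun(mesh$centroids[, 1], mesh$centroids[, 2]) -
      sc$sigma_baseline_fun(mesh$centroids[, 1], mesh$centroids[, 2])
    painted <- paint_elements(change, mesh, sc$extent, sc$M, sc$N)
    pn <- normalize_image(painted)
    gn <- normalize_image(st$ground_truth)
    frac_diff <- mean(abs(pn$values - gn$values) > 0.25)
    expect_lt(frac_diff, 0.02)
  }
})

test_that("scene archive and PGM export write readable files", {
  sc <- small_scene()
  f <- withr::local_tempfile(fileext = ".txt")
  write_scene_archive(apply_pattern(sc, "a"), f)
  a <- eitdct:::read_archive(f)
  expect_equal(dim(a$lung_mask), c(64, 64))
  expect_equal(a$ground_truth[sc$lung_mask][1], -0.25)
  g <- withr::local_tempfile(fileext = ".pgm")
  export_pgm(sc$ct_surrogate, g)
  expect_equal(readLines(g, n = 1), "P2")
})
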