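test_that("cosine basis has the DCT-II normalization and orthonormality", {
  b <- build_dct_basis(16, 12, 16, 12)
  # constant member
  expect_equal(dct_member(b, 0, 0),
               matrix(1 / sqrt(16 * 12), 16, 12), tolerance = 1e-12)
  # full-order stack is orthonormal under the pixelwise inner product
  G <- crossprod(b$stack)
  expect_lt(max(abs(G - diag(ncol(G)))), 1e-10)
})

test_that("full-order analysis/synthesis round-trips an arbitrary raster", {
  set.seed(11)
  A <- matrix(rnorm(32 * 32), 32, 32)
  b <- build_dct_basis(32, 32, 32, 32)
  coef <- as.numeric(crossprod(b$stack, as.vector(A)))
  back <- matrix(b$stack %*% coef, 32, 32)
  expect_lt(max(abs(back - A)), 1e-10)
})

test_that("truncated coefficients match the direct transform", {
  set.seed(12)
  A <- matrix(rnorm(10 * 8), 10, 8)
  b <- build_dct_basis(10, 8, 4, 3)
  coef <- as.numeric(crossprod(b$stack, as.vector(A)))
  V <- oracle_dct2(A, 4, 3)
  im <- dct_index_map(4, 3)
  expect_equal(coef, V[cbind(im$p + 1, im$q + 1)], tolerance = 1e-12)
})

test_that("index rule j(p, q) = q * n_x + p + 1 holds", {
  im <- dct_index_map(15, 15)
  expect_equal(im$j[im$p == 2 & im$q == 0], 3L)
  expect_equal(im$j[im$p == 0 & im$q == 1], 16L)
  expect_equal(nrow(im), 225L)
  # dct_member agrees with the stacked column order
  b <- build_dct_basis(8, 8, 4, 4)
  expect_equal(as.vector(dct_member(b, 2, 0)), b$stack[, 3])
})

test_that("prior masking confines and is idempotent for binary priors", {
  sc <- small_scene()
  b <- build_dct_basis(64, 64, 6, 6)
  cp <- make_contour_prior(sc$lung_mask, sc$extent)
  mb <- mask_basis(b, cp)
  out <- !as.vector(sc$lung_mask)
  expect_true(all(mb$stack[out, ] == 0))
  mb2 <- mask_basis(mb, cp)
  expect_equal(mb2$stack, mb$stack)
  # all-ones prior leaves the basis unchanged
  ones <- make_contour_prior(matrix(1, 64, 64), sc$extent)
  expect_equal(mask_basis(b, ones)$stack, b$stack)
  # any coefficient combination restores to zero outside the mask
  set.seed(4)
  H <- restore_image(rnorm(36), mb, sc$extent)
  expect_true(all(H$values[!sc$lung_mask] == 0))
  # contour and detail masks differ only inside the lung
  dp <- make_detail_prior(sc$ct_surrogate, sc$lung_mask)
  md <- mask_basis(b, dp)
  expect_true(all(md$stack[out, ] == mb$stack[out, ]))
})

test_that("contour and detail priors obey their value contracts", {
  sc <- small_scene()
  cp <- make_contour_prior(sc$lung_mask, sc$extent)
  expect_setequal(unique(as.vector(cp$weights)), c(0, 1))
  expect_error(make_contour_prior(matrix(0, 8, 8)), "empty")
  hu <- matrix(c(-1000, 0, -700, -1500, 500, -200), 2, 3)
  mask <- matrix(TRUE, 2, 3)
  dp <- make_detail_prior(hu, mask)
  expect_equal(as.vector(dp$weights), c(1, 0, 0.7, 1, 0, 0.2))
  expect_error(make_detail_prior(hu, matrix(TRUE, 3, 2)), "shape")
})

test_that("element projection K follows the index rule and keeps rank", {
  sc <- small_scene()
  mesh <- build_mesh(sc$thorax_polygon, 16, 1200)
  b <- build_dct_basis(64, 64, 6, 6)
  cp <- make_contour_prior(sc$lung_mask, sc$extent)
  sb <- build_K(mask_basis(b, cp), mesh, sc$extent)
  expect_equal(dim(sb$K), c(nrow(mesh$elements), 36L))
  expect_equal(qr(sb$K)$rank, 36L)
  # K column 3 is the element projection of C(2, 0)
  map <- pixel_element_map(mesh, 64, 64, sc$extent)
  manual <- as.numeric(map$agg %*% sb$basis$stack[, 3])
  expect_equal(sb$K[, 3], manual, tolerance = 1e-12)
  # constant member: elements fully inside the lung get 1/sqrt(M*N)
  K1 <- sb$K[, 1]
  deep <- which(vapply(seq_len(nrow(mesh$elements)), function(e) {
    cx <- mesh$centroids[e, 1]; cy <- mesh$centroids[e, 2]
    l <- sc$lungs$left
    ((cx - l$cx) / (l$ax * 0.7))^2 + ((cy - l$cy) / (l$ay * 0.7))^2 < 1 &&
      cy > sc$dorsal_cut + 0.1
  }, logical(1)))
  expect_equal(unique(round(K1[deep], 10)), round(1 / sqrt(64 * 64), 10))
  # elements fully outside the lung project to zero
  far <- which(mesh$centroids[, 1]^2 + mesh$centroids[, 2]^2 < 0.02)
  expect_true(all(K1[far] == 0))
})

test_that("Jacobian reduction is plain matrix algebra", {
  set.seed(5)
  J <- matrix(rnorm(208 * 50), 208, 50)
  K <- matrix(rnorm(50 * 9), 50, 9)
  JD <- reduce_jacobian(J, K)
  expect_equal(dim(JD), c(208L, 9L))
  for (j in c(1, 5, 9)) expect_equal(JD[, j], as.numeric(J %*% K[, j]))
  ones <- matrix(1, 50, 1)
  expect_equal(as.numeric(reduce_jacobian(J, ones)), rowSums(J))
  expect_error(reduce_jacobian(J, matrix(1, 49, 2)), "mismatch")
})
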