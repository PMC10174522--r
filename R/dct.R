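# Truncated 2D DCT-II basis, prior masking, and the projection onto FEM
# elements that yields the reduced Jacobian.

#' Build a truncated orthonormal 2D cosine basis
#'
#' Basis member D(p, q), p = 0..n_x-1 (row frequencies), q = 0..n_y-1
#' (column frequencies), with DCT-II orthonormal scaling: alpha_0 =
#' sqrt(1/M), alpha_p = sqrt(2/M) otherwise. Columns of the stacked matrix
#' are ordered by j(p, q) = q * n_x + p + 1 (p varying fastest), matching
#' the coefficient indexing used throughout.
#'
#' @param M,N raster rows / columns
#' @param n_x,n_y retained frequencies per axis (default 15 x 15 = 225)
#' @return a `dct_basis` holding the (M*N) x (n_x*n_y) stack matrix
#' @export
build_dct_basis <- function(M, N, n_x = 15L, n_y = 15L) {
  if (n_x < 1 || n_y < 1 || n_x > M || n_y > N) {
    stop("DCT orders must satisfy 1 <= n_x <= M, 1 <= n_y <= N")
  }
  m <- 0:(M - 1); n <- 0:(N - 1)
  Cm <- vapply(0:(n_x - 1), function(p) {
    a <- if (p == 0) sqrt(1 / M) else sqrt(2 / M)
    a * cos((2 * m + 1) * p * pi / (2 * M))
  }, numeric(M))
  Cn <- vapply(0:(n_y - 1), function(q) {
    a <- if (q == 0) sqrt(1 / N) else sqrt(2 / N)
    a * cos((2 * n + 1) * q * pi / (2 * N))
  }, numeric(N))
  # kronecker(Cn, Cm): column j = q*n_x + p + 1 is vec(Cm[,p] o Cn[,q])
  stack <- kronecker(Cn, Cm)
  structure(list(M = as.integer(M), N = as.integer(N),
                 n_x = as.integer(n_x), n_y = as.integer(n_y),
                 stack = stack,
                 index_map = dct_index_map(n_x, n_y)),
            class = "dct_basis")
}

#' Coefficient index rule j(p, q) = q * n_x + p + 1
#' @param n_x,n_y retained frequencies per axis
#' @return tibble with columns j, p, q
#' @export
dct_index_map <- function(n_x = 15L, n_y = 15L) {
  j <- seq_len(n_x * n_y)
  tibble::tibble(j = j, p = (j - 1L) %% n_x, q = (j - 1L) %/% n_x)
}

#' @export
print.dct_basis <- function(x, ...) {
  cat(sprintf("<dct_basis> %d x %d raster, %d x %d frequencies (%d members)%s\n",
              x$M, x$N, x$n_x, x$n_y, x$n_x * x$n_y,
              if (!is.null(x$prior_kind)) paste0(", masked by ", x$prior_kind, " prior") else ""))
  invisible(x)
}

#' Extract one basis member as an M x N matrix
#' @param basis a `dct_basis` (masked or not)
#' @param p,q frequency indices (0-based)
#' @export
dct_member <- function(basis, p, q) {
  j <- q * basis$n_x + p + 1
  matrix(basis$stack[, j], basis$M, basis$N)
}

#' Mask a cosine basis with a structural prior
#'
#' Multiplies every basis member pixelwise by the prior weights, producing
#' the stack C(p, q) whose span is confined to the prior support.
#'
#' @param basis a `dct_basis`
#' @param prior a `structural_prior` on the same raster
#' @return a masked `dct_basis` (field `prior_weights` set)
#' @export
mask_basis <- function(basis, prior) {
  w <- prior$weights
  if (nrow(w) != basis$M || ncol(w) != basis$N) {
    stop("shape error: prior raster does not match basis raster")
  }
  basis$stack <- basis$stack * as.vector(w)
  basis$prior_weights <- w
  basis$prior_kind <- prior$kind
  basis
}

# ---- pixel-to-element map ---------------------------------------------

# cache keyed by mesh geometry + raster registration
.map_cache <- new.env(parent = emptyenv())

#' Map raster pixels to covering FEM elements
#'
#' Assigns each pixel centre to the mesh element containing it (0 when the
#' centre lies outside the mesh). The companion aggregation operator takes
#' the mean of covered pixel values per element; elements covering no pixel
#' centre fall back to the nearest pixel centre.
#'
#' @param mesh an `eit_mesh`
#' @param M,N raster size
#' @param extent raster extent registered to mesh coordinates
#' @return list with `pix2el` (integer vector, length M*N, column-major) and
#'   `agg` (sparse n_elems x (M*N) averaging matrix)
#' @export
pixel_element_map <- function(mesh, M, N, extent) {
  key <- rlang::hash(list(mesh$nodes, mesh$elements, M, N, extent))
  hit <- .map_cache[[key]]
  if (!is.null(hit)) return(hit)
  pc <- pixel_centres(extent, M, N)
  if (max(pc$x) < min(mesh$nodes[, 1]) || min(pc$x) > max(mesh$nodes[, 1]) ||
      max(pc$y) < min(mesh$nodes[, 2]) || min(pc$y) > max(mesh$nodes[, 2])) {
    stop("registration error: raster extent and mesh are disjoint")
  }
  dx <- (extent$xmax - extent$xmin) / N
  dy <- (extent$ymax - extent$ymin) / M
  pix2el <- integer(M * N)
  el <- mesh$elements; nd <- mesh$nodes
  for (e in seq_len(nrow(el))) {
    px <- nd[el[e, ], 1]; py <- nd[el[e, ], 2]
    cs <- which(pc$x >= min(px) - dx & pc$x <= max(px) + dx)
    rs <- which(pc$y >= min(py) - dy & pc$y <= max(py) + dy)
    if (!length(cs) || !length(rs)) next
    xs <- rep(pc$x[cs], each = length(rs))
    ys <- rep(pc$y[rs], times = length(cs))
    d1 <- (px[2] - px[1]) * (ys - py[1]) - (py[2] - py[1]) * (xs - px[1])
    d2 <- (px[3] - px[2]) * (ys - py[2]) - (py[3] - py[2]) * (xs - px[2])
    d3 <- (px[1] - px[3]) * (ys - py[3]) - (py[1] - py[3]) * (xs - px[3])
    tol <- -1e-12
    inside <- d1 >= tol & d2 >= tol & d3 >= tol
    if (any(inside)) {
      rows <- rep(rs, times = length(cs))[inside]
      cols <- rep(cs, each = length(rs))[inside]
      pix2el[(cols - 1L) * M + rows] <- e
    }
  }
  # aggregation: mean of covered pixels; empty elements -> nearest pixel
  covered <- pix2el > 0L
  ii <- pix2el[covered]
  jj <- which(covered)
  cnt <- tabulate(ii, nbins = nrow(el))
  vals <- 1 / cnt[ii]
  empty <- which(cnt == 0)
  if (length(empty)) {
    for (e in empty) {
      cx <- mesh$centroids[e, 1]; cy <- mesh$centroids[e, 2]
      col <- pmin(pmax(round((cx - extent$xmin) / dx + 0.5), 1), N)
      row <- pmin(pmax(round((extent$ymax - cy) / dy + 0.5), 1), M)
      ii <- c(ii, e); jj <- c(jj, (col - 1L) * M + row); vals <- c(vals, 1)
    }
  }
  agg <- Matrix::sparseMatrix(i = ii, j = jj, x = vals,
                              dims = c(nrow(el), M * N))
  out <- list(pix2el = pix2el, agg = agg, n_empty = length(empty))
  .map_cache[[key]] <- out
  out
}

#' Project a masked basis onto FEM elements
#'
#' Builds K, whose column j is the element-space projection of the masked
#' basis member C(p, q) (mean of the pixel values covered by each element).
#'
#' @param basis a masked `dct_basis`
#' @param inverse_mesh the reconstruction mesh
#' @param extent raster extent registered to mesh coordinates
#' @return a `subset_basis` holding the basis, K, and the index map
#' @export
build_K <- function(basis, inverse_mesh, extent) {
  map <- pixel_element_map(inverse_mesh, basis$M, basis$N, extent)
  K <- as.matrix(map$agg %*% basis$stack)
  structure(list(basis = basis, K = K, index_map = basis$index_map,
                 extent = extent, J_DCT = NULL),
            class = "subset_basis")
}

#' Reduce a Jacobian with the element-space basis projection
#'
#' J_DCT = J %*% K: the reduced Jacobian maps changes of the masked-cosine
#' coefficients to boundary-voltage changes.
#'
#' @param J Jacobian matrix (n_meas x n_elems)
#' @param subset a `subset_basis` from [build_K()] (or a bare K matrix)
#' @return the `subset_basis` with `J_DCT` filled in (or the product matrix
#'   when a bare matrix was supplied)
#' @export
reduce_jacobian <- function(J, subset) {
  K <- if (inherits(subset, "subset_basis")) subset$K else subset
  if (ncol(J) != nrow(K)) stop("dimension mismatch: ncol(J) != nrow(K)")
  JD <- J %*% K
  if (inherits(subset, "subset_basis")) {
    subset$J_DCT <- JD
    subset
  } else {
    JD
  }
}

#' @export
print.subset_basis <- function(x, ...) {
  cat(sprintf("<subset_basis> K: %d x %d%s\n", nrow(x$K), ncol(x$K),
              if (!is.null(x$J_DCT)) sprintf(", J_DCT: %d x %d",
                                             nrow(x$J_DCT), ncol(x$J_DCT)) else ""))
  invisible(x)
}
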