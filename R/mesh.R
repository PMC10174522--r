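#' @importFrom Matrix sparseMatrix Diagonal t crossprod solve
#' @importFrom stats rnorm sd median quantile approx
NULL

# ---- polygon helpers ---------------------------------------------------

#' Signed area of a closed polygon (positive = counter-clockwise)
#' @param p two-column matrix of vertices (not repeated at the end)
#' @keywords internal
polygon_area_signed <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

polygon_centroid <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  c(sum((x + xn) * cr), sum((y + yn) * cr)) / (6 * a)
}

# brute-force simplicity check: no two non-adjacent edges intersect
polygon_is_simple <- function(p, tol = 1e-12) {
  n <- nrow(p)
  a1 <- p; a2 <- p[c(2:n, 1), ]
  seg_int <- function(p1, p2, q1, q2) {
    d1 <- p2 - p1; d2 <- q2 - q1
    den <- d1[1] * d2[2] - d1[2] * d2[1]
    if (abs(den) < tol) return(FALSE)
    s <- ((q1[1] - p1[1]) * d2[2] - (q1[2] - p1[2]) * d2[1]) / den
    t <- ((q1[1] - p1[1]) * d1[2] - (q1[2] - p1[2]) * d1[1]) / den
    s > tol && s < 1 - tol && t > tol && t < 1 - tol
  }
  for (i in seq_len(n - 2)) {
    jmax <- if (i == 1) n - 1 else n
    for (j in (i + 2):jmax) {
      if (seg_int(a1[i, ], a2[i, ], a1[j, ], a2[j, ])) return(FALSE)
    }
  }
  TRUE
}

# star-shapedness about the centroid: vertex angles strictly increase (CCW)
polygon_is_star <- function(p, ctr) {
  ang <- atan2(p[, 2] - ctr[2], p[, 1] - ctr[1])
  d <- diff(c(ang, ang[1] + 2 * pi))
  d <- (d + 2 * pi) %% (2 * pi)
  all(d > 1e-9) && abs(sum(d) - 2 * pi) < 1e-6
}

# exact radius of the polygon boundary along direction theta from ctr
polygon_radius <- function(theta, poly, ctr) {
  rel <- sweep(poly, 2, ctr)
  ang <- atan2(rel[, 2], rel[, 1])
  o <- order(ang)
  rel <- rel[o, , drop = FALSE]
  ang <- ang[o]
  th <- ((theta + pi) %% (2 * pi)) - pi
  i <- findInterval(th, ang)
  i[i == 0] <- length(ang)          # wraps to the last->first segment
  j <- i %% length(ang) + 1
  p1 <- rel[i, , drop = FALSE]
  e <- rel[j, , drop = FALSE] - p1
  dx <- cos(th); dy <- sin(th)
  den <- dx * e[, 2] - dy * e[, 1]
  t <- (p1[, 1] * e[, 2] - p1[, 2] * e[, 1]) / den
  t
}

# cumulative arc length and interpolation of boundary points
polygon_arclen <- function(poly) {
  n <- nrow(poly)
  nxt <- poly[c(2:n, 1), , drop = FALSE]
  seg <- sqrt(rowSums((nxt - poly)^2))
  list(cum = c(0, cumsum(seg)), total = sum(seg))
}

polygon_point_at <- function(s, poly, arc) {
  n <- nrow(poly)
  s <- s %% arc$total
  i <- findInterval(s, arc$cum, rightmost.closed = TRUE)
  i[i > n] <- n
  j <- i %% n + 1
  f <- (s - arc$cum[i]) / (arc$cum[i + 1] - arc$cum[i])
  poly[i, , drop = FALSE] * (1 - f) + poly[j, , drop = FALSE] * f
}

# ---- mesh construction -------------------------------------------------

#' Build a 2D triangular FEM mesh of a star-shaped domain with electrodes
#'
#' Triangulates the interior of a simple, star-shaped closed polygon with a
#' structured polar mesh (concentric rings stitched together) and places
#' `n_elec` electrodes equidistantly by boundary arc length, the first
#' centred on the ventral (+y) boundary point. Electrodes are groups of
#' consecutive boundary nodes used by the complete electrode model.
#'
#' @param boundary_polygon two-column matrix of vertices of a simple closed
#'   polygon (last vertex not repeated); must be star-shaped about its
#'   centroid
#' @param n_elec number of electrodes (>= 4)
#' @param target_element_count requested number of triangles (>= 500 for the
#'   default phantom work; smaller values are accepted for coarse tests)
#' @param electrode_coverage fraction of the inter-electrode arc covered by
#'   each electrode
#' @param contact_impedance scalar or per-electrode contact impedance of the
#'   complete electrode model (arbitrary units x length)
#' @return an object of class `eit_mesh`: nodes, elements (node-index
#'   triples, counter-clockwise), per-element conductivity (initialised to
#'   1), electrode node groups, element areas and centroids
#' @export
build_mesh <- function(boundary_polygon, n_elec = 16L,
                       target_element_count = 3000L,
                       electrode_coverage = 0.45,
                       contact_impedance = 1e-2) {
  poly <- as.matrix(boundary_polygon)
  if (ncol(poly) != 2 || nrow(poly) < 3) stop("boundary_polygon must be an n x 2 matrix with n >= 3")
  if (all(poly[1, ] == poly[nrow(poly), ])) poly <- poly[-nrow(poly), , drop = FALSE]
  if (n_elec < 4) stop("n_elec must be >= 4")
  if (!polygon_is_simple(poly)) stop("geometry error: boundary polygon is self-intersecting")
  if (polygon_area_signed(poly) < 0) poly <- poly[nrow(poly):1, , drop = FALSE]
  ctr <- polygon_centroid(poly)
  if (!polygon_is_star(poly, ctr)) {
    stop("mesh error: polygon is not star-shaped about its centroid; the polar mesher requires a star-shaped domain")
  }

  # ring layout: ~equilateral triangles need boundary node spacing ~ ring spacing
  K <- max(3L, as.integer(ceiling(sqrt(target_element_count / (2 * pi)))))
  n_b <- max(2L * n_elec, as.integer(n_elec * round(target_element_count / K / n_elec)))

  # boundary nodes: equidistant in arc length, anchored at the ventral point
  arc <- polygon_arclen(poly)
  r_up <- polygon_radius(pi / 2, poly, ctr)
  p_up <- ctr + r_up * c(0, 1)
  # arc position of the ventral point
  d2 <- function(a, b) sqrt(sum((a - b)^2))
  n <- nrow(poly)
  segd <- vapply(seq_len(n), function(i) {
    j <- i %% n + 1
    v <- poly[j, ] - poly[i, ]; w <- p_up - poly[i, ]
    t <- sum(v * w) / sum(v * v)
    if (t < -1e-9 || t > 1 + 1e-9) return(Inf)
    d2(poly[i, ] + pmin(pmax(t, 0), 1) * v, p_up)
  }, numeric(1))
  i0 <- which.min(segd)
  j0 <- i0 %% n + 1
  v <- poly[j0, ] - poly[i0, ]
  t0 <- sum(v * (p_up - poly[i0, ])) / sum(v * v)
  s0 <- arc$cum[i0] + pmin(pmax(t0, 0), 1) * (arc$cum[i0 + 1] - arc$cum[i0])

  s_b <- s0 + arc$total * (seq_len(n_b) - 1) / n_b
  bpts <- polygon_point_at(s_b, poly, arc)
  bang <- atan2(bpts[, 2] - ctr[2], bpts[, 1] - ctr[1])

  # nodes: center (1), interior rings, boundary ring
  nodes <- matrix(ctr, nrow = 1)
  ring_idx <- vector("list", K + 1)
  ring_ang <- vector("list", K + 1)
  ring_idx[[1]] <- 1L
  ring_ang[[1]] <- 0
  for (k in seq_len(K - 1)) {
    nk <- max(6L, as.integer(round(n_b * k / K)))
    th <- 2 * pi * (seq_len(nk) - 1) / nk + (k %% 2) * pi / nk + pi / 2
    th <- ((th + pi) %% (2 * pi)) - pi
    rk <- polygon_radius(th, poly, ctr)
    pts <- cbind(ctr[1] + (k / K) * rk * cos(th), ctr[2] + (k / K) * rk * sin(th))
    idx <- nrow(nodes) + seq_len(nk)
    nodes <- rbind(nodes, pts)
    ring_idx[[k + 1]] <- as.integer(idx)
    ring_ang[[k + 1]] <- th
  }
  bidx <- nrow(nodes) + seq_len(n_b)
  nodes <- rbind(nodes, bpts)
  ring_idx[[K + 1]] <- as.integer(bidx)
  ring_ang[[K + 1]] <- bang

  # triangulate: center fan + stitched annuli
  tris <- list()
  r1 <- ring_idx[[2]]; n1 <- length(r1)
  tris[[1]] <- cbind(1L, r1, r1[c(2:n1, 1)])
  for (k in 2:K) {
    tris[[k]] <- stitch_rings(ring_idx[[k]], ring_ang[[k]],
                              ring_idx[[k + 1]], ring_ang[[k + 1]])
  }
  elements <- do.call(rbind, tris)
  dimnames(elements) <- NULL

  # enforce positive orientation
  a <- tri_signed_areas(nodes, elements)
  flip <- which(a < 0)
  if (length(flip)) {
    tmp <- elements[flip, 2]
    elements[flip, 2] <- elements[flip, 3]
    elements[flip, 3] <- tmp
    a <- abs(a)
  }
  if (any(a <= 0)) stop("mesh error: degenerate (zero-area) triangle produced")

  # electrodes: groups of consecutive boundary nodes around each centre
  n_per <- n_b / n_elec
  hw <- max(1L, as.integer(floor(electrode_coverage * n_per / 2)))
  electrodes <- lapply(seq_len(n_elec), function(l) {
    c0 <- (l - 1) * n_per + 1
    off <- (c0 - hw - 1):(c0 + hw - 1) %% n_b + 1
    as.integer(bidx[off])
  })

  zc <- rep_len(contact_impedance, n_elec)
  centroids <- (nodes[elements[, 1], , drop = FALSE] +
                nodes[elements[, 2], , drop = FALSE] +
                nodes[elements[, 3], , drop = FALSE]) / 3

  m <- structure(list(
    nodes = nodes,
    elements = elements,
    element_conductivity = rep(1, nrow(elements)),
    electrodes = electrodes,
    contact_impedance = zc,
    boundary = as.integer(bidx),
    areas = a,
    centroids = centroids,
    polygon = poly,
    centre = ctr,
    n_elec = as.integer(n_elec)
  ), class = "eit_mesh")

  n_el <- nrow(elements)
  if (target_element_count >= 500 &&
      (n_el < 0.7 * target_element_count || n_el > 1.3 * target_element_count)) {
    stop(sprintf("mesh error: produced %d elements, outside 30%% of target %d",
                 n_el, target_element_count))
  }
  m
}

# stitch two concentric node rings into a triangle strip (angle merge)
stitch_rings <- function(inner_idx, inner_ang, outer_idx, outer_ang) {
  m <- length(inner_idx); n <- length(outer_idx)
  base <- inner_ang[which.min(inner_ang)]
  unwrap <- function(a) base + ((a - base) %% (2 * pi))
  ai <- unwrap(inner_ang); ao <- unwrap(outer_ang)
  oi <- order(ai); I <- inner_idx[oi]; A <- ai[oi]
  oo <- order(ao); O <- outer_idx[oo]; B <- ao[oo]
  Aext <- c(A, A[1] + 2 * pi)
  Bext <- c(B, B[1] + 2 * pi)
  wi <- function(k) (k - 1L) %% m + 1L
  wj <- function(k) (k - 1L) %% n + 1L
  ci <- 1L; cj <- 1L
  tris <- matrix(0L, m + n, 3)
  for (s in seq_len(m + n)) {
    adv_outer <- if (cj > n) FALSE else if (ci > m) TRUE else Bext[cj + 1L] <= Aext[ci + 1L]
    if (adv_outer) {
      tris[s, ] <- c(I[wi(ci)], O[wj(cj)], O[wj(cj + 1L)])
      cj <- cj + 1L
    } else {
      tris[s, ] <- c(I[wi(ci)], O[wj(cj)], I[wi(ci + 1L)])
      ci <- ci + 1L
    }
  }
  tris
}

tri_signed_areas <- function(nodes, elements) {
  x1 <- nodes[elements[, 1], 1]; y1 <- nodes[elements[, 1], 2]
  x2 <- nodes[elements[, 2], 1]; y2 <- nodes[elements[, 2], 2]
  x3 <- nodes[elements[, 3], 1]; y3 <- nodes[elements[, 3], 2]
  ((x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1)) / 2
}

#' @export
print.eit_mesh <- function(x, ...) {
  cat(sprintf("<eit_mesh> %d nodes, %d elements, %d electrodes\n",
              nrow(x$nodes), nrow(x$elements), x$n_elec))
  invisible(x)
}

#' Replace per-element conductivity
#' @param mesh an `eit_mesh`
#' @param sigma per-element conductivity vector (strictly positive) or a
#'   vectorised function of (x, y) evaluated at element centroids
#' @return the mesh with updated conductivity
#' @export
set_conductivity <- function(mesh, sigma) {
  if (is.function(sigma)) sigma <- sigma(mesh$centroids[, 1], mesh$centroids[, 2])
  sigma <- rep_len(sigma, nrow(mesh$elements))
  if (any(!is.finite(sigma)) || any(sigma <= 0)) {
    stop("element conductivity must be finite and strictly positive")
  }
  mesh$element_conductivity <- sigma
  mesh
}

#' Export a mesh as OFF-style plain text
#' @param mesh an `eit_mesh`
#' @param file output path
#' @export
export_mesh_off <- function(mesh, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines("OFF", con)
  writeLines(sprintf("%d %d 0", nrow(mesh$nodes), nrow(mesh$elements)), con)
  writeLines(sprintf("%.10g %.10g 0", mesh$nodes[, 1], mesh$nodes[, 2]), con)
  writeLines(sprintf("3 %d %d %d", mesh$elements[, 1] - 1L,
                     mesh$elements[, 2] - 1L, mesh$elements[, 3] - 1L), con)
  invisible(file)
}
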