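# Synthetic thorax phantom: geometry, CT-like surrogate raster in Hounsfield
# units, the five lung conductivity patterns, and the graded dorsal
# atelectasis series. Orientation convention: ventral = +y; raster row 1 is
# the most ventral row.

#' Construct a pixel image registered to physical coordinates
#' @param values M x N numeric matrix (row 1 = most ventral)
#' @param extent named vector/list with xmin, xmax, ymin, ymax
#' @param semantics one of "hounsfield", "conductivity", "prior_weight",
#'   "eit_image"
#' @return a `pixel_image`
#' @export
pixel_image <- function(values, extent, semantics = "eit_image") {
  extent <- as.list(extent)
  stopifnot(is.matrix(values),
            all(c("xmin", "xmax", "ymin", "ymax") %in% names(extent)))
  if (!all(is.finite(unlist(extent[c("xmin", "xmax", "ymin", "ymax")])))) {
    stop("extent must be finite")
  }
  structure(list(values = values, extent = extent, semantics = semantics),
            class = "pixel_image")
}

#' @export
print.pixel_image <- function(x, ...) {
  cat(sprintf("<pixel_image %s> %d x %d, x:[%.3g, %.3g] y:[%.3g, %.3g]\n",
              x$semantics, nrow(x$values), ncol(x$values),
              x$extent$xmin, x$extent$xmax, x$extent$ymin, x$extent$ymax))
  invisible(x)
}

# pixel-centre coordinates; rows run ventral (ymax) -> dorsal (ymin)
pixel_centres <- function(extent, M, N) {
  dx <- (extent$xmax - extent$xmin) / N
  dy <- (extent$ymax - extent$ymin) / M
  list(x = extent$xmin + (seq_len(N) - 0.5) * dx,
       y = extent$ymax - (seq_len(M) - 0.5) * dy)
}

# evaluate f(x, y) on the full pixel grid, returning an M x N matrix
eval_on_grid <- function(f, extent, M, N) {
  pc <- pixel_centres(extent, M, N)
  xs <- rep(pc$x, each = M)
  ys <- rep(pc$y, times = N)
  matrix(f(xs, ys), M, N)
}

#' Generate the baseline synthetic thorax scene
#'
#' A smooth ellipse-like thorax contour (slightly flattened dorsally, with a
#' small seeded low-order perturbation) containing two dorsally flattened
#' elliptical lung regions. Baseline conductivity is 0.5 inside the lungs
#' and 1 elsewhere (arbitrary units); the CT surrogate is -700 HU in
#' ventilated lung and soft-tissue values (~40 HU) elsewhere.
#'
#' @param M,N raster rows / columns (>= 64)
#' @param seed integer seed controlling the contour perturbation
#' @return a `phantom_scene` with thorax polygon, lung masks, CT surrogate,
#'   conductivity field functions and a (zero) ground-truth change raster
#' @export
make_thorax_scene <- function(M = 128L, N = 128L, seed = 1L) {
  if (M < 64 || N < 64) stop("raster must be at least 64 x 64")
  set.seed(as.integer(seed))
  pert <- stats::runif(4, -1, 1) * 0.012
  a <- 1.0; b <- 0.78
  th <- seq(0, 2 * pi, length.out = 97)[-97]
  r_ell <- a * b / sqrt((b * cos(th))^2 + (a * sin(th))^2)
  dors <- exp(-((((th + pi / 2 + pi) %% (2 * pi)) - pi) / 0.55)^2)
  r <- r_ell * (1 - 0.10 * dors) *
    (1 + pert[1] * cos(2 * th) + pert[2] * sin(2 * th) +
         pert[3] * cos(3 * th) + pert[4] * sin(3 * th))
  poly <- cbind(r * cos(th), r * sin(th))

  lungs <- list(
    left  = list(cx = -0.43, cy = -0.02, ax = 0.30, ay = 0.46),
    right = list(cx =  0.43, cy = -0.02, ax = 0.30, ay = 0.46)
  )
  dorsal_cut <- -0.42   # flat dorsal truncation of both lungs

  lung_label_fun <- function(x, y) {
    lab <- integer(length(x))
    for (i in seq_along(lungs)) {
      l <- lungs[[i]]
      inside <- ((x - l$cx) / l$ax)^2 + ((y - l$cy) / l$ay)^2 <= 1 &
        y >= dorsal_cut
      lab[inside] <- i
    }
    lab
  }
  in_lung_fun <- function(x, y) lung_label_fun(x, y) > 0L

  extent <- list(xmin = min(poly[, 1]), xmax = max(poly[, 1]),
                 ymin = min(poly[, 2]), ymax = max(poly[, 2]))
  lung_label <- eval_on_grid(function(x, y) lung_label_fun(x, y), extent, M, N)
  lung_mask <- lung_label > 0

  ct <- matrix(40, M, N)
  ct[lung_mask] <- -700
  scene <- structure(list(
    thorax_polygon = poly,
    extent = extent,
    M = as.integer(M), N = as.integer(N),
    lungs = lungs,
    dorsal_cut = dorsal_cut,
    lung_label = lung_label,
    lung_mask = lung_mask,
    in_lung_fun = in_lung_fun,
    lung_label_fun = lung_label_fun,
    ct_surrogate = pixel_image(ct, extent, "hounsfield"),
    sigma_baseline_fun = function(x, y) ifelse(in_lung_fun(x, y), 0.5, 1),
    sigma_target_fun = function(x, y) ifelse(in_lung_fun(x, y), 0.5, 1),
    ground_truth = pixel_image(matrix(0, M, N), extent, "conductivity"),
    state = "baseline",
    seed = as.integer(seed)
  ), class = "phantom_scene")
  scene
}

#' @export
print.phantom_scene <- function(x, ...) {
  cat(sprintf("<phantom_scene '%s'> raster %d x %d, lung area %.1f%% of thorax\n",
              x$state, x$M, x$N,
              100 * sum(x$lung_mask) / sum(in_polygon(
                rep(pixel_centres(x$extent, x$M, x$N)$x, each = x$M),
                rep(pixel_centres(x$extent, x$M, x$N)$y, times = x$N),
                x$thorax_polygon))))
  invisible(x)
}

# point-in-polygon (even-odd), vectorised over points
in_polygon <- function(x, y, poly) {
  n <- nrow(poly)
  inside <- logical(length(x))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    cross <- ((yi > y) != (yj > y)) &
      (x < (xj - xi) * (y - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

# global lung bounding box (analytic, before rasterization)
lung_bbox <- function(scene) {
  l <- scene$lungs
  list(xmin = min(vapply(l, function(u) u$cx - u$ax, 0)),
       xmax = max(vapply(l, function(u) u$cx + u$ax, 0)),
       ymin = max(scene$dorsal_cut,
                  min(vapply(l, function(u) u$cy - u$ay, 0))),
       ymax = max(vapply(l, function(u) u$cy + u$ay, 0)))
}

# finalize a target state: set sigma_target_fun, ground truth raster and the
# CT surrogate encoding the ground-truth weights as Hounsfield units
finish_state <- function(scene, sigma_fun, nominal_fun, state,
                         ct_fun = NULL) {
  scene$sigma_target_fun <- sigma_fun
  gt <- eval_on_grid(function(x, y) {
    ifelse(scene$in_lung_fun(x, y),
           nominal_fun(x, y) - scene$sigma_baseline_fun(x, y), 0)
  }, scene$extent, scene$M, scene$N)
  scene$ground_truth <- pixel_image(gt, scene$extent, "conductivity")
  if (is.null(ct_fun)) {
    # ground-truth-derived weights grade by ventilation, i.e. the magnitude
    # of the tidal conductivity change: the most ventilated area maps to 1
    # (encoded as -1000 HU), unventilated area to 0 (0 HU)
    mx <- max(abs(gt))
    w <- if (mx > 0) abs(gt) / mx else matrix(0, scene$M, scene$N)
    ct <- matrix(40, scene$M, scene$N)
    ct[scene$lung_mask] <- -1000 * w[scene$lung_mask]
  } else {
    ct <- eval_on_grid(ct_fun, scene$extent, scene$M, scene$N)
  }
  scene$ct_surrogate <- pixel_image(ct, scene$extent, "hounsfield")
  scene$state <- state
  scene
}

#' Apply one of the five lung conductivity patterns
#'
#' Patterns (conductivity in arbitrary units, lung baseline 0.5,
#' background 1): (a) uniform 0.25 across both lungs; (b) gradient from 1 at
#' the ventral lung edge decreasing linearly to 0.25 dorsally; (c) per-lung
#' radial gradient from 1 at the lung centre to 0.25 at the periphery;
#' (d) four high-contrast circular patches, ventral patches at 1 and dorsal
#' patches at 0 (floored at 1e-3 for solvability), rest of lung unchanged;
#' (e) 8 x 8 chessboard over the lung bounding box alternating 0 (floored)
#' and 1. The ground-truth raster stores the nominal change (using 0, not
#' the floor) and the CT surrogate encodes the ground-truth weights.
#'
#' @param scene a baseline `phantom_scene`
#' @param pattern_id one of "a".."e"
#' @param sigma_floor replacement for nominal 0 conductivity in the forward
#'   model
#' @return the scene in the target state
#' @export
apply_pattern <- function(scene, pattern_id, sigma_floor = 1e-3) {
  if (scene$state != "baseline") stop("apply_pattern expects a baseline scene")
  if (!pattern_id %in% c("a", "b", "c", "d", "e")) {
    stop("unknown pattern_id: ", pattern_id)
  }
  bb <- lung_bbox(scene)
  lungs <- scene$lungs
  base_f <- scene$sigma_baseline_fun
  inl <- scene$in_lung_fun
  labf <- scene$lung_label_fun

  lung_sigma <- switch(pattern_id,
    a = function(x, y, floor_val) rep(0.25, length(x)),
    b = function(x, y, floor_val) {
      t <- (y - bb$ymin) / (bb$ymax - bb$ymin)
      0.25 + 0.75 * pmin(pmax(t, 0), 1)
    },
    c = function(x, y, floor_val) {
      lab <- labf(x, y)
      out <- numeric(length(x))
      for (i in seq_along(lungs)) {
        l <- lungs[[i]]; sel <- lab == i
        if (!any(sel)) next
        d <- sqrt(((x[sel] - l$cx) / l$ax)^2 + ((y[sel] - l$cy) / l$ay)^2)
        out[sel] <- 1 - 0.75 * pmin(d, 1)
      }
      out
    },
    d = function(x, y, floor_val) {
      out <- base_f(x, y)        # unchanged lung stays at baseline
      lab <- labf(x, y)
      for (i in seq_along(lungs)) {
        l <- lungs[[i]]
        rv <- 0.35 * l$ax
        dv <- sqrt((x - l$cx)^2 + (y - (l$cy + 0.50 * l$ay))^2)
        dd <- sqrt((x - l$cx)^2 + (y - (l$cy - 0.50 * l$ay))^2)
        out[lab == i & dv <= rv] <- 1
        out[lab == i & dd <= rv] <- floor_val
      }
      out
    },
    e = function(x, y, floor_val) {
      w <- (bb$xmax - bb$xmin) / 8
      h <- (bb$ymax - bb$ymin) / 8
      i <- floor((x - bb$xmin) / w)
      j <- floor((y - bb$ymin) / h)
      ifelse((i + j) %% 2 == 0, floor_val, 1)
    })

  sig_f <- function(x, y) {
    out <- base_f(x, y)
    sel <- inl(x, y)
    if (any(sel)) out[sel] <- lung_sigma(x[sel], y[sel], sigma_floor)
    out
  }
  nom_f <- function(x, y) {
    out <- base_f(x, y)
    sel <- inl(x, y)
    if (any(sel)) out[sel] <- lung_sigma(x[sel], y[sel], 0)
    out
  }
  finish_state(scene, sig_f, nom_f, paste0("pattern_", pattern_id))
}

#' Apply a graded dorsal atelectasis state
#'
#' The dorsal-most horizontal slab holding `fraction` of each lung's area is
#' marked atelectatic: it keeps the baseline conductivity (no ventilation
#' signal) and its CT surrogate is set to 0 HU. The remaining lung changes
#' to `ventilation_sigma` and stays at -700 HU.
#'
#' @param scene a baseline `phantom_scene`
#' @param fraction atelectatic area fraction per lung, in [0, 0.5]
#' @param ventilation_sigma conductivity of the ventilated lung in the
#'   target state
#' @return the scene in the target state, with `atelectasis_cuts` recording
#'   the per-lung dorsal cut heights
#' @export
apply_atelectasis <- function(scene, fraction, ventilation_sigma = 0.25) {
  if (scene$state != "baseline") stop("apply_atelectasis expects a baseline scene")
  if (fraction < 0 || fraction > 0.5) stop("fraction must lie in [0, 0.5]")
  pc <- pixel_centres(scene$extent, scene$M, scene$N)
  ygrid <- matrix(rep(pc$y, times = scene$N), scene$M, scene$N)
  # per-lung dorsal cut: the pixel-row boundary whose dorsal share of the
  # lung's pixels is closest to the requested fraction
  cuts <- vapply(seq_along(scene$lungs), function(i) {
    ys <- ygrid[scene$lung_label == i]
    if (fraction == 0) return(scene$dorsal_cut - 1e-9)
    uy <- sort(unique(ys))
    frac_below <- vapply(uy, function(u) mean(ys <= u), numeric(1))
    k <- which.min(abs(frac_below - fraction))
    uy[k] + 1e-9
  }, numeric(1))
  labf <- scene$lung_label_fun
  atel_f <- function(x, y) {
    lab <- labf(x, y)
    lab > 0 & y < cuts[pmax(lab, 1)]
  }
  base_f <- scene$sigma_baseline_fun
  inl <- scene$in_lung_fun
  sig_f <- function(x, y) {
    out <- base_f(x, y)
    sel <- inl(x, y) & !atel_f(x, y)
    out[sel] <- ventilation_sigma
    out
  }
  ct_f <- function(x, y) {
    out <- rep(40, length(x))
    out[inl(x, y)] <- -700
    out[atel_f(x, y)] <- 0
    out
  }
  scene <- finish_state(scene, sig_f, sig_f, sprintf("atelectasis_%g", fraction),
                        ct_fun = ct_f)
  scene$atelectasis_fraction <- fraction
  scene$atelectasis_cuts <- cuts
  scene$atelectatic_fun <- atel_f
  scene
}

#' Rasterize per-element values onto the scene's pixel grid
#'
#' Paints a per-element field of a mesh onto the M x N raster by
#' containing-element lookup at every pixel centre (the inverse direction of
#' the pixel-to-element map used for the cosine basis).
#'
#' @param values per-element numeric vector
#' @param mesh the mesh the values live on
#' @param extent raster extent (defaults to the mesh bounding box)
#' @param M,N raster size
#' @param fill value for pixels outside the mesh
#' @return a `pixel_image`
#' @export
paint_elements <- function(values, mesh, extent = NULL, M = 128L, N = 128L,
                           fill = 0) {
  if (is.null(extent)) {
    extent <- list(xmin = min(mesh$polygon[, 1]), xmax = max(mesh$polygon[, 1]),
                   ymin = min(mesh$polygon[, 2]), ymax = max(mesh$polygon[, 2]))
  }
  map <- pixel_element_map(mesh, M, N, extent)
  img <- matrix(fill, M, N)
  ok <- map$pix2el > 0L
  img[ok] <- values[map$pix2el[ok]]
  pixel_image(img, extent, "eit_image")
}

#' Export the CT surrogate as 16-bit PGM text for inspection
#' @param img a `pixel_image` with hounsfield semantics
#' @param file output path
#' @export
export_pgm <- function(img, file) {
  v <- img$values
  v <- round((v - min(v)) / max(max(v) - min(v), 1e-12) * 65535)
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c("P2", sprintf("%d %d", ncol(v), nrow(v)), "65535"), con)
  apply(v, 1, function(row) writeLines(paste(row, collapse = " "), con))
  invisible(file)
}
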