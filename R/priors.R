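# Structural priors derived from a morphological (CT-like) raster.

new_structural_prior <- function(weights, kind, extent) {
  structure(list(weights = weights, kind = kind, extent = extent),
            class = "structural_prior")
}

#' @export
print.structural_prior <- function(x, ...) {
  cat(sprintf("<structural_prior %s> %d x %d, support %d px\n",
              x$kind, nrow(x$weights), ncol(x$weights), sum(x$weights > 0)))
  invisible(x)
}

#' Binary lung-contour prior
#'
#' Weight 1 inside the lung mask, 0 outside: reconstruction support is
#' restricted to the lung region with no further grading.
#'
#' @param lung_mask logical/0-1 M x N matrix, or a `pixel_image`
#' @param extent raster extent (taken from the image if one is given)
#' @return a `structural_prior` of kind "contour"
#' @export
make_contour_prior <- function(lung_mask, extent = NULL) {
  if (inherits(lung_mask, "pixel_image")) {
    extent <- lung_mask$extent
    lung_mask <- lung_mask$values
  }
  m <- matrix(as.numeric(lung_mask != 0), nrow(lung_mask), ncol(lung_mask))
  if (sum(m) == 0) stop("empty lung mask")
  new_structural_prior(m, "contour", extent)
}

#' Graded detail prior from a Hounsfield-unit raster
#'
#' Inside the lung, weight = HU / (-1000) clamped to [0, 1]: pure air
#' (-1000 HU) maps to 1, normal aerated lung (-700 HU) to 0.7, and
#' atelectasis / edema / infiltrates (~0 HU) to 0, inhibiting reconstruction
#' there. Outside the lung the weight is 0.
#'
#' @param ct `pixel_image` with hounsfield semantics (or bare matrix)
#' @param lung_mask logical M x N matrix matching `ct`
#' @param extent raster extent (taken from `ct` if it is a `pixel_image`)
#' @return a `structural_prior` of kind "detail"
#' @export
make_detail_prior <- function(ct, lung_mask, extent = NULL) {
  if (inherits(ct, "pixel_image")) {
    extent <- ct$extent
    ct <- ct$values
  }
  if (!all(dim(ct) == dim(lung_mask))) stop("shape error: ct and lung_mask dimensions differ")
  w <- pmin(pmax(ct / (-1000), 0), 1)
  w[!(lung_mask != 0)] <- 0
  new_structural_prior(w, "detail", extent)
}
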