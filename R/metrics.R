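# Image normalization, l2-norm image difference against ground truth, and
# the global inhomogeneity (GI) index.

#' Min-max normalize an image to [0, 1]
#'
#' Different reconstruction algorithms produce pixel values on different
#' arbitrary scales; images are rescaled to [0, 1] before comparison. A
#' constant image (undefined min-max) maps to all zeros.
#'
#' @param img a `pixel_image` or bare matrix
#' @return same type as the input, rescaled
#' @export
normalize_image <- function(img) {
  v <- if (inherits(img, "pixel_image")) img$values else img
  if (any(!is.finite(v))) stop("data error: non-finite pixel values")
  rg <- range(v)
  v <- if (rg[2] > rg[1]) (v - rg[1]) / (rg[2] - rg[1]) else v * 0
  if (inherits(img, "pixel_image")) {
    img$values <- v
    img
  } else {
    v
  }
}

#' l2-norm image difference
#'
#' sqrt of the pixelwise sum of squared differences between a reconstruction
#' and the ground truth (both already normalized to [0, 1]). Set
#' `squared = TRUE` for the raw sum of squares; orderings and relative
#' comparisons are unaffected by the monotone square root.
#'
#' @param recon,truth `pixel_image`s or matrices of identical size
#' @param squared return the sum of squares instead of its square root
#' @return non-negative scalar
#' @export
l2_image_difference <- function(recon, truth, squared = FALSE) {
  a <- if (inherits(recon, "pixel_image")) recon$values else recon
  b <- if (inherits(truth, "pixel_image")) truth$values else truth
  if (!all(dim(a) == dim(b))) stop("shape mismatch between recon and truth")
  ss <- sum((a - b)^2)
  if (squared) ss else sqrt(ss)
}

#' Global inhomogeneity (GI) index of a tidal image
#'
#' Sum of absolute deviations of the lung-region pixel values from their
#' median, divided by the lung-region sum. Zero for a homogeneous lung;
#' invariant under positive scaling of the image. The lung mask is fixed
#' externally (conventionally from CT) so values are comparable across
#' frames and methods.
#'
#' @param tidal a `pixel_image` or matrix (tidal EIT image)
#' @param lung_mask logical M x N matrix
#' @return the GI index (scalar)
#' @export
gi_index <- function(tidal, lung_mask) {
  v <- if (inherits(tidal, "pixel_image")) tidal$values else tidal
  if (!all(dim(v) == dim(lung_mask))) stop("shape mismatch between image and mask")
  h <- v[lung_mask != 0]
  if (!length(h)) stop("metric error: empty lung region")
  s <- sum(h)
  if (s == 0) stop("metric error: zero lung-region sum")
  sum(abs(h - stats::median(h))) / s
}
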