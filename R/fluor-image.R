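#' Two-channel fluorescence image
#'
#' Container for a max-projected two-channel immunofluorescence image: the
#' signal channel (e.g. CSE1 staining) and the stentorin autofluorescence
#' channel that delineates the cell body, plus pixel calibration and exposure
#' metadata. Intensities are in arbitrary units (a.u.).
#'
#' @param signal Numeric matrix, signal channel (rows = y, cols = x).
#' @param autofluor Numeric matrix, autofluorescence channel, same dimensions.
#' @param pixel_size Pixel size (um/px, `> 0`).
#' @param exposure_s Exposure time in seconds (`> 0`).
#' @return Object of class `"fluor_image"`.
#' @export
fluor_image <- function(signal, autofluor, pixel_size, exposure_s = 1) {
  if (!is.matrix(signal) || !is.matrix(autofluor)) {
    stop("both channels must be matrices")
  }
  if (!all(dim(signal) == dim(autofluor))) {
    stop("channels must share dimensions")
  }
  if (!is.finite(pixel_size) || pixel_size <= 0) {
    stop("pixel_size must be positive")
  }
  if (is.null(exposure_s) || is.na(exposure_s) || !is.numeric(exposure_s) ||
      exposure_s <= 0) {
    stop("exposure_s metadata is required and must be positive")
  }
  if (any(signal < 0) || any(autofluor < 0)) {
    stop("intensities must be non-negative")
  }
  structure(list(signal = signal, autofluor = autofluor,
                 pixel_size = as.numeric(pixel_size),
                 exposure_s = as.numeric(exposure_s)),
            class = "fluor_image")
}

#' @export
print.fluor_image <- function(x, ...) {
  cat(sprintf(
    "<fluor_image> %d x %d px @ %g um/px, exposure %g s, signal range [%g, %g] a.u.\n",
    nrow(x$signal), ncol(x$signal), x$pixel_size, x$exposure_s,
    min(x$signal), max(x$signal)))
  invisible(x)
}

#' Normalize an image to 1 s exposure
#'
#' Divides both channels by the exposure time and sets the exposure to 1 s so
#' intensities from different acquisitions are comparable. Idempotent.
#'
#' @param image A [fluor_image()].
#' @return A [fluor_image()] with `exposure_s = 1`.
#' @export
normalize_exposure <- function(image) {
  stopifnot(inherits(image, "fluor_image"))
  fluor_image(image$signal / image$exposure_s,
              image$autofluor / image$exposure_s,
              pixel_size = image$pixel_size, exposure_s = 1)
}

#' Cell mask from the stentorin autofluorescence channel
#'
#' Thresholds the autofluorescence channel (moment-preserving threshold by
#' default), keeps the largest 8-connected component and fills holes,
#' producing the cell-body mask within which whole-cell signal intensity is
#' averaged.
#'
#' @param image A [fluor_image()] or a numeric matrix (the autofluorescence
#'   channel).
#' @param threshold Either `"moments"` (default) or a numeric threshold.
#' @return Binary matrix (1 = cell).
#' @export
cell_mask_from_stentorin <- function(image, threshold = "moments") {
  ch <- if (inherits(image, "fluor_image")) image$autofluor else image
  thr <- if (identical(threshold, "moments")) moments_threshold(ch)
         else as.numeric(threshold)
  bw <- matrix(as.integer(ch > thr), nrow = nrow(ch))
  if (sum(bw) == 0) stop("empty foreground: no cell found above threshold")
  lab <- label_components(bw)
  sizes <- tabulate(lab[lab > 0])
  keep <- which.max(sizes)
  mask <- matrix(as.integer(lab == keep), nrow = nrow(lab))
  mask <- EBImage::fillHull(mask)
  matrix(as.integer(mask != 0), nrow = nrow(lab))
}

#' Mean signal intensity within a mask
#'
#' Arithmetic mean of the signal channel over the mask's foreground pixels
#' (the whole-cell average-intensity measurement).
#'
#' @param signal Numeric matrix or [fluor_image()] (its signal channel is
#'   used).
#' @param mask Binary matrix, same dimensions.
#' @return Mean intensity (a.u.).
#' @export
mean_intensity_in_mask <- function(signal, mask) {
  if (inherits(signal, "fluor_image")) signal <- signal$signal
  if (!all(dim(signal) == dim(mask))) stop("signal and mask dimensions differ")
  n <- sum(mask != 0)
  if (n == 0) stop("empty mask")
  mean(signal[mask != 0])
}
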