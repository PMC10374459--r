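#' Rolling-ball background subtraction
#'
#' Classical rolling-ball background estimation: the background is the
#' grayscale morphological opening of the image with a non-flat, ball-shaped
#' structuring element of the given radius (the surface a ball of that radius
#' traces when rolled beneath the intensity landscape). Features narrower
#' than the ball — the puncta — are removed from the background estimate and
#' therefore preserved in the difference, which is clipped at 0. Image
#' borders are handled by edge replication.
#'
#' @param image Numeric matrix (exposure-normalized intensities).
#' @param radius_um Ball radius in um; must map to at least 1 px.
#' @param pixel_size Pixel size (um/px).
#' @param return_background If `TRUE`, return the background estimate
#'   instead of the subtracted image.
#' @return Numeric matrix: `pmax(image - background, 0)` (or the background).
#' @export
rolling_ball_subtract <- function(image, radius_um, pixel_size,
                                  return_background = FALSE) {
  if (inherits(image, "fluor_image")) {
    pixel_size <- image$pixel_size
    image <- image$signal
  }
  r_px <- radius_um / pixel_size
  if (!is.finite(r_px) || r_px < 1) {
    stop("rolling-ball radius must be at least 1 pixel (got ",
         signif(r_px, 3), " px)")
  }
  r <- ceiling(r_px)
  dx <- rep(-r:r, times = 2 * r + 1)
  dy <- rep(-r:r, each = 2 * r + 1)
  d2 <- dx^2 + dy^2
  keep <- d2 <= r_px^2
  dx <- dx[keep]; dy <- dy[keep]
  ball <- sqrt(r_px^2 - d2[keep])

  nr <- nrow(image); nc <- ncol(image)
  shift <- function(m, sy, sx) {
    # edge-replicated shift: m[i + sy, j + sx] with clamped indices
    ri <- pmin(pmax(seq_len(nr) + sy, 1L), nr)
    ci <- pmin(pmax(seq_len(nc) + sx, 1L), nc)
    m[ri, ci, drop = FALSE]
  }
  ero <- matrix(Inf, nr, nc)
  for (k in seq_along(dx)) {
    ero <- pmin(ero, shift(image, dy[k], dx[k]) - ball[k])
  }
  bg <- matrix(-Inf, nr, nc)
  for (k in seq_along(dx)) {
    bg <- pmax(bg, shift(ero, -dy[k], -dx[k]) + ball[k])
  }
  if (return_background) bg else pmax(image - bg, 0)
}

#' Moment-preserving (Tsai) threshold
#'
#' Selects the threshold whose binarization preserves the first three
#' gray-level moments of the image histogram: the image's moments determine
#' two representative levels and the fraction `p0` of pixels that should fall
#' below threshold; the threshold is the gray level at which the cumulative
#' histogram first reaches `p0`. Computed on a 256-bin histogram spanning the
#' image's intensity range, so the result is invariant under appending empty
#' histogram bins.
#'
#' @param image Numeric matrix with at least two distinct values.
#' @param n_bins Histogram resolution (default 256).
#' @return Threshold on the image's intensity scale; foreground is
#'   `image > threshold`.
#' @export
moments_threshold <- function(image, n_bins = 256L) {
  v <- as.vector(image)
  lo <- min(v); hi <- max(v)
  if (!is.finite(lo) || !is.finite(hi) || lo == hi) {
    stop("constant image: no threshold exists")
  }
  bin <- pmin(floor((v - lo) / (hi - lo) * n_bins), n_bins - 1L)
  h <- tabulate(bin + 1L, nbins = n_bins) / length(v)
  z <- (seq_len(n_bins) - 1)
  m1 <- sum(h * z); m2 <- sum(h * z^2); m3 <- sum(h * z^3)
  cd <- m2 - m1^2
  if (cd <= 0) stop("degenerate histogram: no threshold exists")
  c0 <- (-m2^2 + m1 * m3) / cd
  c1 <- (-m3 + m2 * m1) / cd
  disc <- sqrt(max(c1^2 - 4 * c0, 0))
  z0 <- (-c1 - disc) / 2
  z1 <- (-c1 + disc) / 2
  p0 <- (z1 - m1) / (z1 - z0)
  cum <- cumsum(h)
  # the bin whose cumulative fraction is closest to the ideal tail fraction
  t_bin <- which.min(abs(cum - p0))
  # upper edge of the selected bin, mapped back to the intensity scale
  lo + t_bin / n_bins * (hi - lo)
}

#' Segment fluorescent puncta
#'
#' The puncta quantification chain: rolling-ball background subtraction,
#' Gaussian blur, moment-preserving threshold, watershed separation of
#' touching spots on the distance transform, region measurement, then a size
#' gate keeping equivalent-circle diameters in `[min_d_um, max_d_um]` and an
#' optional mean-intensity floor. Mean intensities are measured on the
#' background-subtracted (un-blurred) image, so they report spot signal above
#' local background in exposure-normalized units.
#'
#' @param image A [fluor_image()] (must be exposure-normalized, i.e.
#'   `exposure_s == 1`) or a numeric matrix plus `pixel_size`.
#' @param sigma_um Gaussian blur sigma (um, default 0.5).
#' @param rolling_ball_um Rolling-ball radius (um, default 5).
#' @param min_d_um,max_d_um Size gate on equivalent diameter (um), defaults
#'   0.75 and 10.
#' @param intensity_floor Optional mean-intensity floor (a.u.,
#'   exposure-normalized); puncta below it are excluded. `NULL` disables.
#' @param pixel_size Pixel size (um/px), required for bare matrices.
#' @return Data.frame with one row per punctum: `label`, `area_um2`,
#'   `eq_diameter_um`, `mean_intensity`, `centroid_x_px`, `centroid_y_px`.
#' @export
segment_puncta <- function(image, sigma_um = 0.5, rolling_ball_um = 5,
                           min_d_um = 0.75, max_d_um = 10,
                           intensity_floor = NULL, pixel_size = NULL) {
  if (inherits(image, "fluor_image")) {
    if (abs(image$exposure_s - 1) > 1e-9) {
      stop("image must be exposure-normalized first (see normalize_exposure)")
    }
    pixel_size <- image$pixel_size
    img <- image$signal
  } else {
    if (is.null(pixel_size)) stop("pixel_size is required for a bare matrix")
    img <- image
  }
  sub <- rolling_ball_subtract(img, rolling_ball_um, pixel_size)
  blurred <- EBImage::gblur(sub, sigma = max(sigma_um / pixel_size, 0.3))
  blurred <- matrix(as.numeric(blurred), nrow = nrow(sub))
  empty <- data.frame(label = integer(0), area_um2 = numeric(0),
                      eq_diameter_um = numeric(0), mean_intensity = numeric(0),
                      centroid_x_px = numeric(0), centroid_y_px = numeric(0))
  if (max(blurred) == min(blurred)) return(empty)
  thr <- moments_threshold(blurred)
  bw <- matrix(as.integer(blurred > thr), nrow = nrow(blurred))
  if (sum(bw) == 0) return(empty)
  d <- EBImage::distmap(bw)
  # seed-suppression depth: half the minimum accepted diameter
  lab <- EBImage::watershed(d, tolerance = 0.5 * min_d_um / pixel_size)
  lab <- matrix(as.integer(lab), nrow = nrow(bw))
  labs <- setdiff(sort(unique(as.vector(lab))), 0L)
  if (length(labs) == 0) return(empty)
  rows <- lapply(labs, function(l) {
    idx <- which(lab == l, arr.ind = TRUE)
    npx <- nrow(idx)
    area <- npx * pixel_size^2
    data.frame(label = l,
               area_um2 = area,
               eq_diameter_um = 2 * sqrt(area / pi),
               mean_intensity = mean(sub[idx]),
               centroid_x_px = mean(idx[, 2]),
               centroid_y_px = mean(idx[, 1]))
  })
  out <- do.call(rbind, rows)
  out <- out[out$eq_diameter_um >= min_d_um & out$eq_diameter_um <= max_d_um, ,
             drop = FALSE]
  if (!is.null(intensity_floor)) {
    out <- out[out$mean_intensity >= intensity_floor, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}
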