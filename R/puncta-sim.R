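#' Synthetic two-channel puncta image with ground truth
#'
#' Renders a fixture for the puncta quantification chain: channel 1 carries
#' isotropic Gaussian spots over a smooth linear background with shot-like
#' noise (Gaussian, sd proportional to the square root of the local signal),
#' and channel 2 is a filled ellipse standing in for the stentorin
#' autofluorescence that outlines the cell. All spots are placed inside the
#' cell ellipse with a minimum pairwise separation, and every spot is listed
#' in the ground-truth table. Deterministic given `seed`.
#'
#' Spot "diameter" is the full width at half maximum (FWHM) of the Gaussian
#' profile; the nominal mean intensity recorded in the ground truth is the
#' average of the profile over the FWHM disc (`~0.7214 * amplitude`).
#'
#' @param n_spots Number of spots (default 12).
#' @param dims Image dimensions `c(rows, cols)` in px (default `c(200, 200)`).
#' @param pixel_size Pixel size (um/px, default 0.4).
#' @param diameter_range_um FWHM range to draw spot sizes from (um,
#'   default `c(1.5, 4)`).
#' @param amplitude_range Peak amplitude range (a.u., default
#'   `c(4000, 9000)`).
#' @param diameters_um,amplitudes Optional explicit per-spot values
#'   (override the ranges; recycled to `n_spots`).
#' @param background_base Background offset (a.u., default 300).
#' @param background_slope Linear background gain across the frame, as a
#'   fraction of `background_base` from left edge to right edge (default 0.5).
#' @param noise_sd Noise sd at `background_base` intensity (a.u., default 30);
#'   local sd scales as `sqrt(intensity / background_base)`. 0 disables noise.
#' @param min_separation_um Minimum centre-to-centre spot distance (um,
#'   default 8).
#' @param cell_value Autofluorescence plateau inside the cell (default 800).
#' @param exposure_s Exposure metadata attached to the image (default 1).
#' @param seed Integer seed (required).
#' @return A [fluor_image()] with attribute `"ground_truth"`: list with
#'   `spots` (data.frame `x_px`, `y_px`, `diameter_um`, `sigma_px`,
#'   `amplitude`, `mean_intensity_nominal`), `background`
#'   (`base`, `gain_x`), and `cell` (`cx_px`, `cy_px`, `a_px`, `b_px`,
#'   `area_um2`).
#' @export
render_puncta_image <- function(n_spots = 12,
                                dims = c(200, 200),
                                pixel_size = 0.4,
                                diameter_range_um = c(1.5, 4),
                                amplitude_range = c(4000, 9000),
                                diameters_um = NULL,
                                amplitudes = NULL,
                                background_base = 300,
                                background_slope = 0.5,
                                noise_sd = 30,
                                min_separation_um = 8,
                                cell_value = 800,
                                exposure_s = 1,
                                seed) {
  if (missing(seed)) stop("a seed is required for reproducible rendering")
  set.seed(as.integer(seed))
  nr <- dims[1]; nc <- dims[2]
  cx <- (nc + 1) / 2; cy <- (nr + 1) / 2
  a <- 0.42 * nc; b <- 0.40 * nr
  xg <- matrix(rep(seq_len(nc), each = nr), nrow = nr)
  yg <- matrix(rep(seq_len(nr), times = nc), nrow = nr)
  in_cell <- ((xg - cx) / a)^2 + ((yg - cy) / b)^2 <= 1

  if (is.null(diameters_um)) {
    diameters_um <- stats::runif(n_spots, diameter_range_um[1],
                                 diameter_range_um[2])
  } else {
    diameters_um <- rep_len(diameters_um, n_spots)
  }
  if (is.null(amplitudes)) {
    amplitudes <- stats::runif(n_spots, amplitude_range[1],
                               amplitude_range[2])
  } else {
    amplitudes <- rep_len(amplitudes, n_spots)
  }
  sigma_px <- diameters_um / (2 * sqrt(2 * log(2))) / pixel_size

  # rejection-sample spot centres: inside the cell (with margin) and apart
  min_sep_px <- min_separation_um / pixel_size
  xs <- numeric(0); ys <- numeric(0)
  tries <- 0
  while (length(xs) < n_spots && tries < 20000) {
    tries <- tries + 1
    i <- length(xs) + 1
    margin <- 3 * sigma_px[i] + 2
    px <- stats::runif(1, 1 + margin, nc - margin)
    py <- stats::runif(1, 1 + margin, nr - margin)
    inside <- ((px - cx) / (a - margin / 1))^2 +
              ((py - cy) / (b - margin / 1))^2 <= 1
    if (!inside) next
    if (length(xs) > 0 &&
        min(sqrt((xs - px)^2 + (ys - py)^2)) < min_sep_px) next
    xs <- c(xs, px); ys <- c(ys, py)
  }
  if (length(xs) < n_spots) {
    stop("could not place ", n_spots, " spots with separation ",
         min_separation_um, " um inside the cell; reduce n_spots or ",
         "min_separation_um")
  }

  background <- background_base *
    (1 + background_slope * (xg - 1) / max(nc - 1, 1))
  signal <- background
  for (i in seq_len(n_spots)) {
    d2 <- (xg - xs[i])^2 + (yg - ys[i])^2
    win <- d2 <= (5 * sigma_px[i])^2
    signal[win] <- signal[win] +
      amplitudes[i] * exp(-d2[win] / (2 * sigma_px[i]^2))
  }
  if (noise_sd > 0) {
    sd_local <- noise_sd * sqrt(pmax(signal, 0) / background_base)
    signal <- signal + stats::rnorm(length(signal), 0, 1) * sd_local
  }
  signal <- pmax(signal, 0)

  autofluor <- matrix(0, nr, nc)
  autofluor[in_cell] <- cell_value
  if (noise_sd > 0) {
    autofluor <- pmax(autofluor +
      stats::rnorm(length(autofluor), 0, noise_sd / 2), 0)
  }

  img <- fluor_image(signal, autofluor, pixel_size = pixel_size,
                     exposure_s = exposure_s)
  # channels record what the camera would see at this exposure
  if (exposure_s != 1) {
    img <- fluor_image(signal * exposure_s, autofluor * exposure_s,
                       pixel_size = pixel_size, exposure_s = exposure_s)
  }
  attr(img, "ground_truth") <- list(
    spots = data.frame(x_px = xs, y_px = ys,
                       diameter_um = diameters_um,
                       sigma_px = sigma_px,
                       amplitude = amplitudes,
                       mean_intensity_nominal = 0.7214 * amplitudes),
    background = list(base = background_base, gain_x = background_slope),
    cell = list(cx_px = cx, cy_px = cy, a_px = a, b_px = b,
                area_um2 = pi * a * b * pixel_size^2)
  )
  img
}

#' Match segmented puncta to ground-truth spots
#'
#' Greedy nearest-centroid matching within `max_dist_um`; each ground-truth
#' spot is matched at most once. Returns recall and precision of the
#' segmentation against the fixture's spot list.
#'
#' @param puncta Data.frame from [segment_puncta()].
#' @param truth Ground-truth spots data.frame (see [render_puncta_image()]).
#' @param pixel_size Pixel size (um/px).
#' @param max_dist_um Match radius (um, default 2).
#' @return List with `n_true`, `n_detected`, `n_matched`, `recall`,
#'   `precision`.
#' @export
match_puncta <- function(puncta, truth, pixel_size, max_dist_um = 2) {
  n_true <- nrow(truth); n_det <- nrow(puncta)
  matched_true <- rep(FALSE, n_true)
  n_matched <- 0L
  if (n_det > 0 && n_true > 0) {
    for (i in seq_len(n_det)) {
      d <- sqrt((truth$x_px - puncta$centroid_x_px[i])^2 +
                (truth$y_px - puncta$centroid_y_px[i])^2) * pixel_size
      d[matched_true] <- Inf
      j <- which.min(d)
      if (d[j] <= max_dist_um) {
        matched_true[j] <- TRUE
        n_matched <- n_matched + 1L
      }
    }
  }
  list(n_true = n_true, n_detected = n_det, n_matched = n_matched,
       recall = if (n_true > 0) n_matched / n_true else NA_real_,
       precision = if (n_det > 0) n_matched / n_det else NA_real_)
}
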