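test_that("exposure normalization rescales to 1 s and is idempotent", {
  img <- fluor_image(matrix(10, 4, 4), matrix(2, 4, 4),
                     pixel_size = 0.4, exposure_s = 0.5)
  norm <- normalize_exposure(img)
  expect_equal(norm$signal, matrix(20, 4, 4))
  expect_equal(norm$exposure_s, 1)
  expect_equal(normalize_exposure(norm)$signal, norm$signal)
  unit <- fluor_image(matrix(10, 4, 4), matrix(2, 4, 4), 0.4, exposure_s = 1)
  expect_equal(normalize_exposure(unit)$signal, unit$signal)
  expect_error(fluor_image(matrix(10, 4, 4), matrix(2, 4, 4), 0.4,
                           exposure_s = NA), "exposure")
})

test_that("the cell mask tracks the autofluorescence footprint", {
  img <- render_puncta_image(n_spots = 6, seed = 13)
  gt <- attr(img, "ground_truth")
  mask <- cell_mask_from_stentorin(img)
  expect_rel_error_lt(sum(mask) * img$pixel_size^2, gt$cell$area_um2, 0.05)
  # uniform zero image: no threshold exists
  expect_error(cell_mask_from_stentorin(matrix(0, 20, 20)), "constant image")
  # largest-component rule
  two <- matrix(0, 40, 40)
  two[5:30, 5:30] <- 100    # big blob
  two[35:37, 35:37] <- 100  # small blob
  m2 <- cell_mask_from_stentorin(two, threshold = 50)
  expect_true(all(m2[5:30, 5:30] == 1))
  expect_true(all(m2[35:37, 35:37] == 0))
})

test_that("mean intensity in mask equals the brute-force pixel loop", {
  expect_equal(mean_intensity_in_mask(matrix(7.5, 5, 5), matrix(1, 5, 5)),
               7.5)
  half <- matrix(c(rep(0, 10), rep(10, 10)), nrow = 4)
  expect_equal(mean_intensity_in_mask(half, matrix(1, 4, 5)), 5)
  set.seed(15)
  sig <- matrix(runif(900, 0, 100), 30, 30)
  mask <- matrix(rbinom(900, 1, 0.4), 30, 30)
  acc <- 0; n <- 0
  for (i in 1:30) for (j in 1:30) {
    if (mask[i, j] == 1) { acc <- acc + sig[i, j]; n <- n + 1 }
  }
  expect_equal(mean_intensity_in_mask(sig, mask), acc / n, tolerance = 1e-9)
  expect_error(mean_intensity_in_mask(sig, matrix(0, 30, 30)), "empty mask")
})

test_that("rolling ball removes smooth structure and keeps narrow peaks", {
  const <- matrix(40, 30, 30)
  expect_equal(rolling_ball_subtract(const, 4, 1), matrix(0, 30, 30))
  # constant plateau with a single-pixel spike: the spike survives almost
  # untouched (the ball's crown pokes in by a fraction of a grey level)
  spiked <- const
  spiked[15, 15] <- 140
  out <- rolling_ball_subtract(spiked, 4, 1)
  expect_gt(out[15, 15], 99.5)
  expect_lt(max(out[-((15 - 1) * 30 + 15)]), 0.2)
  # linear gradient is reproduced within 5% away from spots/borders
  img <- render_puncta_image(n_spots = 4, noise_sd = 0, seed = 17)
  gt <- attr(img, "ground_truth")
  bg_true <- gt$background$base *
    (1 + gt$background$gain_x *
       (col(img$signal) - 1) / (ncol(img$signal) - 1))
  bg_est <- rolling_ball_subtract(img$signal, 5, img$pixel_size,
                                  return_background = TRUE)
  inner <- 25:175
  spot_free <- matrix(TRUE, nrow(img$signal), ncol(img$signal))
  for (i in seq_len(nrow(gt$spots))) {
    d2 <- (col(spot_free) - gt$spots$x_px[i])^2 +
          (row(spot_free) - gt$spots$y_px[i])^2
    spot_free[d2 <= (5 * gt$spots$sigma_px[i] + 5 / img$pixel_size)^2] <- FALSE
  }
  sel <- spot_free[inner, inner]
  rel <- abs(bg_est[inner, inner] - bg_true[inner, inner]) /
    bg_true[inner, inner]
  expect_lt(max(rel[sel]), 0.05)
  expect_error(rolling_ball_subtract(const, 0.5, 1), "at least 1 pixel")
})

test_that("moments threshold separates a two-level histogram", {
  two_level <- matrix(c(rep(10, 128), rep(200, 128)), 16, 16)
  thr <- moments_threshold(two_level)
  expect_gt(thr, 10)
  expect_lt(thr, 200)
  expect_error(moments_threshold(matrix(5, 4, 4)), "constant")
  # affine intensity maps move the threshold along with the data
  thr2 <- moments_threshold(two_level * 3 + 50)
  expect_equal(thr2, thr * 3 + 50, tolerance = 1e-9)
  # replicating every pixel (scaling the histogram) changes nothing
  thr3 <- moments_threshold(rbind(two_level, two_level))
  expect_equal(thr3, thr)
})

test_that("moments threshold agrees with the brute-force moment-preserving search", {
  # cleanly bimodal: two narrow clusters with an empty valley between them
  set.seed(19)
  img <- matrix(c(rnorm(600, 40, 3), rnorm(400, 200, 5)), 25, 40)
  img <- pmax(img, 0)
  thr <- moments_threshold(img)
  # brute force: for each candidate threshold, pick z0/z1 preserving the
  # first two moments at that tail fraction and score the third-moment error
  v <- as.vector(img)
  lo <- min(v); hi <- max(v)
  bin <- pmin(floor((v - lo) / (hi - lo) * 256), 255)
  h <- tabulate(bin + 1L, nbins = 256) / length(v)
  z <- 0:255
  m1 <- sum(h * z); m2 <- sum(h * z^2); m3 <- sum(h * z^3)
  best <- Inf; best_t <- NA
  cum <- cumsum(h)
  for (t in 1:255) {
    p0 <- cum[t]
    if (p0 <= 0 || p0 >= 1) next
    # z0, z1 solving p0 z0 + p1 z1 = m1 and p0 z0^2 + p1 z1^2 = m2
    p1 <- 1 - p0
    disc <- p1 / p0 * (m2 - m1^2)
    if (disc < 0) next
    z0 <- m1 - sqrt(disc)
    z1 <- m1 + sqrt(p0 / p1 * (m2 - m1^2))
    err <- abs(p0 * z0^3 + p1 * z1^3 - m3)
    if (err < best) { best <- err; best_t <- t }
  }
  thr_brute <- lo + best_t / 256 * (hi - lo)
  # the p-tile solution and the exhaustive moment-error minimizer land in
  # the same inter-mode valley, within one histogram bin of each other
  expect_lte(abs(thr - thr_brute), 2 * (hi - lo) / 256)
  # and both separate the two clusters
  for (t in c(thr, thr_brute)) {
    expect_true(all(img[img < 60] < t))
    expect_true(all(img[img > 180] > t))
  }
})

test_that("well-separated spots are recovered exactly", {
  img <- render_puncta_image(n_spots = 10, seed = 23)
  gt <- attr(img, "ground_truth")
  p <- segment_puncta(img)
  expect_identical(nrow(p), nrow(gt$spots))
  m <- match_puncta(p, gt$spots, img$pixel_size)
  expect_equal(m$recall, 1)
  expect_equal(m$precision, 1)
})

test_that("the size gate removes out-of-range spots", {
  img <- render_puncta_image(n_spots = 2, diameters_um = c(0.4, 2),
                             amplitudes = c(6000, 6000), noise_sd = 10,
                             min_separation_um = 20, seed = 3)
  p <- segment_puncta(img)
  expect_identical(nrow(p), 1L)
  expect_gte(p$eq_diameter_um, 0.75)
  expect_lte(p$eq_diameter_um, 10)
})

test_that("the intensity floor removes dim puncta only", {
  img <- render_puncta_image(n_spots = 2, diameters_um = c(6, 2.5),
                             amplitudes = c(2200, 7000), noise_sd = 10,
                             min_separation_um = 25, seed = 4)
  before <- segment_puncta(img)
  expect_identical(nrow(before), 2L)
  expect_lt(min(before$mean_intensity), 2000)
  expect_gt(max(before$mean_intensity), 2000)
  after <- segment_puncta(img, intensity_floor = 2000)
  expect_identical(nrow(after), 1L)
  expect_gte(after$mean_intensity, 2000)
})

test_that("puncta counts are invariant to a constant background offset", {
  img <- render_puncta_image(n_spots = 8, seed = 29)
  base <- segment_puncta(img)
  shifted <- fluor_image(img$signal + 500, img$autofluor,
                         pixel_size = img$pixel_size, exposure_s = 1)
  off <- segment_puncta(shifted)
  expect_identical(nrow(off), nrow(base))
})

test_that("un-normalized images are refused", {
  img <- render_puncta_image(n_spots = 3, seed = 31, exposure_s = 0.5)
  expect_error(segment_puncta(img), "exposure-normalized")
  expect_silent(p <- segment_puncta(normalize_exposure(img)))
  expect_identical(nrow(p), 3L)
})
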