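# Programmatic raster fixtures shared across the suite.

raster_disc <- function(radius_px, pad = 4L) {
  n <- 2L * ceiling(radius_px) + 2L * pad + 1L
  ctr <- (n + 1) / 2
  x <- matrix(rep(seq_len(n), each = n), nrow = n) - ctr
  y <- matrix(rep(seq_len(n), times = n), nrow = n) - ctr
  matrix(as.integer(x^2 + y^2 <= radius_px^2), nrow = n)
}

raster_square <- function(side_px, pad = 4L) {
  n <- side_px + 2L * pad
  m <- matrix(0L, n, n)
  m[(pad + 1):(pad + side_px), (pad + 1):(pad + side_px)] <- 1L
  m
}

raster_ellipse <- function(a_px, b_px, angle = 0, pad = 4L) {
  n <- 2L * ceiling(a_px) + 2L * pad + 1L
  ctr <- (n + 1) / 2
  x <- matrix(rep(seq_len(n), each = n), nrow = n) - ctr
  y <- matrix(rep(seq_len(n), times = n), nrow = n) - ctr
  u <- cos(angle) * x + sin(angle) * y
  v <- -sin(angle) * x + cos(angle) * y
  matrix(as.integer((u / a_px)^2 + (v / b_px)^2 <= 1), nrow = n)
}

# random but seed-stable beads-on-a-string models
random_specs <- function(n, seed) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    k <- sample(1:6, 1)
    radii <- runif(k, 8, 16)
    gaps <- if (k > 1) runif(k - 1, 3, 15) else numeric(0)
    nucleus_spec(radii, gaps, connector_radius = runif(1, 0.5, 1.5))
  })
}

expect_rel_error_lt <- function(estimate, truth, tol) {
  expect_lt(abs(estimate - truth) / abs(truth), tol)
}
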