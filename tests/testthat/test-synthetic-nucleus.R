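test_that("analytic volume matches closed forms", {
  # single sphere
  expect_equal(analytic_volume(nucleus_spec(15)), 4 / 3 * pi * 15^3)
  # two spheres plus one connector cylinder
  sp <- nucleus_spec(c(10, 10), gap_lengths = 5, connector_radius = 1)
  expect_equal(analytic_volume(sp), 2 * 4 / 3 * pi * 1000 + pi * 5)
  # gaps -> 0 and thin connector: sum of sphere volumes
  sp0 <- nucleus_spec(c(8, 12, 9), gap_lengths = c(0, 0),
                      connector_radius = 1e-6)
  expect_equal(analytic_volume(sp0), sum(4 / 3 * pi * c(8, 12, 9)^3),
               tolerance = 1e-9)
})

test_that("analytic volume is additive and invariant under node relabeling", {
  sp <- nucleus_spec(c(9, 14, 11), c(4, 7), connector_radius = 1.2)
  parts <- sum(4 / 3 * pi * sp$node_radii^3) +
    sum(pi * 1.2^2 * sp$gap_lengths)
  expect_equal(analytic_volume(sp), parts)
  rev_sp <- nucleus_spec(rev(sp$node_radii), rev(sp$gap_lengths), 1.2)
  expect_equal(analytic_volume(rev_sp), analytic_volume(sp))
})

test_that("invalid nucleus specs are rejected", {
  expect_error(nucleus_spec(c(10, -1), 5), "positive")
  expect_error(nucleus_spec(c(10, 10), c(5, 5)), "gap lengths")
  expect_error(nucleus_spec(c(10, 10), -1), "non-negative")
  expect_error(nucleus_spec(c(10, 10), 5, connector_radius = 10), "smaller")
  expect_error(nucleus_spec(c(10, 10), 5, connector_radius = 0), "positive")
})

test_that("rendered sphere silhouette is a digitized disc", {
  m <- render_silhouette(nucleus_spec(15), pixel_size = 0.5)
  # projection of a 15 um sphere at 0.5 um/px is a disc of radius 30 px
  expect_rel_error_lt(sum(m$raster), pi * 30^2, 0.02)
  # widest column reaches the full diameter
  expect_equal(max(colSums(m$raster)), 60, tolerance = 1)
})

test_that("two-node silhouette has exactly two local maxima of column height", {
  m <- render_silhouette(nucleus_spec(c(12, 12), 6, 1), pixel_size = 0.5)
  h <- colSums(m$raster)
  h <- h[h > 0]
  plateau <- rle(as.vector(h))
  v <- plateau$values
  n_max <- sum(vapply(seq_along(v), function(i) {
    left <- if (i == 1) -Inf else v[i - 1]
    right <- if (i == length(v)) -Inf else v[i + 1]
    v[i] > left && v[i] > right
  }, logical(1)))
  expect_identical(n_max, 2L)
})

test_that("halving pixel size quadruples the foreground pixel count", {
  sp <- nucleus_spec(c(14, 10), 8, 1)
  n1 <- sum(render_silhouette(sp, 1.0)$raster)
  n2 <- sum(render_silhouette(sp, 0.5)$raster)
  expect_rel_error_lt(n2, 4 * n1, 0.02)
})

test_that("silhouette area converges to the analytic area", {
  # a sphere digitizes with cleanly shrinking error
  sph <- nucleus_spec(15)
  errs <- vapply(c(1.0, 0.5, 0.25), function(s) {
    abs(sum(render_silhouette(sph, s)$raster) * s^2 - pi * 15^2) /
      (pi * 15^2)
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
  # a chain with connectors converges below 1% by 0.25 um/px
  sp <- nucleus_spec(c(15, 11), 9, 1)
  target <- analytic_silhouette_area(sp)
  chain_errs <- vapply(c(1.0, 0.5, 0.25), function(s) {
    abs(sum(render_silhouette(sp, s)$raster) * s^2 - target) / target
  }, numeric(1))
  expect_lt(max(chain_errs), 0.02)
  expect_lt(chain_errs[3], 0.01)
})

test_that("too-small rasters are rejected with the required extent", {
  expect_error(render_silhouette(nucleus_spec(15), 0.5, width_px = 30),
               "need at least")
})

test_that("simulated time courses honour their ground-truth contract", {
  sim <- simulate_timecourse(n_cells = 4, seed = 11)
  vb <- attr(sim, "baseline_volume_um3")
  for (cell in sim) {
    gt <- cell$ground_truth
    # peak fold change is exact in the noiseless ground truth
    expect_equal(max(gt$true_volume_um3) / vb, 1.35)
    # the volume maximum falls on the frame of minimum node count
    expect_identical(which.max(gt$true_volume_um3), which.min(gt$node_count))
    # node counts decline to 1 and recover
    expect_identical(min(gt$node_count), 1L)
    expect_identical(gt$node_count[1], 10L)
    expect_identical(gt$node_count[nrow(gt)], 10L)
  }
})

test_that("the simulator is deterministic given its seed", {
  a <- simulate_timecourse(n_cells = 3, seed = 42)
  b <- simulate_timecourse(n_cells = 3, seed = 42)
  expect_identical(a, b)
  c <- simulate_timecourse(n_cells = 3, seed = 43)
  expect_false(identical(a, c))
})

test_that("a noiseless single frame reproduces the baseline model", {
  sim <- simulate_timecourse(n_cells = 1, n_frames = 1, noise_sd = 0,
                             jitter_frames = 0, seed = 1)
  sp <- sim[[1]]$specs[[1]]
  base <- baseline_macronucleus()
  expect_equal(sp$node_radii, base$node_radii, tolerance = 1e-10)
  expect_equal(sp$gap_lengths, base$gap_lengths)
  expect_equal(analytic_volume(sp), analytic_volume(base), tolerance = 1e-10)
})

test_that("attenuated coalescence bottoms out at the requested node count", {
  sim <- simulate_timecourse(n_cells = 2, min_node_count = 5, seed = 9)
  for (cell in sim) {
    expect_identical(min(cell$ground_truth$node_count), 5L)
  }
})

test_that("puncta rendering is deterministic and backgrounds are exact", {
  a <- render_puncta_image(n_spots = 5, seed = 21)
  b <- render_puncta_image(n_spots = 5, seed = 21)
  expect_identical(a$signal, b$signal)
  expect_identical(attr(a, "ground_truth"), attr(b, "ground_truth"))
  # zero spots, zero noise: channel 1 is exactly the smooth background
  bg <- render_puncta_image(n_spots = 0, noise_sd = 0, seed = 1)
  gt <- attr(bg, "ground_truth")
  nc <- ncol(bg$signal)
  expected <- gt$background$base *
    (1 + gt$background$gain_x * (seq_len(nc) - 1) / (nc - 1))
  expect_equal(bg$signal[1, ], expected, tolerance = 1e-12)
  expect_true(all(apply(bg$signal, 2, function(col) length(unique(col)) == 1)))
})

test_that("all generated spots lie inside the cell ellipse", {
  img <- render_puncta_image(n_spots = 15, seed = 5)
  gt <- attr(img, "ground_truth")
  cell <- gt$cell
  d <- ((gt$spots$x_px - cell$cx_px) / cell$a_px)^2 +
       ((gt$spots$y_px - cell$cy_px) / cell$b_px)^2
  expect_true(all(d <= 1))
})
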