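make_tc <- function(counts, volumes = NULL, interval = 5) {
  data.frame(cell_id = "c1",
             time_min = (seq_along(counts) - 1) * interval,
             node_count = counts,
             total_volume_um3 = if (is.null(volumes)) rep(1, length(counts))
                                else volumes)
}

test_that("alignment puts T = 0 at the first minimum-node-count frame", {
  tc <- align_at_min_nodes(make_tc(c(8, 6, 2, 5)))
  expect_equal(tc$aligned_time_min, c(-10, -5, 0, 5))
  expect_equal(attr(tc, "t_min_nodes"), 10)
  # tie-break: first occurrence of the minimum
  tc2 <- align_at_min_nodes(make_tc(c(4, 1, 1, 6)))
  expect_equal(attr(tc2, "t_min_nodes"), 5)
  expect_equal(tc2$aligned_time_min[2], 0)
  # constant counts: align at first frame, warn
  expect_warning(tc3 <- align_at_min_nodes(make_tc(c(3, 3, 3))), "equal")
  expect_equal(attr(tc3, "t_min_nodes"), 0)
})

test_that("aggregation reduces to the cell's own curve for one cell", {
  tc <- align_at_min_nodes(make_tc(c(5, 2, 4), volumes = c(10, 30, 12)))
  curve <- aggregate_curves(tc, "total_volume_um3")
  expect_equal(curve$mean, c(10, 30, 12))
  expect_true(all(is.na(curve$ci95_halfwidth)))
})

test_that("aggregation pools cells with t-based confidence bands", {
  a <- align_at_min_nodes(make_tc(c(5, 2, 4), volumes = c(10, 30, 12)))
  b <- align_at_min_nodes(make_tc(c(6, 2, 3), volumes = c(10, 30, 12)))
  curve <- aggregate_curves(list(a, b), "total_volume_um3")
  expect_equal(curve$mean, c(10, 30, 12))
  expect_equal(curve$ci95_halfwidth, rep(0, 3))
  expect_equal(curve$n_cells, rep(2, 3))
  # a cell observed on a disjoint grid contributes no n<2 gridpoints
  c3 <- align_at_min_nodes(make_tc(c(9, 1), volumes = c(5, 50), interval = 3))
  curve2 <- aggregate_curves(list(a, b, c3), "total_volume_um3")
  expect_true(all(curve2$n_cells >= 2))
  # halfwidth formula is the t-quantile one
  d1 <- align_at_min_nodes(make_tc(c(5, 1), volumes = c(10, 20)))
  d2 <- align_at_min_nodes(make_tc(c(5, 1), volumes = c(14, 26)))
  curve3 <- aggregate_curves(list(d1, d2), "total_volume_um3")
  expect_equal(curve3$ci95_halfwidth[1],
               qt(0.975, 1) * sd(c(10, 14)) / sqrt(2))
})

test_that("coalescence is three nodes or fewer, monotonically", {
  expect_true(classify_coalesced(3))
  expect_false(classify_coalesced(4))
  expect_true(classify_coalesced(1))
  counts <- 0:12
  cls <- classify_coalesced(counts)
  # monotone: once TRUE at count k, TRUE for every smaller count
  expect_true(all(diff(as.integer(cls)) <= 0))
  expect_identical(which(cls), 1:4)  # counts 0..3
})

test_that("coalescence fraction counts cells ever coalesced by a time", {
  cells <- lapply(1:12, function(i) {
    make_tc(if (i <= 10) c(8, 5, 2, 6) else c(8, 7, 6, 6))
  })
  expect_equal(coalescence_fraction(cells, by_time = 15), 100 * 10 / 12)
  expect_equal(coalescence_fraction(cells, by_time = 5), 0)
  all_coal <- lapply(1:5, function(i) make_tc(c(4, 2, 1)))
  expect_equal(coalescence_fraction(all_coal, by_time = 10), 100)
})

test_that("node count difference spans the observation window", {
  tc <- make_tc(c(9, 7, 3, 5), interval = 15)
  expect_identical(node_count_difference(tc, window_min = c(0, 45)), 6L)
  flat <- make_tc(c(4, 4, 4), interval = 15)
  expect_identical(node_count_difference(flat, window_min = c(0, 30)), 0L)
  expect_error(node_count_difference(tc, window_min = c(500, 600)),
               "at least 2 frames")
})

test_that("control cohorts show larger node-count swings than attenuated ones", {
  ctrl <- simulate_timecourse(n_cells = 6, seed = 7)
  rnai <- simulate_timecourse(n_cells = 6, min_node_count = 5, seed = 7)
  window <- c(0, 120)
  diff_of <- function(sim) {
    mean(vapply(sim, function(cell) {
      node_count_difference(cell$ground_truth, window_min = window)
    }, integer(1)))
  }
  expect_gt(diff_of(ctrl), diff_of(rnai))
})

test_that("per-cell volume test compares extreme-node-count frames", {
  # identical volumes in both groups: p = 1 by convention
  tc <- make_tc(c(8, 8, 1, 1), volumes = c(5, 5, 5, 5))
  expect_warning(res <- per_cell_volume_test(tc), "zero variance")
  expect_equal(res$p_value, 1)
  # insufficient frames at an extreme: no result
  tc2 <- make_tc(c(8, 5, 1, 1), volumes = c(5, 6, 9, 9.5))
  expect_message(res2 <- per_cell_volume_test(tc2), "insufficient")
  expect_null(res2)
  # a clear volume increase is detected
  tc3 <- make_tc(c(8, 8, 8, 1, 1, 1),
                 volumes = c(100, 102, 99, 135, 133, 136))
  res3 <- per_cell_volume_test(tc3)
  expect_lt(res3$p_value, 0.01)
  expect_gt(res3$statistic, 0)  # oriented as coalesced minus baseline
})

test_that("flat cells produce uniform p-values (type-I calibration)", {
  # volumes fluctuate around a constant mean; p should be U[0,1]
  set.seed(101)
  n_rep <- 500
  pvals <- vapply(seq_len(n_rep), function(i) {
    counts <- c(rep(8L, 6), rep(1L, 6))
    vols <- 114000 * (1 + rnorm(12, 0, 0.05))
    per_cell_volume_test(make_tc(counts, volumes = vols))$p_value
  }, numeric(1))
  ks <- suppressWarnings(ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
  expect_lt(mean(pvals < 0.05), 0.10)
})

test_that("simulated cohorts recover their construction end to end", {
  # low-measurement-noise regime: the per-cell volume argmax cannot drift
  # more than one frame from the alignment event
  sim <- simulate_timecourse(n_cells = 5, noise_sd = 0.02, seed = 3)
  meas <- measure_cohort(sim, pixel_size = 1)
  cells <- split(meas, meas$cell_id)
  aligned <- lapply(cells, align_at_min_nodes)
  for (tc in aligned) {
    t_peak <- tc$aligned_time_min[which.max(tc$total_volume_um3)]
    expect_lte(abs(t_peak), 5)
  }
  # volume per node spikes at coalescence; at study-level noise the
  # aggregate curve still peaks on the alignment event
  sim2 <- simulate_timecourse(n_cells = 5, seed = 3)
  cells2 <- split(measure_cohort(sim2, pixel_size = 1), ~ cell_id)
  aligned2 <- lapply(cells2, align_at_min_nodes)
  vpn <- aggregate_curves(aligned2, "volume_per_node_um3")
  expect_equal(vpn$aligned_time_min[which.max(vpn$mean)], 0)
  vol <- aggregate_curves(aligned2, "total_volume_um3")
  expect_equal(vol$aligned_time_min[which.max(vol$mean)], 0)
})
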