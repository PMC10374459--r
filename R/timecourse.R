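#' Align a time course at the minimum node count
#'
#' Shifts a per-cell measurement table so that `aligned_time_min = 0` at the
#' first frame attaining the cell's minimum node count (first occurrence is
#' the tie-break: the time at which the cell reached its minimum). All
#' macronuclear cycles are averaged on this event-aligned clock.
#'
#' @param timecourse Data.frame with at least `time_min` and `node_count`
#'   columns (one cell).
#' @return The input with an added `aligned_time_min` column and attribute
#'   `t_min_nodes`; class `"aligned_timecourse"`. If every node count is
#'   equal, alignment falls back to the first frame with a warning.
#' @export
align_at_min_nodes <- function(timecourse) {
  stopifnot(is.data.frame(timecourse),
            all(c("time_min", "node_count") %in% names(timecourse)))
  tc <- timecourse[order(timecourse$time_min), , drop = FALSE]
  if (nrow(tc) < 2) stop("need at least 2 frames to align")
  if (length(unique(tc$node_count)) == 1) {
    warning("all node counts equal; aligning at the first frame")
  }
  t0 <- tc$time_min[which.min(tc$node_count)]
  tc$aligned_time_min <- tc$time_min - t0
  attr(tc, "t_min_nodes") <- t0
  class(tc) <- c("aligned_timecourse", class(tc))
  tc
}

#' Aggregate aligned time courses into a mean curve with 95% CI band
#'
#' Averages a quantity over cells at each observed aligned frame time (no
#' interpolation: all cells share the frame interval, so aligned times fall
#' on a common grid). The confidence halfwidth uses the t-distribution,
#' `qt(0.975, n - 1) * sd / sqrt(n)`, appropriate for the ~10-cell cohorts
#' involved. Gridpoints observed in fewer than 2 cells are omitted.
#'
#' @param aligned_cells List of [align_at_min_nodes()] results (or a single
#'   one, for which the curve is the cell's own values with no CI).
#' @param value Name of the column to aggregate (e.g.
#'   `"volume_per_node_um3"`).
#' @return Data.frame `aligned_time_min`, `mean`, `ci95_halfwidth`,
#'   `n_cells`. For a single cell all gridpoints are kept with
#'   `ci95_halfwidth = NA`.
#' @export
aggregate_curves <- function(aligned_cells, value = "volume_per_node_um3") {
  if (is.data.frame(aligned_cells)) aligned_cells <- list(aligned_cells)
  if (length(aligned_cells) == 0) stop("no cells to aggregate")
  rows <- lapply(aligned_cells, function(tc) {
    stopifnot(value %in% names(tc))
    data.frame(aligned_time_min = tc$aligned_time_min, value = tc[[value]])
  })
  d <- do.call(rbind, rows)
  d <- d[is.finite(d$value), , drop = FALSE]
  grid <- sort(unique(d$aligned_time_min))
  out <- do.call(rbind, lapply(grid, function(g) {
    v <- d$value[d$aligned_time_min == g]
    n <- length(v)
    hw <- if (n >= 2) stats::qt(0.975, n - 1) * stats::sd(v) / sqrt(n)
          else NA_real_
    data.frame(aligned_time_min = g, mean = mean(v), ci95_halfwidth = hw,
               n_cells = n)
  }))
  if (length(aligned_cells) > 1) {
    out <- out[out$n_cells >= 2, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Is a macronucleus coalesced at this node count?
#'
#' Coalescence is defined operationally as having 3 nodes or fewer.
#'
#' @param node_count Integer vector, `>= 0`.
#' @param threshold Node-count threshold (default 3).
#' @return Logical vector.
#' @export
classify_coalesced <- function(node_count, threshold = 3) {
  stopifnot(all(node_count >= 0))
  node_count <= threshold
}

#' Fraction of cells that have coalesced by a given time
#'
#' A cell counts as coalesced at time `by_time` if any frame at or before
#' `by_time` is coalesced per [classify_coalesced()].
#'
#' @param cells List of per-cell data.frames with `time_min` and
#'   `node_count`.
#' @param by_time Time (min).
#' @param threshold Coalescence node-count threshold (default 3).
#' @return Percentage in `[0, 100]`.
#' @export
coalescence_fraction <- function(cells, by_time, threshold = 3) {
  if (is.data.frame(cells)) cells <- split(cells, cells$cell_id)
  hits <- vapply(cells, function(tc) {
    any(classify_coalesced(tc$node_count[tc$time_min <= by_time], threshold))
  }, logical(1))
  100 * mean(hits)
}

#' Node-count range within an observation window
#'
#' The difference between the largest and the smallest node count observed
#' for one cell within the window (default 270-480 min post shock, i.e.
#' 4.5-8 h), the per-cell summary used to compare coalescence extent between
#' treatment groups.
#'
#' @param timecourse Per-cell data.frame with `time_min`, `node_count`.
#' @param window_min Two-element window in minutes (default `c(270, 480)`).
#' @return Integer, max minus min node count in the window.
#' @export
node_count_difference <- function(timecourse, window_min = c(270, 480)) {
  sel <- timecourse$time_min >= window_min[1] &
         timecourse$time_min <= window_min[2]
  if (sum(sel) < 2) {
    stop("need at least 2 frames within the window [",
         window_min[1], ", ", window_min[2], "] min")
  }
  counts <- timecourse$node_count[sel]
  as.integer(max(counts) - min(counts))
}

#' Per-cell test for a volume increase at coalescence
#'
#' Welch's two-tailed t-test comparing total volumes measured at frames
#' attaining the cell's maximum node count against frames attaining its
#' minimum node count (strict equality to the extreme counts). This is the
#' per-cell significance test behind the "fraction of cells with a
#' significant volume increase" summary.
#'
#' @param timecourse Per-cell data.frame with `node_count` and
#'   `total_volume_um3`.
#' @return A `stat_result`, or `NULL` (with a message) when either group has
#'   fewer than 2 frames.
#' @export
per_cell_volume_test <- function(timecourse) {
  stopifnot(all(c("node_count", "total_volume_um3") %in% names(timecourse)))
  nmax <- max(timecourse$node_count)
  nmin <- min(timecourse$node_count)
  v_max_nodes <- timecourse$total_volume_um3[timecourse$node_count == nmax]
  v_min_nodes <- timecourse$total_volume_um3[timecourse$node_count == nmin]
  if (length(v_max_nodes) < 2 || length(v_min_nodes) < 2) {
    message("insufficient frames at the extreme node counts (",
            length(v_max_nodes), " at max, ", length(v_min_nodes),
            " at min); no test performed")
    return(NULL)
  }
  # mean1 = volumes at minimum node count (coalesced), so t > 0 indicates
  # the volume increase
  welch_t(v_min_nodes, v_max_nodes, tails = "two")
}
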