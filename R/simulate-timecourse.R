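#' Default baseline macronucleus for simulations
#'
#' Ten nodes of 14 um radius joined by 13 um gaps with 0.75 um connectors:
#' a ~397 um moniliform chain whose closed-form volume (~115,000 um^3)
#' matches the scale of resting macronuclear volumes.
#'
#' @return A [nucleus_spec()].
#' @export
baseline_macronucleus <- function() {
  nucleus_spec(node_radii = rep(14, 10), gap_lengths = rep(13, 9),
               connector_radius = 0.75)
}

#' Simulate a cohort of macronuclear coalescence cycles
#'
#' Generates per-frame beads-on-a-string models for `n_cells` cells
#' undergoing one shape-change cycle, with full ground truth. Each cell
#' follows the same canonical trajectory (time-shifted by a small per-cell
#' jitter):
#'
#' * node count holds at the baseline count, declines stepwise to 1 at the
#'   cell's coalescence time, stays coalesced for `coalesced_duration`
#'   minutes, then renodulates back to the baseline count;
#' * true total volume follows a piecewise-linear peak, symmetric about the
#'   coalescence time, of height `peak_fold_change` times baseline and
#'   half-width `peak_halfwidth`, so the volume maximum falls exactly on the
#'   first minimum-node-count frame (the event used for time alignment).
#'
#' At each frame the target volume is realised as `n` equal spheres plus
#' connectors, and all radii are then scaled by a shared lognormal factor so
#' that the frame's rendered volume carries multiplicative measurement noise
#' with standard deviation `noise_sd` (the noise is applied to radii as
#' `exp(eps/3)` so that it acts with sd `noise_sd` on the volume scale;
#' lognormal form keeps radii positive). The ground-truth table records the
#' noiseless trajectory.
#'
#' All randomness is drawn from the single integer `seed`; the same seed
#' reproduces the cohort exactly.
#'
#' @param n_cells Number of cells (default 11).
#' @param baseline_spec Baseline [nucleus_spec()]; default
#'   [baseline_macronucleus()].
#' @param peak_fold_change Peak true volume / baseline volume, `>= 1`
#'   (default 1.35).
#' @param coalescence_time Nominal time of full coalescence (min post shock
#'   within the simulated window; default 60).
#' @param n_frames Frames per cell (default 25).
#' @param frame_interval Minutes between frames (default 5).
#' @param noise_sd Multiplicative measurement noise sd on the volume scale
#'   (default 0.05).
#' @param peak_halfwidth Half-width of the volume peak (min, default 45).
#' @param coalesced_duration Minutes spent at 1 node (default 20).
#' @param renodulation_duration Minutes to climb back to the baseline node
#'   count (default 30).
#' @param jitter_frames Per-cell coalescence-time jitter, uniform on
#'   `-jitter_frames:jitter_frames` frames (default 1).
#' @param min_node_count Node count reached at coalescence (default 1).
#'   Values above 1 emulate attenuated coalescence, as seen when the
#'   shape-change machinery is knocked down: the node count bottoms out
#'   higher, so the per-cell node-count range shrinks.
#' @param seed Integer seed (required).
#' @return Object of class `"coalescence_cohort"`: a list of cells, each with
#'   `cell_id`, `t_coalescence`, `specs` (list of per-frame
#'   [nucleus_spec()]s) and `ground_truth` (data.frame `time_min`,
#'   `node_count`, `true_volume_um3`); plus cohort-level attributes
#'   `peak_fold_change`, `coalescence_time`, `frame_interval`.
#' @export
simulate_timecourse <- function(n_cells = 11,
                                baseline_spec = baseline_macronucleus(),
                                peak_fold_change = 1.35,
                                coalescence_time = 60,
                                n_frames = 25,
                                frame_interval = 5,
                                noise_sd = 0.05,
                                peak_halfwidth = 45,
                                coalesced_duration = 20,
                                renodulation_duration = 30,
                                jitter_frames = 1,
                                min_node_count = 1,
                                seed) {
  stopifnot(inherits(baseline_spec, "nucleus_spec"))
  if (peak_fold_change < 1) stop("peak_fold_change must be >= 1")
  if (missing(seed)) stop("a seed is required for reproducible simulation")
  set.seed(as.integer(seed))
  n0 <- length(baseline_spec$node_radii)
  vb <- analytic_volume(baseline_spec)
  gap <- if (n0 > 1) mean(baseline_spec$gap_lengths) else 13
  rc <- baseline_spec$connector_radius
  times <- (seq_len(n_frames) - 1) * frame_interval
  sdlog <- sqrt(log(1 + noise_sd^2))

  cells <- lapply(seq_len(n_cells), function(ci) {
    tc <- coalescence_time
    if (jitter_frames > 0) {
      tc <- tc + sample(seq(-jitter_frames, jitter_frames), 1) * frame_interval
    }
    nodes <- node_count_schedule(times, n0, tc, peak_halfwidth,
                                 coalesced_duration, renodulation_duration,
                                 n_min = min_node_count)
    vols <- vb * (1 + (peak_fold_change - 1) *
                    pmax(0, 1 - abs(times - tc) / peak_halfwidth))
    specs <- vector("list", n_frames)
    for (f in seq_len(n_frames)) {
      n <- nodes[f]
      v_conn <- if (n > 1) (n - 1) * pi * rc^2 * gap else 0
      r <- ((vols[f] - v_conn) * 3 / (4 * pi * n))^(1 / 3)
      noise <- exp(stats::rnorm(1, 0, sdlog) / 3)
      specs[[f]] <- nucleus_spec(
        node_radii = rep(r * noise, n),
        gap_lengths = rep(gap, max(0, n - 1)),
        connector_radius = rc
      )
    }
    list(cell_id = sprintf("cell%02d", ci),
         t_coalescence = tc,
         specs = specs,
         ground_truth = data.frame(time_min = times, node_count = nodes,
                                   true_volume_um3 = vols))
  })
  structure(cells,
            class = "coalescence_cohort",
            peak_fold_change = peak_fold_change,
            coalescence_time = coalescence_time,
            frame_interval = frame_interval,
            noise_sd = noise_sd,
            baseline_volume_um3 = vb,
            seed = as.integer(seed))
}

#' Canonical node-count trajectory
#'
#' Baseline plateau, stepwise decline reaching exactly `n_min` at `tc`
#' (counts are clamped to `>= n_min + 1` before `tc` so the first minimum
#' falls on `tc`), a coalesced plateau, then a stepwise climb back to `n0`.
#'
#' @keywords internal
node_count_schedule <- function(times, n0, tc, decline_duration,
                                coalesced_duration, renodulation_duration,
                                n_min = 1) {
  n_min <- as.integer(max(1, min(n_min, n0)))
  t_decline <- tc - decline_duration
  t_rise <- tc + coalesced_duration
  vapply(times, function(t) {
    if (t <= t_decline) return(as.integer(n0))
    if (t < tc) {
      n <- round(n0 + (n_min - n0) * (t - t_decline) / (tc - t_decline))
      return(as.integer(min(n0, max(min(n_min + 1, n0), n))))
    }
    if (t <= t_rise) return(n_min)
    if (t < t_rise + renodulation_duration) {
      n <- round(n_min + (n0 - n_min) * (t - t_rise) / renodulation_duration)
      return(as.integer(max(n_min, min(n0, n))))
    }
    as.integer(n0)
  }, integer(1))
}

#' @export
print.coalescence_cohort <- function(x, ...) {
  cat(sprintf(
    "<coalescence_cohort> %d cells x %d frames (%g min interval), peak fold change %.2f, seed %d\n",
    length(x), nrow(x[[1]]$ground_truth), attr(x, "frame_interval"),
    attr(x, "peak_fold_change"), attr(x, "seed")))
  invisible(x)
}

#' Measure a simulated cohort through the silhouette pipeline
#'
#' Renders every frame of every cell at the requested resolution, estimates
#' total volume with the stack-of-cylinders model, and assembles the per-cell
#' measurement table used by the time-course analyses. Node counts can come
#' from the simulator's ground truth (the analogue of the original visually
#' counted input) or be re-measured by watershed segmentation.
#'
#' @param cohort A [simulate_timecourse()] result.
#' @param pixel_size Rendering/measurement resolution (um/px, default 1).
#' @param count_method `"truth"` (default) or `"watershed"`.
#' @param min_seed_depth_um Watershed seed depth when re-counting nodes.
#' @return A data.frame of measurements: `cell_id`, `time_min`,
#'   `node_count`, `total_volume_um3`, `volume_per_node_um3`.
#' @export
measure_cohort <- function(cohort, pixel_size = 1,
                           count_method = c("truth", "watershed"),
                           min_seed_depth_um = 2) {
  stopifnot(inherits(cohort, "coalescence_cohort"))
  count_method <- match.arg(count_method)
  out <- lapply(cohort, function(cell) {
    vol <- numeric(length(cell$specs))
    cnt <- integer(length(cell$specs))
    for (f in seq_along(cell$specs)) {
      m <- render_silhouette(cell$specs[[f]], pixel_size = pixel_size)
      vol[f] <- total_volume(m)
      cnt[f] <- if (count_method == "truth") {
        cell$ground_truth$node_count[f]
      } else {
        count_nodes(segment_nodes(m, min_seed_depth_um = min_seed_depth_um))
      }
    }
    data.frame(cell_id = cell$cell_id,
               time_min = cell$ground_truth$time_min,
               node_count = cnt,
               total_volume_um3 = vol,
               volume_per_node_um3 = ifelse(cnt > 0, vol / cnt, NA_real_))
  })
  do.call(rbind, out)
}
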