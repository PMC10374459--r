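# stentorquant

Quantification of the macronuclear shape-change cycle in the giant ciliate
*Stentor coeruleus*.

The *Stentor* macronucleus is a ~400 µm "string of beads": ~30 µm nodes
joined by 1–2 µm strands under one nuclear envelope. During regeneration
the chain coalesces into a single mass, elongates, and renodulates — and
its total volume transiently rises by roughly a third while it does so.
The observational record of this cycle is brightfield imaging of compressed
live cells: per timepoint, a manually traced 2D binary silhouette of the
macronucleus plus a visually counted node number. This package is for
researchers who need to turn such records into calibrated volumes, node
morphometrics, event-aligned population curves and significance tests —
and to validate every step against synthetic data with known ground truth.

## What it computes

**Volume from a silhouette** (`total_volume`, `chord_profile`,
`volume_of_revolution`): with the macronuclear midline horizontal and
assuming rotational symmetry of the nodes about it, each raster column of
width *s* is a cylinder of radius *h(x)·s/2*, giving

> V = Σₓ π (h(x)·s/2)² s

where *h(x)* is the column's foreground-pixel chord. Components are
labelled with 8-connectivity and auto-rotated so their principal axis is
horizontal before measurement.

**Node segmentation and morphometrics** (`segment_nodes`, `count_nodes`,
`measure_nodes`): watershed on the Euclidean distance transform with
h-maxima seed suppression at the connector scale (2 µm) splits the chain
at its constrictions; per node the package reports area, chain-code
perimeter, circularity 4πA/P² (capped at 1), equivalent diameter, and the
rotational-symmetry control ratio (`symmetry_ratio`).

**Event-aligned time courses** (`align_at_min_nodes`, `aggregate_curves`,
`per_cell_volume_test`, `coalescence_fraction`, `node_count_difference`):
per-cell curves are aligned at the first frame of minimum node count and
averaged with t-based 95% confidence bands; coalescence is ≤ 3 nodes; the
per-cell volume change is tested by Welch's t between frames at the
extreme node counts.

**Statistics battery** (`welch_t`, `welch_t_summary`, `ks_2sample`,
`mann_whitney_u`, `mean_ci95`): Welch's t from raw data or the six summary
numbers (Welch–Satterthwaite df), two-sample Kolmogorov–Smirnov with the
small-sample-corrected asymptotic p, Mann–Whitney U with an exact
small-sample null, and t-based confidence intervals.

**Puncta quantification** (`segment_puncta`, `cell_mask_from_stentorin`,
`rolling_ball_subtract`, `moments_threshold`): whole-cell mean intensity
inside an autofluorescence-derived mask, and spot segmentation via
rolling-ball background subtraction → Gaussian blur → moment-preserving
threshold → watershed, with a 0.75–10 µm equivalent-diameter gate and an
optional mean-intensity floor (e.g. 2000 a.u.).

**Synthetic ground truth** (`nucleus_spec`, `render_silhouette`,
`simulate_timecourse`, `render_puncta_image`): beads-on-a-string models
with closed-form volume (spheres plus connector cylinders), full
coalescence-cycle cohorts with exact ground-truth trajectories, and
two-channel puncta images with per-spot ground truth — all deterministic
given one integer seed.

## A worked example

```r
library(stentorquant)

# an 11-cell simulated cohort, measured end to end at 1 um/px
sim   <- simulate_timecourse(n_cells = 11, seed = 1)
meas  <- measure_cohort(sim, pixel_size = 1)
cells <- split(meas, meas$cell_id)

# event-aligned aggregate volume curve and its peak fold change
aligned <- lapply(cells, align_at_min_nodes)
curve   <- aggregate_curves(aligned, "total_volume_um3")
max(curve$mean) / mean(curve$mean[curve$aligned_time_min <= -45])
#> [1] 1.325733

# per-cell Welch tests of volume at minimum- vs maximum-node-count frames
sapply(cells, function(tc) per_cell_volume_test(tc)$p_value)
#>       cell01       cell02       cell03       cell04       cell05       cell06
#> 3.273371e-06 6.473338e-04 4.628999e-04 2.262276e-03 3.385989e-05 1.047369e-04
#>       cell07       cell08       cell09       cell10       cell11
#> 2.419546e-03 2.796380e-03 6.409933e-04 1.400514e-03 8.446306e-04
```

The cohort was simulated with a 1.35 peak volume fold change and 5%
measurement noise: the aggregate curve recovers the fold change within 2%
here, and all 11 cells individually test significant at p < 0.02.

The pooled summary-statistic pathway takes published group summaries
directly — volumes at maximum node count (n = 137, 114,000 ± 43,000 µm³)
versus at minimum node count (n = 136, 154,000 ± 65,000 µm³):

```r
welch_t_summary(137, 114000, 43000, 136, 154000, 65000)
#> Welch's t-test (two-tailed)
#>   statistic = -5.99205, df = 233.9, p = 7.77e-09
```

a volume increase significant far below the 10⁻⁴ level.

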