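---
title: "Quantifying the Stentor macronuclear shape-change cycle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the Stentor macronuclear shape-change cycle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stentorquant)
```

## The measurement problem

The macronucleus of *Stentor coeruleus* is a moniliform chain, roughly
400 µm long, of ~30 µm nodes joined by 1–2 µm strands under a single
nuclear envelope. During regeneration (and division) the chain coalesces
into one compact mass, elongates, and renodulates. Because long-term
fluorescence imaging of these pigmented, photosensitive, fast-moving cells
is impractical, the cycle is observed in brightfield through a compression
chamber, and the quantitative record of each timepoint is a manually traced
**2D binary silhouette** of the macronucleus plus a visually counted number
of nodes. This package turns those silhouettes into volumes, node
morphometrics, event-aligned population curves and significance tests, and
provides a synthetic-data generator so that every stage can be validated
against known ground truth.

## Volume from a silhouette: the stack-of-cylinders model

With the macronuclear midline horizontal, each raster column of width
$s$ (the pixel size in µm) is treated as a cylinder whose radius is half
the silhouette's chord in that column, assuming rotational symmetry of the
nodes about the midline:

$$V \;=\; \sum_x \pi \left( \frac{h(x)\,s}{2} \right)^{\!2} s ,$$

where $h(x)$ is the chord height in pixels. Rotational symmetry is a
measured property of the real nodes (diameters re-measured after a cell
rotates 90° about its long axis stay within ~10% of each other;
`symmetry_ratio()` implements that control), and the compression chamber
(~115 µm deep) is far taller than a node, so the silhouette is not an
artifact of flattening.

Conventions the package fixes where the workflow left a choice:

* **Chord height is the column's foreground-pixel count**, not the
  max-minus-min extent. The two coincide for convex column sections, and
  counting is robust to single-pixel tracing holes. This is asserted as
  this package's definition, not as a claim about any other implementation.
* **Components are auto-oriented**: each 8-connected component is rotated
  about its centroid so that its second-moment principal axis is
  horizontal (bilinear interpolation, re-binarized at 0.5), replacing the
  manual re-arrangement of nodes. Rotations below 5° are skipped; rotation
  changes the area by well under 2% at working resolutions.
* **8-connectivity** is used for components, because traced outlines touch
  diagonally. Thin connectors typically merge all nodes into one
  component; that is correct for a whole-macronucleus volume, and the
  estimate is additive over whatever components exist.
* **Isotropic pixels are required**; anisotropic input is rejected rather
  than silently resampled.

At 0.5 µm/px a rendered 15 µm sphere is recovered within 2% of
$\tfrac43\pi 15^3$, and at 0.25 µm/px random beads-on-a-string models are
recovered within 3% of their closed-form volume; the error decreases with
pixel size.

## Synthetic ground truth

`nucleus_spec()` describes a chain of spherical nodes on a straight
horizontal axis, consecutive nodes joined by a cylindrical connector that
spans exactly the gap between the sphere surfaces. Because the connector
meets the spheres at their surfaces, node and connector volumes are
disjoint and the total is closed-form:

$$V = \sum_i \tfrac43 \pi r_i^3 + \sum_j \pi r_c^2 g_j ,$$

which is what makes the model useful as an independent oracle — no
sphere–cylinder intersection terms. `render_silhouette()` rasterizes the
axial cross-section with a pixel-centre-in-region rule, which is
unambiguous and converges to the analytic cross-section area as the pixel
size shrinks.

The default baseline model is 10 nodes of 14 µm radius with 13 µm gaps and
0.75 µm connectors: a ~397 µm chain of ~115,000 µm³, matching the scale of
resting macronuclei. A single connector contributes ~23 µm³ — five orders
of magnitude below a node — so the choice of connector radius is
immaterial to volume but sets the constriction depth that node
segmentation must resolve.

### Simulated coalescence cycles

`simulate_timecourse()` generates cohorts on a 5-minute frame clock (the
live-imaging cadence). Each cell follows a canonical trajectory tied to
its own coalescence time $t_c$ (jittered by ±1 frame across cells):

* **node count**: baseline plateau, stepwise decline starting when the
  volume starts rising, reaching the minimum (1 node; higher for
  attenuated-coalescence cohorts via `min_node_count`) exactly at $t_c$,
  a 20-minute coalesced plateau, then a stepwise climb back;
* **true volume**: a piecewise-linear peak, symmetric about $t_c$, of
  height `peak_fold_change` (default 1.35, the ratio implied by pooled
  volumes of ~154,000 vs ~114,000 µm³) and half-width 45 min. The
  functional form of the real peak is not known beyond being narrow and
  symmetric, so the simplest shape with those properties is used.

Placing the volume maximum on the *first* minimum-node-count frame makes
the ground truth satisfy, by construction, the property the analysis
exploits: aligning cells at minimum node count aligns their volume peaks.

**Measurement noise.** Real volumes inherit tracing and focus error at the
whole-silhouette level, so noise is applied per frame as one shared
lognormal factor on the radii, scaled as $\exp(\varepsilon/3)$ so that it
acts with standard deviation `noise_sd` on the *volume* scale (default
0.05, i.e. 5% volume noise — a frame-to-frame variability the source data
do not quantify, chosen here as a realistic tracing-error magnitude and
used consistently everywhere). The lognormal form keeps radii positive.
The ground-truth table always records the noiseless trajectory, so
`max(true volume)/baseline` equals `peak_fold_change` exactly.

Simulated frames realize each target volume as *equal-radius* nodes; real
macronuclei have unequal nodes, uneven gaps and curved axes. Passing tests
therefore validate the estimator and statistics under the model's
geometry, not the tracing of real brightfield images, which remains
manual.

## Node counting and morphometrics

`segment_nodes()` automates what was done visually: the Euclidean distance
transform of the silhouette is flooded by a seeded watershed in which
regional maxima shallower than `min_seed_depth_um` (default 2 µm, the
connector scale) are suppressed. Nodes (~14 µm deep in the distance map)
and connectors (~1 µm) are two orders apart in depth, so counts are exact
for rendered chains of 1–15 nodes even with 3 µm gaps. The labels
partition the foreground exactly, so per-node areas sum to the silhouette
area.

**Circularity** is the classical $4\pi A / P^2$, capped at 1. The
perimeter estimator matters: naive pixel-edge counting gives $8R$ for a
disc and caps circularity near 0.62. The package measures the 8-connected
boundary chain through boundary-pixel centres with weights 1 (straight)
and $\sqrt2$ (diagonal), which scores a digitized disc of radius 30 px at
~0.91 and a digitized square at ~0.83 (ideal $\pi/4 \approx 0.785$).
Absolute circularities remain estimator-dependent — thresholding and
smoothing choices shift them by several hundredths — so only orderings and
within-study comparisons are meaningful, and regions under 5 px are
flagged unreliable and excluded from averages. Per-cell circularity is the
unweighted mean over that cell's reliable nodes, so a many-noded cell
cannot dominate a population average.

Node "diameter" defaults to the equivalent-area diameter
$2\sqrt{A/\pi}$; the maximum vertical chord is also reported, since the
original measurements did not pin down an estimator.

## Event-aligned time courses

Cells coalesce at different clock times, so curves are aligned at the
frame of **minimum node count** before averaging; ties break to the first
occurrence (the time the cell *reached* its minimum), which is
deterministic. Aggregation happens only at observed aligned frame times
(all cells share the 5-min interval; no interpolation), with t-based 95%
bands ($t_{0.975,\,n-1}\, s/\sqrt n$ — appropriate at ~11 cells, where the
normal quantile would undercover) and gridpoints seen in fewer than two
cells omitted.

Derived summaries follow the study's operational definitions: coalescence
is ≤ 3 nodes; the coalescence fraction counts cells ever coalesced by a
time; the node-count difference is max − min within a window (default
270–480 min, i.e. 4.5–8 h post shock). The per-cell volume test is a
two-tailed Welch test of total volume at frames *strictly at* the maximum
node count versus frames strictly at the minimum — whether the original
groups used strict equality or a tolerance band is not stated, and strict
equality is the reproducible choice. On simulated 11-cell cohorts at the
default conditions, 10 or 11 of 11 cells come out significant at
p < 0.02, and the aggregate volume curve recovers the 1.35 fold change
within 5%.

## The statistics battery

All tests are implemented from their definitions (base R supplies only the
distribution functions), with R's `t.test`, `ks.test` and `wilcox.test`
serving as independent cross-checks in the test suite:

* **Welch's t** — from raw samples or the six summary numbers (the two
  pathways agree to machine precision), Welch–Satterthwaite df, one- or
  two-tailed with an explicit direction parameter (one-tailed uses were
  reported without a stated direction, so the caller must choose). Tail
  probabilities are computed in log space so extreme statistics do not
  underflow. Two samples with zero variance and equal means return p = 1
  by convention, with a warning.
* **Two-sample Kolmogorov–Smirnov** — $D$ is the exact ECDF supremum; the
  p-value uses the asymptotic Kolmogorov series at
  $\lambda = (\sqrt{n_e} + 0.12 + 0.11/\sqrt{n_e})\,D$ with
  $n_e = n_1 n_2/(n_1+n_2)$, the standard small-sample correction.
* **Mann–Whitney U** — midrank ties; exact p from the count recursion
  (equivalent to full enumeration) when the data are tie-free and
  $n_1 n_2 \le 400$, beyond which exactness buys nothing at these sample
  sizes and the tie-corrected, continuity-corrected normal approximation
  takes over. $U$ is reported for sample 1 ($U = 0$ when all of sample 1
  lies below sample 2).
* **Mean ± 95% CI** — the t-based interval; coverage is verified by
  simulation (93–97% across 2000 draws).

Welch's type-I error at $\alpha = 0.05$ sits within [0.03, 0.07] over
1000 null simulations.

## Puncta quantification

The immunofluorescence pathway works on max-projected two-channel images.
Whole-cell intensity uses a mask from the stentorin autofluorescence
channel (moment-preserving threshold, largest component, holes filled);
intensities are first normalized to 1 s exposure so acquisitions are
comparable.

Spot quantification chains: **rolling-ball background subtraction →
Gaussian blur → moment-preserving (Tsai) threshold → watershed separation
→ size gate → optional intensity floor.** Numerical choices:

* The rolling ball is the classical non-flat grayscale opening with a
  ball-shaped element (edge-replicated borders). It reproduces a linear
  background exactly in the interior and removes features narrower than
  the ball. The radius (default 5 µm here, configurable) and the blur
  sigma (default 0.5 µm) were not recorded by the source workflow and are
  package defaults sized to 0.75–10 µm spots.
* The Tsai threshold preserves the first three histogram moments; the
  attainable tail fraction closest to the ideal one picks the bin (the
  standard p-tile rule), on a 256-bin histogram over the image's range.
  The exhaustive moment-error search lands in the same inter-mode valley.
* Watershed seeds are suppressed below half the minimum accepted spot
  diameter, so one spot does not shatter.
* The size gate keeps equivalent-circle **diameters** in [0.75, 10] µm —
  the bounds are length-valued, so a diameter (not area) reading is the
  defensible interpretation, and the bounds are configurable.
* The intensity floor (the study's value is 2000 a.u., motivated by
  peptide-block background always falling below that) is applied to the
  exposure-normalized mean intensity of the background-subtracted spot.
  Whether the original floor referred to raw camera counts or normalized
  units is not stated; normalized units are used because the floor is
  applied downstream of exposure normalization in this pipeline.

On seeded fixtures with spot separation > 3σ and SNR ≥ 5, recall and
precision are ≥ 95%, and the gates remove exactly the ground-truth
out-of-range spots.

## Problem sizes and determinism

Every stochastic stage hangs off one integer seed, and simulated cohorts
are byte-reproducible. The validation suite uses the study-scale problem
sizes: 11-cell cohorts of 25 frames at 5-min intervals measured at
1 µm/px (estimator bias at that resolution is sub-percent and cancels in
fold-change ratios), 20-seed replication for the stochastic recovery
checks, oracle comparisons at 0.25 µm/px, 1000 null simulations for
type-I calibration and 2000 for CI coverage.

## Known limitations

* Straight-axis geometry only: no curved-midline straightening
  (skeleton-based arc-length integration). Real traces were straightened
  manually upstream; strongly curved silhouettes will be mis-measured.
* No node tracking across frames; paired before/after diameter controls
  take their measurements as given input.
* Absolute circularity values are estimator-specific; compare only within
  one pipeline.
* The puncta generator draws isotropic Gaussian spots on a linear
  background — it does not emulate pigment-stripe texture, spectral
  bleed-through, or out-of-focus haze, so real-image performance must be
  validated separately.

## A worked example

```{r, eval = FALSE}
library(stentorquant)

# simulate and measure an 11-cell cohort
sim <- simulate_timecourse(n_cells = 11, seed = 1)
meas <- measure_cohort(sim, pixel_size = 1)

# align at minimum node count and aggregate
cells <- split(meas, meas$cell_id)
aligned <- lapply(cells, align_at_min_nodes)
curve <- aggregate_curves(aligned, "total_volume_um3")
max(curve$mean) / mean(curve$mean[curve$aligned_time_min <= -45])

# per-cell volume tests
sapply(cells, function(tc) per_cell_volume_test(tc)$p_value)

# the pooled summary-statistic test
welch_t_summary(137, 114000, 43000, 136, 154000, 65000)
```
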