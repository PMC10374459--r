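#' Segment macronuclear nodes by watershed on the distance transform
#'
#' Automates node identification on a binary silhouette: the Euclidean
#' distance transform of the foreground is flooded by a seeded watershed in
#' which regional maxima shallower than `min_seed_depth_um` are suppressed
#' (h-maxima style). Nodes (radius ~15 um) and connectors (~1 um) are far
#' apart in distance-transform depth, so the default depth of 2 um — the
#' connector scale — splits the chain at its constrictions without
#' oversegmenting single nodes.
#'
#' @param mask A [silhouette_mask()], or binary matrix plus `pixel_size`.
#' @param min_seed_depth_um Suppression depth for watershed seeds (um).
#' @param pixel_size Pixel size (um), required for bare matrices.
#' @return Integer label matrix; 0 = background, 1..k = nodes. The labels
#'   partition the foreground exactly.
#' @export
segment_nodes <- function(mask, min_seed_depth_um = 2, pixel_size = NULL) {
  if (inherits(mask, "silhouette_mask")) pixel_size <- mask$pixel_size
  if (is.null(pixel_size)) stop("pixel_size is required for a bare matrix")
  m <- as_mask_matrix(mask)
  if (sum(m) == 0) return(matrix(0L, nrow(m), ncol(m)))
  d <- EBImage::distmap(m)
  w <- EBImage::watershed(d, tolerance = min_seed_depth_um / pixel_size)
  matrix(as.integer(w), nrow = nrow(m))
}

#' Number of distinct nodes in a labelling
#'
#' @param labeled Integer label matrix from [segment_nodes()].
#' @return Count of distinct non-zero labels.
#' @export
count_nodes <- function(labeled) {
  length(setdiff(unique(as.vector(labeled)), 0L))
}

#' Chain-code boundary length of a binary region
#'
#' Perimeter estimated from the 8-connected boundary chain through boundary
#' pixel centres: straight steps count 1 pixel, diagonal steps sqrt(2). This
#' corrects the strong upward bias of naive pixel-edge counting (which gives
#' 8R for a disc of radius R and caps digitized-disc circularity near 0.62).
#' Only the outer contour is measured; interior holes do not contribute.
#'
#' @param region Binary matrix of a single connected region.
#' @return Perimeter in pixels (0 for regions too small to trace).
#' @keywords internal
region_perimeter_px <- function(region) {
  if (sum(region) < 2) return(0)
  oc <- EBImage::ocontour(region)
  if (length(oc) == 0) return(0)
  pts <- oc[[1]]
  if (nrow(pts) < 2) return(0)
  d <- rbind(diff(pts), pts[1, ] - pts[nrow(pts), ])
  steps <- abs(d[, 1]) + abs(d[, 2])
  sum(steps == 1) + sqrt(2) * sum(steps == 2)
}

#' Circularity of one labelled region
#'
#' The shape descriptor `4 * pi * area / perimeter^2`, capped at 1 (the value
#' for a perfect circle); elongated or jagged regions score lower. Perimeter
#' uses the chain-code estimator of [region_perimeter_px()]. Regions smaller
#' than 5 pixels cannot be measured reliably and return `NA`.
#'
#' @param region Binary matrix of a single region (or a label matrix plus
#'   `label`).
#' @param pixel_size Pixel size (um); circularity itself is dimensionless and
#'   calibration-independent, the argument is accepted for interface symmetry.
#' @param label Optional label to extract when `region` is a label matrix.
#' @return Circularity in `[0, 1]`, or `NA` for unreliable regions.
#' @export
node_circularity <- function(region, pixel_size = 1, label = NULL) {
  if (!is.null(label)) region <- matrix(as.integer(region == label),
                                        nrow = nrow(region))
  region <- matrix(as.integer(region != 0), nrow = nrow(region))
  a <- sum(region)
  if (a < 5) return(NA_real_)
  p <- region_perimeter_px(region)
  if (p <= 0) return(NA_real_)
  min(1, 4 * pi * a / p^2)
}

#' Per-node morphometric records
#'
#' Measures every labelled node: area, chain-code perimeter, circularity
#' (capped at 1), equivalent-area diameter `2 * sqrt(area / pi)`, the maximum
#' vertical chord, and the centroid. Nodes below 5 pixels are flagged
#' unreliable (`reliable = FALSE`) and are excluded from per-cell circularity
#' averages.
#'
#' @param labeled Integer label matrix from [segment_nodes()].
#' @param pixel_size Pixel size (um).
#' @param cell_id,frame Optional provenance columns.
#' @return A data.frame with one row per node: `cell_id`, `frame`, `label`,
#'   `area_um2`, `perimeter_um`, `circularity`, `eq_diameter_um`,
#'   `max_vertical_chord_um`, `centroid_x_px`, `centroid_y_px`, `reliable`.
#' @export
measure_nodes <- function(labeled, pixel_size, cell_id = NA_character_,
                          frame = NA_integer_) {
  labs <- setdiff(sort(unique(as.vector(labeled))), 0L)
  rows <- lapply(labs, function(l) {
    idx <- which(labeled == l, arr.ind = TRUE)
    npx <- nrow(idx)
    comp <- crop_component(labeled, l)
    per_px <- region_perimeter_px(comp)
    circ <- if (npx >= 5 && per_px > 0) min(1, 4 * pi * npx / per_px^2)
            else NA_real_
    data.frame(
      cell_id = cell_id, frame = frame, label = l,
      area_um2 = npx * pixel_size^2,
      perimeter_um = per_px * pixel_size,
      circularity = circ,
      eq_diameter_um = 2 * sqrt(npx * pixel_size^2 / pi),
      max_vertical_chord_um = max(table(idx[, 2])) * pixel_size,
      centroid_x_px = mean(idx[, 2]),
      centroid_y_px = mean(idx[, 1]),
      reliable = npx >= 5
    )
  })
  if (length(rows) == 0) {
    return(data.frame(cell_id = character(0), frame = integer(0),
                      label = integer(0), area_um2 = numeric(0),
                      perimeter_um = numeric(0), circularity = numeric(0),
                      eq_diameter_um = numeric(0),
                      max_vertical_chord_um = numeric(0),
                      centroid_x_px = numeric(0), centroid_y_px = numeric(0),
                      reliable = logical(0)))
  }
  do.call(rbind, rows)
}

#' Mean node circularity of one cell
#'
#' Unweighted mean over the reliable nodes of a single cell. Averaging within
#' the cell first ensures that, at the population level, cells with many
#' nodes do not overpower cells with fewer nodes.
#'
#' @param nodes Data.frame of node records ([measure_nodes()]) for one cell,
#'   or a numeric vector of circularities.
#' @return Mean circularity, or `NA` if no reliable node exists.
#' @export
mean_circularity_per_cell <- function(nodes) {
  circ <- if (is.data.frame(nodes)) {
    nodes$circularity[isTRUE_vec(nodes$reliable) & !is.na(nodes$circularity)]
  } else {
    nodes[!is.na(nodes)]
  }
  if (length(circ) == 0) return(NA_real_)
  mean(circ)
}

isTRUE_vec <- function(x) !is.na(x) & x

#' Rotational-symmetry ratio of a node
#'
#' Control for the rotational-symmetry assumption of the volume model: the
#' ratio of a node's diameter measured at two orientations 90 degrees apart
#' (e.g. before and after the swimming cell rotates about its long axis).
#' A node passes when the ratio deviates from 1 by at most `tolerance`
#' (default 10%).
#'
#' @param diameter_0deg,diameter_90deg Diameters (um), both `> 0`.
#' @param tolerance Maximum allowed `|ratio - 1|`.
#' @return List with `ratio` and logical `pass`.
#' @export
symmetry_ratio <- function(diameter_0deg, diameter_90deg, tolerance = 0.10) {
  if (!is.finite(diameter_0deg) || diameter_0deg <= 0 ||
      !is.finite(diameter_90deg) || diameter_90deg <= 0) {
    stop("both diameters must be positive")
  }
  ratio <- diameter_0deg / diameter_90deg
  list(ratio = ratio, pass = abs(ratio - 1) <= tolerance)
}
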