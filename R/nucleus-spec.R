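#' Parametric beads-on-a-string nucleus model
#'
#' Constructs the geometric model used throughout the package as synthetic
#' ground truth: a chain of spherical nodes on a common straight horizontal
#' axis, consecutive nodes joined by a cylindrical connector that spans the
#' axial gap between their surfaces. Because connectors attach exactly at the
#' sphere surfaces, node and connector volumes are disjoint and the total
#' volume has a closed form (see [analytic_volume()]).
#'
#' The default scale mirrors the Stentor coeruleus macronucleus: nodes of
#' roughly 30 um diameter joined by 1-2 um wide strands, forming a chain on
#' the order of 400 um.
#'
#' @param node_radii Numeric vector of node radii (um), all `> 0`.
#' @param gap_lengths Numeric vector of axial gaps between consecutive sphere
#'   surfaces (um), length `length(node_radii) - 1`, all `>= 0`.
#' @param connector_radius Radius of the connecting cylinders (um); must be
#'   positive and smaller than the smallest node radius.
#' @return An object of class `"nucleus_spec"`.
#' @examples
#' sp <- nucleus_spec(c(15, 15), gap_lengths = 5, connector_radius = 1)
#' analytic_volume(sp)
#' @export
nucleus_spec <- function(node_radii, gap_lengths = numeric(0),
                         connector_radius = 0.75) {
  node_radii <- as.numeric(node_radii)
  gap_lengths <- as.numeric(gap_lengths)
  n <- length(node_radii)
  if (n < 1L) stop("a nucleus_spec needs at least one node")
  if (any(!is.finite(node_radii)) || any(node_radii <= 0)) {
    stop("all node radii must be positive and finite")
  }
  if (length(gap_lengths) != n - 1L) {
    stop("need exactly ", n - 1L, " gap lengths for ", n, " nodes, got ",
         length(gap_lengths))
  }
  if (n > 1L && (any(!is.finite(gap_lengths)) || any(gap_lengths < 0))) {
    stop("all gap lengths must be non-negative and finite")
  }
  if (!is.finite(connector_radius) || connector_radius <= 0) {
    stop("connector_radius must be positive")
  }
  if (connector_radius >= min(node_radii)) {
    stop("connector_radius (", connector_radius,
         ") must be smaller than the smallest node radius (",
         min(node_radii), ")")
  }
  structure(
    list(node_radii = node_radii,
         gap_lengths = gap_lengths,
         connector_radius = connector_radius),
    class = "nucleus_spec"
  )
}

#' @export
print.nucleus_spec <- function(x, ...) {
  cat(sprintf(
    "<nucleus_spec> %d node(s), radii %s um, connector r = %g um\n",
    length(x$node_radii),
    paste(signif(x$node_radii, 4), collapse = ", "),
    x$connector_radius))
  cat(sprintf("  chain length %.1f um, analytic volume %.1f um^3\n",
              chain_length(x), analytic_volume(x)))
  invisible(x)
}

#' Axial positions of node centres
#'
#' Node 1 touches the axial origin (`x = 0`) with its left surface; each
#' subsequent centre follows after the preceding node's radius, the gap, and
#' its own radius.
#'
#' @param spec A [nucleus_spec()].
#' @return Numeric vector of centre x-coordinates (um).
#' @keywords internal
node_centers <- function(spec) {
  r <- spec$node_radii
  g <- spec$gap_lengths
  n <- length(r)
  centers <- numeric(n)
  centers[1] <- r[1]
  if (n > 1) {
    for (i in 2:n) centers[i] <- centers[i - 1] + r[i - 1] + g[i - 1] + r[i]
  }
  centers
}

#' Total axial extent of a nucleus model
#'
#' @param spec A [nucleus_spec()].
#' @return Chain length (um), `2 * sum(radii) + sum(gaps)`.
#' @export
chain_length <- function(spec) {
  stopifnot(inherits(spec, "nucleus_spec"))
  2 * sum(spec$node_radii) + sum(spec$gap_lengths)
}

#' Closed-form volume of a beads-on-a-string model
#'
#' Connectors span only the axial gap between sphere surfaces, so the total
#' volume is an exact disjoint sum of sphere and cylinder terms:
#' \deqn{V = \sum_i \tfrac{4}{3}\pi r_i^3 + \sum_j \pi r_c^2 g_j.}
#' This is the independent oracle against which the silhouette-based
#' volume-of-revolution estimator is validated.
#'
#' @param spec A [nucleus_spec()].
#' @return Volume in um^3.
#' @export
analytic_volume <- function(spec) {
  stopifnot(inherits(spec, "nucleus_spec"))
  sum(4 / 3 * pi * spec$node_radii^3) +
    sum(pi * spec$connector_radius^2 * spec$gap_lengths)
}
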