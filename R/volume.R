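#' Label connected components with 8-connectivity
#'
#' Traced outlines frequently touch only diagonally, so the package uses
#' 8-connectivity throughout. EBImage's labelling is 4-connected; labels that
#' touch along a diagonal are merged afterwards with a union-find pass.
#'
#' @param mask A [silhouette_mask()] or binary matrix.
#' @return Integer matrix of labels (0 = background, 1..k = components).
#' @export
label_components <- function(mask) {
  m <- as_mask_matrix(mask)
  lab <- EBImage::bwlabel(m)
  lab <- matrix(as.integer(lab), nrow = nrow(m))
  k <- max(lab)
  if (k < 2L) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  # diagonal neighbour pairs: (i, j)-(i+1, j+1) and (i+1, j)-(i, j+1)
  a1 <- lab[-nr, -nc]; b1 <- lab[-1, -1]
  a2 <- lab[-1, -nc];  b2 <- lab[-nr, -1]
  pairs <- rbind(
    cbind(as.vector(a1), as.vector(b1)),
    cbind(as.vector(a2), as.vector(b2))
  )
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 &
                 pairs[, 1] != pairs[, 2], , drop = FALSE]
  if (nrow(pairs) > 0) {
    parent <- seq_len(k)
    find <- function(i) {
      while (parent[i] != i) {
        parent[i] <<- parent[parent[i]]
        i <- parent[i]
      }
      i
    }
    for (r in seq_len(nrow(pairs))) {
      ra <- find(pairs[r, 1]); rb <- find(pairs[r, 2])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
    root <- vapply(seq_len(k), find, integer(1))
    remap <- c(0L, match(root, sort(unique(root))))
    lab <- matrix(remap[lab + 1L], nrow = nr)
  }
  lab
}

#' Rotate a binary raster about its centroid
#'
#' Inverse-mapped bilinear rotation followed by re-binarization at 0.5. The
#' output raster is enlarged to contain the rotated component.
#'
#' @param m Binary matrix (rows = y, cols = x).
#' @param angle Rotation angle in radians, counter-clockwise in the
#'   (x right, y down) raster frame.
#' @return Binary matrix.
#' @keywords internal
rotate_raster <- function(m, angle) {
  nr <- nrow(m); nc <- ncol(m)
  ca <- cos(angle); sa <- sin(angle)
  # output extent: rotated bounding box plus a 1-px guard
  nco <- ceiling(abs(nc * ca) + abs(nr * sa)) + 2L
  nro <- ceiling(abs(nc * sa) + abs(nr * ca)) + 2L
  cx <- (nc + 1) / 2; cy <- (nr + 1) / 2
  cxo <- (nco + 1) / 2; cyo <- (nro + 1) / 2
  xo <- matrix(rep(seq_len(nco), each = nro), nrow = nro) - cxo
  yo <- matrix(rep(seq_len(nro), times = nco), nrow = nro) - cyo
  # inverse map (rotate output coords by -angle back into the source frame)
  xs <- ca * xo + sa * yo + cx
  ys <- -sa * xo + ca * yo + cy
  x0 <- floor(xs); y0 <- floor(ys)
  fx <- xs - x0; fy <- ys - y0
  pick <- function(ix, iy) {
    ok <- ix >= 1 & ix <= nc & iy >= 1 & iy <= nr
    v <- numeric(length(ix))
    v[ok] <- m[cbind(iy[ok], ix[ok])]
    v
  }
  v <- pick(x0, y0) * (1 - fx) * (1 - fy) +
       pick(x0 + 1, y0) * fx * (1 - fy) +
       pick(x0, y0 + 1) * (1 - fx) * fy +
       pick(x0 + 1, y0 + 1) * fx * fy
  matrix(as.integer(v >= 0.5), nrow = nro)
}

#' Principal-axis angle of a binary component
#'
#' Angle (radians) between the component's principal axis (from second-order
#' central moments) and the horizontal raster axis, in (-pi/2, pi/2].
#'
#' @param m Binary matrix containing the component.
#' @return Angle in radians.
#' @keywords internal
principal_angle <- function(m) {
  idx <- which(m != 0, arr.ind = TRUE)
  y <- idx[, 1]; x <- idx[, 2]
  mu20 <- stats::var(x) * (length(x) - 1) / length(x)
  mu02 <- stats::var(y) * (length(y) - 1) / length(y)
  mu11 <- mean(x * y) - mean(x) * mean(y)
  0.5 * atan2(2 * mu11, mu20 - mu02)
}

#' Auto-orient a component so its principal axis is horizontal
#'
#' Replaces the manual step of arranging the macronuclear midline
#' horizontally before the volume-of-revolution calculation: the component is
#' rotated about its centroid so that its principal axis (second-moment
#' eigenvector) aligns with the raster's horizontal axis. Rotation uses
#' bilinear interpolation re-binarized at 0.5; if the measured angle is
#' already within `angle_tolerance_deg` no rotation is applied.
#'
#' @param mask A [silhouette_mask()] or binary matrix holding one component
#'   (use [label_components()] + cropping for multi-component masks).
#' @param angle_tolerance_deg Angular tolerance (degrees) below which the
#'   mask is returned unchanged. Default 5.
#' @param min_pixels Components smaller than this are rejected as degenerate.
#' @return A [silhouette_mask()] with horizontal principal axis.
#' @export
orient_component <- function(mask, angle_tolerance_deg = 5, min_pixels = 10L) {
  ps <- if (inherits(mask, "silhouette_mask")) mask$pixel_size else 1
  cid <- if (inherits(mask, "silhouette_mask")) mask$cell_id else NA_character_
  frm <- if (inherits(mask, "silhouette_mask")) mask$frame else NA_integer_
  m <- as_mask_matrix(mask)
  npx <- sum(m)
  if (npx < min_pixels) {
    stop("degenerate component: ", npx, " foreground pixels (need >= ",
         min_pixels, ")")
  }
  ang <- principal_angle(m)
  if (abs(ang) <= angle_tolerance_deg * pi / 180) {
    return(silhouette_mask(m, ps, cell_id = cid, frame = frm))
  }
  out <- rotate_raster(m, -ang)
  darea <- abs(sum(out) - npx) / npx
  if (darea >= 0.02) {
    warning(sprintf(
      "area changed by %.1f%% during re-orientation (rotation by %.1f deg)",
      100 * darea, ang * 180 / pi))
  }
  silhouette_mask(out, ps, cell_id = cid, frame = frm)
}

#' Column-wise chord profile of a silhouette
#'
#' The radius function of the solid-of-revolution model: for each raster
#' column x, `h(x)` is the number of foreground pixels in that column, so the
#' local revolution radius is `h(x) * pixel_size / 2`. Counting pixels
#' (rather than taking max minus min extent) makes the profile robust to
#' single-pixel tracing holes; the two conventions coincide for convex column
#' sections.
#'
#' @param mask A [silhouette_mask()] or binary matrix.
#' @param pixel_size Required when `mask` is a bare matrix.
#' @return An object of class `"chord_profile"`: list with `h` (pixels per
#'   column) and `pixel_size` (um).
#' @export
chord_profile <- function(mask, pixel_size = NULL) {
  if (inherits(mask, "silhouette_mask")) pixel_size <- mask$pixel_size
  if (is.null(pixel_size)) stop("pixel_size is required for a bare matrix")
  m <- as_mask_matrix(mask)
  structure(list(h = colSums(m), pixel_size = pixel_size),
            class = "chord_profile")
}

#' Volume of revolution from a chord profile
#'
#' The stack-of-cylinders estimator: each column of width `s = pixel_size`
#' contributes a cylinder of radius `h(x) * s / 2` (rotational symmetry about
#' the horizontal midline is assumed), so
#' \deqn{V = \sum_x \pi \left(\frac{h(x)\,s}{2}\right)^2 s.}
#'
#' @param profile A [chord_profile()].
#' @return Volume in um^3 (0 for an empty profile).
#' @export
volume_of_revolution <- function(profile) {
  stopifnot(inherits(profile, "chord_profile"))
  s <- profile$pixel_size
  sum(pi * (profile$h * s / 2)^2 * s)
}

#' Total macronuclear volume of a silhouette mask
#'
#' Labels the mask's connected components (8-connectivity), auto-orients each
#' component so its principal axis is horizontal, and sums the
#' volume-of-revolution estimates. Components below `min_pixels` are measured
#' without re-orientation (rotating a near-degenerate speck is meaningless
#' and its volume contribution is at the resolution floor).
#'
#' @param mask A [silhouette_mask()], or a binary matrix with `pixel_size`.
#' @param pixel_size Pixel size (um), required for bare matrices.
#' @param angle_tolerance_deg Forwarded to [orient_component()].
#' @param min_pixels Minimum component size for re-orientation.
#' @return Total volume (um^3). An empty mask returns 0 with a warning.
#' @export
total_volume <- function(mask, pixel_size = NULL, angle_tolerance_deg = 5,
                         min_pixels = 10L) {
  if (inherits(mask, "silhouette_mask")) {
    pixel_size <- mask$pixel_size
  } else {
    if (is.null(pixel_size)) stop("pixel_size is required for a bare matrix")
    mask <- silhouette_mask(mask, pixel_size)
  }
  lab <- label_components(mask)
  k <- max(lab)
  if (k == 0L) {
    warning("empty mask: total volume is 0")
    return(0)
  }
  total <- 0
  for (i in seq_len(k)) {
    comp <- crop_component(lab, i)
    if (sum(comp) >= min_pixels) {
      comp <- orient_component(silhouette_mask(comp, pixel_size),
                               angle_tolerance_deg = angle_tolerance_deg,
                               min_pixels = min_pixels)$raster
    }
    total <- total +
      volume_of_revolution(chord_profile(comp, pixel_size = pixel_size))
  }
  total
}

#' Crop one labelled component to its padded bounding box
#' @keywords internal
crop_component <- function(lab, label, pad = 1L) {
  idx <- which(lab == label, arr.ind = TRUE)
  r0 <- max(1L, min(idx[, 1]) - pad); r1 <- min(nrow(lab), max(idx[, 1]) + pad)
  c0 <- max(1L, min(idx[, 2]) - pad); c1 <- min(ncol(lab), max(idx[, 2]) + pad)
  sub <- lab[r0:r1, c0:c1, drop = FALSE]
  matrix(as.integer(sub == label), nrow = nrow(sub))
}
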