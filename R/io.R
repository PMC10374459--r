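#' Read a silhouette mask from PNG or TIFF
#'
#' Any non-zero pixel is foreground; for RGBA images foreground is the
#' non-transparent region (alpha > 0), matching masks exported as PNGs with
#' transparent backgrounds. Multi-frame TIFF stacks are rejected.
#'
#' @param path File path (`.png`, `.tif`/`.tiff`).
#' @param pixel_size_um Pixel calibration (um/px).
#' @param cell_id,frame Optional provenance labels.
#' @return A [silhouette_mask()].
#' @export
read_mask <- function(path, pixel_size_um, cell_id = NA_character_,
                      frame = NA_integer_) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  arr <- if (ext == "png") {
    png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    x <- tiff::readTIFF(path, all = TRUE)
    if (is.list(x) && length(x) > 1) {
      stop("multi-frame TIFF stacks are not supported: ", path)
    }
    if (is.list(x)) x[[1]] else x
  } else {
    stop("unsupported mask format: .", ext)
  }
  m <- if (length(dim(arr)) == 2) {
    arr != 0
  } else if (dim(arr)[3] %in% c(2, 4)) {
    arr[, , dim(arr)[3]] > 0          # alpha channel present
  } else {
    apply(arr != 0, c(1, 2), any)
  }
  silhouette_mask(m * 1L, pixel_size_um, cell_id = cell_id, frame = frame)
}

#' Write a silhouette mask as an 8-bit PNG or TIFF
#'
#' Foreground is written as 255, background as 0.
#'
#' @param mask A [silhouette_mask()] or binary matrix.
#' @param path Output path (`.png` or `.tif`/`.tiff`).
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  m <- as_mask_matrix(mask)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(m * 1.0, target = path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(m * 1.0, where = path, bits.per.sample = 8L)
  } else {
    stop("unsupported mask format: .", ext)
  }
  invisible(path)
}

#' Write a two-channel fluorescence image as 16-bit TIFF
#'
#' Channels are stored as two samples per pixel, scaled by `scale_max` into
#' the 16-bit range. Pixel size, exposure and the intensity scale are written
#' to a plain-text sidecar file (`<path>.meta`, `key = value` lines) so
#' [read_fluor_tiff()] can restore the calibrated object.
#'
#' @param image A [fluor_image()].
#' @param path Output path.
#' @param scale_max Intensity mapped to the top of the 16-bit range
#'   (default: the image maximum).
#' @return `path`, invisibly.
#' @export
write_fluor_tiff <- function(image, path, scale_max = NULL) {
  stopifnot(inherits(image, "fluor_image"))
  if (is.null(scale_max)) {
    scale_max <- max(image$signal, image$autofluor, 1)
  }
  arr <- array(0, dim = c(nrow(image$signal), ncol(image$signal), 2))
  arr[, , 1] <- pmin(image$signal / scale_max, 1)
  arr[, , 2] <- pmin(image$autofluor / scale_max, 1)
  tiff::writeTIFF(arr, where = path, bits.per.sample = 16L)
  write_config(list(pixel_size_um = image$pixel_size,
                    exposure_s = image$exposure_s,
                    scale_max = scale_max),
               paste0(path, ".meta"))
  invisible(path)
}

#' Read a two-channel fluorescence TIFF written by [write_fluor_tiff()]
#'
#' @param path File path.
#' @param pixel_size_um,exposure_s Overrides for images without the
#'   `<path>.meta` sidecar (an error is raised if the sidecar is absent and
#'   these are not given).
#' @return A [fluor_image()].
#' @export
read_fluor_tiff <- function(path, pixel_size_um = NULL, exposure_s = NULL) {
  # two-sample grayscale layout triggers a benign ExtraSamples note
  arr <- suppressWarnings(tiff::readTIFF(path))
  meta <- if (file.exists(paste0(path, ".meta"))) {
    read_config(paste0(path, ".meta"))
  } else {
    list()
  }
  ps <- if (!is.null(pixel_size_um)) pixel_size_um else meta$pixel_size_um
  ex <- if (!is.null(exposure_s)) exposure_s else meta$exposure_s
  sc <- if (!is.null(meta$scale_max)) meta$scale_max else 1
  if (is.null(ps)) stop("pixel size not recorded in file; pass pixel_size_um")
  if (is.null(ex)) stop("exposure not recorded in file; pass exposure_s")
  if (length(dim(arr)) != 3 || dim(arr)[3] < 2) {
    stop("expected a two-channel TIFF: ", path)
  }
  fluor_image(arr[, , 1] * sc, arr[, , 2] * sc,
              pixel_size = ps, exposure_s = ex)
}

#' Write a flat key-value config / spec file
#' @param x Named list of scalars (vectors are comma-joined).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(x, path) {
  lines <- vapply(names(x), function(k) {
    paste0(k, " = ", paste(x[[k]], collapse = ","))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a flat key-value config file
#' @param path File path.
#' @return Named list; numeric-looking values are converted.
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  out <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(parts) < 2) next
    key <- trimws(parts[1])
    val <- trimws(paste(parts[-1], collapse = "="))
    vals <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(vals))
    out[[key]] <- if (all(!is.na(num))) num else vals
  }
  out
}

#' Serialize a nucleus model to a flat key-value file
#' @param spec A [nucleus_spec()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_nucleus_spec <- function(spec, path) {
  stopifnot(inherits(spec, "nucleus_spec"))
  write_config(list(node_radii_um = spec$node_radii,
                    gap_lengths_um = spec$gap_lengths,
                    connector_radius_um = spec$connector_radius), path)
}

#' Read a nucleus model from a flat key-value file
#' @param path File path.
#' @return A [nucleus_spec()].
#' @export
read_nucleus_spec <- function(path) {
  cfg <- read_config(path)
  nucleus_spec(node_radii = cfg$node_radii_um,
               gap_lengths = if (is.null(cfg$gap_lengths_um)) numeric(0)
                             else cfg$gap_lengths_um,
               connector_radius = cfg$connector_radius_um)
}
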