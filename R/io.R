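#' Load a calibrated image stack from a TIFF file
#'
#' Reads a single- or multi-frame TIFF and resolves the physical pixel size.
#' An explicit \code{pixel_size_override} always wins; otherwise the TIFF
#' resolution tags are used: \code{inch} and \code{cm} resolution units are
#' converted to micrometres, and ImageJ-style files that store
#' \code{unit=micron} (or \code{um}) in the image description are read as
#' pixels-per-micrometre. If neither source yields a pixel size the file is
#' considered uncalibrated and an error is raised, because every downstream
#' parameter is expressed in physical units.
#'
#' @param path Path to a TIFF file.
#' @param pixel_size_override Optional pixel size in micrometres; overrides
#'   any file metadata.
#' @param channel For multi-channel (RGB) files, which channel to keep.
#' @return An \code{\link{image_stack}}.
#' @export
load_stack <- function(path, pixel_size_override = NULL, channel = 1L) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (!is.null(pixel_size_override)) check_pixel_size(pixel_size_override)
  frames <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  if (!is.list(frames)) frames <- list(frames)
  ps <- pixel_size_override %||% pixel_size_from_tiff(frames[[1L]])
  if (is.null(ps))
    stop("no pixel size: file '", path, "' carries no usable resolution ",
         "metadata and no override was given")
  mats <- lapply(frames, function(f) {
    if (length(dim(f)) == 3L) f <- f[, , channel]
    f[f < 0] <- 0
    attributes(f) <- list(dim = dim(f))  # drop TIFF info attributes
    f
  })
  image_stack(mats, ps, provenance = path)
}

# Resolve µm/px from the attributes readTIFF attaches to a frame, or NULL.
# Anisotropic in-plane calibration is rejected: the morphometry assumes one
# isotropic pixel size.
pixel_size_from_tiff <- function(frame) {
  xres <- attr(frame, "x.resolution")
  if (is.null(xres) || !is.finite(xres) || xres <= 0) return(NULL)
  yres <- attr(frame, "y.resolution")
  if (!is.null(yres) && is.finite(yres) && yres > 0 &&
      abs(yres - xres) > 1e-6 * xres)
    stop("anisotropic pixel calibration (x.resolution != y.resolution) ",
         "is not supported")
  unit <- attr(frame, "resolution.unit") %||% "none"
  desc <- attr(frame, "description") %||% ""
  if (identical(unit, "inch")) return(25400 / xres)
  if (identical(unit, "cm"))   return(10000 / xres)
  if (grepl("unit=(micron|um|µm)", desc)) return(1 / xres)
  NULL
}

#' Write a calibrated image or stack as 32-bit float TIFF
#'
#' The pixel size cannot be embedded in the TIFF tags by the underlying
#' writer, so callers that need round-trip calibration should keep it in a
#' sidecar (the synthetic scene writer does this) or pass an override when
#' re-loading.
#'
#' @param x A \code{calibrated_image} or \code{image_stack}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_image <- function(x, path) {
  frames <- if (inherits(x, "image_stack")) x$frames
            else if (inherits(x, "calibrated_image")) list(x$pixels)
            else stop("`x` must be a calibrated_image or image_stack")
  tiff::writeTIFF(frames, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}

#' Read per-cell regions from a label mask or ImageJ ROI file
#'
#' Two dialects are accepted: an integer label-mask raster (TIFF; 0 =
#' background, each positive label = one cell) and ImageJ ROI files
#' (single \code{.roi} or a \code{.zip} of ROIs; rectangle, oval, polygon,
#' freehand and traced types). Both are converted to one binary
#' \code{\link{cell_region}} per cell.
#'
#' @param path Path to a \code{.tif}/\code{.tiff} label mask, a \code{.roi}
#'   file or a \code{.zip} of ROI files.
#' @param dim Image dimensions \code{c(rows, cols)}; required for ROI files,
#'   and checked against a label mask.
#' @return A list of \code{\link{cell_region}} objects.
#' @export
read_cell_regions <- function(path, dim = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    lab <- tiff::readTIFF(path)
    if (length(base::dim(lab)) == 3L) lab <- lab[, , 1L]
    if (!is.null(dim) && !identical(base::dim(lab), as.integer(dim)))
      stop("label mask dimensions do not match the image")
    # integer TIFFs are rescaled to [0,1] on read, so treat each distinct
    # non-zero value as one label rather than trusting absolute values
    vals <- sort(unique(round(lab[lab > 0], 6L)))
    if (length(vals) == 0L) stop("label mask contains no cells")
    lapply(seq_along(vals), function(i)
      cell_region(abs(lab - vals[i]) < 1e-6, cell_id = sprintf("cell_%02d", i)))
  } else if (ext == "roi") {
    if (is.null(dim)) stop("`dim` is required to rasterize ROI files")
    list(roi_to_region(read_ij_roi(path), dim,
                       cell_id = tools::file_path_sans_ext(basename(path))))
  } else if (ext == "zip") {
    if (is.null(dim)) stop("`dim` is required to rasterize ROI files")
    tmp <- tempfile("rois")
    files <- utils::unzip(path, exdir = tmp)
    files <- sort(files[tolower(tools::file_ext(files)) == "roi"])
    if (length(files) == 0L) stop("no .roi entries in ", path)
    lapply(files, function(f)
      roi_to_region(read_ij_roi(f), dim,
                    cell_id = tools::file_path_sans_ext(basename(f))))
  } else {
    stop("unsupported cell-region format: .", ext)
  }
}

# --- minimal ImageJ .roi decoder -------------------------------------------
# Binary layout (big-endian): bytes 0-3 magic "Iout", 4-5 version, 6 type,
# 8-15 top/left/bottom/right int16, 16-17 n coordinates, 64.. n*int16 x then
# n*int16 y relative to (left, top). Only the shape types needed for cell
# outlines are supported.
read_ij_roi <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  if (length(raw) < 64L || rawToChar(raw[1:4]) != "Iout")
    stop("not an ImageJ ROI file: ", path)
  i16 <- function(off, n = 1L)
    readBin(raw[(off + 1L):(off + 2L * n)], "integer", n = n, size = 2L,
            signed = TRUE, endian = "big")
  type <- as.integer(raw[7L])
  top <- i16(8L); left <- i16(10L); bottom <- i16(12L); right <- i16(14L)
  n <- i16(16L)
  out <- list(type = type, top = top, left = left, bottom = bottom,
              right = right)
  if (type %in% c(0L, 7L, 8L)) {  # polygon, freehand, traced
    if (n < 3L) stop("ROI polygon has fewer than 3 vertices")
    out$x <- left + i16(64L, n)
    out$y <- top + i16(64L + 2L * n, n)
  } else if (!type %in% c(1L, 2L)) {
    stop("unsupported ImageJ ROI type code: ", type)
  }
  out
}

roi_to_region <- function(roi, dim, cell_id) {
  nr <- dim[1L]; nc <- dim[2L]
  # pixel centres in ImageJ coordinates (origin at the top-left image corner)
  cx <- matrix(rep(seq_len(nc) - 0.5, each = nr), nr, nc)
  cy <- matrix(rep(seq_len(nr) - 0.5, times = nc), nr, nc)
  mask <- if (roi$type == 1L) {
    cx >= roi$left & cx <= roi$right & cy >= roi$top & cy <= roi$bottom
  } else if (roi$type == 2L) {
    a <- (roi$right - roi$left) / 2; b <- (roi$bottom - roi$top) / 2
    x0 <- (roi$left + roi$right) / 2; y0 <- (roi$top + roi$bottom) / 2
    ((cx - x0) / a)^2 + ((cy - y0) / b)^2 <= 1
  } else {
    m <- points_in_polygon(as.vector(cx), as.vector(cy), roi$x, roi$y)
    matrix(m, nr, nc)
  }
  cell_region(mask, cell_id = cell_id)
}

# Even-odd rule, vectorized over query points.
points_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Export a segmentation as a label-mask TIFF for visual QC
#'
#' @param objects List of segmented objects (see
#'   \code{\link{segment_objects}}).
#' @param dim Image dimensions \code{c(rows, cols)}.
#' @param path Output TIFF path.
#' @return \code{path}, invisibly.
#' @export
write_label_mask <- function(objects, dim, path) {
  lab <- matrix(0, dim[1L], dim[2L])
  for (ob in objects) lab[ob$coords] <- ob$label
  tiff::writeTIFF(lab, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}
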