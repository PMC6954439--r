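#' Calibrated 2D intensity image
#'
#' The unit-bearing container used throughout the pipeline: a matrix of
#' non-negative intensities (rows = y, columns = x) plus the physical edge
#' length of one pixel in micrometres. All physical-unit parameters
#' (filter radii, areas, length thresholds) are converted to pixels through
#' \code{pixel_size}.
#'
#' @param pixels Numeric matrix of finite, non-negative intensities.
#' @param pixel_size Pixel edge length in micrometres (isotropic in-plane).
#' @param provenance Optional character scalar recording the source
#'   (file path, frame index, processing step).
#' @return An object of class \code{calibrated_image} with fields
#'   \code{pixels}, \code{pixel_size} and \code{provenance}.
#' @export
calibrated_image <- function(pixels, pixel_size, provenance = NULL) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("`pixels` must be a numeric matrix")
  if (nrow(pixels) < 1L || ncol(pixels) < 1L)
    stop("image must have at least one row and one column")
  if (!all(is.finite(pixels)))
    stop("all intensities must be finite")
  if (any(pixels < 0))
    stop("all intensities must be non-negative")
  check_pixel_size(pixel_size)
  structure(
    list(pixels = pixels, pixel_size = as.numeric(pixel_size),
         provenance = provenance),
    class = "calibrated_image"
  )
}

check_pixel_size <- function(pixel_size) {
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L ||
      !is.finite(pixel_size) || pixel_size <= 0)
    stop("`pixel_size` must be a single finite value > 0 (µm per pixel)")
  invisible(pixel_size)
}

#' @export
print.calibrated_image <- function(x, ...) {
  cat(sprintf("<calibrated_image> %d x %d px, %.4g µm/px, range [%.4g, %.4g]\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
dim.calibrated_image <- function(x) dim(x$pixels)

#' Ordered stack of calibrated frames
#'
#' All frames share one pixel size and one set of dimensions; the stack is
#' the raw form of a multi-focal-plane acquisition before Z-projection.
#'
#' @param frames List of numeric matrices with identical dimensions.
#' @param pixel_size Pixel edge length in micrometres, shared by all frames.
#' @param provenance Optional character scalar.
#' @return An object of class \code{image_stack}.
#' @export
image_stack <- function(frames, pixel_size, provenance = NULL) {
  if (!is.list(frames) || length(frames) < 1L)
    stop("`frames` must be a non-empty list of matrices")
  d <- dim(frames[[1L]])
  for (f in frames) {
    if (!is.matrix(f) || !is.numeric(f))
      stop("every frame must be a numeric matrix")
    if (!identical(dim(f), d))
      stop("all frames must share the same dimensions")
    if (!all(is.finite(f)) || any(f < 0))
      stop("all frame intensities must be finite and non-negative")
  }
  check_pixel_size(pixel_size)
  structure(
    list(frames = frames, pixel_size = as.numeric(pixel_size),
         provenance = provenance),
    class = "image_stack"
  )
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$frames[[1L]])
  cat(sprintf("<image_stack> %d frame(s), %d x %d px, %.4g µm/px\n",
              length(x$frames), d[1L], d[2L], x$pixel_size))
  invisible(x)
}

#' Binary region naming one cell
#'
#' Cells are outlined upstream (label masks or ImageJ ROI files); a
#' \code{cell_region} scopes segmentation and statistics to one cell.
#'
#' @param mask Logical matrix, same shape as the image it applies to, with
#'   at least one \code{TRUE} pixel.
#' @param cell_id Character identifier for the cell.
#' @return An object of class \code{cell_region}.
#' @export
cell_region <- function(mask, cell_id) {
  if (is.numeric(mask)) {
    storage <- mask != 0
    dim(storage) <- dim(mask)
    mask <- storage
  }
  if (!is.matrix(mask) || !is.logical(mask))
    stop("`mask` must be a logical (or 0/1 numeric) matrix")
  if (!any(mask))
    stop("cell region mask is empty")
  if (length(cell_id) != 1L)
    stop("`cell_id` must be a single identifier")
  structure(list(mask = mask, cell_id = as.character(cell_id)),
            class = "cell_region")
}

#' Z-project an image stack to a single 2D image
#'
#' Collapses the focal planes with a per-pixel statistic. The default (and
#' currently only) method is maximum-intensity projection, the standard
#' choice for thin, bright, curvilinear structures such as a
#' MitoTracker-stained network.
#'
#' @param stack An \code{\link{image_stack}}.
#' @param method Projection statistic; only \code{"max"} is supported.
#' @return A \code{\link{calibrated_image}} with the stack's pixel size.
#' @export
z_project <- function(stack, method = "max") {
  if (!inherits(stack, "image_stack")) stop("`stack` must be an image_stack")
  method <- match.arg(method, "max")
  proj <- Reduce(pmax, stack$frames)
  calibrated_image(proj, stack$pixel_size,
                   provenance = paste0(stack$provenance %||% "", " [max-projection]"))
}

#' Restrict an image to a single cell
#'
#' Sets all intensities outside the cell's mask to zero so that every
#' downstream object is clipped at the manually outlined cell boundary.
#'
#' @param image A \code{\link{calibrated_image}}.
#' @param region A \code{\link{cell_region}} with the same dimensions.
#' @return A \code{\link{calibrated_image}} masked to the region.
#' @export
apply_cell_region <- function(image, region) {
  if (!inherits(image, "calibrated_image")) stop("`image` must be a calibrated_image")
  if (!inherits(region, "cell_region")) stop("`region` must be a cell_region")
  if (!identical(dim(image$pixels), dim(region$mask)))
    stop("image and cell region have different dimensions")
  px <- image$pixels
  px[!region$mask] <- 0
  calibrated_image(px, image$pixel_size,
                   provenance = paste0(image$provenance %||% "",
                                       " [cell ", region$cell_id, "]"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
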