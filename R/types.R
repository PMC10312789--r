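#' Domain containers for light-field reconstruction
#'
#' All image-like objects are plain numeric arrays wrapped in light S3
#' classes. Axis convention (column-major, as R stores arrays):
#' \itemize{
#'   \item \code{volume}: \code{(H, W, D)} -- rows, columns, depth planes.
#'   \item \code{lf_image}: \code{(H, W)} -- a single camera exposure.
#'   \item \code{psf_stack}: \code{(H, W, D)} -- one 2D PSF plane per depth.
#'   \item \code{view_stack}: \code{(crop, crop, n_views)} -- per-lens crops.
#' }
#' Depth plane \code{z} of a volume is projected through PSF plane \code{z}.
#'
#' @param data numeric array of the dimensionality stated above
#' @param voxel_size numeric length-3 \code{(dz, dy, dx)} in micrometres;
#'   metadata only, never used in computation
#' @return an object of the corresponding class wrapping \code{data}
#' @name cwflow-types
NULL

#' @rdname cwflow-types
#' @export
volume <- function(data, voxel_size = c(1, 1, 1)) {
  data <- as_grid(data, 3L, "volume")
  if (any(data < 0)) stop("volume values must be non-negative")
  structure(list(data = data, voxel_size = as.numeric(voxel_size)),
            class = "volume")
}

#' @rdname cwflow-types
#' @export
lf_image <- function(data) {
  data <- as_grid(data, 2L, "lf_image")
  if (any(data < 0)) stop("lf_image values must be non-negative")
  structure(list(data = data), class = "lf_image")
}

#' @rdname cwflow-types
#' @export
psf_stack <- function(data) {
  data <- as_grid(data, 3L, "psf_stack")
  if (any(data < 0)) stop("psf_stack values must be non-negative")
  structure(list(planes = data), class = "psf_stack")
}

#' @rdname cwflow-types
#' @export
view_stack <- function(data) {
  data <- as_grid(data, 3L, "view_stack")
  if (any(data < 0)) stop("view_stack values must be non-negative")
  structure(list(data = data), class = "view_stack")
}

#' Lenslet layout
#'
#' The detected (or configured) centers of the micro-lens sub-images on the
#' camera, plus the side length of the square window cropped around each
#' center. Centers are 1-based \code{(row, col)} pixel coordinates; windows
#' may overlap and may extend past the image border (out-of-bounds pixels are
#' zero-filled by [crop_views()]). The crop window for a center \code{(r, c)}
#' places the center pixel at 1-based index \code{crop_size \%/\% 2 + 1}.
#'
#' @param centers integer matrix \code{n x 2} of \code{(row, col)} centers
#' @param crop_size integer side length of the square crop window
#' @return a \code{lens_layout} object
#' @export
lens_layout <- function(centers, crop_size) {
  centers <- matrix(as.integer(round(centers)), ncol = 2)
  if (nrow(centers) < 1) stop("lens_layout needs at least one center")
  crop_size <- as.integer(crop_size)
  if (crop_size < 1) stop("crop_size must be >= 1")
  structure(list(centers = centers, crop_size = crop_size),
            class = "lens_layout")
}

as_grid <- function(x, ndim, what) {
  if (inherits(x, c("volume", "psf_stack", "lf_image", "view_stack")))
    x <- grid_of(x)
  x <- as.array(x)
  if (ndim == 2L && length(dim(x)) == 3L && dim(x)[3] == 1L)
    x <- array(x, dim(x)[1:2])
  if (ndim == 3L && length(dim(x)) == 2L)
    x <- array(x, c(dim(x), 1L))
  if (length(dim(x)) != ndim)
    stop(sprintf("%s expects a %dD array, got %dD", what, ndim, length(dim(x))))
  if (!all(is.finite(x))) stop(sprintf("%s contains non-finite values", what))
  storage.mode(x) <- "double"
  x
}

# raw numeric grid behind any container
grid_of <- function(x) {
  if (inherits(x, "psf_stack")) return(x$planes)
  if (is.list(x) && !is.null(x$data)) return(x$data)
  as.array(x)
}

#' @export
print.volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume %d x %d x %d, range [%.4g, %.4g]>\n",
              d[1], d[2], d[3], min(x$data), max(x$data)))
  invisible(x)
}

#' @export
print.psf_stack <- function(x, ...) {
  d <- dim(x$planes)
  cat(sprintf("<psf_stack %d x %d, %d depth planes>\n", d[1], d[2], d[3]))
  invisible(x)
}

#' @export
print.lens_layout <- function(x, ...) {
  cat(sprintf("<lens_layout: %d lenses, crop %d>\n",
              nrow(x$centers), x$crop_size))
  invisible(x)
}

#' @export
print.lf_image <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<lf_image %d x %d, max %.4g>\n", d[1], d[2], max(x$data)))
  invisible(x)
}

#' @export
print.view_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<view_stack: %d views of %d x %d>\n", d[3], d[1], d[2]))
  invisible(x)
}
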