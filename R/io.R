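#' Read and write stacks as multi-page TIFF
#'
#' Volumes, PSF stacks and view stacks are stored as 32-bit multi-page TIFF,
#' one page per depth plane (or per view). Because the TIFF writer stores
#' samples in \code{[0, 1]}, data are scaled by their maximum on write and the
#' scale factor is recorded in a JSON sidecar (\code{<file>.json}); reading
#' restores the original intensities. An all-zero stack writes scale 1.
#'
#' @param x a \code{volume}, \code{psf_stack}, \code{view_stack},
#'   \code{lf_image} or bare array
#' @param path output / input file path
#' @return \code{write_tiff_stack}: \code{path}, invisibly.
#'   \code{read_tiff_stack}: a numeric array \code{(H, W, pages)}.
#' @export
write_tiff_stack <- function(x, path) {
  g <- grid_of(x)
  if (length(dim(g)) == 2L) g <- array(g, c(dim(g), 1L))
  sc <- max(abs(g))
  if (sc == 0) sc <- 1
  pages <- lapply(seq_len(dim(g)[3]), function(k) g[, , k] / sc)
  suppressWarnings(tiff::writeTIFF(pages, path, bits.per.sample = 32L))
  jsonlite::write_json(list(scale = sc, dim = dim(g)),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_tiff_stack
#' @export
read_tiff_stack <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) if (length(dim(p)) == 3L) p[, , 1] else p)
  g <- array(unlist(pages), c(dim(pages[[1]]), length(pages)))
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    g <- g * meta$scale
  }
  g
}

#' Read/write a lenslet layout as JSON
#'
#' Serialized as \code{{"centers": [[r, c], ...], "crop_size": n}} with
#' 1-based pixel coordinates.
#'
#' @param layout a [lens_layout()]
#' @param path file path
#' @return \code{read_layout}: a \code{lens_layout}
#' @export
write_layout <- function(layout, path) {
  stopifnot(inherits(layout, "lens_layout"))
  jsonlite::write_json(
    list(centers = unname(apply(layout$centers, 1, as.list)),
         crop_size = layout$crop_size),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_layout
#' @export
read_layout <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  cs <- x$centers
  if (is.list(cs)) cs <- do.call(rbind, lapply(cs, unlist))
  lens_layout(matrix(cs, ncol = 2), x$crop_size)
}

#' Save / load a trained model directory
#'
#' One parameter archive per component (LR-NN and each flow level) plus a
#' JSON manifest recording the configuration, seeds and shapes, so a model
#' can be inspected without loading it.
#'
#' @param model a \code{cwfa_model} from [build_model()]
#' @param dir directory to create / read
#' @return \code{load_model}: a \code{cwfa_model}
#' @export
save_model <- function(model, dir) {
  stopifnot(inherits(model, "cwfa_model"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("cwflow")),
    config = unclass(model$config),
    n_levels = length(model$levels),
    level_detail_depth = vapply(model$levels, function(l) l$detail_depth, 0)
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  saveRDS(model, file.path(dir, "model.rds"))
  invisible(dir)
}

#' @rdname save_model
#' @export
load_model <- function(dir) {
  p <- file.path(dir, "model.rds")
  if (!file.exists(p)) stop("no model found at: ", dir)
  readRDS(p)
}

# run rnorm/runif/etc. under a temporary seed, restoring the caller's RNG
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}
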