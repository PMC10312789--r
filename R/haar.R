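#' Orthonormal axial Haar transform
#'
#' Pairs consecutive depth planes of a volume into an approximation
#' (half axial resolution) and detail coefficients, leaving the lateral
#' resolution untouched. With the orthonormal \code{1/sqrt(2)} normalization
#' the transform is an isometry: energy is conserved exactly and its Jacobian
#' determinant is 1, so it contributes nothing to a log-likelihood.
#'
#' For consecutive depth planes \code{(a, b)}:
#' approximation \code{= (a + b)/sqrt(2)}, detail \code{= (a - b)/sqrt(2)}.
#'
#' @param v numeric array \code{(H, W, D)} with \code{D} even, or a
#'   \code{volume}
#' @return [haar_axial_forward()]: a \code{haar_pair} with fields
#'   \code{approximation} and \code{details}, both \code{(H, W, D/2)} arrays.
#' @export
haar_axial_forward <- function(v) {
  g <- as_grid(v, 3L, "haar input")
  d <- dim(g)[3]
  if (d %% 2L != 0L) stop("axial Haar transform needs an even depth, got ", d)
  odd <- g[, , seq(1L, d, by = 2L), drop = FALSE]
  evn <- g[, , seq(2L, d, by = 2L), drop = FALSE]
  structure(list(approximation = (odd + evn) / sqrt(2),
                 details       = (odd - evn) / sqrt(2)),
            class = "haar_pair")
}

#' @rdname haar_axial_forward
#' @param approximation array \code{(H, W, D/2)}, or a \code{haar_pair}
#'   (in which case \code{details} is taken from it)
#' @param details array matching \code{approximation} in shape
#' @return [haar_axial_inverse()]: the reconstructed \code{(H, W, D)} array.
#' @export
haar_axial_inverse <- function(approximation, details = NULL) {
  if (inherits(approximation, "haar_pair")) {
    details <- approximation$details
    approximation <- approximation$approximation
  }
  a <- as_grid(approximation, 3L, "approximation")
  dd <- as_grid(details, 3L, "details")
  if (!identical(dim(a), dim(dd)))
    stop("approximation and details shapes differ")
  d2 <- dim(a)[3]
  out <- array(0, c(dim(a)[1:2], 2L * d2))
  out[, , seq(1L, 2L * d2, by = 2L)] <- (a + dd) / sqrt(2)
  out[, , seq(2L, 2L * d2, by = 2L)] <- (a - dd) / sqrt(2)
  out
}

#' Multi-level axial Haar pyramid
#'
#' Applies [haar_axial_forward()] repeatedly to the approximation. Level
#' \code{i} (1-based list index) holds the detail coefficients \code{D_i}
#' produced when going from scale \code{i-1} to scale \code{i}; the final
#' approximation is the coarsest volume \code{V_n}.
#'
#' @param v array \code{(H, W, D)} with \code{D} divisible by \code{2^levels}
#' @param levels number of halvings
#' @return list with \code{details} (list of length \code{levels}),
#'   \code{approx} (the coarsest volume) and \code{approx_per_level}
#'   (list: \code{V_1 ... V_n})
#' @export
haar_pyramid <- function(v, levels) {
  g <- as_grid(v, 3L, "pyramid input")
  if (dim(g)[3] %% (2^levels) != 0L)
    stop(sprintf("depth %d is not divisible by 2^%d", dim(g)[3], levels))
  details <- vector("list", levels)
  approxes <- vector("list", levels)
  cur <- g
  for (i in seq_len(levels)) {
    hp <- haar_axial_forward(cur)
    details[[i]] <- hp$details
    approxes[[i]] <- hp$approximation
    cur <- hp$approximation
  }
  list(details = details, approx = cur, approx_per_level = approxes)
}

# i-fold axial reduction of a grid (approximation pathway only)
haar_reduce <- function(v, times) {
  g <- as_grid(v, 3L, "haar_reduce input")
  for (i in seq_len(times)) g <- haar_axial_forward(g)$approximation
  g
}
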