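#' Conditional affine transform (CAT) flow
#'
#' The invertible building block of the wavelet-flow levels. A small
#' convolutional subnet maps the condition features to an elementwise
#' \emph{scale} and \emph{translation}, applied to the flow input in either
#' direction:
#' \deqn{forward:\ y = s(c) \odot x + t(c), \qquad
#'       inverse:\ x = (y - t(c)) / s(c)}
#' The scale is parameterized as \code{s = exp(clamp * tanh(raw / clamp))},
#' which keeps it strictly positive and bounded in
#' \code{[exp(-clamp), exp(clamp)]}, so the block is invertible for any
#' subnet output. Because \code{s} and \code{t} depend only on the condition,
#' the Jacobian in \code{x} is diagonal and the log-determinant is exactly
#' \code{sum(log s)}.
#'
#' A \code{conditional_flow} composes several CAT blocks with a fixed, seeded
#' channel permutation before each block after the first (permutations are
#' volume preserving, so they add nothing to the log-determinant). The final
#' subnet layer of every block is zero-initialized, so a freshly built flow
#' is the identity map with zero log-determinant.
#'
#' @param n_channels number of data channels (Haar detail planes) the flow
#'   transforms
#' @param cond_channels number of condition-feature channels
#' @param n_blocks number of CAT blocks (default 6)
#' @param hidden hidden width of each block's subnet (default 14 channels)
#' @param clamp soft-clamp bound on \code{log s}
#' @param seed integer controlling subnet init and the channel permutations
#' @return a \code{conditional_flow} object
#' @export
conditional_flow <- function(n_channels, cond_channels, n_blocks = 6L,
                             hidden = 14L, clamp = 2.0, seed = 1L) {
  with_seed(seed, {
    blocks <- vector("list", n_blocks)
    perms <- vector("list", n_blocks)
    for (k in seq_len(n_blocks)) {
      blocks[[k]] <- convnet(c(cond_channels, hidden, 2L * n_channels),
                             zero_last = TRUE)
      perms[[k]] <- if (k == 1L) seq_len(n_channels)
      else sample.int(n_channels)
    }
    structure(list(blocks = blocks, perms = perms, clamp = clamp,
                   n_channels = n_channels, cond_channels = cond_channels,
                   hidden = hidden),
              class = "conditional_flow")
  })
}

# scale/translation of one block given condition features, with caches
cat_subnet <- function(block, cond, clamp, nch) {
  fw <- net_fwd(cond, block)
  raw <- fw$y[, , seq_len(nch), , drop = FALSE]
  tr <- fw$y[, , nch + seq_len(nch), , drop = FALSE]
  th <- tanh(raw / clamp)
  g <- clamp * th
  list(s = exp(g), g = g, th = th, t = tr, fw = fw)
}

#' Apply a single CAT block
#'
#' Exposed mainly for testing the exact log-determinant; [flow_apply()] is
#' the user-facing composition.
#'
#' @param block one element of \code{flow$blocks}
#' @param x data array \code{(H, W, C, N)}
#' @param cond_features condition features \code{(H, W, Cc, N)}
#' @param direction \code{"forward"} or \code{"inverse"}
#' @param clamp soft-clamp bound
#' @return list \code{(y, log_det)}; \code{log_det} is a length-N vector
#' @export
cat_block <- function(block, x, cond_features,
                      direction = c("forward", "inverse"), clamp = 2.0) {
  direction <- match.arg(direction)
  nch <- dim(x)[3]
  sn <- cat_subnet(block, cond_features, clamp, nch)
  if (!all(is.finite(sn$s)) || !all(is.finite(sn$t)))
    stop("numeric error: non-finite subnet output")
  ld <- apply(sn$g, 4, sum)
  if (direction == "forward") list(y = sn$s * x + sn$t, log_det = ld)
  else list(y = (x - sn$t) / sn$s, log_det = -ld)
}

#' Apply a conditional flow in either direction
#'
#' Forward maps data to the latent space, accumulating the exact
#' change-of-variables log-determinant; inverse reverses the composition
#' exactly, so \code{flow_apply(flow_apply(x, c, "forward"), c, "inverse")}
#' recovers \code{x} to floating-point precision.
#'
#' @param flow a [conditional_flow()]
#' @param x data array \code{(H, W, C, N)} (latent \code{z} for the inverse
#'   direction); a 3D array is treated as a single sample
#' @param cond_features condition features \code{(H, W, Cc, N)}
#' @param direction \code{"forward"} or \code{"inverse"}
#' @return list with \code{z} (or \code{x}) and per-sample \code{log_det}
#'   (length-N vector)
#' @export
flow_apply <- function(flow, x, cond_features,
                       direction = c("forward", "inverse")) {
  direction <- match.arg(direction)
  x <- as_batch(x)
  cond_features <- as_batch(cond_features)
  k <- length(flow$blocks)
  ld <- numeric(dim(x)[4])
  if (direction == "forward") {
    for (i in seq_len(k)) {
      x <- x[, , flow$perms[[i]], , drop = FALSE]
      st <- cat_block(flow$blocks[[i]], x, cond_features, "forward",
                      flow$clamp)
      x <- st$y
      ld <- ld + st$log_det
    }
    list(z = x, log_det = ld)
  } else {
    for (i in rev(seq_len(k))) {
      st <- cat_block(flow$blocks[[i]], x, cond_features, "inverse",
                      flow$clamp)
      x <- st$y
      ld <- ld + st$log_det
      x[, , flow$perms[[i]], ] <- x
    }
    list(x = x, log_det = ld)
  }
}

as_batch <- function(x) {
  x <- as.array(x)
  if (length(dim(x)) == 3L) x <- array(x, c(dim(x), 1L))
  if (length(dim(x)) != 4L) stop("expected a (H, W, C[, N]) array")
  x
}

#' Negative log-likelihood of a latent code
#'
#' Training form (per sample): \code{||z||^2 / 2 - log_det + rho *
#' param_sq_norm}, the exact negative log-likelihood of the data under the
#' flow up to the Gaussian normalizing constant. The normalized form divides
#' the first two terms by the number of elements and adds \code{log(2*pi)/2},
#' giving a per-element NLL comparable across levels and volume sizes (used
#' for out-of-distribution scoring).
#'
#' @param z latent array (any shape)
#' @param log_det accumulated log-determinant (scalar, for one sample)
#' @param rho weight of the Gaussian parameter prior
#' @param param_sq_norm squared L2 norm of the model parameters
#' @return list \code{(train, per_element)}
#' @export
nll <- function(z, log_det, rho = 0, param_sq_norm = 0) {
  sq <- sum(z^2)
  train <- sq / 2 - log_det + rho * param_sq_norm
  per_element <- (sq / 2 - log_det) / length(z) + 0.5 * log(2 * pi)
  list(train = train, per_element = per_element)
}

#' Draw a latent sample at a given temperature
#'
#' Returns \code{T * eps} with \code{eps ~ N(0, 1)} under a seeded generator.
#' Temperature 0 short-circuits to exact zeros without consuming any random
#' numbers, so zero-temperature reconstruction is fully deterministic (the
#' modal sample). The caller's RNG state is left untouched when a seed is
#' given.
#'
#' @param shape integer vector of array dimensions
#' @param temperature scale \code{T >= 0}
#' @param seed optional integer seed
#' @return numeric array of dimension \code{shape}
#' @export
sample_latent <- function(shape, temperature = 0, seed = NULL) {
  if (temperature < 0) stop("temperature must be >= 0")
  if (temperature == 0) return(array(0, shape))
  with_seed(seed, array(temperature * stats::rnorm(prod(shape)), shape))
}

# --- training-oriented passes with caches ----------------------------------

flow_fwd_cache <- function(flow, x, cond) {
  k <- length(flow$blocks)
  caches <- vector("list", k)
  ld <- numeric(dim(x)[4])
  for (i in seq_len(k)) {
    x <- x[, , flow$perms[[i]], , drop = FALSE]
    sn <- cat_subnet(flow$blocks[[i]], cond, flow$clamp, flow$n_channels)
    caches[[i]] <- c(sn, list(x_in = x))
    x <- sn$s * x + sn$t
    ld <- ld + apply(sn$g, 4, sum)
  }
  list(z = x, log_det = ld, caches = caches)
}

# backward through the cached forward pass.
# dz: gradient on z; dld: scalar coefficient multiplying log_det in the loss
# (the same for every sample). Returns grads per block plus dcond.
flow_fwd_bwd <- function(flow, fw, dz, dld) {
  k <- length(flow$blocks)
  grads <- vector("list", k)
  dcond <- NULL
  for (i in rev(seq_len(k))) {
    ca <- fw$caches[[i]]
    ds <- dz * ca$x_in                      # dL/ds via y = s*x + t
    dt <- dz
    dg <- ds * ca$s + dld                   # + logdet term, elementwise
    draw <- dg * (1 - ca$th^2)
    dy_sub <- abind4(draw, dt)
    nb <- net_bwd(dy_sub, flow$blocks[[i]], ca$fw)
    grads[[i]] <- nb$grads
    dcond <- if (is.null(dcond)) nb$dx else dcond + nb$dx
    dz <- dz * ca$s                         # into the block input
    dz[, , flow$perms[[i]], ] <- dz         # undo the permutation
  }
  list(grads = grads, dcond = dcond)
}

flow_inv_cache <- function(flow, z, cond) {
  k <- length(flow$blocks)
  caches <- vector("list", k)
  x <- z
  for (i in rev(seq_len(k))) {
    sn <- cat_subnet(flow$blocks[[i]], cond, flow$clamp, flow$n_channels)
    caches[[i]] <- sn
    x <- (x - sn$t) / sn$s
    caches[[i]]$w_out <- x
    x_un <- x
    x_un[, , flow$perms[[i]], ] <- x
    x <- x_un
  }
  list(x = x, caches = caches)
}

# backward through the cached inverse pass, given dL/dx on the output.
flow_inv_bwd <- function(flow, iv, dx) {
  k <- length(flow$blocks)
  grads <- vector("list", k)
  dcond <- NULL
  for (i in seq_len(k)) {
    ca <- iv$caches[[i]]
    d <- dx[, , flow$perms[[i]], , drop = FALSE]  # undo the un-permute
    dt <- -d / ca$s
    ds <- -d * ca$w_out / ca$s
    dg <- ds * ca$s
    draw <- dg * (1 - ca$th^2)
    dy_sub <- abind4(draw, dt)
    nb <- net_bwd(dy_sub, flow$blocks[[i]], ca$fw)
    grads[[i]] <- nb$grads
    dcond <- if (is.null(dcond)) nb$dx else dcond + nb$dx
    dx <- d / ca$s                                # gradient on the block input
  }
  list(grads = grads, dcond = dcond)
}

# concatenate two (H, W, C, N) arrays along the channel axis
abind4 <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

flow_params <- function(flow) flow$blocks

flow_set_params <- function(flow, params) {
  flow$blocks <- params
  flow
}
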