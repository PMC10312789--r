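#' @useDynLib cwflow, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Minimal convolutional network engine with hand-written backpropagation.
#
# Feature maps are batched 4D arrays (H, W, C, N). Convolutions are 3x3,
# stride 1, zero padding 1 (shape preserving), implemented by im2col +
# matrix multiplication so the whole training batch is one BLAS call.
# This is deliberately small: two-layer subnets at desk scale do not
# justify an external deep-learning dependency.

KSIZE <- 3L

# He-style init; final layers of subnets are zero-initialized by callers so
# flows start at the identity map.
conv_layer <- function(cin, cout, zero = FALSE) {
  n <- KSIZE * KSIZE * cin
  w <- if (zero) array(0, c(KSIZE, KSIZE, cin, cout))
  else array(stats::rnorm(n * cout, sd = sqrt(2 / n)),
             c(KSIZE, KSIZE, cin, cout))
  list(W = w, b = numeric(cout))
}

# (H, W, C, N) -> matrix (H*W*N) x (9*C), rows ordered (h, w, n); column
# (kr, kc, ci) sits at kr + 3*(kc-1) + 9*(ci-1), matching the column-major
# flattening of a (3, 3, cin, cout) weight array. Compiled kernels; see
# src/conv_ops.cpp.
im2col <- function(x) {
  d <- dim(x)
  im2col_cpp(x, d[1], d[2], d[3], d[4])
}

col2im <- function(dcol, h, w, cc, n) {
  col2im_cpp(dcol, h, w, cc, n)
}

conv_fwd <- function(x, layer) {
  d <- dim(x)
  cout <- dim(layer$W)[4]
  xcol <- im2col(x)
  wmat <- matrix(layer$W, ncol = cout)
  ymat <- sweep(xcol %*% wmat, 2, layer$b, "+")
  y <- aperm(array(ymat, c(d[1], d[2], d[4], cout)), c(1, 2, 4, 3))
  list(y = y, xcol = xcol, din = d)
}

conv_bwd <- function(dy, layer, cache) {
  d <- cache$din
  cout <- dim(layer$W)[4]
  dymat <- matrix(aperm(dy, c(1, 2, 4, 3)), ncol = cout)
  dW <- array(crossprod(cache$xcol, dymat), dim(layer$W))
  db <- colSums(dymat)
  dcol <- dymat %*% t(matrix(layer$W, ncol = cout))
  dx <- col2im(dcol, d[1], d[2], d[3], d[4])
  list(dx = dx, grads = list(W = dW, b = db))
}

LRELU_SLOPE <- 0.1

lrelu <- function(x) {
  neg <- x < 0
  x[neg] <- LRELU_SLOPE * x[neg]
  x
}

lrelu_bwd <- function(dy, x) {
  neg <- x < 0
  dy[neg] <- LRELU_SLOPE * dy[neg]
  dy
}

# A plain stack of conv layers with leaky-ReLU between (linear final layer).
convnet <- function(channels, zero_last = TRUE) {
  n <- length(channels) - 1L
  layers <- vector("list", n)
  for (i in seq_len(n))
    layers[[i]] <- conv_layer(channels[i], channels[i + 1L],
                              zero = zero_last && i == n)
  layers
}

net_fwd <- function(x, net) {
  k <- length(net)
  caches <- vector("list", k)
  pre <- vector("list", k)
  for (i in seq_len(k)) {
    cf <- conv_fwd(x, net[[i]])
    caches[[i]] <- cf
    pre[[i]] <- cf$y
    x <- if (i < k) lrelu(cf$y) else cf$y
  }
  list(y = x, caches = caches, pre = pre)
}

net_bwd <- function(dy, net, fw) {
  k <- length(net)
  grads <- vector("list", k)
  for (i in rev(seq_len(k))) {
    if (i < k) dy <- lrelu_bwd(dy, fw$pre[[i]])
    cb <- conv_bwd(dy, net[[i]], fw$caches[[i]])
    grads[[i]] <- cb$grads
    dy <- cb$dx
  }
  list(dx = dy, grads = grads)
}

# --- parameter-tree utilities ----------------------------------------------

# walk two congruent nested lists of arrays, applying f leaf-wise
tree_map2 <- function(a, b, f) {
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (i in seq_along(a)) out[[i]] <- tree_map2(a[[i]], b[[i]], f)
    out
  } else f(a, b)
}

tree_map <- function(a, f) {
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (i in seq_along(a)) out[[i]] <- tree_map(a[[i]], f)
    out
  } else f(a)
}

tree_sum <- function(a, f = identity) {
  if (is.list(a)) sum(vapply(a, tree_sum, 0, f = f)) else sum(f(a))
}

tree_add <- function(a, b) {
  if (is.null(a)) return(b)
  tree_map2(a, b, `+`)
}

param_sq_norm <- function(params) tree_sum(params, function(x) x^2)

# --- AdamW: adaptive moments with decoupled weight decay --------------------
# The decoupled decay term implements the Gaussian parameter prior
# rho * ||Theta||^2 of the training objective.

adamw_init <- function(params) {
  list(m = tree_map(params, function(x) x * 0),
       v = tree_map(params, function(x) x * 0),
       t = 0L)
}

adamw_step <- function(params, grads, state, lr, weight_decay = 0,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- tree_map2(state$m, grads, function(m, g) beta1 * m +
                         (1 - beta1) * g)
  state$v <- tree_map2(state$v, grads, function(v, g) beta2 * v +
                         (1 - beta2) * g^2)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- tree_map2(state$m, state$v, function(m, v)
    (m / bc1) / (sqrt(v / bc2) + eps))
  params <- tree_map2(params, upd, function(p, u)
    p - lr * u - lr * weight_decay * p)
  list(params = params, state = state)
}
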