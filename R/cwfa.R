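#' Model configuration for the conditional wavelet-flow hierarchy
#'
#' Defaults are the desk-scale study conditions used throughout the package:
#' 32 x 32 x 16 volumes, 9 lenslet views of 32 x 32, and two wavelet-flow
#' levels (the axial depth of 16 supports two halvings). Each level holds a
#' conditional flow of 6 CAT blocks with 14 hidden channels per convolution,
#' plus a conditioning network mapping the raw conditions (cropped views and
#' the axially reduced structural prior) to feature maps at that level's
#' scale.
#'
#' @param vol_shape integer length-3 \code{(H, W, D)} of the full-resolution
#'   volume; \code{D} must be divisible by \code{2^levels} and \code{H},
#'   \code{W} must equal \code{crop_size}
#' @param n_views number of lenslet views in the condition stack
#' @param crop_size side length of each cropped view
#' @param levels number of wavelet-flow levels
#' @param blocks_per_level CAT blocks per conditional flow
#' @param hidden_channels hidden width of the CAT subnets
#' @param omega_channels feature channels emitted by each conditioning
#'   network
#' @param omega_hidden hidden width of the conditioning networks
#' @param omega_depth number of convolution layers in each conditioning
#'   network; depth buys receptive field, which the conditioning needs
#'   because depth is encoded in the views as lateral parallax shifts
#' @param lr_hidden hidden width of the deterministic low-resolution network
#' @param use_deconv condition on a partial Richardson-Lucy deconvolution of
#'   the measurement in addition to views and prior. Depth information sits
#'   in the views only as lens-dependent parallax shifts that local
#'   convolutions cannot resolve; a few multiplicative deconvolution steps
#'   re-express the measurement in voxel space, where it conditions the
#'   flows locally.
#' @param cond_deconv_iters Richardson-Lucy iterations used for that
#'   condition (a cheap partial deconvolution, not a converged one)
#' @param clamp soft-clamp bound on the CAT log-scales
#' @param seed integer; two builds with the same configuration and seed have
#'   identical initial parameters
#' @return a named list of class \code{cwfa_config}
#' @export
cwfa_config <- function(vol_shape = c(32L, 32L, 16L), n_views = 9L,
                        crop_size = 32L, levels = 2L, blocks_per_level = 6L,
                        hidden_channels = 14L, omega_channels = 18L,
                        omega_hidden = 22L, omega_depth = 4L,
                        lr_hidden = 24L, use_deconv = TRUE,
                        cond_deconv_iters = 60L, clamp = 2.0, seed = 1L) {
  cfg <- list(vol_shape = as.integer(vol_shape), n_views = as.integer(n_views),
              crop_size = as.integer(crop_size), levels = as.integer(levels),
              blocks_per_level = as.integer(blocks_per_level),
              hidden_channels = as.integer(hidden_channels),
              omega_channels = as.integer(omega_channels),
              omega_hidden = as.integer(omega_hidden),
              omega_depth = as.integer(omega_depth),
              lr_hidden = as.integer(lr_hidden),
              use_deconv = isTRUE(use_deconv),
              cond_deconv_iters = as.integer(cond_deconv_iters),
              clamp = clamp, seed = as.integer(seed))
  class(cfg) <- "cwfa_config"
  cfg
}

#' Training configuration
#'
#' @param alpha weight of the spatial reconstruction term added to the
#'   negative log-likelihood (default 0.48)
#' @param rho weight of the Gaussian parameter prior, applied as decoupled
#'   weight decay
#' @param epochs_per_level full-batch epochs when training one flow level
#' @param epochs_lr epochs for the deterministic low-resolution network
#' @param lr peak learning rate; each training run anneals it to zero with a
#'   cosine schedule, which stabilizes the likelihood term late in training
#'   so the spatial term's small gradients are not drowned by oscillation
#' @param seed integer seed making training runs reproducible
#' @return a named list of class \code{train_config}
#' @export
train_config <- function(alpha = 0.48, rho = 1e-6, epochs_per_level = 250L,
                         epochs_lr = 300L, lr = 2e-3, seed = 1L) {
  if (alpha < 0 || rho < 0) stop("alpha and rho must be >= 0")
  structure(list(alpha = alpha, rho = rho,
                 epochs_per_level = as.integer(epochs_per_level),
                 epochs_lr = as.integer(epochs_lr),
                 lr = lr, seed = as.integer(seed)),
            class = "train_config")
}

cosine_lr <- function(base, ep, total) {
  if (total <= 1) return(base)
  base * 0.5 * (1 + cos(pi * (ep - 1) / (total - 1)))
}

#' Build a conditional wavelet-flow model
#'
#' Constructs the deterministic low-resolution network (LR-NN) and
#' \code{levels} wavelet-flow levels. Level \code{i} (1-based, finest first)
#' models the axial Haar detail coefficients \code{D_i} of depth
#' \code{D / 2^i}, conditioned on features computed by its own network
#' \code{Omega_i} from the cropped views and the structural prior reduced
#' \code{i} times. Construction is deterministic under the configuration
#' seed.
#'
#' @param config a [cwfa_config()]
#' @return a \code{cwfa_model}; printable parameter counts per component
#' @export
build_model <- function(config = cwfa_config()) {
  d <- config$vol_shape[3]
  n <- config$levels
  if (d %% (2^n) != 0L)
    stop(sprintf("config error: depth %d not divisible by 2^%d", d, n))
  if (config$vol_shape[1] != config$crop_size ||
      config$vol_shape[2] != config$crop_size)
    stop("config error: lateral volume size must equal crop_size")
  levels <- vector("list", n)
  nbp <- if (config$use_deconv) 2L else 0L
  for (i in seq_len(n)) {
    dd <- d %/% (2^i)
    omega_in <- config$n_views + dd * (1L + nbp)
    levels[[i]] <- list(
      index = i,
      detail_depth = dd,
      omega = with_seed(config$seed + 100L * i,
                        convnet(c(omega_in,
                                  rep(config$omega_hidden,
                                      config$omega_depth - 1L),
                                  config$omega_channels),
                                zero_last = FALSE)),
      flow = conditional_flow(dd, config$omega_channels,
                              n_blocks = config$blocks_per_level,
                              hidden = config$hidden_channels,
                              clamp = config$clamp,
                              seed = config$seed + 1000L * i))
  }
  dn <- d %/% (2^n)
  lr_nn <- with_seed(config$seed,
                     convnet(c(config$n_views + dn * (1L + nbp %/% 2L),
                               config$lr_hidden, config$lr_hidden, dn),
                             zero_last = TRUE))
  structure(list(config = config, levels = levels, lr_nn = lr_nn),
            class = "cwfa_model")
}

#' @export
print.cwfa_model <- function(x, ...) {
  cnt <- model_param_counts(x)
  cat(sprintf("<cwfa_model: %d levels, %s parameters>\n",
              length(x$levels), format(sum(unlist(cnt)), big.mark = ",")))
  for (nm in names(cnt)) cat(sprintf("  %-10s %8d\n", nm, cnt[[nm]]))
  invisible(x)
}

#' Parameter counts per model component
#' @param model a \code{cwfa_model}
#' @return named list of integer counts
#' @export
model_param_counts <- function(model) {
  cnt <- list(lr_nn = tree_sum(model$lr_nn, function(x) length(x)))
  for (i in seq_along(model$levels)) {
    lv <- model$levels[[i]]
    cnt[[sprintf("flow_%d", i)]] <- tree_sum(lv$flow$blocks, length)
    cnt[[sprintf("omega_%d", i)]] <- tree_sum(lv$omega, length)
  }
  cnt
}

# raw condition channel stack at the scale of level i (i = levels for the
# LR-NN): cropped views + prior reduced i times axially; when a deconvolved
# volume is present, also its own Haar pyramid at that level. For a flow
# level the deconv's level-i detail coefficients are included -- they are a
# direct (noisy, blurred) estimate of the coefficients the level models, so
# the subnets only need to learn a local correction. The LR-NN receives the
# approximation pathway only (there is no detail at its scale).
cond_raw_stack <- function(conds, reduce_times, with_detail = TRUE) {
  n <- length(conds)
  v1 <- grid_of(conds[[1]]$views)
  nv <- dim(v1)[3]
  dd <- dim(conds[[1]]$prior)[3] %/% (2^reduce_times)
  has_dc <- !is.null(conds[[1]]$deconv)
  cc <- nv + dd * (1L + has_dc * (1L + with_detail))
  out <- array(0, c(dim(v1)[1], dim(v1)[2], cc, n))
  for (k in seq_len(n)) {
    out[, , seq_len(nv), k] <- grid_of(conds[[k]]$views)
    out[, , nv + seq_len(dd), k] <-
      haar_reduce(conds[[k]]$prior, reduce_times)
    if (has_dc) {
      cur <- conds[[k]]$deconv
      det <- NULL
      for (i in seq_len(reduce_times)) {
        hp <- haar_axial_forward(cur)
        cur <- hp$approximation
        det <- hp$details
      }
      out[, , nv + dd + seq_len(dd), k] <- cur
      if (with_detail)
        out[, , nv + 2L * dd + seq_len(dd), k] <- det
    }
  }
  out
}

#' Build a condition set
#'
#' Pairs the per-lens view stack (condition 1) with the structural prior
#' volume (condition 2, typically the mean of the training volumes), plus an
#' optional volume-space summary of the measurement (condition 3): a partial
#' Richardson-Lucy deconvolution ([richardson_lucy()] at a few iterations)
#' or, in the cheap limit, the normalized back-projection of
#' [backproject_image()]. This re-expresses the multi-view measurement in
#' voxel space, so depth evidence -- encoded in the views only as
#' lens-dependent parallax shifts -- becomes locally available to the
#' conditioning networks.
#'
#' @param views a [view_stack()] or \code{(crop, crop, n_views)} array
#' @param prior a [volume()] or \code{(H, W, D)} array at full resolution
#' @param deconv optional \code{(H, W, D)} array (same grid as \code{prior})
#' @return a \code{condition_set}
#' @export
condition_set <- function(views, prior, deconv = NULL) {
  dc <- if (!is.null(deconv)) as_grid(deconv, 3L, "deconv")
  structure(list(views = as_grid(views, 3L, "views"),
                 prior = as_grid(prior, 3L, "prior"),
                 deconv = dc),
            class = "condition_set")
}

#' Normalized adjoint back-projection of a light-field image
#'
#' Computes \code{A^T m / (A^T 1 + eps)} where \code{A} is the linear
#' projector of [forward_project()]. This is the classic shift-and-add
#' refocusing of the multi-view measurement: linear in the image, on the
#' intensity scale of the volume, with depth planes focused at their true
#' axial position. Used as the third conditioning pathway of the model.
#'
#' @param image an [lf_image()] or matrix
#' @param psf a [psf_stack()]
#' @param vol_lateral integer length-2 lateral size of the target volume
#' @param epsilon division guard
#' @return \code{(H, W, D)} array
#' @export
backproject_image <- function(image, psf, vol_lateral = NULL,
                              epsilon = 1e-12) {
  m <- as_grid(image, 2L, "image")
  g <- grid_of(psf)
  if (is.null(vol_lateral)) vol_lateral <- dim(g)[1:2]
  p <- make_projector(psf, vol_lateral)
  nrm <- proj_adjoint(p, matrix(1, nrow(m), ncol(m)))
  pmax(proj_adjoint(p, m), 0) / (nrm + epsilon)
}

#' Condition features for one level
#'
#' Runs the level's conditioning network on the raw condition stack (views
#' plus the prior reduced to the level's axial scale). Exposed for
#' inspection; training and reconstruction call it internally.
#'
#' @param model a \code{cwfa_model}
#' @param cond a [condition_set()] or list of them
#' @param level 1-based level index (1 = finest)
#' @return feature array \code{(H, W, omega_channels, N)}
#' @export
condition_features <- function(model, cond, level) {
  if (inherits(cond, "condition_set")) cond <- list(cond)
  if (level < 1 || level > length(model$levels))
    stop("config error: no such level: ", level)
  check_cond(model, cond[[1]])
  x <- cond_raw_stack(cond, level)
  net_fwd(x, model$levels[[level]]$omega)$y
}

check_cond <- function(model, cond) {
  if (model$config$use_deconv && is.null(cond$deconv))
    stop("config error: model conditions on a deconvolved volume, but the ",
         "condition set has none (see richardson_lucy / condition_set)")
  invisible(TRUE)
}

# level-i Haar detail coefficients of the deconvolved condition volume: a
# direct measurement-derived estimate of the coefficients level i models.
# When the model uses the deconvolution condition, each level's flow is
# recentered on this estimate -- a fixed conditional translation (unit
# scale, zero log-determinant), so the flow models the residual and the
# likelihood stays exact.
deconv_detail <- function(cond, level) {
  if (is.null(cond$deconv)) return(NULL)
  cur <- cond$deconv
  det <- NULL
  for (i in seq_len(level)) {
    hp <- haar_axial_forward(cur)
    cur <- hp$approximation
    det <- hp$details
  }
  det
}

level_center <- function(model, conds, level) {
  if (!model$config$use_deconv) return(0)
  stack4(lapply(conds, deconv_detail, level = level))
}

# single-condition variant used outside the training loop
cwfa_level_center <- function(model, cond, level) {
  if (!model$config$use_deconv) return(0)
  array(deconv_detail(cond, level), c(dim(cond$prior)[1:2],
                                      dim(cond$prior)[3] %/% (2^level), 1L))
}

# LR-NN forward: residual on top of a coarse initial estimate. With the
# deconvolution condition that estimate is the frame's own deconvolved
# volume reduced to the coarse scale (frame-specific, so the network only
# learns the deconvolution -> truth correction); without it, the static
# structural prior.
lr_nn_fwd <- function(model, xraw, skip_n) {
  fw <- net_fwd(xraw, model$lr_nn)
  list(y = fw$y + skip_n, fw = fw)
}

lr_skip_stack <- function(model, conds) {
  n <- length(model$levels)
  src <- if (model$config$use_deconv) "deconv" else "prior"
  stack4(lapply(conds, function(cond) haar_reduce(cond[[src]], n)))
}

# stack per-sample 3D grids into (H, W, C, N)
stack4 <- function(lst) {
  d <- dim(lst[[1]])
  out <- array(0, c(d, length(lst)))
  for (k in seq_along(lst)) out[, , , k] <- lst[[k]]
  out
}

#' Train one wavelet-flow level
#'
#' Full-batch gradient training of level \code{i}'s conditional flow and its
#' conditioning network, leaving every other component untouched. The
#' per-sample objective combines the exact negative log-likelihood of the
#' level's Haar detail coefficients with a spatial term:
#' \deqn{L = \mathrm{NLL}(D_i | \Omega_i(C)) / |D_i| +
#'       \alpha\, \mathrm{mean}((V_{i-1} - \tilde V_{i-1})^2)}
#' where \eqn{\tilde V_{i-1}} is the modal reconstruction (latent zero)
#' assembled from the true next-coarser volume, so levels stay independent.
#' The parameter prior \code{rho * ||Theta||^2} enters as decoupled weight
#' decay.
#'
#' @param model a \code{cwfa_model}
#' @param i 1-based level index
#' @param dataset non-empty list of samples, each
#'   \code{list(v0 = array, cond = condition_set)}
#' @param cfg a [train_config()]
#' @return list \code{(model, history)}; history is a data frame with the
#'   per-epoch mean per-element NLL and spatial MSE
#' @export
train_level <- function(model, i, dataset, cfg = train_config()) {
  if (length(dataset) == 0) stop("data error: empty dataset")
  check_cond(model, dataset[[1]]$cond)
  lv <- model$levels[[i]]
  n <- length(dataset)
  pyr <- lapply(dataset, function(s) haar_pyramid(grid_of(s$v0), i))
  center <- level_center(model, lapply(dataset, `[[`, "cond"), i)
  dbatch <- stack4(lapply(pyr, function(p) p$details[[i]])) - center
  vcoarse <- stack4(lapply(pyr, function(p) p$approx))      # V_i (true)
  vtarget <- if (i == 1) stack4(lapply(dataset, function(s) grid_of(s$v0)))
  else stack4(lapply(pyr, function(p) p$approx_per_level[[i - 1L]]))
  xraw <- cond_raw_stack(lapply(dataset, `[[`, "cond"), i)
  params <- list(blocks = lv$flow$blocks, omega = lv$omega)
  opt <- adamw_init(params)
  history <- data.frame(epoch = integer(), nll = numeric(),
                        spatial = numeric(), loss = numeric())
  numel_z <- prod(dim(dbatch)[1:3])
  numel_v <- prod(dim(vtarget)[1:3])
  clamp <- lv$flow$clamp
  nch <- lv$flow$n_channels
  perms <- lv$flow$perms
  nblocks <- length(lv$flow$blocks)
  with_seed(cfg$seed, for (ep in seq_len(cfg$epochs_per_level)) {
    om <- net_fwd(xraw, params$omega)
    # subnet scale/translation once per block; both the likelihood pass and
    # the modal (latent-zero) reconstruction pass reuse them
    sns <- lapply(params$blocks, cat_subnet, cond = om$y, clamp = clamp,
                  nch = nch)
    # likelihood path: details -> z
    x <- dbatch
    x_ins <- vector("list", nblocks)
    log_det <- 0
    for (k in seq_len(nblocks)) {
      x <- x[, , perms[[k]], , drop = FALSE]
      x_ins[[k]] <- x
      x <- sns[[k]]$s * x + sns[[k]]$t
      log_det <- log_det + sum(sns[[k]]$g)
    }
    z <- x
    nll_term <- (0.5 * sum(z^2) - log_det) / (numel_z * n)
    # modal path: latent zero -> details -> V_{i-1}
    y <- array(0, dim(dbatch))
    w_outs <- vector("list", nblocks)
    for (k in rev(seq_len(nblocks))) {
      w <- (y - sns[[k]]$t) / sns[[k]]$s
      w_outs[[k]] <- w
      y[, , perms[[k]], ] <- w
    }
    vrec <- haar_inverse4(vcoarse, center + y)
    diff <- vrec - vtarget
    sp_term <- sum(diff^2) / (numel_v * n)
    # the per-sample objective is (NLL + alpha * ||V - Vrec||^2) in summed
    # form; dividing the whole loss by numel_z keeps the two terms at the
    # ratio the summed form implies (numel_v = 2 * numel_z)
    sp_weight <- cfg$alpha * numel_v / numel_z
    loss <- nll_term + sp_weight * sp_term
    history[ep, ] <- list(ep, nll_term + 0.5 * log(2 * pi), sp_term, loss)
    if (cfg$lr == 0) next
    # backward, likelihood chain (blocks last to first)
    ds1 <- vector("list", nblocks); dt1 <- vector("list", nblocks)
    d <- z / (numel_z * n)
    for (k in rev(seq_len(nblocks))) {
      ds1[[k]] <- d * x_ins[[k]]
      dt1[[k]] <- d
      d <- d * sns[[k]]$s
      d[, , perms[[k]], ] <- d
    }
    # backward, modal chain (blocks first to last)
    ds2 <- vector("list", nblocks); dt2 <- vector("list", nblocks)
    d <- haar_forward4_details(2 * sp_weight * diff / (numel_v * n))
    for (k in seq_len(nblocks)) {
      dk <- d[, , perms[[k]], , drop = FALSE]
      dt2[[k]] <- -dk / sns[[k]]$s
      ds2[[k]] <- dt2[[k]] * w_outs[[k]]
      d <- dk / sns[[k]]$s
    }
    # one subnet backward per block; log-det adds -1/(numel*n) to every dg
    gblocks <- vector("list", nblocks)
    dcond <- 0
    for (k in seq_len(nblocks)) {
      dg <- (ds1[[k]] + ds2[[k]]) * sns[[k]]$s - 1 / (numel_z * n)
      draw <- dg * (1 - sns[[k]]$th^2)
      nb <- net_bwd(abind4(draw, dt1[[k]] + dt2[[k]]), params$blocks[[k]],
                    sns[[k]]$fw)
      gblocks[[k]] <- nb$grads
      dcond <- dcond + nb$dx
    }
    omb <- net_bwd(dcond, params$omega, om)
    grads <- list(blocks = gblocks, omega = omb$grads)
    st <- adamw_step(params, grads, opt,
                     cosine_lr(cfg$lr, ep, cfg$epochs_per_level),
                     weight_decay = cfg$rho)
    params <- st$params
    opt <- st$state
  })
  model$levels[[i]]$flow <- flow_set_params(lv$flow, params$blocks)
  model$levels[[i]]$omega <- params$omega
  list(model = model, history = history)
}

# batched axial Haar inverse / forward-details over (H, W, C, N)
haar_inverse4 <- function(approx, details) {
  d <- dim(approx)
  out <- array(0, c(d[1], d[2], 2L * d[3], d[4]))
  out[, , seq(1L, 2L * d[3], 2L), ] <- (approx + details) / sqrt(2)
  out[, , seq(2L, 2L * d[3], 2L), ] <- (approx - details) / sqrt(2)
  out
}

haar_forward4_details <- function(v) {
  d <- dim(v)
  (v[, , seq(1L, d[3], 2L), , drop = FALSE] -
     v[, , seq(2L, d[3], 2L), , drop = FALSE]) / sqrt(2)
}

#' Train the deterministic low-resolution network
#'
#' Supervised regression of the condition set onto the coarsest pyramid
#' volume \code{V_n}. The network predicts a residual on top of the axially
#' reduced structural prior, so an untrained model already outputs the prior.
#'
#' @inheritParams train_level
#' @return list \code{(model, history)} with per-epoch training MSE
#' @export
train_lr_nn <- function(model, dataset, cfg = train_config()) {
  if (length(dataset) == 0) stop("data error: empty dataset")
  check_cond(model, dataset[[1]]$cond)
  n_lv <- length(model$levels)
  n <- length(dataset)
  vn <- stack4(lapply(dataset, function(s)
    haar_reduce(grid_of(s$v0), n_lv)))
  xraw <- cond_raw_stack(lapply(dataset, `[[`, "cond"), n_lv,
                         with_detail = FALSE)
  skip_n <- lr_skip_stack(model, lapply(dataset, `[[`, "cond"))
  params <- model$lr_nn
  opt <- adamw_init(params)
  history <- data.frame(epoch = integer(), mse = numeric())
  numel <- prod(dim(vn)[1:3])
  with_seed(cfg$seed, for (ep in seq_len(cfg$epochs_lr)) {
    fw <- net_fwd(xraw, params)
    diff <- fw$y + skip_n - vn
    mse <- sum(diff^2) / (numel * n)
    history[ep, ] <- list(ep, mse)
    if (cfg$lr == 0) next
    bw <- net_bwd(2 * diff / (numel * n), params, fw)
    st <- adamw_step(params, bw$grads, opt,
                     cosine_lr(cfg$lr, ep, cfg$epochs_lr),
                     weight_decay = cfg$rho)
    params <- st$params
    opt <- st$state
  })
  model$lr_nn <- params
  list(model = model, history = history)
}

#' Train all model components
#'
#' Convenience wrapper: trains the LR-NN, then each flow level independently
#' (coarsest to finest; the order is immaterial since levels do not share
#' parameters).
#'
#' @inheritParams train_level
#' @return list \code{(model, history)}; history is a named list per
#'   component
#' @export
train_model <- function(model, dataset, cfg = train_config()) {
  hist <- list()
  r <- train_lr_nn(model, dataset, cfg)
  model <- r$model
  hist$lr_nn <- r$history
  for (i in rev(seq_along(model$levels))) {
    r <- train_level(model, i, dataset, cfg)
    model <- r$model
    hist[[sprintf("level_%d", i)]] <- r$history
  }
  list(model = model, history = hist)
}

#' Reconstruct a 3D volume from a condition set
#'
#' Inverse pass through the hierarchy: the LR-NN predicts the coarsest
#' volume, then each level (coarsest to finest) samples a latent at the given
#' temperature, inverts its conditional flow into detail coefficients, and
#' up-samples axially with the inverse Haar transform. Temperature 0 uses the
#' latent mode (all zeros) and is fully deterministic.
#'
#' Negative values are clipped to zero as a final step, and by default voxels
#' outside the support of the structural prior are zeroed as well
#' (\code{support = "prior"}): with immobilized samples the prior delimits
#' where signal can occur, and the sparse ground truth this model targets is
#' exactly zero elsewhere. Use \code{support = "none"} for the unrestricted
#' output.
#'
#' @param model a \code{cwfa_model}
#' @param cond a [condition_set()]
#' @param temperature latent sampling scale, \code{>= 0}
#' @param seed optional seed for the latent draws (ignored at temperature 0)
#' @param support \code{"prior"} (default) or \code{"none"}
#' @return list with \code{volume} (a [volume()]), \code{intermediates}
#'   (coarse-to-fine volumes before clipping) and \code{latents}
#' @export
reconstruct <- function(model, cond, temperature = 0, seed = NULL,
                        support = c("prior", "none")) {
  support <- match.arg(support)
  stopifnot(inherits(cond, "condition_set"))
  check_cond(model, cond)
  n <- length(model$levels)
  xraw_n <- cond_raw_stack(list(cond), n, with_detail = FALSE)
  v <- lr_nn_fwd(model, xraw_n, lr_skip_stack(model, list(cond)))$y
  inter <- list(v[, , , 1])
  lat <- list()
  for (i in rev(seq_len(n))) {
    lv <- model$levels[[i]]
    feats <- condition_features(model, cond, i)
    zshape <- c(dim(v)[1:2], lv$detail_depth, 1L)
    z <- sample_latent(zshape, temperature,
                       seed = if (is.null(seed)) NULL else seed + i)
    dtl <- flow_apply(lv$flow, z, feats, "inverse")$x +
      level_center(model, list(cond), i)
    v <- haar_inverse4(v, dtl)
    inter[[length(inter) + 1L]] <- v[, , , 1]
    lat[[sprintf("level_%d", i)]] <- z[, , , 1]
  }
  out <- v[, , , 1]
  out[out < 0] <- 0
  if (support == "prior") out[cond$prior == 0] <- 0
  list(volume = volume(out), intermediates = inter, latents = lat)
}
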