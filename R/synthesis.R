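#' Generate a synthetic neural-activity scene
#'
#' Emulates an immobilized animal imaged over time: neuron positions are
#' fixed across frames, only the activity changes. Positions are drawn
#' uniformly inside the volume with a minimum pairwise separation of
#' \code{2 * sigma} (bounded rejection sampling); each neuron's amplitude
#' series is a Bernoulli(\code{event_rate}) onset train convolved with a
#' causal exponential kernel \code{exp(-t / decay)} (calcium-indicator-like:
#' sparse onsets, exponential decay). Fully reproducible under the seed.
#'
#' @param n_neurons number of neurons
#' @param shape integer length-3 \code{(H, W, D)} of the volume grid
#' @param frames number of time frames
#' @param event_rate per-frame onset probability
#' @param decay exponential decay constant in frames
#' @param burn_in number of unrecorded frames simulated before frame 1, so
#'   the activity process is in steady state when the recording starts (an
#'   acquisition joins ongoing activity; without burn-in the first frames
#'   would be unrealistically silent)
#' @param sigma isotropic Gaussian blob width in voxels; blobs are truncated
#'   at \code{3 * sigma} so volumes have exactly-zero background
#' @param seed integer seed
#' @return a \code{synthetic_scene}: positions (\code{n x 3}), amplitude
#'   matrix (\code{n x frames}) and the generating parameters
#' @export
generate_scene <- function(n_neurons = 5L, shape = c(32L, 32L, 16L),
                           frames = 40L, event_rate = 0.3, decay = 3,
                           sigma = 1.1, burn_in = 20L, seed = 1L) {
  stopifnot(n_neurons >= 1, frames >= 1, decay > 0, sigma > 0)
  with_seed(seed, {
    min_sep <- 2 * sigma
    margin <- ceiling(sigma)  # keep blob cores inside the grid
    lo <- c(margin, margin, min(margin, shape[3] %/% 4 + 1L))
    hi <- shape - lo + 1L
    if (any(hi < lo)) stop("placement error: volume too small for sigma")
    pos <- matrix(0, 0, 3)
    tries <- 0L
    while (nrow(pos) < n_neurons) {
      tries <- tries + 1L
      if (tries > 5000L)
        stop(sprintf(
          "placement error: placed %d of %d neurons at separation %.1f",
          nrow(pos), n_neurons, min_sep))
      p <- c(sample(lo[1]:hi[1], 1), sample(lo[2]:hi[2], 1),
             sample(lo[3]:hi[3], 1))
      if (nrow(pos) == 0 ||
          all(sqrt(rowSums(sweep(pos, 2, p)^2)) >= min_sep))
        pos <- rbind(pos, p)
    }
    total <- burn_in + frames
    onsets <- matrix(stats::rbinom(n_neurons * total, 1, event_rate),
                     n_neurons, total)
    # onset train convolved with exp(-t/decay); the AR(1) recursion
    # a_t = o_t + exp(-1/decay) * a_{t-1} computes it exactly, keeping
    # amplitudes identically zero before a neuron's first event
    phi <- exp(-1 / decay)
    amp <- t(apply(onsets, 1, function(o)
      as.numeric(stats::filter(o, phi, method = "recursive"))))
    amp <- matrix(amp, n_neurons, total)[, burn_in + seq_len(frames),
                                         drop = FALSE]
    structure(list(positions = unname(pos), amplitudes = amp,
                   sigma = sigma, shape = as.integer(shape),
                   frames = as.integer(frames), event_rate = event_rate,
                   decay = decay, seed = as.integer(seed)),
              class = "synthetic_scene")
  })
}

# render one frame of a scene: sum of truncated Gaussian blobs
scene_frame <- function(scene, t) {
  g <- array(0, scene$shape)
  for (k in seq_len(nrow(scene$positions))) {
    a <- scene$amplitudes[k, t]
    if (a == 0) next
    g <- g + a * blob_grid(scene$shape, scene$positions[k, ], scene$sigma)
  }
  g
}

blob_grid <- function(shape, pos, sigma) {
  rad <- ceiling(3 * sigma)
  rs <- max(1L, pos[1] - rad):min(shape[1], pos[1] + rad)
  cs <- max(1L, pos[2] - rad):min(shape[2], pos[2] + rad)
  zs <- max(1L, pos[3] - rad):min(shape[3], pos[3] + rad)
  g <- array(0, shape)
  dr <- outer(rs - pos[1], cs - pos[2], function(a, b) a^2 + b^2)
  for (zi in seq_along(zs)) {
    r2 <- dr + (zs[zi] - pos[3])^2
    v <- exp(-r2 / (2 * sigma^2))
    v[r2 > (3 * sigma)^2] <- 0
    g[rs, cs, zs[zi]] <- v
  }
  g
}

#' Render a scene into a training/evaluation dataset
#'
#' For every frame builds the ground-truth volume, projects it through the
#' lenslet PSF into a light-field image (optionally Poisson-sampled), crops
#' the per-lens views, and attaches the condition set. The structural prior
#' is the voxelwise mean of the training-split volumes; the default split
#' uses the first 10 frames for training and halves the remainder into
#' validation and test.
#'
#' @param scene a [generate_scene()] result
#' @param psf a [psf_stack()]
#' @param layout a [lens_layout()]
#' @param noise \code{"none"} or \code{"poisson"}
#' @param noise_scale expected photon count at intensity 1 when
#'   \code{noise = "poisson"}
#' @param n_train number of training frames (default 10)
#' @param cond_deconv_iters Richardson-Lucy iterations for the per-frame
#'   deconvolution condition; 0 disables the third condition
#' @param seed seed for the noise sampling
#' @return a \code{dataset_bundle}: \code{frames} (list of
#'   \code{list(v0, image, cond)}), \code{prior}, \code{split}
#'   (\code{train}/\code{val}/\code{test} indices), \code{layout},
#'   \code{scene}
#' @export
render_dataset <- function(scene, psf, layout, noise = c("none", "poisson"),
                           noise_scale = 1000, n_train = 10L,
                           cond_deconv_iters = 60L, seed = 1L) {
  noise <- match.arg(noise)
  n_train <- min(as.integer(n_train), scene$frames)
  p <- make_projector(psf, scene$shape[1:2])
  vols <- lapply(seq_len(scene$frames), function(t) scene_frame(scene, t))
  imgs <- lapply(vols, function(v) pmax(proj_apply(p, v), 0))
  if (noise == "poisson") {
    imgs <- with_seed(seed, lapply(imgs, function(img)
      matrix(stats::rpois(length(img), img * noise_scale) / noise_scale,
             nrow(img), ncol(img))))
  }
  train_idx <- seq_len(n_train)
  rest <- setdiff(seq_len(scene$frames), train_idx)
  val_idx <- rest[seq_len(length(rest) %/% 2)]
  test_idx <- setdiff(rest, val_idx)
  prior <- Reduce(`+`, vols[train_idx]) / length(train_idx)
  frames <- lapply(seq_len(scene$frames), function(t) {
    views <- crop_views(lf_image(imgs[[t]]), layout)
    dc <- if (cond_deconv_iters > 0)
      rl_deconv_cond(p, imgs[[t]], scene$shape, cond_deconv_iters)
    list(v0 = vols[[t]], image = imgs[[t]],
         cond = condition_set(views, prior, dc))
  })
  structure(list(frames = frames, prior = prior,
                 split = list(train = train_idx, val = val_idx,
                              test = test_idx),
                 layout = layout, scene = scene, psf = psf,
                 cond_deconv_iters = as.integer(cond_deconv_iters)),
            class = "dataset_bundle")
}

# partial RL deconvolution on a prebuilt projector (condition 3)
rl_deconv_cond <- function(p, img, shape, iterations, eps = 1e-12) {
  v <- array(max(mean(img), eps), shape)
  norm <- proj_adjoint(p, matrix(1, nrow(img), ncol(img)))
  for (it in seq_len(iterations)) {
    est <- proj_apply(p, v)
    v <- v * proj_adjoint(p, img / (est + eps)) / (norm + eps)
    v[v < 0] <- 0
  }
  v
}

#' Generate an out-of-distribution dataset family
#'
#' Two families that a model trained on sparse neural activity should reject:
#' \describe{
#'   \item{beads}{isolated sub-voxel fluorescent beads (tight Gaussian spots,
#'     sigma 0.8 voxel), bead count per frame Poisson with mean
#'     \code{density * n_voxels}; densities spanning several orders of
#'     magnitude emulate a serial dilution.}
#'   \item{non_sparse}{an in-distribution scene \emph{plus} a smooth
#'     low-frequency background occupying more than half the voxels,
#'     emulating the autofluorescence of unprocessed acquisitions.}
#' }
#' Both are rendered through the same optics as [render_dataset()], with
#' their own 10-frame-mean prior.
#'
#' @param kind \code{"beads"} or \code{"non_sparse"}
#' @param psf,layout the imaging geometry
#' @param density beads per voxel (beads family)
#' @param background_level peak background intensity relative to the
#'   foreground (non_sparse family)
#' @param shape,frames volume grid and number of frames
#' @param seed integer seed
#' @return a \code{dataset_bundle}
#' @export
generate_ood <- function(kind = c("beads", "non_sparse"), psf, layout,
                         density = 1e-3, background_level = 0.3,
                         shape = c(32L, 32L, 16L), frames = 10L,
                         cond_deconv_iters = 60L, seed = 1L) {
  kind <- match.arg(kind)
  p <- make_projector(psf, shape[1:2])
  bead_counts <- NULL
  vols <- with_seed(seed, {
    if (kind == "beads") {
      bead_counts <- stats::rpois(frames, density * prod(shape))
      lapply(seq_len(frames), function(t) {
        g <- array(0, shape)
        n <- bead_counts[t]
        if (n > 0) {
          for (b in seq_len(n)) {
            pos <- c(sample.int(shape[1], 1), sample.int(shape[2], 1),
                     sample.int(shape[3], 1))
            g <- g + blob_grid(shape, pos, 0.8)
          }
        }
        g
      })
    } else {
      sc <- generate_scene(shape = shape, frames = frames,
                           seed = seed + 7L)
      lapply(seq_len(frames), function(t) {
        bg <- smooth_background(shape, background_level)
        scene_frame(sc, t) + bg
      })
    }
  })
  n_train <- min(10L, frames)
  prior <- Reduce(`+`, vols[seq_len(n_train)]) / n_train
  framelist <- lapply(vols, function(v) {
    img <- lf_image(pmax(proj_apply(p, v), 0))
    dc <- if (cond_deconv_iters > 0)
      rl_deconv_cond(p, img$data, shape, cond_deconv_iters)
    list(v0 = v, image = img$data,
         cond = condition_set(crop_views(img, layout), prior, dc))
  })
  structure(list(frames = framelist, prior = prior,
                 split = list(train = seq_len(n_train),
                              val = integer(0),
                              test = setdiff(seq_len(frames),
                                             seq_len(n_train))),
                 layout = layout, kind = kind, psf = psf,
                 bead_counts = bead_counts),
            class = "dataset_bundle")
}

# smooth positive low-frequency field: trilinear upsampling of a coarse
# uniform grid; strictly positive, so it occupies every voxel
smooth_background <- function(shape, level) {
  coarse <- array(stats::runif(4 * 4 * 2, 0.2, 1), c(4, 4, 2))
  out <- array(0, shape)
  gr <- seq(1, 4, length.out = shape[1])
  gc <- seq(1, 4, length.out = shape[2])
  gz <- seq(1, 2, length.out = shape[3])
  fr <- floor(gr); cr <- pmin(fr + 1, 4); wr <- gr - fr
  fc <- floor(gc); ccx <- pmin(fc + 1, 4); wc <- gc - fc
  fz <- floor(gz); cz <- pmin(fz + 1, 2); wz <- gz - fz
  for (z in seq_len(shape[3])) {
    a <- coarse[, , fz[z]] * (1 - wz[z]) + coarse[, , cz[z]] * wz[z]
    ar <- a[fr, , drop = FALSE] * (1 - wr) + a[cr, , drop = FALSE] * wr
    out[, , z] <- ar[, fc, drop = FALSE] * rep(1 - wc, each = shape[1]) +
      ar[, ccx, drop = FALSE] * rep(wc, each = shape[1])
  }
  out * level
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Training pairs from a dataset bundle
#'
#' @param bundle a \code{dataset_bundle}
#' @param which split name (\code{"train"}, \code{"val"}, \code{"test"}) or
#'   an integer vector of frame indices
#' @return list of \code{list(v0, cond)} samples as consumed by
#'   [train_model()]
#' @export
bundle_pairs <- function(bundle, which = "train") {
  idx <- if (is.character(which)) bundle$split[[which]] else which
  lapply(bundle$frames[idx], function(f) list(v0 = f$v0, cond = f$cond))
}
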