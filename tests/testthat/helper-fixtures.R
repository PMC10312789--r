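# Small shared fixtures, all built in code.

# 3-lens layout inside a 32 x 32 image; separations > 3 * spot_sigma
tiny_layout <- function(crop = 12L) {
  lens_layout(rbind(c(8, 8), c(8, 24), c(24, 16)), crop)
}

tiny_psf <- function(depth = 6L, sigma = 1.5, parallax = 0.7) {
  synthesize_psf(tiny_layout(), depth, sigma, parallax, c(32, 32))
}

random_volume <- function(shape, seed = 1) {
  set.seed(seed)
  array(runif(prod(shape)), shape)
}

# a small randomized conditional flow (fresh flows are the identity, so
# tests that need a non-trivial map perturb the subnets)
random_flow <- function(n_channels, cond_channels, n_blocks = 4L,
                        hidden = 6L, seed = 1L, spread = 0.3) {
  fl <- conditional_flow(n_channels, cond_channels, n_blocks = n_blocks,
                         hidden = hidden, seed = seed)
  set.seed(seed + 1L)
  fl$blocks <- rapply(fl$blocks,
                      function(x) x + stats::rnorm(length(x)) * spread,
                      how = "replace")
  fl
}

# tiny model + dataset for training-path tests
tiny_model_setup <- function(seed = 5L, n_samples = 2L, bp = TRUE) {
  cfgm <- cwfa_config(vol_shape = c(8, 8, 8), n_views = 2, crop_size = 8,
                      levels = 2, blocks_per_level = 2, hidden_channels = 4,
                      omega_channels = 3, omega_hidden = 4, omega_depth = 2,
                      lr_hidden = 4, use_deconv = bp, seed = seed)
  m <- build_model(cfgm)
  set.seed(seed)
  ds <- lapply(seq_len(n_samples), function(i) {
    v0 <- array(runif(8 * 8 * 8), c(8, 8, 8))
    prior <- array(runif(8 * 8 * 8), c(8, 8, 8))
    bpv <- if (bp) array(runif(8 * 8 * 8), c(8, 8, 8))
    cond <- condition_set(array(runif(8 * 8 * 2), c(8, 8, 2)), prior, bpv)
    list(v0 = v0, cond = cond)
  })
  list(model = m, dataset = ds, config = cfgm)
}

params_checksum <- function(x) {
  sum(unlist(rapply(x, function(a) sum(a * seq_along(a)), how = "unlist")))
}
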