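# Shared desk-scale study scenario for the acceptance tests: a 3x3 lenslet
# array imaging 32x32x16 volumes, 10 training frames of a 40-frame
# recording, a 2-level model trained with the package defaults. Built once
# and memoized; several acceptance tests reuse it.

.scenario_cache <- new.env(parent = emptyenv())

scenario_layout <- function(image_size = 96L, grid = 3L, crop = 32L) {
  step <- image_size %/% (grid + 1L)
  lens_layout(as.matrix(expand.grid(row = step * seq_len(grid),
                                    col = step * seq_len(grid))), crop)
}

acceptance_scenario <- function(seed = 1L) {
  key <- paste0("s", seed)
  if (!is.null(.scenario_cache[[key]])) return(.scenario_cache[[key]])
  layout <- scenario_layout()
  psf <- synthesize_psf(layout, 16L, 2.0, 1.0, c(96L, 96L))
  scene <- generate_scene(seed = seed)
  bundle <- render_dataset(scene, psf, layout, seed = seed)
  model <- build_model(cwfa_config(seed = seed))
  trained <- train_model(model, bundle_pairs(bundle, "train"),
                         train_config(seed = seed))
  sc <- list(layout = layout, psf = psf, scene = scene, bundle = bundle,
             model = trained$model, history = trained$history, seed = seed)
  .scenario_cache[[key]] <- sc
  sc
}

# LR-only baseline: zero detail coefficients all the way up
lr_only_reconstruction <- function(model, cond) {
  n <- length(model$levels)
  rec <- reconstruct(model, cond, temperature = 0)
  v <- rec$intermediates[[1]]
  for (i in seq_len(n)) {
    z <- array(0, c(dim(v)[1:2], dim(v)[3], 1))
    v <- cwflow:::haar_inverse4(array(v, c(dim(v), 1L)), z)[, , , 1]
  }
  v[v < 0] <- 0
  v[cond$prior == 0] <- 0
  v
}

eval_frames <- function(model, bundle, idx, temperature = 0, seed = NULL) {
  ps <- numeric(0); mp <- numeric(0)
  for (t in idx) {
    f <- bundle$frames[[t]]
    rec <- reconstruct(model, f$cond, temperature = temperature,
                       seed = seed)$volume$data
    ps <- c(ps, psnr(f$v0, rec))
    mp <- c(mp, mape_masked(f$v0, rec))
  }
  list(psnr = mean(ps), mape = mean(mp))
}

# per-frame NLL scores at the monitored level for a whole bundle
bundle_scores <- function(model, bundle, idx, level = 2L) {
  vapply(idx, function(t) {
    f <- bundle$frames[[t]]
    likelihood_of(model, f$v0, f$cond)$per_level_nll[level]
  }, 0)
}
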