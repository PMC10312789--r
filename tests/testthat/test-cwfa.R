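test_that("model construction chains shapes and is seed-deterministic", {
  # depth 2, one level: LR volume depth 1
  cfg1 <- cwfa_config(vol_shape = c(8, 8, 2), n_views = 2, crop_size = 8,
                      levels = 1, blocks_per_level = 2, omega_depth = 2,
                      seed = 1)
  m1 <- build_model(cfg1)
  expect_length(m1$levels, 1)
  expect_equal(m1$levels[[1]]$detail_depth, 1)

  # default chain: depth 16, two levels -> detail depths 8, 4
  m <- build_model(cwfa_config(seed = 2))
  expect_equal(vapply(m$levels, function(l) l$detail_depth, 0), c(8, 4))

  # the full four-level hierarchy builds when the depth supports it
  m4 <- build_model(cwfa_config(levels = 4, seed = 2))
  expect_equal(vapply(m4$levels, function(l) l$detail_depth, 0),
               c(8, 4, 2, 1))

  # identical seeds give identical initial parameters (bytewise)
  ma <- build_model(cwfa_config(seed = 7))
  mb <- build_model(cwfa_config(seed = 7))
  expect_identical(serialize(ma, NULL), serialize(mb, NULL))
  mc <- build_model(cwfa_config(seed = 8))
  expect_false(identical(serialize(ma, NULL), serialize(mc, NULL)))

  expect_error(build_model(cwfa_config(vol_shape = c(32, 32, 12),
                                       crop_size = 32, levels = 3)),
               "not divisible")
  cnt <- model_param_counts(m)
  expect_true(all(unlist(cnt) > 0))
})

test_that("condition features are finite, level-scaled and view-sensitive", {
  ts <- tiny_model_setup(seed = 31)
  m <- ts$model
  cond0 <- condition_set(array(0, c(8, 8, 2)), array(0, c(8, 8, 8)),
                         array(0, c(8, 8, 8)))
  f0 <- condition_features(m, cond0, 1)
  expect_true(all(is.finite(f0)))

  # the prior pathway at level i is i applications of the Haar approximation
  s <- ts$dataset[[1]]
  for (i in 1:2) {
    x <- cwflow:::cond_raw_stack(list(s$cond), i)
    want <- cwflow:::haar_reduce(s$cond$prior, i)
    expect_equal(x[, , 2 + seq_len(dim(want)[3]), 1], want)
    expect_equal(dim(condition_features(m, s$cond, i))[3],
                 ts$config$omega_channels)
  }

  # perturbing a single view pixel changes the features
  cond2 <- s$cond
  cond2$views[3, 3, 1] <- cond2$views[3, 3, 1] + 0.5
  f1 <- condition_features(m, s$cond, 1)
  f2 <- condition_features(m, cond2, 1)
  expect_gt(max(abs(f1 - f2)), 0)

  expect_error(condition_features(m, s$cond, 5), "no such level")
})

test_that("level training optimizes only its own parameters, deterministically", {
  ts <- tiny_model_setup(seed = 33)
  cfg <- train_config(alpha = 0, epochs_per_level = 12, lr = 5e-3, seed = 3)
  before <- list(l1 = params_checksum(ts$model$levels[[1]]$flow$blocks),
                 l2 = params_checksum(ts$model$levels[[2]]$flow$blocks),
                 o2 = params_checksum(ts$model$levels[[2]]$omega),
                 lr = params_checksum(ts$model$lr_nn))
  r <- train_level(ts$model, 1, ts$dataset[1], cfg)
  # single sample, alpha 0: per-element NLL drops over the first epochs
  expect_lt(tail(r$history$nll, 1), r$history$nll[1])
  # only level 1 (flow + omega) moved
  expect_false(params_checksum(r$model$levels[[1]]$flow$blocks) ==
                 before$l1)
  expect_identical(params_checksum(r$model$levels[[2]]$flow$blocks),
                   before$l2)
  expect_identical(params_checksum(r$model$levels[[2]]$omega), before$o2)
  expect_identical(params_checksum(r$model$lr_nn), before$lr)

  # frozen learning rate: loss constant across epochs
  r0 <- train_level(ts$model, 1, ts$dataset, train_config(
    epochs_per_level = 5, lr = 0, seed = 3))
  expect_equal(diff(r0$history$loss), rep(0, 4))

  # identical seeds and data reproduce the loss curve exactly
  ra <- train_level(ts$model, 1, ts$dataset, cfg)
  rb <- train_level(ts$model, 1, ts$dataset, cfg)
  expect_identical(ra$history, rb$history)

  expect_error(train_level(ts$model, 1, list(), cfg), "empty dataset")
})

test_that("the LR-NN regresses conditions onto the coarse volume", {
  ts <- tiny_model_setup(seed = 35, n_samples = 1)
  cfg <- train_config(epochs_lr = 200, lr = 5e-3, seed = 4)
  r <- train_lr_nn(ts$model, ts$dataset, cfg)
  expect_lt(tail(r$history$mse, 1), r$history$mse[1] / 10)

  # lr = 0 leaves parameters untouched
  r0 <- train_lr_nn(ts$model, ts$dataset,
                    train_config(epochs_lr = 3, lr = 0))
  expect_identical(params_checksum(r0$model$lr_nn),
                   params_checksum(ts$model$lr_nn))

  # an all-zero target shrinks the network output norm
  ds0 <- lapply(ts$dataset, function(s) {
    s$v0 <- array(0, dim(s$v0)); s
  })
  out_norm <- function(model) {
    xraw <- cwflow:::cond_raw_stack(list(ds0[[1]]$cond), 2, with_detail = FALSE)
    skip <- cwflow:::lr_skip_stack(model, list(ds0[[1]]$cond))
    sqrt(mean(cwflow:::lr_nn_fwd(model, xraw, skip)$y^2))
  }
  rz <- train_lr_nn(ts$model, ds0, cfg)
  expect_lt(out_norm(rz$model), out_norm(ts$model))
})

test_that("reconstruction is exact with oracle components and deterministic at T = 0", {
  ts <- tiny_model_setup(seed = 37)
  m <- ts$model
  s <- ts$dataset[[1]]

  # T = 0 twice: bitwise identical
  r1 <- reconstruct(m, s$cond, temperature = 0)
  r2 <- reconstruct(m, s$cond, temperature = 0)
  expect_identical(r1$volume$data, r2$volume$data)

  # oracle: flows forced to the identity (zero subnets are the fresh
  # initialization; the channel permutations are reset too) with z set to
  # the true details and the true coarse volume reproduce V_0 exactly
  for (i in 1:2)
    m$levels[[i]]$flow$perms <- lapply(m$levels[[i]]$flow$perms,
                                       function(p) seq_along(p))
  pyr <- haar_pyramid(s$v0, 2)
  v <- array(pyr$approx, c(dim(pyr$approx), 1))
  for (i in 2:1) {
    feats <- condition_features(m, s$cond, i)
    z <- array(pyr$details[[i]], c(dim(pyr$details[[i]]), 1))
    dtl <- flow_apply(m$levels[[i]]$flow, z, feats, "inverse")$x
    v <- cwflow:::haar_inverse4(v, dtl)
  }
  expect_lt(max(abs(v[, , , 1] - s$v0)), 1e-6)

  # support gating: outside the prior support the output is exactly zero
  cond_sp <- s$cond
  cond_sp$prior[1:2, , ] <- 0
  r3 <- reconstruct(m, cond_sp, temperature = 0, support = "prior")
  expect_true(all(r3$volume$data[1:2, , ] == 0))
  r4 <- reconstruct(m, cond_sp, temperature = 0, support = "none")
  expect_true(all(r4$volume$data >= 0))
})
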