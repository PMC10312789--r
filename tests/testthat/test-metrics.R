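test_that("PSNR matches its textbook formula and caps at zero MSE", {
  v <- random_volume(c(6, 6, 4), 1)
  expect_equal(psnr(v, v), 100)

  # reference max 1, uniform error 0.1: 20 dB
  r <- array(0.5, c(4, 4, 2)); r[1, 1, 1] <- 1
  e <- r + 0.1
  expect_equal(psnr(r, e), 20, tolerance = 1e-12)

  # random pair vs direct recomputation
  set.seed(7)
  for (rep in 1:5) {
    r <- random_volume(c(5, 5, 3), rep)
    e <- r + array(rnorm(75, sd = 0.05), c(5, 5, 3))
    want <- 10 * log10(max(r)^2 / mean((r - e)^2))
    expect_lt(abs(psnr(r, e) - want), 1e-9)
  }

  expect_error(psnr(array(0, c(2, 2, 2)), array(1, c(2, 2, 2))),
               "all-zero")
  expect_error(psnr(random_volume(c(2, 2, 2)), random_volume(c(3, 2, 2))),
               "shape")

  # invariance under joint scaling (peak tracks the reference max)
  r <- random_volume(c(5, 5, 2), 3); e <- random_volume(c(5, 5, 2), 4)
  expect_equal(psnr(r, e), psnr(10 * r, 10 * e), tolerance = 1e-9)
})

test_that("masked MAPE follows its definition on the union support", {
  v <- random_volume(c(5, 5, 3), 2)
  expect_equal(mape_masked(v, v), 0)

  # uniform reference 1 on its support, estimate 0.9: exactly 10%
  r <- array(0, c(4, 4, 2)); r[1:2, 1:2, 1] <- 1
  e <- r * 0.9
  expect_equal(mape_masked(r, e), 0.1, tolerance = 1e-12)

  # element-wise loop oracle reproduces the vectorized value
  set.seed(8)
  r <- array(rbinom(60, 1, 0.4) * runif(60), c(5, 4, 3))
  e <- array(rbinom(60, 1, 0.4) * runif(60), c(5, 4, 3))
  eps <- 1e-6 * max(abs(r))
  acc <- 0; cnt <- 0
  for (i in seq_along(r)) {
    if (r[i] != 0 || e[i] != 0) {
      acc <- acc + abs(r[i] - e[i]) / max(abs(r[i]), eps)
      cnt <- cnt + 1
    }
  }
  expect_equal(mape_masked(r, e), acc / cnt, tolerance = 1e-12)

  # empty mask: zero by convention; joint scaling invariance
  expect_equal(mape_masked(array(0, c(2, 2, 1)), array(0, c(2, 2, 1))), 0)
  expect_equal(mape_masked(r, e), mape_masked(5 * r, 5 * e),
               tolerance = 1e-12)
})

test_that("planted blinking neurons are recovered as traces", {
  set.seed(9)
  shape <- c(12, 12, 8)
  pos <- rbind(c(4, 4, 3), c(9, 9, 6))
  amps <- rbind(abs(sin(1:15)) + 0.2, abs(cos(1:15)) + 0.2)
  blob <- function(p, a) {
    g <- array(0, shape)
    g[p[1] + (-1:1), p[2] + (-1:1), p[3]] <- a * 0.5
    g[p[1], p[2], p[3]] <- a
    g
  }
  seq1 <- lapply(1:15, function(t) blob(pos[1, ], amps[1, t]))
  tr1 <- extract_traces(seq1, 1, radius = 2)
  expect_length(tr1, 1)
  expect_equal(tr1[[1]]$position, pos[1, ])
  expect_gt(stats::cor(tr1[[1]]$activity, amps[1, ]), 0.99)

  seq2 <- lapply(1:15, function(t)
    blob(pos[1, ], amps[1, t]) + blob(pos[2, ], amps[2, t]))
  tr2 <- extract_traces(seq2, 2, radius = 2)
  expect_length(tr2, 2)
  got <- do.call(rbind, lapply(tr2, `[[`, "position"))
  expect_equal(got[order(got[, 1]), ], pos)

  # constant sequences have zero temporal variance: no traces
  static <- lapply(1:5, function(t) blob(pos[1, ], 1))
  tr0 <- extract_traces(static, 2, radius = 2)
  expect_length(tr0, 0)
  expect_true(attr(tr0, "short"))
})

test_that("trace PCC matches the closed-form Pearson coefficient", {
  set.seed(10)
  shape <- c(10, 10, 6)
  mk <- function(vals) lapply(vals, function(a) {
    g <- array(0, shape); g[5, 5, 3] <- a; g
  })
  ref <- mk(c(1, 3, 2, 5, 4))
  tr <- extract_traces(ref, 1, radius = 1)
  expect_equal(trace_pcc(tr, ref, radius = 1), 1.0)

  # negated (mean-centered) estimate: r = -1
  vals <- c(1, 3, 2, 5, 4)
  neg <- mk(max(vals) + min(vals) - vals)
  expect_equal(trace_pcc(tr, neg, radius = 1), -1.0)

  # hand-computed r on a printed 5-point series
  est <- mk(c(2, 2.5, 2.2, 4.8, 3.9))
  a <- vals; b <- c(2, 2.5, 2.2, 4.8, 3.9)
  want <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(trace_pcc(tr, est, radius = 1), want, tolerance = 1e-12)

  # zero-variance estimate contributes r = 0
  expect_equal(trace_pcc(tr, mk(rep(1, 5)), radius = 1), 0)
  expect_error(trace_pcc(tr, ref[1], radius = 1), "2 frames")
})
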