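# independent brute-force pairing oracle: literal nearest-preceding-partner
# sums, written as plain loops
oracle_pair_delta <- function(pre, post, p) {
  d <- 0
  for (tp in post) {
    prev <- pre[pre < tp]
    if (length(prev)) d <- d + p$lr * exp(-(tp - max(prev)) / p$p_tau)
  }
  for (tr in pre) {
    prev <- post[post < tr]
    if (length(prev)) d <- d - p$lr * exp((max(prev) - tr) / p$d_tau)
  }
  d
}

test_that("the STDP window takes its defining values", {
  p <- stdpParams(lr = 1)
  expect_equal(stdpDelta(0, 17, p), exp(-1), tolerance = 1e-12)
  expect_equal(stdpDelta(34, 0, p), -exp(-1), tolerance = 1e-12)
  expect_identical(stdpDelta(5, 5, p), 0)
  # right limit at zero lag is +LR
  expect_equal(stdpDelta(0, 1e-9, p), 1, tolerance = 1e-6)
  # causal pairs potentiate, anti-causal depress, for all lags
  lags <- c(0.1, 1, 5, 17, 40, 100)
  expect_true(all(stdpDelta(0, lags, p) > 0))
  expect_true(all(stdpDelta(lags, 0, p) < 0))
  # vectorized evaluation matches the closed form
  expect_equal(stdpDelta(0, lags, p), exp(-lags / 17), tolerance = 1e-12)
})

test_that("applySTDP matches a brute-force pairing oracle on random trains", {
  p <- stdpParams(lr = 0.01, w_min = 0, w_max = 100)
  set.seed(21)
  for (i in 1:20) {
    pre <- sort(runif(sample(1:8, 1), 0, 300))
    post <- sort(runif(sample(1:8, 1), 0, 300))
    proj <- data.frame(src = 0L, tgt = 1L, weight = 50, delay = 1,
                       kind = "ampa", plastic = TRUE, projection = "x")
    ev <- data.frame(cell = c(rep(0L, length(pre)), rep(1L, length(post))),
                     time = c(pre, post))
    got <- applySTDP(proj, ev, ev, p)$weight - 50
    expect_equal(got, oracle_pair_delta(pre, post, p), tolerance = 1e-10)
  }
})

test_that("causal pairings potentiate and empty rasters change nothing", {
  p <- stdpParams(lr = 0.001, w_min = 0, w_max = 1)
  proj <- data.frame(src = 0L, tgt = 1L, weight = 0.5, delay = 1,
                     kind = "ampa", plastic = TRUE, projection = "x")
  ev <- data.frame(cell = rep(c(0L, 1L), 10),
                   time = as.vector(rbind(seq(10, 100, 10),
                                          seq(11, 101, 10))))
  expect_gt(applySTDP(proj, ev, ev, p)$weight, 0.5)
  empty <- data.frame(cell = integer(), time = numeric())
  expect_identical(applySTDP(proj, empty, empty, p)$weight, 0.5)
  proj$plastic <- FALSE
  expect_error(applySTDP(proj, ev, ev, p), "contract violation")
})

test_that("uncorrelated equal-rate trains depress on average", {
  # d_tau > p_tau widens the depression window
  p <- stdpParams(lr = 0.01, w_min = 0, w_max = 1e6)
  set.seed(31)
  deltas <- replicate(300, {
    pre <- sort(runif(rpois(1, 6), 0, 300))
    post <- sort(runif(rpois(1, 6), 0, 300))
    oracle_pair_delta(pre, post, p)
  })
  expect_lt(mean(deltas), 0)
})

test_that("the Hebbian control is order-blind and lag-independent", {
  proj <- data.frame(src = 0L, tgt = 1L, weight = 0.2, delay = 1,
                     kind = "ampa", plastic = TRUE, projection = "x")
  silent <- data.frame(cell = integer(), time = numeric())
  expect_identical(hebbianUpdate(proj, silent, silent, amplitude = 0.1,
                                 w_max = 1)$weight, 0.2)
  # post fires 200 ms before pre: still potentiated
  ev <- data.frame(cell = c(1L, 0L), time = c(10, 210))
  expect_equal(hebbianUpdate(proj, ev, ev, amplitude = 0.1, w_max = 1)$weight,
               0.3)
  # any lag gives the same increment
  for (lag in c(1, 50, 250)) {
    ev2 <- data.frame(cell = c(0L, 1L), time = c(10, 10 + lag))
    expect_equal(hebbianUpdate(proj, ev2, ev2, amplitude = 0.1,
                               w_max = 1)$weight, 0.3)
  }
})

test_that("normalization drives the mean to mid-range and preserves ratios", {
  set.seed(41)
  w <- runif(200, 0, 2e-4)
  out <- normalizeWeights(w, 0, 2e-4)
  expect_lt(abs(mean(out) - 1e-4), 1e-6)
  # already at target: unchanged within tolerance
  expect_equal(normalizeWeights(out, 0, 2e-4), out, tolerance = 1e-6)
  # doubling then normalizing preserves ratios among unclipped weights
  big <- normalizeWeights(w * 2, 0, 2e-4)
  unclipped <- big > 0 & big < 2e-4
  r1 <- w[unclipped] / w[unclipped][1]
  r2 <- big[unclipped] / big[unclipped][1]
  expect_equal(r1, r2, tolerance = 1e-9)
  # degenerate all-zero vector resets uniformly
  expect_identical(normalizeWeights(rep(0, 5), 0, 2e-4), rep(1e-4, 5))
  # data.frame in, data.frame out
  df <- data.frame(weight = w)
  expect_s3_class(normalizeWeights(df, 0, 2e-4), "data.frame")
})
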