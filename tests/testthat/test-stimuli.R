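test_that("cone activation formulas give the printed values", {
  at <- function(rgb) {
    d <- rgbToConeRates(colorPatch(rgb, dims = c(1, 1)))
    c(S = d$S[1, 1], M = d$M[1, 1], L = d$L[1, 1])
  }
  expect_equal(unname(at(c(0, 0, 0))), c(0, 0, 0))
  expect_equal(unname(at(c(1, 1, 1))), c(40, 40, 40))
  # pure red drives the M cone strongly too
  r <- at(c(1, 0, 0))
  expect_equal(unname(r), c(0, 40 * 0.7 / 1.95, 40 / 1.95), tolerance = 1e-12)
  expect_equal(unname(r[["M"]]), 14.359, tolerance = 1e-4)
  expect_equal(unname(r[["L"]]), 20.513, tolerance = 1e-4)
})

test_that("cone rates are monotone per channel and L/M mirror R/G", {
  set.seed(3)
  for (i in 1:25) {
    rgb <- runif(3)
    base <- rgbToConeRates(colorPatch(rgb, c(1, 1)))
    for (ch in 1:3) {
      up <- rgb; up[ch] <- min(1, up[ch] + 0.2)
      bumped <- rgbToConeRates(colorPatch(up, c(1, 1)))
      expect_true(all(c(bumped$S >= base$S, bumped$M >= base$M,
                        bumped$L >= base$L)))
    }
    expect_identical(base$L[1, 1] >= base$M[1, 1], rgb[1] >= rgb[2])
  }
})

test_that("noise-free 40 Hz train has 12 spikes on the 25 ms grid in 300 ms", {
  net <- buildNetwork(tiny_config())
  d <- rgbToConeRates(colorPatch(c(1, 1, 1), c(1, 1)))
  sp <- generateInputSpikes(net, d, 300, noise_frac = 0)
  r_cell <- sp$time[sp$cell == 0]
  expect_length(r_cell, 12)
  expect_equal(r_cell, seq(0, 275, by = 25))
  # silent channel emits nothing
  d0 <- rgbToConeRates(colorPatch(c(0, 0, 0), c(1, 1)))
  expect_identical(nrow(generateInputSpikes(net, d0, 300, 0)), 0L)
})

test_that("spike count over 1 s of a noise-free train equals round(f) +- 1", {
  net <- buildNetwork(tiny_config())
  for (rgb in list(c(1, 0, 0), c(0.3, 0.8, 0.1), c(0, 0, 1))) {
    d <- rgbToConeRates(colorPatch(rgb, c(1, 1)))
    sp <- generateInputSpikes(net, d, 1000, noise_frac = 0)
    f <- c(d$L, d$M, d$S)
    for (i in which(f > 0))
      expect_lte(abs(sum(sp$cell == i - 1) - round(f[i])), 1)
  }
})

test_that("onset delays span up to one interspike interval across cells", {
  cfg <- runConfig(network_seed = 11L)
  net <- buildNetwork(cfg)
  expect_true(all(net@inputDelays >= 0 & net@inputDelays < 25))
  expect_gt(diff(range(net@inputDelays)), 20)   # ~24 ms of final-spike offset
  # first spikes of a full-rate drive reproduce the delays
  d <- rgbToConeRates(colorPatch(c(1, 1, 1), c(10, 10)))
  sp <- generateInputSpikes(net, d, 300, noise_frac = 0)
  first <- tapply(sp$time, sp$cell, min)
  expect_equal(as.numeric(first), unname(net@inputDelays), tolerance = 1e-9)
})

test_that("jitter mode preserves the nominal rate and the phase structure", {
  net <- buildNetwork(tiny_config())
  d <- rgbToConeRates(colorPatch(c(1, 1, 1), c(1, 1)))
  set.seed(5)
  sp <- generateInputSpikes(net, d, 1000, noise_frac = 0.1, mode = "jitter")
  expect_lte(abs(sum(sp$cell == 0) - 40), 1)
  tt <- sp$time[sp$cell == 0]
  expect_lt(max(abs(tt - round(tt / 25) * 25)), 2.5 + 1e-9)
})

test_that("patch sampler covers its styles deterministically", {
  set.seed(9)
  a <- synthPatchSampler(3, c(10, 10), "smooth_field")
  set.seed(9)
  b <- synthPatchSampler(3, c(10, 10), "smooth_field")
  expect_identical(a, b)
  set.seed(1)
  corners <- synthPatchSampler(5, c(6, 6), "uniform_color", palette = "corners")
  expect_true(all(vapply(corners, function(p) all(p %in% c(0, 1)), logical(1))))
  set.seed(2)
  tt <- synthPatchSampler(2, c(8, 8), "two_tone")
  expect_lte(length(unique(as.vector(tt[[1]][, , 1]))), 2)
})

test_that("smooth fields have broad hue coverage with mid channel means", {
  set.seed(17)
  ps <- synthPatchSampler(2000, c(10, 10), "smooth_field")
  for (ch in 1:3) {
    m <- mean(vapply(ps, function(p) mean(p[, , ch]), numeric(1)))
    expect_gte(m, 0.3); expect_lte(m, 0.7)
  }
  rng <- range(vapply(ps[1:100], range, numeric(2)))
  expect_lt(rng[1], 0.1); expect_gt(rng[2], 0.9)
})

test_that("color patches are validated", {
  expect_error(colorPatch(array(2, c(2, 2, 3))), "\\[0, 1\\]")
  expect_error(colorPatch(matrix(0.5, 2, 2)), "rows x cols x 3")
  p <- colorPatch(c(0.2, 0.4, 0.6), dims = c(3, 4))
  expect_identical(dim(p), c(3L, 4L, 3L))
  expect_true(all(p[, , 2] == 0.4))
})
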