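test_that("full configuration builds 5700 cells with the stated layer dims", {
  net <- buildNetwork(preset("paper_full"))
  expect_identical(nCells(net), 5700L)
  ly <- net@layers
  expect_identical(ly$rows[ly$name %in% c("R", "G", "B")], rep(10, 3))
  expect_identical(ly$rows[ly$name %in% c("L", "C1", "C2")], rep(30, 3))
  expect_identical(ly$rows[ly$name %in% c("V1L4", "V1L23", "V1L5")], rep(30, 3))
})

test_that("koniocellular pathway terminates in L2/3, bypassing L4", {
  net <- buildNetwork(small_config())
  expect_identical(nrow(synapses(net, "C2->V1L4")), 0L)
  expect_gt(nrow(synapses(net, "C2->V1L23")), 0)
})

test_that("excitatory edges carry 1 ms delay, inhibitory 4 ms", {
  sy <- synapses(buildNetwork(small_config()))
  expect_true(all(sy$delay[sy$kind == "ampa"] == 1))
  expect_true(all(sy$delay[sy$kind == "gaba"] == 4))
})

test_that("a 1x1 network realizes the opponent channel formulas edge by edge", {
  net <- buildNetwork(tiny_config())
  signed <- function(proj) {
    e <- synapses(net, proj)
    if (nrow(e) == 0) return(character(0))
    e$kind
  }
  # L = R + G
  expect_identical(signed("R->L"), "ampa")
  expect_identical(signed("G->L"), "ampa")
  expect_length(signed("B->L"), 0)
  # C1 = R - G
  expect_identical(signed("R->C1"), "ampa")
  expect_identical(signed("G->C1"), "gaba")
  expect_length(signed("B->C1"), 0)
  # C2 = (R + G) - B
  expect_identical(signed("R->C2"), "ampa")
  expect_identical(signed("G->C2"), "ampa")
  expect_identical(signed("B->C2"), "gaba")
})

test_that("topographic map scales, blocks and clips as specified", {
  # identical dims, radius 0: identity
  m <- topographicMap(c(8, 8), c(8, 8), c(3, 5), radius = 0)
  expect_equal(unname(as.matrix(m)), matrix(c(3, 5), 1))
  # 10x10 -> 30x30: each 3x3 target block shares one source position
  srcs <- vapply(0:2, function(dr)
    paste(unlist(topographicMap(c(10, 10), c(30, 30), c(12 + dr, 21), 0)),
          collapse = ","), character(1))
  expect_identical(length(unique(srcs)), 1L)
  expect_equal(unlist(topographicMap(c(10, 10), c(30, 30), c(12, 21), 0),
                      use.names = FALSE), c(4, 7))
  # corner clipping: corner region never larger than interior region
  corner <- nrow(topographicMap(c(10, 10), c(10, 10), c(0, 0), radius = 1))
  interior <- nrow(topographicMap(c(10, 10), c(10, 10), c(5, 5), radius = 1))
  expect_lte(corner, interior)
  expect_identical(corner, 4L)
  expect_identical(interior, 9L)
})

test_that("Mexican-hat counts, kinds and sparsity behave as defined", {
  set.seed(1)
  e <- mexicanHatEdges(7, 7, r_exc = 1, r_inh = 2, p_connect = 1)
  interior <- e[e$src == 3 * 7 + 3, ]
  expect_identical(sum(interior$kind == "ampa"), 8L)
  expect_identical(sum(interior$kind == "gaba"), 16L)
  expect_false(any(e$src == e$tgt))
  # kind is gaba exactly when Chebyshev distance exceeds r_exc
  d <- pmax(abs(e$src %/% 7 - e$tgt %/% 7), abs(e$src %% 7 - e$tgt %% 7))
  expect_identical(e$kind == "gaba", d > 1)
  expect_true(all(d <= 2))
  # p_connect = 0: no lateral edges at all
  set.seed(2)
  expect_identical(nrow(mexicanHatEdges(7, 7, 1, 2, p_connect = 0)), 0L)
})

test_that("network construction is a pure function of config and seed", {
  cfg <- small_config(network_seed = 42L)
  a <- buildNetwork(cfg); b <- buildNetwork(cfg)
  expect_identical(a@synapses, b@synapses)
  expect_identical(a@inputDelays, b@inputDelays)
  c2 <- buildNetwork(small_config(network_seed = 43L))
  expect_false(identical(a@synapses$weight, c2@synapses$weight))
})

test_that("fixed photoreceptor->LGN weights survive plastic training bit for bit", {
  net <- buildNetwork(small_config(network_seed = 7L, lr = 1e-5))
  fixed_before <- net@synapses[!net@synapses$plastic, ]
  set.seed(1)
  for (i in 1:3)
    net <- runTrial(net, colorPatch(runif(3), c(2, 2)), 150, rule = "stdp")$network
  expect_identical(net@synapses[!net@synapses$plastic, ], fixed_before)
  # and the plastic ones did change
  expect_false(identical(net@synapses$weight,
                         buildNetwork(small_config(network_seed = 7L,
                                                   lr = 1e-5))@synapses$weight))
})

test_that("receptive fields grow through the hierarchy", {
  rf <- receptiveFieldSizes(buildNetwork(small_config()))
  lgn <- mean(rf[c("L", "C1", "C2")])
  expect_lte(lgn, rf["V1L4"])
  expect_lte(rf["V1L4"], rf["V1L23"])
  expect_lte(rf["V1L23"], rf["V1L5"])
})

test_that("inconsistent grid dims are a configuration error", {
  expect_error(buildNetwork(runConfig(pr_rows = 3, pr_cols = 3,
                                      lgn_rows = 10, lgn_cols = 10)),
               "integer multiple")
})
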