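test_that("a black patch evokes no spikes anywhere", {
  net <- buildNetwork(small_config())
  set.seed(1)
  out <- runTrial(net, colorPatch(c(0, 0, 0), c(2, 2)), 200)
  expect_identical(nrow(out$raster@events), 0L)
})

test_that("trials are bit-identical under identical seeds", {
  net <- buildNetwork(small_config(network_seed = 5L))
  patch <- colorPatch(c(0.8, 0.3, 0.6), c(2, 2))
  set.seed(77); a <- runTrial(net, patch, 300)
  set.seed(77); b <- runTrial(net, patch, 300)
  expect_identical(a$raster@events, b$raster@events)
  set.seed(78); c2 <- runTrial(net, patch, 300)
  expect_false(identical(a$raster@events, c2$raster@events))
})

test_that("event delivery honours the 1 ms and 4 ms synaptic delays", {
  cfg <- tiny_config()
  net <- buildNetwork(cfg)
  probe <- function(projection, record_cell) {
    n2 <- net
    n2@synapses <- net@synapses[net@synapses$projection == projection, ]
    drive <- colorspike:::.cs_simulate(
      n2, data.frame(cell = n2@synapses$src[1], time = 10), 30, 0.025,
      record_cells = record_cell)
    ctrl <- colorspike:::.cs_simulate(
      n2, data.frame(cell = integer(), time = numeric()), 30, 0.025,
      record_cells = record_cell)
    v <- drive$vtrace[, 1]; v0 <- ctrl$vtrace[, 1]
    t <- seq_along(v) * 0.025
    t[which(abs(v - v0) > 1e-9)[1]]
  }
  # excitatory R->L edge: effect at 10 + 1 ms (to within one step)
  t_exc <- probe("R->L", 3L)        # L cell has global id 3
  expect_lt(abs(t_exc - 11), 0.075)
  # inhibitory B->C2 edge: effect at 10 + 4 ms
  t_inh <- probe("B->C2", 5L)       # C2 cell has global id 5
  expect_lt(abs(t_inh - 14), 0.075)
})

test_that("frozen plasticity leaves weights bit-identical", {
  net <- buildNetwork(small_config())
  set.seed(2)
  out <- runTrial(net, colorPatch(c(1, 1, 1), c(2, 2)), 200, rule = "frozen")
  expect_identical(out$network@synapses$weight, net@synapses$weight)
  tr <- trainNetwork(net, n_iterations = 0, trace = FALSE)
  expect_identical(tr$network@synapses, net@synapses)
})

test_that("normalization keeps every plastic projection at mid-range", {
  cfg <- small_config(lr = 1e-5)
  net <- buildNetwork(cfg)
  set.seed(4)
  for (i in 1:3)
    net <- runTrial(net, colorPatch(runif(3), c(2, 2)), 300, rule = "stdp")$network
  sy <- net@synapses[net@synapses$plastic, ]
  for (pr in unique(sy$projection))
    expect_lt(abs(mean(sy$weight[sy$projection == pr]) -
                  (cfg$w_min + cfg$w_max) / 2), 1e-6)
})

test_that("no cell exceeds 200 Hz under full-field drive (no runaway)", {
  net <- buildNetwork(preset("desk_small"))
  set.seed(3)
  out <- runTrial(net, colorPatch(c(1, 1, 1), c(5, 5)), 300, rule = "frozen")
  ev <- out$raster@events
  ev <- ev[!ev$layer %in% c("R", "G", "B"), ]
  counts <- table(ev$cell)
  expect_lt(max(counts) / 0.3, 200)
})

test_that("zero transforms and zero noise make presentations identical", {
  cfg <- small_config(noise_frac = 0)
  net <- buildNetwork(cfg)
  set.seed(6)
  rt <- testColors(net, colors = colorPalette("corners")[c("red", "blue")],
                   n_transforms = 2, transform_frac = 0, duration = 150)
  x <- rates(rt)
  cd <- SummarizedExperiment::colData(rt)
  for (s in unique(cd$stimulus)) {
    cols <- which(cd$stimulus == s)
    expect_identical(x[, cols[1]], x[, cols[2]])
  }
})

test_that("the ON/OFF protocol silences inputs after removal", {
  net <- buildNetwork(preset("desk_small"))
  set.seed(8)
  rs <- onOffProtocol(net, colors = list(red = c(1, 0, 0)))
  expect_named(rs, "red")
  r <- rs$red
  expect_identical(r@metadata$on_ms, 240)
  expect_identical(r@metadata$off_ms, 60)
  ins <- spikes(r, layer = c("R", "G", "B"))
  expect_true(all(ins$time < 240))
  expect_identical(r@duration, 300)
})

test_that("rate tables carry grid coordinates and presentation labels", {
  net <- buildNetwork(small_config())
  set.seed(9)
  rt <- testColors(net, colors = list(white = c(1, 1, 1)), n_transforms = 2,
                   duration = 100)
  expect_s4_class(rt, "RateTable")
  expect_identical(ncol(rt), 2L)
  expect_identical(nrow(rt), nCells(net))
  rd <- SummarizedExperiment::rowData(rt)
  expect_setequal(unique(rd$layer), layerNames(net))
  expect_true(all(rates(rt) >= 0))
  expect_identical(dim(rates(rt, layer = "V1L5")), c(16L, 2L))
})
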