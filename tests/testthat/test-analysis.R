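test_that("clustering coefficient matches the brute-force double loop", {
  set.seed(51)
  for (rep in 1:5) {
    rt <- random_rate_table(6, 6, n_stim = 3, n_trans = 2)
    fr <- sapply(unique(SummarizedExperiment::colData(rt)$stimulus),
                 function(s) rowMeans(rates(rt)[,
                   SummarizedExperiment::colData(rt)$stimulus == s]))
    for (nrm in c("minmax", "max", "none")) {
      got <- clusteringCoefficient(rt, layer = NULL, normalize = nrm)$C
      expect_equal(got, oracle_clustering(fr, 6, 6, nrm), tolerance = 1e-10)
    }
  }
})

test_that("clustering extremes: saturated grid gives 1, silent grid 0", {
  ones <- rateTable(matrix(5, 16, 4), stimulus = rep(c("a", "b"), each = 2),
                    transform = rep(1:2, 2), dims = c(4, 4))
  ws <- capture_warnings(cc <- clusteringCoefficient(ones))
  expect_match(ws, "degenerate", all = TRUE)
  expect_identical(cc$C, 1)
  zeros <- rateTable(matrix(0, 16, 4), stimulus = rep(c("a", "b"), each = 2),
                     transform = rep(1:2, 2), dims = c(4, 4))
  ws0 <- capture_warnings(cz <- clusteringCoefficient(zeros))
  expect_match(ws0, "degenerate", all = TRUE)
  expect_identical(cz$C, 0)
})

test_that("single-cell information reaches exactly 3 bits for 8 stimuli", {
  set.seed(52)
  rt <- ideal_rate_table(n_stim = 8, n_trans = 4)
  si <- singleCellInfo(rt)
  expect_identical(si$ceiling_bits, 3)
  expect_equal(max(si$max_info), 3, tolerance = 1e-12)
  # a flat cell carries nothing
  flat <- rateTable(matrix(7, 2, 16), stimulus = rep(paste0("s", 1:8), each = 2),
                    transform = rep(1:2, 8), dims = c(1, 2))
  expect_identical(singleCellInfo(flat)$max_info, c(0, 0))
})

test_that("information measures match brute-force implementations", {
  set.seed(53)
  rt <- random_rate_table(3, 3, n_stim = 4, n_trans = 3)
  x <- rates(rt)
  stim <- SummarizedExperiment::colData(rt)$stimulus
  si <- singleCellInfo(rt)
  expect_equal(si$max_info, oracle_single_info(x, stim), tolerance = 1e-10)
  mi <- multipleCellInfo(rt, max_cells = 5)
  for (k in c(1, 3, 5))
    expect_equal(mi$info[k],
                 oracle_multi_info(x, stim, mi$ranking[1:k]), tolerance = 1e-10)
})

test_that("information is invariant to stimulus relabeling and bounded", {
  set.seed(54)
  rt <- random_rate_table(3, 3, n_stim = 4, n_trans = 3)
  x <- rates(rt)
  cd <- SummarizedExperiment::colData(rt)
  relabeled <- rateTable(x, stimulus = paste0("zz_", cd$stimulus),
                         transform = cd$transform, dims = c(3, 3))
  expect_equal(sort(singleCellInfo(rt)$max_info),
               sort(singleCellInfo(relabeled)$max_info), tolerance = 1e-12)
  expect_equal(multipleCellInfo(rt, max_cells = 4)$info,
               multipleCellInfo(relabeled, max_cells = 4)$info,
               tolerance = 1e-12)
  expect_true(all(singleCellInfo(rt)$max_info <= log2(4) + 1e-12))
  expect_true(all(multipleCellInfo(rt, max_cells = 9)$info <= log2(4) + 1e-12))
})

test_that("a perfectly selective population decodes all stimuli at ceiling", {
  set.seed(55)
  rt <- ideal_rate_table(n_stim = 8, n_trans = 4, cells_per_stim = 1)
  mi <- suppressWarnings(multipleCellInfo(rt, max_cells = 8))
  expect_equal(mi$info[8], 3, tolerance = 1e-6)
  expect_true(all(diff(mi$info) >= -1e-9))  # adding ranked cells never hurts here
})

test_that("an uninformative table decodes near zero bits", {
  set.seed(56)
  # all cells respond identically to every stimulus (plus tiny noise)
  x <- matrix(rnorm(6 * 24, 5, 0.01), 6)
  rt <- rateTable(x, stimulus = rep(paste0("s", 1:4), each = 6),
                  transform = rep(1:6, 4), dims = c(2, 3))
  mi <- multipleCellInfo(rt, max_cells = 3)
  expect_lt(mi$info[3], 0.35)   # within estimator bias at this sample size
})

test_that("ON/OFF selection ranks window counts with index tie-breaks", {
  # five early-bursting cells, the rest late
  early <- make_raster(cell = rep(c(3, 7, 11, 19, 23), each = 4),
                       time = rep(seq(5, 50, 15), 5))
  late <- make_raster(cell = rep(0:9, 2), time = runif(20, 250, 295),
                      meta = list(on_ms = 240, off_ms = 60))
  combined <- new("SpikeRaster",
                  events = rbind(early@events, late@events)[
                    order(c(early@events$time, late@events$time)), ],
                  duration = 300, metadata = list(on_ms = 240, off_ms = 60))
  sel <- selectOnOffCells(combined, layer = "V1L5", n_select = 5)
  expect_setequal(sel$on$cell, c(3, 7, 11, 19, 23))
  expect_true(all(sel$off$count >= 1))
  # silent raster: all-zero counts
  silent <- make_raster(cell = integer(), time = numeric(),
                        meta = list(on_ms = 240))
  s0 <- selectOnOffCells(silent, n_select = 5)
  expect_identical(nrow(s0$on), 0L)
  # ties broken by ascending cell id
  tie <- make_raster(cell = c(9, 2, 5), time = c(10, 20, 30),
                     meta = list(on_ms = 240))
  expect_equal(selectOnOffCells(tie, n_select = 3)$on$cell, c(2, 5, 9))
})

test_that("opponent-cell selection intersects pools and flags short lists", {
  on_r <- make_raster(cell = 0:19, time = rep(10, 20),
                      meta = list(on_ms = 240, off_ms = 60))
  off_g <- make_raster(cell = c(0:4, 50:54), time = rep(250, 10),
                       meta = list(on_ms = 240, off_ms = 60))
  rs <- list(red = on_r, green = off_g)
  sel <- selectOpponentCells(rs, "red", "green", n_pool = 20, n_select = 3)
  expect_false(sel$short)
  expect_identical(sel$n_qualifying, 5L)
  expect_true(all(sel$cells$cell %in% 0:4))
  # degenerate: primary == opponent
  both <- selectOpponentCells(list(red = on_r), "red", "red",
                              n_pool = 20, n_select = 3)
  expect_true(both$short)          # nothing fires in the red OFF window
  # too few qualifying: flagged short
  short <- selectOpponentCells(rs, "red", "green", n_pool = 3, n_select = 5)
  expect_true(short$short)
})

test_that("weight bimodality scores uniform and binary distributions", {
  set.seed(57)
  u <- runif(20000, 0, 1)
  wb <- weightBimodality(u, 0, 1)
  expect_equal(wb$near_bound_fraction, 0.2, tolerance = 0.02)
  expect_equal(wb$bimodality_coefficient, 5 / 9, tolerance = 0.02)
  b <- c(rep(0, 60), rep(1, 40))
  expect_identical(weightBimodality(b, 0, 1)$near_bound_fraction, 1)
  expect_gt(weightBimodality(b, 0, 1)$bimodality_coefficient, 0.9)
  expect_error(weightBimodality(1:5), "at least 10")
})
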