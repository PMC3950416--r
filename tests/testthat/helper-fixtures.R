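# shared fixtures: tiny configurations and hand-built rasters

tiny_config <- function(...) {
  runConfig(pr_rows = 1, pr_cols = 1, lgn_rows = 1, lgn_cols = 1,
            v1_rows = 1, v1_cols = 1, input_delays = FALSE, ...)
}

small_config <- function(...) {
  runConfig(pr_rows = 2, pr_cols = 2, lgn_rows = 4, lgn_cols = 4,
            v1_rows = 4, v1_cols = 4, ...)
}

# raster data.frame from bare (cell, time) pairs on a single grid
make_raster <- function(cell, time, rows = 10, cols = 10, layer = "V1L5",
                        duration = 300, meta = list()) {
  ord <- order(time, cell)
  ev <- data.frame(layer = rep(layer, length.out = length(cell)),
                   cell = cell[ord],
                   row = cell[ord] %/% cols, col = cell[ord] %% cols,
                   time = time[ord])
  new("SpikeRaster", events = ev, duration = duration, metadata = meta)
}

# random rate table on a grid
random_rate_table <- function(n_row = 6, n_col = 6, n_stim = 4, n_trans = 3,
                              max_rate = 10) {
  x <- matrix(runif(n_row * n_col * n_stim * n_trans, 0, max_rate),
              n_row * n_col)
  rateTable(x, stimulus = rep(paste0("s", seq_len(n_stim)), each = n_trans),
            transform = rep(seq_len(n_trans), n_stim),
            dims = c(n_row, n_col))
}

# idealized table: each cell prefers one stimulus, tiny within-stimulus noise
ideal_rate_table <- function(n_stim = 8, n_trans = 4, cells_per_stim = 2,
                             sd = 0.01) {
  n <- n_stim * cells_per_stim
  x <- matrix(0, n, n_stim * n_trans)
  stim <- rep(seq_len(n_stim), each = n_trans)
  for (i in seq_len(n)) {
    pref <- (i - 1) %/% cells_per_stim + 1
    x[i, ] <- ifelse(stim == pref, 10, 0) + rnorm(ncol(x), 0, sd)
  }
  x <- pmax(x, 0)
  rateTable(x, stimulus = paste0("s", stim),
            transform = rep(seq_len(n_trans), n_stim), dims = c(1, n))
}
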