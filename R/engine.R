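## Clock-driven simulation wrapper and the training / testing protocols.

## run an expression with a temporary RNG seed, restoring the caller's stream
.with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(expr)
}

.layer_of <- function(net, cells) {
  ly <- net@layers
  idx <- findInterval(cells, ly$offset)
  ly$name[idx]
}

.cell_coords <- function(net, cells) {
  ly <- net@layers
  idx <- findInterval(cells, ly$offset)
  local <- cells - ly$offset[idx]
  data.frame(row = local %/% ly$cols[idx], col = local %% ly$cols[idx])
}

## core simulation: input spike trains in, full raster out
.cs_simulate <- function(net, input_spikes, duration, dt = net@config$dt,
                         record_cells = integer(), i_inj = NULL) {
  ly <- net@layers
  n_total <- sum(ly$rows * ly$cols)
  kind <- integer(n_total)
  for (i in seq_len(nrow(ly)))
    if (ly$kind[i] == "hh")
      kind[ly$offset[i] + seq_len(ly$rows[i] * ly$cols[i])] <- 1L
  n_hh <- sum(kind)
  rest <- restingState(net@membrane)
  state0 <- matrix(rep(c(rest$v, rest$m, rest$h, rest$n, 0, 0), each = n_hh),
                   n_hh, 6)
  sy <- net@synapses
  ord <- order(sy$src)
  syo <- sy[ord, ]
  src_ptr <- c(0L, cumsum(tabulate(syo$src + 1L, nbins = n_total)))
  if (is.null(i_inj)) i_inj <- numeric(n_hh)
  hh_index <- cumsum(kind) - 1L           # global -> hh index (for kind==1)
  rec_hh <- if (length(record_cells)) as.integer(hh_index[record_cells + 1L])
            else integer()
  mb <- net@membrane
  P <- list(cm = mb$cm, g_pas = mb$g_pas, e_leak = mb$e_leak,
            g_na = mb$g_na, e_na = mb$e_na, g_k = mb$g_k, e_k = mb$e_k,
            area_cm2 = mb$area_cm2,
            tau_ampa = net@synParams$ampa$tau, e_ampa = net@synParams$ampa$e_rev,
            tau_gaba = net@synParams$gaba$tau, e_gaba = net@synParams$gaba$e_rev,
            v_thresh = mb$v_thresh, refractory_ms = mb$refractory_ms)
  res <- cs_engine_run(kind, state0,
                       as.integer(src_ptr), as.integer(syo$tgt),
                       as.numeric(syo$weight),
                       as.integer(round(syo$delay / dt)),
                       as.integer(syo$kind == "gaba"),
                       as.integer(input_spikes$cell),
                       as.numeric(input_spikes$time),
                       dt, duration, i_inj, P, rec_hh)
  ev <- rbind(
    data.frame(cell = input_spikes$cell, time = input_spikes$time),
    data.frame(cell = res$spike_cell, time = res$spike_time))
  ev <- ev[order(ev$time, ev$cell), , drop = FALSE]
  events <- cbind(data.frame(layer = .layer_of(net, ev$cell), cell = ev$cell),
                  .cell_coords(net, ev$cell), time = ev$time)
  rownames(events) <- NULL
  list(events = events, state = res$state, vtrace = res$vtrace)
}

#' Run one stimulation trial
#'
#' Generates input spike trains for the patch (with the configured rate
#' noise and the network's fixed onset delays), integrates the whole
#' network for `duration` ms with all synaptic delays honoured, applies
#' the selected plasticity rule to the plastic projections from the
#' trial's spike raster, and normalizes each plastic projection's weights
#' to mid-range. Uses the current RNG stream for the input noise; with
#' equal seeds and inputs the result is bit-identical.
#'
#' @param net a [NetworkModel-class].
#' @param patch a [colorPatch()] matching the photoreceptor grid.
#' @param duration trial length, ms (default: the configured iteration
#'   length).
#' @param rule `"frozen"` (no plasticity), `"stdp"` or `"hebbian"`.
#' @param record_cells optional global cell ids whose voltage traces are
#'   returned.
#' @return list with `raster` (a [SpikeRaster-class]) and `network` (the
#'   possibly updated model); when voltages were recorded, also `vtrace`
#'   and `vtime`.
#' @examples
#' cfg <- runConfig(pr_rows = 2, pr_cols = 2, lgn_rows = 2, lgn_cols = 2,
#'                  v1_rows = 2, v1_cols = 2, input_delays = FALSE)
#' net <- buildNetwork(cfg)
#' set.seed(1)
#' out <- runTrial(net, colorPatch(c(1, 1, 1), dims = c(2, 2)), 100)
#' out$raster
#' @export
runTrial <- function(net, patch, duration = net@config$iteration_ms,
                     rule = c("frozen", "stdp", "hebbian"),
                     record_cells = NULL) {
  rule <- match.arg(rule)
  cfg <- net@config
  drive <- rgbToConeRates(patch, cfg$max_rate_hz)
  ins <- generateInputSpikes(net, drive, duration, cfg$noise_frac,
                             mode = cfg$noise_mode)
  sim <- .cs_simulate(net, ins, duration, cfg$dt,
                      record_cells = record_cells %||% integer())
  raster <- new("SpikeRaster", events = sim$events, duration = duration,
                metadata = list(rule = rule))
  if (rule != "frozen") {
    sy <- net@synapses
    pl <- which(sy$plastic)
    params <- .stdp_from_config(cfg)
    upd <- if (rule == "stdp") {
      applySTDP(sy[pl, ], raster, raster, params)
    } else {
      hebbianUpdate(sy[pl, ], raster, raster, amplitude = cfg$lr,
                    window = c(0, duration),
                    w_min = cfg$w_min, w_max = cfg$w_max)
    }
    sy$weight[pl] <- upd$weight
    for (pr in unique(sy$projection[pl])) {
      sel <- pl[sy$projection[pl] == pr]
      sy$weight[sel] <- normalizeWeights(sy$weight[sel], cfg$w_min, cfg$w_max)
    }
    net@synapses <- sy
  }
  out <- list(raster = raster, network = net)
  if (!is.null(record_cells)) {
    out$vtrace <- sim$vtrace
    out$vtime <- seq_len(nrow(sim$vtrace)) * cfg$dt
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Train a network on a patch source
#'
#' Iterates [runTrial()] over a sequence of color patches under the
#' selected plasticity rule, tracking per-iteration mean firing rates,
#' periodic clustering coefficients of the V1 layers (measured with
#' plasticity frozen on the corner-color palette) and near-bound weight
#' fractions. Patches default to the configured synthetic style, drawn
#' with the configured input seed; the whole run is a pure function of
#' (network, config).
#'
#' @param net a [NetworkModel-class].
#' @param patches optional list of [colorPatch()]; defaults to
#'   `n_iterations` synthetic patches of the configured style.
#' @param rule plasticity rule; defaults to the configured one.
#' @param n_iterations number of 300 ms training iterations; defaults to
#'   the configured count.
#' @param trace logical; record the training trace (default `TRUE`).
#' @return list with `network` (trained) and `trace` (data.frame with
#'   `iteration`, mean V1 rates, clustering coefficients at the trace
#'   cadence, near-bound weight fraction), plus `weights_initial` and
#'   `weights_final` snapshots of the plastic weights.
#' @export
trainNetwork <- function(net, patches = NULL,
                         rule = net@config$rule,
                         n_iterations = net@config$n_iterations,
                         trace = TRUE) {
  cfg <- net@config
  rule <- match.arg(rule, c("stdp", "hebbian", "frozen"))
  set.seed(cfg$input_seed)
  if (is.null(patches))
    patches <- synthPatchSampler(max(n_iterations, 1), c(cfg$pr_rows, cfg$pr_cols),
                                 style = cfg$train_style)
  if (n_iterations > length(patches))
    stop("patch source yields fewer patches than n_iterations")
  w0 <- net@synapses$weight[net@synapses$plastic]
  rows <- list()
  for (it in seq_len(n_iterations)) {
    res <- runTrial(net, patches[[it]], cfg$iteration_ms, rule)
    net <- res$network
    if (trace) {
      ev <- res$raster@events
      v1 <- ev[ev$layer %in% c("V1L4", "V1L23", "V1L5"), ]
      mean_rate <- nrow(v1) / nCells(net, c("V1L4", "V1L23", "V1L5")) /
        cfg$iteration_ms * 1000
      row <- data.frame(iteration = it, mean_v1_rate = mean_rate,
                        nearbound = NA_real_, C_V1L4 = NA_real_,
                        C_V1L23 = NA_real_, C_V1L5 = NA_real_,
                        Craw_V1L4 = NA_real_, Craw_V1L23 = NA_real_,
                        Craw_V1L5 = NA_real_)
      if (it %% cfg$trace_cadence == 0 || it == n_iterations || it == 1) {
        w <- net@synapses$weight[net@synapses$plastic]
        row$nearbound <- weightBimodality(w, cfg$w_min, cfg$w_max)$near_bound_fraction
        rt <- .with_seed(cfg$noise_seed + it,
                         testColors(net, n_transforms = 1,
                                    duration = cfg$trace_test_ms))
        for (lyr in c("V1L4", "V1L23", "V1L5")) {
          row[[paste0("C_", lyr)]] <-
            suppressWarnings(clusteringCoefficient(rt, layer = lyr)$C)
          row[[paste0("Craw_", lyr)]] <-
            clusteringCoefficient(rt, layer = lyr, normalize = "none")$C
        }
      }
      rows[[it]] <- row
    }
  }
  list(network = net,
       trace = if (trace) do.call(rbind, rows) else NULL,
       weights_initial = w0,
       weights_final = net@synapses$weight[net@synapses$plastic])
}

#' Present test colors and collect mean rates
#'
#' Presents each color (and `n_transforms - 1` slightly varied versions of
#' it, each RGB channel scaled by an independent factor within
#' `transform_frac` and clipped to `[0, 1]`) full-field for `duration` ms
#' with plasticity disabled, and returns the mean firing rate of every
#' cell for every presentation. Response variability across transforms
#' comes from the transform jitter and the 10% input rate noise.
#'
#' @param net a [NetworkModel-class].
#' @param colors named list of RGB triples; default the eight RGB-cube
#'   corners (the 0/1 combinations).
#' @param n_transforms presentations per color (the first is the
#'   unvaried color).
#' @param transform_frac RGB jitter fraction (default 0.01, i.e. +-1%).
#' @param duration ms per presentation.
#' @return a [RateTable-class].
#' @export
testColors <- function(net, colors = colorPalette("corners"),
                       n_transforms = net@config$n_transforms,
                       transform_frac = net@config$transform_frac,
                       duration = net@config$iteration_ms) {
  cfg <- net@config
  dims <- c(cfg$pr_rows, cfg$pr_cols)
  nstim <- length(colors)
  counts <- matrix(0, nCells(net), nstim * n_transforms)
  stim <- character(0); trans <- integer(0)
  jcol <- 0
  for (s in seq_len(nstim)) {
    for (tr in seq_len(n_transforms)) {
      rgb <- unlist(colors[[s]])
      if (tr > 1)
        rgb <- pmin(pmax(rgb * (1 + runif(3, -transform_frac, transform_frac)), 0), 1)
      res <- runTrial(net, colorPatch(rgb, dims), duration, rule = "frozen")
      ev <- res$raster@events
      jcol <- jcol + 1
      if (nrow(ev)) {
        tab <- tabulate(ev$cell + 1L, nbins = nCells(net))
        counts[, jcol] <- tab
      }
      stim <- c(stim, names(colors)[s] %||% as.character(s))
      trans <- c(trans, tr)
    }
  }
  rateTable(counts / duration * 1000, net = net, stimulus = stim,
            transform = trans)
}

#' Construct a rate table
#'
#' Builds a [RateTable-class] from a cells x presentations rate matrix.
#' Cell grid coordinates are taken from the network when one is given;
#' otherwise cells are laid out row-major on a `dims` grid (required by
#' the spatial clustering statistic only).
#'
#' @param x numeric matrix of mean rates (Hz), cells x presentations.
#' @param net optional [NetworkModel-class] supplying layer/coordinates.
#' @param stimulus character vector, one label per column.
#' @param transform integer vector, one transform index per column.
#' @param layer layer label(s) for the rows when `net` is absent.
#' @param dims grid dims `c(rows, cols)` when `net` is absent (default:
#'   a single row of cells).
#' @return a [RateTable-class].
#' @examples
#' rt <- rateTable(matrix(runif(36, 0, 10), 6), stimulus = rep(c("a", "b", "c"), 2),
#'                 transform = rep(1:2, each = 3), dims = c(2, 3))
#' rates(rt)
#' @export
rateTable <- function(x, net = NULL, stimulus, transform,
                      layer = "cells", dims = NULL) {
  x <- as.matrix(x)
  if (length(stimulus) != ncol(x) || length(transform) != ncol(x))
    stop("stimulus/transform must have one entry per column")
  if (!is.null(net)) {
    cells <- seq_len(nCells(net)) - 1L
    rd <- cbind(data.frame(layer = .layer_of(net, cells), cell = cells),
                .cell_coords(net, cells))
  } else {
    n <- nrow(x)
    if (is.null(dims)) dims <- c(1L, n)
    if (prod(dims) != n) stop("dims do not match the number of cells")
    cells <- seq_len(n) - 1L
    rd <- data.frame(layer = layer, cell = cells,
                     row = cells %/% dims[2], col = cells %% dims[2])
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(rate = x),
    rowData = rd,
    colData = S4Vectors::DataFrame(stimulus = stimulus, transform = transform))
  new("RateTable", se)
}

#' ON/OFF stimulation protocol
#'
#' For each color: one trial of `on_ms` full-field stimulation followed by
#' `off_ms` of no visual input (no input spikes at all), with spike (and
#' optionally voltage) recording and plasticity disabled. The raster
#' metadata records the window bounds so cell-selection functions can find
#' the ON window (first part of stimulation) and OFF window (after
#' removal).
#'
#' @param net a [NetworkModel-class].
#' @param colors named list of RGB triples; default the eight named test
#'   colors.
#' @param on_ms,off_ms stimulus and silence durations (defaults 240/60).
#' @param record_cells optional global cell ids to record voltages for.
#' @param noise_mode input noise reading; the default `"jitter"` preserves
#'   the phase alignment of the input trains, which the protocol's delay
#'   mechanism depends on (see [generateInputSpikes()]).
#' @return named list of [SpikeRaster-class], one per color.
#' @export
onOffProtocol <- function(net, colors = colorPalette("named"),
                          on_ms = net@config$on_ms, off_ms = net@config$off_ms,
                          record_cells = NULL, noise_mode = "jitter") {
  stopifnot(on_ms > 0, off_ms > 0)
  cfg <- net@config
  dims <- c(cfg$pr_rows, cfg$pr_cols)
  out <- lapply(seq_along(colors), function(s) {
    drive <- rgbToConeRates(colorPatch(unlist(colors[[s]]), dims), cfg$max_rate_hz)
    ins <- generateInputSpikes(net, drive, on_ms, cfg$noise_frac,
                               mode = noise_mode)
    sim <- .cs_simulate(net, ins, on_ms + off_ms, cfg$dt,
                        record_cells = record_cells %||% integer())
    md <- list(stimulus = names(colors)[s] %||% as.character(s),
               on_ms = on_ms, off_ms = off_ms)
    r <- new("SpikeRaster", events = sim$events, duration = on_ms + off_ms,
             metadata = md)
    if (!is.null(record_cells))
      attr(r, "vtrace") <- sim$vtrace
    r
  })
  names(out) <- names(colors) %||% as.character(seq_along(colors))
  out
}
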