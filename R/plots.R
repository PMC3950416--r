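## Base-graphics views of rasters, weights, training traces and
## information curves.

#' Plot a spike raster
#'
#' @param raster a [SpikeRaster-class].
#' @param layer layer (or cell-name) filter; `NULL` plots everything.
#' @param cells optional subset of global cell ids, plotted in order.
#' @param main title.
#' @return invisibly, the plotted events.
#' @export
plotRaster <- function(raster, layer = NULL, cells = NULL, main = NULL) {
  ev <- spikes(raster, layer = layer)
  if (!is.null(cells)) {
    ev <- ev[ev$cell %in% cells, ]
    ev$y <- match(ev$cell, cells)
  } else {
    ids <- sort(unique(ev$cell))
    ev$y <- match(ev$cell, ids)
  }
  plot(ev$time, ev$y, pch = "|", cex = 0.6,
       xlab = "time (ms)", ylab = "cell",
       xlim = c(0, raster@duration), main = main %||% "")
  md <- raster@metadata
  if (!is.null(md$on_ms)) graphics::abline(v = md$on_ms, lty = 2)
  invisible(ev)
}

#' Plot weight histograms before/after training
#'
#' @param w_before,w_after plastic weight vectors.
#' @param w_max range bound used for the axis.
#' @return invisibly, `NULL`.
#' @export
plotWeightHistogram <- function(w_before, w_after, w_max = max(w_after)) {
  op <- graphics::par(mfrow = c(1, 2)); on.exit(graphics::par(op))
  graphics::hist(w_before, breaks = 30, xlim = c(0, w_max),
                 main = "before training", xlab = "weight (uS)")
  graphics::hist(w_after, breaks = 30, xlim = c(0, w_max),
                 main = "after training", xlab = "weight (uS)")
  invisible(NULL)
}

#' Plot clustering-coefficient training dynamics
#'
#' @param trace_stdp training trace (see [trainNetwork()]).
#' @param trace_hebbian optional control trace overlaid.
#' @return invisibly, `NULL`.
#' @export
plotClusteringTrace <- function(trace_stdp, trace_hebbian = NULL) {
  tr <- trace_stdp[!is.na(trace_stdp$C_V1L5), ]
  plot(tr$iteration, tr$C_V1L5, type = "o", pch = 16,
       xlab = "iteration", ylab = "clustering coefficient C",
       ylim = c(0, max(tr$C_V1L5, 0.1, na.rm = TRUE) * 1.3))
  graphics::lines(tr$iteration, tr$C_V1L4, lty = 3)
  graphics::lines(tr$iteration, tr$C_V1L23, lty = 2)
  if (!is.null(trace_hebbian)) {
    th <- trace_hebbian[!is.na(trace_hebbian$C_V1L5), ]
    graphics::lines(th$iteration, th$C_V1L5, type = "o", pch = 8)
  }
  graphics::legend("topleft", bty = "n",
                   legend = c("L5 (STDP)", "L2/3", "L4",
                              if (!is.null(trace_hebbian)) "L5 (Hebbian)"),
                   lty = c(1, 2, 3, if (!is.null(trace_hebbian)) 1),
                   pch = c(16, NA, NA, if (!is.null(trace_hebbian)) 8))
  invisible(NULL)
}

#' Plot single- and multiple-cell information curves
#'
#' @param rt_naive,rt_trained rate tables of the naive and trained
#'   network on the same palette.
#' @param layer layer to analyse.
#' @param max_cells largest population size for the multiple-cell curve.
#' @return invisibly, the computed curves.
#' @export
plotInformationCurves <- function(rt_naive, rt_trained, layer = "V1L5",
                                  max_cells = 15) {
  op <- graphics::par(mfrow = c(1, 2)); on.exit(graphics::par(op))
  s0 <- singleCellInfo(rt_naive, layer = layer)
  s1 <- singleCellInfo(rt_trained, layer = layer)
  plot(sort(s1$max_info, decreasing = TRUE), type = "l",
       xlab = "cell rank", ylab = "single-cell information (bits)",
       ylim = c(0, s1$ceiling_bits))
  graphics::lines(sort(s0$max_info, decreasing = TRUE), lty = 3)
  graphics::abline(h = s1$ceiling_bits, col = "grey")
  m0 <- multipleCellInfo(rt_naive, max_cells = max_cells, layer = layer)
  m1 <- multipleCellInfo(rt_trained, max_cells = max_cells, layer = layer)
  plot(m1$n_cells, m1$info, type = "o", pch = 16,
       xlab = "number of cells", ylab = "multiple-cell information (bits)",
       ylim = c(0, m1$ceiling_bits))
  graphics::lines(m0$n_cells, m0$info, type = "o", lty = 3)
  graphics::abline(h = m1$ceiling_bits, col = "grey")
  graphics::legend("bottomright", bty = "n", legend = c("trained", "naive"),
                   lty = c(1, 3), pch = c(16, 1))
  invisible(list(single = list(naive = s0, trained = s1),
                 multiple = list(naive = m0, trained = m1)))
}

#' Plot per-color response maps of one layer
#'
#' @param rt a [RateTable-class].
#' @param layer layer name.
#' @return invisibly, `NULL`.
#' @export
plotColorResponseMaps <- function(rt, layer = "V1L5") {
  lr <- .layer_stim_rates(rt, layer)
  ns <- ncol(lr$fr)
  op <- graphics::par(mfrow = c(2, ceiling(ns / 2))); on.exit(graphics::par(op))
  nr <- max(lr$row) + 1; nc <- max(lr$col) + 1
  for (s in seq_len(ns)) {
    m <- matrix(NA, nr, nc)
    m[cbind(lr$row + 1, lr$col + 1)] <- lr$fr[, s]
    graphics::image(t(m)[, nr:1], main = lr$stims[s], axes = FALSE,
                    col = grDevices::hcl.colors(20, "YlOrRd", rev = TRUE))
  }
  invisible(NULL)
}
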