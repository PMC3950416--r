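## Rate-based statistics: spatial clustering coefficient, single-cell and
## Bayesian multiple-cell stimulus information, ON/OFF and opponent cell
## selection, weight bimodality. Each has a brute-force-checkable form.

## per-stimulus mean rate matrix (cells x stimuli) for one layer,
## averaging over transforms, plus the layer grid coordinates
.layer_stim_rates <- function(rt, layer) {
  rd <- SummarizedExperiment::rowData(rt)
  keep <- if (is.null(layer)) rep(TRUE, nrow(rd)) else rd$layer %in% layer
  x <- SummarizedExperiment::assay(rt, "rate")[keep, , drop = FALSE]
  cd <- SummarizedExperiment::colData(rt)
  stims <- unique(cd$stimulus)
  fr <- vapply(stims, function(s)
    rowMeans(x[, cd$stimulus == s, drop = FALSE]), numeric(nrow(x)))
  fr <- matrix(fr, nrow = nrow(x), dimnames = list(NULL, stims))
  list(fr = fr, stims = stims,
       row = rd$row[keep], col = rd$col[keep])
}

#' Spatial clustering coefficient of stimulus-evoked rates
#'
#' Quantifies spatial co-activation: for each cell i and stimulus s, the
#' mean pairwise product of normalized firing rates over the cell's square
#' neighborhood (3x3 = 9 cells including i by default, truncated at
#' borders with the pair count adjusted),
#' \deqn{C_{s,i} = \frac{\sum_{l<m} FR_{s,l}\, FR_{s,m}}{\binom{k_i}{2}}}
#' averaged over all cells and stimuli. Rates are min-max normalized to
#' `[0, 1]` per stimulus across the layer before the products, so
#' `C` is 1 when every cell is maximally active and 0 when the layer is
#' silent. This is a co-activation statistic on the grid, not the
#' graph-theoretic clustering coefficient.
#'
#' The `normalize` argument selects the rate scaling used before the
#' products: `"minmax"` (default; bounds C to `[0, 1]` and makes it a pure
#' spatial-correlation measure), `"max"` (divide by the per-stimulus
#' maximum) or `"none"` (raw rates in Hz, the literal reading of the
#' defining sums; the statistic then also grows with overall firing, which
#' is what lets it track training-induced rate growth). See the vignette
#' for the trade-off.
#'
#' @param rt a [RateTable-class] (transforms of a stimulus are averaged).
#' @param k neighborhood size; must be an odd square (9 = 3x3 default).
#' @param layer layer name(s) to analyse; `NULL` uses all rows (they must
#'   then share one grid).
#' @param normalize rate scaling, see Details.
#' @return list with `C` (scalar), `per_cell` (cells x stimuli matrix of
#'   `C_{s,i}`), `k`, `stimuli`, `normalize`.
#' @export
clusteringCoefficient <- function(rt, k = 9, layer = NULL,
                                  normalize = c("minmax", "max", "none")) {
  normalize <- match.arg(normalize)
  side <- sqrt(k)
  if (side != floor(side) || side %% 2 != 1)
    stop("k must be an odd square (e.g. 9 for a 3x3 neighborhood)")
  rad <- (side - 1) / 2
  lr <- .layer_stim_rates(rt, layer)
  fr <- lr$fr
  nr <- max(lr$row) + 1; nc <- max(lr$col) + 1
  per_cell <- matrix(NA_real_, nrow(fr), ncol(fr),
                     dimnames = list(NULL, lr$stims))
  for (s in seq_len(ncol(fr))) {
    x <- fr[, s]
    rng <- range(x)
    if (normalize == "none") {
      xn <- x
    } else if (diff(rng) == 0) {
      warning("degenerate normalization: all rates equal for stimulus '",
              lr$stims[s], "'")
      xn <- rep(if (rng[1] > 0) 1 else 0, length(x))
    } else if (normalize == "minmax") {
      xn <- (x - rng[1]) / diff(rng)
    } else {
      xn <- x / rng[2]
    }
    grid <- matrix(NA_real_, nr, nc)
    grid[cbind(lr$row + 1, lr$col + 1)] <- xn
    for (i in seq_along(x)) {
      rr <- max(0, lr$row[i] - rad):min(nr - 1, lr$row[i] + rad)
      cc <- max(0, lr$col[i] - rad):min(nc - 1, lr$col[i] + rad)
      vals <- as.vector(grid[rr + 1, cc + 1])
      ki <- length(vals)
      # sum over unordered pairs l < m of vals[l] * vals[m]
      per_cell[i, s] <- (sum(vals)^2 - sum(vals^2)) / 2 / choose(ki, 2)
    }
  }
  list(C = mean(per_cell), per_cell = per_cell, k = k, stimuli = lr$stims,
       normalize = normalize)
}

#' Single-cell stimulus-specific information
#'
#' For each cell, the information its response carries about the presence
#' of each stimulus,
#' \deqn{I(s, R) = \sum_{r} P(r|s) \log_2 \frac{P(r|s)}{P(r)}}
#' with responses discretized into `n_bins` equal-width bins over the
#' cell's observed range, `P(r|s)` estimated over the transforms of `s`
#' and `P(r)` over all presentations. The theoretical ceiling is
#' `log2(nStims)` (3 bits for 8 stimuli). A cell with zero response range
#' carries 0 bits by convention.
#'
#' @param rt a [RateTable-class].
#' @param n_bins number of response bins (default 8).
#' @param layer optional layer restriction.
#' @return list with `max_info` (per-cell maximum over stimuli, bits),
#'   `per_stimulus` (cells x stimuli matrix), `ceiling_bits`, `order`
#'   (cells ranked by `max_info`, as row indices).
#' @export
singleCellInfo <- function(rt, n_bins = 8, layer = NULL) {
  stopifnot(n_bins >= 2)
  rd <- SummarizedExperiment::rowData(rt)
  keep <- if (is.null(layer)) rep(TRUE, nrow(rd)) else rd$layer %in% layer
  x <- SummarizedExperiment::assay(rt, "rate")[keep, , drop = FALSE]
  cd <- SummarizedExperiment::colData(rt)
  stims <- unique(cd$stimulus)
  ns <- length(stims)
  info <- matrix(0, nrow(x), ns, dimnames = list(NULL, stims))
  for (i in seq_len(nrow(x))) {
    r <- x[i, ]
    rng <- range(r)
    if (diff(rng) == 0) next                       # zero range -> 0 bits
    b <- pmin(floor((r - rng[1]) / diff(rng) * n_bins) + 1L, n_bins)
    pr <- tabulate(b, n_bins) / length(b)
    for (s in seq_len(ns)) {
      bs <- b[cd$stimulus == stims[s]]
      prs <- tabulate(bs, n_bins) / length(bs)
      nz <- prs > 0
      info[i, s] <- sum(prs[nz] * log2(prs[nz] / pr[nz]))
    }
  }
  mx <- apply(info, 1, max)
  list(max_info = mx, per_stimulus = info, ceiling_bits = log2(ns),
       order = order(mx, decreasing = TRUE))
}

#' Multiple-cell stimulus information by Bayesian decoding
#'
#' Measures how well a growing population identifies the stimulus. Cells
#' are added in decreasing order of single-cell information; for each
#' subset size the stimulus of every presentation is decoded from the
#' joint response under independent per-cell Gaussian likelihoods
#' (mean and SD over that stimulus's transforms, SD floored at
#' `sd_floor`), the posterior mass is accumulated into the
#' (actual, decoded) confusion distribution, and the mutual information
#' of that distribution is reported. A population that decodes all of
#' `nStims` equiprobable stimuli perfectly reaches `log2(nStims)` bits.
#'
#' @param rt a [RateTable-class].
#' @param max_cells largest subset size (default: all cells of the layer,
#'   capped at 30).
#' @param layer optional layer restriction.
#' @param n_bins bins for the single-cell ranking.
#' @param sd_floor lower bound on the Gaussian SD (Hz); zero-variance
#'   cells otherwise produce degenerate posteriors (a warning is emitted
#'   when the floor engages).
#' @param ranking optional explicit cell ordering (row indices within the
#'   layer) overriding the single-cell ranking.
#' @return list with `info` (bits, one entry per subset size), `n_cells`,
#'   `ceiling_bits`, `ranking`.
#' @export
multipleCellInfo <- function(rt, max_cells = NULL, layer = NULL, n_bins = 8,
                             sd_floor = 1e-3, ranking = NULL) {
  rd <- SummarizedExperiment::rowData(rt)
  keep <- if (is.null(layer)) rep(TRUE, nrow(rd)) else rd$layer %in% layer
  x <- SummarizedExperiment::assay(rt, "rate")[keep, , drop = FALSE]
  cd <- SummarizedExperiment::colData(rt)
  stims <- unique(cd$stimulus)
  ns <- length(stims)
  if (is.null(ranking))
    ranking <- singleCellInfo(rt, n_bins = n_bins, layer = layer)$order
  if (is.null(max_cells)) max_cells <- min(nrow(x), 30L)
  stopifnot(max_cells >= 1, max_cells <= nrow(x))
  # per-cell, per-stimulus Gaussian response models
  mu <- matrix(vapply(stims, function(s)
    rowMeans(x[, cd$stimulus == s, drop = FALSE]), numeric(nrow(x))), nrow(x))
  sdv <- matrix(vapply(stims, function(s)
    apply(x[, cd$stimulus == s, drop = FALSE], 1, sd), numeric(nrow(x))), nrow(x))
  sdv[is.na(sdv)] <- 0
  if (any(sdv < sd_floor))
    warning("SD floor engaged for ", sum(sdv < sd_floor),
            " (cell, stimulus) response models")
  sdv <- pmax(sdv, sd_floor)
  pres_s <- match(cd$stimulus, stims)
  info <- numeric(max_cells)
  for (nc_use in seq_len(max_cells)) {
    cells <- ranking[seq_len(nc_use)]
    joint <- matrix(0, ns, ns)                     # P(s, s')
    for (j in seq_len(ncol(x))) {
      ll <- numeric(ns)
      for (sp in seq_len(ns))
        ll[sp] <- sum(dnorm(x[cells, j], mu[cells, sp], sdv[cells, sp], log = TRUE))
      post <- exp(ll - max(ll))
      post <- post / sum(post)
      joint[pres_s[j], ] <- joint[pres_s[j], ] + post
    }
    joint <- joint / sum(joint)
    ps <- rowSums(joint); psp <- colSums(joint)
    nz <- joint > 0
    info[nc_use] <- sum(joint[nz] * log2(joint[nz] / outer(ps, psp)[nz]))
  }
  list(info = info, n_cells = seq_len(max_cells), ceiling_bits = log2(ns),
       ranking = ranking)
}

#' Number of cells needed to reach a fraction of the information plateau
#'
#' Convenience summary of a [multipleCellInfo()] curve: the smallest
#' subset size whose information reaches `frac` of the curve's maximum.
#'
#' @param mci result of [multipleCellInfo()].
#' @param frac plateau fraction (default 0.95).
#' @return integer cell count.
#' @export
cellsToPlateau <- function(mci, frac = 0.95) {
  which(mci$info >= frac * max(mci$info))[1]
}

## spike counts per cell of one layer inside a time window
.window_counts <- function(raster, layer, window) {
  ev <- spikes(raster, layer = layer, window = window)
  ev
}

#' Select ON and OFF cells from an ON/OFF trial
#'
#' ON cells are those that respond the most during the first `sel_ms` of
#' stimulation; OFF cells respond the most during the `sel_ms` after
#' stimulus removal. Ranking is by window spike count, ties broken by
#' cell id (ascending).
#'
#' @param raster a [SpikeRaster-class] from [onOffProtocol()] (its
#'   metadata supplies the on/off bounds).
#' @param layer layer to rank (default `"V1L5"`).
#' @param n_select list length (default 30).
#' @param sel_ms selection window length, ms (default 60).
#' @return list with `on` and `off` data.frames (`cell`, `count`), each
#'   with `n_select` rows.
#' @export
selectOnOffCells <- function(raster, layer = "V1L5", n_select = 30, sel_ms = 60) {
  md <- raster@metadata
  on_ms <- md$on_ms %||% raster@duration
  rank_window <- function(window) {
    ly <- raster@events[raster@events$layer == layer, , drop = FALSE]
    all_cells <- sort(unique(ly$cell))
    ev <- ly[ly$time >= window[1] & ly$time < window[2], , drop = FALSE]
    cnt <- table(factor(ev$cell, levels = all_cells))
    df <- data.frame(cell = as.integer(names(cnt)), count = as.integer(cnt))
    df <- df[order(-df$count, df$cell), ]
    head(df, n_select)
  }
  list(on = rank_window(c(0, sel_ms)),
       off = rank_window(c(on_ms, on_ms + sel_ms)))
}

#' Select color-opponent ON/OFF cells
#'
#' The two-stage opponent-cell search: first the `n_pool` cells with the
#' strongest ON response to the primary color, then, within that pool,
#' the `n_select` cells with the strongest OFF response to the opponent
#' color. Cells with no OFF response do not qualify; when fewer than
#' `n_select` qualify the (shorter) list is returned with `short = TRUE`
#' -- the signature of the no-input-delay ablation.
#'
#' @param rasters named list of [SpikeRaster-class] from
#'   [onOffProtocol()].
#' @param primary_color,opponent_color names into `rasters` (e.g. `"red"`
#'   and `"green"`).
#' @param n_pool ON pool size (default 100).
#' @param n_select final list size (default 30).
#' @param layer layer to search (default `"V1L5"`).
#' @param sel_ms selection window length, ms.
#' @return list with `cells` (data.frame `cell`, `on_count`, `off_count`),
#'   `short` (logical), `n_qualifying`.
#' @export
selectOpponentCells <- function(rasters, primary_color, opponent_color,
                                n_pool = 100, n_select = 30,
                                layer = "V1L5", sel_ms = 60) {
  stopifnot(primary_color %in% names(rasters), opponent_color %in% names(rasters))
  on_sel <- selectOnOffCells(rasters[[primary_color]], layer = layer,
                             n_select = n_pool, sel_ms = sel_ms)$on
  pool <- on_sel[on_sel$count > 0, , drop = FALSE]
  off_sel <- selectOnOffCells(rasters[[opponent_color]], layer = layer,
                              n_select = .Machine$integer.max, sel_ms = sel_ms)$off
  m <- merge(pool, off_sel, by = "cell", suffixes = c("_on", "_off"))
  m <- m[m$count_off > 0, , drop = FALSE]
  m <- m[order(-m$count_off, m$cell), ]
  qualified <- nrow(m)
  m <- head(m, n_select)
  names(m) <- c("cell", "on_count", "off_count")
  list(cells = m, short = qualified < n_select, n_qualifying = qualified)
}

#' Bimodality of a weight distribution
#'
#' Reports the fraction of weights within 10% of either range bound (the
#' "binarization" of a trained projection) together with Sarle's
#' bimodality coefficient \eqn{(\gamma^2 + 1)/\kappa} (values above ~0.55,
#' the uniform-distribution value, indicate bimodality). A uniform
#' distribution over the range has a near-bound fraction of 0.2; a fully
#' binarized one has 1.
#'
#' @param w numeric weights (at least 10).
#' @param w_min,w_max range bounds (default: observed range).
#' @return list with `near_bound_fraction` and `bimodality_coefficient`.
#' @export
weightBimodality <- function(w, w_min = min(w), w_max = max(w)) {
  if (length(w) < 10) stop("need at least 10 weights")
  rng <- w_max - w_min
  frac <- mean(w <= w_min + 0.1 * rng | w >= w_max - 0.1 * rng)
  n <- length(w)
  m <- mean(w); s <- sd(w)
  bc <- if (s == 0) NA_real_ else {
    g1 <- sum((w - m)^3) / n / s^3
    g2 <- sum((w - m)^4) / n / s^4
    (g1^2 + 1) / g2
  }
  list(near_bound_fraction = frac, bimodality_coefficient = bc)
}
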