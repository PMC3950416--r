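## STDP weight updates, the order-blind Hebbian control rule, and
## per-projection weight normalization.

#' STDP parameters
#'
#' @param lr learning rate (weight change per pairing at zero lag), uS.
#' @param p_tau potentiation time constant, ms (default 17).
#' @param d_tau depression time constant, ms (default 34).
#' @param w_min,w_max weight bounds, uS.
#' @return named parameter list.
#' @export
stdpParams <- function(lr = 2e-7, p_tau = 17, d_tau = 34,
                       w_min = 0, w_max = 2e-4) {
  stopifnot(lr > 0, p_tau > 0, d_tau > 0, w_min >= 0, w_min < w_max)
  list(lr = lr, p_tau = p_tau, d_tau = d_tau, w_min = w_min, w_max = w_max)
}

## STDP parameters implied by a run configuration
.stdp_from_config <- function(cfg) {
  stdpParams(lr = cfg$lr, p_tau = cfg$p_tau, d_tau = cfg$d_tau,
             w_min = cfg$w_min, w_max = cfg$w_max)
}

#' STDP weight change for one spike pair
#'
#' The pair-based exponential STDP window
#' \deqn{\Delta w = \begin{cases}
#'   LR\, e^{-\Delta t / p_{tau}} & \Delta t > 0 \\
#'   -LR\, e^{\Delta t / d_{tau}} & \Delta t < 0
#' \end{cases}, \qquad \Delta t = t_{post} - t_{pre}}
#' Causal order (pre before post) potentiates, anti-causal depresses; the
#' depression window (`d_tau` = 34 ms) is wider than the potentiation
#' window (`p_tau` = 17 ms). `\Delta t = 0` is undefined by the rule and
#' returns 0 by convention. Vectorized over spike times.
#'
#' @param t_pre,t_post spike times, ms.
#' @param params [stdpParams()].
#' @return weight change(s), same sign convention as above.
#' @examples
#' p <- stdpParams(lr = 1)
#' stdpDelta(0, 17, p)    # exp(-1)
#' stdpDelta(34, 0, p)    # -exp(-1)
#' @export
stdpDelta <- function(t_pre, t_post, params = stdpParams()) {
  dt <- t_post - t_pre
  ifelse(dt > 0, params$lr * exp(-dt / params$p_tau),
         ifelse(dt < 0, -params$lr * exp(dt / params$d_tau), 0))
}

## Nearest-neighbour pairing: each post spike pairs with the closest
## preceding pre spike (potentiation), each pre spike with the closest
## preceding post spike (depression). Simultaneous spikes do not pair.
.stdp_pair_delta <- function(pre, post, params) {
  d <- 0
  if (length(pre) && length(post)) {
    idx <- findInterval(post - 1e-9, pre)
    hit <- idx > 0
    if (any(hit))
      d <- d + sum(params$lr * exp(-(post[hit] - pre[idx[hit]]) / params$p_tau))
    idx <- findInterval(pre - 1e-9, post)
    hit <- idx > 0
    if (any(hit))
      d <- d - sum(params$lr * exp(-(pre[hit] - post[idx[hit]]) / params$d_tau))
  }
  d
}

## spike-time list indexed by global cell id + 1
.spike_list <- function(x, n_cells) {
  ev <- if (is(x, "SpikeRaster")) x@events else x
  out <- vector("list", n_cells)
  if (nrow(ev)) {
    sp <- split(ev$time, ev$cell)
    out[as.integer(names(sp)) + 1L] <- sp
  }
  out
}

#' Apply STDP to a plastic projection
#'
#' Accumulates, for every plastic edge, the summed [stdpDelta()] over
#' nearest-neighbour spike pairings between its source and target cells,
#' then clips the weights to `[w_min, w_max]`.
#'
#' @param projection data.frame of synapses (as in
#'   [synapses()]); every row must be plastic.
#' @param preSpikes,postSpikes a [SpikeRaster-class] or a data.frame with
#'   `cell` (global id) and `time` columns. They may be the same object
#'   (one trial's full raster).
#' @param params [stdpParams()].
#' @param pairing `"nearest"` (nearest-neighbour, default). All-to-all
#'   pairing is intentionally not offered: with regular 40 Hz trains it
#'   couples every spike to every other and the update loses its locality.
#' @return the projection with updated weights.
#' @export
applySTDP <- function(projection, preSpikes, postSpikes = preSpikes,
                      params = stdpParams(), pairing = "nearest") {
  if (!all(projection$plastic))
    stop("contract violation: applySTDP on a non-plastic projection")
  pairing <- match.arg(pairing, "nearest")
  n_cells <- max(projection$src, projection$tgt) + 1L
  pre_l <- .spike_list(preSpikes, n_cells)
  post_l <- .spike_list(postSpikes, n_cells)
  w <- projection$weight
  pre_has <- lengths(pre_l[projection$src + 1L]) > 0
  post_has <- lengths(post_l[projection$tgt + 1L]) > 0
  for (e in which(pre_has & post_has)) {
    w[e] <- w[e] + .stdp_pair_delta(pre_l[[projection$src[e] + 1L]],
                                    post_l[[projection$tgt[e] + 1L]], params)
  }
  projection$weight <- pmin(pmax(w, params$w_min), params$w_max)
  projection
}

#' Order-blind Hebbian control update
#'
#' The control rule used to probe the role of spike timing: a plastic
#' weight is potentiated by `amplitude` once per presentation whenever
#' both its source and target cell spiked at least once inside the
#' window, regardless of order or lag; weights are then clipped.
#' Combined with mid-range normalization this rule carries no timing
#' information, only co-activation.
#'
#' @param projection plastic synapse data.frame.
#' @param preSpikes,postSpikes as in [applySTDP()].
#' @param amplitude weight increment per presentation, uS.
#' @param window `c(from, to)` ms.
#' @param w_min,w_max clip bounds.
#' @return the projection with updated weights.
#' @export
hebbianUpdate <- function(projection, preSpikes, postSpikes = preSpikes,
                          amplitude = 2e-7, window = c(0, 300),
                          w_min = 0, w_max = 2e-4) {
  if (!all(projection$plastic))
    stop("contract violation: hebbianUpdate on a non-plastic projection")
  n_cells <- max(projection$src, projection$tgt) + 1L
  inwin <- function(x) {
    ev <- if (is(x, "SpikeRaster")) x@events else x
    ev[ev$time >= window[1] & ev$time <= window[2], , drop = FALSE]
  }
  pre_n <- lengths(.spike_list(inwin(preSpikes), n_cells))
  post_n <- lengths(.spike_list(inwin(postSpikes), n_cells))
  both <- pre_n[projection$src + 1L] > 0 & post_n[projection$tgt + 1L] > 0
  projection$weight <- pmin(pmax(projection$weight + amplitude * both, w_min), w_max)
  projection
}

#' Normalize plastic weights to mid-range
#'
#' Rescales a weight vector multiplicatively so its mean sits at the
#' middle of the allowed range, clipping to the bounds and repeating the
#' rescale-and-clip until the mean is within tolerance of the target (at
#' most `max_pass` passes). Applied after every training iteration to
#' prevent runaway excitation. An all-zero vector is reset uniformly to
#' the target (degenerate case).
#'
#' @param w numeric weight vector (or a projection data.frame with a
#'   `weight` column, returned in kind).
#' @param w_min,w_max range bounds.
#' @param target_mean target mean; default `(w_min + w_max) / 2`.
#' @param tol convergence tolerance on the mean.
#' @param max_pass pass cap.
#' @return normalized weights (vector in, vector out; data.frame in,
#'   data.frame out).
#' @examples
#' w <- runif(100, 0, 1e-3)
#' mean(normalizeWeights(w, 0, 1e-3))   # 5e-4 within 1e-6
#' @export
normalizeWeights <- function(w, w_min = 0, w_max = 2e-4,
                             target_mean = (w_min + w_max) / 2,
                             tol = 1e-6, max_pass = 100) {
  df <- NULL
  if (is.data.frame(w)) { df <- w; w <- df$weight }
  if (!length(w)) stop("normalizeWeights needs at least one weight")
  if (all(w == 0)) {
    w <- rep(target_mean, length(w))
  } else {
    for (i in seq_len(max_pass)) {
      mu <- mean(w)
      if (abs(mu - target_mean) <= tol) break
      w <- pmin(pmax(w * target_mean / mu, w_min), w_max)
    }
  }
  if (!is.null(df)) { df$weight <- w; df } else w
}
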