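## Stimulus front end: RGB patches -> trichromatic cone rates -> regular
## input spike trains with rate noise and fixed per-cell onset delays,
## plus a synthetic patch generator standing in for natural-image crops.

#' Validate / construct an RGB color patch
#'
#' @param x either a `rows x cols x 3` array with values in `[0, 1]`, or a
#'   length-3 RGB vector that is expanded to a full-field patch.
#' @param dims `c(rows, cols)` used when expanding a full-field color.
#' @return a `rows x cols x 3` array of class `ColorPatch`.
#' @examples
#' p <- colorPatch(c(1, 0, 0), dims = c(10, 10))  # full-field red
#' dim(p)
#' @export
colorPatch <- function(x, dims = c(10, 10)) {
  if (is.numeric(x) && is.null(dim(x)) && length(x) == 3)
    x <- array(rep(x, each = prod(dims)), dim = c(dims, 3))
  if (!(is.array(x) && length(dim(x)) == 3 && dim(x)[3] == 3))
    stop("input error: a color patch must be a rows x cols x 3 array")
  if (any(x < 0 | x > 1) || any(!is.finite(x)))
    stop("input error: channel values must lie in [0, 1]")
  structure(x, class = "ColorPatch")
}

#' Convert an RGB patch to trichromatic cone firing rates
#'
#' Per-pixel application of the cone activation formulas with a 40 Hz
#' ceiling:
#' \deqn{S = 40 B,\quad M = 40\frac{G + 0.7R + 0.25B}{1.95},\quad
#'       L = 40\frac{R + 0.7G + 0.25B}{1.95}}
#' so that a stimulus perceived as red also drives the green (M-cone)
#' channel strongly. The photoreceptor grids are named R/G/B after the
#' channel that dominates them but carry the L/M/S-cone rates respectively
#' (R grid = L cone, G grid = M cone, B grid = S cone).
#'
#' @param patch a [colorPatch()].
#' @param max_rate_hz rate ceiling, Hz (default 40).
#' @return list of matrices `L`, `M`, `S` (Hz), each `rows x cols`.
#' @examples
#' d <- rgbToConeRates(colorPatch(c(1, 0, 0), dims = c(1, 1)))
#' c(S = d$S[1, 1], M = d$M[1, 1], L = d$L[1, 1])
#' @export
rgbToConeRates <- function(patch, max_rate_hz = 40) {
  patch <- colorPatch(unclass(patch), dims = dim(patch)[1:2])
  nr <- dim(patch)[1]; nc <- dim(patch)[2]
  R <- matrix(patch[, , 1], nr, nc)
  G <- matrix(patch[, , 2], nr, nc)
  B <- matrix(patch[, , 3], nr, nc)
  den <- 1 + 0.7 + 0.25
  list(S = max_rate_hz * B,
       M = max_rate_hz * (G + R * 0.7 + B * 0.25) / den,
       L = max_rate_hz * (R + G * 0.7 + B * 0.25) / den)
}

## global input-cell order: layer R (L-cone rates), G (M), B (S), row-major
.input_rate_vector <- function(net, drive) {
  c(t(drive$L), t(drive$M), t(drive$S))
}

#' Generate input spike trains from a cone drive
#'
#' Each photoreceptor cell with rate f > 0 emits a regular (clock-like)
#' train phase-shifted by the cell's fixed onset delay (drawn once at
#' network construction, uniform over one interspike interval of the rate
#' ceiling; reduced modulo the cell's own interval). Silent cells emit
#' nothing. Uses the current RNG stream.
#'
#' The 10% input noise has two readings, selected by `mode`:
#' \describe{
#'   \item{`"rate"`}{(default) per-presentation multiplicative rate noise:
#'     the effective rate is `f * (1 + eps)`, `eps ~ U(-noise_frac,
#'     +noise_frac)` drawn once per cell per presentation. Used for
#'     training and rate-based testing.}
#'   \item{`"jitter"`}{per-spike timing jitter: the rate is exactly `f`
#'     and each spike is displaced by `U(-noise_frac, +noise_frac)` of one
#'     interspike interval. This preserves the phase alignment of the
#'     trains across a presentation, which the spike-timing experiments
#'     (ON/OFF protocol, delay ablation) depend on; rate noise would by
#'     itself stagger the final input spikes by more than one interval and
#'     void the delay mechanism under test.}
#'   \item{`"poisson"`}{Poisson spiking at rate `f`, for rate-code
#'     comparisons.}
#' }
#'
#' @param net a [NetworkModel-class] (supplies the delays and cell ids).
#' @param drive cone rates from [rgbToConeRates()]; dims must match the
#'   photoreceptor grid.
#' @param duration ms.
#' @param noise_frac multiplicative rate-noise fraction (default from the
#'   network's config).
#' @param mode `"rate"`, `"jitter"` or `"poisson"` (see Details;
#'   `"regular"` is accepted as an alias of `"rate"`).
#' @return data.frame `cell` (global id), `time` (ms), sorted by time.
#' @examples
#' net <- buildNetwork(runConfig(pr_rows = 1, pr_cols = 1, lgn_rows = 1,
#'   lgn_cols = 1, v1_rows = 1, v1_cols = 1, input_delays = FALSE))
#' d <- rgbToConeRates(colorPatch(c(1, 1, 1), dims = c(1, 1)))
#' sp <- generateInputSpikes(net, d, 300, noise_frac = 0)
#' nrow(sp[sp$cell == 0, ])   # 12 spikes: 0, 25, ..., 275 ms
#' @export
generateInputSpikes <- function(net, drive, duration,
                                noise_frac = net@config$noise_frac,
                                mode = c("rate", "jitter", "poisson", "regular")) {
  mode <- match.arg(mode)
  if (mode == "regular") mode <- "rate"
  stopifnot(duration > 0, noise_frac >= 0)
  f <- .input_rate_vector(net, drive)
  if (length(f) != length(net@inputDelays))
    stop("drive dims do not match the photoreceptor grid")
  eps <- runif(length(f), -noise_frac, noise_frac)
  feff <- if (mode == "rate") f * (1 + eps) else f
  out <- vector("list", length(f))
  for (i in which(feff > 0)) {
    isi <- 1000 / feff[i]
    d0 <- net@inputDelays[i] %% isi
    n_sp <- max(0L, ceiling((duration - d0) / isi - 1e-9))
    grid <- d0 + isi * (seq_len(n_sp) - 1)
    tt <- switch(mode,
      rate = grid,
      jitter = {
        tj <- grid + runif(n_sp, -noise_frac * isi, noise_frac * isi)
        sort(tj[tj >= 0 & tj < duration])
      },
      poisson = {
        tp <- cumsum(rexp(ceiling(duration / isi * 3) + 10, rate = 1 / isi))
        tp[tp < duration]
      })
    if (length(tt))
      out[[i]] <- data.frame(cell = i - 1L, time = tt)
  }
  out <- do.call(rbind, out)
  if (is.null(out)) out <- data.frame(cell = integer(), time = numeric())
  out <- out[order(out$time, out$cell), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## bilinear upsampling of a coarse control grid to rows x cols
.interp_grid <- function(coarse, rows, cols) {
  kr <- nrow(coarse); kc <- ncol(coarse)
  ri <- seq(1, kr, length.out = rows)
  ci <- seq(1, kc, length.out = cols)
  r0 <- pmin(floor(ri), kr - 1); c0 <- pmin(floor(ci), kc - 1)
  fr <- ri - r0; fc <- ci - c0
  a <- coarse[r0, c0, drop = FALSE]; b <- coarse[r0, c0 + 1, drop = FALSE]
  cc <- coarse[r0 + 1, c0, drop = FALSE]; d <- coarse[r0 + 1, c0 + 1, drop = FALSE]
  wa <- outer(1 - fr, 1 - fc); wb <- outer(1 - fr, fc)
  wc <- outer(fr, 1 - fc); wd <- outer(fr, fc)
  a * wa + b * wb + cc * wc + d * wd
}

#' Synthetic color-patch sampler
#'
#' Emulates small crops of natural color scenes: spatially correlated
#' pixels whose hues cover the RGB cube. Three styles:
#' \describe{
#'   \item{`smooth_field`}{each channel is a coarse random control grid
#'     bilinearly upsampled, giving smooth fields with channel values
#'     spanning `[0, 1]` and long-run channel means near 0.5;}
#'   \item{`uniform_color`}{constant patches at random RGB-cube corners
#'     and interior points (`palette = "corners"` restricts to corners);}
#'   \item{`two_tone`}{the patch is split by a random line between two
#'     random colors.}
#' }
#' Uses the current RNG stream; identical seeds give identical sequences.
#'
#' @param n_patches number of patches.
#' @param dims `c(rows, cols)`.
#' @param style one of `"smooth_field"`, `"uniform_color"`, `"two_tone"`.
#' @param palette for `uniform_color`: `"mixed"` (corners and interior) or
#'   `"corners"`.
#' @param coarse control-grid side for `smooth_field` (default scales with
#'   the patch so correlation length is a few pixels).
#' @return list of [colorPatch()] objects.
#' @examples
#' set.seed(1)
#' ps <- synthPatchSampler(3, c(10, 10), style = "smooth_field")
#' range(ps[[1]])
#' @export
synthPatchSampler <- function(n_patches, dims = c(10, 10),
                              style = c("smooth_field", "uniform_color", "two_tone"),
                              palette = c("mixed", "corners"),
                              coarse = NULL) {
  style <- match.arg(style); palette <- match.arg(palette)
  stopifnot(n_patches > 0)
  rows <- dims[1]; cols <- dims[2]
  if (is.null(coarse)) coarse <- max(2, ceiling(max(rows, cols) / 4) + 1)
  corners <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  lapply(seq_len(n_patches), function(i) {
    px <- switch(style,
      smooth_field = {
        ar <- array(0, c(rows, cols, 3))
        for (ch in 1:3)
          ar[, , ch] <- .interp_grid(matrix(runif(coarse^2), coarse), rows, cols)
        ar
      },
      uniform_color = {
        col <- if (palette == "corners" || runif(1) < 0.5)
          corners[sample(nrow(corners), 1), ] else runif(3)
        array(rep(col, each = rows * cols), c(rows, cols, 3))
      },
      two_tone = {
        c1 <- runif(3); c2 <- runif(3)
        th <- runif(1, 0, pi)
        cx <- (rows - 1) / 2; cy <- (cols - 1) / 2
        g <- expand.grid(r = 0:(rows - 1), c = 0:(cols - 1))
        side <- (g$r - cx) * cos(th) + (g$c - cy) * sin(th) >= 0
        ar <- array(0, c(rows, cols, 3))
        for (ch in 1:3)
          ar[, , ch] <- matrix(ifelse(side, c1[ch], c2[ch]), rows, cols)
        ar
      })
    colorPatch(px, dims)
  })
}

#' Standard test palettes
#'
#' `"corners"`: the eight 0/1 combinations of the RGB cube, the stimulus
#' set of the information analyses. `"named"`: the eight named colors used
#' in the ON/OFF protocol (red, orange, yellow, green, aqua, blue, purple,
#' pink).
#'
#' @param which palette name.
#' @return named list of length-3 RGB vectors.
#' @export
colorPalette <- function(which = c("corners", "named")) {
  which <- match.arg(which)
  if (which == "corners") {
    g <- expand.grid(R = 0:1, G = 0:1, B = 0:1)
    nm <- c("black", "red", "green", "yellow", "blue", "magenta", "cyan", "white")
    setNames(lapply(seq_len(nrow(g)), function(i) as.numeric(g[i, ])), nm)
  } else {
    list(red = c(1, 0, 0), orange = c(1, 0.5, 0), yellow = c(1, 1, 0),
         green = c(0, 1, 0), aqua = c(0, 1, 1), blue = c(0, 0, 1),
         purple = c(0.5, 0, 1), pink = c(1, 0.4, 0.7))
  }
}
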