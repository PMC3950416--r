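# literal brute-force implementations used as oracles

oracle_clustering <- function(fr, rows, cols, normalize = "minmax") {
  vals <- c()
  for (s in seq_len(ncol(fr))) {
    x <- fr[, s]
    xn <- switch(normalize,
      minmax = if (diff(range(x)) == 0) rep(ifelse(max(x) > 0, 1, 0), length(x))
               else (x - min(x)) / diff(range(x)),
      none = x,
      max = x / max(x))
    for (i in seq_along(x)) {
      r0 <- (i - 1) %/% cols; c0 <- (i - 1) %% cols
      acc <- 0; k <- 0; members <- c()
      for (j in seq_along(x)) {
        r1 <- (j - 1) %/% cols; c1 <- (j - 1) %% cols
        if (max(abs(r1 - r0), abs(c1 - c0)) <= 1) members <- c(members, j)
      }
      ki <- length(members)
      for (a in seq_len(ki - 1)) for (b in (a + 1):ki)
        acc <- acc + xn[members[a]] * xn[members[b]]
      vals <- c(vals, acc / choose(ki, 2))
    }
  }
  mean(vals)
}

oracle_single_info <- function(x, stim, n_bins = 8) {
  stims <- unique(stim)
  out <- matrix(0, nrow(x), length(stims))
  for (i in seq_len(nrow(x))) {
    r <- x[i, ]
    if (diff(range(r)) == 0) next
    b <- pmin(floor((r - min(r)) / diff(range(r)) * n_bins) + 1, n_bins)
    for (s in seq_along(stims)) {
      acc <- 0
      bs <- b[stim == stims[s]]
      for (bin in 1:n_bins) {
        prs <- mean(bs == bin); pr <- mean(b == bin)
        if (prs > 0) acc <- acc + prs * log2(prs / pr)
      }
      out[i, s] <- acc
    }
  }
  apply(out, 1, max)
}

oracle_multi_info <- function(x, stim, cells, sd_floor = 1e-3) {
  stims <- unique(stim)
  ns <- length(stims)
  mu <- sapply(stims, function(s) rowMeans(x[, stim == s, drop = FALSE]))
  sdv <- sapply(stims, function(s) apply(x[, stim == s, drop = FALSE], 1, sd))
  sdv <- pmax(sdv, sd_floor)
  joint <- matrix(0, ns, ns)
  for (j in seq_len(ncol(x))) {
    post <- numeric(ns)
    for (sp in seq_len(ns)) {
      ll <- 0
      for (c in cells) ll <- ll + dnorm(x[c, j], mu[c, sp], sdv[c, sp], log = TRUE)
      post[sp] <- ll
    }
    post <- exp(post - max(post)); post <- post / sum(post)
    s_true <- match(stim[j], stims)
    joint[s_true, ] <- joint[s_true, ] + post
  }
  joint <- joint / sum(joint)
  acc <- 0
  for (a in 1:ns) for (b in 1:ns)
    if (joint[a, b] > 0)
      acc <- acc + joint[a, b] * log2(joint[a, b] /
                                      (sum(joint[a, ]) * sum(joint[, b])))
  acc
}
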