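# Independent from-scratch oracles for the drift detectors. The streaming
# implementations maintain state instance by instance; these recompute every
# statistic from the raw error vector at every index (vectorised over each
# reset segment), so agreement checks the full state machine: running
# statistics, minimum/maximum tracking, warning-zone entries, coincident
# warnings and resets.

# DDM oracle: returns tibble(level, index [0-based], episode)
oracle_ddm <- function(errors, min_instances = 30, warn_sigma = 2,
                       drift_sigma = 3) {
  out <- list()
  offset <- 0L
  episode <- 1L
  e <- as.integer(errors)
  while (length(e)) {
    n <- length(e)
    idx <- seq_len(n)
    p <- cumsum(e) / idx
    s <- sqrt(p * (1 - p) / idx)
    ps <- p + s
    ps_valid <- ifelse(idx >= min_instances, ps, Inf)
    m <- cummin(ps_valid)
    # first index attaining each running minimum (strict improvement)
    improved <- ps_valid < c(Inf, m[-n])
    argmin <- cummax(ifelse(improved, idx, 0L))
    p_min <- ifelse(argmin > 0, p[pmax(argmin, 1)], Inf)
    s_min <- ifelse(argmin > 0, s[pmax(argmin, 1)], Inf)
    valid <- idx >= min_instances & argmin > 0
    drift_zone <- valid & ps > p_min + drift_sigma * s_min
    warn_zone <- valid & ps > p_min + warn_sigma * s_min
    t_star <- if (any(drift_zone)) which(drift_zone)[1] else n + 1L
    # warning events: entries into the warning zone before the drift
    before <- warn_zone & idx < t_star & !drift_zone
    entries <- which(before & !c(FALSE, before[-n]))
    for (t in entries) {
      out[[length(out) + 1L]] <- data.frame(level = "warning",
                                            index = offset + t - 1L,
                                            episode = episode)
    }
    if (t_star <= n) {
      if (!length(entries)) {
        out[[length(out) + 1L]] <- data.frame(level = "warning",
                                              index = offset + t_star - 1L,
                                              episode = episode)
      }
      out[[length(out) + 1L]] <- data.frame(level = "drift",
                                            index = offset + t_star - 1L,
                                            episode = episode)
      offset <- offset + t_star
      e <- e[-seq_len(t_star)]
      episode <- episode + 1L
    } else {
      break
    }
  }
  if (!length(out)) {
    return(data.frame(level = character(0), index = integer(0),
                      episode = integer(0)))
  }
  do.call(rbind, out)
}

# EDDM oracle: per reset segment all distance statistics are recomputed in
# one vectorised pass over the error positions (cumulative sums rather than
# maintained state), with the max-tracking, gating, warning-entry and reset
# logic rebuilt independently of the streaming implementation.
oracle_eddm <- function(errors, min_errors = 30, alpha = 0.95, beta = 0.90) {
  out <- list()
  e <- as.integer(errors)
  n <- length(e)
  episode <- 1L
  start <- 1L
  repeat {
    pos <- start - 1L + which(e[start:n] == 1L)
    drifted <- FALSE
    if (length(pos) >= 2) {
      d <- diff(pos)
      k <- seq_along(d)
      s1 <- cumsum(d)
      s2 <- cumsum(d^2)
      mu <- s1 / k
      vr <- pmax((s2 - s1^2 / k) / pmax(k - 1, 1), 0)
      vr[k == 1] <- 0
      m2s <- mu + 2 * sqrt(vr)
      m2s_max <- cummax(m2s)
      ne <- k + 1L                     # errors seen at each distance update
      gate <- ne >= min_errors & m2s_max > 0
      ratio <- m2s / m2s_max
      warn_zone <- gate & ratio < alpha
      drift_zone <- gate & ratio < beta
      q_star <- if (any(drift_zone)) which(drift_zone)[1] else length(d) + 1L
      before <- warn_zone & k < q_star & !drift_zone
      entries <- which(before & !c(FALSE, before[-length(d)]))
      for (q in entries) {
        out[[length(out) + 1L]] <- data.frame(level = "warning",
                                              index = pos[q + 1L] - 1L,
                                              episode = episode)
      }
      if (q_star <= length(d)) {
        if (!length(entries)) {
          out[[length(out) + 1L]] <- data.frame(level = "warning",
                                                index = pos[q_star + 1L] - 1L,
                                                episode = episode)
        }
        out[[length(out) + 1L]] <- data.frame(level = "drift",
                                              index = pos[q_star + 1L] - 1L,
                                              episode = episode)
        start <- pos[q_star + 1L] + 1L
        episode <- episode + 1L
        drifted <- TRUE
      }
    }
    if (!drifted || start > n) break
  }
  if (!length(out)) {
    return(data.frame(level = character(0), index = integer(0),
                      episode = integer(0)))
  }
  do.call(rbind, out)
}

# brute-force per-entry outlier recomputation (n-1 sd, strict 2-sd rule)
oracle_outlier_mask <- function(m, groups) {
  mask <- matrix(FALSE, nrow(m), ncol(m), dimnames = dimnames(m))
  for (i in seq_len(nrow(m))) {
    for (j in seq_len(ncol(m))) {
      rows <- which(groups == groups[i])
      mu <- mean(m[rows, j])
      sg <- sd(m[rows, j])
      mask[i, j] <- abs(m[i, j] - mu) > 2 * sg
    }
  }
  mask
}

# brute-force per-entry scaling recomputation on the fitting matrix
oracle_scale <- function(m, method, power_exponent = 0.5) {
  out <- m
  for (j in seq_len(ncol(m))) {
    x <- m[, j]
    mu <- mean(x); sg <- sd(x); lo <- min(x); hi <- max(x)
    out[, j] <- switch(method,
      none = x,
      centering = x - mu,
      autoscaling = (x - mu) / sg,
      pareto = (x - mu) / sqrt(sg),
      range = (x - mu) / (hi - lo),
      vast = ((x - mu) / sg) * (mu / sg),
      level = (x - mu) / mu,
      log10 = log10(x),
      power = x^power_exponent)
  }
  out
}

events_key <- function(ev) {
  ev <- as.data.frame(ev)[, c("level", "index", "episode")]
  ev[order(ev$index, ev$level), , drop = FALSE]
}
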