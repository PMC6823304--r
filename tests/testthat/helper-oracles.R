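# Independent brute-force oracles. Each deliberately avoids the code path
# it checks: episode clustering via pairwise-gap graph components, entropies
# via explicit template loops, spectral power via direct DFT summation.

# All maximal clusters of suprathreshold samples by pairwise gap testing,
# then duration/duty filtering, done with none of the package's machinery.
oracle_episodes <- function(time_s, hr, cfg) {
  supra <- which(hr >= cfg$tachy_threshold)
  if (!length(supra)) {
    return(data.frame(start_s = numeric(0), end_s = numeric(0),
                      n_samples = integer(0), n_supra = integer(0),
                      duty = numeric(0)))
  }
  ts <- time_s[supra]
  gap_s <- cfg$merge_gap_min * 60
  adj <- abs(outer(ts, ts, "-")) <= gap_s
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  out <- do.call(rbind, lapply(split(ts, comp), function(tt) {
    s <- min(tt); e <- max(tt)
    n <- sum(time_s >= s & time_s <= e)
    data.frame(start_s = s, end_s = e, n_samples = n, n_supra = length(tt))
  }))
  out$duty <- out$n_supra / out$n_samples
  out <- out[out$end_s - out$start_s >= cfg$min_duration_min * 60 &
               out$duty >= cfg$min_duty, , drop = FALSE]
  out <- out[order(out$start_s), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# ApEn by exhaustive template counting (self-matches included).
oracle_apen <- function(x, m, r) {
  N <- length(x)
  phi <- function(mm) {
    n <- N - mm + 1
    logs <- numeric(n)
    for (i in seq_len(n)) {
      cnt <- 0L
      for (j in seq_len(n)) {
        if (max(abs(x[i:(i + mm - 1)] - x[j:(j + mm - 1)])) <= r)
          cnt <- cnt + 1L
      }
      logs[i] <- log(cnt / n)
    }
    mean(logs)
  }
  phi(m) - phi(m + 1)
}

# SampEn by exhaustive pair counting over the first N - m templates.
oracle_sampen <- function(x, m, r) {
  N <- length(x)
  n <- N - m
  A <- 0L; B <- 0L
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)])) <= r) B <- B + 1L
      if (max(abs(x[i:(i + m)] - x[j:(j + m)])) <= r) A <- A + 1L
    }
  }
  if (A == 0 || B == 0) return(NA_real_)
  -log(A / B)
}

# Band power by direct DFT summation (no fft()).
oracle_dft_power <- function(g, period_s = 60, fmax_hz = 1 / 120) {
  N <- length(g)
  total <- 0
  for (k in 0:(N - 1)) {
    if (k / (N * period_s) > fmax_hz + 1e-12) next
    Xk <- sum(g * exp(-2i * pi * k * (0:(N - 1)) / N))
    total <- total + Mod(Xk)^2
  }
  total
}

# Sum of sample autocorrelations by direct lagged products.
oracle_acf_sum <- function(x, max_lag) {
  xc <- x - mean(x)
  denom <- sum(xc^2)
  s <- 0
  for (k in seq_len(max_lag))
    s <- s + sum(xc[1:(length(x) - k)] * xc[(k + 1):length(x)]) / denom
  s
}

# AUC by exhaustive concordance pair counting (ties count 1/2).
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# OLS slope via lm(), per minute.
oracle_slope <- function(time_s, values) {
  unname(stats::coef(stats::lm(values ~ I(time_s / 60)))[2])
}
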