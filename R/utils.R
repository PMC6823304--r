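# Internal helpers shared across modules.

CHANNELS <- c("hr", "rr", "spo2", "abpsys", "abpdias", "abpmean")
SPECTRAL_CHANNELS <- c("hr", "rr", "spo2")

#' Run code with a private, reproducible RNG state
#'
#' Seeds the RNG, runs `expr`, and restores whatever RNG state the caller
#' had, so package functions never perturb user-level random streams.
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.null(old <- get0(".Random.seed", envir = globalenv()))) {
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# Deterministic per-unit seed stream; kept below 2^31.
derive_seed <- function(seed, index) {
  (as.numeric(seed) * 1009 + as.numeric(index) * 7919) %% 2147483647
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Subtract closed intervals `cut` (2-col matrix start,end) from [lo, hi].
# Returns a 2-col matrix of the remaining (possibly empty) intervals.
subtract_intervals <- function(lo, hi, cut) {
  segs <- matrix(c(lo, hi), ncol = 2)
  if (is.null(cut) || nrow(cut) == 0) return(segs)
  cut <- cut[order(cut[, 1]), , drop = FALSE]
  out <- matrix(numeric(0), ncol = 2)
  for (k in seq_len(nrow(cut))) {
    nxt <- matrix(numeric(0), ncol = 2)
    for (i in seq_len(nrow(segs))) {
      a <- segs[i, 1]; b <- segs[i, 2]
      cs <- cut[k, 1]; ce <- cut[k, 2]
      if (ce < a || cs > b) {
        nxt <- rbind(nxt, c(a, b))
      } else {
        if (cs > a) nxt <- rbind(nxt, c(a, cs))
        if (ce < b) nxt <- rbind(nxt, c(ce, b))
      }
    }
    segs <- nxt
    if (nrow(segs) == 0) break
  }
  segs
}
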