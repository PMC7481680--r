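# Naive per-window, per-lag Pearson recomputation of the windowed
# cross-correlation, used as an independent oracle.
naive_wcc <- function(x, y, p) {
  n <- length(x); lags <- -p$max_lag:p$max_lag
  starts <- seq.int(1L, n - p$window + 1L, by = p$step)
  out <- matrix(NA_real_, length(starts), length(lags),
                dimnames = list(NULL, as.character(lags)))
  for (si in seq_along(starts)) {
    for (li in seq_along(lags)) {
      l <- lags[li]; s <- starts[si]; m <- p$window - abs(l)
      if (l >= 0) {
        u <- x[s:(s + m - 1)]; v <- y[(s + l):(s + l + m - 1)]
      } else {
        u <- x[(s - l):(s - l + m - 1)]; v <- y[s:(s + m - 1)]
      }
      if (anyNA(u) || anyNA(v) || sd(u) < 1e-8 || sd(v) < 1e-8) next
      out[si, li] <- cor(u, v)
    }
  }
  out
}
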