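# Vectorized one-way repeated-measures ANOVA over many cells.
#
# y: n_subjects x k_conditions x n_cells array. Returns per-cell F and p for
# the condition main effect with df (k - 1, (n - 1)(k - 1)). This is the
# classical subject-by-condition decomposition; stats::aov with an
# Error(subject) stratum is the reference implementation it is checked
# against in the tests (a closed form is used because heatmaps have tens of
# thousands of cells).
rm_anova_cells <- function(y) {
  stopifnot(length(dim(y)) == 3L)
  n <- dim(y)[1]; k <- dim(y)[2]; nc <- dim(y)[3]
  if (n < 2L || k < 2L) stop("need >= 2 subjects and >= 2 conditions")
  ym <- matrix(y, n * k, nc)                      # rows vary subject fastest
  subj <- rep(seq_len(n), times = k)
  cond <- rep(seq_len(k), each = n)
  grand <- colMeans(ym)
  sm <- rowsum(ym, subj) / k                      # n x nc subject means
  cm <- rowsum(ym, cond) / n                      # k x nc condition means
  ss_cond <- n * colSums(sweep(cm, 2, grand)^2)
  resid <- ym - sm[subj, , drop = FALSE] - cm[cond, , drop = FALSE] +
    matrix(grand, n * k, nc, byrow = TRUE)
  ss_err <- colSums(resid^2)
  df1 <- k - 1; df2 <- (n - 1) * (k - 1)
  fstat <- (ss_cond / df1) / (ss_err / df2)
  fstat[ss_err < 1e-300 & ss_cond < 1e-300] <- NaN
  p <- pf(fstat, df1, df2, lower.tail = FALSE)
  list(F = fstat, p = p, df1 = df1, df2 = df2)
}

# Vectorized paired t-test over many cells. a, b: n x n_cells matrices.
paired_t_cells <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  n <- nrow(a)
  d <- a - b
  m <- colMeans(d)
  s <- sqrt(colSums(sweep(d, 2, m)^2) / (n - 1))
  tstat <- m / (s / sqrt(n))
  p <- 2 * pt(abs(tstat), df = n - 1, lower.tail = FALSE)
  list(t = tstat, p = p, df = n - 1)
}

# One- or two-tailed p-value for a Pearson correlation.
cor_p_value <- function(r, n, tails = c("two", "one"),
                        direction = c("auto", "positive", "negative")) {
  tails <- match.arg(tails)
  direction <- match.arg(direction)
  df <- n - 2
  tstat <- r * sqrt(df / (1 - r^2))
  if (tails == "two") {
    2 * pt(abs(tstat), df, lower.tail = FALSE)
  } else {
    signed <- switch(direction,
                     auto = abs(tstat),
                     positive = tstat,
                     negative = -tstat)
    pt(signed, df, lower.tail = FALSE)
  }
}
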