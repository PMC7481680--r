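#' Partner agreement on subjective scores
#'
#' Pearson correlation, across dyads, between the two partners' scores on
#' each questionnaire scale (two-tailed).
#'
#' @param scores_1,scores_2 data.frames of per-participant scores with one
#'   row per dyad (partner 1 and partner 2), sharing score columns.
#' @param columns score columns to test (default: the standard set).
#' @return data.frame with `score`, `r`, `p`, `n`; scales with zero
#'   variance in either partner are flagged `NA` with a message.
#' @export
partner_agreement <- function(scores_1, scores_2, columns = SCORE_COLS) {
  stopifnot(nrow(scores_1) == nrow(scores_2))
  out <- lapply(columns, function(col) {
    x <- scores_1[[col]]; y <- scores_2[[col]]
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 4L || sd(x[ok]) < 1e-12 || sd(y[ok]) < 1e-12) {
      message("partner agreement undefined for '", col, "'")
      return(data.frame(score = col, r = NA_real_, p = NA_real_,
                        n = sum(ok)))
    }
    ct <- cor.test(x[ok], y[ok])
    data.frame(score = col, r = unname(ct$estimate), p = ct$p.value,
               n = sum(ok))
  })
  do.call(rbind, out)
}

#' Correlate a behavioural summary with a subjective score
#'
#' Pearson correlation across dyads with a configurable tail policy and
#' optional Bonferroni correction by the number of scores tested.
#'
#' @param behaviour,score numeric vectors (one value per dyad); incomplete
#'   dyads are dropped pairwise.
#' @param tails `"two"` or `"one"`.
#' @param direction for one-tailed tests: `"positive"`/`"negative"` for a
#'   directional hypothesis, `"auto"` to test the observed direction.
#' @param bonferroni_m number of comparisons for the adjusted p (default 1
#'   = no correction).
#' @param alpha significance level (default 0.05).
#' @return one-row data.frame with `r`, `p`, `p_adj`, `n`, `significant`.
#' @export
correlate_behaviour_scores <- function(behaviour, score,
                                       tails = c("two", "one"),
                                       direction = c("auto", "positive",
                                                     "negative"),
                                       bonferroni_m = 1, alpha = 0.05) {
  tails <- match.arg(tails)
  direction <- match.arg(direction)
  ok <- !is.na(behaviour) & !is.na(score)
  if (sum(ok) < 4L) stop("need >= 4 complete dyads")
  x <- behaviour[ok]; y <- score[ok]
  if (sd(x) < 1e-12 || sd(y) < 1e-12) {
    message("correlation undefined: constant column")
    return(data.frame(r = NA_real_, p = NA_real_, p_adj = NA_real_,
                      n = sum(ok), significant = NA))
  }
  r <- cor(x, y)
  p <- cor_p_value(r, sum(ok), tails, direction)
  p_adj <- min(1, bonferroni_m * p)
  data.frame(r = r, p = p, p_adj = p_adj, n = sum(ok),
             significant = p_adj < alpha)
}

#' Flag outlier dyads by a standard-deviation rule
#'
#' @param x numeric vector.
#' @param threshold_sd number of standard deviations from the mean beyond
#'   which a value is an outlier (default 3).
#' @return logical vector (`NA` stays `NA`-safe: missing values are never
#'   flagged).
#' @export
outlier_flags <- function(x, threshold_sd = 3) {
  if (threshold_sd <= 0) stop("threshold must be positive")
  z <- (x - mean(x, na.rm = TRUE)) / sd(x, na.rm = TRUE)
  out <- abs(z) > threshold_sd
  out[is.na(out)] <- FALSE
  out
}

#' Outlier-controlled partial correlation
#'
#' Partial Pearson correlation of a behaviour and a score controlling for a
#' binary outlier indicator built from an SD rule on a named control
#' variable; keeps every dyad in the analysis (an exclusion mode is also
#' available). When the rule flags no dyads the result equals the simple
#' correlation and is flagged as a pass-through.
#'
#' @param behaviour,score numeric vectors per dyad.
#' @param control variable the outlier rule applies to.
#' @param threshold_sd SD threshold (default 3).
#' @param mode `"indicator"` (partial correlation on an indicator
#'   covariate) or `"exclude"` (drop the flagged dyads).
#' @param tails,direction tail policy as in
#'   [correlate_behaviour_scores()].
#' @return one-row data.frame with `r`, `p`, `n`, `n_outliers`,
#'   `pass_through`.
#' @export
partial_correlation_outlier_control <- function(behaviour, score, control,
                                                threshold_sd = 3,
                                                mode = c("indicator",
                                                         "exclude"),
                                                tails = c("two", "one"),
                                                direction = c("auto",
                                                              "positive",
                                                              "negative")) {
  mode <- match.arg(mode)
  tails <- match.arg(tails)
  direction <- match.arg(direction)
  ok <- !is.na(behaviour) & !is.na(score) & !is.na(control)
  x <- behaviour[ok]; y <- score[ok]
  flags <- outlier_flags(control[ok], threshold_sd)
  n_out <- sum(flags)
  if (mode == "exclude" && n_out > 0) {
    keep <- !flags
    r <- cor(x[keep], y[keep])
    p <- cor_p_value(r, sum(keep), tails, direction)
    return(data.frame(r = r, p = p, n = sum(keep), n_outliers = n_out,
                      pass_through = FALSE))
  }
  if (n_out == 0 || sd(as.numeric(flags)) < 1e-12) {
    r <- cor(x, y)
    p <- cor_p_value(r, length(x), tails, direction)
    return(data.frame(r = r, p = p, n = length(x), n_outliers = n_out,
                      pass_through = TRUE))
  }
  z <- as.numeric(flags)
  rxy <- cor(x, y); rxz <- cor(x, z); ryz <- cor(y, z)
  r <- (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
  n <- length(x)
  df <- n - 3
  tstat <- r * sqrt(df / (1 - r^2))
  p <- if (tails == "two") {
    2 * pt(abs(tstat), df, lower.tail = FALSE)
  } else {
    signed <- switch(direction, auto = abs(tstat), positive = tstat,
                     negative = -tstat)
    pt(signed, df, lower.tail = FALSE)
  }
  data.frame(r = r, p = p, n = n, n_outliers = n_out, pass_through = FALSE)
}

#' Permutation check of a parametric test
#'
#' Recomputes a test's p-value from a permutation null: sign flips of the
#' paired differences for a paired t statistic, or shuffles of one variable
#' for a correlation, with add-one smoothing
#' `p = (1 + #(|T*| >= |T|)) / (n_perm + 1)`.
#'
#' @param x,y paired samples (paired t) or the two correlated variables.
#' @param statistic `"paired_t"` or `"correlation"`.
#' @param n_perm number of permutations (default 1000; < 100 warns).
#' @param seed RNG seed.
#' @return list with `observed` statistic, `p_permutation`, `p_parametric`
#'   and `n_perm`.
#' @export
permutation_check <- function(x, y, statistic = c("paired_t", "correlation"),
                              n_perm = 1000, seed = 1) {
  statistic <- match.arg(statistic)
  if (n_perm < 100) warning("fewer than 100 permutations is unreliable")
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  set.seed(seed)
  if (statistic == "paired_t") {
    d <- x - y
    tobs <- mean(d) / (sd(d) / sqrt(n))
    null <- vapply(seq_len(n_perm), function(i) {
      ds <- d * sample(c(-1, 1), n, replace = TRUE)
      mean(ds) / (sd(ds) / sqrt(n))
    }, numeric(1))
    p_param <- 2 * pt(abs(tobs), n - 1, lower.tail = FALSE)
    obs <- tobs
  } else {
    obs <- cor(x, y)
    null <- vapply(seq_len(n_perm), function(i) cor(x, sample(y)),
                   numeric(1))
    p_param <- cor_p_value(obs, n, "two")
  }
  p_perm <- (1 + sum(abs(null) >= abs(obs))) / (n_perm + 1)
  list(observed = obs, p_permutation = p_perm, p_parametric = p_param,
       n_perm = n_perm)
}

#' Per-cell correlation of orientation heatmaps with a score
#'
#' Correlates, for every heatmap cell, the per-dyad % time with the
#' dyad-mean score, with a Bonferroni-by-scores significance mask.
#'
#' @param histograms list of (smoothed) `orientation_histogram`s, one per
#'   dyad.
#' @param score numeric vector, one dyad-mean value per dyad.
#' @param bonferroni_m number of scores tested (default 1).
#' @param tails,direction tail policy (one-tailed directional by default
#'   policy of the caller; defaults here are two-tailed).
#' @param alpha significance level.
#' @return list with matrices `r`, `p`, `sig` (Bonferroni-masked) and the
#'   sample size `n`; a constant score yields an error.
#' @export
orientation_duration_score_map <- function(histograms, score,
                                           bonferroni_m = 1,
                                           tails = c("two", "one"),
                                           direction = c("auto", "positive",
                                                         "negative"),
                                           alpha = 0.05) {
  tails <- match.arg(tails)
  direction <- match.arg(direction)
  ok <- !is.na(score)
  if (sum(ok) < 4L) stop("need >= 4 dyads with scores")
  if (sd(score[ok]) < 1e-12) stop("constant score: correlation map undefined")
  histograms <- histograms[ok]
  score <- score[ok]
  dims <- dim(histograms[[1]])
  ymat <- vapply(histograms, as.numeric, numeric(prod(dims)))  # cells x dyads
  n <- length(score)
  sc <- scale(score)[, 1]
  ys <- (ymat - rowMeans(ymat)) / apply(ymat, 1, sd)
  r <- as.numeric(ys %*% sc) / (n - 1)
  r[!is.finite(r)] <- NA_real_
  p <- cor_p_value(r, n, tails, direction)
  rmat <- matrix(r, dims[1], dims[2])
  pmat <- matrix(p, dims[1], dims[2])
  padj <- pmin(1, bonferroni_m * pmat)
  list(r = rmat, p = pmat, sig = padj < alpha & !is.na(padj), n = n)
}
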