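records_fixture <- function(n = 6) {
  truth <- data.frame(time_s = rep(seq_len(n), each = 2),
                      participant = rep(c("p1", "p2"), n),
                      looks_partner = rep(c(TRUE, FALSE), n),
                      looks_target = rep(c(FALSE, TRUE), n))
  truth
}

test_that("merge_annotations: agreement stands, third rater breaks ties", {
  truth <- records_fixture()
  rec <- simulate_annotation_panel(truth, error_rates = c(0, 0, 0))
  m <- merge_annotations(rec)
  expect_equal(m$looks_partner, truth$looks_partner)
  expect_equal(m$looks_target, truth$looks_target)
  # plant one disagreement; r3 must decide it
  rec2 <- rec
  i <- which(rec2$rater == "r1")[1]
  rec2$looks_partner[i] <- !rec2$looks_partner[i]
  m2 <- merge_annotations(rec2)
  r3val <- rec2$looks_partner[rec2$rater == "r3"][1]
  expect_equal(m2$looks_partner[1], r3val)
  # only the disagreeing question is re-decided
  expect_equal(m2$looks_target, truth$looks_target)
})

test_that("disagreement without a third rater is an unresolved-sample error", {
  truth <- records_fixture()
  rec <- simulate_annotation_panel(truth, error_rates = c(0, 0))
  i <- which(rec$rater == "r2")[3]
  rec$looks_target[i] <- !rec$looks_target[i]
  expect_error(merge_annotations(rec), "unresolved-sample")
  expect_error(merge_annotations(rec[rec$rater == "r1", ]), "two raters")
})

test_that("dyadic_gaze_label covers the category table with precedence", {
  expect_equal(as.character(dyadic_gaze_label(TRUE, FALSE, TRUE, FALSE)),
               "eye_contact")
  expect_equal(as.character(dyadic_gaze_label(FALSE, TRUE, FALSE, TRUE)),
               "joint_attention")
  expect_equal(as.character(dyadic_gaze_label(TRUE, FALSE, FALSE, TRUE)),
               "other_oriented")
  expect_equal(as.character(dyadic_gaze_label(FALSE, TRUE, TRUE, FALSE)),
               "other_oriented")
  expect_equal(as.character(dyadic_gaze_label(FALSE, FALSE, TRUE, FALSE)),
               "away")
  # partner-looking precedence when both booleans are set
  expect_equal(as.character(dyadic_gaze_label(TRUE, TRUE, TRUE, TRUE)),
               "eye_contact")
})

test_that("naive Bayes matches a hand-computed two-class oracle", {
  # 1D, two classes with known Gaussians; posterior computable by hand
  x <- matrix(c(-1.2, -0.8, -1.0, 0.8, 1.2, 1.0), ncol = 1)
  y <- c("a", "a", "a", "b", "b", "b")
  m <- train_gaze_classifier(x, y, seed = 1)
  # standardization: center/scale from the (full, already balanced) sample
  xs <- (x - mean(x)) / sd(x)
  mu_a <- mean(xs[1:3]); mu_b <- mean(xs[4:6])
  v_a <- var(xs[1:3]); v_b <- var(xs[4:6])
  newx <- matrix(c(-0.9, 0.95), ncol = 1)
  news <- (newx - mean(x)) / sd(x)
  ll <- function(z, mu, v) -0.5 * ((z - mu)^2 / v + log(2 * pi * v))
  post_a <- exp(ll(news, mu_a, v_a)) /
    (exp(ll(news, mu_a, v_a)) + exp(ll(news, mu_b, v_b)))
  po <- predict(m, newx, type = "posterior")
  expect_equal(po[, "a"], as.numeric(post_a), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(as.character(predict(m, newx)), c("a", "b"))
})

test_that("naive Bayes agrees with e1071::naiveBayes on balanced data", {
  set.seed(40)
  n <- 120
  X <- rbind(matrix(rnorm(2 * n, 0), n, 2), matrix(rnorm(2 * n, 2), n, 2))
  y <- rep(c("a", "b"), each = n)
  m <- train_gaze_classifier(X, y, seed = 1)
  ref <- e1071::naiveBayes(x = as.data.frame(X), y = factor(y))
  Xt <- matrix(rnorm(100, 1), 50, 2)
  # balanced subsample is the full sample here, so decisions should agree
  # away from the boundary; compare posteriors directly
  po <- predict(m, Xt, type = "posterior")
  pr <- predict(ref, as.data.frame(Xt), type = "raw")
  expect_gt(cor(po[, "a"], pr[, "a"]), 0.999)
  expect_equal(as.character(predict(m, Xt)),
               as.character(predict(ref, as.data.frame(Xt))))
})

test_that("training is balanced and the variance floor engages", {
  set.seed(41)
  X <- cbind(c(rnorm(50), rnorm(5, 4)), 1)   # constant second feature
  y <- c(rep("a", 50), rep("b", 5))
  m <- train_gaze_classifier(X, y)
  expect_equal(m$n_per_class, 5L)
  expect_true(all(m$vars >= m$variance_floor))
  expect_equal(unname(m$priors), rep(0.5, 2))
  expect_error(train_gaze_classifier(X, c(rep("a", 54), "b")), "< 2 samples")
  expect_error(predict(m, X[, 1, drop = FALSE]), "feature-set mismatch")
})

test_that("random-split CV reports mean class accuracy, not pooled", {
  set.seed(42)
  # class b tiny but perfectly separable; class c big and random vs a
  X <- rbind(matrix(rnorm(200), 100, 2),
             matrix(rnorm(20, 10), 10, 2),
             matrix(rnorm(200), 100, 2))
  y <- rep(c("a", "b", "c"), c(100, 10, 100))
  cv <- crossvalidate_random_split(X, y, iterations = 10, seed = 1)
  # pooled accuracy would hide b; mean class accuracy includes it at ~1
  expect_gt(cv$class_accuracy["b"], 0.95)
  expect_equal(cv$mean_class_accuracy, mean(cv$class_accuracy),
               tolerance = 1e-12)
  expect_equal(dim(cv$per_iteration), c(10L, 3L))
})

test_that("leave-one-dyad-out CV holds out whole dyads", {
  set.seed(43)
  nd <- 4
  X <- NULL; y <- NULL; dy <- NULL
  for (d in seq_len(nd)) {
    X <- rbind(X, matrix(rnorm(120, 0), 60, 2),
               matrix(rnorm(120, 3), 60, 2))
    y <- c(y, rep(c("a", "b"), each = 60))
    dy <- c(dy, rep(paste0("d", d), 120))
  }
  cv <- crossvalidate_leave_one_dyad_out(X, y, dy)
  expect_equal(nrow(cv$per_dyad), nd)
  expect_gt(cv$mean_class_accuracy, 0.9)
  expect_error(crossvalidate_leave_one_dyad_out(X, y, rep("d1", length(y))),
               ">= 3 dyads")
})

test_that("predict_prevalence rows sum to 100 over requested conditions", {
  gen <- small_dyad(seed = 5)
  s <- gen$session
  u1 <- resample_uniform(s$streams$p1$k2)
  u2 <- resample_uniform(s$streams$p2$k2)
  gf <- gaze_features(u1, u2)
  st <- gen$truth$states
  idx <- vapply(gf$t, function(t) which.min(abs(st$t - t)), integer(1))
  y <- dyadic_gaze_label(st$p1_partner[idx], st$p1_target[idx],
                         st$p2_partner[idx], st$p2_target[idx])
  keep <- gf$valid & !is.na(y)
  m <- train_gaze_classifier(gf$features[keep, ], y[keep], seed = 1)
  prev <- predict_prevalence(m, gf, s$annotations)
  expect_false("pause" %in% rownames(prev))
  expect_equal(unname(rowSums(prev)), rep(100, nrow(prev)), tolerance = 1e-9)
})

test_that("confusion-adjusted prevalence inverts a known leak exactly", {
  # two classes, b systematically leaks 20% into a; adjustment undoes it
  set.seed(45)
  n <- 4000
  y <- rep(c("a", "b"), c(n * 0.3, n * 0.7))
  pred <- y
  leak <- which(y == "b")[seq_len(0.2 * n * 0.7)]
  pred[leak] <- "a"
  X <- cbind(ifelse(y == "a", -1, 1) + rnorm(n, 0, 0.1))
  m <- train_gaze_classifier(X, y, seed = 1)
  C <- rbind(a = c(1, 0), b = c(0.2, 0.8))
  # hand-check the linear system on the observed proportions
  p_obs <- as.numeric(table(factor(pred, levels = c("a", "b")))) / n
  p_true <- solve(t(C), p_obs)
  expect_equal(unname(p_true), c(0.3, 0.7), tolerance = 1e-9)
  # and through the exported interface
  ann <- trial_annotations(1, "conversation", 0, n)
  gf_like <- list(features = X, t = seq_len(n) - 0.5, valid = rep(TRUE, n))
  raw <- predict_prevalence(m, gf_like, ann)
  adj <- predict_prevalence(m, gf_like, ann, confusion = diag(2))
  expect_equal(raw, adj, tolerance = 1e-9)   # identity confusion: no change
})

test_that("feature-set ladder widths are cumulative", {
  gen <- small_dyad(seed = 6)
  u1 <- resample_uniform(gen$session$streams$p1$k2)
  u2 <- resample_uniform(gen$session$streams$p2$k2)
  widths <- vapply(c("yaw", "yaw_pitch", "yaw_pitch_location",
                     "yaw_pitch_location_vector"),
                   function(fs) ncol(gaze_features(u1, u2, fs)$features),
                   integer(1))
  expect_equal(unname(widths), c(2L, 4L, 10L, 16L))
})

test_that("accuracy_null_band centres on chance for shuffled labels", {
  set.seed(44)
  labels <- sample(GAZE_LEVELS, 4000, replace = TRUE)
  pred <- sample(GAZE_LEVELS, 4000, replace = TRUE)
  nb <- accuracy_null_band(pred, labels, n_perm = 200, seed = 1)
  expect_lt(abs(nb$quantiles[["50%"]] - 0.25), 0.02)
  expect_gt(nb$quantiles[["97.5%"]], nb$quantiles[["2.5%"]])
})
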