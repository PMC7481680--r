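#' Merge two (plus tie-break) raters' gaze annotations
#'
#' Annotation records answer, per time point and participant, two binary
#' questions: is this participant looking at their partner, and at the
#' shared target. Where the first two raters agree, their value stands;
#' where they disagree on a question, the third rater breaks the tie and
#' the majority (two-thirds) vote is taken — only for the disagreeing
#' questions.
#'
#' @param records data.frame with columns `time_s`, `rater`, `participant`,
#'   `looks_partner`, `looks_target` (logical/0-1). Raters are the sorted
#'   unique values of `rater`: the first two are the primary raters, an
#'   optional third the tie-breaker.
#' @return data.frame with one row per `time_s` x `participant` and
#'   consensus columns `looks_partner`, `looks_target`.
#' @export
merge_annotations <- function(records) {
  need <- c("time_s", "rater", "participant", "looks_partner", "looks_target")
  stopifnot(all(need %in% names(records)))
  raters <- sort(unique(records$rater))
  if (length(raters) < 2L) stop("need at least two raters")
  key <- function(df) paste(df$time_s, df$participant, sep = "\r")
  pick <- function(r) {
    sub <- records[records$rater == r, ]
    sub[order(sub$time_s, sub$participant), ]
  }
  r1 <- pick(raters[1]); r2 <- pick(raters[2])
  if (!identical(key(r1), key(r2))) {
    stop("raters 1 and 2 are not aligned on the same time points")
  }
  out <- r1[c("time_s", "participant")]
  r3 <- if (length(raters) >= 3L) pick(raters[3]) else NULL
  for (q in c("looks_partner", "looks_target")) {
    v1 <- as.logical(r1[[q]]); v2 <- as.logical(r2[[q]])
    cons <- v1
    dis <- which(v1 != v2)
    if (length(dis)) {
      if (is.null(r3)) {
        stop("unresolved-sample error: rater disagreement without a third ",
             "rater at time(s) ",
             paste(unique(r1$time_s[dis]), collapse = ", "))
      }
      m3 <- match(key(r1[dis, ]), key(r3))
      if (anyNA(m3)) {
        stop("unresolved-sample error: third rater missing time(s) ",
             paste(unique(r1$time_s[dis][is.na(m3)]), collapse = ", "))
      }
      v3 <- as.logical(r3[[q]][m3])
      # with v1 != v2 the third rater is the majority
      cons[dis] <- v3
    }
    out[[q]] <- cons
  }
  rownames(out) <- NULL
  out
}

#' Dyadic gaze category from consensus looking booleans
#'
#' Categories: *eye contact* (both look at the partner), *joint attention*
#' (both at the target), *other-oriented* (one at the partner, the other at
#' the target), *away* (someone looks at neither). Partner-looking takes
#' precedence over target-looking when an annotation marks both true for
#' one participant.
#'
#' @param p1_partner,p1_target,p2_partner,p2_target logical vectors.
#' @return factor with levels eye_contact, joint_attention, other_oriented,
#'   away.
#' @export
dyadic_gaze_label <- function(p1_partner, p1_target, p2_partner, p2_target) {
  look <- function(pa, ta) ifelse(pa, "partner", ifelse(ta, "target", "none"))
  l1 <- look(as.logical(p1_partner), as.logical(p1_target))
  l2 <- look(as.logical(p2_partner), as.logical(p2_target))
  lab <- ifelse(l1 == "partner" & l2 == "partner", "eye_contact",
         ifelse(l1 == "target" & l2 == "target", "joint_attention",
         ifelse((l1 == "partner" & l2 == "target") |
                (l1 == "target" & l2 == "partner"), "other_oriented",
                "away")))
  factor(lab, levels = GAZE_LEVELS)
}

#' Head-pose feature matrix for gaze classification
#'
#' Builds the per-sample dyadic feature vector from the two participants'
#' preprocessed streams: relational yaw (degrees), optionally head pitch,
#' head location (3D, m) and the full gaze unit vector, concatenated over
#' both participants. Feature sets form the cumulative ladder
#' yaw < yaw+pitch < +location < +vector.
#'
#' @param stream_1,stream_2 `uniform_stream`s in a common frame/grid.
#' @param feature_set one of `"yaw"`, `"yaw_pitch"`, `"yaw_pitch_location"`,
#'   `"yaw_pitch_location_vector"` (default: full ladder top).
#' @return list with `features` (matrix), `t`, `valid`, and the
#'   `feature_set` tag.
#' @export
gaze_features <- function(stream_1, stream_2,
                          feature_set = c("yaw_pitch_location_vector",
                                          "yaw", "yaw_pitch",
                                          "yaw_pitch_location")) {
  feature_set <- match.arg(feature_set)
  h1 <- stream_1$joints[["head"]]; h2 <- stream_2$joints[["head"]]
  g1 <- gaze_vector(stream_1$orient[, 1], stream_1$orient[, 2])
  g2 <- gaze_vector(stream_2$orient[, 1], stream_2$orient[, 2])
  feats <- cbind(ryaw_1 = relative_yaw(g1, h1, h2),
                 ryaw_2 = relative_yaw(g2, h2, h1))
  if (feature_set != "yaw") {
    feats <- cbind(feats, pitch_1 = stream_1$orient[, 2],
                   pitch_2 = stream_2$orient[, 2])
  }
  if (feature_set %in% c("yaw_pitch_location", "yaw_pitch_location_vector")) {
    loc <- cbind(h1, h2)
    colnames(loc) <- c(paste0("loc1_", c("x", "y", "z")),
                       paste0("loc2_", c("x", "y", "z")))
    feats <- cbind(feats, loc)
  }
  if (feature_set == "yaw_pitch_location_vector") {
    gv <- cbind(g1, g2)
    colnames(gv) <- c(paste0("gv1_", c("x", "y", "z")),
                      paste0("gv2_", c("x", "y", "z")))
    feats <- cbind(feats, gv)
  }
  valid <- stats::complete.cases(feats)
  list(features = feats, t = stream_1$t, valid = valid,
       feature_set = feature_set)
}

#' Train the Gaussian naive-Bayes gaze classifier
#'
#' Fits per-class Gaussian feature statistics on a random balanced
#' subsample (per-class n = size of the smallest class, sampled without
#' replacement) with uniform class priors. Features are standardized by the
#' subsample's mean and standard deviation, and class variances are floored
#' (in standardized units) so degenerate constant features cannot produce
#' infinite likelihoods.
#'
#' @param features n x p numeric matrix.
#' @param labels gaze category per row (factor or character; all four
#'   classes must be present with >= 2 samples each).
#' @param seed RNG seed for the balanced subsample.
#' @param variance_floor minimum per-class feature variance in standardized
#'   units (default 1e-6).
#' @return object of class `gaze_classifier`.
#' @export
train_gaze_classifier <- function(features, labels, seed = 1,
                                  variance_floor = 1e-6) {
  features <- as.matrix(features)
  lv <- unique(as.character(labels))
  lv <- if (all(lv %in% GAZE_LEVELS)) intersect(GAZE_LEVELS, lv) else sort(lv)
  labels <- factor(labels, levels = lv)
  counts <- table(labels)
  if (any(counts < 2L)) {
    stop("training error: class(es) with < 2 samples: ",
         paste(names(counts)[counts < 2], collapse = ", "))
  }
  set.seed(seed)
  n_bal <- min(counts)
  keep <- unlist(lapply(levels(labels), function(cl) {
    idx <- which(labels == cl)
    sample(idx, n_bal)
  }))
  x <- features[keep, , drop = FALSE]
  y <- labels[keep]
  center <- colMeans(x)
  scl <- apply(x, 2, sd)
  scl[scl < 1e-12] <- 1
  xs <- sweep(sweep(x, 2, center), 2, scl, "/")
  stat_by_class <- function(f) {
    m <- vapply(levels(y), function(cl) f(xs[y == cl, , drop = FALSE]),
                numeric(ncol(xs)))
    if (is.null(dim(m))) m <- matrix(m, nrow = 1)
    t(m)
  }
  means <- stat_by_class(colMeans)
  vars <- stat_by_class(function(z) apply(z, 2, var))
  rownames(means) <- rownames(vars) <- levels(y)
  vars[vars < variance_floor] <- variance_floor
  structure(list(classes = levels(labels), means = means, vars = vars,
                 priors = setNames(rep(1 / nlevels(y), nlevels(y)),
                                   levels(labels)),
                 center = center, scale = scl,
                 variance_floor = variance_floor,
                 n_per_class = n_bal,
                 feature_names = colnames(features)),
            class = "gaze_classifier")
}

#' Predict gaze categories with a trained classifier
#'
#' @param object a `gaze_classifier`.
#' @param newdata n x p feature matrix matching the training features.
#' @param type `"class"` for labels, `"posterior"` for the class posterior
#'   matrix.
#' @param ... unused.
#' @return factor of labels or posterior matrix. Ties go to the first class
#'   in the classifier's class order (deterministic).
#' @export
predict.gaze_classifier <- function(object, newdata,
                                    type = c("class", "posterior"), ...) {
  type <- match.arg(type)
  x <- as.matrix(newdata)
  if (ncol(x) != length(object$center)) {
    stop("contract error: feature-set mismatch between model and data (",
         ncol(x), " vs ", length(object$center), " features)")
  }
  xs <- sweep(sweep(x, 2, object$center), 2, object$scale, "/")
  k <- length(object$classes)
  ll <- matrix(NA_real_, nrow(x), k, dimnames = list(NULL, object$classes))
  for (j in seq_len(k)) {
    mu <- object$means[j, ]; v <- object$vars[j, ]
    ll[, j] <- log(object$priors[j]) -
      0.5 * rowSums(sweep(sweep(xs, 2, mu)^2, 2, v, "/") +
                    matrix(log(2 * pi * v), nrow(x), ncol(x), byrow = TRUE))
  }
  if (type == "posterior") {
    mx <- apply(ll, 1, max)
    po <- exp(ll - mx)
    return(po / rowSums(po))
  }
  factor(object$classes[max.col(ll, ties.method = "first")],
         levels = object$classes)
}

# Confusion matrix (rows = truth) and per-class accuracies.
confusion_stats <- function(truth, pred, classes = GAZE_LEVELS) {
  truth <- factor(truth, levels = classes)
  pred <- factor(pred, levels = classes)
  cm <- table(truth, pred)
  present <- rowSums(cm) > 0
  acc <- rep(NA_real_, length(classes))
  acc[present] <- diag(cm)[present] / rowSums(cm)[present]
  names(acc) <- classes
  rn <- cm / pmax(rowSums(cm), 1)
  list(confusion = cm, confusion_rownorm = rn, class_accuracy = acc,
       mean_class_accuracy = mean(acc, na.rm = TRUE))
}

#' Random-split cross-validation of the gaze classifier
#'
#' Repeated stratified half-splits of the pooled labelled samples: the
#' classifier is trained (balanced) on one half and tested on the other;
#' the per-class accuracies are averaged across iterations rather than
#' pooling an overall accuracy, so unbalanced categories do not inflate the
#' score.
#'
#' @param features n x p feature matrix.
#' @param labels gaze category per row.
#' @param iterations number of half-split iterations (default 50).
#' @param seed RNG seed.
#' @return list with `class_accuracy` (mean per class),
#'   `mean_class_accuracy`, per-iteration accuracies, and the mean
#'   row-normalized `confusion` matrix.
#' @export
crossvalidate_random_split <- function(features, labels, iterations = 50,
                                       seed = 1) {
  features <- as.matrix(features)
  lv <- unique(as.character(labels))
  lv <- if (all(lv %in% GAZE_LEVELS)) intersect(GAZE_LEVELS, lv) else sort(lv)
  labels <- factor(labels, levels = lv)
  counts <- table(labels)
  if (any(counts < 2L)) stop("class with < 2 samples")
  set.seed(seed)
  accs <- matrix(NA_real_, iterations, length(lv),
                 dimnames = list(NULL, lv))
  confs <- array(0, c(length(lv), length(lv), iterations),
                 dimnames = list(lv, lv, NULL))
  for (it in seq_len(iterations)) {
    train_idx <- unlist(lapply(levels(labels), function(cl) {
      idx <- which(labels == cl)
      sample(idx, floor(length(idx) / 2))
    }))
    test_idx <- setdiff(seq_along(labels), train_idx)
    model <- train_gaze_classifier(features[train_idx, , drop = FALSE],
                                   labels[train_idx],
                                   seed = sample.int(2^30, 1))
    pred <- predict(model, features[test_idx, , drop = FALSE])
    st <- confusion_stats(labels[test_idx], pred, classes = lv)
    accs[it, ] <- st$class_accuracy
    confs[, , it] <- st$confusion_rownorm
  }
  list(class_accuracy = colMeans(accs, na.rm = TRUE),
       mean_class_accuracy = mean(colMeans(accs, na.rm = TRUE), na.rm = TRUE),
       per_iteration = accs,
       confusion = apply(confs, c(1, 2), mean))
}

#' Leave-one-dyad-out cross-validation of the gaze classifier
#'
#' One fold per dyad: train (balanced) on all other dyads' samples, test on
#' the held-out dyad. Classes absent from a fold's test set are excluded
#' from that fold's mean.
#'
#' @param features n x p feature matrix.
#' @param labels gaze category per row.
#' @param dyad dyad id per row.
#' @param seed RNG seed.
#' @return list with `per_dyad` (fold x class accuracy matrix),
#'   `fold_means`, and the overall `mean_class_accuracy`.
#' @export
crossvalidate_leave_one_dyad_out <- function(features, labels, dyad,
                                             seed = 1) {
  features <- as.matrix(features)
  lv <- unique(as.character(labels))
  lv <- if (all(lv %in% GAZE_LEVELS)) intersect(GAZE_LEVELS, lv) else sort(lv)
  labels <- factor(labels, levels = lv)
  dyads <- unique(dyad)
  if (length(dyads) < 3L) stop("need >= 3 dyads for leave-one-dyad-out")
  set.seed(seed)
  accs <- matrix(NA_real_, length(dyads), length(lv),
                 dimnames = list(as.character(dyads), lv))
  for (i in seq_along(dyads)) {
    test <- dyad == dyads[i]
    if (!any(test)) {
      warning("dyad ", dyads[i], " has no labelled samples; fold skipped")
      next
    }
    model <- train_gaze_classifier(features[!test, , drop = FALSE],
                                   labels[!test], seed = sample.int(2^30, 1))
    pred <- predict(model, features[test, , drop = FALSE])
    accs[i, ] <- confusion_stats(labels[test], pred,
                                 classes = lv)$class_accuracy
  }
  fold_means <- rowMeans(accs, na.rm = TRUE)
  list(per_dyad = accs, fold_means = fold_means,
       mean_class_accuracy = mean(fold_means, na.rm = TRUE))
}

#' Predict gaze-category prevalence over a full session
#'
#' Applies a trained classifier to every valid sample and reports the
#' percentage of valid time spent in each gaze category per condition.
#'
#' @param model a `gaze_classifier`.
#' @param features result of [gaze_features()] on the preprocessed session.
#' @param annotations [trial_annotations()] delimiting the conditions;
#'   samples outside any trial are dropped.
#' @param conditions conditions to report (default: all annotated except
#'   pauses).
#' @param confusion optional row-normalized confusion matrix (truth rows x
#'   predicted columns, classes in the model's class order), e.g. the
#'   cross-validated `confusion` from [crossvalidate_random_split()]. When
#'   supplied, raw label counts are corrected for systematic
#'   misclassification by solving the classify-and-count system
#'   `t(C) p_true = p_observed` per condition (negative solutions are
#'   clipped and the row renormalized).
#' @return matrix (condition x gaze category) of percentages; each row sums
#'   to 100.
#' @export
predict_prevalence <- function(model, features, annotations,
                               conditions = NULL, confusion = NULL) {
  ok <- features$valid
  pred <- rep(NA_character_, length(ok))
  pred[ok] <- as.character(predict(model,
                                   features$features[ok, , drop = FALSE]))
  cond_of <- rep(NA_character_, length(ok))
  for (i in seq_len(nrow(annotations))) {
    sel <- features$t >= annotations$start_s[i] &
      features$t <= annotations$end_s[i]
    cond_of[sel] <- annotations$condition[i]
  }
  if (is.null(conditions)) {
    conditions <- setdiff(unique(annotations$condition), "pause")
  }
  out <- matrix(NA_real_, length(conditions), length(model$classes),
                dimnames = list(conditions, model$classes))
  if (!is.null(confusion)) {
    confusion <- as.matrix(confusion)
    k <- length(model$classes)
    stopifnot(all(dim(confusion) == c(k, k)))
  }
  for (cd in conditions) {
    sel <- !is.na(pred) & !is.na(cond_of) & cond_of == cd
    if (!any(sel)) next
    tab <- table(factor(pred[sel], levels = model$classes))
    p_obs <- as.numeric(tab) / sum(tab)
    if (!is.null(confusion)) {
      p_adj <- tryCatch(solve(t(confusion), p_obs),
                        error = function(e) p_obs)
      p_adj <- pmax(p_adj, 0)
      p_obs <- p_adj / sum(p_adj)
    }
    out[cd, ] <- 100 * p_obs
  }
  out
}

#' Permutation null band for mean class accuracy
#'
#' Shuffles the labels against fixed predictions to build the chance
#' distribution of the mean per-class accuracy.
#'
#' @param pred predicted labels.
#' @param labels true labels.
#' @param n_perm number of permutations (default 1000).
#' @param seed RNG seed.
#' @return list with the null `quantiles` (2.5, 50, 95, 97.5 percent), the
#'   null `max`, and the observed mean class accuracy.
#' @export
accuracy_null_band <- function(pred, labels, n_perm = 1000, seed = 1) {
  set.seed(seed)
  classes <- sort(unique(c(as.character(labels), as.character(pred))))
  if (all(classes %in% GAZE_LEVELS)) {
    classes <- intersect(GAZE_LEVELS, classes)
  }
  obs <- confusion_stats(labels, pred, classes)$mean_class_accuracy
  null <- vapply(seq_len(n_perm), function(i) {
    confusion_stats(sample(labels), pred, classes)$mean_class_accuracy
  }, numeric(1))
  list(observed = obs,
       quantiles = quantile(null, c(0.025, 0.5, 0.95, 0.975)),
       max = max(null))
}
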