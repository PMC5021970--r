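# Linear SVM scoring of the mitochondrial feature panel, repeated
# stratified cross-validation, and the two-threshold combined classifier.

#' Train a linear SVM on the mitochondrial features
#'
#' Linear soft-margin SVM in the nu parameterization: `nu` upper-bounds
#' the fraction of margin violators, so "assume 1% of outliers" maps to
#' nu = 0.01. Features are z-scored internally (the scaling is stored
#' and reapplied at prediction). Decision scores are oriented so that
#' higher means more patient-like.
#'
#' @param x Numeric matrix / data frame of features (by convention the 7
#'   mitochondrial features; other widths are accepted with
#'   `check_width = FALSE`).
#' @param labels Two-class vector.
#' @param positive Label of the positive (patient) class.
#' @param outlier_fraction Assumed outlier fraction (default 0.01).
#' @param check_width Error when ncol(x) != 7 (default TRUE).
#' @return Object of class `mito_svm` with the fitted model, scaling,
#'   orientation, and training `scores`.
#' @export
train_linear_svm <- function(x, labels, positive = "patient",
                             outlier_fraction = 0.01, check_width = TRUE) {
  x <- as.matrix(x)
  if (check_width && ncol(x) != 7L) {
    stop("expected the 7 mitochondrial features (use check_width = FALSE to override)")
  }
  labels <- as.character(labels)
  if (length(unique(labels)) != 2L) stop("labels must contain exactly 2 classes")
  if (!positive %in% labels) stop("positive class absent from labels")
  ctr <- colMeans(x)
  sds <- apply(x, 2, stats::sd)
  sds[sds == 0] <- 1
  z <- scale(x, center = ctr, scale = sds)
  y <- factor(labels)
  fit <- e1071::svm(z, y, type = "nu-classification", kernel = "linear",
                    nu = outlier_fraction, scale = FALSE)
  dec <- as.numeric(attr(stats::predict(fit, z, decision.values = TRUE),
                         "decision.values"))
  flip <- if (mean(dec[labels == positive]) >= mean(dec[labels != positive])) 1 else -1
  structure(list(fit = fit, center = ctr, scale = sds, flip = flip,
                 positive = positive, scores = flip * dec,
                 outlier_fraction = outlier_fraction),
            class = "mito_svm")
}

#' @describeIn train_linear_svm Decision scores for new data (higher =
#'   more patient-like).
#' @param object A `mito_svm`.
#' @param newdata Feature matrix with the training columns.
#' @param ... Unused.
#' @export
predict.mito_svm <- function(object, newdata, ...) {
  z <- scale(as.matrix(newdata), center = object$center, scale = object$scale)
  dec <- as.numeric(attr(stats::predict(object$fit, z, decision.values = TRUE),
                         "decision.values"))
  object$flip * dec
}

# Stratified k-fold assignment: within each class, a random permutation
# is dealt round-robin into k folds, so folds partition the data and
# every fold sees both classes whenever n >= k per class.
stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    if (length(idx) < k) stop("class '", cl, "' has fewer than k samples")
    fold[idx[sample.int(length(idx))]] <- rep(seq_len(k), length.out = length(idx))
  }
  fold
}

#' Repeated stratified cross-validated SVM AUC
#'
#' Runs `n_repeats` independent experiments of stratified k-fold
#' cross-validation with a linear SVM. In each repeat, every sample is
#' scored exactly once by a model trained without it (z-scoring uses
#' training-fold statistics only); the pooled test scores give one AUC
#' per repeat.
#'
#' @param x Feature matrix (samples x features).
#' @param labels Two-class vector.
#' @param positive Positive (patient) class label.
#' @param n_repeats Number of CV experiments (default 100).
#' @param k Folds (default 5).
#' @param outlier_fraction Passed to [train_linear_svm()].
#' @param seed Seed fixing all fold assignments.
#' @return Object of class `cv_result`: `auc` (per repeat), `mean_auc`,
#'   `scores` (n x n_repeats matrix of test-fold scores), `n_repeats`,
#'   `k`, `seed`.
#' @export
repeated_cv_auc <- function(x, labels, positive = "patient", n_repeats = 100L,
                            k = 5L, outlier_fraction = 0.01, seed = NULL) {
  x <- as.matrix(x)
  labels <- as.character(labels)
  n <- nrow(x)
  stopifnot(length(labels) == n)
  with_seed(seed, {
    aucs <- numeric(n_repeats)
    score_mat <- matrix(NA_real_, n, n_repeats)
    for (r in seq_len(n_repeats)) {
      fold <- stratified_folds(labels, k)
      sc <- numeric(n)
      for (f in seq_len(k)) {
        test <- fold == f
        m <- train_linear_svm(x[!test, , drop = FALSE], labels[!test],
                              positive = positive,
                              outlier_fraction = outlier_fraction,
                              check_width = FALSE)
        sc[test] <- predict(m, x[test, , drop = FALSE])
      }
      score_mat[, r] <- sc
      aucs[r] <- auc_fast(sc, labels == positive)
    }
    structure(list(auc = aucs, mean_auc = mean(aucs), scores = score_mat,
                   n_repeats = n_repeats, k = k, seed = seed),
              class = "cv_result")
  })
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("repeated CV: %d x %d-fold, mean AUC = %.3f (range %.3f-%.3f)\n",
              x$n_repeats, x$k, x$mean_auc, min(x$auc), max(x$auc)))
  invisible(x)
}

#' Two-threshold combined classifier
#'
#' Combines the mitochondrial SVM score with the ganglion volume using
#' two empirical quantile thresholds. The quantiles encode the prior
#' class mix (60% patients / 40% controls in the original design): the
#' score threshold is the `q_score` quantile of the scores, the volume
#' threshold the `q_volume` quantile of the volumes. A ganglion is
#' called a patient when its score is at or above the score threshold
#' AND (default) its ganglion volume is at or below the volume threshold
#' — patients have high scores and small ganglia. Quantiles use linear
#' interpolation between order statistics (type 7).
#'
#' @param svm_scores Numeric SVM decision scores (higher = patient-like).
#' @param ganglion_volumes Numeric ganglion volumes (um^3).
#' @param truth True class labels.
#' @param positive Positive (patient) label.
#' @param q_score Quantile for the score threshold (default 0.6).
#' @param q_volume Quantile for the volume threshold (default 0.4).
#' @param rule "AND" (default) or "OR".
#' @return List with `predictions` (logical, TRUE = patient),
#'   `score_threshold`, `volume_threshold`, and `confusion`
#'   (a [evaluate_confusion()] summary).
#' @export
combined_classify <- function(svm_scores, ganglion_volumes, truth,
                              positive = "patient", q_score = 0.6,
                              q_volume = 0.4, rule = c("AND", "OR")) {
  rule <- match.arg(rule)
  stopifnot(length(svm_scores) == length(ganglion_volumes),
            length(svm_scores) == length(truth),
            all(is.finite(svm_scores)), all(is.finite(ganglion_volumes)),
            q_score > 0, q_score < 1, q_volume > 0, q_volume < 1)
  if (length(unique(svm_scores)) == 1L) stop("degenerate input: all SVM scores equal")
  if (length(unique(ganglion_volumes)) == 1L) {
    stop("degenerate input: all ganglion volumes equal")
  }
  ts <- stats::quantile(svm_scores, q_score, type = 7, names = FALSE)
  tv <- stats::quantile(ganglion_volumes, q_volume, type = 7, names = FALSE)
  hit_score <- svm_scores >= ts
  hit_vol <- ganglion_volumes <= tv
  pred <- if (rule == "AND") hit_score & hit_vol else hit_score | hit_vol
  list(predictions = pred, score_threshold = ts, volume_threshold = tv,
       rule = rule,
       confusion = evaluate_confusion(pred, truth == positive))
}

#' Confusion summary
#'
#' Counts and rates: sensitivity = TP / (TP + FN) (true positive rate),
#' specificity = TN / (TN + FP) (one minus the false positive rate).
#'
#' @param predictions Logical vector (TRUE = predicted positive).
#' @param truth Logical vector (TRUE = actual positive).
#' @return List of class `confusion_summary`: `tp`, `fp`, `tn`, `fn`,
#'   `sensitivity`, `specificity`.
#' @export
evaluate_confusion <- function(predictions, truth) {
  stopifnot(length(predictions) == length(truth), length(truth) > 0L,
            is.logical(predictions), is.logical(truth))
  tp <- sum(predictions & truth)
  fp <- sum(predictions & !truth)
  tn <- sum(!predictions & !truth)
  fn <- sum(!predictions & truth)
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn,
                 sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
                 specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_),
            class = "confusion_summary")
}

#' @export
print.confusion_summary <- function(x, ...) {
  cat(sprintf("confusion: TP %d, FP %d, TN %d, FN %d | sensitivity %.3f, specificity %.3f\n",
              x$tp, x$fp, x$tn, x$fn, x$sensitivity, x$specificity))
  invisible(x)
}
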