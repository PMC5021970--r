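# Group-level statistics: permutation tests on the absolute mean
# difference, Spearman correlations with hierarchical clustering,
# ROC/AUC, and PCA.

#' Two-group permutation test on the absolute mean difference
#'
#' The observed statistic is |mean(x) - mean(y)|. Group labels are
#' randomly reshuffled (keeping the group sizes) `n_perm` times and the
#' statistic recomputed; the p-value uses the add-one estimator
#' p = (1 + #\{permuted >= observed\}) / (n_perm + 1), so it is never
#' exactly zero and is two-sided by construction.
#'
#' @param x,y Numeric vectors (>= 2 finite values each).
#' @param n_perm Number of shuffles (default 100000).
#' @param seed Optional seed for reproducibility.
#' @return List of class `permutation_result`: `observed`, `p_value`,
#'   `n_perm`, `seed`.
#' @export
permutation_test <- function(x, y, n_perm = 100000L, seed = NULL) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 2L || length(y) < 2L) stop("each group needs >= 2 values")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("non-finite values")
  nx <- length(x); ny <- length(y)
  pool <- c(x, y)
  tot <- sum(pool)
  obs <- abs(mean(x) - mean(y))
  eps <- 1e-12 * max(1, obs)
  count <- with_seed(seed, {
    hits <- 0L
    for (i in seq_len(n_perm)) {
      sx <- sum(pool[sample.int(nx + ny, nx)])
      stat <- abs(sx / nx - (tot - sx) / ny)
      if (stat >= obs - eps) hits <- hits + 1L
    }
    hits
  })
  structure(list(observed = obs, p_value = (1 + count) / (n_perm + 1),
                 n_perm = n_perm, seed = seed),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("permutation test: |mean difference| = %g, p = %g (%d shuffles)\n",
              x$observed, x$p_value, x$n_perm))
  invisible(x)
}

#' Spearman rank correlation
#'
#' Rank correlation with midrank ties; the two-sided p-value uses the
#' t approximation (appropriate in the presence of ties).
#'
#' @param x,y Equal-length numeric vectors (n >= 3).
#' @return List with `rho` and `p_value`.
#' @export
spearman_cor <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  if (stats::var(rank(x)) == 0 || stats::var(rank(y)) == 0) {
    stop("zero variance in ranks: Spearman correlation undefined")
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  list(rho = unname(ct$estimate), p_value = ct$p.value)
}

#' ROC curve and AUC
#'
#' Sweeps all unique score thresholds ("predict positive when score >=
#' threshold"), computes TPR/FPR, and integrates the curve by the
#' trapezoidal rule, which equals the fraction of positive/negative pairs
#' ordered correctly with ties counted one half. The p-value against
#' AUC = 0.5 comes from a label-permutation test (default) or the
#' Mann-Whitney normal approximation.
#'
#' @param scores Numeric scores (higher = more positive-like).
#' @param labels Vector of class labels; both classes must be present.
#' @param positive Value of `labels` denoting the positive class.
#' @param p_method "permutation" or "normal"; NULL skips the p-value.
#' @param n_perm Permutations for the p-value (default 10000).
#' @param seed Optional seed.
#' @return List of class `roc_result`: `thresholds`, `tpr`, `fpr`, `auc`,
#'   `p_value`.
#' @export
roc_auc <- function(scores, labels, positive, p_method = NULL,
                    n_perm = 10000L, seed = NULL) {
  stopifnot(length(scores) == length(labels))
  pos <- labels == positive
  if (!any(pos) || all(pos)) stop("both classes must be present")
  np <- sum(pos); nn <- sum(!pos)
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(scores[pos] >= t) / np, numeric(1))
  fpr <- vapply(thr, function(t) sum(scores[!pos] >= t) / nn, numeric(1))
  tpr <- c(0, tpr); fpr <- c(0, fpr)  # curve from (0,0) to (1,1)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  p <- NULL
  if (!is.null(p_method)) {
    p_method <- match.arg(p_method, c("permutation", "normal"))
    if (p_method == "permutation") {
      obs_dev <- abs(auc - 0.5)
      hits <- with_seed(seed, {
        h <- 0L
        for (i in seq_len(n_perm)) {
          perm_pos <- logical(length(scores))
          perm_pos[sample.int(length(scores), np)] <- TRUE
          a <- auc_fast(scores, perm_pos)
          if (abs(a - 0.5) >= obs_dev - 1e-12) h <- h + 1L
        }
        h
      })
      p <- (1 + hits) / (n_perm + 1)
    } else {
      # Mann-Whitney U normal approximation (two-sided)
      u <- auc * np * nn
      mu <- np * nn / 2
      sigma <- sqrt(np * nn * (np + nn + 1) / 12)
      p <- 2 * stats::pnorm(-abs(u - mu) / sigma)
    }
  }
  structure(list(thresholds = thr, tpr = tpr, fpr = fpr, auc = auc,
                 p_value = p),
            class = "roc_result")
}

# Rank-based AUC (identical to the trapezoidal value; used in permutation
# loops where building the full curve would be wasteful).
auc_fast <- function(scores, pos) {
  r <- rank(scores)
  np <- sum(pos); nn <- sum(!pos)
  (sum(r[pos]) - np * (np + 1) / 2) / (np * nn)
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.4f%s\n", x$auc,
              if (!is.null(x$p_value)) sprintf(", p vs 0.5 = %g", x$p_value) else ""))
  invisible(x)
}

#' @export
plot.roc_result <- function(x, ...) {
  graphics::plot(x$fpr, x$tpr, type = "l", xlim = c(0, 1), ylim = c(0, 1),
                 xlab = "False positive rate", ylab = "True positive rate", ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' PCA embedding of a feature matrix
#'
#' Features are z-scored before decomposition (they span orders of
#' magnitude and are analysed on log scales; an optional log10 transform
#' is applied first). Constant features are dropped with a warning.
#'
#' @param x Numeric matrix / data frame (samples x features), no NAs.
#' @param n_components Components to keep (default all).
#' @param log10_transform Apply log10 before z-scoring (default FALSE;
#'   requires strictly positive values).
#' @return List with `scores`, `loadings`, `variance_fraction`.
#' @export
pca_embed <- function(x, n_components = NULL, log10_transform = FALSE) {
  x <- as.matrix(x)
  stopifnot(nrow(x) >= 2L, ncol(x) >= 2L)
  if (anyNA(x)) stop("missing values: impute or drop before PCA")
  if (log10_transform) {
    if (any(x <= 0)) stop("log10 transform requires positive values")
    x <- log10(x)
  }
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    warning("dropping constant feature(s): ",
            paste(colnames(x)[sds == 0], collapse = ", "))
    x <- x[, sds > 0, drop = FALSE]
  }
  z <- scale(x)
  pc <- stats::prcomp(z, center = FALSE, scale. = FALSE)
  k <- min(n_components %||% ncol(z), ncol(pc$rotation))
  vf <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x[, seq_len(k), drop = FALSE],
       loadings = pc$rotation[, seq_len(k), drop = FALSE],
       variance_fraction = vf[seq_len(k)])
}

#' Spearman correlation matrix with hierarchical clustering
#'
#' Pairwise Spearman correlations (pairwise-complete observations, so
#' missing clinical scores are tolerated without imputation), reordered
#' by agglomerative average-linkage clustering of the Euclidean distances
#' between rows of the correlation matrix.
#'
#' @param x Numeric matrix / data frame (>= 3 variables).
#' @return List with `rho` (reordered matrix), `order` (variable order),
#'   `hclust` (the dendrogram object), `rho_unordered`.
#' @export
correlation_clustermap <- function(x) {
  x <- as.matrix(x)
  stopifnot(ncol(x) >= 3L)
  sds <- apply(x, 2, stats::sd, na.rm = TRUE)
  if (any(!is.finite(sds)) || any(sds == 0)) {
    stop("variable(s) with zero variance: ",
         paste(colnames(x)[!is.finite(sds) | sds == 0], collapse = ", "))
  }
  rho <- stats::cor(x, method = "spearman", use = "pairwise.complete.obs")
  hc <- stats::hclust(stats::dist(rho, method = "euclidean"),
                      method = "average")
  ord <- hc$order
  list(rho = rho[ord, ord], order = colnames(x)[ord], hclust = hc,
       rho_unordered = rho)
}
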