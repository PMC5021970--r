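# Linear SVM, repeated stratified CV, combined two-threshold classifier.

test_that("linear SVM separates a separable toy set and orients scores", {
  toy <- separable_toy(n = 15L)
  m <- train_linear_svm(toy$x, toy$labels)
  pred <- m$scores >= 0
  expect_equal(mean(pred == (toy$labels == "patient")), 1)
  expect_gt(mean(m$scores[toy$labels == "patient"]),
            mean(m$scores[toy$labels == "control"]))
  expect_error(train_linear_svm(toy$x[, 1:3], toy$labels), "7 mitochondrial")
  expect_error(train_linear_svm(toy$x, rep("patient", 30)), "2 classes")
})

test_that("duplicating every row leaves the decision boundary unchanged", {
  toy <- separable_toy(n = 12L, gap = 4)
  m1 <- train_linear_svm(toy$x, toy$labels)
  m2 <- train_linear_svm(rbind(toy$x, toy$x), c(toy$labels, toy$labels))
  s1 <- predict(m1, toy$x)
  s2 <- predict(m2, toy$x)
  expect_equal(sign(s1), sign(s2))
  expect_gt(cor(s1, s2), 0.999)
})

test_that("the outlier budget controls whether a mislabeled point is fit", {
  set.seed(21)
  n <- 20L
  x <- rbind(matrix(rnorm(n * 2, 0, 0.5), ncol = 2),
             matrix(rnorm(n * 2, 4, 0.5), ncol = 2))
  lab <- rep(c("control", "patient"), each = n)
  lab[1] <- "patient"   # one mislabeled control deep in control territory
  loose <- train_linear_svm(x, lab, outlier_fraction = 0.5, check_width = FALSE)
  # the loose budget sacrifices the outlier: it stays on the control side
  expect_lt(loose$scores[1], 0)
  # and the boundary still separates the clean points
  clean_acc <- mean((loose$scores[-1] >= 0) == (lab[-1] == "patient"))
  expect_equal(clean_acc, 1)
})

test_that("stratified folds partition the data with both classes per fold", {
  lab <- rep(c("patient", "control"), c(26, 14))
  set.seed(10)
  for (i in 1:10) {
    f <- mitoganglia:::stratified_folds(lab, 5L)
    expect_setequal(unique(f), 1:5)
    expect_equal(length(f), 40L)
    for (k in 1:5) {
      expect_true(all(c("patient", "control") %in% lab[f == k]))
    }
    tab <- table(f[lab == "patient"])
    expect_lte(diff(range(tab)), 1)   # balanced within class
  }
  expect_error(mitoganglia:::stratified_folds(rep(c("a", "b"), c(3, 40)), 5L),
               "fewer than k")
})

test_that("repeated CV is deterministic and calibrated", {
  toy <- separable_toy(n = 15L, gap = 6)
  cv1 <- repeated_cv_auc(toy$x, toy$labels, n_repeats = 5L, k = 5L, seed = 3L)
  cv2 <- repeated_cv_auc(toy$x, toy$labels, n_repeats = 5L, k = 5L, seed = 3L)
  expect_identical(cv1$auc, cv2$auc)
  expect_gt(cv1$mean_auc, 0.99)        # separable: near-perfect
  expect_true(all(!is.na(cv1$scores))) # every sample scored every repeat
  # null: labels independent of features
  set.seed(99)
  xn <- matrix(rnorm(60 * 4), ncol = 4)
  ln <- rep(c("patient", "control"), each = 30)
  cvn <- repeated_cv_auc(xn, ln, n_repeats = 10L, k = 5L, seed = 5L)
  se <- sd(cvn$auc) / sqrt(10) + 0.05
  expect_lt(abs(cvn$mean_auc - 0.5), 3 * se)
})

test_that("combined classifier reproduces the worked two-threshold example", {
  # 6 patients / 4 controls; patients hold scores {10,9,8,7,3,2}; volumes
  # anti-aligned with scores.
  scores <- 1:10
  volumes <- 11 - scores
  truth <- ifelse(scores %in% c(10, 9, 8, 7, 3, 2), "patient", "control")
  res <- combined_classify(scores, volumes, truth, q_score = 0.6, q_volume = 0.4)
  # enumeration with the interpolated quantile definition:
  ts <- quantile(scores, 0.6, type = 7)   # 6.4
  tv <- quantile(volumes, 0.4, type = 7)  # 4.6
  want <- (scores >= ts) & (volumes <= tv)
  expect_equal(res$predictions, want)
  expect_equal(res$confusion$tp, 4L)
  expect_equal(res$confusion$fp, 0L)
  expect_equal(res$confusion$fn, 2L)
  expect_equal(res$confusion$tn, 4L)
  expect_equal(res$confusion$sensitivity, 4 / 6)
  expect_equal(res$confusion$specificity, 1)
})

test_that("perfectly separating inputs give sensitivity = specificity = 1", {
  truth <- rep(c("patient", "control"), c(6, 4))
  scores <- c(7:12, 1:4)
  volumes <- c(1:6, 20:23)
  res <- combined_classify(scores, volumes, truth, q_score = 0.4, q_volume = 0.6)
  expect_equal(res$confusion$sensitivity, 1)
  expect_equal(res$confusion$specificity, 1)
  expect_error(combined_classify(rep(1, 10), volumes, truth), "SVM scores")
  expect_error(combined_classify(scores, rep(2, 10), truth), "volumes")
})

test_that("AND rule is never more sensitive nor less specific than either part", {
  set.seed(61)
  for (i in 1:25) {
    n <- 30L
    truth <- sample(c("patient", "control"), n, replace = TRUE,
                    prob = c(0.6, 0.4))
    if (length(unique(truth)) < 2) next
    scores <- rnorm(n) + (truth == "patient") * runif(1, 0, 2)
    volumes <- rlnorm(n) * ifelse(truth == "patient", runif(1, 0.4, 1), 1)
    both <- combined_classify(scores, volumes, truth)
    ts <- both$score_threshold; tv <- both$volume_threshold
    conf1 <- evaluate_confusion(scores >= ts, truth == "patient")
    conf2 <- evaluate_confusion(volumes <= tv, truth == "patient")
    expect_lte(both$confusion$sensitivity, min(conf1$sensitivity, conf2$sensitivity))
    expect_gte(both$confusion$specificity, max(conf1$specificity, conf2$specificity))
  }
})

test_that("quantile thresholds commute with monotone transforms", {
  set.seed(62)
  n <- 40L
  truth <- sample(c("patient", "control"), n, replace = TRUE)
  truth[1:2] <- c("patient", "control")
  scores <- rnorm(n); volumes <- rlnorm(n, meanlog = 3)
  a <- combined_classify(scores, volumes, truth)
  b <- combined_classify(exp(scores), volumes^3, truth)   # strictly increasing
  expect_equal(a$predictions, b$predictions)
  expect_equal(unclass(a$confusion), unclass(b$confusion))
})

test_that("confusion arithmetic", {
  pred <- rep(c(TRUE, FALSE), c(6, 12))
  truth <- rep(c(TRUE, FALSE, TRUE, FALSE), c(5, 1, 3, 9))
  cf <- evaluate_confusion(pred, truth)
  expect_equal(cf$tp, 5L); expect_equal(cf$fp, 1L)
  expect_equal(cf$fn, 3L); expect_equal(cf$tn, 9L)
  expect_equal(cf$sensitivity, 0.625)
  expect_equal(cf$specificity, 0.9)
  t2 <- c(TRUE, FALSE, TRUE)
  expect_equal(evaluate_confusion(t2, t2)$sensitivity, 1)
  expect_equal(evaluate_confusion(!t2, t2)$specificity, 0)
})
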