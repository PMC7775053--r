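mk_table <- function(n, d, sep = 0, seed = 1, xor = FALSE) {
  set.seed(seed)
  y <- rep(c("benign", "malignant"), length.out = n)
  X <- matrix(rnorm(n * d), n, d)
  if (xor) {
    s1 <- sample(c(-1, 1), n, replace = TRUE)
    s2 <- ifelse(y == "malignant", s1, -s1)
    X[, 1] <- s1 * 2 + rnorm(n, sd = 0.2)
    X[, 2] <- s2 * 2 + rnorm(n, sd = 0.2)
  } else if (sep > 0) {
    X[y == "malignant", 1] <- X[y == "malignant", 1] + sep
  }
  df <- as.data.frame(X)
  names(df) <- paste0("f", seq_len(d))
  df$label <- factor(y, levels = c("benign", "malignant"))
  df
}

test_that("roc_metrics reproduces the confusion arithmetic", {
  y <- rep(c(TRUE, FALSE), c(10, 10))
  pred <- c(rep(TRUE, 9), FALSE, rep(FALSE, 8), TRUE, TRUE)
  r <- roc_metrics(y, score = as.numeric(pred), pred)
  expect_equal(r$sensitivity, 90)
  expect_equal(r$specificity, 80)
  expect_equal(r$accuracy, 85)
  expect_equal(r$PPV, 100 * 9 / 11, tolerance = 1e-6)   # 81.8%
  expect_equal(r$NPV, 100 * 8 / 9, tolerance = 1e-6)    # 88.9%
  expect_equal(unname(r$confusion), c(9, 2, 8, 1))
  expect_error(roc_metrics(rep(TRUE, 5), 1:5, rep(TRUE, 5)), "both classes")
})

test_that("AUC equals the brute-force pairwise probability", {
  set.seed(4)
  for (i in 1:10) {
    y <- sample(c(TRUE, FALSE), 20, replace = TRUE)
    if (all(y) || !any(y)) next
    s <- sample(1:8, 20, replace = TRUE)  # with ties
    brute <- mean(outer(s[y], s[!y], function(a, b)
      (a > b) + 0.5 * (a == b)))
    expect_equal(roc_metrics(y, s, y)$AUC, brute)
  }
  # perfectly ordered scores
  y <- rep(c(FALSE, TRUE), each = 10)
  expect_equal(roc_metrics(y, seq_len(20), y)$AUC, 1.0)
  # label-independent scores at n = 1000
  set.seed(9)
  y2 <- rep(c(FALSE, TRUE), 500)
  expect_lt(abs(roc_metrics(y2, rnorm(1000), y2)$AUC - 0.5), 0.05)
})

test_that("KNN memorizes with k = 1 and LDA separates clear classes", {
  tb <- mk_table(40, 3, sep = 6, seed = 2)
  res <- fit_predict(classifier_spec("knn", k = 1), tb, tb)
  expect_equal(res$pred, tb$label == "malignant")
  big <- mk_table(200, 2, sep = 6, seed = 3)
  half <- seq_len(100)
  r2 <- fit_predict(classifier_spec("lda"), big[half, ], big[-half, ])
  expect_gte(mean(r2$pred == (big$label[-half] == "malignant")), 0.99)
})

test_that("LDA agrees with the MASS reference on a shared-covariance task", {
  skip_if_not_installed("MASS")
  tb <- mk_table(60, 4, sep = 2, seed = 5)
  te <- mk_table(60, 4, sep = 2, seed = 6)
  ours <- fit_predict(classifier_spec("lda"), tb, te)
  m <- MASS::lda(label ~ ., data = tb)
  theirs <- predict(m, te)$class == "malignant"
  expect_gte(mean(ours$pred == theirs), 0.95)
})

test_that("SVM-RBF solves the concentric-circles problem LDA cannot", {
  set.seed(12)
  n <- 60
  r <- rep(c(1, 3), each = n / 2) + rnorm(n, sd = 0.15)
  th <- runif(n, 0, 2 * pi)
  df <- data.frame(x = r * cos(th), y = r * sin(th),
                   label = factor(rep(c("benign", "malignant"),
                                      each = n / 2),
                                  levels = c("benign", "malignant")))
  rs <- fit_predict(classifier_spec("svm", C = 10, gamma = 1), df, df)
  expect_gte(mean(rs$pred == (df$label == "malignant")), 0.95)
  rl <- fit_predict(classifier_spec("lda"), df, df)
  expect_lt(mean(rl$pred == (df$label == "malignant")), 0.8)
})

test_that("SVM grid search stays on the declared grid, deterministically", {
  tb <- mk_table(30, 3, sep = 5, seed = 7)
  X <- as.matrix(tb[1:3]); y <- tb$label == "malignant"
  gs1 <- grid_search_svm(X, y, seed = 3)
  gs2 <- grid_search_svm(X, y, seed = 3)
  expect_identical(gs1[c("C", "gamma")], gs2[c("C", "gamma")])
  expect_true(gs1$C %in% 2^seq(-5, 15, by = 2))
  expect_true(gs1$gamma %in% 2^seq(-15, 3, by = 2))
  # wide-margin separable data: the tuned model nails the training set
  fit <- qusradiomics:::svm_fit(X, y, gs1$C, gs1$gamma)
  expect_equal(qusradiomics:::svm_predict(fit, X)$pred, y)
})

test_that("the LM-trained ANN learns XOR and stops on validation failures", {
  # noiseless XOR, 4 points repeated 25 times
  X <- matrix(rep(c(0, 0, 1, 1, 0, 1, 0, 1), 25), ncol = 2)
  y <- xor(X[, 1] > 0.5, X[, 2] > 0.5)
  ok <- 0
  for (s in 1:10) {
    fit <- train_ann(X, y, hidden = 20, max_epochs = 1000, seed = s)
    acc <- mean(qusradiomics:::ann_predict(fit, X)$pred == y)
    if (acc == 1) ok <- ok + 1
  }
  expect_gte(ok, 9)
  # an untrained (zero-epoch) network sits at chance on balanced data
  net <- qusradiomics:::ann_init(2, 20, seed = 1)
  p <- qusradiomics:::ann_forward(net, X)$Y[, 2] > 0.5
  expect_gt(mean(p == y), 0.3)
  expect_lt(mean(p == y), 0.7)
  # validation-failure early stopping halts well before the epoch cap
  set.seed(30)
  Xn <- matrix(rnorm(40 * 2), 40, 2)
  yn <- rep(c(TRUE, FALSE), 20)
  fit <- train_ann(Xn, yn, matrix(rnorm(20 * 2), 20, 2),
                   rep(c(TRUE, FALSE), 10), max_epochs = 1000, seed = 2)
  expect_lt(fit$epochs, 1000)
})

test_that("SFS picks decisive features and respects the cap", {
  tb <- mk_table(40, 6, seed = 11)
  tb$f3 <- ifelse(tb$label == "malignant", 5, -5) + rnorm(40, sd = 0.1)
  sel <- sfs_select(tb, classifier_spec("lda"))
  expect_equal(sel, "f3")   # perfect separator found first, F1 = 1
  # pure noise: never more than max_features
  noise <- mk_table(60, 30, seed = 12)
  sel2 <- sfs_select(noise, classifier_spec("lda"), max_features = 10)
  expect_lte(length(sel2), 10)
  # jointly informative XOR pair: selected together, pair beats singles
  xo <- mk_table(80, 2, xor = TRUE, seed = 13)
  spec <- classifier_spec("knn", k = 3)
  sel3 <- sfs_select(xo, spec, max_features = 4)
  expect_setequal(sel3, c("f1", "f2"))
  f1_pair <- f1_score(xo$label, fit_predict(spec, xo, xo)$pred)
  f1_single <- vapply(c("f1", "f2"), function(f) {
    sub <- xo[c(f, "label")]
    f1_score(xo$label, fit_predict(spec, sub, sub)$pred)
  }, 0)
  expect_true(all(f1_pair > f1_single))
  one_class <- tb; one_class$label <- factor(rep("benign", 40),
                                             levels = c("benign",
                                                        "malignant"))
  expect_error(sfs_select(one_class, classifier_spec("lda")), "both classes")
})

test_that("SFS is deterministic for a fixed table and seed", {
  tb <- mk_table(40, 10, sep = 1, seed = 14)
  expect_identical(sfs_select(tb, classifier_spec("lda"), seed = 5),
                   sfs_select(tb, classifier_spec("lda"), seed = 5))
})

test_that("LOOCV pools n held-out folds and nails separable data", {
  tb <- mk_table(24, 5, sep = 8, seed = 15)
  r <- evaluate_loocv(tb, classifier_spec("lda"), max_features = 3)
  expect_equal(r$n_folds, 24)
  expect_equal(length(r$selected_features), 24)
  expect_equal(r$accuracy, 100)
  expect_equal(r$AUC, 1.0)
  expect_error(evaluate_loocv(tb[1:5, ], classifier_spec("lda")), "10")
})

test_that("LOOCV on permuted labels stays at chance (no leakage)", {
  correct <- 0; total <- 0
  for (s in 1:3) {
    tb <- mk_table(20, 6, sep = 4, seed = 20 + s)
    set.seed(100 + s)
    tb$label <- sample(tb$label)
    if (all(tb$label == "benign") || all(tb$label == "malignant")) next
    r <- evaluate_loocv(tb, classifier_spec("lda"), max_features = 3,
                        seed = s)
    correct <- correct + sum(r$confusion[c("TP", "TN")])
    total <- total + sum(r$confusion)
  }
  # pooled accuracy must not beat chance (binomial upper check)
  expect_lt(correct / total, 0.5 + 2.6 * sqrt(0.25 / total))
})

test_that("hold-out uses stratified 70/30 splits and averages reports", {
  y <- rep(c(TRUE, FALSE), c(101, 92))   # the clinical cohort's balance
  te <- qusradiomics:::stratified_holdout(y, 0.30, seed = 1)
  expect_equal(length(te), 58)            # 135 train / 58 test
  expect_equal(sum(y[te]), round(58 * 101 / 193))
  tb <- mk_table(40, 5, sep = 8, seed = 16)
  r1 <- evaluate_holdout(tb, classifier_spec("lda"), realizations = 4,
                         seed = 2)
  r2 <- evaluate_holdout(tb, classifier_spec("lda"), realizations = 4,
                         seed = 2)
  expect_equal(r1$accuracy, r2$accuracy)
  expect_equal(r1$AUC, r2$AUC)
  expect_equal(r1$accuracy, 100)
  expect_equal(length(r1$per_realization), 4)
  expect_error(evaluate_holdout(tb[1:10, ], classifier_spec("lda")), "20")
})
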