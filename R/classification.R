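# Forward sequential feature selection, ROC metrics, and the two
# validation schemes (LOOCV, repeated stratified hold-out). The malignant
# class is the positive class throughout.

#' F1 score with malignant as the positive class
#'
#' @param truth,pred logical vectors (TRUE = malignant) or factors with a
#'   `"malignant"` level.
#' @return harmonic mean of precision and sensitivity; 0 when undefined.
#' @export
f1_score <- function(truth, pred) {
  truth <- as_malignant(truth); pred <- as_malignant(pred)
  tp <- sum(truth & pred)
  fp <- sum(!truth & pred)
  fn <- sum(truth & !pred)
  if (2 * tp + fp + fn == 0) return(0)
  2 * tp / (2 * tp + fp + fn)
}

as_malignant <- function(x) {
  if (is.logical(x)) x else x == "malignant"
}

#' Forward sequential feature selection maximizing training F1
#'
#' Greedy forward addition: at each size the candidate feature whose
#' addition maximizes the training-set F1 (resubstitution, malignant
#' positive) is appended, up to `max_features`. The returned subset is the
#' prefix achieving the maximum F1 along the path, with ties resolved to
#' the earliest (smallest) size; candidate ties resolve to the
#' lowest-index column.
#'
#' Candidate ties (several features reaching the same training F1 -- always
#' the case for flexible models that interpolate the training set) are
#' broken by the magnitude of the feature's two-sample t statistic, then by
#' column order; both rules are deterministic.
#'
#' @param train data.frame with feature columns and `label`.
#' @param spec a [classifier_spec()].
#' @param max_features cap on the subset size (default 10).
#' @param seed passed to [fit_predict()].
#' @return character vector of selected feature names (in addition order).
#' @export
sfs_select <- function(train, spec, max_features = 10, seed = 1) {
  feats <- setdiff(names(train), "label")
  y <- train$label == "malignant"
  if (all(y) || !any(y)) stop("training table must contain both classes")
  max_features <- min(max_features, length(feats))
  tstat <- vapply(feats, function(f) {
    a <- train[[f]][y]; b <- train[[f]][!y]
    sp <- sqrt((stats::var(a) * (length(a) - 1) +
                  stats::var(b) * (length(b) - 1)) /
                 (length(a) + length(b) - 2))
    abs(mean(a) - mean(b)) / (sp + 1e-12)
  }, 0)
  selected <- character(0)
  path_f1 <- numeric(0)
  remaining <- feats
  for (size in seq_len(max_features)) {
    best_f1 <- -Inf; best_feat <- NULL
    for (f in remaining) {
      cols <- c(selected, f)
      sub <- train[c(cols, "label")]
      # candidate scoring uses fixed default hyperparameters; the expensive
      # grid search is run once on the final subset (see tune_spec)
      cand_spec <- spec
      if (spec$kind == "svm" && (is.null(spec$C) || is.null(spec$gamma))) {
        cand_spec$C <- 1; cand_spec$gamma <- 1 / length(cols)
      }
      res <- fit_predict(cand_spec, sub, sub, seed = seed)
      f1 <- f1_score(y, res$pred)
      if (f1 > best_f1 + 1e-12 ||
          (abs(f1 - best_f1) <= 1e-12 && !is.null(best_feat) &&
           tstat[f] > tstat[best_feat] + 1e-12)) {
        best_f1 <- f1; best_feat <- f
      }
    }
    selected <- c(selected, best_feat)
    path_f1 <- c(path_f1, best_f1)
    remaining <- setdiff(remaining, best_feat)
    if (best_f1 >= 1) break
  }
  selected[seq_len(which.max(path_f1))]
}

#' ROC and confusion-matrix metrics
#'
#' Sensitivity, specificity, accuracy, PPV and NPV (percent) from the hard
#' predictions; AUC as the Mann-Whitney statistic of the continuous
#' scores, ties counted one half.
#'
#' @param labels true labels (logical or factor, malignant positive).
#' @param scores continuous scores, larger = more malignant.
#' @param predictions hard predictions.
#' @return list of class `qus_classification_report`.
#' @export
roc_metrics <- function(labels, scores, predictions) {
  y <- as_malignant(labels); p <- as_malignant(predictions)
  if (all(y) || !any(y)) stop("both classes must be present")
  tp <- sum(y & p); fn <- sum(y & !p)
  tn <- sum(!y & !p); fp <- sum(!y & p)
  r <- rank(scores)
  n1 <- sum(y); n0 <- sum(!y)
  auc <- (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  pct <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  structure(list(
    sensitivity = pct(tp, tp + fn),
    specificity = pct(tn, tn + fp),
    accuracy = pct(tp + tn, tp + tn + fp + fn),
    PPV = pct(tp, tp + fp),
    NPV = pct(tn, tn + fn),
    AUC = auc,
    confusion = c(TP = tp, FP = fp, TN = tn, FN = fn)
  ), class = "qus_classification_report")
}

#' Leave-one-out cross-validation of the full pipeline
#'
#' For each of the n folds the left-out lesion is predicted by a model
#' built entirely within the fold: feature standardization, forward SFS
#' and any hyperparameter search are all refit on the n-1 training rows.
#' Pooled held-out predictions and scores yield the report.
#'
#' @param table feature table with `label`.
#' @param spec a [classifier_spec()].
#' @param max_features SFS cap.
#' @param seed base seed; fold f uses `seed + f` internally.
#' @return a `qus_classification_report` with an extra element
#'   `selected_features` (list, per fold).
#' @export
evaluate_loocv <- function(table, spec, max_features = 10, seed = 1) {
  n <- nrow(table)
  if (n < 10) stop("LOOCV needs at least 10 observations")
  y <- table$label == "malignant"
  preds <- logical(n); scores <- numeric(n)
  sel <- vector("list", n)
  for (f in seq_len(n)) {
    train <- table[-f, , drop = FALSE]
    if (all(train$label == "malignant") || all(train$label == "benign"))
      stop("a training fold lost one class entirely")
    feats <- sfs_select(train, spec, max_features, seed = seed + f)
    spec_f <- tune_spec(spec, train[c(feats, "label")], seed = seed + f)
    res <- fit_predict(spec_f, train[c(feats, "label")],
                       table[f, c(feats, "label"), drop = FALSE],
                       seed = seed + f)
    preds[f] <- res$pred; scores[f] <- res$score
    sel[[f]] <- feats
  }
  rep <- roc_metrics(y, scores, preds)
  rep$selected_features <- sel
  rep$n_folds <- n
  rep
}

#' Repeated stratified hold-out validation
#'
#' `realizations` stratified random 70/30 train/test splits (the ANN
#' effectively uses 70/15/15 because [fit_predict()] carves a validation
#' subset out of the training portion); the full pipeline (SFS,
#' hyperparameters, fitting) is refit on each training split and metrics
#' are averaged over realizations.
#'
#' @param table feature table with `label`.
#' @param spec a [classifier_spec()].
#' @param realizations number of random splits (default 10).
#' @param train_frac training fraction (default 0.70).
#' @param max_features SFS cap.
#' @param seed base seed; realization r uses `seed + r`.
#' @return a `qus_classification_report` of averaged metrics, with
#'   `per_realization` reports attached.
#' @export
evaluate_holdout <- function(table, spec, realizations = 10,
                             train_frac = 0.70, max_features = 10,
                             seed = 1) {
  n <- nrow(table)
  if (n < 20) stop("hold-out validation needs at least 20 observations")
  y <- table$label == "malignant"
  reports <- vector("list", realizations)
  for (r in seq_len(realizations)) {
    sp <- seed + r
    repeat {
      te <- stratified_holdout(y, 1 - train_frac, sp)
      if (any(y[te]) && any(!y[te]) && any(y[-te]) && any(!y[-te])) break
      sp <- sp + 1000L   # resample with the next seed; logged below
    }
    train <- table[-te, , drop = FALSE]
    feats <- sfs_select(train, spec, max_features, seed = seed + r)
    spec_r <- tune_spec(spec, train[c(feats, "label")], seed = seed + r)
    res <- fit_predict(spec_r, train[c(feats, "label")],
                       table[te, c(feats, "label"), drop = FALSE],
                       seed = seed + r)
    rep_r <- roc_metrics(y[te], res$score, res$pred)
    rep_r$selected_features <- feats
    reports[[r]] <- rep_r
  }
  metrics <- c("sensitivity", "specificity", "accuracy", "PPV", "NPV", "AUC")
  avg <- lapply(metrics, function(m)
    mean(vapply(reports, function(x) x[[m]], 0), na.rm = TRUE))
  names(avg) <- metrics
  avg$confusion <- Reduce(`+`, lapply(reports, `[[`, "confusion"))
  avg$per_realization <- reports
  structure(avg, class = "qus_classification_report")
}

# fill in SVM hyperparameters by grid search on the (standardized)
# training subset; other classifiers pass through unchanged
tune_spec <- function(spec, train, seed = 1) {
  if (spec$kind != "svm" || (!is.null(spec$C) && !is.null(spec$gamma)))
    return(spec)
  feats <- setdiff(names(train), "label")
  X <- as.matrix(train[feats])
  y <- train$label == "malignant"
  X <- apply_standardizer(X, standardizer(X))
  gs <- grid_search_svm(X, y, seed = seed)
  spec$C <- gs$C; spec$gamma <- gs$gamma
  spec
}

# stratified sample of test indices with largest-remainder rounding
stratified_holdout <- function(y, test_frac, seed) {
  set.seed(seed)
  n <- length(y)
  n_test <- round(n * test_frac)
  idx1 <- which(y); idx0 <- which(!y)
  n1 <- round(n_test * length(idx1) / n)
  n0 <- n_test - n1
  n1 <- min(max(n1, 1L), length(idx1) - 1L)
  n0 <- min(max(n0, 1L), length(idx0) - 1L)
  c(sample_from(idx1, n1), sample_from(idx0, n0))
}

# sample() without the scalar-x surprise
sample_from <- function(x, size) x[sample.int(length(x), size)]

#' @export
print.qus_classification_report <- function(x, ...) {
  cat("Classification report (malignant = positive)\n")
  for (m in c("sensitivity", "specificity", "accuracy", "PPV", "NPV"))
    cat(sprintf("  %-12s %5.1f%%\n", m, x[[m]]))
  cat(sprintf("  %-12s %5.3f\n", "AUC", x$AUC))
  if (!is.null(x$confusion))
    cat("  confusion   TP =", x$confusion["TP"], " FP =", x$confusion["FP"],
        " TN =", x$confusion["TN"], " FN =", x$confusion["FN"], "\n")
  invisible(x)
}
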