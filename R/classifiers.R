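# The four classifiers: two-class LDA, k-nearest neighbours, RBF-kernel
# SVM trained by SMO, and a shallow feedforward network trained with
# Levenberg-Marquardt. All operate on numeric feature matrices that are
# standardized with training-set statistics by the caller (fit_predict).

#' Classifier specification
#'
#' @param kind one of `"lda"`, `"knn"`, `"svm"`, `"ann"`.
#' @param k KNN neighbour count; `NULL` selects the best of 1/3/5 by
#'   training F1.
#' @param C,gamma SVM-RBF hyperparameters; `NULL` triggers a grid search
#'   on the training set.
#' @param hidden ANN hidden-layer width (default 20).
#' @param max_epochs ANN Levenberg-Marquardt epoch cap (default 1000).
#' @export
classifier_spec <- function(kind = c("lda", "knn", "svm", "ann"),
                            k = NULL, C = NULL, gamma = NULL,
                            hidden = 20L, max_epochs = 1000L) {
  kind <- match.arg(kind)
  if (!is.null(k) && !k %in% c(1, 3, 5)) stop("k must be one of 1, 3, 5")
  structure(list(kind = kind, k = k, C = C, gamma = gamma,
                 hidden = as.integer(hidden),
                 max_epochs = as.integer(max_epochs)),
            class = "qus_classifier_spec")
}

standardizer <- function(X) {
  mu <- colMeans(X)
  sd <- apply(X, 2, stats::sd)
  sd[!is.finite(sd) | sd < 1e-12] <- 1
  list(mu = mu, sd = sd)
}

apply_standardizer <- function(X, st) {
  sweep(sweep(X, 2, st$mu), 2, st$sd, `/`)
}

# ---- LDA -------------------------------------------------------------

lda_fit <- function(X, y) {
  # y: logical, TRUE = positive (malignant)
  X0 <- X[!y, , drop = FALSE]; X1 <- X[y, , drop = FALSE]
  n0 <- nrow(X0); n1 <- nrow(X1)
  if (n0 < 1 || n1 < 1) stop("both classes required")
  mu0 <- colMeans(X0); mu1 <- colMeans(X1)
  S <- (crossprod(sweep(X0, 2, mu0)) + crossprod(sweep(X1, 2, mu1))) /
    max(n0 + n1 - 2, 1)
  d <- ncol(X)
  ridge <- 1e-6 * mean(diag(S))
  if (!is.finite(ridge) || ridge <= 0) ridge <- 1e-6
  Sol <- tryCatch(solve(S, cbind(mu1 - mu0)),
                  error = function(e) solve(S + diag(ridge, d),
                                            cbind(mu1 - mu0)))
  w <- drop(Sol)
  b <- -sum(w * (mu0 + mu1)) / 2 + log(n1 / n0)
  list(w = w, b = b)
}

lda_predict <- function(fit, X) {
  z <- drop(X %*% fit$w) + fit$b
  score <- 1 / (1 + exp(-z))   # posterior P(malignant)
  list(pred = z > 0, score = score)
}

# ---- KNN -------------------------------------------------------------

# exclude_self: leave-one-out voting, used when a training set is scored
# against itself (k selection, SFS candidate evaluation) -- otherwise each
# point's own vote makes resubstitution F1 degenerate at k = 1
knn_predict <- function(Xtr, ytr, Xte, k, exclude_self = FALSE) {
  n <- nrow(Xtr)
  k <- min(k, n - exclude_self)
  pred <- logical(nrow(Xte)); score <- numeric(nrow(Xte))
  for (i in seq_len(nrow(Xte))) {
    d2 <- colSums((t(Xtr) - Xte[i, ])^2)
    if (exclude_self) d2[i] <- Inf
    nb <- order(d2)[1:k]
    frac <- mean(ytr[nb])
    score[i] <- frac
    pred[i] <- frac > 0.5
  }
  list(pred = pred, score = score)
}

# ---- SVM-RBF via SMO -------------------------------------------------

rbf_kernel <- function(A, B, gamma) {
  an <- rowSums(A^2); bn <- rowSums(B^2)
  d2 <- outer(an, bn, `+`) - 2 * tcrossprod(A, B)
  exp(-gamma * pmax(d2, 0))
}

svm_fit <- function(X, y, C, gamma, tol = 1e-3, max_passes = 8,
                    max_iter = 5000) {
  # y logical -> {-1, +1}
  yv <- ifelse(y, 1, -1)
  n <- nrow(X)
  K <- rbf_kernel(X, X, gamma)
  alpha <- numeric(n)
  b <- 0
  fcache <- function() drop(K %*% (alpha * yv)) + b
  passes <- 0; iter <- 0
  while (passes < max_passes && iter < max_iter) {
    changed <- 0
    E <- fcache() - yv
    for (i in seq_len(n)) {
      Ei <- sum(K[, i] * alpha * yv) + b - yv[i]
      if ((yv[i] * Ei < -tol && alpha[i] < C) ||
          (yv[i] * Ei > tol && alpha[i] > 0)) {
        j <- which.max(abs(Ei - E[-i]))
        j <- seq_len(n)[-i][j]
        Ej <- sum(K[, j] * alpha * yv) + b - yv[j]
        ai_old <- alpha[i]; aj_old <- alpha[j]
        if (yv[i] != yv[j]) {
          L <- max(0, aj_old - ai_old); H <- min(C, C + aj_old - ai_old)
        } else {
          L <- max(0, ai_old + aj_old - C); H <- min(C, ai_old + aj_old)
        }
        if (L >= H) next
        eta <- 2 * K[i, j] - K[i, i] - K[j, j]
        if (eta >= 0) next
        aj <- aj_old - yv[j] * (Ei - Ej) / eta
        aj <- min(max(aj, L), H)
        if (abs(aj - aj_old) < 1e-7) next
        ai <- ai_old + yv[i] * yv[j] * (aj_old - aj)
        alpha[i] <- ai; alpha[j] <- aj
        b1 <- b - Ei - yv[i] * (ai - ai_old) * K[i, i] -
          yv[j] * (aj - aj_old) * K[i, j]
        b2 <- b - Ej - yv[i] * (ai - ai_old) * K[i, j] -
          yv[j] * (aj - aj_old) * K[j, j]
        b <- if (ai > 0 && ai < C) b1
             else if (aj > 0 && aj < C) b2
             else (b1 + b2) / 2
        changed <- changed + 1
      }
      iter <- iter + 1
    }
    passes <- if (changed == 0) passes + 1 else 0
  }
  sv <- alpha > 1e-8
  list(X = X[sv, , drop = FALSE], coef = (alpha * yv)[sv], b = b,
       gamma = gamma)
}

svm_predict <- function(fit, X) {
  if (nrow(fit$X) == 0) {
    z <- rep(fit$b, nrow(X))
  } else {
    z <- drop(rbf_kernel(X, fit$X, fit$gamma) %*% fit$coef) + fit$b
  }
  list(pred = z > 0, score = z)
}

#' Grid search for the SVM-RBF soft margin and kernel width
#'
#' Exhaustive search over `C = 2^(-5, -3, ..., 15)` and
#' `gamma = 2^(-15, -13, ..., 3)` scored by stratified k-fold F1
#' (malignant positive) on the training set. Ties resolve to the smallest
#' `C`, then the smallest `gamma`.
#'
#' @param X standardized training matrix; `y` logical (TRUE = malignant).
#' @param C_grid,gamma_grid candidate values.
#' @param n_folds stratified folds (default 5).
#' @param seed fold-assignment seed.
#' @return list with `C`, `gamma`, `f1`.
#' @export
grid_search_svm <- function(X, y, C_grid = 2^seq(-5, 15, by = 2),
                            gamma_grid = 2^seq(-15, 3, by = 2),
                            n_folds = 5, seed = 1) {
  folds <- stratified_folds(y, n_folds, seed)
  best <- list(C = C_grid[1], gamma = gamma_grid[1], f1 = -Inf)
  for (C in C_grid) for (gamma in gamma_grid) {
    preds <- logical(length(y))
    for (f in seq_len(max(folds))) {
      te <- folds == f
      if (all(y[!te]) || !any(y[!te])) next
      fit <- svm_fit(X[!te, , drop = FALSE], y[!te], C, gamma)
      preds[te] <- svm_predict(fit, X[te, , drop = FALSE])$pred
    }
    f1 <- f1_score(y, preds)
    if (f1 > best$f1 + 1e-12) best <- list(C = C, gamma = gamma, f1 = f1)
  }
  best
}

stratified_folds <- function(y, n_folds, seed) {
  set.seed(seed)
  folds <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    idx <- idx[sample.int(length(idx))]
    folds[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  folds
}

# ---- ANN: 1 hidden sigmoid layer, softmax output, LM training --------

ann_init <- function(d, hidden, seed) {
  set.seed(seed)
  list(W1 = matrix(stats::runif((d + 1) * hidden, -0.5, 0.5) / sqrt(d + 1),
                   d + 1, hidden),
       W2 = matrix(stats::runif((hidden + 1) * 2, -0.5, 0.5) /
                     sqrt(hidden + 1),
                   hidden + 1, 2))
}

ann_forward <- function(net, X) {
  A <- 1 / (1 + exp(-(cbind(1, X) %*% net$W1)))
  Z <- cbind(1, A) %*% net$W2
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  Y <- E / rowSums(E)
  list(A = A, Y = Y)
}

ann_pack <- function(net) c(as.vector(net$W1), as.vector(net$W2))

ann_unpack <- function(theta, d, hidden) {
  n1 <- (d + 1) * hidden
  list(W1 = matrix(theta[1:n1], d + 1, hidden),
       W2 = matrix(theta[-(1:n1)], hidden + 1, 2))
}

# residuals (network output minus one-hot target) and Jacobian d r / d theta
ann_residual_jacobian <- function(net, X, Tgt) {
  n <- nrow(X); d <- ncol(X); H <- ncol(net$W1)
  fw <- ann_forward(net, X)
  A <- fw$A; Y <- fw$Y
  R <- Y - Tgt                       # n x 2
  Xb <- cbind(1, X)                  # n x (d+1)
  Ab <- cbind(1, A)                  # n x (H+1)
  P <- (d + 1) * H + (H + 1) * 2
  J <- matrix(0, 2 * n, P)
  for (k in 1:2) {
    rows <- (k - 1) * n + seq_len(n)
    # dY[, k] / dZ[, m] = Y_k (delta_km - Y_m)
    G <- Y[, k] * ((k == col(Y)) - Y)             # n x 2
    # W2 block: dY_k/dW2[h, m] = G[, m] * Ab[, h]
    for (m in 1:2) {
      cols <- (d + 1) * H + (m - 1) * (H + 1) + seq_len(H + 1)
      J[rows, cols] <- Ab * G[, m]
    }
    # W1 block: dY_k/dW1[j, h] = (sum_m G[, m] W2[h+1, m]) * A_h(1-A_h) * Xb_j
    Gw <- G %*% t(net$W2[-1, , drop = FALSE])     # n x H
    D <- Gw * A * (1 - A)                         # n x H
    for (h in seq_len(H)) {
      cols <- (h - 1) * (d + 1) + seq_len(d + 1)
      J[rows, cols] <- Xb * D[, h]
    }
  }
  list(R = as.vector(R), J = J, loss = mean(R^2))
}

#' Train the shallow ANN with Levenberg-Marquardt
#'
#' A two-layer feedforward network (sigmoid hidden layer, softmax output)
#' trained in full batch on the mean squared error against one-hot
#' targets. Per epoch the damped Gauss-Newton step
#' `delta = -(J'J + mu I)^{-1} J'r` is tried; on improvement it is
#' accepted and `mu` is divided by 10, otherwise `mu` is multiplied by 10
#' and the step retried, aborting the epoch loop when `mu` exceeds 1000.
#' Training stops at `max_epochs`, when the gradient norm falls below
#' 1e-7, or when the validation error fails to improve 6 times in a row
#' (the weights from the best validation epoch are restored).
#'
#' @param X,y standardized training matrix and logical labels
#'   (TRUE = malignant).
#' @param X_val,y_val optional validation split for early stopping.
#' @param hidden hidden-layer width (default 20).
#' @param max_epochs epoch cap (default 1000).
#' @param seed weight-initialization seed.
#' @return list with the trained weights and the stopping epoch.
#' @export
train_ann <- function(X, y, X_val = NULL, y_val = NULL, hidden = 20,
                      max_epochs = 1000, seed = 1) {
  d <- ncol(X)
  Tgt <- cbind(!y, y) * 1
  net <- ann_init(d, hidden, seed)
  mu <- 1e-3
  best_val <- Inf; val_fail <- 0; best_net <- net
  use_val <- !is.null(X_val) && nrow(X_val) > 0
  if (use_val) Tval <- cbind(!y_val, y_val) * 1
  rj <- ann_residual_jacobian(net, X, Tgt)
  plateau <- 0
  epoch <- 0
  while (epoch < max_epochs) {
    epoch <- epoch + 1
    if (!is.finite(rj$loss)) stop("non-finite ANN training loss")
    JtJ <- crossprod(rj$J)
    g <- crossprod(rj$J, rj$R)
    if (sqrt(sum(g^2)) < 1e-7) break
    improved <- FALSE
    while (mu <= 1000) {
      step <- tryCatch(
        solve(JtJ + diag(mu, ncol(JtJ)), g),
        error = function(e) NULL)
      if (!is.null(step)) {
        theta_new <- ann_pack(net) - drop(step)
        net_new <- ann_unpack(theta_new, d, hidden)
        rj_new <- ann_residual_jacobian(net_new, X, Tgt)
        if (is.finite(rj_new$loss) && rj_new$loss < rj$loss) {
          rel_gain <- (rj$loss - rj_new$loss) / max(rj$loss, 1e-300)
          net <- net_new; rj <- rj_new
          mu <- max(mu * 0.1, 1e-12)
          improved <- TRUE
          # without a validation set, stop once LM has plateaued
          plateau <- if (rel_gain < 1e-6) plateau + 1 else 0
          break
        }
      }
      mu <- mu * 10
    }
    if (!improved) break
    if (!use_val && plateau >= 6) break
    if (use_val) {
      vloss <- mean((ann_forward(net, X_val)$Y - Tval)^2)
      if (vloss < best_val - 1e-12) {
        best_val <- vloss; val_fail <- 0; best_net <- net
      } else {
        val_fail <- val_fail + 1
        if (val_fail >= 6) { net <- best_net; break }
      }
    }
  }
  if (use_val && best_val < Inf &&
      mean((ann_forward(net, X_val)$Y - Tval)^2) > best_val)
    net <- best_net
  list(net = net, epochs = epoch)
}

ann_predict <- function(fit, X) {
  Y <- ann_forward(fit$net, X)$Y
  list(pred = Y[, 2] > 0.5, score = Y[, 2])
}

#' Fit a classifier on a training table and predict a test table
#'
#' Features are standardized using training-set statistics. KNN with
#' `k = NULL` picks the best of k in 1/3/5 by training F1; SVM with
#' missing hyperparameters runs [grid_search_svm()] on the training set;
#' the ANN carves a validation subset out of the training rows for early
#' stopping (fraction `ann_val_frac`).
#'
#' @param spec a [classifier_spec()].
#' @param train,test data.frames with identical feature columns plus
#'   `label`.
#' @param seed seed for any internal randomness (fold assignment,
#'   validation split, weight init).
#' @param ann_val_frac fraction of training rows held out for ANN
#'   validation (default 0.15 / 0.85, the share a 70/15/15 overall split
#'   implies within its 85% training portion).
#' @return list with `pred` (logical, TRUE = malignant) and `score`
#'   (continuous, larger = more malignant).
#' @export
fit_predict <- function(spec, train, test, seed = 1,
                        ann_val_frac = 0.15 / 0.85) {
  stopifnot(inherits(spec, "qus_classifier_spec"))
  feats <- setdiff(names(train), "label")
  if (!identical(feats, setdiff(names(test), "label")))
    stop("train and test feature columns differ")
  Xtr <- as.matrix(train[feats]); Xte <- as.matrix(test[feats])
  ytr <- train$label == "malignant"
  if (all(ytr) || !any(ytr)) stop("training set must contain both classes")
  st <- standardizer(Xtr)
  Xtr <- apply_standardizer(Xtr, st)
  Xte <- apply_standardizer(Xte, st)
  switch(spec$kind,
    lda = lda_predict(lda_fit(Xtr, ytr), Xte),
    knn = {
      self_eval <- identical(train, test)
      k <- spec$k
      if (is.null(k)) {
        f1s <- vapply(c(1, 3, 5), function(kk)
          f1_score(ytr, knn_predict(Xtr, ytr, Xtr, kk,
                                    exclude_self = TRUE)$pred), 0)
        k <- c(1, 3, 5)[which.max(f1s)]
      }
      knn_predict(Xtr, ytr, Xte, k, exclude_self = self_eval)
    },
    svm = {
      C <- spec$C; gamma <- spec$gamma
      if (is.null(C) || is.null(gamma)) {
        gs <- grid_search_svm(Xtr, ytr, seed = seed)
        C <- gs$C; gamma <- gs$gamma
      }
      svm_predict(svm_fit(Xtr, ytr, C, gamma), Xte)
    },
    ann = {
      n <- nrow(Xtr)
      set.seed(seed)
      n_val <- round(ann_val_frac * n)
      # validation-based early stopping only when the carved-out set is
      # large enough to be meaningful (>= 3 per class); tiny training sets
      # rely on LM's own convergence instead
      if (n_val >= 6 && sum(ytr) > 3 && sum(!ytr) > 3) {
        pos <- which(ytr); neg <- which(!ytr)
        take <- function(idx, k) idx[sample.int(length(idx),
                                                min(k, length(idx) - 1L))]
        val_idx <- c(take(pos, max(3L, round(n_val * mean(ytr)))),
                     take(neg, max(3L, round(n_val * mean(!ytr)))))
        tr_idx <- setdiff(seq_len(n), val_idx)
        fit <- train_ann(Xtr[tr_idx, , drop = FALSE], ytr[tr_idx],
                         Xtr[val_idx, , drop = FALSE], ytr[val_idx],
                         hidden = spec$hidden,
                         max_epochs = spec$max_epochs, seed = seed)
      } else {
        fit <- train_ann(Xtr, ytr, hidden = spec$hidden,
                         max_epochs = spec$max_epochs, seed = seed)
      }
      ann_predict(fit, Xte)
    })
}
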