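# Seven classifier backends behind a single fit/predict interface.
# Hyperparameter names follow the conventional grid-search vocabulary:
# LR "C" (inverse regularization strength), KNN "k", QDA "reg_param", SVM
# "C"/"gamma" (RBF kernel), RF "max_depth"/"n_estimators". Features are
# z-scored (parameters learned on the training data) for the scale-sensitive
# models (LR, KNN, SVM, QDA); NB, LDA and RF are fed raw values.

#' Classifier specification
#'
#' @param name One of `"LR"`, `"KNN"`, `"NB"`, `"LDA"`, `"QDA"`, `"SVM"`,
#'   `"RF"`.
#' @param grid Data frame of hyperparameter combinations to grid-search
#'   (one column per parameter); `NULL` takes the default grid from
#'   [default_grids()]. NB has an empty grid.
#' @return List of class `classifier_spec`.
#' @export
classifier_spec <- function(name, grid = NULL) {
  name <- match.arg(name, c("LR", "KNN", "NB", "LDA", "QDA", "SVM", "RF"))
  if (is.null(grid)) grid <- default_grids()[[name]]
  if (nrow(grid) < 1L) stop("grid must have at least one row")
  structure(list(name = name, grid = grid), class = "classifier_spec")
}

#' Default hyperparameter grids for the seven classifiers
#'
#' The default grids span the values reported by grid search in the
#' turning-classification setting: LR C in 0.1-1000 (decades), KNN k 2-6,
#' NB parameter-free, LDA with one discriminant component (the binary
#' case), QDA regularization including 0.001/0.3/0.5, an RBF-kernel SVM C
#' x gamma grid including C = 1e-5/7.6/29.6 and gamma 0.001-10, and RF
#' depth {10, 20, 30} x trees {500, 1500}.
#'
#' @param compact If `TRUE`, return small grids (2-4 combinations, RF with
#'   100 trees) for quick simulation studies.
#' @return Named list of data frames.
#' @export
default_grids <- function(compact = FALSE) {
  if (compact) {
    return(list(
      LR = data.frame(C = c(0.1, 10)),
      KNN = data.frame(k = c(3, 5)),
      NB = data.frame(row.names = 1),
      LDA = data.frame(n_components = 1),
      QDA = data.frame(reg_param = c(0.001, 0.3)),
      SVM = expand.grid(C = c(1, 29.6), gamma = c(0.01, 0.1)),
      RF = expand.grid(max_depth = c(10, 20), n_estimators = 100)))
  }
  list(
    LR = data.frame(C = c(0.1, 1, 10, 100, 1000)),
    KNN = data.frame(k = 2:6),
    NB = data.frame(row.names = 1),
    LDA = data.frame(n_components = 1),
    QDA = data.frame(reg_param = c(0.001, 0.1, 0.3, 0.5)),
    SVM = expand.grid(C = c(1e-5, 0.1, 1, 7.6, 29.6, 100),
                      gamma = c(0.001, 0.01, 0.1, 1, 10)),
    RF = expand.grid(max_depth = c(10, 20, 30),
                     n_estimators = c(500, 1500)))
}

scale_fit <- function(X) {
  mu <- colMeans(X)
  sd <- apply(X, 2, stats::sd)
  sd[sd < 1e-12] <- 1
  list(mu = mu, sd = sd)
}
scale_apply <- function(X, sc) sweep(sweep(X, 2, sc$mu), 2, sc$sd, "/")

rbf_kernel <- function(A, B, gamma) {
  an <- rowSums(A^2); bn <- rowSums(B^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(A, B)
  exp(-gamma * pmax(d2, 0))
}

fit_svm_rbf <- function(X, y01, C, gamma) {
  ys <- 2 * y01 - 1
  n <- nrow(X)
  K <- rbf_kernel(X, X, gamma)
  Q <- (ys %o% ys) * K
  sol <- quadprog::solve.QP(
    Dmat = Q + diag(1e-8 * max(diag(Q), 1), n),
    dvec = rep(1, n),
    Amat = cbind(ys, diag(n), -diag(n)),
    bvec = c(0, rep(0, n), rep(-C, n)),
    meq = 1)
  a <- pmin(pmax(sol$solution, 0), C)
  sv <- a > 1e-10
  free <- sv & a < C - 1e-10
  f_wo_b <- drop(K %*% (a * ys))
  b <- if (any(free)) mean(ys[free] - f_wo_b[free]) else
    if (any(sv)) mean(ys[sv] - f_wo_b[sv]) else mean(ys) * 0
  list(alpha = a[sv], ys = ys[sv], Xsv = X[sv, , drop = FALSE], b = b,
       gamma = gamma, fallback = mean(y01) >= 0.5)
}

predict_svm_rbf <- function(model, X) {
  if (length(model$alpha) == 0L)
    return(rep(as.integer(model$fallback), nrow(X)))
  f <- drop(rbf_kernel(X, model$Xsv, model$gamma) %*%
              (model$alpha * model$ys)) + model$b
  as.integer(f >= 0)
}

fit_gnb <- function(X, y01) {
  classes <- 0:1
  eps <- 1e-9 * max(apply(X, 2, stats::var), 1e-12)
  stats_by <- lapply(classes, function(cl) {
    Xi <- X[y01 == cl, , drop = FALSE]
    list(mu = colMeans(Xi),
         var = apply(Xi, 2, stats::var) + eps,
         logprior = log(nrow(Xi) / nrow(X)))
  })
  list(stats = stats_by)
}

predict_gnb <- function(model, X) {
  ll <- vapply(model$stats, function(s) {
    -0.5 * rowSums(sweep(sweep(X, 2, s$mu)^2, 2, s$var, "/")) -
      0.5 * sum(log(2 * pi * s$var)) + s$logprior
  }, numeric(nrow(X)))
  if (is.null(dim(ll))) ll <- matrix(ll, nrow = 1)
  as.integer(ll[, 2] > ll[, 1])
}

fit_qda_reg <- function(X, y01, reg_param) {
  stats_by <- lapply(0:1, function(cl) {
    Xi <- X[y01 == cl, , drop = FALSE]
    S <- stats::cov(Xi)
    S <- (1 - reg_param) * S + reg_param * diag(ncol(X))
    S <- S + diag(1e-8, ncol(X))
    ch <- chol(S)
    list(mu = colMeans(Xi), chol_inv = backsolve(ch, diag(ncol(X))),
         logdet = 2 * sum(log(diag(ch))),
         logprior = log(nrow(Xi) / nrow(X)))
  })
  list(stats = stats_by)
}

predict_qda_reg <- function(model, X) {
  ll <- vapply(model$stats, function(s) {
    D <- sweep(X, 2, s$mu) %*% s$chol_inv
    -0.5 * rowSums(D^2) - 0.5 * s$logdet + s$logprior
  }, numeric(nrow(X)))
  if (is.null(dim(ll))) ll <- matrix(ll, nrow = 1)
  as.integer(ll[, 2] > ll[, 1])
}

#' Fit one classifier
#'
#' @param name Classifier name (see [classifier_spec()]).
#' @param params Named list / one-row data frame of hyperparameters.
#' @param X Numeric feature matrix (training).
#' @param y Binary labels.
#' @return Model object of class `turn360_classifier` for
#'   [predict_classifier()].
#' @export
fit_classifier <- function(name, params, X, y) {
  X <- as.matrix(X)
  y01 <- as_binary(y)
  params <- as.list(params)
  scaled <- name %in% c("LR", "KNN", "SVM", "QDA")
  sc <- if (scaled) scale_fit(X) else NULL
  Xs <- if (scaled) scale_apply(X, sc) else X
  model <- switch(
    name,
    LR = {
      n <- nrow(Xs)
      if (ncol(Xs) == 1L)  # glmnet requires >= 2 columns
        Xs <- cbind(Xs, .pad = 0)
      suppressWarnings(  # tiny inner folds trip glmnet's small-n warning
        glmnet::glmnet(Xs, factor(y01), family = "binomial", alpha = 0,
                       lambda = 1 / (n * params$C), standardize = FALSE,
                       thresh = 1e-10))
    },
    KNN = list(X = Xs, y = y01, k = params$k),
    NB = fit_gnb(Xs, y01),
    LDA = {
      # lda() errors on variables constant within groups (common for step
      # counts in tiny simulated folds); drop them, or fall back to the
      # majority class when nothing informative remains
      wsd <- vapply(seq_len(ncol(Xs)), function(j)
        max(tapply(Xs[, j], y01, stats::sd)), numeric(1))
      keep <- which(is.finite(wsd) & wsd > 1e-10)
      if (length(keep) == 0L)
        list(majority = as.integer(mean(y01) >= 0.5), keep = integer())
      else
        list(fit = suppressWarnings(
               MASS::lda(Xs[, keep, drop = FALSE], grouping = factor(y01))),
             keep = keep)
    },
    QDA = fit_qda_reg(Xs, y01, params$reg_param),
    SVM = fit_svm_rbf(Xs, y01, params$C, params$gamma),
    RF = {
      mtry <- max(1L, floor(sqrt(ncol(Xs))))
      .rf_fit_cpp(Xs, y01, as.integer(params$n_estimators),
                  as.integer(params$max_depth), mtry, 2L)
    },
    stop("unknown classifier: ", name))
  structure(list(name = name, model = model, scaler = sc),
            class = "turn360_classifier")
}

#' Predict binary class labels
#'
#' @param fit Result of [fit_classifier()].
#' @param X Feature matrix.
#' @return Integer vector of 0/1 predictions.
#' @export
predict_classifier <- function(fit, X) {
  X <- as.matrix(X)
  Xs <- if (!is.null(fit$scaler)) scale_apply(X, fit$scaler) else X
  switch(
    fit$name,
    LR = {
      if (ncol(Xs) == 1L) Xs <- cbind(Xs, .pad = 0)
      as.integer(drop(stats::predict(fit$model, newx = Xs,
                                     type = "response")) >= 0.5)
    },
    KNN = as.integer(as.character(
      FNN::knn(fit$model$X, Xs, factor(fit$model$y),
               k = min(fit$model$k, nrow(fit$model$X))))),
    NB = predict_gnb(fit$model, Xs),
    LDA = {
      if (length(fit$model$keep) == 0L)
        rep(fit$model$majority, nrow(Xs))
      else
        as.integer(as.character(suppressWarnings(
          stats::predict(fit$model$fit,
                         Xs[, fit$model$keep, drop = FALSE]))$class))
    },
    QDA = predict_qda_reg(fit$model, Xs),
    SVM = predict_svm_rbf(fit$model, Xs),
    RF = as.integer(.rf_predict_cpp(fit$model, Xs) >= 0.5))
}
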