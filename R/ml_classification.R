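#' Random oversampling to class balance
#'
#' Resamples the minority class with replacement until both classes have
#' the majority-class size; deterministic given `seed`. Applied strictly
#' inside training folds by [run_cv()] so duplicated samples never reach a
#' test fold.
#'
#' @param features Feature data frame / matrix.
#' @param labels Binary labels.
#' @param seed Seed.
#' @return List with `features`, `labels` and the row `index` into the
#'   input.
#' @export
random_oversample <- function(features, labels, seed = 1) {
  y <- as_binary(labels)
  if (length(unique(y)) < 2L) stop("need both classes to oversample")
  set.seed(seed)
  n_by <- table(y)
  n_max <- max(n_by)
  idx <- seq_along(y)
  for (cl in names(n_by)[n_by < n_max]) {
    members <- which(y == as.integer(cl))
    extra <- members[sample.int(length(members), n_max - length(members),
                                replace = TRUE)]
    idx <- c(idx, extra)
  }
  list(features = features[idx, , drop = FALSE], labels = y[idx],
       index = idx)
}

stratified_folds <- function(y, k, seed) {
  set.seed(seed)
  fold <- integer(length(y))
  for (cl in unique(y)) {
    members <- which(y == cl)
    members <- members[sample.int(length(members))]
    fold[members] <- rep_len(seq_len(k), length(members))
  }
  fold
}

#' Support-weighted classification metrics
#'
#' Accuracy plus class-support-weighted precision, recall and F1 (percent).
#' With weighting by true-class support, weighted recall equals accuracy
#' identically.
#'
#' @param predictions,truth Binary vectors.
#' @return Named numeric vector (`accuracy`, `precision`, `recall`, `f1`),
#'   in percent.
#' @export
weighted_metrics <- function(predictions, truth) {
  y <- as_binary(truth); p <- as.integer(predictions)
  stopifnot(length(y) == length(p), length(y) > 0)
  acc <- mean(p == y)
  per_class <- vapply(c(0L, 1L), function(cl) {
    tp <- sum(p == cl & y == cl)
    prec <- if (sum(p == cl) > 0) tp / sum(p == cl) else 0
    rec <- if (sum(y == cl) > 0) tp / sum(y == cl) else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    c(prec, rec, f1, sum(y == cl))
  }, numeric(4))
  w <- per_class[4, ] / length(y)
  100 * c(accuracy = acc,
          precision = sum(w * per_class[1, ]),
          recall = sum(w * per_class[2, ]),
          f1 = sum(w * per_class[3, ]))
}

#' Row-normalized confusion matrix
#'
#' Rows are true classes normalized by true-class counts (row-stochastic);
#' columns are predictions.
#'
#' @param predictions,truth Binary vectors.
#' @return 2x2 matrix with dimnames `true`/`pred`.
#' @export
confusion_matrix_normalized <- function(predictions, truth) {
  y <- as_binary(truth); p <- as.integer(predictions)
  if (length(unique(y)) < 2L) stop("both classes must appear in `truth`")
  cm <- matrix(0, 2, 2, dimnames = list(true = c("0", "1"),
                                        pred = c("0", "1")))
  for (cl in 0:1)
    for (pr in 0:1)
      cm[cl + 1, pr + 1] <- sum(y == cl & p == pr) / sum(y == cl)
  cm
}

grid_search <- function(spec, X, y, seed, inner_k = 3) {
  if (nrow(spec$grid) == 1L) return(spec$grid[1, , drop = FALSE])
  ki <- min(inner_k, min(table(y)))
  if (ki < 2L) return(spec$grid[1, , drop = FALSE])
  fold <- stratified_folds(y, ki, seed)
  acc <- numeric(nrow(spec$grid))
  for (g in seq_len(nrow(spec$grid))) {
    correct <- 0L; total <- 0L
    for (f in seq_len(ki)) {
      tr <- fold != f; te <- fold == f
      if (length(unique(y[tr])) < 2L || min(table(y[tr])) < 2L) next
      os <- random_oversample(X[tr, , drop = FALSE], y[tr],
                              seed = seed + 131L * f)
      set.seed(seed + 977L * f + g)
      m <- fit_classifier(spec$name, spec$grid[g, , drop = FALSE],
                          os$features, os$labels)
      pr <- predict_classifier(m, X[te, , drop = FALSE])
      correct <- correct + sum(pr == y[te]); total <- total + sum(te)
    }
    acc[g] <- if (total > 0) correct / total else 0
  }
  spec$grid[which.max(acc), , drop = FALSE]
}

#' Oversampled stratified cross-validation of multiple classifiers
#'
#' Stratified `k`-fold cross-validation: within each training fold the
#' minority class is randomly oversampled, hyperparameters are chosen by an
#' inner 3-fold grid search (also oversampling only within inner training
#' folds), the model is refit on the oversampled training fold and
#' evaluated on the untouched test fold. The test fold never contains
#' oversampled duplicates. The report is a pure function of
#' `(table, labels, specs, k, seed)`.
#'
#' @param table Feature data frame.
#' @param labels Binary labels.
#' @param specs List of [classifier_spec()] (default: all seven with their
#'   default grids).
#' @param k Number of folds.
#' @param seed Seed controlling folds, oversampling and stochastic models.
#' @param oversample_before_cv If `TRUE`, oversample once before splitting
#'   (the permissive protocol, inflates estimates; for comparison only).
#' @return List of class `cv_report`: per classifier a list with
#'   `fold_metrics` (k x 4, percent), `mean`, `sd`, `chosen` (per-fold
#'   hyperparameters), `confusion` (pooled, row-normalized); plus `k`,
#'   `seed` and the pooled `predictions`.
#' @export
run_cv <- function(table, labels, specs = NULL, k = 5, seed = 1,
                   oversample_before_cv = FALSE) {
  y <- as_binary(labels)
  X <- as.data.frame(table)
  if (is.null(specs))
    specs <- lapply(c("LR", "KNN", "NB", "LDA", "QDA", "SVM", "RF"),
                    classifier_spec)
  names(specs) <- vapply(specs, `[[`, character(1), "name")
  if (length(unique(y)) < 2L) stop("need both classes present")
  if (min(table(y)) < k)
    stop("a class has fewer than k members; use a smaller k")
  if (oversample_before_cv) {
    os <- random_oversample(X, y, seed = seed)
    X <- os$features; y <- os$labels
  }
  fold <- stratified_folds(y, k, seed + 10000L)
  out <- list()
  for (spec in specs) {
    fm <- matrix(NA_real_, k, 4,
                 dimnames = list(NULL, c("accuracy", "precision", "recall",
                                         "f1")))
    chosen <- list()
    pool_pred <- integer(length(y))
    for (f in seq_len(k)) {
      tr <- fold != f; te <- fold == f
      Xtr <- X[tr, , drop = FALSE]; ytr <- y[tr]
      best <- grid_search(spec, Xtr, ytr, seed = seed + 37L * f)
      os <- random_oversample(Xtr, ytr, seed = seed + 53L * f)
      set.seed(seed + 71L * f)
      m <- fit_classifier(spec$name, best, os$features, os$labels)
      pr <- predict_classifier(m, X[te, , drop = FALSE])
      fm[f, ] <- weighted_metrics(pr, y[te])
      chosen[[f]] <- best
      pool_pred[te] <- pr
    }
    out[[spec$name]] <- list(
      fold_metrics = fm,
      mean = colMeans(fm), sd = apply(fm, 2, stats::sd),
      chosen = chosen,
      confusion = confusion_matrix_normalized(pool_pred, y),
      predictions = pool_pred)
  }
  structure(list(classifiers = out, k = k, seed = seed, labels = y,
                 fold = fold),
            class = "cv_report")
}

#' @export
#' @method print cv_report
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %d-fold CV, seed %d\n", x$k, x$seed))
  for (nm in names(x$classifiers)) {
    m <- x$classifiers[[nm]]
    cat(sprintf("  %-4s accuracy %5.1f +/- %4.1f  precision %5.1f  F1 %5.1f\n",
                nm, m$mean["accuracy"], m$sd["accuracy"],
                m$mean["precision"], m$mean["f1"]))
  }
  invisible(x)
}

#' Paired t-test over fold accuracies of two classifiers
#'
#' Both classifiers must come from the same [run_cv()] report (same folds
#' and seed). Degenerate cases are flagged: identical accuracies give
#' t = 0, p = 1; a constant non-zero difference has zero variance and the
#' p-value is reported as 0 with `degenerate = TRUE`.
#'
#' @param report A `cv_report`.
#' @param name_a,name_b Classifier names to compare.
#' @return List with `t`, `df`, `p`, `mean_diff`, `degenerate`.
#' @export
paired_fold_test <- function(report, name_a, name_b) {
  stopifnot(inherits(report, "cv_report"))
  a <- report$classifiers[[name_a]]$fold_metrics[, "accuracy"]
  b <- report$classifiers[[name_b]]$fold_metrics[, "accuracy"]
  if (length(a) != length(b)) stop("fold mismatch")
  d <- a - b
  k <- length(d)
  if (all(d == 0)) return(list(t = 0, df = k - 1, p = 1, mean_diff = 0,
                               degenerate = FALSE))
  s <- stats::sd(d)
  if (s == 0) return(list(t = Inf * sign(mean(d)), df = k - 1, p = 0,
                          mean_diff = mean(d), degenerate = TRUE))
  t <- mean(d) / (s / sqrt(k))
  list(t = t, df = k - 1, p = 2 * stats::pt(-abs(t), k - 1),
       mean_diff = mean(d), degenerate = FALSE)
}
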