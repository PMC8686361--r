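# ---- logistic helpers ----

logit_loglik <- function(y, p) sum(y * log(p) + (1 - y) * log1p(-p))

#' Nagelkerke pseudo-R-squared of a fitted binomial glm
#'
#' Max-rescaled Cox-Snell R^2: `(1 - (L0/L1)^(2/n)) / (1 - L0^(2/n))`, with
#' `L0` the likelihood of the intercept-only model. 0 for the null model,
#' 1 for perfect fit.
#'
#' @param fit A fitted `glm` with binomial family.
#' @return Numeric in `[0, 1]`.
#' @export
nagelkerke_r2 <- function(fit) {
  n <- length(fit$y)
  ll1 <- as.numeric(stats::logLik(fit))
  ll0 <- -fit$null.deviance / 2
  cs <- 1 - exp(2 * (ll0 - ll1) / n)
  denom <- 1 - exp(2 * ll0 / n)
  if (denom <= 0) return(0)
  max(0, min(1, cs / denom))
}

# Firth-penalized logistic regression by IRLS with hat-value score
# correction; fallback for complete separation (no logistf in the stack)
firth_logistic <- function(X, y, max_iter = 200, tol = 1e-8) {
  X <- cbind(`(Intercept)` = 1, as.matrix(X))
  beta <- rep(0, ncol(X))
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    p <- stats::plogis(eta)
    W <- p * (1 - p)
    XW <- X * sqrt(W)
    XtWX <- crossprod(XW)
    XtWXinv <- tryCatch(solve(XtWX), error = function(e) NULL)
    if (is.null(XtWXinv)) break
    h <- rowSums((X %*% XtWXinv) * X) * W
    U <- drop(crossprod(X, y - p + h * (0.5 - p)))
    step <- drop(XtWXinv %*% U)
    if (max(abs(step)) > 5) step <- step * 5 / max(abs(step))
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  eta <- drop(X %*% beta)
  p <- stats::plogis(eta)
  W <- p * (1 - p)
  se <- sqrt(diag(solve(crossprod(X * sqrt(W)))))
  list(coef = stats::setNames(beta, colnames(X)),
       se = stats::setNames(se, colnames(X)))
}

fit_is_separated <- function(fit) {
  !fit$converged || any(abs(stats::coef(fit)[-1]) > 15) ||
    any(fit$fitted.values > 1 - 1e-8) && any(fit$fitted.values < 1e-8)
}

#' Univariable logistic screen
#'
#' Fits a univariable binomial logistic model per feature and keeps those
#' with p below `alpha` (Wald test on the slope). Constant features are
#' excluded with a warning; completely separating features are kept (the
#' screen is a keep/drop decision, and separation implies discrimination),
#' with the p-value from a Firth-penalized refit.
#'
#' @param table Data frame of candidate features.
#' @param labels Binary outcome (0/1, logical, or 2-level factor).
#' @param alpha Significance threshold.
#' @return Data frame with `feature`, `p`, `kept`.
#' @export
univariable_screen <- function(table, labels, alpha = 0.05) {
  y <- as_binary(labels)
  if (length(unique(y)) < 2L) stop("need both classes present")
  res <- lapply(names(table), function(nm) {
    x <- table[[nm]]
    if (stats::sd(x) == 0) {
      warning("constant feature excluded: ", nm)
      return(data.frame(feature = nm, p = NA_real_, kept = FALSE))
    }
    fit <- suppressWarnings(stats::glm(y ~ x, family = stats::binomial()))
    if (fit_is_separated(fit)) {
      fr <- firth_logistic(matrix(x, ncol = 1), y)
      z <- fr$coef[2] / fr$se[2]
      p <- 2 * stats::pnorm(-abs(z))
    } else {
      p <- summary(fit)$coefficients[2, 4]
    }
    data.frame(feature = nm, p = p, kept = p < alpha)
  })
  do.call(rbind, res)
}

#' Iterative variance-inflation-factor filter
#'
#' VIF_j = 1 / (1 - R^2_j) from regressing candidate j on the other
#' candidates; while any VIF exceeds the threshold, the largest is dropped
#' and VIFs recomputed. The conventional collinearity screen preceding
#' stepwise logistic selection (threshold 2.5).
#'
#' @param table Data frame of features.
#' @param candidates Character vector of candidate columns.
#' @param threshold VIF threshold.
#' @return List with `retained`, `dropped` and the final `vif` vector.
#' @export
vif_filter <- function(table, candidates, threshold = 2.5) {
  retained <- candidates
  dropped <- character()
  vif_of <- function(vars) {
    vapply(vars, function(v) {
      others <- setdiff(vars, v)
      if (length(others) == 0L) return(1)
      r2 <- suppressWarnings(  # exact collinearity is expected input here
        summary(stats::lm(stats::reformulate(others, response = v),
                          data = table)))$r.squared
      if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
    }, numeric(1))
  }
  while (length(retained) >= 2L) {
    v <- vif_of(retained)
    if (max(v) <= threshold) break
    worst <- names(v)[which.max(v)]
    dropped <- c(dropped, worst)
    retained <- setdiff(retained, worst)
  }
  v <- if (length(retained) >= 2L) vif_of(retained) else
    stats::setNames(rep(1, length(retained)), retained)
  list(retained = retained, dropped = dropped, vif = v)
}

as_binary <- function(labels) {
  if (is.factor(labels)) labels <- as.integer(labels) - 1L
  if (is.character(labels)) labels <- as.integer(factor(labels)) - 1L
  if (is.logical(labels)) labels <- as.integer(labels)
  u <- sort(unique(labels))
  if (length(u) == 2L && !all(u %in% c(0L, 1L)))
    labels <- as.integer(labels == u[2])
  else if (length(u) > 2L)
    stop("labels must have exactly two levels")
  # single-level input passes through; callers report the missing class
  as.integer(labels)
}

#' Stepwise binary logistic regression with forced covariates
#'
#' Forward stepwise selection with backward removal on likelihood-ratio
#' p-values (enter at `p_enter`, remove at `p_remove`; the classical
#' stepwise defaults 0.05/0.10). Covariates are always kept in the model.
#' On complete separation of the final model, coefficients and standard
#' errors come from a Firth-penalized refit (with a warning).
#'
#' @param table Data frame containing candidate features (and covariates).
#' @param labels Binary outcome.
#' @param candidates Candidate feature names (default: all columns not in
#'   `covariates`).
#' @param covariates Character vector of forced-in covariate columns (may
#'   be `NULL`).
#' @param p_enter,p_remove Entry/removal thresholds on LR-test p-values.
#' @return List of class `selection_result`: `selected`, `coefficients`
#'   (data frame with B, SE, OR, CI, p per selected feature),
#'   `nagelkerke_r2`, `trace` (entry/removal order), `fit`.
#' @export
stepwise_logistic <- function(table, labels, candidates = NULL,
                              covariates = NULL,
                              p_enter = 0.05, p_remove = 0.10) {
  y <- as_binary(labels)
  if (is.null(candidates)) candidates <- setdiff(names(table), covariates)
  dat <- cbind(table, .y = y)
  base_terms <- if (length(covariates)) covariates else "1"
  fit_with <- function(terms) {
    f <- stats::reformulate(c(base_terms, terms), response = ".y")
    suppressWarnings(stats::glm(f, family = stats::binomial(), data = dat))
  }
  lr_p <- function(small, big, df = 1) {
    stat <- small$deviance - big$deviance
    stats::pchisq(max(stat, 0), df = df, lower.tail = FALSE)
  }
  current <- character()
  trace <- list()
  repeat {
    changed <- FALSE
    cur_fit <- fit_with(current)
    # forward step
    pool <- setdiff(candidates, current)
    if (length(pool)) {
      pv <- vapply(pool, function(v) lr_p(cur_fit, fit_with(c(current, v))),
                   numeric(1))
      if (min(pv) < p_enter) {
        add <- pool[which.min(pv)]
        current <- c(current, add)
        trace[[length(trace) + 1L]] <- list(action = "enter", feature = add,
                                            p = min(pv))
        changed <- TRUE
      }
    }
    # backward step
    if (length(current)) {
      big <- fit_with(current)
      pv <- vapply(current, function(v)
        lr_p(fit_with(setdiff(current, v)), big), numeric(1))
      if (max(pv) > p_remove) {
        rm_ <- current[which.max(pv)]
        current <- setdiff(current, rm_)
        trace[[length(trace) + 1L]] <- list(action = "remove", feature = rm_,
                                            p = max(pv))
        changed <- TRUE
      }
    }
    if (!changed) break
    if (length(trace) > 4 * (length(candidates) + 1)) break  # cycling guard
  }
  fit <- fit_with(current)
  cf <- summary(fit)$coefficients
  if (fit_is_separated(fit) && length(current)) {
    warning("complete separation: reporting Firth-penalized estimates")
    fr <- firth_logistic(as.matrix(dat[, c(covariates, current), drop = FALSE]),
                         y)
    keep <- intersect(rownames(cf), names(fr$coef))
    cf[keep, 1] <- fr$coef[keep]
    cf[keep, 2] <- fr$se[keep]
    cf[keep, 3] <- cf[keep, 1] / cf[keep, 2]
    cf[keep, 4] <- 2 * stats::pnorm(-abs(cf[keep, 3]))
  }
  rows <- intersect(rownames(cf), current)
  coefs <- data.frame(
    feature = rows,
    B = cf[rows, 1], SE = cf[rows, 2],
    OR = exp(cf[rows, 1]),
    ci_low = exp(cf[rows, 1] - 1.96 * cf[rows, 2]),
    ci_high = exp(cf[rows, 1] + 1.96 * cf[rows, 2]),
    p = cf[rows, 4], row.names = NULL)
  structure(list(selected = current, coefficients = coefs,
                 nagelkerke_r2 = nagelkerke_r2(fit),
                 covariates = covariates, trace = trace, fit = fit),
            class = "selection_result")
}

#' @export
#' @method print selection_result
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> %d feature(s) selected, Nagelkerke R2 = %.3f\n",
              length(x$selected), x$nagelkerke_r2))
  if (nrow(x$coefficients)) {
    df <- x$coefficients
    df$`OR (95% CI)` <- sprintf("%.3f (%.3f-%.3f)", df$OR, df$ci_low,
                                df$ci_high)
    print(df[, c("feature", "B", "SE", "OR (95% CI)", "p")], digits = 3)
  }
  invisible(x)
}

#' Empirical ROC analysis with the Youden-index cutoff
#'
#' Builds the empirical ROC over all thresholds (midpoints between sorted
#' unique score values, plus sentinels), computes the AUC by the
#' trapezoidal rule (equal to the Mann-Whitney U statistic divided by
#' n1*n0), and picks the cutoff maximising Youden's J = sensitivity +
#' specificity - 1. Ties in J are broken toward the cutoff closest to the
#' midpoint of the two class medians. The AUC is reported un-flipped
#' (values below 0.5 indicate that cases score lower; see `direction`),
#' with a p-value against AUC = 0.5 from the normal approximation to U.
#'
#' @param values Numeric scores.
#' @param labels Binary outcome (1 = case).
#' @return List of class `roc_result`: `auc`, `p`, `cutoff`,
#'   `sensitivity`, `specificity`, `youden`, `direction` (`">="` when cases
#'   score higher).
#' @export
roc_youden <- function(values, labels) {
  y <- as_binary(labels)
  if (length(unique(y)) < 2L) stop("need both classes present")
  x1 <- values[y == 1]; x0 <- values[y == 0]
  n1 <- length(x1); n0 <- length(x0)
  # AUC as normalized Mann-Whitney U (handles ties by 1/2)
  r <- rank(c(x1, x0))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  auc <- u / (n1 * n0)
  # normal approximation (with tie correction) against AUC = 0.5
  ties <- table(values)
  tie_term <- sum(ties^3 - ties)
  n <- n0 + n1
  sigma_u <- sqrt(n1 * n0 / 12 * (n + 1 - tie_term / (n * (n - 1))))
  z <- (u - n1 * n0 / 2) / sigma_u
  p <- 2 * stats::pnorm(-abs(z))
  # candidate cutoffs: midpoints between sorted unique values + sentinels
  sv <- sort(unique(values))
  cand <- c(sv[1] - 1, if (length(sv) > 1) (sv[-1] + sv[-length(sv)]) / 2,
            sv[length(sv)] + 1)
  dir_up <- auc >= 0.5   # cases tend to score higher
  sens <- vapply(cand, function(ct)
    if (dir_up) mean(x1 >= ct) else mean(x1 <= ct), numeric(1))
  spec <- vapply(cand, function(ct)
    if (dir_up) mean(x0 < ct) else mean(x0 > ct), numeric(1))
  j <- sens + spec - 1
  best <- which(j >= max(j) - 1e-12)
  if (length(best) > 1L) {
    mid <- (stats::median(x1) + stats::median(x0)) / 2
    best <- best[which.min(abs(cand[best] - mid))]
  }
  structure(list(auc = auc, p = p, cutoff = cand[best],
                 sensitivity = sens[best], specificity = spec[best],
                 youden = j[best],
                 direction = if (dir_up) ">=" else "<="),
            class = "roc_result")
}

#' Full feature-selection pipeline
#'
#' Univariable screen, VIF filter, stepwise logistic selection with forced
#' covariates, and per-selected-feature ROC/Youden cutoffs — the selection
#' report structure used for the classification case definitions.
#'
#' @inheritParams stepwise_logistic
#' @param alpha Univariable screen threshold.
#' @param vif_threshold VIF threshold.
#' @return List with `screen`, `vif`, `selection` and `roc` (list of
#'   [roc_youden()] results per selected feature).
#' @export
select_features <- function(table, labels, covariates = NULL, alpha = 0.05,
                            vif_threshold = 2.5,
                            p_enter = 0.05, p_remove = 0.10) {
  feats <- setdiff(names(table), covariates)
  scr <- univariable_screen(table[feats], labels, alpha = alpha)
  cand <- scr$feature[scr$kept]
  vf <- if (length(cand) >= 2L) vif_filter(table, cand, vif_threshold) else
    list(retained = cand, dropped = character(),
         vif = stats::setNames(rep(1, length(cand)), cand))
  sel <- stepwise_logistic(table, labels, candidates = vf$retained,
                           covariates = covariates,
                           p_enter = p_enter, p_remove = p_remove)
  roc <- lapply(stats::setNames(sel$selected, sel$selected), function(f)
    roc_youden(table[[f]], labels))
  list(screen = scr, vif = vf, selection = sel, roc = roc)
}
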