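#' Blockwise stepwise multivariable linear regression
#'
#' Models a clinical score as a function of turning features after
#' adjustment: block 1 (physical covariates: age, sex, height, BMI) is
#' forced into the model; block 2 (turning features) enters by forward
#' stepwise selection with backward removal on partial-F p-values
#' (defaults 0.05 to enter, 0.10 to remove). Covariates are never removed
#' regardless of significance.
#'
#' @param table Data frame holding the dependent variable, covariates and
#'   candidate features.
#' @param dependent Name of the clinical dependent variable (numeric).
#' @param candidates Names of block-2 candidate features.
#' @param covariates Names of block-1 forced covariates (may be `NULL`).
#' @param p_enter,p_remove Entry/removal thresholds.
#' @return List of class `regression_report`: `selected`, `coefficients`
#'   (term, estimate, SE, t, p), `r_squared`, `trace`, `fit`.
#' @export
stepwise_linear_blocks <- function(table, dependent, candidates,
                                   covariates = c("age", "sex", "height",
                                                  "bmi"),
                                   p_enter = 0.05, p_remove = 0.10) {
  if (!dependent %in% names(table)) stop("dependent variable not in table")
  y <- table[[dependent]]
  if (!is.numeric(y)) stop("dependent variable must be numeric")
  if (stats::sd(y, na.rm = TRUE) == 0) stop("dependent variable is constant")
  keep <- stats::complete.cases(table[c(dependent, covariates, candidates)])
  dat <- table[keep, , drop = FALSE]
  if (nrow(dat) <= length(covariates) + 2)
    stop("too few complete cases for the covariate block")
  base_terms <- if (length(covariates)) covariates else "1"
  fit_with <- function(terms)
    stats::lm(stats::reformulate(c(base_terms, terms), response = dependent),
              data = dat)
  partial_f_p <- function(small, big) {
    a <- stats::anova(small, big)
    a$`Pr(>F)`[2]
  }
  current <- character(); trace <- list()
  repeat {
    changed <- FALSE
    cur <- fit_with(current)
    pool <- setdiff(candidates, current)
    if (length(pool)) {
      pv <- vapply(pool, function(v) partial_f_p(cur, fit_with(c(current, v))),
                   numeric(1))
      if (min(pv, na.rm = TRUE) < p_enter) {
        add <- pool[which.min(pv)]
        current <- c(current, add)
        trace[[length(trace) + 1L]] <- list(action = "enter", term = add,
                                            p = min(pv, na.rm = TRUE))
        changed <- TRUE
      }
    }
    if (length(current)) {
      big <- fit_with(current)
      pv <- vapply(current, function(v)
        partial_f_p(fit_with(setdiff(current, v)), big), numeric(1))
      if (max(pv) > p_remove) {
        rm_ <- current[which.max(pv)]
        current <- setdiff(current, rm_)
        trace[[length(trace) + 1L]] <- list(action = "remove", term = rm_,
                                            p = max(pv))
        changed <- TRUE
      }
    }
    if (!changed) break
    if (length(trace) > 4 * (length(candidates) + 1)) break
  }
  fit <- fit_with(current)
  cf <- summary(fit)$coefficients
  structure(list(
    dependent = dependent, selected = current, covariates = covariates,
    coefficients = data.frame(term = rownames(cf), estimate = cf[, 1],
                              se = cf[, 2], t = cf[, 3], p = cf[, 4],
                              row.names = NULL),
    r_squared = summary(fit)$r.squared, trace = trace, fit = fit),
    class = "regression_report")
}

#' @export
#' @method print regression_report
print.regression_report <- function(x, ...) {
  cat(sprintf("<regression_report> %s ~ [%s] + stepwise(%s); R2 = %.3f\n",
              x$dependent, paste(x$covariates, collapse = ", "),
              paste(x$selected, collapse = ", "), x$r_squared))
  invisible(x)
}

#' Pearson or Spearman correlation with p-value
#'
#' Thin wrapper over [stats::cor.test()] returning the coefficient and the
#' two-sided p-value; errors on zero-variance input instead of returning
#' `NA`.
#'
#' @param x,y Numeric vectors of equal length (>= 3).
#' @param method `"pearson"` or `"spearman"`.
#' @return List with `estimate`, `p`, `method`, `n`.
#' @export
correlate <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in input")
  ct <- suppressWarnings(stats::cor.test(x, y, method = method))
  list(estimate = unname(ct$estimate), p = ct$p.value, method = method,
       n = length(x))
}
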