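test_that("univariable screen keeps discriminative and drops flat features", {
  set.seed(1)
  y <- rep(0:1, each = 40)
  tab <- data.frame(good = rnorm(80) + 1.5 * y,
                    noise = rnorm(80),
                    flat = rep(2, 80),
                    sep = ifelse(y == 1, 10, -10) + rnorm(80, 0, 0.01))
  scr <- suppressWarnings(univariable_screen(tab, y))
  expect_true(scr$kept[scr$feature == "good"])
  expect_false(scr$kept[scr$feature == "flat"])
  expect_true(scr$kept[scr$feature == "sep"])  # separation still kept
  expect_warning(univariable_screen(tab["flat"], y), "constant")
  expect_error(univariable_screen(tab, rep(1, 80)), "both classes")
})

test_that("VIF matches the analytic value for a correlated pair", {
  set.seed(2)
  n <- 4000
  a <- rnorm(n)
  b <- 0.9 * a + sqrt(1 - 0.81) * rnorm(n)
  cc <- rnorm(n)
  tab <- data.frame(a = a, b = b, c = cc)
  r2 <- summary(lm(a ~ b + c, tab))$r.squared
  vf <- vif_filter(tab, c("a", "b", "c"), threshold = 2.5)
  # analytic: VIF of either member ~ 1/(1-0.81) ~ 5.26 > 2.5, one is dropped
  expect_length(vf$dropped, 1L)
  expect_true(vf$dropped %in% c("a", "b"))
  expect_true(all(vf$vif <= 2.5))
  # orthogonal features all survive with VIF ~ 1
  orth <- data.frame(x = rnorm(500), y = rnorm(500), z = rnorm(500))
  vo <- vif_filter(orth, c("x", "y", "z"))
  expect_identical(vo$retained, c("x", "y", "z"))
  expect_true(all(abs(vo$vif - 1) < 0.05))
})

test_that("stepwise logistic recovers a planted effect with honest CI", {
  set.seed(3)
  n <- 500
  x <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("f1", "f2", "f3")))
  y <- rbinom(n, 1, plogis(x[, 1]))  # planted log-OR 1.0 on f1
  sel <- stepwise_logistic(as.data.frame(x), y)
  expect_true("f1" %in% sel$selected)
  cf <- sel$coefficients[sel$coefficients$feature == "f1", ]
  expect_true(log(cf$ci_low) < 1 && 1 < log(cf$ci_high))
  # OR/CI internally consistent with B and SE
  expect_equal(cf$OR, exp(cf$B), tolerance = 1e-12)
  expect_equal(cf$ci_low, exp(cf$B - 1.96 * cf$SE), tolerance = 1e-12)
  expect_equal(cf$ci_high, exp(cf$B + 1.96 * cf$SE), tolerance = 1e-12)
})

test_that("null model has Nagelkerke R2 = 0 and selects nothing", {
  set.seed(4)
  tab <- data.frame(x = rnorm(100))
  sel <- stepwise_logistic(tab, rep(0:1, 50), candidates = "x")
  expect_identical(sel$selected, character(0))
  expect_equal(sel$nagelkerke_r2, 0, tolerance = 1e-9)
})

test_that("forced covariates stay in the model", {
  set.seed(5)
  n <- 200
  tab <- data.frame(age = rnorm(n, 70, 5), feat = rnorm(n))
  y <- rbinom(n, 1, 0.5)
  sel <- stepwise_logistic(tab, y, candidates = "feat", covariates = "age")
  expect_true("age" %in% names(coef(sel$fit)))
})

test_that("ROC: AUC equals the normalized Mann-Whitney U exactly", {
  for (s in 1:25) {
    set.seed(s)
    n1 <- sample(5:30, 1); n0 <- sample(5:30, 1)
    v <- c(rnorm(n1, 0.5), rnorm(n0))
    y <- rep(c(1, 0), c(n1, n0))
    r <- roc_youden(v, y)
    u <- suppressWarnings(wilcox.test(v[y == 1], v[y == 0])$statistic)
    expect_equal(r$auc, unname(u) / (n1 * n0), tolerance = 1e-12)
  }
})

test_that("Youden cutoff matches a brute-force threshold scan", {
  for (s in 1:10) {
    set.seed(s + 100)
    v <- round(rnorm(50), 1)  # ties on purpose
    y <- rbinom(50, 1, plogis(v))
    if (length(unique(y)) < 2) next
    r <- roc_youden(v, y)
    up <- r$direction == ">="
    sv <- sort(unique(v))
    cand <- c(sv[1] - 1, (sv[-1] + sv[-length(sv)]) / 2, sv[length(sv)] + 1)
    j <- vapply(cand, function(ct) {
      if (up) mean(v[y == 1] >= ct) + mean(v[y == 0] < ct) - 1
      else mean(v[y == 1] <= ct) + mean(v[y == 0] > ct) - 1
    }, numeric(1))
    expect_equal(r$youden, max(j), tolerance = 1e-12)
    expect_equal(r$sensitivity + r$specificity - 1, r$youden,
                 tolerance = 1e-12)
  }
})

test_that("ROC endpoints: perfect separation and inversion", {
  r <- roc_youden(c(1, 2, 3, 4), c(0, 0, 1, 1))
  expect_equal(r$auc, 1)
  expect_equal(r$sensitivity, 1)
  expect_equal(r$specificity, 1)
  expect_true(r$cutoff > 2 && r$cutoff <= 3)
  r2 <- roc_youden(c(1, 2, 3, 4), c(1, 1, 0, 0))
  expect_equal(r2$auc, 0)
  expect_identical(r2$direction, "<=")
  expect_error(roc_youden(1:4, rep(1, 4)), "both classes")
})

test_that("select_features wires screen, VIF, stepwise and ROC together", {
  tab <- simulate_feature_table(80, c(strong = 1.8, none = 0), n_noise = 2,
                                seed = 11)
  res <- select_features(tab$features, tab$labels)
  expect_true("strong" %in% res$selection$selected)
  expect_true(all(res$selection$selected %in% names(res$roc)))
  roc1 <- res$roc[["strong"]]
  expect_gt(roc1$auc, 0.8)
})

test_that("selection on exchangeable groups has near-nominal error rates", {
  # univariable screen: 10 noise features at alpha = 0.05 keep ~0.5 on average
  kept <- numeric(100)
  n_sel <- numeric(100)
  for (s in 1:100) {
    set.seed(3000 + s)
    X <- as.data.frame(matrix(rnorm(200 * 10), 200, 10))
    names(X) <- paste0("f", 1:10)
    y <- rep(0:1, each = 100)
    kept[s] <- sum(univariable_screen(X, y)$kept)
    sel <- stepwise_logistic(X[1:5], y)
    n_sel[s] <- length(sel$selected)
  }
  expect_gt(mean(kept), 0.2)
  expect_lt(mean(kept), 0.9)   # nominal expectation alpha * 10 = 0.5
  # stepwise admits a noise feature with probability ~ 1 - 0.95^5 ~ 0.23,
  # i.e. per-candidate error stays near the nominal alpha
  expect_lt(mean(n_sel > 0), 0.40)
  expect_gt(mean(n_sel > 0), 0.08)
})
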