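test_that("standardization is fitted on training rows and applied elsewhere", {
  set.seed(10)
  x <- data.frame(a = rnorm(60, 5, 2), b = runif(60), flag = rbinom(60, 1, 0.5))
  tr <- 1:40
  std <- standardize_fit(x[tr, ])
  expect_setequal(std$cols, c("a", "b"))  # binary columns left alone
  z <- standardize_apply(std, x)
  expect_equal(mean(z$a[tr]), 0, tolerance = 1e-12)
  expect_equal(sd(z$a[tr]), 1, tolerance = 1e-12)
  expect_equal(z$flag, x$flag)
  # test rows transformed with training statistics: mean generally not 0
  expect_gt(abs(mean(z$a[-tr])), 1e-3)
  # idempotence on already-standardized input
  std2 <- standardize_fit(z[tr, ])
  z2 <- standardize_apply(std2, z)
  expect_equal(z2$a, z$a, tolerance = 1e-9)

  x$dead <- 1
  expect_error(standardize_fit(x, cols = c("a", "dead")), "dead")
})

test_that("stratified splits are disjoint, complete and label-balanced", {
  labels <- factor(rep(c("x", "y"), c(60, 171)))
  sp <- split_cohort(labels, seed = 3)
  expect_length(intersect(sp$train, sp$val), 0)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_setequal(c(sp$train, sp$val, sp$test), seq_along(labels))
  frac_tr <- mean(labels[sp$train] == "x")
  expect_true(abs(frac_tr - 60 / 231) <= 0.03)
  expect_identical(sp, split_cohort(labels, seed = 3))
  expect_false(identical(sp$train, split_cohort(labels, seed = 4)$train))
})

test_that("the shrinkage grid covers 1e-3 to 1 and includes 0.03", {
  g <- lasso_alpha_grid()
  expect_true(all(diff(g) < 0))
  expect_equal(max(g), 1)
  expect_equal(min(g), 1e-3)
  expect_true(0.03 %in% g)
})

test_that("LASSO selection spans the no-shrinkage and full-shrinkage limits", {
  set.seed(11)
  n <- 120
  x <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, paste0("f", 1:4)))
  y <- rbinom(n, 1, plogis(x %*% c(1.5, -1.2, 0.9, 1.1)))
  tiny <- lasso_cv_select(x, y, alpha_grid = c(1e-4), seed = 1)
  expect_setequal(tiny$selected_features, colnames(x))
  huge <- expect_message(lasso_cv_select(x, y, alpha_grid = c(5), seed = 1),
                         "no feature survived")
  expect_length(huge$selected_features, 0)
  expect_error(lasso_cv_select(x, rep(1, n)), "two classes")
})

test_that("the selected set shrinks (weakly) as the penalty grows", {
  set.seed(12)
  n <- 150
  x <- matrix(rnorm(n * 20), n, 20, dimnames = list(NULL, paste0("f", 1:20)))
  y <- rbinom(n, 1, plogis(x[, 1:5] %*% rep(1, 5)))
  sizes <- vapply(c(0.001, 0.01, 0.05, 0.2, 0.8), function(a)
    length(lasso_cv_select(x, y, alpha_grid = a, seed = 2)$selected_features),
    numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("feature selection sees only the training rows", {
  set.seed(13)
  co <- gen_cohort(n = 120, seed = 13)
  feats <- c(clinical_cols, aal90_labels()$region[1:30])
  sp <- split_cohort(co$outcome, seed = 13)
  std <- standardize_fit(co[sp$train, feats])
  xs <- standardize_apply(std, co[feats])
  sel1 <- lasso_cv_select(xs[sp$train, feats], co$outcome[sp$train], seed = 5)
  # perturb everything outside the training rows: labels and features
  co2 <- co
  co2$outcome[sp$test] <- rev(co2$outcome[sp$test])
  co2[sp$test, feats] <- co2[sp$test, feats] * 5 + 1
  xs2 <- standardize_apply(std, co2[feats])
  sel2 <- lasso_cv_select(xs2[sp$train, feats], co2$outcome[sp$train], seed = 5)
  expect_identical(sel1$selected_features, sel2$selected_features)
  expect_identical(sel1$alpha, sel2$alpha)
})

test_that("ridge weights rank features and normalize to a unit maximum", {
  expect_equal(as.numeric(ridge_weights(matrix(rnorm(50), 50, 1,
                                               dimnames = list(NULL, "solo")),
                                        rbinom(50, 1, 0.5))), 1)
  set.seed(14)
  n <- 300
  x <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("a", "b", "c")))
  x <- cbind(x, dup = x[, "a"] + rnorm(n, sd = 1e-6))
  y <- rbinom(n, 1, plogis(2 * x[, "a"] + 0.5 * x[, "b"]))
  w <- ridge_weights(x, y, seed = 1)
  expect_equal(max(w), 1)
  expect_true(all(w >= 0 & w <= 1))
  # duplicated predictors share their coefficient under the L2 penalty
  expect_equal(unname(w["a"]), unname(w["dup"]), tolerance = 0.15)
  ws <- ridge_weights(x, y, normalize = "sum", seed = 1)
  expect_equal(sum(ws), 1)
})

test_that("the dominant planted feature receives the top ridge weight", {
  wins <- vapply(1:20, function(s) {
    set.seed(s)
    n <- 300
    x <- matrix(rnorm(n * 6), n, 6, dimnames = list(NULL, paste0("f", 1:6)))
    y <- rbinom(n, 1, plogis(x %*% c(2, rep(0.4, 5))))
    w <- ridge_weights(x, y, seed = s)
    unname(w["f1"]) == 1
  }, logical(1))
  expect_gte(sum(wins), 18)
})

test_that("the nested F-test matches brute-force RSS arithmetic", {
  # 6-point hand dataset, one added regressor
  y <- c(1.2, 2.3, 2.9, 4.1, 5.2, 5.8)
  x1 <- data.frame(a = c(1, 2, 3, 4, 5, 6))
  x2 <- cbind(x1, b = c(0.1, 0.5, 0.2, 0.9, 0.3, 0.8))
  res <- nested_ols_ftest(y, x1, x2)
  rss1 <- sum(resid(lm(y ~ a, x1))^2)
  rss2 <- sum(resid(lm(y ~ a + b, x2))^2)
  f_hand <- ((rss1 - rss2) / (4 - 3)) / (rss2 / 3)
  expect_equal(res$f_stat, f_hand, tolerance = 1e-12)
  expect_equal(res$rss1, rss1); expect_equal(res$rss2, rss2)
  expect_equal(res$df1, 4); expect_equal(res$df2, 3)
  an <- anova(lm(y ~ a, x1), lm(y ~ a + b, x2))
  expect_equal(res$f_stat, an$F[2], tolerance = 1e-10)
  expect_equal(res$p_value, an$`Pr(>F)`[2], tolerance = 1e-10)
})

test_that("non-nested or degenerate designs are refused", {
  y <- rnorm(30)
  x1 <- data.frame(a = rnorm(30))
  x2 <- data.frame(a = rnorm(30), b = rnorm(30))  # same name, new content
  expect_error(nested_ols_ftest(y, x1, x2), "differ in content")
  expect_error(nested_ols_ftest(y, x1, x1), "adds no feature")
  x3 <- cbind(x1, b = x1$a * 2)  # collinear addition
  expect_error(nested_ols_ftest(y, x1, x3), "collinear")
  expect_error(nested_ols_ftest(y, data.frame(z = rnorm(30)), x2), "missing")
})

test_that("the combined model never explains less variance than the clinical one", {
  set.seed(15)
  for (i in 1:8) {
    n <- 80
    x1 <- data.frame(a = rnorm(n), b = rnorm(n))
    x2 <- cbind(x1, c = rnorm(n), d = rnorm(n))
    res <- nested_ols_ftest(rnorm(n), x1, x2)
    expect_gte(res$r2_combined, res$r2_clinical)
    expect_gte(res$f_stat, 0)
  }
})

test_that("motor improvement is the OFF-to-ON percent change", {
  expect_equal(motor_improvement_pct(50, 25), 50)
  expect_equal(motor_improvement_pct(40, 40), 0)
  expect_true(is.na(suppressMessages(motor_improvement_pct(0, 5))))
})
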