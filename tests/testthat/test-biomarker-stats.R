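test_that("BH adjustment equals the literal step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.2), 0.2)                       # m = 1
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  set.seed(8)
  for (i in 1:20) {
    p <- runif(sample(3:40, 1))
    expect_equal(bh_adjust(p), brute_bh(p))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("two-group comparison matches a hand-computed t-test", {
  # two points per group: Welch t reduces to a closed form
  a <- c(1, 3); b <- c(6, 10)
  g <- group_compare(data.frame(r1 = a), data.frame(r1 = b))
  se <- sqrt(var(a) / 2 + var(b) / 2)
  expect_equal(g$t_stat, (mean(a) - mean(b)) / se)
  df <- se^4 / ((var(a) / 2)^2 / 1 + (var(b) / 2)^2 / 1)
  expect_equal(g$p_raw, 2 * pt(-abs(g$t_stat), df))
  expect_equal(g$cohens_d, (mean(a) - mean(b)) /
                 sqrt((var(a) + var(b)) / 2))
  expect_equal(g$direction, "lower_in_PD")
})

test_that("group comparison is antisymmetric and null on identical groups", {
  cc <- gen_case_control_fd(n_per_group = 12, seed = 4)
  fwd <- group_compare(cc$pd, cc$hc)
  rev <- group_compare(cc$hc, cc$pd)
  expect_equal(fwd$t_stat, -rev$t_stat)
  expect_equal(fwd$p_raw, rev$p_raw)
  expect_true(all(fwd$direction != rev$direction |
                    fwd$t_stat == 0))

  same <- group_compare(cc$pd, cc$pd)
  expect_true(all(same$t_stat == 0))
  expect_true(all(same$cohens_d == 0))
  expect_false(any(same$significant))

  expect_error(group_compare(cc$pd, cc$hc[, 1:10]), "differ")
})

test_that("planted case-control effects are recovered region-wise", {
  cc <- gen_case_control_fd(n_per_group = 70, effect_d = 1.2, seed = 3)
  g <- group_compare(cc$pd, cc$hc)
  planted <- names(default_affected_regions())
  hits <- g$region[g$significant]
  expect_gte(sum(planted %in% hits), 8)
  expect_lte(sum(!hits %in% planted), 5)
  # directions follow the planted signs
  sub <- g[g$region %in% planted & g$significant, ]
  expect_true(all(sign(sub$cohens_d) ==
                    default_affected_regions()[sub$region]))
})

test_that("Anderson-Darling check flags non-normal residuals", {
  set.seed(5)
  expect_false(check_normality(runif(500))$normal)
  gauss <- check_normality(rnorm(500))
  expect_true(is.finite(gauss$ad_stat))
  expect_equal(nrow(gauss$qq_points), 500)
  expect_equal(gauss$qq_points$sample, sort(gauss$qq_points$sample))
  expect_error(check_normality(rep(1, 50)), "constant")
  expect_error(check_normality(rnorm(5)), "at least 8")
})

test_that("motor totals exclude rigidity and postural-stability items", {
  sheet <- data.frame("3.1" = c(2, 1), "3.2" = c(1, 0),
                      "3.3a" = c(3, 2), "3.3b" = c(2, 2),
                      "3.12" = c(4, 1), "3.17" = c(1, 2),
                      check.names = FALSE)
  expect_equal(motor_total(sheet), c(2 + 1 + 1, 1 + 0 + 2))
  expect_equal(motor_total(sheet, exclude_items = character(0)),
               rowSums(sheet))
  expect_error(motor_total(sheet[, c("3.3a", "3.12"), drop = FALSE]),
               "no items left")
})

test_that("severity regression recovers a noise-free planted slope exactly", {
  set.seed(6)
  n <- 40
  fd <- rnorm(n, 2.3, 0.1); age <- rnorm(n, 65, 9); sex <- rbinom(n, 1, 0.4)
  y <- 10 + 25 * fd + 0.2 * age + 3 * sex
  row <- severity_regression(fd, y, age, sex, med_state = "OFF")
  expect_equal(row$coef, 25, tolerance = 1e-8)
  expect_lt(row$ci_high - row$ci_low, 1e-6)
  expect_equal(row$med_state, "OFF")
})

test_that("severity regression is calibrated under planted signal and null", {
  set.seed(7)
  est <- replicate(400, {
    n <- 231
    fd <- rnorm(n); age <- rnorm(n); sex <- rbinom(n, 1, 0.33)
    y <- 0.15 * fd + 0.1 * age + rnorm(n)
    r <- severity_regression(fd, y, age, sex)
    c(r$coef, r$ci_low <= 0.15 && 0.15 <= r$ci_high)
  })
  expect_true(abs(mean(est[1, ]) - 0.15) <= 0.03)
  expect_true(abs(mean(est[2, ]) - 0.95) <= 0.03)  # CI coverage

  rej <- replicate(400, {
    n <- 231
    r <- severity_regression(rnorm(n), rnorm(n), rnorm(n),
                             rbinom(n, 1, 0.33))
    r$p_raw < 0.05
  })
  expect_true(abs(mean(rej) - 0.05) <= 0.03)
})

test_that("severity regression rejects degenerate designs", {
  fd <- rnorm(20)
  expect_error(severity_regression(fd, rnorm(20), fd, rbinom(20, 1, 0.5)),
               "rank-deficient")
  expect_error(severity_regression(rnorm(4), rnorm(4), rnorm(4), c(0, 1, 0, 1)),
               "too few")
})

test_that("the severity scan runs one model per region and state", {
  co <- gen_cohort(n = 60, seed = 9)
  fd <- co[, aal90_labels()$region[1:12]]
  clin <- data.frame(motor_off = co$motor_off, motor_on = co$motor_on,
                     age = co$age, sex = co$sex)
  scan <- severity_scan(fd, clin)
  expect_equal(nrow(scan), 24)  # 12 regions x OFF/ON
  expect_true(all(scan$p_adj >= scan$p_raw - 1e-12))
  expect_true(all(scan$ci_low <= scan$coef & scan$coef <= scan$ci_high))
  expect_true(all(abs(scan$partial_r) <= 1))
})
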