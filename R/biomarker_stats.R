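#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment (delegates to
#' [stats::p.adjust()] with `method = "BH"` after validating the input).
#'
#' @param p numeric vector of raw p-values in `[0, 1]`.
#' @return adjusted p-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  p <- as.numeric(p)
  if (anyNA(p) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}

#' Anderson-Darling normality check
#'
#' Used on regression residuals before relying on t-based inference.
#' Returns the Anderson-Darling statistic, its p-value, the decision at the
#' requested level, and the ordered quantile pairs for a QQ plot.
#'
#' @param residuals numeric vector, n >= 8, non-constant.
#' @param alpha significance level for the normality decision.
#' @return list: `ad_stat`, `p`, `normal` (logical, `p > alpha`),
#'   `qq_points` data.frame(theoretical, sample).
#' @export
check_normality <- function(residuals, alpha = 0.05) {
  x <- as.numeric(residuals)
  if (length(x) < 8L)
    stop("need at least 8 observations for the Anderson-Darling test",
         call. = FALSE)
  if (stats::sd(x) == 0)
    stop("residuals are constant (zero variance)", call. = FALSE)
  ad <- nortest::ad.test(x)
  n <- length(x)
  qq <- data.frame(
    theoretical = stats::qnorm(stats::ppoints(n)),
    sample = sort((x - mean(x)) / stats::sd(x)))
  list(ad_stat = unname(ad$statistic), p = ad$p.value,
       normal = ad$p.value > alpha, qq_points = qq)
}

#' Cohen's d with pooled standard deviation
#'
#' @param x,y numeric samples (each n >= 2).
#' @return standardized mean difference `(mean(x) - mean(y)) / s_pooled`.
#' @export
cohens_d <- function(x, y) {
  nx <- length(x); ny <- length(y)
  stopifnot(nx >= 2L, ny >= 2L)
  sp <- sqrt(((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) /
               (nx + ny - 2))
  if (sp == 0) return(0)
  (mean(x) - mean(y)) / sp
}

#' Region-wise case-control comparison of FD
#'
#' Two-sided t-tests (Welch by default) comparing every regional FD column
#' between a patient and a control table, with Benjamini-Hochberg
#' adjustment across the region family and pooled-SD Cohen's d.
#'
#' @param fd_pd,fd_hc data.frames of regional FD (identical region column
#'   sets; a `subject_id` column, if present, is ignored). Each group needs
#'   >= 2 subjects.
#' @param var_equal `FALSE` (default) for Welch's t-test; `TRUE` for
#'   Student's.
#' @param alpha adjusted-significance threshold recorded in `significant`.
#' @return data.frame: `region`, `t_stat`, `p_raw`, `p_adj`, `cohens_d`,
#'   `direction` (`higher_in_PD` / `lower_in_PD`), `significant`.
#' @export
group_compare <- function(fd_pd, fd_hc, var_equal = FALSE, alpha = 0.05) {
  drop_id <- function(d) d[, setdiff(names(d), "subject_id"), drop = FALSE]
  a <- drop_id(as.data.frame(fd_pd))
  b <- drop_id(as.data.frame(fd_hc))
  if (!setequal(names(a), names(b)))
    stop("region sets differ between the two groups", call. = FALSE)
  b <- b[names(a)]
  if (nrow(a) < 2L || nrow(b) < 2L)
    stop("need >= 2 subjects per group", call. = FALSE)
  rows <- lapply(names(a), function(r) {
    tt <- stats::t.test(a[[r]], b[[r]], var.equal = var_equal)
    d <- cohens_d(a[[r]], b[[r]])
    data.frame(region = r, t_stat = unname(tt$statistic),
               p_raw = tt$p.value, cohens_d = d,
               direction = if (d >= 0) "higher_in_PD" else "lower_in_PD",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- bh_adjust(out$p_raw)
  out$significant <- out$p_adj < alpha
  out[c("region", "t_stat", "p_raw", "p_adj", "cohens_d", "direction",
        "significant")]
}

#' Motor-exam total excluding rigidity and postural-stability items
#'
#' Totals an MDS-UPDRS part III score sheet while dropping the rigidity
#' (3.3) and postural-stability (3.12) items, as appropriate for exams
#' performed virtually where those items cannot be assessed.
#'
#' @param items data.frame of per-item scores; column names carry the item
#'   codes (e.g. `"3.1"`, `"3.3a"`, ..., `"3.18"`).
#' @param exclude_items item-code prefixes to drop before totalling.
#' @return numeric vector of per-row totals.
#' @export
motor_total <- function(items, exclude_items = c("3.3", "3.12")) {
  stopifnot(is.data.frame(items), ncol(items) >= 1L)
  drop <- Reduce(`|`, lapply(exclude_items, function(code) {
    nm <- names(items)
    nm == code | startsWith(nm, paste0(code, ".")) |
      grepl(paste0("^", gsub("\\.", "\\\\.", code), "[a-z]$"), nm)
  }), accumulate = FALSE, init = rep(FALSE, ncol(items)))
  keep <- names(items)[!drop]
  if (length(keep) == 0L) stop("no items left after exclusion", call. = FALSE)
  rowSums(items[, keep, drop = FALSE])
}

#' Covariate-adjusted FD-severity regression for one region
#'
#' OLS of the motor score on the region's FD with age and sex as
#' covariates. Reports the raw FD coefficient with its t-based 95% CI and
#' p-value, the standardized FD coefficient, and the partial correlation of
#' FD with severity given the covariates (both candidates for a reported
#' "R"; they are labelled explicitly).
#'
#' @param fd regional FD values.
#' @param motor_scores severity proxy (e.g. [motor_total()] of the
#'   preoperative exam).
#' @param age,sex covariates; `sex` coded 0/1.
#' @param med_state `"OFF"` or `"ON"`, recorded in the output.
#' @param conf_level CI level.
#' @return one-row data.frame: `med_state`, `coef`, `se`, `p_raw`,
#'   `ci_low`, `ci_high`, `std_coef`, `partial_r`, `n`.
#' @export
severity_regression <- function(fd, motor_scores, age, sex,
                                med_state = c("OFF", "ON"),
                                conf_level = 0.95) {
  med_state <- match.arg(med_state)
  df <- data.frame(y = as.numeric(motor_scores), fd = as.numeric(fd),
                   age = as.numeric(age), sex = as.numeric(sex))
  df <- df[stats::complete.cases(df), , drop = FALSE]
  p_predictors <- 3L
  if (nrow(df) <= p_predictors + 2L)
    stop("too few observations for the severity regression", call. = FALSE)
  fit <- stats::lm(y ~ fd + age + sex, data = df)
  if (fit$rank < p_predictors + 1L)
    stop("rank-deficient design (collinear predictors)", call. = FALSE)
  sm <- summary(fit)
  co <- sm$coefficients["fd", ]
  ci <- stats::confint(fit, "fd", level = conf_level)
  # standardized coefficient and partial correlation given age + sex
  std_coef <- unname(co["Estimate"]) * stats::sd(df$fd) / stats::sd(df$y)
  tval <- unname(co["t value"])
  df_res <- fit$df.residual
  partial_r <- tval / sqrt(tval^2 + df_res)
  data.frame(med_state = med_state, coef = unname(co["Estimate"]),
             se = unname(co["Std. Error"]), p_raw = unname(co["Pr(>|t|)"]),
             ci_low = ci[1], ci_high = ci[2], std_coef = std_coef,
             partial_r = partial_r, n = nrow(df),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' FD-severity scan over all regions and both medication states
#'
#' Runs [severity_regression()] for every regional FD column against the
#' OFF- and ON-medication motor totals (one model per region x state,
#' 180 models for a 90-region table) and adjusts p-values over the whole
#' family with Benjamini-Hochberg.
#'
#' @param fd data.frame of regional FD columns (plus optional
#'   `subject_id`).
#' @param clinical data.frame with `motor_off`, `motor_on`, `age`, `sex`
#'   aligned row-wise with `fd`.
#' @param alpha adjusted-significance threshold.
#' @return data.frame with one row per region x state:
#'   [severity_regression()] columns plus `region`, `p_adj`, `significant`.
#' @export
severity_scan <- function(fd, clinical, alpha = 0.05) {
  stopifnot(all(c("motor_off", "motor_on", "age", "sex") %in%
                  names(clinical)))
  regions <- setdiff(names(fd), "subject_id")
  rows <- list()
  for (r in regions) {
    for (state in c("OFF", "ON")) {
      y <- if (state == "OFF") clinical$motor_off else clinical$motor_on
      row <- severity_regression(fd[[r]], y, clinical$age, clinical$sex,
                                 med_state = state)
      row$region <- r
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  out$p_adj <- bh_adjust(out$p_raw)
  out$significant <- out$p_adj < alpha
  out[c("region", "med_state", "coef", "se", "p_raw", "p_adj", "ci_low",
        "ci_high", "std_coef", "partial_r", "n", "significant")]
}
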