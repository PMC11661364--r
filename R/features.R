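#' Percent preoperative motor improvement
#'
#' `100 * (OFF - ON) / OFF`: the percent improvement in the motor exam from
#' the OFF- to the ON-medication state, the standard measure of
#' preoperative levodopa responsiveness. Subjects with an OFF score of 0
#' yield `NA` (and should be excluded upstream).
#'
#' @param motor_off,motor_on motor totals in the two medication states.
#' @return percent improvement (positive = better on medication).
#' @export
motor_improvement_pct <- function(motor_off, motor_on) {
  out <- ifelse(motor_off == 0, NA_real_,
                100 * (motor_off - motor_on) / motor_off)
  if (anyNA(out))
    message(sprintf("motor_improvement_pct: %d subject(s) with OFF score 0 set to NA",
                    sum(is.na(out))))
  out
}

#' Fit a standardization transform on training rows
#'
#' Continuous features are centred and scaled to mean 0 / SD 1 using
#' statistics from the training rows only; the same transform is then
#' applied to validation and test rows so no information leaks across the
#' split.
#'
#' @param x data.frame or matrix of features (training rows).
#' @param cols columns to standardize; default = all numeric columns with
#'   more than two distinct values (binary 0/1 encodings are left alone).
#' @return object of class `standardizer` (per-column `mean`, `sd`,
#'   `cols`).
#' @export
standardize_fit <- function(x, cols = NULL) {
  x <- as.data.frame(x)
  if (is.null(cols)) {
    cols <- names(x)[vapply(x, function(v)
      is.numeric(v) && length(unique(v)) > 2L, logical(1))]
  }
  mu <- vapply(x[cols], mean, numeric(1))
  sd <- vapply(x[cols], stats::sd, numeric(1))
  if (any(sd == 0))
    stop(sprintf("zero-variance column(s): %s",
                 paste(cols[sd == 0], collapse = ", ")), call. = FALSE)
  structure(list(mean = mu, sd = sd, cols = cols), class = "standardizer")
}

#' Apply a fitted standardization transform
#'
#' @param object a `standardizer` from [standardize_fit()].
#' @param x data.frame with at least the fitted columns.
#' @return `x` with the fitted columns replaced by z-scores.
#' @export
standardize_apply <- function(object, x) {
  stopifnot(inherits(object, "standardizer"))
  x <- as.data.frame(x)
  for (cn in object$cols)
    x[[cn]] <- (x[[cn]] - object$mean[[cn]]) / object$sd[[cn]]
  x
}

#' Stratified train/validation/test split
#'
#' Seeded stratified shuffle into ~70/15/15 fractions (by default),
#' preserving the class mix of `labels` in every part.
#'
#' @param labels outcome labels (factor or vector) of length n.
#' @param fractions length-3 positive fractions summing to 1.
#' @param seed integer RNG seed.
#' @return list of integer index vectors `train`, `val`, `test`
#'   (disjoint, covering `1:n`).
#' @export
split_cohort <- function(labels, fractions = c(0.70, 0.15, 0.15),
                         seed = 1L) {
  stopifnot(length(fractions) == 3L, all(fractions > 0),
            abs(sum(fractions) - 1) < 1e-8)
  labels <- as.factor(labels)
  n <- length(labels)
  parts <- list(train = integer(0), val = integer(0), test = integer(0))
  set.seed(seed)
  for (lev in levels(labels)) {
    idx <- sample(which(labels == lev))
    m <- length(idx)
    n_tr <- round(fractions[1] * m)
    n_va <- round(fractions[2] * m)
    n_tr <- min(n_tr, m); n_va <- min(n_va, m - n_tr)
    parts$train <- c(parts$train, idx[seq_len(n_tr)])
    parts$val <- c(parts$val, idx[n_tr + seq_len(n_va)])
    parts$test <- c(parts$test, idx[setdiff(seq_len(m),
                                            seq_len(n_tr + n_va))])
  }
  lapply(parts, sort)
}

#' Default LASSO shrinkage grid
#'
#' Logarithmic grid of 25 shrinkage factors over `[1e-3, 1]`, with 0.03
#' included explicitly.
#'
#' @return decreasing numeric vector (as glmnet expects).
#' @export
lasso_alpha_grid <- function() {
  g <- sort(unique(c(10^seq(-3, 0, length.out = 25), 0.03)),
            decreasing = TRUE)
  g
}

make_stratified_folds <- function(labels, nfolds, seed) {
  labels <- as.factor(labels)
  fold <- integer(length(labels))
  set.seed(seed)
  for (lev in levels(labels)) {
    idx <- sample(which(labels == lev))
    fold[idx] <- rep_len(seq_len(nfolds), length(idx))
  }
  fold
}

#' LASSO feature selection tuned by cross-validated ROC AUC
#'
#' Fits an L1-penalized model over a grid of shrinkage factors, scores each
#' factor by mean held-out ROC AUC under stratified 5-fold
#' cross-validation, picks the factor with the best AUC, refits on the full
#' training set at that factor and returns the features with nonzero
#' coefficients. The default `loss = "binomial"` pairs the L1 selector with
#' the classification AUC it is scored by; `loss = "gaussian"` selects
#' against the continuous outcome instead (AUC is still computed from the
#' fitted scores against `labels`).
#'
#' @param x numeric matrix/data.frame of standardized training features.
#' @param y outcome used for fitting: binary labels (binomial) or a
#'   continuous outcome (gaussian).
#' @param labels binary labels used for AUC scoring; defaults to `y`.
#' @param alpha_grid shrinkage factors (glmnet `lambda`); default
#'   [lasso_alpha_grid()].
#' @param nfolds,seed cross-validation folds and RNG seed.
#' @param loss `"binomial"` (default) or `"gaussian"`.
#' @return object of class `selection_result`: `alpha` (chosen factor),
#'   `selected_features`, `cv_auc_by_alpha` (data.frame `alpha`, `auc`),
#'   `coef` (named coefficients at the chosen factor), `loss`, `seed`.
#' @export
lasso_cv_select <- function(x, y, labels = NULL,
                            alpha_grid = lasso_alpha_grid(),
                            nfolds = 5L, seed = 1L,
                            loss = c("binomial", "gaussian")) {
  loss <- match.arg(loss)
  x <- as.matrix(x)
  if (is.null(labels)) labels <- y
  lab <- as.integer(as.factor(labels)) - 1L
  if (length(unique(lab)) != 2L)
    stop("labels must contain exactly two classes", call. = FALSE)
  yfit <- if (loss == "binomial") lab else as.numeric(y)
  alpha_grid <- sort(as.numeric(alpha_grid), decreasing = TRUE)
  fold <- make_stratified_folds(lab, nfolds, seed)
  auc_mat <- matrix(NA_real_, nrow = nfolds, ncol = length(alpha_grid))
  for (f in seq_len(nfolds)) {
    tr <- fold != f
    if (length(unique(lab[!tr])) < 2L || length(unique(lab[tr])) < 2L)
      stop("a fold lost one of the classes; use stratified labels",
           call. = FALSE)
    fit <- glmnet::glmnet(x[tr, , drop = FALSE], yfit[tr],
                          family = loss, lambda = alpha_grid,
                          standardize = FALSE)
    pred <- stats::predict(fit, x[!tr, , drop = FALSE], type = "link",
                           exact = FALSE)
    for (j in seq_len(ncol(pred)))
      auc_mat[f, j] <- auc_score(pred[, j], lab[!tr])
  }
  mean_auc <- colMeans(auc_mat)
  # ties broken toward the larger shrinkage factor (sparser model)
  best <- which(mean_auc == max(mean_auc))[1]
  alpha <- alpha_grid[best]
  full <- glmnet::glmnet(x, yfit, family = loss, lambda = alpha_grid,
                         standardize = FALSE)
  beta <- as.matrix(stats::coef(full))[, best]
  beta <- beta[setdiff(names(beta), "(Intercept)")]
  selected <- names(beta)[beta != 0]
  if (length(selected) == 0L)
    message("lasso_cv_select: no feature survived the chosen shrinkage")
  structure(list(alpha = alpha, selected_features = selected,
                 cv_auc_by_alpha = data.frame(alpha = alpha_grid,
                                              auc = mean_auc),
                 coef = beta, loss = loss, seed = seed),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> %d feature(s) at shrinkage %.4g (CV AUC %.3f, %s loss)\n",
              length(x$selected_features), x$alpha,
              max(x$cv_auc_by_alpha$auc), x$loss))
  invisible(x)
}

#' Ridge-derived feature weights
#'
#' L2-penalized (ridge) fit on the selected features; the absolute
#' coefficients, scaled so the largest equals 1, serve as per-feature
#' hyperedge weights expressing relative importance. The penalty is chosen
#' by cross-validation unless given.
#'
#' @param x matrix/data.frame of the selected (standardized) features.
#' @param y binary labels (binomial loss) or continuous outcome
#'   (gaussian).
#' @param lambda ridge penalty; `NULL` = pick by 5-fold [glmnet::cv.glmnet()].
#' @param normalize `"max"` (default): `|beta| / max|beta|`, giving weights
#'   in (0, 1] with maximum 1; `"sum"`: `|beta| / sum|beta|`.
#' @param loss `"binomial"` or `"gaussian"`.
#' @param seed RNG seed for the CV fold draw.
#' @return named numeric weights (one per column of `x`), attribute
#'   `lambda`.
#' @export
ridge_weights <- function(x, y, lambda = NULL,
                          normalize = c("max", "sum"),
                          loss = c("binomial", "gaussian"), seed = 1L) {
  normalize <- match.arg(normalize)
  loss <- match.arg(loss)
  x <- as.matrix(x)
  if (ncol(x) < 1L) stop("need at least one selected feature", call. = FALSE)
  yfit <- if (loss == "binomial") as.integer(as.factor(y)) - 1L
  else as.numeric(y)
  if (ncol(x) == 1L) {
    w <- stats::setNames(1, colnames(x))
    attr(w, "lambda") <- NA_real_
    return(w)
  }
  if (is.null(lambda)) {
    set.seed(seed)
    cv <- glmnet::cv.glmnet(x, yfit, family = loss, alpha = 0,
                            nfolds = 5, standardize = FALSE)
    lambda <- cv$lambda.min
  }
  fit <- glmnet::glmnet(x, yfit, family = loss, alpha = 0,
                        lambda = lambda, standardize = FALSE)
  beta <- abs(as.matrix(stats::coef(fit))[-1, 1])
  w <- switch(normalize,
              max = beta / max(beta),
              sum = beta / sum(beta))
  attr(w, "lambda") <- lambda
  w
}

#' Nested-model variance analysis (F-test)
#'
#' Fits two OLS models of the same outcome — a clinical-features model and
#' a combined model whose design strictly contains the clinical one — and
#' tests whether the additional features significantly improve the fit:
#' `F = ((RSS1 - RSS2) / (df1 - df2)) / (RSS2 / df2)` with `RSS_i` the
#' residual sums of squares and `df_i` the residual degrees of freedom of
#' the reduced (1) and full (2) model.
#'
#' @param y outcome vector.
#' @param x_clinical design matrix/data.frame of the reduced model (no
#'   intercept column; one is added).
#' @param x_combined design of the full model; must contain every clinical
#'   column plus at least one more.
#' @return object of class `variance_result`: `r2_clinical`,
#'   `r2_combined`, `rss1`, `rss2`, `df1`, `df2`, `f_stat`, `p_value`.
#' @export
nested_ols_ftest <- function(y, x_clinical, x_combined) {
  y <- as.numeric(y)
  x1 <- as.matrix(as.data.frame(x_clinical))
  x2 <- as.matrix(as.data.frame(x_combined))
  if (!all(colnames(x1) %in% colnames(x2)))
    stop("designs are not nested: clinical columns missing from combined",
         call. = FALSE)
  if (!isTRUE(all.equal(unname(x2[, colnames(x1), drop = FALSE]),
                        unname(x1))))
    stop("designs are not nested: shared columns differ in content",
         call. = FALSE)
  if (ncol(x2) <= ncol(x1))
    stop("not strictly nested: the combined model adds no feature",
         call. = FALSE)
  if (length(y) <= ncol(x2) + 1L)
    stop("too few observations for the combined model", call. = FALSE)
  fit1 <- stats::lm.fit(cbind(`(Intercept)` = 1, x1), y)
  fit2 <- stats::lm.fit(cbind(`(Intercept)` = 1, x2), y)
  rss1 <- sum(fit1$residuals^2)
  rss2 <- sum(fit2$residuals^2)
  df1 <- length(y) - fit1$rank
  df2 <- length(y) - fit2$rank
  if (df1 == df2)
    stop("not strictly nested: added columns are collinear with the clinical design",
         call. = FALSE)
  ss_tot <- sum((y - mean(y))^2)
  f_stat <- ((rss1 - rss2) / (df1 - df2)) / (rss2 / df2)
  structure(list(r2_clinical = 1 - rss1 / ss_tot,
                 r2_combined = 1 - rss2 / ss_tot,
                 rss1 = rss1, rss2 = rss2, df1 = df1, df2 = df2,
                 f_stat = f_stat,
                 p_value = stats::pf(f_stat, df1 - df2, df2,
                                     lower.tail = FALSE)),
            class = "variance_result")
}

#' @export
print.variance_result <- function(x, ...) {
  cat(sprintf(
    "<variance_result> R2 %.3f -> %.3f; F(%d, %d) = %.3f, p = %.3g\n",
    x$r2_clinical, x$r2_combined, x$df1 - x$df2, x$df2, x$f_stat,
    x$p_value))
  invisible(x)
}
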