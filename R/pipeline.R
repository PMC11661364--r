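#' Assemble a run configuration
#'
#' Central configuration for the end-to-end runs. Accepts a YAML file path
#' or a list; anything not supplied falls back to the defaults below. All
#' seeds and choices are recorded in the emitted manifest so a report can
#' be regenerated exactly.
#'
#' @param config `NULL`, a list, or a path to a YAML file.
#' @return list of class `run_config`: `seed`, `fractions` (train/val/test,
#'   summing to 1), `alpha` (significance level), `k`, `tune_k` (logical),
#'   `k_grid`, `hgnn` (an [hgnn_config()]), `lasso_loss`.
#' @export
run_config <- function(config = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config)) config <- list()
  defaults <- list(seed = 1L, fractions = c(0.70, 0.15, 0.15),
                   alpha = 0.05, k = 12L, tune_k = FALSE, k_grid = 5:13,
                   lasso_loss = "binomial", hgnn = list())
  cfg <- utils::modifyList(defaults, config)
  if (abs(sum(cfg$fractions) - 1) > 1e-8)
    stop("split fractions must sum to 1", call. = FALSE)
  hg_args <- cfg$hgnn
  hg_args$k <- cfg$k
  if (is.null(hg_args$seed)) hg_args$seed <- cfg$seed
  cfg$hgnn <- do.call(hgnn_config, hg_args)
  structure(cfg, class = "run_config")
}

clinical_features <- function() {
  c("age", "sex", "target_stn", "bilateral", "motor_improvement_pct")
}

run_manifest <- function(config, extra = list()) {
  c(list(package = "fdbs",
         version = as.character(utils::packageVersion("fdbs")),
         r_version = paste(R.version$major, R.version$minor, sep = "."),
         seed = config$seed,
         fractions = config$fractions, alpha = config$alpha,
         k = config$k, tune_k = config$tune_k,
         hgnn = unclass(config$hgnn), lasso_loss = config$lasso_loss),
    extra)
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tables <- Filter(is.data.frame, report)
  for (nm in names(tables))
    utils::write.csv(tables[[nm]],
                     file.path(out_dir, paste0(nm, ".csv")),
                     row.names = FALSE)
  scalars <- Filter(function(x) !is.data.frame(x) &&
                      !inherits(x, "hgnn_fit"), report)
  jsonlite::write_json(scalars, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       pretty = TRUE)
  yaml::write_yaml(report$manifest, file.path(out_dir, "manifest.yaml"))
  invisible(out_dir)
}

#' Biomarker-validation run: case-control FD comparison + classifier
#'
#' Executes the validation arm end to end: per-region normality check of
#' the two-group residuals, region-wise case-control comparison with BH
#' adjustment, and — when significant regions exist — a PD-vs-HC HGNN
#' classifier on the significant FD features (ridge weights recomputed on
#' the training split of this task).
#'
#' @param fd_pd,fd_hc regional FD tables (`subject_id` + region columns).
#' @param config a [run_config()] (or list / YAML path coerced through
#'   it).
#' @param out_dir optional directory for the CSV/JSON report + manifest.
#' @return list of class `validation_report`: `comparison` (the
#'   [group_compare()] table), `significant_regions`, `normality`
#'   (per-region Anderson-Darling p on pooled within-group residuals),
#'   `classifier` ([train_hgnn()] fit or `NULL`), `metrics`, `manifest`.
#' @export
run_biomarker_validation <- function(fd_pd, fd_hc, config = run_config(),
                                     out_dir = NULL) {
  if (!inherits(config, "run_config")) config <- run_config(config)
  comparison <- group_compare(fd_pd, fd_hc, alpha = config$alpha)
  sig <- comparison$region[comparison$significant]
  drop_id <- function(d) d[, setdiff(names(d), "subject_id"), drop = FALSE]
  a <- drop_id(fd_pd); b <- drop_id(fd_hc)
  normality <- data.frame(
    region = names(a),
    ad_p = vapply(names(a), function(r) {
      resid <- c(a[[r]] - mean(a[[r]]), b[[r]] - mean(b[[r]]))
      check_normality(resid)$p
    }, numeric(1)), row.names = NULL)
  classifier <- NULL
  metrics <- NULL
  if (length(sig) >= 1L) {
    x_all <- rbind(a[sig], b[sig])
    labels <- factor(rep(c("PD", "HC"), c(nrow(a), nrow(b))),
                     levels = c("HC", "PD"))  # positive class = PD
    splits <- split_cohort(labels, config$fractions, seed = config$seed)
    std <- standardize_fit(x_all[splits$train, , drop = FALSE])
    xs <- standardize_apply(std, x_all)
    w <- if (length(sig) > 1L)
      ridge_weights(xs[splits$train, , drop = FALSE],
                    labels[splits$train], seed = config$seed)
    else stats::setNames(1, sig)
    hg <- build_feature_hypergraphs(xs, k = config$hgnn$k, weights = w)
    classifier <- train_hgnn(hg, as.matrix(xs), labels, splits,
                             config$hgnn)
    metrics <- classifier$metrics
  }
  report <- list(comparison = comparison,
                 significant_regions = sig,
                 normality = normality,
                 classifier = classifier,
                 metrics = metrics,
                 manifest = run_manifest(config,
                                         list(task = "biomarker_validation",
                                              n_pd = nrow(a),
                                              n_hc = nrow(b))))
  class(report) <- "validation_report"
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' Outcome-prediction run: selection, variance analysis, HGNN gap
#'
#' The full outcome arm on one cohort table: stratified 70/15/15 split;
#' standardization fitted on the training rows; LASSO selection tuned by
#' cross-validated AUC on the training rows only; ridge feature weights;
#' nested-model variance analysis of the percent LEDD change (clinical vs
#' clinical + selected FD, training rows); hypergraph construction over
#' all subjects; optional selection of k by validation AUC; HGNN training
#' of the clinical-only and combined models and their test-set comparison.
#'
#' @param cohort data.frame as produced by [gen_cohort()] (clinical
#'   columns, 90 FD columns, `delta_ledd_pct`, `outcome`).
#' @param config a [run_config()].
#' @param out_dir optional directory for the CSV/JSON report + manifest.
#' @return list of class `prediction_report`: `selection`
#'   ([lasso_cv_select()] result), `ridge_weights`, `variance`
#'   ([nested_ols_ftest()] result), `k_search` (or `NULL`),
#'   `clinical_fit`, `combined_fit`, `auc_clinical`, `auc_combined`,
#'   `auc_gap`, `manifest`.
#' @export
run_outcome_prediction <- function(cohort, config = run_config(),
                                   out_dir = NULL) {
  if (!inherits(config, "run_config")) config <- run_config(config)
  clin <- clinical_features()
  regions <- intersect(aal90_labels()$region, names(cohort))
  stopifnot(length(regions) > 0L, all(clin %in% names(cohort)),
            all(c("delta_ledd_pct", "outcome") %in% names(cohort)))
  feats <- c(clin, regions)
  keep <- stats::complete.cases(cohort[feats])
  cohort <- cohort[keep, , drop = FALSE]
  splits <- split_cohort(cohort$outcome, config$fractions,
                         seed = config$seed)
  std <- standardize_fit(cohort[splits$train, feats, drop = FALSE])
  xs <- standardize_apply(std, cohort[feats])
  y <- cohort$outcome
  tr <- splits$train
  selection <- lasso_cv_select(xs[tr, feats, drop = FALSE],
                               y[tr], alpha_grid = lasso_alpha_grid(),
                               seed = config$seed,
                               loss = config$lasso_loss)
  sel_fd <- setdiff(selection$selected_features, clin)
  # the combined model is the clinical model plus the selected FD features
  selected <- c(clin, sel_fd)
  if (length(sel_fd) == 0L)
    message("no FD feature selected; combined model reduces to clinical")
  w_combined <- ridge_weights(xs[tr, selected, drop = FALSE], y[tr],
                              seed = config$seed)
  w_clinical <- ridge_weights(xs[tr, clin, drop = FALSE], y[tr],
                              seed = config$seed)
  variance <- if (length(sel_fd) > 0L)
    nested_ols_ftest(cohort$delta_ledd_pct[tr],
                     xs[tr, clin, drop = FALSE],
                     xs[tr, c(clin, sel_fd), drop = FALSE])
  else NULL
  k_search <- NULL
  k_use <- config$hgnn$k
  if (isTRUE(config$tune_k)) {
    k_search <- tune_k(xs[selected], y, splits, config$hgnn,
                       weights = w_combined, k_grid = config$k_grid)
    k_use <- k_search$best_k
  }
  cfg_used <- config$hgnn; cfg_used$k <- as.integer(k_use)
  hg_combined <- build_feature_hypergraphs(xs[selected], k = k_use,
                                           weights = w_combined)
  hg_clinical <- build_feature_hypergraphs(xs[clin], k = k_use,
                                           weights = w_clinical)
  combined_fit <- train_hgnn(hg_combined, as.matrix(xs[selected]), y,
                             splits, cfg_used)
  clinical_fit <- train_hgnn(hg_clinical, as.matrix(xs[clin]), y,
                             splits, cfg_used)
  report <- list(
    selection = selection,
    ridge_weights = w_combined,
    variance = variance,
    k_search = k_search,
    clinical_fit = clinical_fit,
    combined_fit = combined_fit,
    auc_clinical = clinical_fit$metrics$auc,
    auc_combined = combined_fit$metrics$auc,
    auc_gap = combined_fit$metrics$auc - clinical_fit$metrics$auc,
    manifest = run_manifest(config,
                            list(task = "outcome_prediction",
                                 n = nrow(cohort), k_used = k_use,
                                 selected_features = selected)))
  class(report) <- "prediction_report"
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.prediction_report <- function(x, ...) {
  cat(sprintf("<prediction_report> %d features selected at alpha %.3g\n",
              length(x$selection$selected_features), x$selection$alpha))
  if (!is.null(x$variance))
    cat(sprintf("  R2 clinical %.3f -> combined %.3f (F = %.2f, p = %.3g)\n",
                x$variance$r2_clinical, x$variance$r2_combined,
                x$variance$f_stat, x$variance$p_value))
  cat(sprintf("  test AUC: clinical %.3f vs combined %.3f (gap %+.3f)\n",
              x$auc_clinical, x$auc_combined, x$auc_gap))
  invisible(x)
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> %d significant region(s) of %d\n",
              length(x$significant_regions), nrow(x$comparison)))
  if (!is.null(x$metrics))
    cat(sprintf("  PD-vs-HC test AUC %.3f, sens %.3f, spec %.3f\n",
                x$metrics$auc, x$metrics$sensitivity,
                x$metrics$specificity))
  invisible(x)
}
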