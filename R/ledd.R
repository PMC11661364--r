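#' Levodopa-equivalence conversion factors
#'
#' Loads a drug-to-levodopa-equivalence factor table. The package ships an
#' editable default (`inst/extdata/ledd_conversion_factors.csv`) with
#' commonly used literature factors; sites should review and adapt it —
#' no factor is treated as ground truth. Plain levodopa must map to 1.0.
#'
#' @param path CSV with columns `drug_name`, `factor`; default = shipped
#'   table.
#' @return named numeric vector of positive factors.
#' @export
ledd_factors <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "ledd_conversion_factors.csv",
                        package = "fdbs", mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("drug_name", "factor") %in% names(tab)))
  f <- stats::setNames(as.numeric(tab$factor), tab$drug_name)
  if (any(f <= 0) || anyNA(f))
    stop("conversion factors must be positive numbers", call. = FALSE)
  if ("levodopa" %in% names(f) && f[["levodopa"]] != 1.0)
    stop("levodopa must have conversion factor 1.0", call. = FALSE)
  f
}

#' Levodopa-equivalent daily dose of a medication schedule
#'
#' Sums `dose_mg * intakes_per_day * factor` over all entries. Every drug
#' must be present in the factor table; unknown drugs raise an error naming
#' them rather than being silently skipped.
#'
#' @param entries data.frame with columns `drug_name`, `dose_mg` (dose per
#'   intake), `intakes_per_day`.
#' @param factors named numeric vector from [ledd_factors()].
#' @return LEDD in mg/day (0 for an empty schedule).
#' @export
compute_ledd <- function(entries, factors) {
  if (nrow(entries) == 0L) return(0)
  stopifnot(all(c("drug_name", "dose_mg", "intakes_per_day") %in%
                  names(entries)))
  if (any(entries$dose_mg < 0) || any(entries$intakes_per_day < 0))
    stop("doses and intake counts must be >= 0", call. = FALSE)
  unknown <- setdiff(unique(entries$drug_name), names(factors))
  if (length(unknown) > 0L)
    stop(sprintf("unknown drug(s) in schedule: %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  sum(entries$dose_mg * entries$intakes_per_day *
        factors[entries$drug_name])
}

#' Select pre- and post-surgery visits
#'
#' Pre = the visit closest before surgery (largest strictly negative
#' offset; a visit on the surgery day, offset 0, does not count as
#' preoperative). Post = the visit nearest to 6 months of active
#' stimulation; at equal distance from 6 months the earlier visit wins.
#'
#' @param offsets visit offsets in months relative to surgery (signed).
#' @return list with `pre` and `post` offsets.
#' @export
select_visits <- function(offsets) {
  offsets <- as.numeric(offsets)
  pre_cand <- offsets[offsets < 0]
  post_cand <- offsets[offsets > 0]
  if (length(pre_cand) == 0L)
    stop("no preoperative visit (offset < 0)", call. = FALSE)
  if (length(post_cand) == 0L)
    stop("no postoperative visit (offset > 0)", call. = FALSE)
  pre <- max(pre_cand)
  d <- abs(post_cand - 6)
  post <- min(post_cand[d == min(d)])  # tie -> earlier visit
  list(pre = pre, post = post)
}

#' Pre-to-post percent change in LEDD
#'
#' `100 * (LEDDpre - LEDDpost) / LEDDpre`; positive values mean the daily
#' medication dose was reduced after DBS.
#'
#' @param ledd_pre,ledd_post LEDD in mg/day; `ledd_pre` must be > 0.
#' @return signed percent change.
#' @export
delta_ledd <- function(ledd_pre, ledd_post) {
  if (any(ledd_pre <= 0))
    stop("undefined ΔLEDD: LEDDpre must be > 0", call. = FALSE)
  100 * (ledd_pre - ledd_post) / ledd_pre
}

#' Binary DBS outcome label from percent LEDD change
#'
#' `delta <= 0` (dose unchanged or increased) maps to `no_decrease`,
#' `delta > 0` (dose reduced) to `decrease`; `decrease` is the favourable
#' outcome and the positive class throughout the package.
#'
#' @param delta_pct percent change from [delta_ledd()].
#' @return factor with levels `no_decrease`, `decrease`.
#' @export
outcome_label <- function(delta_pct) {
  factor(ifelse(delta_pct > 0, "decrease", "no_decrease"),
         levels = c("no_decrease", "decrease"))
}

#' LEDD outcomes for a medication table
#'
#' Per subject: visit-wise LEDD, visit selection, percent change and
#' outcome label. Entries outside the +/- 12 month window are dropped;
#' subjects without a usable pre or post visit are excluded and reported in
#' the `excluded` attribute (with reasons) rather than erroring the run.
#'
#' @param meds data.frame with columns `subject_id`, `drug_name`, `dose_mg`,
#'   `intakes_per_day`, `visit_offset_months`.
#' @param factors named factor vector from [ledd_factors()].
#' @param window inclusion window in months around surgery.
#' @return data.frame: `subject_id`, `ledd_pre`, `ledd_post`,
#'   `delta_ledd_pct`, `outcome` (factor), `pre_offset`, `post_offset`;
#'   attribute `excluded` = data.frame(subject_id, reason).
#' @export
ledd_outcomes <- function(meds, factors = ledd_factors(),
                          window = c(-12, 12)) {
  need <- c("subject_id", "drug_name", "dose_mg", "intakes_per_day",
            "visit_offset_months")
  stopifnot(all(need %in% names(meds)))
  meds <- meds[meds$visit_offset_months >= window[1] &
                 meds$visit_offset_months <= window[2], , drop = FALSE]
  out <- list()
  excluded <- list()
  for (sid in unique(meds$subject_id)) {
    sub <- meds[meds$subject_id == sid, , drop = FALSE]
    row <- tryCatch({
      vis <- select_visits(unique(sub$visit_offset_months))
      pre <- compute_ledd(
        sub[sub$visit_offset_months == vis$pre, , drop = FALSE], factors)
      post <- compute_ledd(
        sub[sub$visit_offset_months == vis$post, , drop = FALSE], factors)
      delta <- delta_ledd(pre, post)
      data.frame(subject_id = sid, ledd_pre = pre, ledd_post = post,
                 delta_ledd_pct = delta,
                 outcome = outcome_label(delta),
                 pre_offset = vis$pre, post_offset = vis$post,
                 stringsAsFactors = FALSE)
    }, error = function(e) conditionMessage(e))
    if (is.character(row)) {
      excluded[[length(excluded) + 1L]] <-
        data.frame(subject_id = sid, reason = row,
                   stringsAsFactors = FALSE)
      message(sprintf("ledd_outcomes: excluding subject %s (%s)", sid, row))
    } else {
      out[[length(out) + 1L]] <- row
    }
  }
  if (length(out) == 0L)
    stop("no subject had both a pre- and a post-surgery visit",
         call. = FALSE)
  res <- do.call(rbind, out)
  attr(res, "excluded") <- if (length(excluded) > 0L)
    do.call(rbind, excluded)
  else data.frame(subject_id = character(0), reason = character(0))
  res
}
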