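#' Regions with planted case-control FD effects
#'
#' Default set of nine regions given a group effect in the case-control
#' generator: seven cortical regions where complexity is increased in
#' patients and two subcortical regions (putamen, pallidum) where it is
#' decreased.
#'
#' @return named numeric vector: region -> effect direction (+1 / -1).
#' @export
default_affected_regions <- function() {
  c(Frontal_Sup_L = 1, Frontal_Sup_Medial_L = 1, Supp_Motor_Area_L = 1,
    Insula_L = 1, Occipital_Inf_R = 1, Paracentral_Lobule_L = 1,
    Paracentral_Lobule_R = 1, Putamen_R = -1, Pallidum_R = -1)
}

fd_region_means <- function(regions, seed) {
  # fixed plausible per-region means in the 2.0-2.6 band
  set.seed(seed)
  stats::setNames(stats::runif(length(regions), 2.0, 2.6), regions)
}

#' Synthetic case-control regional FD tables
#'
#' Draws per-region FD values (Gaussian around plausible region means, SD
#' `fd_sd`) for a patient and a control group, planting a standardized
#' group difference of Cohen's d `effect_d` in the `affected` regions with
#' the given directions (positive = higher in patients).
#'
#' @param n_per_group subjects per group.
#' @param affected named direction vector as in
#'   [default_affected_regions()]; use `NULL` for a null (no-effect)
#'   cohort.
#' @param effect_d planted effect size in pooled-SD units.
#' @param fd_sd within-group SD of each region's FD.
#' @param regions region names (default AAL-90).
#' @param seed RNG seed.
#' @return list with data.frames `pd` and `hc` (subject_id + one column
#'   per region) and the generating parameters in `params`.
#' @export
gen_case_control_fd <- function(n_per_group = 70L,
                                affected = default_affected_regions(),
                                effect_d = 1.2, fd_sd = 0.1,
                                regions = aal90_labels()$region,
                                seed = 1L) {
  stopifnot(n_per_group >= 2L)
  if (!is.null(affected) && !all(names(affected) %in% regions))
    stop("affected regions must be a subset of the region set",
         call. = FALSE)
  mu <- fd_region_means(regions, seed)
  set.seed(seed + 1L)
  draw <- function(n, shift) {
    m <- matrix(stats::rnorm(n * length(regions), sd = fd_sd), nrow = n)
    m <- sweep(m, 2, mu + shift, `+`)
    colnames(m) <- regions
    m
  }
  shift <- stats::setNames(rep(0, length(regions)), regions)
  if (!is.null(affected))
    shift[names(affected)] <- affected * effect_d * fd_sd
  pd <- draw(n_per_group, shift)
  hc <- draw(n_per_group, 0)
  list(pd = data.frame(subject_id = sprintf("PD%03d", seq_len(n_per_group)),
                       pd, check.names = FALSE),
       hc = data.frame(subject_id = sprintf("HC%03d", seq_len(n_per_group)),
                       hc, check.names = FALSE),
       params = list(n_per_group = n_per_group, affected = affected,
                     effect_d = effect_d, fd_sd = fd_sd, seed = seed))
}

#' Default outcome-predictive FD regions
#'
#' Eight regions whose (standardized) FD carries the planted DBS-outcome
#' signal in [gen_cohort()].
#'
#' @return character vector of region names.
#' @export
default_outcome_regions <- function() {
  c("Paracentral_Lobule_R", "Occipital_Mid_L", "Olfactory_R",
    "Frontal_Mid_L", "Cingulum_Ant_R", "Amygdala_L", "Occipital_Inf_R",
    "Caudate_R")
}

#' Synthetic DBS cohort with planted outcome structure
#'
#' Emulates the structure of a real DBS cohort: demographics (age 65 +/- 9,
#' 33% female), 42% STN / 58% GPi targets, 80% bilateral implants,
#' preoperative motor scores with ~53 +/- 16 % levodopa response, 90
#' regional FD values, and a percent LEDD change built from a
#' target-dependent mixture (STN mean +35, GPi mean +10, residual SD 25 —
#' two divergent medication trajectories) plus planted FD-borne and
#' motor-responsiveness signal. The binary outcome label is derived from
#' the generated percent change via [outcome_label()] (the LEDD module's
#' rule), never re-implemented here.
#'
#' @param n cohort size.
#' @param seed RNG seed; the cohort is a pure function of the arguments.
#' @param stn_fraction probability of an STN target.
#' @param bilateral_fraction probability of bilateral implantation.
#' @param outcome_regions regions carrying FD-borne outcome signal.
#' @param fd_effect percent-points of LEDD change per SD of the aggregated
#'   outcome-region FD (0 = signal-free FD).
#' @param motor_effect percent-points per SD of preoperative motor
#'   responsiveness.
#' @param target_means named vector `c(STN=, GPi=)` of mean LEDD change by
#'   target.
#' @param within_target_sd total SD of the LEDD change within each target
#'   group (percent points); the residual noise SD is derived from it after
#'   subtracting the planted FD and motor components, so the mixture keeps
#'   this spread whatever signal is planted.
#' @param severity_regions,severity_effect regions and strength (motor
#'   points per SD of FD) of a planted FD-severity association in the OFF
#'   state.
#' @param fd_sd per-region FD standard deviation.
#' @return data.frame (one row per subject): `subject_id`, `age`, `sex`
#'   (1 = female), `target` (factor STN/GPi), `target_stn` (0/1),
#'   `bilateral` (0/1), `motor_off`, `motor_on`,
#'   `motor_improvement_pct`, 90 FD columns, `delta_ledd_pct`, `outcome`
#'   (factor, positive class `decrease`). Generating parameters are stored
#'   in `attr(, "params")`.
#' @export
gen_cohort <- function(n = 231L, seed = 1L,
                       stn_fraction = 96 / 231,
                       bilateral_fraction = 0.80,
                       outcome_regions = default_outcome_regions(),
                       fd_effect = 22, motor_effect = 8,
                       target_means = c(STN = 35, GPi = 10),
                       within_target_sd = 25,
                       severity_regions = c("Supp_Motor_Area_L",
                                            "Lingual_R", "Parietal_Inf_L"),
                       severity_effect = 3,
                       fd_sd = 0.1) {
  stopifnot(n >= 10L)
  regions <- aal90_labels()$region
  stopifnot(all(outcome_regions %in% regions),
            all(severity_regions %in% regions))
  mu <- fd_region_means(regions, seed)
  set.seed(seed + 1L)
  age <- round(stats::rnorm(n, 65, 9))
  sex <- stats::rbinom(n, 1, 0.33)            # 1 = female
  target <- factor(ifelse(stats::rbinom(n, 1, stn_fraction) == 1L,
                          "STN", "GPi"), levels = c("GPi", "STN"))
  bilateral <- stats::rbinom(n, 1, bilateral_fraction)
  z <- matrix(stats::rnorm(n * length(regions)), nrow = n,
              dimnames = list(NULL, regions))
  fd <- sweep(z * fd_sd, 2, mu, `+`)
  # aggregated standardized FD signals (unit variance)
  z_out <- rowMeans(z[, outcome_regions, drop = FALSE]) *
    sqrt(length(outcome_regions))
  z_sev <- rowMeans(z[, severity_regions, drop = FALSE]) *
    sqrt(length(severity_regions))
  noise_var <- within_target_sd^2 - fd_effect^2 - motor_effect^2
  if (noise_var <= 0)
    stop("planted effects exceed the within-target spread; increase within_target_sd",
         call. = FALSE)
  noise_sd <- sqrt(noise_var)
  motor_off <- pmax(round(40 + severity_effect * z_sev +
                            stats::rnorm(n, 0, 10)), 8)
  imp <- pmin(pmax(stats::rnorm(n, 53, 16), 5), 95)
  motor_on <- pmax(motor_off * (1 - imp / 100), 0)
  imp_pct <- motor_improvement_pct(motor_off, motor_on)
  delta <- unname(target_means[as.character(target)]) +
    fd_effect * z_out +
    motor_effect * as.numeric(scale(imp_pct)) +
    stats::rnorm(n, 0, noise_sd)
  outcome <- outcome_label(delta)
  if (length(unique(outcome)) < 2L)
    stop("degenerate outcome mixture: only one class generated",
         call. = FALSE)
  out <- data.frame(subject_id = sprintf("S%03d", seq_len(n)),
                    age = age, sex = sex, target = target,
                    target_stn = as.integer(target == "STN"),
                    bilateral = bilateral,
                    motor_off = motor_off, motor_on = motor_on,
                    motor_improvement_pct = imp_pct,
                    fd, check.names = FALSE)
  out$delta_ledd_pct <- delta
  out$outcome <- outcome
  attr(out, "params") <- list(
    n = n, seed = seed, stn_fraction = stn_fraction,
    bilateral_fraction = bilateral_fraction,
    outcome_regions = outcome_regions, fd_effect = fd_effect,
    motor_effect = motor_effect, target_means = target_means,
    within_target_sd = within_target_sd, noise_sd = noise_sd,
    severity_regions = severity_regions,
    severity_effect = severity_effect, fd_sd = fd_sd)
  out
}

#' Synthetic medication histories
#'
#' Multi-visit medication schedules within +/- 12 months of surgery, with
#' at least one pre- and one post-surgery visit per subject. A planted
#' pre-surgery LEDD and percent change determine the doses: the visit
#' closest before surgery carries the planted LEDDpre, the visit nearest 6
#' months the planted LEDDpost, so running the LEDD pipeline on the output
#' recovers the planted change up to dose rounding (0.01 mg on levodopa,
#' 0.001 mg on the agonist). Drug names come from the shipped factor
#' table.
#'
#' @param n subjects.
#' @param seed RNG seed.
#' @param stn_fraction mix of STN targets driving the planted change.
#' @param target_means,noise_sd planted percent-change mixture (see
#'   [gen_cohort()]).
#' @return data.frame with columns `subject_id`, `drug_name`, `dose_mg`,
#'   `intakes_per_day`, `visit_offset_months`; the planted truth is in
#'   `attr(, "planted")` (subject_id, target, ledd_pre, ledd_post,
#'   delta_ledd_pct).
#' @export
gen_medication_history <- function(n = 20L, seed = 1L,
                                   stn_fraction = 96 / 231,
                                   target_means = c(STN = 35, GPi = 10),
                                   noise_sd = 25) {
  stopifnot(n >= 1L)
  set.seed(seed)
  rows <- list()
  planted <- list()
  for (i in seq_len(n)) {
    sid <- sprintf("M%03d", i)
    target <- if (stats::rbinom(1, 1, stn_fraction) == 1L) "STN" else "GPi"
    ledd_pre <- exp(stats::rnorm(1, log(1000), 0.25))
    delta <- stats::rnorm(1, target_means[[target]], noise_sd)
    delta <- min(delta, 95)  # keep the post dose positive
    ledd_post <- ledd_pre * (1 - delta / 100)
    pre_off <- sort(sample(-11:-1, sample(1:3, 1)))
    post_off <- sort(sample(2:11, sample(1:3, 1)))
    post_sel <- post_off[which.min(abs(post_off - 6))]
    visit_ledd <- c(
      stats::setNames(ledd_pre * stats::runif(length(pre_off), 0.9, 1.1),
                      pre_off),
      stats::setNames(ledd_post * stats::runif(length(post_off), 0.9, 1.1),
                      post_off))
    visit_ledd[as.character(max(pre_off))] <- ledd_pre
    visit_ledd[as.character(post_sel)] <- ledd_post
    for (off in names(visit_ledd)) {
      L <- visit_ledd[[off]]
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = sid,
        drug_name = c("levodopa", "pramipexole"),
        dose_mg = c(round(0.7 * L / 3, 2), round(0.3 * L / 100 / 2, 3)),
        intakes_per_day = c(3L, 2L),
        visit_offset_months = as.numeric(off),
        stringsAsFactors = FALSE)
    }
    planted[[i]] <- data.frame(subject_id = sid, target = target,
                               ledd_pre = ledd_pre, ledd_post = ledd_post,
                               delta_ledd_pct = delta,
                               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "planted") <- do.call(rbind, planted)
  out
}
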