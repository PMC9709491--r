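#' Specification of the synthetic within-trial dataset
#'
#' Describes the generator for a synthetic stand-in for the trial's
#' individual-patient data: per-arm EQ-5D-5L utilities at 0, 3, 6, 9, 12
#' and 18 months and per-participant NHS/PSS cost components. Defaults are
#' calibrated so that 12-month mean QALYs are about 0.875 (adalimumab) and
#' 0.855 (standard care), adalimumab injection costs average about 2,030
#' GBP, and other NHS costs are small, matching the reported trial
#' marginals. The generated data are complete (no missingness).
#'
#' @param n_per_arm Participants per arm.
#' @param n_sites Number of recruiting sites.
#' @param baseline_utility_placebo,baseline_utility_ada Mean of the
#'   (pre-truncation) Normal baseline EQ-5D utility per arm; defaults are
#'   set so the truncated 12-month QALY means land on the calibration
#'   targets. A small baseline imbalance is deliberate: the regression
#'   adjustment, not the crude means, recovers the treatment effect.
#' @param utility_sd Between-participant SD of baseline utility.
#' @param utility_noise_sd SD of the visit-level utility noise.
#' @param qaly_effect True arm effect on follow-up utilities (adalimumab
#'   minus placebo).
#' @param injection_cost_mean,injection_cost_sd Adalimumab-arm injection
#'   cost (drug plus administration; placebo arm incurs 0).
#' @param gp_rate,gp_cost Expected GP consultations per participant and
#'   unit cost.
#' @param physio_rate,physio_cost Expected physiotherapy contacts and unit
#'   cost.
#' @param surgery_prob,surgery_cost Probability of early surgery during
#'   follow-up and its cost.
#' @param age_mean,age_sd Age distribution.
#' @return An object of class `dd_trial_spec`.
#' @export
trial_spec <- function(n_per_arm = 70, n_sites = 2,
                       baseline_utility_placebo = 0.867,
                       baseline_utility_ada = 0.889,
                       utility_sd = 0.12, utility_noise_sd = 0.06,
                       qaly_effect = 0.004,
                       injection_cost_mean = 2030, injection_cost_sd = 360,
                       gp_rate = 0.10, gp_cost = 39,
                       physio_rate = 0.10, physio_cost = 45,
                       surgery_prob = 0.014, surgery_cost = 2000,
                       age_mean = 61, age_sd = 9) {
  spec <- as.list(environment())
  class(spec) <- "dd_trial_spec"
  validate_trial_spec(spec)
  spec
}

#' @rdname trial_spec
#' @param spec A `dd_trial_spec` object.
#' @export
validate_trial_spec <- function(spec) {
  if (spec$n_per_arm < 1 || spec$n_per_arm != round(spec$n_per_arm)) {
    stop("validation error: n_per_arm must be a positive integer")
  }
  if (spec$surgery_prob < 0 || spec$surgery_prob > 1) {
    stop("validation error: surgery_prob must lie in [0, 1]")
  }
  for (f in c("utility_sd", "utility_noise_sd", "injection_cost_sd",
              "gp_rate", "physio_rate")) {
    if (spec[[f]] < 0) stop("validation error: ", f, " must be >= 0")
  }
  invisible(spec)
}

.trial_months <- c(0, 3, 6, 9, 12, 18)

#' Generate a synthetic within-trial dataset
#'
#' One row per participant: `arm`, `site`, `age`, utility columns
#' `utility_m0` ... `utility_m18` (EQ-5D index, clamped to
#' \[-0.594, 1\]) and cost columns `cost_injections`, `cost_gp`,
#' `cost_physio`, `cost_surgery` (GBP over 12 months). The placebo arm's
#' injection cost is exactly zero. Deterministic for a fixed seed.
#'
#' @param spec A `dd_trial_spec`.
#' @param seed Integer seed.
#' @return A data frame of class `dd_trial_data`.
#' @export
generate_trial_dataset <- function(spec = trial_spec(), seed = 1L) {
  validate_trial_spec(spec)
  restore <- .Random.seed_guard(derive_seed(seed, 707L))
  on.exit(restore(), add = TRUE)
  n <- 2L * spec$n_per_arm
  arm <- rep(c("adalimumab", "placebo"), each = spec$n_per_arm)
  base_mean <- ifelse(arm == "adalimumab", spec$baseline_utility_ada,
                      spec$baseline_utility_placebo)
  baseline <- pmin(1, pmax(-0.594,
                           stats::rnorm(n, base_mean, spec$utility_sd)))
  df <- data.frame(
    id = seq_len(n), arm = arm,
    site = sample(seq_len(spec$n_sites), n, replace = TRUE),
    age = .rnorm_trunc(n, spec$age_mean, spec$age_sd, lower = 18),
    stringsAsFactors = FALSE
  )
  for (mth in .trial_months) {
    u <- if (mth == 0) baseline else {
      pmin(1, pmax(-0.594,
                   baseline + spec$qaly_effect * (arm == "adalimumab") +
                     stats::rnorm(n, 0, spec$utility_noise_sd)))
    }
    df[[paste0("utility_m", mth)]] <- u
  }
  df$cost_injections <- ifelse(
    arm == "adalimumab",
    pmax(0, stats::rnorm(n, spec$injection_cost_mean,
                         spec$injection_cost_sd)),
    0)
  df$cost_gp <- stats::rpois(n, spec$gp_rate) * spec$gp_cost
  df$cost_physio <- stats::rpois(n, spec$physio_rate) * spec$physio_cost
  df$cost_surgery <- (stats::runif(n) < spec$surgery_prob) *
    spec$surgery_cost
  class(df) <- c("dd_trial_data", "data.frame")
  df
}

#' Read or write a trial dataset as CSV
#' @param data A `dd_trial_data` data frame.
#' @param path File path.
#' @return `read_trial_dataset` returns a `dd_trial_data`;
#'   `write_trial_dataset` returns `path` invisibly.
#' @export
write_trial_dataset <- function(data, path) {
  utils::write.csv(as.data.frame(data), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trial_dataset
#' @export
read_trial_dataset <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(df) <- c("dd_trial_data", "data.frame")
  df
}

#' QALYs by trapezoidal area under the utility curve
#'
#' @param utilities Utility values at each assessment.
#' @param times Assessment times in months, strictly increasing, same
#'   length as `utilities` (>= 2 points).
#' @return QALYs accrued between the first and last assessment (time in
#'   years).
#' @export
qalys_auc <- function(utilities, times) {
  if (length(utilities) != length(times) || length(times) < 2) {
    stop("argument error: need >= 2 matching utility/time points")
  }
  if (any(diff(times) <= 0)) {
    stop("argument error: times must be strictly increasing")
  }
  yrs <- times / 12
  sum(diff(yrs) * (utilities[-1] + utilities[-length(utilities)]) / 2)
}

# Per-participant 12-month QALYs and total costs.
.trial_outcomes <- function(data, horizon_months = 12) {
  months <- .trial_months[.trial_months <= horizon_months]
  ucols <- paste0("utility_m", months)
  qalys <- apply(as.matrix(data[ucols]), 1, qalys_auc, times = months)
  costs <- data$cost_injections + data$cost_gp + data$cost_physio +
    data$cost_surgery
  data.frame(id = data$id, arm = data$arm, site = data$site,
             age = data$age, baseline_utility = data$utility_m0,
             qalys = qalys, costs = costs, stringsAsFactors = FALSE)
}

#' Covariate-adjusted between-arm difference
#'
#' Ordinary least squares regression of the participant-level outcome on
#' treatment arm, adjusted for site and age, and additionally for baseline
#' utility when the outcome is QALYs. Returns the adalimumab-minus-placebo
#' coefficient; confidence intervals are obtained by bootstrapping (see
#' [bootstrap_cua()]).
#'
#' @param data A `dd_trial_data` data frame.
#' @param outcome `"qalys"` or `"costs"`.
#' @param horizon_months Follow-up horizon for the outcome (default 12).
#' @return List with `estimate`, `se` (model-based), and the fitted `model`.
#' @export
adjusted_difference <- function(data, outcome = c("qalys", "costs"),
                                horizon_months = 12) {
  outcome <- match.arg(outcome)
  df <- .trial_outcomes(data, horizon_months)
  df$arm <- factor(df$arm, levels = c("placebo", "adalimumab"))
  df$site <- factor(df$site)
  form <- if (outcome == "qalys") {
    qalys ~ arm + age + site + baseline_utility
  } else {
    costs ~ arm + age + site
  }
  fit <- stats::lm(form, data = df)
  if (any(is.na(stats::coef(fit)))) {
    stop("diagnostic error: collinear covariates in adjustment model")
  }
  est <- stats::coef(fit)[["armadalimumab"]]
  se <- summary(fit)$coefficients["armadalimumab", "Std. Error"]
  list(estimate = est, se = se, model = fit)
}

#' Within-trial bootstrap cost-utility analysis
#'
#' Resamples participants with replacement within each arm; for each
#' replicate, recomputes the covariate-adjusted QALY and cost differences.
#' The ICER point estimate is the adjusted mean cost difference divided by
#' the adjusted mean QALY difference on the full dataset; percentile
#' confidence intervals and the cost-effectiveness acceptability curve
#' (fraction of replicates with positive incremental net benefit at each
#' willingness to pay) come from the replicate cloud. Replicates with a
#' zero QALY difference are kept for the net-benefit curve but excluded
#' from ratio summaries.
#'
#' @param data A `dd_trial_data` data frame.
#' @param n_boot Number of bootstrap replicates (>= 100; default 5000).
#' @param wtp_grid Willingness-to-pay values, GBP per QALY.
#' @param seed Integer seed.
#' @param horizon_months Follow-up horizon (default 12).
#' @return An object of class `dd_cua_result`: list with `delta_qalys`
#'   and `delta_costs` (estimate plus percentile CI), `icer`, `ceac`
#'   (data frame `wtp`, `probability`), `replicates` (data frame of
#'   replicate differences), `n_boot` and `seed`.
#' @export
bootstrap_cua <- function(data, n_boot = 5000,
                          wtp_grid = c(0, 5000, 10000, 15000, 20000,
                                       25000, 30000, 50000),
                          seed = 1L, horizon_months = 12) {
  if (n_boot < 100) stop("argument error: n_boot must be >= 100")
  dq <- adjusted_difference(data, "qalys", horizon_months)$estimate
  dc <- adjusted_difference(data, "costs", horizon_months)$estimate
  restore <- .Random.seed_guard(derive_seed(seed, 808L))
  on.exit(restore(), add = TRUE)
  idx_by_arm <- split(seq_len(nrow(data)), data$arm)
  reps <- t(vapply(seq_len(n_boot), function(b) {
    take <- unlist(lapply(idx_by_arm, function(ix)
      sample(ix, length(ix), replace = TRUE)))
    boot <- data[take, , drop = FALSE]
    c(dq = adjusted_difference(boot, "qalys", horizon_months)$estimate,
      dc = adjusted_difference(boot, "costs", horizon_months)$estimate)
  }, numeric(2)))
  replicates <- data.frame(delta_qalys = reps[, "dq"],
                           delta_costs = reps[, "dc"])
  ci <- function(x) stats::quantile(x, c(0.025, 0.975), names = FALSE)
  ceac_df <- data.frame(
    wtp = wtp_grid,
    probability = vapply(wtp_grid, function(l)
      mean(l * replicates$delta_qalys - replicates$delta_costs > 0),
      numeric(1)))
  structure(list(
    delta_qalys = list(estimate = dq, ci = ci(replicates$delta_qalys)),
    delta_costs = list(estimate = dc, ci = ci(replicates$delta_costs)),
    icer = if (dq == 0) NA_real_ else dc / dq,
    ceac = ceac_df,
    replicates = replicates,
    n_boot = n_boot, seed = seed
  ), class = "dd_cua_result")
}

#' @export
print.dd_cua_result <- function(x, ...) {
  cat("<dd_cua_result>\n")
  cat(sprintf("  adjusted QALY difference: %.4f (95%% CI %.4f to %.4f)\n",
              x$delta_qalys$estimate, x$delta_qalys$ci[1],
              x$delta_qalys$ci[2]))
  cat(sprintf("  adjusted cost difference: %.0f (95%% CI %.0f to %.0f) GBP\n",
              x$delta_costs$estimate, x$delta_costs$ci[1],
              x$delta_costs$ci[2]))
  cat(sprintf("  ICER: %s GBP/QALY\n",
              if (is.na(x$icer)) "undefined" else
                format(round(x$icer), big.mark = ",")))
  p20 <- x$ceac$probability[x$ceac$wtp == 20000]
  if (length(p20) == 1) {
    cat(sprintf("  P(cost-effective at 20,000 GBP/QALY): %.2f\n", p20))
  }
  invisible(x)
}
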