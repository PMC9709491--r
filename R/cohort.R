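#' Specification of the synthetic baseline cohort
#'
#' Describes the joint distribution of baseline characteristics used to
#' generate synthetic patients emulating the 69 UK placebo-arm trial
#' participants with complete baseline data. Marginals are editable
#' assumptions (the trial's baseline table is not public): age Normal,
#' truncated below; baseline EQ-5D utility Normal, truncated to the index
#' range; baseline flexion deformity Uniform on \[0, `fd_max`\] degrees
#' (the inclusion criterion caps it at 30 degrees).
#'
#' @param n Number of patients (default 69).
#' @param age_mean,age_sd,age_min Age distribution in years.
#' @param prop_male Proportion male.
#' @param utility_mean,utility_sd Baseline EQ-5D utility distribution,
#'   truncated to \[-0.594, 1\]; the default truncated mean (about 0.845)
#'   matches the baseline utility means observed in the trial arms.
#' @param ectopic_prev Prevalence of ectopic fibrotic disease (plantar
#'   fibromatosis, Peyronie's disease or Garrod's knuckle pads).
#' @param fd_min,fd_max Range of the baseline flexion deformity, degrees;
#'   `fd_max` may not exceed 30.
#' @return An object of class `dd_cohort_spec`.
#' @export
cohort_spec <- function(n = 69, age_mean = 61, age_sd = 9, age_min = 30,
                        prop_male = 0.80, utility_mean = 0.88,
                        utility_sd = 0.12, ectopic_prev = 0.25,
                        fd_min = 0, fd_max = 20) {
  spec <- list(n = n, age_mean = age_mean, age_sd = age_sd,
               age_min = age_min, prop_male = prop_male,
               utility_mean = utility_mean, utility_sd = utility_sd,
               ectopic_prev = ectopic_prev, fd_min = fd_min, fd_max = fd_max)
  class(spec) <- "dd_cohort_spec"
  validate_cohort_spec(spec)
  spec
}

#' @rdname cohort_spec
#' @param spec A `dd_cohort_spec` object.
#' @export
validate_cohort_spec <- function(spec) {
  if (spec$n < 0 || spec$n != round(spec$n)) {
    stop("validation error: n must be a non-negative integer")
  }
  for (f in c("prop_male", "ectopic_prev")) {
    if (spec[[f]] < 0 || spec[[f]] > 1) {
      stop("validation error: ", f, " must lie in [0, 1]")
    }
  }
  if (spec$age_sd < 0 || spec$utility_sd < 0) {
    stop("validation error: standard deviations must be >= 0")
  }
  if (spec$fd_min < 0 || spec$fd_max > 30 || spec$fd_min > spec$fd_max) {
    stop("validation error: baseline flexion deformity range must lie ",
         "within [0, 30] degrees")
  }
  invisible(spec)
}

.rnorm_trunc <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lower | x > upper)
  while (length(bad) > 0) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < lower | x[bad] > upper]
  }
  x
}

#' Generate a synthetic baseline cohort
#'
#' Draws `spec$n` synthetic patients from the baseline distributions in
#' `spec`. Deterministic for a fixed seed.
#'
#' @param spec A `dd_cohort_spec`, see [cohort_spec()].
#' @param seed Integer seed.
#' @return A data frame of class `dd_cohort` with columns `id`, `age`,
#'   `sex` (`"male"`/`"female"`), `baseline_utility`, `baseline_fd`
#'   (degrees) and `ectopic` (logical).
#' @export
generate_cohort <- function(spec = cohort_spec(), seed = 1L) {
  validate_cohort_spec(spec)
  restore <- .Random.seed_guard(derive_seed(seed, 202L))
  on.exit(restore(), add = TRUE)
  n <- spec$n
  cohort <- data.frame(
    id = seq_len(n),
    age = if (n > 0) .rnorm_trunc(n, spec$age_mean, spec$age_sd,
                                  lower = spec$age_min) else numeric(0),
    sex = ifelse(stats::runif(n) < spec$prop_male, "male", "female"),
    baseline_utility = if (n > 0) {
      .rnorm_trunc(n, spec$utility_mean, spec$utility_sd,
                   lower = -0.594, upper = 1)
    } else numeric(0),
    baseline_fd = stats::runif(n, spec$fd_min, spec$fd_max),
    ectopic = stats::runif(n) < spec$ectopic_prev,
    stringsAsFactors = FALSE
  )
  class(cohort) <- c("dd_cohort", "data.frame")
  cohort
}

#' Read or write a cohort as CSV
#'
#' One row per patient with columns `id`, `age`, `sex`, `baseline_utility`,
#' `baseline_fd`, `ectopic`.
#'
#' @param cohort A `dd_cohort` data frame.
#' @param path File path.
#' @return `read_cohort` returns a `dd_cohort`; `write_cohort` returns
#'   `path` invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  cohort <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("id", "age", "sex", "baseline_utility", "baseline_fd",
              "ectopic")
  missing <- setdiff(needed, names(cohort))
  if (length(missing) > 0) {
    stop("cohort file missing column(s): ", paste(missing, collapse = ", "))
  }
  cohort$ectopic <- as.logical(cohort$ectopic)
  class(cohort) <- c("dd_cohort", "data.frame")
  cohort
}

# Outcome categories at 18 months. Integer codes are used internally.
.dd_outcomes <- c(late_stage = 1L, quiescent = 2L, progressive = 3L)

#' Assign 18-month outcomes from shared uniform deviates
#'
#' Maps one uniform deviate per patient to the three-category 18-month
#' outcome (late-stage / quiescent / still-progressive) under the
#' arm-specific probabilities: late-stage if `u < p_late`, quiescent if
#' `u >= 1 - p_quiescent`, progressive otherwise. Sharing the same deviate
#' across treatment strategies (common random numbers) makes each category
#' monotone in its own probability, so every patient quiescent under
#' standard care is also quiescent under adalimumab whenever the adalimumab
#' quiescence probability is at least as large.
#'
#' @param u Uniform(0, 1) deviates, one per patient.
#' @param p_late,p_quiescent Arm-specific 18-month outcome probabilities.
#' @return Integer vector: 1 = late-stage, 2 = quiescent, 3 = progressive.
#' @export
outcome_from_uniform <- function(u, p_late, p_quiescent) {
  if (p_late < 0 || p_quiescent < 0 || p_late + p_quiescent > 1 + 1e-12) {
    stop("validation error: outcome probabilities invalid")
  }
  out <- rep(.dd_outcomes[["progressive"]], length(u))
  out[u < p_late] <- .dd_outcomes[["late_stage"]]
  out[u >= 1 - p_quiescent] <- .dd_outcomes[["quiescent"]]
  out
}

#' Assign each patient's 18-month outcome under each strategy
#'
#' Draws one uniform deviate per patient and maps it through
#' [outcome_from_uniform()] with the placebo probabilities for standard
#' care and the adalimumab probabilities for both adalimumab strategies
#' (common random numbers across strategies).
#'
#' @param cohort A `dd_cohort`.
#' @param params A `dd_parameters` object (point estimates or one PSA draw).
#' @param seed Integer seed.
#' @return A data frame with one row per patient and one factor column per
#'   strategy, levels `late_stage`, `quiescent`, `progressive`.
#' @export
assign_initial_outcomes <- function(cohort, params, seed = 1L) {
  validate_parameters(params)
  restore <- .Random.seed_guard(derive_seed(seed, 303L))
  on.exit(restore(), add = TRUE)
  u <- stats::runif(nrow(cohort))
  codes <- list(
    standard_care = outcome_from_uniform(u, params$p_late_placebo,
                                         params$p_quiescent_placebo),
    adalimumab_once = outcome_from_uniform(u, params$p_late_ada,
                                           params$p_quiescent_ada),
    adalimumab_repeat = outcome_from_uniform(u, params$p_late_ada,
                                             params$p_quiescent_ada)
  )
  out <- data.frame(id = cohort$id)
  for (s in names(codes)) {
    out[[s]] <- factor(names(.dd_outcomes)[codes[[s]]],
                       levels = names(.dd_outcomes))
  }
  out
}
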