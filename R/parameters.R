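#' @keywords internal
"_PACKAGE"

#' Treatment strategies compared by the model
#'
#' Strategy names, in the conventional reporting order: standard care
#' (no treatment for early-stage disease), a single course of four
#' adalimumab injections, and repeated courses (retreatment each time the
#' nodule reactivates in patients who were quiescent after the initial
#' course).
#'
#' @export
dd_strategies <- function() {
  c("standard_care", "adalimumab_once", "adalimumab_repeat")
}

#' Path to the packaged default parameter configuration
#' @return File path of the default YAML configuration.
#' @export
default_parameter_file <- function() {
  system.file("extdata", "default_params.yaml", package = "dupasim",
              mustWork = TRUE)
}

#' Path to the packaged placeholder late-stage/mortality configuration
#' @return File path of the placeholder YAML configuration.
#' @export
late_stage_defaults_file <- function() {
  system.file("extdata", "late_stage_defaults.yaml", package = "dupasim",
              mustWork = TRUE)
}

.dd_required_fields <- c(
  "p_late_placebo", "p_quiescent_placebo", "p_late_ada", "p_quiescent_ada",
  "qaly_gain_quiescence", "qaly_reg_baseline_utility_coef",
  "qaly_reg_constant", "fd_change_constant", "fd_change_ectopic_coef",
  "fd_change_rmse", "quiescence_duration", "cycle_length", "horizon",
  "trial_period", "discount_rate", "late_stage_threshold", "cost_per_dose",
  "doses_per_course", "trial_other_cost", "uk_prevalent_cases", "wtp_grid"
)

.dd_late_stage_fields <- c(
  "p_elect_surgery", "p_pnf_success", "p_relapse_pnf",
  "p_relapse_fasciectomy", "p_relapse_dermofasciectomy",
  "cost_pnf", "cost_fasciectomy", "cost_dermofasciectomy",
  "disutility_untreated", "disutility_pnf_success", "disutility_pnf_failed",
  "disutility_fasciectomy", "disutility_dermofasciectomy"
)

.dd_mortality_fields <- c(
  "gompertz_a_male", "gompertz_a_female", "gompertz_b", "max_age",
  "hazard_ratio"
)

.dd_provenance_tags <- c(
  "trial_estimate", "structural_assumption", "trial_costing",
  "placeholder_literature"
)

# Parse one config entry, which is either a bare scalar or a
# {value, ci, dist, provenance} mapping.
.parse_entry <- function(entry, name) {
  if (is.list(entry) && !is.null(entry$value)) {
    list(value = entry$value,
         ci = if (!is.null(entry$ci)) as.numeric(entry$ci) else NULL,
         dist = if (!is.null(entry$dist)) entry$dist else "fixed",
         provenance = if (!is.null(entry$provenance)) entry$provenance
                      else "placeholder_literature")
  } else {
    list(value = entry, ci = NULL, dist = "fixed",
         provenance = "placeholder_literature")
  }
}

.parse_block <- function(block) {
  lapply(stats::setNames(names(block), names(block)),
         function(nm) .parse_entry(block[[nm]], nm))
}

#' Load and validate a model parameter configuration
#'
#' Reads a YAML configuration (or an equivalent already-parsed list) holding
#' every input of the lifetime simulation model: 18-month outcome
#' probabilities per arm, the QALY and flexion-deformity regression
#' coefficients, structural assumptions (cycle length, horizon, discounting,
#' quiescence duration, the 30-degree late-stage threshold), treatment
#' costs, and the late-stage surgical-pathway and mortality inputs. When the
#' configuration omits `late_stage_params` or `mortality_params`, the
#' packaged placeholder file ([late_stage_defaults_file()]) fills them in;
#' those values are synthetic placeholders for literature-derived inputs and
#' carry the `placeholder_literature` provenance tag.
#'
#' @param config Path to a YAML file, or a nested list with the same
#'   structure. `NULL` (default) loads the packaged default configuration.
#' @return An object of class `dd_parameters`: a list of point estimates
#'   with nested `late_stage_params` and `mortality_params`, plus a `meta`
#'   element recording each parameter's 95% interval, sampling distribution
#'   and provenance tag.
#' @export
load_parameters <- function(config = NULL) {
  if (is.null(config)) config <- default_parameter_file()
  raw <- if (is.character(config)) yaml::read_yaml(config) else config
  if (!is.list(raw)) stop("configuration must be a YAML file or a list")

  missing <- setdiff(.dd_required_fields, names(raw))
  if (length(missing) > 0) {
    stop("configuration error: missing required field(s): ",
         paste(missing, collapse = ", "))
  }

  entries <- .parse_block(raw[.dd_required_fields])

  defaults <- yaml::read_yaml(late_stage_defaults_file())
  ls_raw <- if (!is.null(raw$late_stage_params)) raw$late_stage_params
            else defaults$late_stage_params
  mort_raw <- if (!is.null(raw$mortality_params)) raw$mortality_params
              else defaults$mortality_params
  ls_entries <- .parse_block(ls_raw)
  mort_entries <- .parse_block(mort_raw)

  miss_ls <- setdiff(.dd_late_stage_fields, names(ls_entries))
  if (length(miss_ls) > 0) {
    stop("configuration error: late_stage_params missing field(s): ",
         paste(miss_ls, collapse = ", "))
  }
  miss_mort <- setdiff(.dd_mortality_fields, names(mort_entries))
  if (length(miss_mort) > 0) {
    stop("configuration error: mortality_params missing field(s): ",
         paste(miss_mort, collapse = ", "))
  }

  params <- lapply(entries, `[[`, "value")
  params$wtp_grid <- as.numeric(params$wtp_grid)
  params$late_stage_params <- lapply(ls_entries, `[[`, "value")
  params$mortality_params <- lapply(mort_entries, `[[`, "value")
  params$mortality_params$life_table <- NULL
  if (!is.null(raw$mortality_params$life_table)) {
    lt <- raw$mortality_params$life_table
    params$mortality_params$life_table <-
      if (is.character(lt)) utils::read.csv(lt) else as.data.frame(lt)
  }

  meta <- c(
    lapply(entries, function(e) e[c("ci", "dist", "provenance")]),
    stats::setNames(
      lapply(ls_entries, function(e) e[c("ci", "dist", "provenance")]),
      paste0("ls_", names(ls_entries))),
    stats::setNames(
      lapply(mort_entries, function(e) e[c("ci", "dist", "provenance")]),
      paste0("mort_", names(mort_entries)))
  )
  params$meta <- meta
  class(params) <- "dd_parameters"
  validate_parameters(params)
  params
}

#' Validate a `dd_parameters` object
#'
#' Checks the structural invariants of the model inputs: probabilities lie
#' in \[0, 1\] and the late-stage plus quiescence probabilities sum to at
#' most 1 within each arm; the cycle length is positive and divides the
#' horizon; costs and the discount rate are non-negative; every parameter
#' carries a recognized provenance tag.
#'
#' @param params A `dd_parameters` object.
#' @return `params`, invisibly; stops with a descriptive error otherwise.
#' @export
validate_parameters <- function(params) {
  prob_fields <- c("p_late_placebo", "p_quiescent_placebo", "p_late_ada",
                   "p_quiescent_ada", "discount_rate")
  for (f in prob_fields) {
    v <- params[[f]]
    if (!is.numeric(v) || v < 0 || v > 1) {
      stop("validation error: ", f, " = ", v, " is outside [0, 1]")
    }
  }
  if (params$p_late_placebo + params$p_quiescent_placebo > 1 + 1e-12) {
    stop("validation error: p_late_placebo + p_quiescent_placebo > 1")
  }
  if (params$p_late_ada + params$p_quiescent_ada > 1 + 1e-12) {
    stop("validation error: p_late_ada + p_quiescent_ada > 1")
  }
  if (params$cycle_length <= 0) {
    stop("validation error: cycle_length must be positive")
  }
  n_cyc <- params$horizon / params$cycle_length
  if (abs(n_cyc - round(n_cyc)) > 1e-9) {
    stop("validation error: horizon must be an integer multiple of ",
         "cycle_length")
  }
  for (f in c("cost_per_dose", "trial_other_cost")) {
    if (params[[f]] < 0) stop("validation error: ", f, " must be >= 0")
  }
  if (params$quiescence_duration <= 0) {
    stop("validation error: quiescence_duration must be positive")
  }
  ls <- params$late_stage_params
  for (f in grep("^p_", .dd_late_stage_fields, value = TRUE)) {
    if (ls[[f]] < 0 || ls[[f]] > 1) {
      stop("validation error: late_stage_params$", f, " is outside [0, 1]")
    }
  }
  for (f in grep("^cost_", .dd_late_stage_fields, value = TRUE)) {
    if (ls[[f]] < 0) {
      stop("validation error: late_stage_params$", f, " must be >= 0")
    }
  }
  tags <- vapply(params$meta, function(m) m$provenance, character(1))
  bad <- tags[!tags %in% .dd_provenance_tags]
  if (length(bad) > 0) {
    stop("validation error: unknown provenance tag(s): ",
         paste(unique(bad), collapse = ", "))
  }
  invisible(params)
}

#' @export
print.dd_parameters <- function(x, ...) {
  cat("<dd_parameters>\n")
  cat(sprintf("  18-month outcomes (placebo): late %.4f, quiescent %.4f\n",
              x$p_late_placebo, x$p_quiescent_placebo))
  cat(sprintf("  18-month outcomes (adalimumab): late %.4f, quiescent %.4f\n",
              x$p_late_ada, x$p_quiescent_ada))
  cat(sprintf("  quiescence duration %.1f y, cycle %.1f y, horizon %d y,\n",
              x$quiescence_duration, x$cycle_length, as.integer(x$horizon)))
  cat(sprintf("  discount %.1f%%/y beyond %.1f y, course cost %d x GBP %d\n",
              100 * x$discount_rate, x$trial_period,
              as.integer(x$doses_per_course), as.integer(x$cost_per_dose)))
  invisible(x)
}

# Derive a 32-bit substream seed from a master seed. Streams are used to
# keep parameter sampling, cohort generation and trajectory simulation
# reproducible yet independent.
derive_seed <- function(master, stream) {
  m <- 2147483629
  as.integer(((as.numeric(master) %% m) * 48271 + as.numeric(stream)) %% m)
}

# Implied standard deviation of a parameter from its 95% interval, assuming
# approximate normality of the bootstrap distribution.
.sd_from_ci <- function(ci) (ci[2] - ci[1]) / (2 * stats::qnorm(0.975))

# Dirichlet concentration implied by the printed means and interval widths
# of the two reported categories of one arm.
.dirichlet_alpha0 <- function(p_late, ci_late, p_q, ci_q) {
  a0 <- function(p, ci) p * (1 - p) / .sd_from_ci(ci)^2 - 1
  mean(c(a0(p_late, ci_late), a0(p_q, ci_q)))
}

.rdirichlet3 <- function(n, alpha) {
  g <- matrix(stats::rgamma(3 * n, shape = rep(alpha, each = n)), nrow = n)
  g / rowSums(g)
}

# Sample one scalar parameter column for the PSA given its meta entry.
.sample_column <- function(n, value, meta) {
  ci <- meta$ci
  switch(meta$dist,
    fixed = rep(value, n),
    normal = stats::rnorm(n, value, .sd_from_ci(ci)),
    uniform = stats::runif(n, ci[1], ci[2]),
    gamma = {
      s <- .sd_from_ci(ci)
      stats::rgamma(n, shape = value^2 / s^2, rate = value / s^2)
    },
    beta = {
      v <- .sd_from_ci(ci)^2
      ab <- value * (1 - value) / v - 1
      if (!is.finite(ab) || ab <= 0) ab <- 1e6
      stats::rbeta(n, value * ab, (1 - value) * ab)
    },
    lognormal = {
      sdlog <- (log(ci[2]) - log(ci[1])) / (2 * stats::qnorm(0.975))
      stats::rlnorm(n, log(value), sdlog)
    },
    stop("unknown sampling distribution: ", meta$dist)
  )
}

#' Sample parameter sets for probabilistic sensitivity analysis
#'
#' Draws `n_draws` joint realizations of every uncertain model input. The
#' four 18-month outcome probabilities are sampled jointly per arm from a
#' three-category Dirichlet (late-stage / quiescent / still-progressive)
#' whose concentration is matched to the printed means and 95% interval
#' widths, which guarantees `p_late + p_quiescent <= 1` in every draw.
#' Regression coefficients and the quiescence utility gain are Normal with
#' SD derived from their 95% intervals; the quiescence duration is Uniform
#' over its sensitivity range (1.5 to 5 years); costs are Gamma,
#' placeholder probabilities Beta, and the mortality hazard ratio
#' log-Normal. Parameters without an interval (e.g. the flexion-deformity
#' residual SD) are held fixed.
#'
#' @param params A `dd_parameters` object (the point estimates).
#' @param n_draws Number of parameter sets to draw (>= 1).
#' @param seed Integer seed; identical inputs give bit-identical draws.
#' @return An object of class `dd_parameter_draws`: list with `n_draws`,
#'   `seed`, the base `params`, and `draws`, a data frame with one row per
#'   draw and one column per sampled parameter (late-stage placeholder
#'   columns are prefixed `ls_`, mortality columns `mort_`).
#' @export
sample_psa <- function(params, n_draws, seed = 1L) {
  if (!inherits(params, "dd_parameters")) stop("params must be dd_parameters")
  if (n_draws < 1) stop("argument error: n_draws must be >= 1")
  n_draws <- as.integer(n_draws)
  old <- .Random.seed_guard(derive_seed(seed, 101L))
  on.exit(old(), add = TRUE)

  m <- params$meta
  a0_pl <- .dirichlet_alpha0(params$p_late_placebo, m$p_late_placebo$ci,
                             params$p_quiescent_placebo,
                             m$p_quiescent_placebo$ci)
  a0_ad <- .dirichlet_alpha0(params$p_late_ada, m$p_late_ada$ci,
                             params$p_quiescent_ada, m$p_quiescent_ada$ci)
  pl <- .rdirichlet3(n_draws, a0_pl * c(params$p_late_placebo,
                                        params$p_quiescent_placebo,
                                        1 - params$p_late_placebo -
                                          params$p_quiescent_placebo))
  ad <- .rdirichlet3(n_draws, a0_ad * c(params$p_late_ada,
                                        params$p_quiescent_ada,
                                        1 - params$p_late_ada -
                                          params$p_quiescent_ada))
  draws <- data.frame(
    p_late_placebo = pl[, 1], p_quiescent_placebo = pl[, 2],
    p_late_ada = ad[, 1], p_quiescent_ada = ad[, 2]
  )

  scalar_fields <- c("qaly_gain_quiescence", "qaly_reg_baseline_utility_coef",
                     "qaly_reg_constant", "fd_change_constant",
                     "fd_change_ectopic_coef", "quiescence_duration",
                     "trial_other_cost")
  for (f in scalar_fields) {
    draws[[f]] <- .sample_column(n_draws, params[[f]], m[[f]])
  }
  for (f in .dd_late_stage_fields) {
    key <- paste0("ls_", f)
    draws[[key]] <- .sample_column(n_draws, params$late_stage_params[[f]],
                                   m[[key]])
  }
  draws$mort_hazard_ratio <- .sample_column(
    n_draws, params$mortality_params$hazard_ratio, m$mort_hazard_ratio)

  # Disutilities may not push utilities below the EQ-5D floor by
  # construction; clip negative Normal draws of non-negative quantities.
  for (f in grep("^ls_disutility", names(draws), value = TRUE)) {
    draws[[f]] <- pmax(draws[[f]], 0)
  }

  structure(list(n_draws = n_draws, seed = seed, params = params,
                 draws = draws),
            class = "dd_parameter_draws")
}

#' Materialize one PSA draw as a full parameter set
#'
#' @param psa_draws A `dd_parameter_draws` object from [sample_psa()].
#' @param i Draw index in `1:n_draws`.
#' @return A `dd_parameters` object with the sampled values substituted.
#' @export
realize_draw <- function(psa_draws, i) {
  if (!inherits(psa_draws, "dd_parameter_draws")) {
    stop("psa_draws must be a dd_parameter_draws object")
  }
  if (i < 1 || i > psa_draws$n_draws) stop("draw index out of range")
  p <- psa_draws$params
  row <- psa_draws$draws[i, ]
  for (f in setdiff(names(row), c())) {
    if (startsWith(f, "ls_")) {
      p$late_stage_params[[sub("^ls_", "", f)]] <- row[[f]]
    } else if (startsWith(f, "mort_")) {
      p$mortality_params[[sub("^mort_", "", f)]] <- row[[f]]
    } else {
      p[[f]] <- row[[f]]
    }
  }
  p
}

# Set the RNG to a given seed and return a restore function.
.Random.seed_guard <- function(seed) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  function() {
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }
}
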