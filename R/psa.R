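#' Run the probabilistic sensitivity analysis
#'
#' For each sampled parameter set, simulates the whole cohort (each patient
#' `n_reps` times) under every strategy with common random numbers across
#' strategies, and records the per-draw mean discounted costs and QALYs
#' together with the supporting outcomes (life years, years with
#' early-stage disease, treatment courses, operations).
#'
#' @param cohort A `dd_cohort` data frame.
#' @param psa_draws A `dd_parameter_draws` from [sample_psa()].
#' @param strategies Character vector of strategy names.
#' @param n_reps Repetitions per patient per draw (>= 1).
#' @param seed Integer seed for the simulation streams.
#' @return An object of class `dd_psa`: list with `metrics` (named list of
#'   `n_draws` x `n_strategies` matrices), `strategies`, `n_draws`,
#'   `n_reps`, `seed` and the originating `psa_draws`.
#' @export
run_psa <- function(cohort, psa_draws, strategies = dd_strategies(),
                    n_reps = 1L, seed = 1L) {
  if (nrow(cohort) == 0) stop("argument error: empty cohort")
  if (n_reps < 1) stop("argument error: n_reps must be >= 1")
  n_draws <- psa_draws$n_draws
  metric_names <- c("qaly_trial", "qaly_model", "qaly_total", "cost_trial",
                    "cost_model", "cost_total", "life_years", "early_years",
                    "courses", "operations")
  metrics <- lapply(stats::setNames(metric_names, metric_names), function(x)
    matrix(NA_real_, n_draws, length(strategies),
           dimnames = list(NULL, strategies)))

  big <- cohort[rep(seq_len(nrow(cohort)), times = n_reps), , drop = FALSE]
  m <- nrow(big)

  for (d in seq_len(n_draws)) {
    params_d <- realize_draw(psa_draws, d)
    n_cycles <- as.integer(round((params_d$horizon - params_d$trial_period) /
                                   params_d$cycle_length))
    streams <- make_streams(n_cycles, m, derive_seed(seed, 10000L + d))
    restore <- .Random.seed_guard(derive_seed(seed, 20000L + d))
    u_outcome <- stats::runif(m)
    restore()
    for (s_idx in seq_along(strategies)) {
      spec <- strategy_spec(strategies[s_idx])
      pl <- spec$arm == "placebo"
      code <- outcome_from_uniform(
        u_outcome,
        if (pl) params_d$p_late_placebo else params_d$p_late_ada,
        if (pl) params_d$p_quiescent_placebo else params_d$p_quiescent_ada)
      sm <- simulate_batch(big, spec, code, params_d, streams)$summary
      for (mn in metric_names) {
        metrics[[mn]][d, s_idx] <- mean(sm[[mn]])
      }
    }
  }
  structure(list(metrics = metrics, strategies = strategies,
                 n_draws = n_draws, n_reps = n_reps, seed = seed,
                 psa_draws = psa_draws),
            class = "dd_psa")
}

#' Write PSA samples to CSV
#'
#' Long format: one row per draw and strategy with the per-draw mean
#' discounted cost and QALYs.
#'
#' @param psa A `dd_psa` object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_psa <- function(psa, path) {
  df <- data.frame(
    draw = rep(seq_len(psa$n_draws), times = length(psa$strategies)),
    strategy = rep(psa$strategies, each = psa$n_draws),
    mean_cost = as.vector(psa$metrics$cost_total),
    mean_qaly = as.vector(psa$metrics$qaly_total)
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

# Net-monetary-benefit matrix (draws x strategies) at willingness to pay.
.nb_matrix <- function(psa, wtp) {
  wtp * psa$metrics$qaly_total - psa$metrics$cost_total
}

# Index of the NB-maximizing strategy per draw; ties go to the cheaper
# strategy in that draw.
.nb_winner <- function(nb, cost) {
  mx <- nb == matrix(apply(nb, 1, max), nrow(nb), ncol(nb))
  cost_w <- ifelse(mx, cost, Inf)
  max.col(-cost_w, ties.method = "first")
}

#' Cost-effectiveness acceptability curves
#'
#' For each willingness-to-pay value, the probability that each strategy
#' has the highest net monetary benefit across PSA draws (ties credited to
#' the cheaper strategy in that draw), and the cost-effectiveness frontier
#' (the strategy with maximal mean net benefit).
#'
#' @param psa A `dd_psa` object (>= 1 draw).
#' @param wtp_grid Willingness-to-pay values, GBP per QALY.
#' @return Data frame with columns `wtp`, `strategy`, `probability`,
#'   `on_frontier`. Probabilities sum to 1 at each `wtp`.
#' @export
ceac <- function(psa, wtp_grid = NULL) {
  if (psa$n_draws < 1) stop("argument error: need >= 1 draw")
  if (is.null(wtp_grid)) wtp_grid <- psa$psa_draws$params$wtp_grid
  cost <- psa$metrics$cost_total
  out <- lapply(wtp_grid, function(l) {
    nb <- .nb_matrix(psa, l)
    win <- .nb_winner(nb, cost)
    prob <- tabulate(win, nbins = length(psa$strategies)) / psa$n_draws
    frontier <- which.max(colMeans(nb))
    data.frame(wtp = l, strategy = psa$strategies, probability = prob,
               on_frontier = seq_along(psa$strategies) == frontier,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Per-patient expected value of perfect information
#'
#' EVPI at a willingness-to-pay threshold: the mean over PSA draws of the
#' best achievable net monetary benefit, minus the net benefit of the
#' strategy that is best on average. Non-negative by construction.
#'
#' @param psa A `dd_psa` object (>= 2 draws).
#' @param wtp Willingness to pay, GBP per QALY.
#' @return EVPI in GBP per patient.
#' @export
evpi_per_patient <- function(psa, wtp) {
  if (psa$n_draws < 2) stop("argument error: need >= 2 draws")
  nb <- .nb_matrix(psa, wtp)
  mean(apply(nb, 1, max)) - max(colMeans(nb))
}

#' Per-patient expected value of partial perfect information
#'
#' Single-loop regression estimator: each strategy's net monetary benefit
#' is regressed on the sampled values of the parameter subset using a
#' generalized additive model (thin-plate spline smoother per parameter);
#' EVPPI is the mean of the per-draw maximum fitted net benefit minus the
#' maximum of the mean fitted net benefits, clipped at zero.
#'
#' @param psa A `dd_psa` object.
#' @param param_subset Character vector of sampled parameter names (columns
#'   of `psa$psa_draws$draws`). The name `"trial"` expands to the
#'   trial-estimated parameters plus the quiescence duration.
#' @param wtp Willingness to pay, GBP per QALY.
#' @param k Basis dimension per smooth; defaults to a size suited to the
#'   number of draws.
#' @return EVPPI in GBP per patient.
#' @export
evppi <- function(psa, param_subset, wtp, k = NULL) {
  if (length(param_subset) == 0) stop("argument error: empty subset")
  if (identical(param_subset, "trial")) param_subset <- trial_parameter_names()
  draws <- psa$psa_draws$draws
  unknown <- setdiff(param_subset, names(draws))
  if (length(unknown) > 0) {
    stop("argument error: unknown parameter(s): ",
         paste(unknown, collapse = ", "))
  }
  # constant columns carry no information and break the smoother
  varying <- param_subset[vapply(draws[param_subset],
                                 function(x) stats::sd(x) > 0, logical(1))]
  if (length(varying) == 0) return(0)
  if (is.null(k)) {
    k <- max(3, min(10, floor(psa$n_draws / (3 * length(varying)))))
  }
  nb <- .nb_matrix(psa, wtp)
  form <- stats::as.formula(paste(
    "nb_s ~", paste(sprintf("s(%s, k = %d)", varying, k), collapse = " + ")))
  fitted <- sapply(seq_len(ncol(nb)), function(s) {
    dat <- draws[varying]
    dat$nb_s <- nb[, s]
    stats::fitted(mgcv::gam(form, data = dat))
  })
  max(0, mean(apply(fitted, 1, max)) - max(colMeans(fitted)))
}

#' Names of the trial-estimated parameters plus the quiescence duration
#'
#' The parameter subset whose perfect resolution a confirmatory trial of
#' the same design could achieve: the four 18-month outcome probabilities,
#' the QALY regression coefficients (including the quiescence utility
#' gain), the flexion-deformity regression coefficients, and the duration
#' of quiescence.
#'
#' @return Character vector of sampled-parameter column names.
#' @export
trial_parameter_names <- function() {
  c("p_late_placebo", "p_quiescent_placebo", "p_late_ada",
    "p_quiescent_ada", "qaly_gain_quiescence",
    "qaly_reg_baseline_utility_coef", "qaly_reg_constant",
    "fd_change_constant", "fd_change_ectopic_coef", "quiescence_duration")
}

#' Scale a per-patient value to the eligible population
#'
#' A bare product: per-patient value times the number of prevalent cases
#' (no incidence stream or population discounting).
#'
#' @param per_patient Value per patient, GBP (>= 0).
#' @param population Number of cases (>= 0).
#' @return Population value, GBP.
#' @export
population_value <- function(per_patient, population) {
  if (per_patient < 0 || population < 0) {
    stop("argument error: inputs must be >= 0")
  }
  per_patient * population
}

# Replace one (possibly nested) parameter value by flat column name.
set_param <- function(params, name, value) {
  if (startsWith(name, "ls_")) {
    params$late_stage_params[[sub("^ls_", "", name)]] <- value
  } else if (startsWith(name, "mort_")) {
    params$mortality_params[[sub("^mort_", "", name)]] <- value
  } else {
    params[[name]] <- value
  }
  params
}

#' One-way (tornado) sensitivity analysis
#'
#' Varies each uncertain parameter to its lower and upper bound (by default
#' its 95% interval, or its sensitivity range where that is what is
#' specified, e.g. 1.5 to 5 years for the quiescence duration), holding all
#' other parameters at their point estimates, and recomputes the ICER of
#' repeated adalimumab courses versus standard care with common random
#' numbers across runs. Results are sorted by the ICER span.
#'
#' @param params A `dd_parameters` object (the base case).
#' @param cohort A `dd_cohort`.
#' @param param_ranges Named list of `c(low, high)` ranges; defaults to
#'   every parameter with an interval in the configuration.
#' @param n_reps Repetitions per patient per run.
#' @param seed Integer seed (shared across runs).
#' @return Data frame with columns `parameter`, `low`, `high`,
#'   `icer_low`, `icer_high`, `icer_base`, sorted by decreasing span.
#' @export
one_way_sa <- function(params, cohort, param_ranges = NULL, n_reps = 50L,
                       seed = 1L) {
  if (is.null(param_ranges)) {
    has_ci <- names(params$meta)[vapply(params$meta, function(m)
      !is.null(m$ci) && !identical(m$dist, "fixed"), logical(1))]
    param_ranges <- lapply(stats::setNames(has_ci, has_ci),
                           function(nm) params$meta[[nm]]$ci)
  }
  strategies <- c("standard_care", "adalimumab_repeat")
  run_icer <- function(p) {
    res <- simulate_strategies(cohort, p, strategies, n_reps = n_reps,
                               seed = seed)
    dq <- res$qaly_total[2] - res$qaly_total[1]
    dc <- res$cost_total[2] - res$cost_total[1]
    if (dq == 0) NA_real_ else dc / dq
  }
  icer_base <- run_icer(params)
  rows <- lapply(names(param_ranges), function(nm) {
    rng <- param_ranges[[nm]]
    data.frame(parameter = nm, low = rng[1], high = rng[2],
               icer_low = run_icer(set_param(params, nm, rng[1])),
               icer_high = run_icer(set_param(params, nm, rng[2])),
               icer_base = icer_base, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  span <- abs(out$icer_high - out$icer_low)
  out[order(-span), , drop = FALSE]
}
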