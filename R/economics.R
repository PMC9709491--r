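#' Discount factor at a given time from randomization
#'
#' Costs and utilities accrued during the 18-month trial period are not
#' discounted; beyond it they are discounted at the annual rate, i.e.
#' `(1 + rate)^-(t - trial_period)`.
#'
#' @param t Time from randomization, years (vectorized, >= 0).
#' @param params A `dd_parameters` object.
#' @return Discount factors in (0, 1\].
#' @export
discount_factor <- function(t, params) {
  if (any(t < 0)) stop("argument error: t must be >= 0")
  ifelse(t <= params$trial_period + 1e-12, 1,
         (1 + params$discount_rate)^(-(t - params$trial_period)))
}

#' Annualized EQ-5D utility by disease state
#'
#' Early-stage utility is predicted from the QALY regression:
#' `constant + coefficient * baseline_utility`, plus the quiescence gain
#' while quiescent. Late-stage states subtract their configured utility
#' decrement from the progressive early-stage utility. Utilities are capped
#' at 1 and floored at the EQ-5D-5L index minimum (-0.594). The dead state
#' has utility 0.
#'
#' @param state State name(s), see [dd_states()].
#' @param baseline_utility Baseline EQ-5D utility (vectorized).
#' @param params A `dd_parameters` object.
#' @return Annualized utility value(s).
#' @export
cycle_utility <- function(state, baseline_utility, params) {
  ls <- params$late_stage_params
  dis_by_state <- c(0, 0, ls$disutility_untreated, ls$disutility_pnf_success,
                    ls$disutility_pnf_failed, ls$disutility_fasciectomy,
                    ls$disutility_dermofasciectomy, 0)
  code <- match(state, dd_states())
  if (any(is.na(code))) stop("unknown state: ", state[is.na(code)][1])
  base <- pmin(1, pmax(-0.594, params$qaly_reg_constant +
                         params$qaly_reg_baseline_utility_coef *
                           baseline_utility))
  u <- base + params$qaly_gain_quiescence * (code == 2L) -
    dis_by_state[code]
  u <- pmin(1, pmax(-0.594, u))
  u[code == 8L] <- 0
  u
}

#' Accrue discounted lifetime cost and QALYs from a trajectory
#'
#' Sums the recorded per-cycle intervention costs and utilities of a
#' simulated trajectory, applying the discount factor at each cycle's start
#' time: QALYs are `utility * cycle_length * discount`, costs are
#' `cost * discount`. Only intervention costs appear in trajectories (no
#' ongoing disease-management cost is modelled post-trial).
#'
#' @param trajectory Trajectory data frame from [simulate_patient()].
#' @param params A `dd_parameters` object.
#' @return List with `cost` (discounted GBP), `qalys` (discounted),
#'   `life_years` (undiscounted, post-trial) and `events` (table of
#'   recorded events).
#' @export
accrue <- function(trajectory, params) {
  d <- discount_factor(trajectory$time, params)
  ev <- trajectory$event[nzchar(trajectory$event)]
  list(cost = sum(trajectory$cost * d),
       qalys = sum(trajectory$utility * params$cycle_length * d),
       life_years = params$cycle_length * nrow(trajectory),
       events = table(unlist(strsplit(ev, " "))))
}

#' Deterministic incremental cost-effectiveness analysis
#'
#' Orders strategies by mean cost, flags strict dominance (another strategy
#' is no more costly and no less effective, strictly better on one) and
#' extended dominance (removed during frontier construction because its
#' incremental cost-effectiveness ratio exceeds that of the next more
#' effective strategy), and computes frontier ICERs between successive
#' non-dominated strategies. A pairwise ICER against `ref` (by default
#' standard care, the conventional comparator) is also reported.
#'
#' @param results Data frame with columns `strategy`, `cost`, `qaly`.
#' @param ref Reference strategy name for pairwise ICERs (`NULL` to skip).
#' @return Data frame sorted by cost with columns `strategy`, `cost`,
#'   `qaly`, `dominated`, `extended_dominated`, `icer_frontier` (vs the
#'   previous frontier strategy; `NA` for the cheapest), and `icer_vs_ref`.
#'   Undefined ratios (zero QALY difference) are returned as `NA` rather
#'   than divided.
#' @export
incremental_analysis <- function(results, ref = "standard_care") {
  if (nrow(results) < 2) stop("argument error: need >= 2 strategies")
  res <- results[order(results$cost, -results$qaly), , drop = FALSE]
  n <- nrow(res)
  dominated <- vapply(seq_len(n), function(i) {
    any(res$cost <= res$cost[i] & res$qaly >= res$qaly[i] &
          (res$cost < res$cost[i] | res$qaly > res$qaly[i]))
  }, logical(1))

  # frontier construction among non-dominated strategies
  cand <- which(!dominated)
  ext <- logical(n)
  repeat {
    k <- length(cand)
    if (k <= 2) break
    icers <- diff(res$qaly[cand])
    icers <- ifelse(icers == 0, Inf, diff(res$cost[cand]) / icers)
    drop <- which(diff(icers) < 0)  # ICER not increasing: middle strategy
    if (length(drop) == 0) break
    ext[cand[drop[1] + 1]] <- TRUE
    cand <- cand[-(drop[1] + 1)]
  }

  icer_frontier <- rep(NA_real_, n)
  if (length(cand) >= 2) {
    dq <- diff(res$qaly[cand])
    dc <- diff(res$cost[cand])
    icer_frontier[cand[-1]] <- ifelse(dq == 0, NA_real_, dc / dq)
  }

  icer_vs_ref <- rep(NA_real_, n)
  if (!is.null(ref) && ref %in% res$strategy) {
    r <- which(res$strategy == ref)
    dq <- res$qaly - res$qaly[r]
    dc <- res$cost - res$cost[r]
    icer_vs_ref <- ifelse(dq == 0, NA_real_, dc / dq)
    icer_vs_ref[r] <- NA_real_
  }

  data.frame(strategy = res$strategy, cost = res$cost, qaly = res$qaly,
             dominated = dominated, extended_dominated = ext,
             icer_frontier = icer_frontier, icer_vs_ref = icer_vs_ref,
             stringsAsFactors = FALSE)
}

#' Simulate all strategies for a cohort at one parameter set
#'
#' Runs the lifetime simulation for every requested strategy with common
#' random numbers (shared streams and shared 18-month outcome deviates), at
#' a single parameter set, averaging over `n_reps` repetitions of each
#' patient.
#'
#' @param cohort A `dd_cohort` data frame.
#' @param params A `dd_parameters` object.
#' @param strategies Character vector of strategy names.
#' @param n_reps Repetitions per patient.
#' @param seed Integer seed.
#' @return Data frame with one row per strategy: mean discounted QALYs and
#'   costs (trial, model, lifetime), life expectancy, years with
#'   early-stage disease, courses of treatment and operations.
#' @export
simulate_strategies <- function(cohort, params, strategies = dd_strategies(),
                                n_reps = 1L, seed = 1L) {
  if (nrow(cohort) == 0) stop("argument error: empty cohort")
  validate_parameters(params)
  big <- cohort[rep(seq_len(nrow(cohort)), times = n_reps), , drop = FALSE]
  m <- nrow(big)
  n_cycles <- as.integer(round((params$horizon - params$trial_period) /
                                 params$cycle_length))
  streams <- make_streams(n_cycles, m, derive_seed(seed, 505L))
  restore <- .Random.seed_guard(derive_seed(seed, 606L))
  u_outcome <- stats::runif(m)
  restore()

  rows <- lapply(strategies, function(s) {
    spec <- strategy_spec(s)
    pl <- spec$arm == "placebo"
    code <- outcome_from_uniform(
      u_outcome,
      if (pl) params$p_late_placebo else params$p_late_ada,
      if (pl) params$p_quiescent_placebo else params$p_quiescent_ada)
    sm <- simulate_batch(big, spec, code, params, streams)$summary
    data.frame(strategy = s,
               qaly_trial = mean(sm$qaly_trial),
               qaly_model = mean(sm$qaly_model),
               qaly_total = mean(sm$qaly_total),
               cost_trial = mean(sm$cost_trial),
               cost_model = mean(sm$cost_model),
               cost_total = mean(sm$cost_total),
               life_years = mean(sm$life_years),
               early_years = mean(sm$early_years),
               courses = mean(sm$courses),
               operations = mean(sm$operations),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
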