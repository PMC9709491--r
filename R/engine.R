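#' Disease-model states
#'
#' The discrete states of the lifetime model: progressive early-stage
#' disease, quiescent early-stage disease, untreated late-stage disease,
#' the post-surgical late-stage states (after an initially successful PNF,
#' after a failed PNF, after limited fasciectomy, after dermofasciectomy)
#' and death. Late-stage entry is permanent (no return to early states) and
#' death is absorbing.
#'
#' @return Character vector of state names in internal coding order.
#' @export
dd_states <- function() {
  c("early_progressive", "early_quiescent", "late_untreated",
    "late_post_pnf_success", "late_post_pnf_failed",
    "late_post_fasciectomy", "late_post_dermofasciectomy", "dead")
}

#' Build a treatment strategy specification
#'
#' @param name One of `"standard_care"` (no treatment for early-stage
#'   disease), `"adalimumab_once"` (a single course of four injections) or
#'   `"adalimumab_repeat"` (retreatment with a further course each time the
#'   nodule reactivates, in patients quiescent after the initial course).
#' @return A list with elements `name`, `initial_course`,
#'   `retreat_on_reactivation` and `arm` (which arm's 18-month outcome
#'   probabilities apply).
#' @export
strategy_spec <- function(name = dd_strategies()) {
  name <- match.arg(name)
  list(name = name,
       initial_course = name != "standard_care",
       retreat_on_reactivation = name == "adalimumab_repeat",
       arm = if (name == "standard_care") "placebo" else "ada")
}

# Annual all-cause mortality hazard at a given age, before the
# disease-specific hazard ratio. Uses the user-supplied life table when
# present, otherwise the synthetic Gompertz form h(age) = a_sex*exp(b*age).
.annual_hazard <- function(age, sex, mortality_params) {
  mp <- mortality_params
  if (!is.null(mp$life_table)) {
    lt <- mp$life_table
    a <- pmin(floor(age), max(lt$age))
    key <- paste(a, sex)
    idx <- match(key, paste(lt$age, lt$sex))
    h <- lt$hazard[idx]
    h[is.na(h)] <- Inf
    return(h)
  }
  a_sex <- ifelse(sex == "male", mp$gompertz_a_male, mp$gompertz_a_female)
  a_sex * exp(mp$gompertz_b * age)
}

#' Per-cycle probability of death
#'
#' Converts the life-table annual hazard at the patient's current age,
#' multiplied by the disease mortality hazard ratio, to a per-cycle death
#' probability: `q = 1 - exp(-HR * h(age, sex) * cycle_length)`. Mortality
#' is independent of disease state and treatment strategy. Ages at or
#' beyond the life-table maximum return probability 1.
#'
#' @param age Age in years (vectorized).
#' @param sex `"male"` or `"female"` (vectorized).
#' @param params A `dd_parameters` object.
#' @return Per-cycle death probabilities.
#' @export
cycle_mortality_prob <- function(age, sex, params) {
  if (any(age < 0)) stop("argument error: age must be >= 0")
  mp <- params$mortality_params
  h <- mp$hazard_ratio * .annual_hazard(age, sex, mp)
  q <- 1 - exp(-h * params$cycle_length)
  q[age >= mp$max_age] <- 1
  q
}

#' Expected remaining life years from randomization
#'
#' Deterministic expectation of the simulated life years for one patient:
#' the trial period plus one cycle length for every model cycle the patient
#' is expected to start alive (patients accrue the full cycle in which they
#' die, matching the simulation's accrual convention).
#'
#' @param age Age at randomization, years.
#' @param sex `"male"` or `"female"`.
#' @param params A `dd_parameters` object.
#' @return Expected life years from randomization (capped at the horizon).
#' @export
life_expectancy <- function(age, sex, params) {
  n_cycles <- as.integer(round((params$horizon - params$trial_period) /
                                 params$cycle_length))
  t_seq <- params$trial_period + (seq_len(n_cycles) - 1) * params$cycle_length
  q <- cycle_mortality_prob(age + t_seq, rep(sex, n_cycles), params)
  surv_start <- cumprod(c(1, 1 - q[-n_cycles]))
  params$trial_period + params$cycle_length * sum(surv_start)
}

# Per-cycle mean and SD of the flexion-deformity increment, scaled from
# the 18-month regression: a cycle of length L contributes mean*(L/1.5)
# and SD*sqrt(L/1.5), so the sum over 1.5 years reproduces the regression
# mean and residual SD.
.fd_step_moments <- function(params, ectopic) {
  frac <- params$cycle_length / 1.5
  mu18 <- params$fd_change_constant +
    ifelse(ectopic, params$fd_change_ectopic_coef, 0)
  list(mean = mu18 * frac, sd = params$fd_change_rmse * sqrt(frac))
}

#' Expected 18-month change in flexion deformity without treatment
#'
#' Sum of the flexion-deformity regression constant and, for patients with
#' ectopic fibrotic disease, the ectopic coefficient.
#'
#' @param params A `dd_parameters` object.
#' @param ectopic Logical: does the patient have ectopic disease?
#' @return Expected change in degrees over 18 months.
#' @export
expected_fd_change <- function(params, ectopic = FALSE) {
  params$fd_change_constant +
    ifelse(ectopic, params$fd_change_ectopic_coef, 0)
}

#' Advance the flexion deformity by one cycle
#'
#' Adds a Gaussian increment with per-cycle mean `mu18 * cycle/1.5` and SD
#' `rmse * sqrt(cycle/1.5)` (where `mu18` is the 18-month regression mean
#' and `rmse` its residual SD), floored at 0 degrees. The increment may be
#' negative.
#'
#' @param fd Current flexion deformity, degrees (vectorized).
#' @param ectopic Logical vector: ectopic disease.
#' @param params A `dd_parameters` object.
#' @return Updated flexion deformity, degrees.
#' @export
progress_flexion <- function(fd, ectopic, params) {
  if (any(fd < 0)) stop("argument error: fd must be >= 0")
  mom <- .fd_step_moments(params, ectopic)
  pmax(0, fd + stats::rnorm(length(fd), mom$mean, mom$sd))
}

#' Next surgical procedure for a late-stage patient
#'
#' Applies the surgical sequencing rules: up to three PNFs, but PNF is only
#' repeated after a PNF that initially succeeded (post-operative flexion
#' deformity of 5 degrees or less) and then relapsed; after any failed PNF,
#' or once three PNFs are exhausted, the next procedure is a limited
#' fasciectomy (at most one); after a relapsed fasciectomy, a
#' dermofasciectomy (at most one); thereafter best supportive care only.
#' Whether the patient elects surgery in a given cycle is governed
#' separately by `late_stage_params$p_elect_surgery`.
#'
#' @param history List with `n_pnf` (count), `pnf_failed` (logical),
#'   `had_fasciectomy` (logical), `had_dermofasciectomy` (logical).
#' @param params A `dd_parameters` object (unused by the sequencing rules
#'   themselves; accepted for interface symmetry).
#' @return One of `"pnf"`, `"limited_fasciectomy"`, `"dermofasciectomy"`,
#'   `"none"`.
#' @export
next_surgical_event <- function(history, params = NULL) {
  needed <- c("n_pnf", "pnf_failed", "had_fasciectomy",
              "had_dermofasciectomy")
  if (!all(needed %in% names(history))) {
    stop("logic error: incomplete surgical history")
  }
  if (history$n_pnf < 0 || history$n_pnf > 3) {
    stop("logic error: n_pnf must lie in 0..3")
  }
  if (!history$pnf_failed && history$n_pnf < 3 &&
      !history$had_fasciectomy && !history$had_dermofasciectomy) {
    "pnf"
  } else if (!history$had_fasciectomy) {
    "limited_fasciectomy"
  } else if (!history$had_dermofasciectomy) {
    "dermofasciectomy"
  } else {
    "none"
  }
}

#' Generate the per-cycle random streams for a batch of patients
#'
#' Five streams drive the simulation: mortality (indexed by calendar
#' cycle, so life years are identical across strategies under common
#' random numbers), flexion-deformity shocks (indexed by the number of
#' progressive cycles experienced, so delaying progression shifts the same
#' shock sequence later in time), and the surgery election, PNF success
#' and relapse streams (indexed by the number of late-stage cycles).
#'
#' @param n_cycles Number of model cycles.
#' @param m Number of simulated patients (cohort size times repetitions).
#' @param seed Integer seed.
#' @return List of five `n_cycles` x `m` matrices.
#' @export
make_streams <- function(n_cycles, m, seed) {
  restore <- .Random.seed_guard(derive_seed(seed, 404L))
  on.exit(restore(), add = TRUE)
  list(
    u_mort = matrix(stats::runif(n_cycles * m), n_cycles, m),
    z_fd = matrix(stats::rnorm(n_cycles * m), n_cycles, m),
    u_elect = matrix(stats::runif(n_cycles * m), n_cycles, m),
    u_succ = matrix(stats::runif(n_cycles * m), n_cycles, m),
    u_relapse = matrix(stats::runif(n_cycles * m), n_cycles, m)
  )
}

# Vectorized lifetime simulation of a batch of patients under one strategy.
#
# cohort: data frame with age, sex, baseline_utility, baseline_fd, ectopic
#   (one row per simulated patient; replicate rows for repetitions).
# outcome_code: integer 18-month outcome per row (1 late, 2 quiescent,
#   3 progressive), already assigned under this strategy's arm.
# streams: matrices from make_streams(); sharing streams across strategies
#   implements common random numbers.
#
# Returns a list with per-patient accrual summaries and, if record = TRUE,
# per-cycle trajectory matrices.
simulate_batch <- function(cohort, strategy, outcome_code, params, streams,
                           record = FALSE) {
  m <- nrow(cohort)
  if (m == 0) stop("argument error: empty cohort")
  cl <- params$cycle_length
  n_cycles <- as.integer(round((params$horizon - params$trial_period) / cl))
  t_seq <- params$trial_period + (seq_len(n_cycles) - 1) * cl
  disc <- discount_factor(t_seq, params)

  ls <- params$late_stage_params
  dis_by_state <- c(0, 0, ls$disutility_untreated, ls$disutility_pnf_success,
                    ls$disutility_pnf_failed, ls$disutility_fasciectomy,
                    ls$disutility_dermofasciectomy, 0)
  op_cost <- c(ls$cost_pnf, ls$cost_fasciectomy, ls$cost_dermofasciectomy)
  rel_by_state <- c(NA, NA, NA, ls$p_relapse_pnf, NA,
                    ls$p_relapse_fasciectomy, ls$p_relapse_dermofasciectomy,
                    NA)
  course_cost <- params$doses_per_course * params$cost_per_dose
  qd <- params$quiescence_duration
  thr <- params$late_stage_threshold

  util0 <- pmin(1, pmax(-0.594, params$qaly_reg_constant +
                          params$qaly_reg_baseline_utility_coef *
                            cohort$baseline_utility))
  mom_frac <- cl / 1.5
  mu_cycle <- (params$fd_change_constant +
                 ifelse(cohort$ectopic, params$fd_change_ectopic_coef, 0)) *
    mom_frac
  sd_cycle <- params$fd_change_rmse * sqrt(mom_frac)
  hr <- params$mortality_params$hazard_ratio
  max_age <- params$mortality_params$max_age

  # initial state at trial end
  state <- integer(m)
  state[outcome_code == 1L] <- 3L
  state[outcome_code == 2L] <- 2L
  state[outcome_code == 3L] <- 1L
  fd <- cohort$baseline_fd
  q_end <- rep(Inf, m)
  q_end[state == 2L] <- params$trial_period + qd
  n_pnf <- integer(m)
  pnf_failed <- logical(m)
  had_fasc <- logical(m)
  had_dermo <- logical(m)
  fd_k <- integer(m)     # progressive cycles experienced
  late_k <- integer(m)   # late-stage cycles experienced

  courses <- as.numeric(rep(strategy$initial_course, m))
  ops <- numeric(m)
  cost_model <- numeric(m)
  qaly_model <- numeric(m)
  life_cycles <- integer(m)
  early_cycles <- integer(m)
  t_late <- rep(NA_real_, m)
  t_late[state == 3L] <- params$trial_period

  # trial-period accrual: everyone survives and holds early-stage disease
  # through the trial; the quiescence utility gain applies over the 6-18
  # month window in which it was estimated (one year).
  qaly_trial <- params$trial_period * util0 +
    params$qaly_gain_quiescence * 1.0 * (outcome_code == 2L)
  cost_trial <- rep(params$trial_other_cost, m) +
    course_cost * as.numeric(strategy$initial_course)

  if (record) {
    rec_state <- matrix(NA_integer_, n_cycles, m)
    rec_fd <- matrix(NA_real_, n_cycles, m)
    rec_cost <- matrix(NA_real_, n_cycles, m)
    rec_util <- matrix(NA_real_, n_cycles, m)
    rec_event <- matrix("", n_cycles, m)
  }

  for (i in seq_len(n_cycles)) {
    t <- t_seq[i]
    d <- disc[i]
    alive <- state != 8L
    if (!any(alive)) break
    cycle_cost <- numeric(m)
    event <- if (record) character(m) else NULL

    # 1. end of quiescence: retreat (same cycle) or resume progression
    qend <- which(alive & state == 2L & t >= q_end - 1e-9)
    if (length(qend) > 0) {
      if (strategy$retreat_on_reactivation) {
        courses[qend] <- courses[qend] + 1
        cycle_cost[qend] <- cycle_cost[qend] + course_cost
        q_end[qend] <- q_end[qend] + qd
        if (record) event[qend] <- "course_started"
      } else {
        state[qend] <- 1L
      }
    }

    # 2. late-stage pathway: capture surgery-eligible set, then relapses
    elig <- which(alive & (state == 3L | state == 5L))
    post <- which(alive & (state == 4L | state == 6L | state == 7L))
    if (length(post) > 0) {
      k <- pmin(late_k[post] + 1L, n_cycles)
      u <- streams$u_relapse[cbind(k, post)]
      rel <- post[u < rel_by_state[state[post]]]
      state[rel] <- 3L
      if (record && length(rel) > 0) event[rel] <- "relapse"
    }
    if (length(elig) > 0) {
      k <- pmin(late_k[elig] + 1L, n_cycles)
      el <- elig[streams$u_elect[cbind(k, elig)] < ls$p_elect_surgery]
      if (length(el) > 0) {
        can_pnf <- !pnf_failed[el] & n_pnf[el] < 3L & !had_fasc[el] &
          !had_dermo[el]
        op <- ifelse(can_pnf, 1L,
                     ifelse(!had_fasc[el], 2L,
                            ifelse(!had_dermo[el], 3L, 0L)))
        pn <- el[op == 1L]
        if (length(pn) > 0) {
          n_pnf[pn] <- n_pnf[pn] + 1L
          ku <- pmin(late_k[pn] + 1L, n_cycles)
          succ <- streams$u_succ[cbind(ku, pn)] < ls$p_pnf_success
          state[pn] <- ifelse(succ, 4L, 5L)
          pnf_failed[pn] <- pnf_failed[pn] | !succ
          cycle_cost[pn] <- cycle_cost[pn] + op_cost[1]
          ops[pn] <- ops[pn] + 1
          if (record) event[pn] <- ifelse(succ, "pnf_success", "pnf_failed")
        }
        lf <- el[op == 2L]
        if (length(lf) > 0) {
          had_fasc[lf] <- TRUE
          state[lf] <- 6L
          cycle_cost[lf] <- cycle_cost[lf] + op_cost[2]
          ops[lf] <- ops[lf] + 1
          if (record) event[lf] <- "limited_fasciectomy"
        }
        df_ <- el[op == 3L]
        if (length(df_) > 0) {
          had_dermo[df_] <- TRUE
          state[df_] <- 7L
          cycle_cost[df_] <- cycle_cost[df_] + op_cost[3]
          ops[df_] <- ops[df_] + 1
          if (record) event[df_] <- "dermofasciectomy"
        }
      }
    }

    # 3. accrual for the full cycle (patients alive at cycle start accrue
    # the whole cycle; survival to the next cycle is tested afterwards)
    util <- util0 + params$qaly_gain_quiescence * (state == 2L) -
      dis_by_state[state]
    util <- pmin(1, pmax(-0.594, util))
    qaly_model <- qaly_model + ifelse(alive, util * cl * d, 0)
    cost_model <- cost_model + cycle_cost * d
    life_cycles <- life_cycles + alive
    early_now <- alive & state <= 2L
    early_cycles <- early_cycles + early_now

    # track late-stage exposure for the surgery streams
    late_now <- alive & state >= 3L & state <= 7L
    late_k[late_now] <- late_k[late_now] + 1L

    # 4. flexion-deformity random walk for progressive patients
    prog <- which(alive & state == 1L)
    if (length(prog) > 0) {
      j <- pmin(fd_k[prog] + 1L, n_cycles)
      delta <- mu_cycle[prog] + sd_cycle * streams$z_fd[cbind(j, prog)]
      fd[prog] <- pmax(0, fd[prog] + delta)
      fd_k[prog] <- fd_k[prog] + 1L
      nl <- prog[fd[prog] > thr]
      if (length(nl) > 0) {
        state[nl] <- 3L
        t_late[nl] <- t + cl
      }
    }

    if (record) {
      rec_state[i, ] <- ifelse(alive, state, 8L)
      rec_fd[i, ] <- fd
      rec_cost[i, ] <- cycle_cost
      rec_util[i, ] <- ifelse(alive, util, NA_real_)
      rec_event[i, ] <- event
    }

    # 5. survival to the next cycle
    age_now <- cohort$age + t
    q <- 1 - exp(-hr * .annual_hazard(age_now, cohort$sex,
                                      params$mortality_params) * cl)
    q[age_now >= max_age] <- 1
    die <- alive & streams$u_mort[i, ] < q
    if (record && any(die)) {
      rec_event[i, die] <- trimws(paste(rec_event[i, die], "death"))
    }
    state[die] <- 8L
  }

  summary <- data.frame(
    qaly_trial = qaly_trial,
    qaly_model = qaly_model,
    cost_trial = cost_trial,
    cost_model = cost_model,
    qaly_total = qaly_trial + qaly_model,
    cost_total = cost_trial + cost_model,
    life_years = params$trial_period + cl * life_cycles,
    early_years = params$trial_period + cl * early_cycles,
    courses = courses,
    operations = ops,
    t_late = t_late
  )
  out <- list(summary = summary)
  if (record) {
    out$record <- list(t = t_seq, state = rec_state, fd = rec_fd,
                       cost = rec_cost, utility = rec_util,
                       event = rec_event)
  }
  out
}

#' Simulate one patient's lifetime disease course
#'
#' Runs the six-month-cycle simulation for a single patient under a named
#' strategy, starting at the end of the 18-month trial in the assigned
#' outcome state and continuing until death or the time horizon. Quiescent
#' patients hold their flexion deformity fixed for the quiescence duration
#' and then either resume progression (standard care, single course) or are
#' retreated in the same cycle and remain quiescent (repeat strategy);
#' progressive patients follow the stochastic flexion-deformity walk and
#' enter untreated late-stage disease when it exceeds the threshold;
#' late-stage patients follow the surgical pathway. Mortality applies in
#' every state.
#'
#' @param patient One-row data frame (or list) with `age`, `sex`,
#'   `baseline_utility`, `baseline_fd`, `ectopic`.
#' @param strategy A strategy name or a [strategy_spec()] list.
#' @param outcome 18-month outcome under this strategy: `"late_stage"`,
#'   `"quiescent"` or `"progressive"`.
#' @param params A `dd_parameters` object.
#' @param seed Integer seed.
#' @return A list with `trajectory`, a data frame (cycle, time, state,
#'   fd, cost, utility, event) of the post-trial lifetime course, and
#'   `summary`, a one-row data frame of accrued totals (trial, model and
#'   lifetime QALYs and costs are discounted where applicable).
#' @export
simulate_patient <- function(patient, strategy, outcome, params, seed = 1L) {
  if (is.character(strategy)) strategy <- strategy_spec(strategy)
  code <- .dd_outcomes[[match.arg(outcome, names(.dd_outcomes))]]
  cohort <- as.data.frame(patient)[1, , drop = FALSE]
  n_cycles <- as.integer(round((params$horizon - params$trial_period) /
                                 params$cycle_length))
  streams <- make_streams(n_cycles, 1L, seed)
  res <- simulate_batch(cohort, strategy, code, params, streams,
                        record = TRUE)
  rec <- res$record
  alive_cycles <- which(!is.na(rec$utility[, 1]))
  traj <- data.frame(
    cycle = alive_cycles,
    time = rec$t[alive_cycles],
    state = dd_states()[rec$state[alive_cycles, 1]],
    fd = rec$fd[alive_cycles, 1],
    cost = rec$cost[alive_cycles, 1],
    utility = rec$utility[alive_cycles, 1],
    event = rec$event[alive_cycles, 1],
    stringsAsFactors = FALSE
  )
  list(trajectory = traj, summary = res$summary)
}

#' Write simulated trajectories to long-format CSV
#'
#' @param trajectory A trajectory data frame from [simulate_patient()], or
#'   a named list of them (names become `patient_id`).
#' @param path Output CSV path.
#' @param strategy Strategy name recorded in the output.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(trajectory, path, strategy = NA_character_) {
  if (is.data.frame(trajectory)) trajectory <- list(`1` = trajectory)
  rows <- do.call(rbind, lapply(names(trajectory), function(id) {
    cbind(patient_id = id, strategy = strategy, trajectory[[id]])
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
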