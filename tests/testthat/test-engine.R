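test_that("flexion-deformity progression reproduces the regression", {
  p <- load_parameters()

  # with zero residual SD the per-cycle change is exactly the scaled mean
  p0 <- p
  p0$fd_change_rmse <- 0
  expect_equal(progress_flexion(10, FALSE, p0), 10 + 0.8631 / 3)
  expect_equal(progress_flexion(10, TRUE, p0), 10 + 9.3820 / 3,
               tolerance = 1e-4)

  # floor at zero degrees
  p0$fd_change_constant <- -50
  expect_equal(progress_flexion(0.5, FALSE, p0), 0)

  # cumulative 18-month change for ectopic patients: mean of three-cycle
  # sums over many simulated walks (started high so the floor is inactive)
  set.seed(31)
  n <- 200000
  fd <- rep(1000, n)
  for (k in 1:3) fd <- progress_flexion(fd, rep(TRUE, n), p)
  change <- fd - 1000
  se <- sd(change) / sqrt(n)
  expect_lt(abs(mean(change) - 9.3821), 3 * se)
  # and the residual SD is reassembled from the per-cycle pieces
  expect_equal(sd(change), 12.6079, tolerance = 0.01 * 12.6079)
})

test_that("surgical sequencing follows the pathway rules", {
  h <- function(n_pnf = 0, pnf_failed = FALSE, fasc = FALSE, dermo = FALSE) {
    list(n_pnf = n_pnf, pnf_failed = pnf_failed, had_fasciectomy = fasc,
         had_dermofasciectomy = dermo)
  }
  expect_equal(next_surgical_event(h()), "pnf")
  expect_equal(next_surgical_event(h(n_pnf = 2)), "pnf")
  # three successful-then-relapsed PNFs exhaust the PNF allowance
  expect_equal(next_surgical_event(h(n_pnf = 3)), "limited_fasciectomy")
  # one failed PNF rules out further PNF
  expect_equal(next_surgical_event(h(n_pnf = 1, pnf_failed = TRUE)),
               "limited_fasciectomy")
  expect_equal(next_surgical_event(h(n_pnf = 3, fasc = TRUE)),
               "dermofasciectomy")
  expect_equal(next_surgical_event(h(fasc = TRUE, dermo = TRUE)), "none")
  expect_error(next_surgical_event(h(n_pnf = 5)), "logic error")
  expect_error(next_surgical_event(list(n_pnf = 1)), "logic error")
})

test_that("cycle mortality matches the hazard transform", {
  p <- load_parameters()
  p$mortality_params$hazard_ratio <- 1
  q1 <- cycle_mortality_prob(70, "male", p)
  h <- p$mortality_params$gompertz_a_male * exp(p$mortality_params$gompertz_b * 70)
  expect_equal(q1, 1 - exp(-h * 0.5))
  # doubling the hazard ratio squares the survival probability
  p2 <- p
  p2$mortality_params$hazard_ratio <- 2
  expect_equal(1 - cycle_mortality_prob(70, "male", p2), (1 - q1)^2)
  # beyond the life-table maximum death is certain
  expect_equal(cycle_mortality_prob(120, "female", p), 1)
  expect_error(cycle_mortality_prob(-1, "male", p), "age")
  # a user life table overrides the Gompertz form
  p3 <- p
  p3$mortality_params$life_table <- data.frame(
    age = rep(0:120, 2), sex = rep(c("male", "female"), each = 121),
    hazard = 0.02)
  expect_equal(cycle_mortality_prob(c(50, 80), c("male", "female"), p3),
               rep(1 - exp(-0.02 * 0.5), 2))
})

test_that("single-patient trajectories honour timing and state rules", {
  p <- load_parameters()
  pat <- test_patient()

  # a patient assigned late-stage starts the model in untreated late stage
  r <- simulate_patient(pat, "standard_care", "late_stage", p, seed = 2)
  expect_equal(r$trajectory$state[1], "late_untreated")
  expect_equal(r$trajectory$time[1], 1.5)
  expect_true(all(diff(r$trajectory$time) == 0.5))
  expect_lte(max(r$trajectory$time), 55)

  # quiescent cycles never change the flexion deformity
  rq <- simulate_patient(pat, "standard_care", "quiescent", p, seed = 2)
  quiet <- rq$trajectory$state == "early_quiescent"
  expect_true(all(rq$trajectory$fd[quiet] == pat$baseline_fd))

  # accrue() reconstructs the engine's own discounted totals
  acc <- accrue(r$trajectory, p)
  expect_equal(acc$cost, r$summary$cost_model, tolerance = 1e-10)
  expect_equal(acc$qalys, r$summary$qaly_model, tolerance = 1e-10)
})

test_that("retreatment course counts follow the closed form", {
  p <- immortal_params()
  pat <- test_patient(age = 45)

  # immortal quiescent patient under repeated courses: continuous
  # quiescence to the horizon, courses = 1 + floor((T - 1.5) / duration)
  r <- simulate_patient(pat, "adalimumab_repeat", "quiescent", p, seed = 5)
  expect_equal(r$summary$courses, 1 + floor((55 - 1.5) / 3))
  expect_true(all(r$trajectory$state %in% "early_quiescent"))
  expect_true(is.na(r$summary$t_late))

  # deterministic death age via a degenerate life table: zero hazard until
  # 80, certain death after; death occurs at the cycle where age reaches 80
  p2 <- p
  p2$mortality_params$life_table <- data.frame(
    age = rep(0:120, 2), sex = rep(c("male", "female"), each = 121),
    hazard = rep(c(rep(0, 80), rep(Inf, 41)), 2))
  pat2 <- test_patient(age = 60.2)
  r2 <- simulate_patient(pat2, "adalimumab_repeat", "quiescent", p2, seed = 5)
  death_time <- r2$summary$life_years
  expect_equal(death_time, 20.5)  # 1.5 + cycles until age crosses 80
  expect_equal(r2$summary$courses, 1 + floor((death_time - 1.5) / 3))

  # a single-course quiescent patient resumes progression instead
  r3 <- simulate_patient(pat, "adalimumab_once", "quiescent", p, seed = 5)
  expect_equal(r3$summary$courses, 1)
  expect_true("early_progressive" %in% r3$trajectory$state)
  first_prog <- min(which(r3$trajectory$state == "early_progressive"))
  expect_equal(r3$trajectory$time[first_prog], 1.5 + 3)
})

test_that("life years are strategy-invariant and time-to-late-stage is
          monotone in quiescence duration under common seeds", {
  p <- load_parameters()
  co <- generate_cohort(cohort_spec(n = 40), seed = 12)
  res <- simulate_strategies(co, p, n_reps = 5, seed = 13)
  expect_equal(res$life_years[1], res$life_years[2], tolerance = 1e-12)
  expect_equal(res$life_years[1], res$life_years[3], tolerance = 1e-12)

  pat <- test_patient(age = 50, baseline_fd = 15)
  t_late <- sapply(c(1.5, 3, 5), function(qd) {
    p2 <- immortal_params(p)
    p2$quiescence_duration <- qd
    r <- simulate_patient(pat, "standard_care", "quiescent", p2, seed = 77)
    tl <- r$summary$t_late
    if (is.na(tl)) Inf else tl
  })
  expect_true(all(diff(t_late) >= 0))
})

test_that("every observed transition is a legal model edge and surgery
          caps hold over many trajectories", {
  p <- load_parameters()
  set.seed(41)
  m <- 3400
  co <- data.frame(
    age = runif(m, 35, 85),
    sex = sample(c("male", "female"), m, replace = TRUE),
    baseline_utility = runif(m, 0.3, 1),
    baseline_fd = runif(m, 0, 30),
    ectopic = runif(m) < 0.25, stringsAsFactors = FALSE)
  n_cycles <- as.integer((p$horizon - p$trial_period) / p$cycle_length)

  # early_quiescent -> late_untreated is legal in one recorded step:
  # reactivation happens at the cycle start and the resumed flexion walk
  # may cross the 30-degree threshold within that same cycle
  legal <- list(
    early_progressive = c("early_progressive", "late_untreated", "dead"),
    early_quiescent = c("early_quiescent", "early_progressive",
                        "late_untreated", "dead"),
    late_untreated = c("late_untreated", "late_post_pnf_success",
                       "late_post_pnf_failed", "late_post_fasciectomy",
                       "late_post_dermofasciectomy", "dead"),
    late_post_pnf_success = c("late_post_pnf_success", "late_untreated",
                              "dead"),
    late_post_pnf_failed = c("late_post_pnf_failed",
                             "late_post_fasciectomy", "dead"),
    late_post_fasciectomy = c("late_post_fasciectomy", "late_untreated",
                              "dead"),
    late_post_dermofasciectomy = c("late_post_dermofasciectomy",
                                   "late_untreated", "dead"),
    dead = "dead")

  for (strat in dd_strategies()) {
    streams <- dupasim::make_streams(n_cycles, m, seed = 55)
    u <- withr::with_seed(56, runif(m))
    spec <- strategy_spec(strat)
    code <- outcome_from_uniform(
      u, if (spec$arm == "placebo") p$p_late_placebo else p$p_late_ada,
      if (spec$arm == "placebo") p$p_quiescent_placebo else p$p_quiescent_ada)
    res <- dupasim:::simulate_batch(co, spec, code, p, streams,
                                    record = TRUE)
    st <- res$record$state
    names_st <- matrix(dd_states()[st], nrow(st), ncol(st))
    legal_pairs <- unlist(lapply(names(legal), function(f)
      paste(f, legal[[f]])))
    bad <- 0L
    for (i in seq_len(nrow(st) - 1)) {
      pair <- paste(names_st[i, ], names_st[i + 1, ])
      bad <- bad + sum(!(pair %in% legal_pairs))
    }
    expect_equal(bad, 0L, label = paste("illegal transitions under", strat))

    # surgery caps from the recorded event log
    ev <- res$record$event
    n_pnf <- colSums(matrix(grepl("^pnf_", ev), nrow(ev), ncol(ev)))
    n_lf <- colSums(matrix(grepl("limited_fasciectomy", ev),
                           nrow(ev), ncol(ev)))
    n_df <- colSums(matrix(grepl("dermofasciectomy", ev),
                           nrow(ev), ncol(ev)))
    expect_true(all(n_pnf <= 3))
    expect_true(all(n_lf <= 1))
    expect_true(all(n_df <= 1))
  }
})

test_that("identical master seeds give bit-identical simulations", {
  p <- load_parameters()
  co <- generate_cohort(cohort_spec(n = 15), seed = 1)
  a <- simulate_strategies(co, p, n_reps = 3, seed = 9)
  b <- simulate_strategies(co, p, n_reps = 3, seed = 9)
  expect_identical(a, b)
  pat <- test_patient()
  ta <- simulate_patient(pat, "adalimumab_repeat", "progressive", p, seed = 4)
  tb <- simulate_patient(pat, "adalimumab_repeat", "progressive", p, seed = 4)
  expect_identical(ta, tb)
})
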