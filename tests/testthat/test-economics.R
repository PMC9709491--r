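test_that("discounting starts at the end of the trial period", {
  p <- load_parameters()
  expect_equal(discount_factor(0, p), 1)
  expect_equal(discount_factor(1.5, p), 1)
  expect_equal(discount_factor(3.5, p), 1.035^-2)
  expect_error(discount_factor(-0.1, p), "t must be >= 0")
  p0 <- p
  p0$discount_rate <- 0
  expect_equal(discount_factor(c(2, 20, 54.5), p0), rep(1, 3))
})

test_that("state utilities follow the QALY regression", {
  p <- load_parameters()
  bu <- 0.8
  u_prog <- cycle_utility("early_progressive", bu, p)
  expect_equal(u_prog, 0.3847 + 0.5410 * bu)
  # quiescence adds exactly the estimated utility gain
  expect_equal(cycle_utility("early_quiescent", bu, p) - u_prog, 0.0395)
  # cap at full health
  expect_equal(cycle_utility("early_quiescent", 1.5, p), 1)
  # zero decrement makes late-stage utility equal the progressive utility
  p0 <- p
  for (f in grep("^disutility", names(p0$late_stage_params), value = TRUE)) {
    p0$late_stage_params[[f]] <- 0
  }
  expect_equal(cycle_utility("late_untreated", bu, p0), u_prog)
  expect_equal(cycle_utility("late_post_fasciectomy", bu, p0), u_prog)
  expect_equal(cycle_utility("dead", bu, p), 0)
})

test_that("accrual applies discounting to costs and utility-time", {
  p <- load_parameters()
  # all-zero utilities accrue no QALYs
  traj <- data.frame(time = c(1.5, 2, 2.5), state = "early_progressive",
                     fd = 0, cost = 0, utility = 0, event = "")
  expect_equal(accrue(traj, p)$qalys, 0)
  # one course at 4.5 years is discounted over three post-trial years
  traj2 <- data.frame(time = 4.5, state = "early_quiescent", fd = 0,
                      cost = 4 * 475, utility = 0, event = "course_started")
  expect_equal(accrue(traj2, p)$cost, 4 * 475 * 1.035^-3)
  # a standard-care patient who never elects surgery accrues no model cost
  p0 <- p
  p0$late_stage_params$p_elect_surgery <- 0
  r <- simulate_patient(test_patient(), "standard_care", "progressive",
                        p0, seed = 3)
  expect_equal(r$summary$cost_model, 0)
  expect_equal(r$summary$courses, 0)
})

test_that("dominance and extended dominance are identified", {
  # strict dominance: same QALYs, higher cost
  toy <- data.frame(strategy = c("a", "b"), cost = c(0, 100),
                    qaly = c(10, 10))
  res <- incremental_analysis(toy, ref = NULL)
  expect_false(res$dominated[res$strategy == "a"])
  expect_true(res$dominated[res$strategy == "b"])

  # extended dominance: middle strategy's ICER exceeds the next one's
  toy2 <- data.frame(strategy = c("a", "b", "c"), cost = c(0, 10, 12),
                     qaly = c(0, 1, 3))
  res2 <- incremental_analysis(toy2, ref = NULL)
  expect_true(res2$extended_dominated[res2$strategy == "b"])
  expect_equal(res2$icer_frontier[res2$strategy == "c"], 4)

  # zero QALY difference is flagged undefined, not divided
  toy3 <- data.frame(strategy = c("standard_care", "x"), cost = c(0, 5),
                     qaly = c(1, 1))
  res3 <- incremental_analysis(toy3)
  expect_true(is.na(res3$icer_vs_ref[res3$strategy == "x"]))
  expect_error(incremental_analysis(toy3[1, ]), ">= 2")
})

test_that("the frontier agrees with a net-benefit oracle on random sets", {
  set.seed(19)
  for (rep in 1:40) {
    k <- sample(3:6, 1)
    df <- data.frame(strategy = paste0("s", 1:k),
                     cost = round(runif(k, 0, 10000), 2),
                     qaly = round(runif(k, 0, 5), 3))
    res <- incremental_analysis(df, ref = NULL)
    onf <- !res$dominated & !res$extended_dominated
    oracle <- oracle_frontier_set(res$cost, res$qaly)
    expect_identical(unname(onf), unname(oracle))
    # frontier ICERs strictly increase
    icers <- res$icer_frontier[!is.na(res$icer_frontier)]
    if (length(icers) > 1) expect_true(all(diff(icers) > 0))
    # removing a dominated strategy never changes the frontier
    if (any(res$dominated)) {
      drop1 <- df[df$strategy != res$strategy[which(res$dominated)[1]], ]
      res_b <- incremental_analysis(drop1, ref = NULL)
      keep <- !res_b$dominated & !res_b$extended_dominated
      expect_identical(sort(res_b$strategy[keep]), sort(res$strategy[onf]))
    }
  }
})

test_that("removing the treatment effect drives incrementals to zero", {
  p <- load_parameters()
  p$p_late_ada <- p$p_late_placebo
  p$p_quiescent_ada <- p$p_quiescent_placebo
  p$cost_per_dose <- 0
  co <- generate_cohort(cohort_spec(n = 50), seed = 2)
  res <- simulate_strategies(co, p, n_reps = 10, seed = 3)
  # with common random numbers a single free course changes nothing at all
  expect_equal(res$qaly_total[2] - res$qaly_total[1], 0, tolerance = 1e-12)
  expect_equal(res$cost_total[2] - res$cost_total[1], 0, tolerance = 1e-12)
  # free retreatment still maintains quiescence, a structural effect; with
  # quiescence outlasting the horizon in every arm, that difference also
  # vanishes and all three strategies coincide
  p$quiescence_duration <- 60
  res2 <- simulate_strategies(co, p, n_reps = 10, seed = 3)
  expect_equal(res2$qaly_total[3] - res2$qaly_total[1], 0, tolerance = 1e-12)
  expect_equal(res2$cost_total[3] - res2$cost_total[1], 0, tolerance = 1e-12)
})
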