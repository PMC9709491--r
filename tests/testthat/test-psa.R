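test_that("PSA output has the right shape and is reproducible", {
  p <- load_parameters()
  co <- generate_cohort(cohort_spec(n = 10), seed = 1)
  dr <- sample_psa(p, 2, seed = 3)
  psa <- run_psa(co, dr, n_reps = 1, seed = 4)
  expect_s3_class(psa, "dd_psa")
  expect_equal(dim(psa$metrics$cost_total), c(2, 3))
  expect_equal(dim(psa$metrics$qaly_total), c(2, 3))
  expect_true(all(is.finite(unlist(psa$metrics))))
  psa2 <- run_psa(co, dr, n_reps = 1, seed = 4)
  expect_identical(psa$metrics, psa2$metrics)
  expect_error(run_psa(co[0, ], dr), "empty cohort")

  path <- withr::local_tempfile(fileext = ".csv")
  write_psa(psa, path)
  back <- read.csv(path)
  expect_equal(nrow(back), 6)
  expect_equal(back$mean_cost, as.vector(psa$metrics$cost_total))
})

test_that("repetitions reduce Monte Carlo error at the root-n rate", {
  p <- load_parameters()
  co <- generate_cohort(cohort_spec(n = 25), seed = 1)
  mean_q <- function(n_reps, seed) {
    simulate_strategies(co, p, "adalimumab_repeat", n_reps = n_reps,
                        seed = seed)$qaly_total
  }
  m1 <- sapply(1:40, function(s) mean_q(1, 1000 + s))
  m4 <- sapply(1:40, function(s) mean_q(4, 2000 + s))
  ratio <- sd(m1) / sd(m4)
  expect_gt(ratio, 1.3)
  expect_lt(ratio, 3.1)
})

test_that("CEAC matches brute force, partitions mass and handles edges", {
  # toy four-draw, two-strategy sample with known net-benefit ordering
  cost <- matrix(c(0, 0, 0, 0, 100, 100, 100, 100), ncol = 2)
  qaly <- matrix(c(1, 1, 1, 1, 1.2, 0.9, 1.3, 1.05), ncol = 2)
  psa <- make_fake_psa(cost, qaly)
  cc <- ceac(psa, 1000)
  expect_equal(cc$probability[cc$strategy == "s2"], 2 / 4)

  # single strategy is always best
  solo <- make_fake_psa(cost[, 1, drop = FALSE], qaly[, 1, drop = FALSE])
  expect_equal(ceac(solo, c(0, 20000))$probability, c(1, 1))

  # random matrices up to 100 x 3: exact equivalence with the loop oracle
  set.seed(23)
  for (rep in 1:25) {
    n <- sample(2:100, 1)
    k <- sample(2:3, 1)
    cost <- matrix(runif(n * k, 0, 5000), n, k)
    qaly <- matrix(runif(n * k, 0, 3), n, k)
    psa <- make_fake_psa(cost, qaly)
    for (wtp in c(0, 15000, 30000)) {
      got <- ceac(psa, wtp)$probability
      expect_equal(got, oracle_ceac(cost, qaly, wtp))
      expect_equal(sum(got), 1)
      expect_equal(evpi_per_patient(psa, wtp),
                   oracle_evpi(cost, qaly, wtp))
      expect_gte(evpi_per_patient(psa, wtp), 0)
    }
  }
})

test_that("EVPI handles degenerate and hand-computed cases", {
  # all draws identical: no decision uncertainty
  cost <- matrix(5, 10, 2)
  qaly <- matrix(c(rep(1, 10), rep(2, 10)), 10, 2)
  expect_equal(evpi_per_patient(make_fake_psa(cost, qaly), 1000), 0)
  # two-draw, two-strategy net-benefit matrix [[1,0],[0,1]]: EVPI = 0.5
  nb <- matrix(c(1, 0, 0, 1), 2, 2)
  psa <- make_fake_psa(cost = -nb, qaly = matrix(0, 2, 2))
  expect_equal(evpi_per_patient(psa, 20000), 0.5)
  expect_error(evpi_per_patient(make_fake_psa(cost[1, , drop = FALSE],
                                              qaly[1, , drop = FALSE]),
                                1000), ">= 2 draws")
})

test_that("EVPPI regression estimator matches structure-known cases", {
  set.seed(29)
  n <- 400
  x <- runif(n)      # informative parameter
  z <- runif(n)      # irrelevant parameter
  # strategy 1 pays 1 when x > 0.5; strategy 2 pays 0.5 always:
  # EVPI = E[max] - max(E) = 0.75 - 0.5 = 0.25, all of it due to x
  nb1 <- as.numeric(x > 0.5)
  nb2 <- rep(0.5, n)
  psa <- make_fake_psa(cost = cbind(-nb1, -nb2),
                       qaly = matrix(0, n, 2))
  psa$psa_draws$draws <- data.frame(x = x, z = z)
  evpi <- evpi_per_patient(psa, 0)
  expect_equal(evpi, 0.25, tolerance = 0.05)
  ev_x <- evppi(psa, "x", 0)
  ev_z <- evppi(psa, "z", 0)
  expect_lt(abs(ev_x - evpi), 0.15 * evpi)
  expect_lt(ev_z, 0.1 * evpi)
  expect_gte(ev_z, 0)
  # the full parameter set recovers (approximately) the EVPI
  ev_all <- evppi(psa, c("x", "z"), 0)
  expect_lt(abs(ev_all - evpi), 0.15 * evpi)
  expect_error(evppi(psa, character(0), 0), "empty subset")
  expect_error(evppi(psa, "nope", 0), "unknown parameter")
})

test_that("population scaling reproduces the printed products", {
  expect_equal(population_value(292, 2584411), 754648012)
  expect_equal(population_value(292, 2584411) / 1e6, 755, tolerance = 0.005)
  expect_equal(population_value(105, 2584411) / 1e6, 272, tolerance = 0.005)
  expect_equal(population_value(0, 2584411), 0)
  expect_error(population_value(-1, 10), ">= 0")
})

test_that("one-way sensitivity analysis brackets the base case", {
  p <- load_parameters()
  co <- generate_cohort(cohort_spec(n = 40), seed = 5)
  ranges <- list(
    qaly_gain_quiescence = c(0.0079, 0.0704),
    quiescence_duration = c(1.5, 5)
  )
  tor <- one_way_sa(p, co, param_ranges = ranges, n_reps = 40, seed = 6)
  expect_equal(nrow(tor), 2)
  expect_true(all(is.finite(tor$icer_base)))
  gain <- tor[tor$parameter == "qaly_gain_quiescence", ]
  # shrinking the quiescence utility gain worsens value for money
  expect_gt(gain$icer_low, gain$icer_base)
  expect_lt(gain$icer_high, gain$icer_base)
  qd <- tor[tor$parameter == "quiescence_duration", ]
  # shorter quiescence means more frequent retreatment: higher ICER
  expect_gt(qd$icer_low, qd$icer_base)
  # a degenerate range reproduces the base case exactly (common seeds)
  tor0 <- one_way_sa(p, co, n_reps = 20, seed = 6, param_ranges = list(
    qaly_gain_quiescence = c(0.0395, 0.0395)))
  expect_equal(tor0$icer_low, tor0$icer_base, tolerance = 1e-12)
})
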