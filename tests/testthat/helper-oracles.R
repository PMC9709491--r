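# Independent brute-force oracles used to cross-check the vectorized
# implementations, plus small fixture builders. Oracles are deliberately
# written as plain loops over draws/strategies.

# Wrap cost/qaly matrices as a minimal dd_psa object.
make_fake_psa <- function(cost, qaly, strategies = NULL) {
  if (is.null(strategies)) {
    strategies <- paste0("s", seq_len(ncol(cost)))
  }
  structure(list(
    metrics = list(cost_total = cost, qaly_total = qaly),
    strategies = strategies, n_draws = nrow(cost), n_reps = 1, seed = 0,
    psa_draws = list(params = list(wtp_grid = c(0, 20000, 30000)))
  ), class = "dd_psa")
}

# Per-strategy probability of maximal net benefit, one draw at a time;
# ties credited to the cheaper strategy.
oracle_ceac <- function(cost, qaly, wtp) {
  wins <- integer(ncol(cost))
  for (d in seq_len(nrow(cost))) {
    nb <- wtp * qaly[d, ] - cost[d, ]
    best <- which(nb == max(nb))
    if (length(best) > 1) best <- best[which.min(cost[d, best])]
    wins[best] <- wins[best] + 1L
  }
  wins / nrow(cost)
}

# EVPI by explicit looping.
oracle_evpi <- function(cost, qaly, wtp) {
  best_each <- numeric(nrow(cost))
  for (d in seq_len(nrow(cost))) {
    best_each[d] <- max(wtp * qaly[d, ] - cost[d, ])
  }
  mean_nb <- numeric(ncol(cost))
  for (s in seq_len(ncol(cost))) {
    mean_nb[s] <- mean(wtp * qaly[, s] - cost[, s])
  }
  mean(best_each) - max(mean_nb)
}

# Strategies on the cost-effectiveness frontier: those that uniquely
# maximize net benefit for some willingness to pay. Evaluation points are
# midpoints between the breakpoints given by all pairwise ICERs, which
# makes the check exact for generic (tie-free) inputs.
oracle_frontier_set <- function(cost, qaly) {
  n <- length(cost)
  ratios <- c()
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      dq <- qaly[j] - qaly[i]
      if (dq > 0) ratios <- c(ratios, (cost[j] - cost[i]) / dq)
    }
  }
  breaks <- sort(unique(pmax(ratios, 0)))
  lambdas <- c(0, (head(c(breaks, 2 * max(breaks, 1)), -1) +
                     c(breaks, 2 * max(breaks, 1))[-1]) / 2,
               2 * max(breaks, 1) + 1)
  on_frontier <- rep(FALSE, n)
  for (l in lambdas) {
    nb <- l * qaly - cost
    best <- which(nb == max(nb))
    if (length(best) == 1) on_frontier[best] <- TRUE
  }
  on_frontier
}

# Minimal one-row patient for engine tests.
test_patient <- function(age = 61, sex = "male", baseline_utility = 0.85,
                         baseline_fd = 10, ectopic = FALSE) {
  data.frame(age = age, sex = sex, baseline_utility = baseline_utility,
             baseline_fd = baseline_fd, ectopic = ectopic,
             stringsAsFactors = FALSE)
}

# Parameters with mortality switched off (immortal within the horizon).
immortal_params <- function(params = load_parameters()) {
  params$mortality_params$gompertz_a_male <- 0
  params$mortality_params$gompertz_a_female <- 0
  params$mortality_params$max_age <- 500
  params
}
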