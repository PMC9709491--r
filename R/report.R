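#' Summarize a PSA into a base-case results table
#'
#' Means over PSA draws with 95% percentile intervals for every recorded
#' outcome per strategy (the conventional reporting of a probabilistic
#' patient-level model), plus incremental costs, QALYs and ICERs versus
#' the reference strategy: incremental means and their percentile
#' intervals come from per-draw differences (common random numbers), the
#' ICER point estimate is the ratio of incremental means, and its interval
#' is the percentile interval of per-draw ICERs among draws with a
#' positive QALY difference.
#'
#' @param psa A `dd_psa` object.
#' @param ref Reference strategy for incrementals.
#' @return List with `strategy_table` (one row per strategy and outcome:
#'   mean, lower, upper) and `incrementals` (one row per non-reference
#'   strategy: delta QALYs, delta costs and ICER with intervals).
#' @export
summarize_psa <- function(psa, ref = "standard_care") {
  qt <- function(x) stats::quantile(x, c(0.025, 0.975), names = FALSE)
  rows <- list()
  for (mn in names(psa$metrics)) {
    mat <- psa$metrics[[mn]]
    for (s in seq_along(psa$strategies)) {
      ci <- qt(mat[, s])
      rows[[length(rows) + 1]] <- data.frame(
        outcome = mn, strategy = psa$strategies[s],
        mean = mean(mat[, s]), lower = ci[1], upper = ci[2],
        stringsAsFactors = FALSE)
    }
  }
  strategy_table <- do.call(rbind, rows)

  r <- which(psa$strategies == ref)
  inc <- lapply(setdiff(seq_along(psa$strategies), r), function(s) {
    dq <- psa$metrics$qaly_total[, s] - psa$metrics$qaly_total[, r]
    dc <- psa$metrics$cost_total[, s] - psa$metrics$cost_total[, r]
    icer <- if (mean(dq) == 0) NA_real_ else mean(dc) / mean(dq)
    ratio <- (dc / dq)[dq > 0]
    icer_ci <- if (length(ratio) >= 2) qt(ratio) else c(NA_real_, NA_real_)
    data.frame(strategy = psa$strategies[s],
               delta_qalys = mean(dq), delta_qalys_lower = qt(dq)[1],
               delta_qalys_upper = qt(dq)[2],
               delta_costs = mean(dc), delta_costs_lower = qt(dc)[1],
               delta_costs_upper = qt(dc)[2],
               icer = icer, icer_lower = icer_ci[1],
               icer_upper = icer_ci[2], stringsAsFactors = FALSE)
  })
  list(strategy_table = strategy_table,
       incrementals = do.call(rbind, inc))
}

.dd_scales <- list(paper = c(n_draws = 1000, n_reps = 100),
                   desk = c(n_draws = 200, n_reps = 20),
                   smoke = c(n_draws = 2, n_reps = 1))

#' Run the full model-based evaluation
#'
#' End-to-end pipeline: load and validate parameters, generate the
#' synthetic cohort, run the probabilistic sensitivity analysis over all
#' three strategies, and derive the base-case results table, incremental
#' analysis, cost-effectiveness acceptability curves, EVPI/EVPPI with
#' population scaling, and the one-way sensitivity (tornado) table.
#'
#' @param config Parameter configuration path or list (`NULL` for the
#'   packaged default).
#' @param scale `"paper"` (1000 draws x 100 repetitions), `"desk"`
#'   (200 x 20) or `"smoke"` (2 x 1); or a numeric
#'   `c(n_draws = , n_reps = )`.
#' @param seed Master seed driving parameter sampling, cohort generation
#'   and simulation streams.
#' @param spec Cohort specification, see [cohort_spec()].
#' @param tornado Logical: also run the one-way sensitivity analysis
#'   (adds a deterministic model run per parameter bound).
#' @param out_dir Optional directory; when given, all tables are written
#'   as CSV plus a JSON run summary.
#' @return An object of class `dd_report`: list with `params`, `cohort`,
#'   `psa`, `summary` (from [summarize_psa()]), `incremental_table`
#'   (deterministic frontier analysis of PSA means), `ceac`, `evpi`,
#'   `evppi_trial`, population values, `tornado` (or `NULL`) and run
#'   metadata.
#' @export
run_base_case <- function(config = NULL, scale = "desk", seed = 1L,
                          spec = cohort_spec(), tornado = FALSE,
                          out_dir = NULL) {
  params <- load_parameters(config)
  sc <- if (is.character(scale)) {
    if (!scale %in% names(.dd_scales)) {
      stop("configuration error: unknown scale '", scale, "'")
    }
    .dd_scales[[scale]]
  } else scale
  cohort <- generate_cohort(spec, seed = derive_seed(seed, 1L))
  draws <- sample_psa(params, n_draws = sc[["n_draws"]],
                      seed = derive_seed(seed, 2L))
  psa <- run_psa(cohort, draws, n_reps = sc[["n_reps"]],
                 seed = derive_seed(seed, 3L))
  summ <- summarize_psa(psa)
  means <- data.frame(
    strategy = psa$strategies,
    cost = colMeans(psa$metrics$cost_total),
    qaly = colMeans(psa$metrics$qaly_total), stringsAsFactors = FALSE)
  inc_table <- incremental_analysis(means)
  ceac_df <- ceac(psa)
  evpi20 <- evpi_per_patient(psa, 20000)
  evppi20 <- evppi(psa, "trial", 20000)
  tor <- if (tornado) {
    one_way_sa(params, cohort, n_reps = max(sc[["n_reps"]], 20L),
               seed = derive_seed(seed, 4L))
  } else NULL

  bundle <- structure(list(
    params = params, cohort = cohort, psa = psa, summary = summ,
    incremental_table = inc_table, ceac = ceac_df,
    evpi = evpi20, evppi_trial = evppi20,
    evpi_population = population_value(evpi20, params$uk_prevalent_cases),
    evppi_population = population_value(evppi20, params$uk_prevalent_cases),
    tornado = tor,
    meta = list(seed = seed, n_draws = sc[["n_draws"]],
                n_reps = sc[["n_reps"]], n_patients = nrow(cohort))
  ), class = "dd_report")
  if (!is.null(out_dir)) write_report_bundle(bundle, out_dir)
  bundle
}

#' Write a report bundle to disk
#'
#' Emits `strategy_table.csv`, `incrementals.csv`, `frontier.csv`,
#' `ceac.csv`, `psa_samples.csv`, `tornado.csv` (when present) and
#' `summary.json` (run metadata, EVPI/EVPPI and population values).
#'
#' @param bundle A `dd_report` from [run_base_case()].
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  utils::write.csv(bundle$summary$strategy_table, p("strategy_table.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$summary$incrementals, p("incrementals.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$incremental_table, p("frontier.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$ceac, p("ceac.csv"), row.names = FALSE)
  write_psa(bundle$psa, p("psa_samples.csv"))
  if (!is.null(bundle$tornado)) {
    utils::write.csv(bundle$tornado, p("tornado.csv"), row.names = FALSE)
  }
  jsonlite::write_json(list(
    meta = bundle$meta,
    evpi_per_patient = bundle$evpi,
    evppi_trial_per_patient = bundle$evppi_trial,
    evpi_population = bundle$evpi_population,
    evppi_population = bundle$evppi_population
  ), p("summary.json"), auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.dd_report <- function(x, ...) {
  cat("<dd_report>\n")
  cat(sprintf("  %d draws x %d reps, %d patients, seed %d\n",
              x$meta$n_draws, x$meta$n_reps, x$meta$n_patients,
              x$meta$seed))
  inc <- x$summary$incrementals
  rep_row <- inc[inc$strategy == "adalimumab_repeat", ]
  if (nrow(rep_row) == 1) {
    cat(sprintf(paste0("  repeated courses vs standard care: +%.3f QALYs,",
                       " +%.0f GBP, ICER %.0f GBP/QALY\n"),
                rep_row$delta_qalys, rep_row$delta_costs, rep_row$icer))
  }
  cat(sprintf("  EVPI %.0f GBP/patient; EVPPI (trial parameters) %.0f\n",
              x$evpi, x$evppi_trial))
  invisible(x)
}

#' Run the within-trial cost-utility analysis end to end
#'
#' Generates the synthetic trial dataset and performs the bootstrap
#' cost-utility analysis.
#'
#' @param spec A `dd_trial_spec` (default calibrated to the reported trial
#'   marginals).
#' @param seed Integer seed.
#' @param n_boot Bootstrap replicates.
#' @param out_dir Optional output directory for `trial_data.csv`,
#'   `within_trial_ceac.csv` and `within_trial_summary.json`.
#' @return A `dd_cua_result`, with the generated dataset attached as
#'   attribute `"data"`.
#' @export
run_within_trial <- function(spec = trial_spec(), seed = 1L, n_boot = 5000,
                             out_dir = NULL) {
  data <- generate_trial_dataset(spec, seed = derive_seed(seed, 11L))
  res <- bootstrap_cua(data, n_boot = n_boot, seed = derive_seed(seed, 12L))
  attr(res, "data") <- data
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_trial_dataset(data, file.path(out_dir, "trial_data.csv"))
    utils::write.csv(res$ceac, file.path(out_dir, "within_trial_ceac.csv"),
                     row.names = FALSE)
    jsonlite::write_json(list(
      delta_qalys = res$delta_qalys, delta_costs = res$delta_costs,
      icer = res$icer, n_boot = res$n_boot, seed = seed
    ), file.path(out_dir, "within_trial_summary.json"),
    auto_unbox = TRUE, digits = NA)
  }
  res
}
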