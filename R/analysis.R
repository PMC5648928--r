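#' Volume-doubling-time summary of a cohort
#'
#' Evolves each patient's burden untreated over a fixed examination interval
#' and applies the two-point VDT formula, summarizing mean and median per
#' stage. Starting burdens default to the initial diameters; passing
#' `start_cells` (e.g. the residual burden after induction chemotherapy)
#' summarizes post-treatment repopulation instead.
#'
#' @param cohort Cohort data frame from [sample_cohort()].
#' @param growth A [growth_model()].
#' @param interval Days between the two examinations.
#' @param start_cells Optional vector of starting cell numbers (one per
#'   patient) overriding the initial diameters.
#' @param config A [sim_config()].
#' @return Data frame with columns `stage`, `n`, `mean_vdt`, `median_vdt`
#'   (days), plus a pooled `"all"` row.
#' @export
cohort_vdt_summary <- function(cohort, growth = growth_model(),
                               interval = 365, start_cells = NULL,
                               config = sim_config()) {
  stopifnot(interval > 0, nrow(cohort) > 0)
  dens <- config$cell_density
  n0 <- if (is.null(start_cells))
    diameter_to_cell_number(cohort$diameter, dens) else start_cells
  stopifnot(length(n0) == nrow(cohort))
  if (growth$model_kind == "exponential") {
    n1 <- n0 * exp(cohort$rho * interval)
  } else {
    kc <- diameter_to_cell_number(growth$carrying_capacity_diameter, dens)
    n1 <- .gomp_step(n0, cohort$rho, kc, interval)
  }
  vdt <- vdt_between(n0, n1, 0, interval)
  by_stage <- lapply(split(vdt, cohort$stage), function(v)
    c(n = length(v), mean_vdt = mean(v), median_vdt = median(v)))
  out <- do.call(rbind, by_stage)
  out <- rbind(out, all = c(length(vdt), mean(vdt), median(vdt)))
  data.frame(stage = rownames(out), n = out[, "n"],
             mean_vdt = out[, "mean_vdt"], median_vdt = out[, "median_vdt"],
             row.names = NULL)
}

#' Compare two treatment arms on common virtual patients
#'
#' For each repetition a fresh cohort is sampled and both schedules are
#' simulated on the same patients with the same master seed, so the
#' per-patient control uniforms and natural-death times are shared across
#' arms (common random numbers); only the treatment differs. The overall
#' survival difference `arm_a - arm_b` is recorded at the requested months.
#'
#' @param dists A [population_distributions()] object.
#' @param schedule_a,schedule_b [treatment_schedule()]s (arm A minus arm B is
#'   reported).
#' @param stage_mix Named stage proportions (see [sample_cohort()]).
#' @param n_per_rep Patients per repetition.
#' @param reps Number of repetitions.
#' @param months Months at which to compare overall survival.
#' @param growth A [growth_model()]; its carrying capacity is taken from
#'   `dists` unless supplied explicitly.
#' @param config A [sim_config()].
#' @param seed Master seed; repetition seeds derive from it.
#' @return Data frame with one row per month: `mean_diff` and `sd_diff`
#'   across repetitions (survival-fraction scale). The per-repetition
#'   differences are attached as attribute `"reps"` (months x reps matrix).
#' @export
compare_arms <- function(dists, schedule_a, schedule_b, stage_mix,
                         n_per_rep = 1e4, reps = 1, months = c(36, 60),
                         growth = NULL, config = sim_config(), seed = 1L) {
  stopifnot(reps >= 1, n_per_rep >= 1)
  if (is.null(growth))
    growth <- growth_model(
      carrying_capacity_diameter = dists$carrying_capacity_diameter)
  diffs <- matrix(NA_real_, length(months), reps)
  for (r in seq_len(reps)) {
    cohort <- sample_cohort(dists, stage_mix, n_per_rep,
                            seed = .derive_seed(seed, paste0("cohort", r)))
    sim_seed <- .derive_seed(seed, paste0("sim", r))
    out_a <- simulate_cohort(cohort, schedule_a, growth, config, seed = sim_seed)
    out_b <- simulate_cohort(cohort, schedule_b, growth, config, seed = sim_seed)
    diffs[, r] <- sf_at(km_curve(out_a), months) -
      sf_at(km_curve(out_b), months)
  }
  res <- data.frame(month = months,
                    mean_diff = rowMeans(diffs),
                    sd_diff = apply(diffs, 1, sd))
  attr(res, "reps") <- diffs
  res
}

#' Arm benefit within growth-rate subgroups
#'
#' Given outcomes of two arms simulated on the same cohort, computes the
#' overall-survival difference `arm_a - arm_b` at a month within growth-rate
#' subgroups defined by the cohort's empirical rho quantiles: below/above the
#' median and the top quartile.
#'
#' @param cohort The shared cohort.
#' @param outcomes_a,outcomes_b Outcomes of the two arms on that cohort.
#' @param month Month at which to compare.
#' @return Data frame with columns `group`, `n`, `benefit`
#'   (survival-fraction scale).
#' @export
rho_stratified_benefit <- function(cohort, outcomes_a, outcomes_b,
                                   month = 36) {
  med <- stratify_by_rho(cohort, 0.5)
  top <- stratify_by_rho(cohort, 0.75)[[2]]
  groups <- list(below_median = med[[1]], above_median = med[[2]],
                 top_quartile = top)
  out <- lapply(names(groups), function(g) {
    ids <- groups[[g]]$id
    a <- outcomes_a[outcomes_a$id %in% ids, ]
    b <- outcomes_b[outcomes_b$id %in% ids, ]
    data.frame(group = g, n = length(ids),
               benefit = sf_at(km_curve(a), month) -
                 sf_at(km_curve(b), month))
  })
  do.call(rbind, out)
}
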