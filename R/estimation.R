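# Staged fitting cascade: growth parameters from untreated curves, then
# radiosensitivity from a radiation-only curve, then the chemotherapy
# parameter from a sequential-CRT curve, each stage freezing its
# predecessors. Every cost evaluation reuses the same master seed (common
# random numbers), so the objective is a deterministic function of the
# parameters and derivative-free optimization is well behaved.

#' Literature initial-volume priors
#'
#' Stage-wise mean and standard deviation of diameter (cm) used to fix the
#' initial-volume distribution during the first growth-fit stage. The stage
#' IV row reuses the stage III prior, which the source literature does not
#' cover.
#'
#' @return Data frame with columns `stage`, `mean`, `sd`, `lower`, `upper`.
#' @export
literature_volume_priors <- function() {
  data.frame(stage = STAGES,
             mean = c(2.5, 3.5, 6.6, 6.6, 6.6),
             sd = c(2.5, 3, 3, 3, 3),
             lower = 0.3,
             upper = c(5, 13, 13, 13, 13))
}

# Truncated-normal diameter sampler (rejection) for the literature priors.
.sample_trunc_normal <- function(n, mean, sd, lower, upper) {
  out <- numeric(0)
  mass <- max(pnorm(upper, mean, sd) - pnorm(lower, mean, sd), 1e-3)
  while (length(out) < n) {
    x <- rnorm(ceiling((n - length(out)) / mass * 1.2) + 16, mean, sd)
    out <- c(out, x[x >= lower & x <= upper])
  }
  out[seq_len(n)]
}

# Apply named parameter overrides to a population_distributions object.
# Scalar fields by name; per-stage volume rows as vol_mu_<stage> /
# vol_sigma_<stage>.
.apply_overrides <- function(dists, overrides) {
  scalars <- c("carrying_capacity_diameter", "rho_mu", "rho_sigma",
               "alpha_mu", "alpha_sigma", "correlation",
               "beta_c_mu", "beta_c_sigma")
  for (nm in names(overrides)) {
    if (nm %in% scalars) {
      dists[[nm]] <- unname(overrides[[nm]])
    } else if (grepl("^vol_(mu|sigma)_", nm)) {
      part <- sub("^vol_(mu|sigma)_.*$", "\\1", nm)
      stage <- sub("^vol_(mu|sigma)_", "", nm)
      i <- match(stage, dists$volume$stage)
      if (is.na(i)) stop("unknown stage in override: ", nm)
      dists$volume[[if (part == "mu") "mu" else "sigma"]][i] <-
        unname(overrides[[nm]])
    } else stop("unknown parameter: ", nm)
  }
  dists
}

# Simulate the model survival curve for one cascade scenario under CRN.
#   scenario: "untreated" (fitted volumes), "untreated_literature",
#             "rt_only", "scrt", "ccrt"
#   For untreated scenarios `stage` selects the curve; treated scenarios use
#   a 50/50 IIIA/IIIB mix.
.scenario_curve <- function(dists, scenario, stage = NULL, n = 1e4,
                            seed = 1L, config = sim_config(),
                            growth_kind = "gompertz", priors = NULL) {
  growth <- growth_model(
    model_kind = growth_kind,
    carrying_capacity_diameter = dists$carrying_capacity_diameter)
  tag <- paste0(scenario, "_", stage %||% "III")
  if (scenario %in% c("untreated", "untreated_literature")) {
    mix <- setNames(1, stage)
    cohort <- sample_cohort(dists, mix, n, alpha_sampling = "none",
                            seed = .derive_seed(seed, paste0("c_", tag)))
    if (scenario == "untreated_literature") {
      pr <- priors[priors$stage == stage, ]
      set.seed(.derive_seed(seed, paste0("d_", tag)))
      cohort$diameter <- .sample_trunc_normal(n, pr$mean, pr$sd, pr$lower,
                                              pr$upper)
    }
    out <- simulate_cohort(cohort, NULL, growth, config,
                           seed = .derive_seed(seed, paste0("s_", tag)))
  } else {
    schedule <- switch(scenario,
                       rt_only = build_rt_only_60gy(0),
                       scrt = build_rtog9410_sequential(),
                       ccrt = build_rtog9410_concurrent(),
                       stop("unknown scenario: ", scenario))
    mix <- c(IIIA = 0.5, IIIB = 0.5)
    cohort <- sample_cohort(dists, mix, n, alpha_sampling = "joint",
                            seed = .derive_seed(seed, paste0("c_", tag)))
    out <- simulate_cohort(cohort, schedule, growth, config,
                           seed = .derive_seed(seed, paste0("s_", tag)))
  }
  km_curve(out)
}

# Bounded derivative-free minimizer: Nelder-Mead on a logistic box
# transform, tracking the best evaluation so far (monotone best-so-far,
# respects bounds).
.nm_box <- function(fn, x0, lower, upper, maxit = 150) {
  stopifnot(length(x0) == length(lower), length(x0) == length(upper),
            all(x0 > lower), all(x0 < upper))
  nm <- names(x0)
  sc <- function(z) lower + (upper - lower) * stats::plogis(z)
  z0 <- stats::qlogis((x0 - lower) / (upper - lower))
  env <- new.env()
  env$best_val <- Inf; env$best_x <- x0; env$trace <- list()
  obj <- function(z) {
    x <- setNames(sc(z), nm)
    v <- fn(x)
    env$trace[[length(env$trace) + 1L]] <- c(x, residual = v)
    if (v < env$best_val) { env$best_val <- v; env$best_x <- x }
    v
  }
  res <- stats::optim(z0, obj, method = "Nelder-Mead",
                      control = list(maxit = maxit))
  trace <- as.data.frame(do.call(rbind, env$trace))
  list(par = env$best_x, residual = env$best_val,
       n_eval = nrow(trace), trace = trace,
       budget_exceeded = res$convergence == 1)
}

#' Fit growth parameters to untreated survival curves
#'
#' The two-stage growth fit. Stage `"A"` frees the carrying capacity and the
#' growth-rate distribution (`K`, `rho_mu`, `rho_sigma`) while the
#' initial-volume distributions are pinned to the literature priors. Stage
#' `"B"` freezes those optima and re-optimizes each stage's lognormal volume
#' parameters (`mu`, `sigma`) against its own curve, which decouples into
#' independent two-parameter fits.
#'
#' @param observed Named list of `survival_curve`s; names are stage labels
#'   (`I`, `II`, `IIIA`, `IIIB`, `IV`). Stage A sums the cost over all
#'   supplied curves with equal weight.
#' @param stage `"A"` or `"B"`.
#' @param dists Starting [population_distributions()]; stage B freezes its
#'   `carrying_capacity_diameter`, `rho_mu`, `rho_sigma`.
#' @param priors Literature volume priors (stage A only).
#' @param n_patients Patients per cost evaluation.
#' @param maxit Optimizer iteration budget per fit.
#' @param config A [sim_config()].
#' @param seed Master seed reused by every evaluation (common random
#'   numbers).
#' @return List with `dists` (updated), `par`, `residual`, `n_eval`,
#'   `trace`, `budget_exceeded`.
#' @export
fit_growth <- function(observed, stage = c("A", "B"),
                       dists = population_distributions(),
                       priors = literature_volume_priors(),
                       n_patients = 1e4, maxit = 150,
                       config = sim_config(), seed = 1L) {
  stage <- match.arg(stage)
  stopifnot(length(observed) >= 1, !is.null(names(observed)))
  if (stage == "A") {
    fn <- function(x) {
      d2 <- .apply_overrides(dists, as.list(x))
      model <- lapply(names(observed), function(s)
        .scenario_curve(d2, "untreated_literature", s, n_patients, seed,
                        config, priors = priors))
      names(model) <- names(observed)
      km_cost(model, observed)
    }
    x0 <- c(carrying_capacity_diameter = dists$carrying_capacity_diameter,
            rho_mu = dists$rho_mu, rho_sigma = dists$rho_sigma)
    fit <- .nm_box(fn, x0,
                   lower = c(13.5, 1e-7, 1e-4),
                   upper = c(80, 2e-2, 5e-2), maxit = maxit)
    fit$dists <- .apply_overrides(dists, as.list(fit$par))
    fit
  } else {
    fits <- list(); total <- 0; nev <- 0; exceeded <- FALSE
    for (s in names(observed)) {
      obs <- observed[[s]]
      fn <- function(x) {
        names(x) <- paste0(c("vol_mu_", "vol_sigma_"), s)
        d2 <- .apply_overrides(dists, as.list(x))
        km_cost(.scenario_curve(d2, "untreated", s, n_patients, seed,
                                config), obs)
      }
      row <- dists$volume[dists$volume$stage == s, ]
      x0 <- c(mu = row$mu, sigma = row$sigma)
      f <- .nm_box(fn, x0, lower = c(-2, 0.05), upper = c(5, 12),
                   maxit = maxit)
      names(f$par) <- paste0(c("vol_mu_", "vol_sigma_"), s)
      dists <- .apply_overrides(dists, as.list(f$par))
      fits[[s]] <- f
      total <- total + f$residual; nev <- nev + f$n_eval
      exceeded <- exceeded || f$budget_exceeded
    }
    list(dists = dists, par = unlist(lapply(fits, `[[`, "par")),
         residual = total, n_eval = nev,
         trace = do.call(rbind, lapply(fits, `[[`, "trace")),
         budget_exceeded = exceeded, stage_fits = fits)
  }
}

#' Fit radiosensitivity to a radiation-only survival curve
#'
#' Frees the radiosensitivity distribution (`alpha_mu`, `alpha_sigma`) with
#' growth parameters frozen, simulating the 60 Gy / 30 fraction course on
#' 50/50 IIIA/IIIB cohorts. The alpha-rho correlation is held at
#' `correlation` (set 0 to fit without it; comparing the two residuals
#' reproduces the correlated model's superior fit).
#'
#' @param observed A `survival_curve` for the radiation-only arm.
#' @param dists [population_distributions()] with growth parameters frozen
#'   from [fit_growth()].
#' @param correlation Correlation held fixed during the fit.
#' @param growth_kind `"gompertz"` (intrinsic repopulation) or
#'   `"gompertz_with_kickoff"`.
#' @inheritParams fit_growth
#' @return List with `dists` (alpha fields and correlation updated, all
#'   growth fields untouched), `par`, `residual`, `n_eval`, `trace`,
#'   `budget_exceeded`.
#' @export
fit_radiation <- function(observed, dists,
                          correlation = dists$correlation,
                          growth_kind = "gompertz",
                          n_patients = 1e4, maxit = 120,
                          config = sim_config(), seed = 1L) {
  dists$correlation <- correlation
  fn <- function(x) {
    d2 <- .apply_overrides(dists, as.list(x))
    km_cost(.scenario_curve(d2, "rt_only", n = n_patients, seed = seed,
                            config = config, growth_kind = growth_kind),
            observed)
  }
  x0 <- c(alpha_mu = dists$alpha_mu, alpha_sigma = dists$alpha_sigma)
  fit <- .nm_box(fn, x0, lower = c(1e-4, 1e-3), upper = c(1, 1),
                 maxit = maxit)
  fit$dists <- .apply_overrides(dists, as.list(fit$par))
  fit
}

#' Fit the chemotherapy parameter to a sequential-CRT curve
#'
#' Frees `beta_c_mu` and `beta_c_sigma` (initialized tiny: the chemotherapy
#' effect is near-deterministic across patients) with growth and radiation
#' frozen, simulating the sequential chemoradiation schedule.
#'
#' @param observed A `survival_curve` for the sequential-CRT arm.
#' @param dists [population_distributions()] with growth and radiation
#'   frozen.
#' @inheritParams fit_radiation
#' @return List as in [fit_radiation()] with the beta_c fields updated.
#' @export
fit_chemo <- function(observed, dists, growth_kind = "gompertz",
                      n_patients = 1e4, maxit = 120,
                      config = sim_config(), seed = 1L) {
  fn <- function(x) {
    d2 <- .apply_overrides(dists, as.list(x))
    km_cost(.scenario_curve(d2, "scrt", n = n_patients, seed = seed,
                            config = config, growth_kind = growth_kind),
            observed)
  }
  x0 <- c(beta_c_mu = dists$beta_c_mu, beta_c_sigma = dists$beta_c_sigma)
  fit <- .nm_box(fn, x0, lower = c(1e-4, 1e-5), upper = c(0.2, 0.01),
                 maxit = maxit)
  fit$dists <- .apply_overrides(dists, as.list(fit$par))
  fit
}

#' Residual surface over two parameters
#'
#' Evaluates the fitting cost on a rectangular grid of two named parameters
#' with everything else frozen, under common random numbers, so repeated
#' evaluation at a node is bit-identical. Used to inspect the valley of the
#' growth fit's (K, rho_sigma) objective.
#'
#' @param dists Base [population_distributions()].
#' @param observed Observed curve or named list (per the scenario).
#' @param params Named list of exactly two numeric grids, names as accepted
#'   by the fit overrides (e.g. `carrying_capacity_diameter`, `rho_sigma`,
#'   `alpha_mu`, `vol_mu_II`, ...).
#' @param scenario `"untreated_literature"` (cost summed over the observed
#'   stage curves, volumes pinned to `priors`), `"untreated"`, `"rt_only"` or
#'   `"scrt"`.
#' @inheritParams fit_growth
#' @return Matrix of residuals, rows indexed by the first grid, columns by
#'   the second; grids attached as dimnames.
#' @export
residual_surface <- function(dists, observed, params,
                             scenario = "untreated_literature",
                             priors = literature_volume_priors(),
                             n_patients = 1e4, config = sim_config(),
                             seed = 1L) {
  stopifnot(is.list(params), length(params) == 2, !is.null(names(params)))
  cost_at <- function(ov) {
    d2 <- .apply_overrides(dists, ov)
    if (scenario %in% c("untreated", "untreated_literature")) {
      model <- lapply(names(observed), function(s)
        .scenario_curve(d2, scenario, s, n_patients, seed, config,
                        priors = priors))
      names(model) <- names(observed)
      km_cost(model, observed)
    } else {
      km_cost(.scenario_curve(d2, scenario, n = n_patients, seed = seed,
                              config = config), observed)
    }
  }
  g1 <- params[[1]]; g2 <- params[[2]]
  out <- matrix(NA_real_, length(g1), length(g2),
                dimnames = list(format(g1), format(g2)))
  for (i in seq_along(g1)) for (j in seq_along(g2))
    out[i, j] <- cost_at(setNames(list(g1[i], g2[j]), names(params)))
  out
}
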