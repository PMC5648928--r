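#' Simulation configuration
#'
#' Global constants of the virtual-trial engine.
#'
#' @param cell_density Tumor cell density, cells per cm^3.
#' @param death_diameter Tumor diameter (cm) at which disease death occurs;
#'   13 cm corresponds to roughly 41 doublings of a just-detectable tumor.
#' @param followup_months Follow-up horizon; patients alive at the horizon
#'   are censored.
#' @param natural_death_annual Annual probability of death from other causes
#'   (life-table value), modeled as an independent constant-hazard competing
#'   risk.
#' @param step_days Integrator step (days) inside the treatment window. The
#'   integrator composes the closed-form growth step with the analytic
#'   chemotherapy kill over each step (operator splitting), so the step only
#'   controls the splitting error.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(cell_density = DEFAULT_CELL_DENSITY,
                       death_diameter = 13,
                       followup_months = 60,
                       natural_death_annual = 0.0148,
                       step_days = 0.1) {
  stopifnot(cell_density > 0, death_diameter > 0, followup_months > 0,
            natural_death_annual >= 0, natural_death_annual < 1,
            step_days > 0)
  structure(list(cell_density = cell_density,
                 death_diameter = death_diameter,
                 followup_months = followup_months,
                 natural_death_annual = natural_death_annual,
                 step_days = step_days),
            class = "sim_config")
}

# Deterministic sub-stream seeds: one stream per purpose so that cohort
# sampling, control draws and natural deaths can be replayed independently.
.derive_seed <- function(master, label) {
  h <- 0
  for (cc in utf8ToInt(label)) h <- (h * 31 + cc) %% 1009001
  as.integer(((as.numeric(master) %% 1000003) * 1013 + h * 7) %%
               2147483646) + 1L
}

#' Poisson tumor-control draw
#'
#' A tumor with `n_cells` expected surviving clonogens is controlled with
#' probability `exp(-n_cells)` (the Poisson zero-class). Given a uniform
#' draw `u`, control is `u < exp(-n_cells)`.
#'
#' @param n_cells Expected surviving cell number(s), >= 0.
#' @param u Uniform(0,1) draw(s); generated if missing.
#' @return Logical vector: controlled or not.
#' @export
tumor_control_draw <- function(n_cells, u = runif(length(n_cells))) {
  stopifnot(all(n_cells >= 0))
  u < exp(-n_cells)
}

#' Sample a time of death from other causes
#'
#' Exponential waiting time with annual hazard `-ln(1 - annual)`, independent
#' of the disease course; reproduces the stated annual other-cause survival
#' reduction exactly (`(1 - annual)^t` survival after `t` years).
#'
#' @param n Number of draws.
#' @param config A [sim_config()].
#' @return Times in months (may be `Inf` when the annual risk is zero).
#' @export
natural_death_time <- function(n, config = sim_config()) {
  rate <- -log(1 - config$natural_death_annual)  # per year
  if (rate <= 0) return(rep(Inf, n))
  rexp(n, rate) * 12
}

#' Time for an untreated tumor to reach the death diameter
#'
#' Closed-form crossing time of the death burden under the growth model:
#' the inversion of the Gompertz solution (or `ln(N_death/n0)/rate` for
#' exponential growth).
#'
#' @param n0 Current cell number(s), below the death burden.
#' @param params A [growth_parameters()] object.
#' @param config A [sim_config()].
#' @return Time(s) in days.
#' @export
time_to_death_diameter <- function(n0, params, config = sim_config()) {
  stopifnot(inherits(params, "growth_parameters"))
  nd <- diameter_to_cell_number(config$death_diameter, config$cell_density)
  if (any(n0 >= nd)) stop("burden already at or past the death diameter")
  if (params$model_kind == "exponential")
    return(log(nd / n0) / params$exp_rate)
  if (params$carrying_capacity_diameter <= config$death_diameter)
    stop("carrying capacity below the death diameter: the tumor never ",
         "reaches it")
  kc <- diameter_to_cell_number(params$carrying_capacity_diameter,
                                config$cell_density)
  .gomp_time_to(n0, nd, params$rho, kc)
}

# Vectorized untreated crossing time (Inf when n0 already tiny relative to
# horizon is fine; caller compares against the follow-up).
.time_to_burden <- function(n0, n1, rho, kc, kind) {
  if (kind == "exponential") log(n1 / n0) / rho
  else .gomp_time_to(n0, n1, rho, kc)
}

#' Simulate a cohort through one treatment arm
#'
#' Event-driven integration of the combined growth / chemotherapy /
#' radiation dynamics for every patient of a cohort, sharing one schedule.
#' The burden grows untreated during each patient's diagnosis-to-treatment
#' delay; inside the treatment window it evolves by operator splitting
#' (closed-form growth step, then the analytic chemotherapy log-kill for the
#' step), radiation fractions act as instantaneous multiplicative survival
#' events, and after the last treatment event the burden follows the growth
#' law in closed form. Death from disease occurs when the burden reaches the
#' death diameter; at the end of the treatment course a single Poisson
#' control draw on the course nadir decides tumor control; controlled and
#' slow-growing patients are censored at the follow-up horizon unless an
#' independent natural death intervenes. The survival clock starts at
#' diagnosis.
#'
#' @param cohort Cohort data frame from [sample_cohort()] (columns
#'   `diameter`, `rho`, `alpha`, `beta_c`, `delay`; `id` and `stage` carried
#'   through if present).
#' @param schedule A [treatment_schedule()], or `NULL` for no treatment.
#' @param growth A [growth_model()] shared by the cohort.
#' @param config A [sim_config()].
#' @param alpha_beta_ratio Linear-quadratic dose ratio, Gy.
#' @param seed Master seed; control draws and natural deaths use independent
#'   sub-streams derived from it, so two arms simulated with the same seed
#'   share patients' uniforms (common random numbers).
#' @return Data frame of outcome records: `survival_months` in (0, 60],
#'   `event` (`death_tumor`, `death_natural`, `censored`), `controlled`,
#'   `nadir_cells`, `end_of_treatment_cells`.
#' @export
simulate_cohort <- function(cohort, schedule = NULL,
                            growth = growth_model(),
                            config = sim_config(),
                            alpha_beta_ratio = 10,
                            seed = 1L) {
  stopifnot(is.data.frame(cohort), inherits(growth, "growth_model"),
            inherits(config, "sim_config"))
  n <- nrow(cohort)
  if (n == 0) stop("empty cohort")
  dens <- config$cell_density
  kc <- diameter_to_cell_number(growth$carrying_capacity_diameter, dens)
  ndeath <- diameter_to_cell_number(config$death_diameter, dens)
  if (growth$model_kind != "exponential" && kc <= ndeath)
    stop("carrying capacity must exceed the death diameter")
  n0 <- diameter_to_cell_number(cohort$diameter, dens)
  rho <- cohort$rho
  kind <- growth$model_kind
  fu_m <- config$followup_months
  fu_days <- fu_m * MONTH_DAYS

  u_ctrl <- local({
    set.seed(.derive_seed(seed, "control")); runif(n)
  })
  nat_m <- local({
    set.seed(.derive_seed(seed, "natural")); natural_death_time(n, config)
  })

  has_events <- !is.null(schedule) &&
    (nrow(schedule$fractions) + nrow(schedule$administrations)) > 0

  if (!has_events) {
    t_tumor_days <- .time_to_burden(n0, ndeath, rho, kc, kind)
    controlled <- rep(FALSE, n)
    nadir <- n0
    eot <- rep(NA_real_, n)
  } else {
    frac <- schedule$fractions
    adm <- schedule$administrations
    delay <- cohort$delay
    h <- config$step_days

    last_event <- max(c(frac$time, adm$time))
    # keep stepping ~7 half-lives past the last administration, then fold the
    # analytic remainder of the drug exposure into one terminal kill
    window_end <- max(c(frac$time,
                        if (nrow(adm)) max(adm$time) + 7 else NULL))
    if (max(delay) + last_event > fu_days)
      stop("schedule events extend past the follow-up horizon")

    # untreated growth during the delay; a patient can cross the death
    # diameter before therapy starts
    t_pre <- .time_to_burden(n0, ndeath, rho, kc, kind)
    died_pre <- t_pre < delay
    n_ts <- if (kind == "exponential") n0 * exp(rho * delay)
            else .gomp_step(n0, rho, kc, delay)

    nsteps <- as.integer(ceiling(round(window_end / h, 9)))
    frac_step <- as.integer(round(frac$time / h))
    if (nrow(frac) && any(abs(frac_step * h - frac$time) > 1e-9))
      frac_step <- as.integer(ceiling(frac$time / h))
    frac_lnk <- frac$dose + frac$dose^2 / alpha_beta_ratio  # times alpha
    kill_at <- tapply(frac_lnk, frac_step, sum)
    kill_steps <- as.integer(names(kill_at))

    step_integral <- vapply(seq_len(nsteps), function(k)
      .conc_integral(adm, (k - 1) * h, k * h), numeric(1))

    kick <- kind == "gompertz_with_kickoff" && nrow(frac) > 0
    if (kick) {
      kick_from <- growth$kickoff_delay
      kick_to <- max(frac$time)
      kick_fac <- 2^(h / growth$kickoff_vdt)
    }

    nn <- n_ts
    nadir <- n_ts
    cross_day <- rep(NA_real_, n)
    beta_c <- cohort$beta_c
    alpha <- cohort$alpha
    if (anyNA(alpha) && nrow(frac) > 0)
      stop("cohort has no alpha values but the schedule contains radiation")
    grow_exp <- kind == "exponential"
    # fractions scheduled exactly at the window origin fire before stepping
    k0 <- match(0L, kill_steps)
    if (!is.na(k0)) {
      nn <- nn * exp(-alpha * kill_at[[k0]])
      nadir <- pmin(nadir, nn)
    }
    for (k in seq_len(nsteps)) {
      t0 <- (k - 1) * h
      if (kick && t0 >= kick_from && t0 < kick_to) {
        nn <- pmin(nn * kick_fac, kc)
      } else if (grow_exp) {
        nn <- nn * exp(rho * h)
      } else {
        nn <- .gomp_step(nn, rho, kc, h)
      }
      if (step_integral[k] > 0) nn <- nn * exp(-beta_c * step_integral[k])
      ki <- match(k, kill_steps)
      if (!is.na(ki)) nn <- nn * exp(-alpha * kill_at[[ki]])
      nadir <- pmin(nadir, nn)
      hit <- is.na(cross_day) & nn >= ndeath
      if (any(hit)) cross_day[hit] <- k * h
    }
    tail_int <- .conc_integral(adm, window_end, Inf)
    if (tail_int > 0) {
      nn <- nn * exp(-beta_c * tail_int)
      nadir <- pmin(nadir, nn)
    }
    eot <- nn

    died_in_rx <- !died_pre & !is.na(cross_day)
    alive_end <- !died_pre & !died_in_rx
    controlled <- alive_end & tumor_control_draw(nadir, u_ctrl)

    t_regrow <- rep(Inf, n)
    reg <- alive_end & !controlled
    if (any(reg))
      t_regrow[reg] <- .time_to_burden(pmin(nn[reg], ndeath * (1 - 1e-12)),
                                       ndeath, rho[reg], kc, kind)
    t_tumor_days <- rep(Inf, n)
    t_tumor_days[died_pre] <- t_pre[died_pre]
    t_tumor_days[died_in_rx] <- delay[died_in_rx] + cross_day[died_in_rx]
    t_tumor_days[reg] <- delay[reg] + window_end + t_regrow[reg]
    nadir[died_pre] <- n0[died_pre]
    eot[died_pre] <- NA_real_
  }

  t_tumor_m <- t_tumor_days / MONTH_DAYS
  survival_months <- pmin(t_tumor_m, nat_m, fu_m)
  event <- ifelse(t_tumor_m <= survival_months & is.finite(t_tumor_m) &
                    t_tumor_m < fu_m, "death_tumor",
                  ifelse(nat_m < fu_m, "death_natural", "censored"))
  survival_months[event == "censored"] <- fu_m
  out <- data.frame(
    id = if ("id" %in% names(cohort)) cohort$id else seq_len(n),
    stage = if ("stage" %in% names(cohort)) cohort$stage else NA_character_,
    survival_months = survival_months,
    event = event,
    controlled = controlled,
    nadir_cells = nadir,
    end_of_treatment_cells = eot)
  rownames(out) <- NULL
  out
}

#' A single virtual patient
#'
#' @param stage AJCC stage label.
#' @param initial_diameter Tumor diameter at diagnosis, cm (detectable floor
#'   0.3 cm; below the death diameter; at most 5 cm for stage I).
#' @param growth A [growth_parameters()] object (per-patient rho).
#' @param radiation A [radiation_parameters()] object.
#' @param beta_c Chemotherapy cell kill per mg/m^3, > 0.
#' @param delay Days between diagnosis and treatment start.
#' @return An object of class `virtual_patient`.
#' @export
virtual_patient <- function(stage, initial_diameter, growth, radiation,
                            beta_c, delay = 14) {
  stopifnot(stage %in% STAGES,
            initial_diameter >= 0.3, initial_diameter < 13,
            inherits(growth, "growth_parameters"),
            inherits(radiation, "radiation_parameters"),
            beta_c > 0, delay >= 0)
  if (stage == "I" && initial_diameter > 5)
    stop("stage I tumors are at most 5 cm")
  structure(list(stage = stage, initial_diameter = initial_diameter,
                 growth = growth, radiation = radiation, beta_c = beta_c,
                 delay = delay),
            class = "virtual_patient")
}

#' Simulate a single patient
#'
#' Thin wrapper around [simulate_cohort()] for one [virtual_patient()].
#'
#' @param patient A [virtual_patient()].
#' @param schedule A [treatment_schedule()] or `NULL`.
#' @param config A [sim_config()].
#' @param seed Master seed for the control and natural-death draws.
#' @return A one-row outcome data frame (see [simulate_cohort()]).
#' @export
simulate_patient <- function(patient, schedule = NULL,
                             config = sim_config(), seed = 1L) {
  stopifnot(inherits(patient, "virtual_patient"))
  cohort <- data.frame(id = 1L, stage = patient$stage,
                       diameter = patient$initial_diameter,
                       rho = patient$growth$rho,
                       alpha = patient$radiation$alpha,
                       beta_c = patient$beta_c,
                       delay = patient$delay)
  simulate_cohort(cohort, schedule, growth = patient$growth, config = config,
                  alpha_beta_ratio = patient$radiation$alpha_beta_ratio,
                  seed = seed)
}

#' Write / read outcome tables as CSV
#'
#' One row per patient; lossless round trip.
#'
#' @param outcomes Outcome data frame from [simulate_cohort()].
#' @param path File path.
#' @return `write_outcomes_csv` returns `path` invisibly; `read_outcomes_csv`
#'   returns the outcome data frame.
#' @export
write_outcomes_csv <- function(outcomes, path) {
  utils::write.csv(outcomes, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_outcomes_csv
#' @export
read_outcomes_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
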