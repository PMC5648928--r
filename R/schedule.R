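#' Radiation sensitivity parameters
#'
#' Linear-quadratic parameters; beta is always derived as
#' `alpha / alpha_beta_ratio` and never stored independently.
#'
#' @param alpha Linear cell-kill coefficient, Gy^-1, > 0.
#' @param alpha_beta_ratio Dose (Gy) at which linear and quadratic kill are
#'   equal; 10 Gy is the standard assumption for NSCLC.
#' @return An object of class `radiation_parameters`.
#' @export
radiation_parameters <- function(alpha, alpha_beta_ratio = 10) {
  stopifnot(is.numeric(alpha), all(alpha > 0), alpha_beta_ratio > 0)
  structure(list(alpha = alpha, alpha_beta_ratio = alpha_beta_ratio),
            class = "radiation_parameters")
}

#' Log cell kill of one radiation fraction
#'
#' Returns `alpha * d + (alpha/ratio) * d^2`; the surviving fraction of the
#' fraction is `exp(-result)`. Fractions multiply, so a course's total kill is
#' the sum of its per-fraction values.
#'
#' @param rad A [radiation_parameters()] object.
#' @param dose Fraction dose(s) in Gy, >= 0.
#' @return Dimensionless natural-log kill.
#' @export
lq_ln_kill <- function(rad, dose) {
  stopifnot(inherits(rad, "radiation_parameters"))
  if (any(dose < 0)) stop("dose must be non-negative")
  rad$alpha * dose + (rad$alpha / rad$alpha_beta_ratio) * dose^2
}

#' Treatment schedule
#'
#' Timed radiation fractions and drug administrations defining one trial arm.
#' Times are days from the schedule origin (the start of therapy); day 1 of a
#' protocol is time 0.
#'
#' @param fractions Data frame with columns `time` (days) and `dose` (Gy,
#'   each > 0 and <= 10, the validity range of the linear-quadratic model), or
#'   `NULL` for none.
#' @param administrations Data frame with columns `drug`, `time` (days),
#'   `cmax` (peak concentration, mg/m^3) and `half_life_hours`, or `NULL`.
#' @param label Free-text arm label.
#' @return An object of class `treatment_schedule`. Event rows are sorted by
#'   time; the object is treated as immutable once built.
#' @export
treatment_schedule <- function(fractions = NULL, administrations = NULL,
                               label = "") {
  if (is.null(fractions))
    fractions <- data.frame(time = numeric(0), dose = numeric(0))
  if (is.null(administrations))
    administrations <- data.frame(drug = character(0), time = numeric(0),
                                  cmax = numeric(0),
                                  half_life_hours = numeric(0))
  stopifnot(all(c("time", "dose") %in% names(fractions)),
            all(c("drug", "time", "cmax", "half_life_hours") %in%
                  names(administrations)))
  if (nrow(fractions)) {
    stopifnot(all(fractions$time >= 0), all(fractions$dose > 0))
    if (any(fractions$dose > 10))
      stop("fraction doses above 10 Gy are outside the validity range of ",
           "the linear-quadratic model")
    fractions <- fractions[order(fractions$time), , drop = FALSE]
  }
  if (nrow(administrations)) {
    stopifnot(all(administrations$time >= 0),
              all(administrations$cmax >= 0),
              all(administrations$half_life_hours > 0))
    administrations <- administrations[order(administrations$time), ,
                                       drop = FALSE]
  }
  rownames(fractions) <- rownames(administrations) <- NULL
  structure(list(fractions = fractions, administrations = administrations,
                 label = label),
            class = "treatment_schedule")
}

#' @export
print.treatment_schedule <- function(x, ...) {
  cat(sprintf("<treatment_schedule '%s'> %d fractions (%.1f Gy total), %d drug administrations\n",
              x$label, nrow(x$fractions), sum(x$fractions$dose),
              nrow(x$administrations)))
  invisible(x)
}

# Per-day decay constants of the administrations.
.adm_lambda <- function(admins) log(2) * 24 / admins$half_life_hours

#' Drug concentration at a time point
#'
#' Each administration decays exponentially from its peak; simultaneous and
#' overlapping doses superpose linearly. Zero before the first administration
#' and right-continuous at administration times.
#'
#' @param schedule A [treatment_schedule()] (or a bare administrations data
#'   frame).
#' @param t Time(s) in days from the schedule origin.
#' @return Total concentration in mg/m^3.
#' @export
concentration_at <- function(schedule, t) {
  admins <- if (inherits(schedule, "treatment_schedule"))
    schedule$administrations else schedule
  if (!nrow(admins)) return(rep(0, length(t)))
  lam <- .adm_lambda(admins)
  vapply(t, function(ti) {
    on <- admins$time <= ti
    sum(admins$cmax[on] * exp(-lam[on] * (ti - admins$time[on])))
  }, numeric(1))
}

# Closed-form integral of the total concentration over [t1, t2]
# (t2 may be Inf). Scalar in t1/t2.
.conc_integral <- function(admins, t1, t2) {
  if (!nrow(admins) || t2 <= t1) return(0)
  lam <- .adm_lambda(admins)
  a <- pmax(t1, admins$time)
  live <- admins$time < t2
  lo <- exp(-lam * (a - admins$time))
  hi <- if (is.finite(t2)) exp(-lam * (t2 - admins$time)) else 0
  sum((admins$cmax / lam * (lo - hi))[live & a < t2])
}

#' Chemotherapy log cell kill over an interval
#'
#' The log-cell-kill model removes cells at rate `beta_c * C(t)`, so the
#' natural-log kill accumulated over `[t1, t2]` is
#' `beta_c * integral(C(t) dt)`, computed analytically as a sum of
#' exponential-segment integrals. Additive over disjoint intervals.
#'
#' @inheritParams concentration_at
#' @param beta_c Chemotherapy cell-kill coefficient(s), per mg/m^3, >= 0. May
#'   be a vector (e.g. one value per patient); the scalar exposure integral is
#'   shared.
#' @param t1,t2 Interval bounds in days, `0 <= t1 <= t2` (`t2` may be `Inf`).
#' @return Dimensionless natural-log kill, same length as `beta_c`.
#' @export
chemo_ln_kill_integral <- function(schedule, beta_c, t1, t2) {
  admins <- if (inherits(schedule, "treatment_schedule"))
    schedule$administrations else schedule
  stopifnot(all(beta_c >= 0), t1 >= 0)
  if (t2 < t1) stop("t2 must not precede t1")
  beta_c * .conc_integral(admins, t1, t2)
}

# Weekday pattern: f fractions at one per weekday from a start day.
.weekday_times <- function(start_day, n_fractions) {
  weeks <- (seq_len(n_fractions) - 1) %/% 5
  days <- (seq_len(n_fractions) - 1) %% 5
  start_day + weeks * 7 + days
}

#' Radiation-only course of 60 Gy in 2 Gy fractions
#'
#' 30 weekday fractions (Monday-Friday pattern, 6 calendar weeks), the
#' prescription of the radiation-only reference trial.
#'
#' @param start_day First fraction day (days from schedule origin).
#' @param weekday_spacing If `FALSE`, fractions fall on consecutive days (a
#'   sensitivity switch; the default weekday pattern spans 40 calendar days).
#' @return A [treatment_schedule()].
#' @export
build_rt_only_60gy <- function(start_day = 0, weekday_spacing = TRUE) {
  stopifnot(start_day >= 0)
  times <- if (weekday_spacing) .weekday_times(start_day, 30)
           else start_day + 0:29
  treatment_schedule(
    fractions = data.frame(time = times, dose = 2),
    label = sprintf("RT-only 60 Gy/30 fx from day %g", start_day))
}

# Chemotherapy content shared by both trial arms: cisplatin 100 mg/m^3 on
# protocol days 1 and 29, vinblastine 5 mg/m^3 weekly for 5 weeks.
.doublet_admins <- function() {
  data.frame(
    drug = c("cisplatin", "cisplatin", rep("vinblastine", 5)),
    time = c(0, 28, seq(0, 28, by = 7)),
    cmax = c(100, 100, rep(5, 5)),
    half_life_hours = 24)
}

#' Sequential chemoradiation preset
#'
#' Cisplatin/vinblastine induction followed by 60 Gy in 2 Gy fractions
#' starting on protocol day 50 (time 49).
#' @return A [treatment_schedule()].
#' @export
build_rtog9410_sequential <- function() {
  rt <- build_rt_only_60gy(49)
  treatment_schedule(fractions = rt$fractions,
                     administrations = .doublet_admins(),
                     label = "sequential CRT (RT from day 50)")
}

#' Concurrent chemoradiation preset
#'
#' The same drug content as the sequential arm with the 60 Gy course starting
#' on protocol day 1 (time 0), concurrent with chemotherapy.
#' @return A [treatment_schedule()].
#' @export
build_rtog9410_concurrent <- function() {
  rt <- build_rt_only_60gy(0)
  treatment_schedule(fractions = rt$fractions,
                     administrations = .doublet_admins(),
                     label = "concurrent CRT (RT from day 1)")
}

#' Chemotherapy-only doublet schedule
#'
#' Repeated cycles of the cisplatin/vinblastine doublet with no radiation:
#' per cycle, cisplatin 100 mg/m^3 on cycle day 1 and vinblastine 5 mg/m^3 on
#' cycle days 1 and 8.
#'
#' @param n_cycles Number of cycles, >= 1.
#' @param cycle_length Days between cycle starts.
#' @return A [treatment_schedule()].
#' @export
build_chemo_only <- function(n_cycles = 4, cycle_length = 28) {
  stopifnot(n_cycles >= 1, cycle_length > 0)
  starts <- (seq_len(n_cycles) - 1) * cycle_length
  admins <- do.call(rbind, lapply(starts, function(s) {
    data.frame(drug = c("cisplatin", "vinblastine", "vinblastine"),
               time = s + c(0, 0, 7),
               cmax = c(100, 5, 5),
               half_life_hours = 24)
  }))
  treatment_schedule(administrations = admins,
                     label = sprintf("chemo-only doublet, %d cycles",
                                     n_cycles))
}

#' Induction segment of a schedule
#'
#' Drops all radiation fractions, keeping the drug administrations; used to
#' study repopulation between induction chemotherapy and radiotherapy.
#'
#' @param schedule A [treatment_schedule()].
#' @return A [treatment_schedule()] with no fractions.
#' @export
chemo_segment <- function(schedule) {
  stopifnot(inherits(schedule, "treatment_schedule"))
  treatment_schedule(administrations = schedule$administrations,
                     label = paste(schedule$label, "(chemo segment)"))
}

#' Write / read a treatment schedule as structured text
#'
#' Schedules serialize to YAML with `fractions: [{day, dose_Gy}]` and
#' `administrations: [{drug, day, cmax_mg_per_m3, half_life_h}]`.
#'
#' @param schedule A [treatment_schedule()].
#' @param path File path.
#' @return `write_schedule_yaml` returns `path` invisibly;
#'   `read_schedule_yaml` returns a [treatment_schedule()].
#' @export
write_schedule_yaml <- function(schedule, path) {
  stopifnot(inherits(schedule, "treatment_schedule"))
  doc <- list(
    label = schedule$label,
    fractions = lapply(seq_len(nrow(schedule$fractions)), function(i) {
      f <- schedule$fractions[i, ]
      list(day = f$time, dose_Gy = f$dose)
    }),
    administrations = lapply(seq_len(nrow(schedule$administrations)),
      function(i) {
        a <- schedule$administrations[i, ]
        list(drug = a$drug, day = a$time, cmax_mg_per_m3 = a$cmax,
             half_life_h = a$half_life_hours)
      }))
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' @rdname write_schedule_yaml
#' @export
read_schedule_yaml <- function(path) {
  doc <- yaml::read_yaml(path)
  fr <- if (length(doc$fractions))
    data.frame(time = vapply(doc$fractions, `[[`, 0, "day"),
               dose = vapply(doc$fractions, `[[`, 0, "dose_Gy"))
  ad <- if (length(doc$administrations))
    data.frame(drug = vapply(doc$administrations, `[[`, "", "drug"),
               time = vapply(doc$administrations, `[[`, 0, "day"),
               cmax = vapply(doc$administrations, `[[`, 0, "cmax_mg_per_m3"),
               half_life_hours = vapply(doc$administrations, `[[`, 0,
                                        "half_life_h"))
  treatment_schedule(fractions = fr, administrations = ad,
                     label = doc$label %||% "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
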