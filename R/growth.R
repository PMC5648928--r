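# Days per month used throughout for survival grids.
MONTH_DAYS <- 365 / 12

#' Default tumor cell density
#'
#' Cells per cubic centimetre of tumor, as measured experimentally for lung
#' cancer. The value scales burdens uniformly and has no effect on fits.
#' @export
DEFAULT_CELL_DENSITY <- 5.8e8

#' Growth model structure shared by a cohort
#'
#' Describes the growth law applied to every patient of a cohort; the
#' per-patient growth rate `rho` lives on the cohort itself (see
#' [sample_cohort()]). The carrying capacity is stored as an equivalent sphere
#' diameter (cm) and converted to a cell number with the configured density at
#' use time.
#'
#' @param model_kind `"gompertz"` (default; repopulation is intrinsic, the
#'   relative growth rate rises as the burden shrinks), `"exponential"`, or
#'   `"gompertz_with_kickoff"` (Gompertz, but replaced by exponential
#'   regrowth with doubling time `kickoff_vdt` from `kickoff_delay` days after
#'   treatment start until the end of the radiation course).
#' @param carrying_capacity_diameter Carrying capacity as a diameter in cm.
#' @param kickoff_delay Days after treatment start at which kickoff
#'   repopulation begins.
#' @param kickoff_vdt Doubling time (days) of kickoff exponential regrowth.
#' @return An object of class `growth_model`.
#' @export
growth_model <- function(model_kind = c("gompertz", "exponential",
                                        "gompertz_with_kickoff"),
                         carrying_capacity_diameter = 30,
                         kickoff_delay = 28, kickoff_vdt = 3) {
  model_kind <- match.arg(model_kind)
  stopifnot(carrying_capacity_diameter > 0, kickoff_vdt > 0,
            kickoff_delay >= 0)
  structure(list(model_kind = model_kind,
                 carrying_capacity_diameter = carrying_capacity_diameter,
                 kickoff_delay = kickoff_delay,
                 kickoff_vdt = kickoff_vdt),
            class = "growth_model")
}

#' Growth parameters for a single tumor
#'
#' A [growth_model()] plus the tumor-specific growth rate, for the
#' single-trajectory operations ([gompertz_solve()], [growth_derivative()],
#' [vdt_instantaneous()], ...).
#'
#' @param rho Gompertz growth rate, per day (natural-log convention: the
#'   burden obeys dN/dt = rho * N * ln(K/N)).
#' @param exp_rate Exponential rate per day; required when
#'   `model_kind = "exponential"`.
#' @inheritParams growth_model
#' @return An object of classes `growth_parameters`, `growth_model`.
#' @export
growth_parameters <- function(rho, carrying_capacity_diameter = 30,
                              model_kind = "gompertz",
                              kickoff_delay = 28, kickoff_vdt = 3,
                              exp_rate = NULL) {
  stopifnot(is.numeric(rho), length(rho) == 1, rho > 0)
  g <- growth_model(model_kind, carrying_capacity_diameter,
                    kickoff_delay, kickoff_vdt)
  if (g$model_kind == "exponential") {
    if (is.null(exp_rate)) exp_rate <- rho
    stopifnot(exp_rate > 0)
  }
  g$rho <- rho
  g$exp_rate <- exp_rate
  class(g) <- c("growth_parameters", "growth_model")
  g
}

#' Convert tumor diameter to cell number
#'
#' Assumes a spherical tumor: N = (pi/6) d^3 * density.
#'
#' @param diameter Diameter(s) in cm.
#' @param density Cells per cm^3.
#' @return Cell number(s); fractional values below 1 are meaningful and kept.
#' @export
diameter_to_cell_number <- function(diameter, density = DEFAULT_CELL_DENSITY) {
  stopifnot(is.numeric(diameter), all(diameter >= 0), density > 0)
  (pi / 6) * diameter^3 * density
}

#' Convert cell number to tumor diameter
#'
#' Exact inverse of [diameter_to_cell_number()].
#'
#' @param n Cell number(s).
#' @inheritParams diameter_to_cell_number
#' @return Diameter(s) in cm.
#' @export
cell_number_to_diameter <- function(n, density = DEFAULT_CELL_DENSITY) {
  stopifnot(is.numeric(n), all(n >= 0), density > 0)
  (6 * n / (pi * density))^(1 / 3)
}

# Internal vectorized Gompertz propagation: n, rho, dt may be vectors.
.gomp_step <- function(n, rho, k_cells, dt) {
  k_cells * exp(log(n / k_cells) * exp(-rho * dt))
}

# Time for a Gompertz trajectory to go from n0 to n1 (either direction);
# requires 0 < n0, n1 < k_cells.
.gomp_time_to <- function(n0, n1, rho, k_cells) {
  log(log(k_cells / n0) / log(k_cells / n1)) / rho
}

#' Closed-form Gompertz trajectory
#'
#' Propagates a burden `n0` forward `dt` days under Gompertz growth:
#' N(dt) = K * exp(-ln(K/n0) * exp(-rho dt)). For an exponential model the
#' solution is n0 * exp(rate * dt).
#'
#' @param n0 Initial cell number (0 < n0 <= capacity cells for Gompertz).
#' @param params A [growth_parameters()] object.
#' @param dt Time step(s), days, >= 0.
#' @param cell_density Cells per cm^3 used to convert the capacity diameter.
#' @return Cell number(s) after `dt` days.
#' @export
gompertz_solve <- function(n0, params, dt,
                           cell_density = DEFAULT_CELL_DENSITY) {
  stopifnot(inherits(params, "growth_parameters"), all(dt >= 0), all(n0 > 0))
  if (params$model_kind == "exponential")
    return(n0 * exp(params$exp_rate * dt))
  kc <- diameter_to_cell_number(params$carrying_capacity_diameter,
                                cell_density)
  if (any(n0 > kc))
    stop("initial burden exceeds the carrying capacity; Gompertz growth is ",
         "undefined above capacity")
  .gomp_step(n0, params$rho, kc, dt)
}

#' Instantaneous growth derivative
#'
#' dN/dt = rho * N * ln(K/N) for Gompertz, rate * N for exponential. Serves as
#' the integrand against which the closed form is verified.
#'
#' @param n Cell number(s) > 0.
#' @inheritParams gompertz_solve
#' @return Growth rate(s) in cells per day.
#' @export
growth_derivative <- function(n, params,
                              cell_density = DEFAULT_CELL_DENSITY) {
  stopifnot(inherits(params, "growth_parameters"))
  if (any(n <= 0)) stop("cell number must be positive")
  if (params$model_kind == "exponential") return(params$exp_rate * n)
  kc <- diameter_to_cell_number(params$carrying_capacity_diameter,
                                cell_density)
  params$rho * n * log(kc / n)
}

#' Growth rate under kickoff repopulation
#'
#' Before the kickoff delay the burden grows along its Gompertz curve; from
#' the delay onward (counting from treatment start) growth is exponential with
#' rate ln(2)/kickoff_vdt, the accelerated-repopulation regime.
#'
#' @param n Current cell number(s).
#' @param t_since_treatment_start Days since the start of therapy.
#' @inheritParams gompertz_solve
#' @return dN/dt in cells per day.
#' @export
kickoff_growth_rate <- function(n, t_since_treatment_start, params,
                                cell_density = DEFAULT_CELL_DENSITY) {
  stopifnot(inherits(params, "growth_parameters"),
            params$model_kind == "gompertz_with_kickoff")
  gomp <- growth_derivative(n, params, cell_density)
  lambda <- log(2) / params$kickoff_vdt
  ifelse(t_since_treatment_start >= params$kickoff_delay, lambda * n, gomp)
}

#' Volume doubling time from two examinations
#'
#' VDT = (t2 - t1) ln(2) / ln(v2/v1). Negative when the tumor shrank over the
#' interval, which is a meaningful signal of regression.
#'
#' @param v1,v2 Volumes (any consistent unit) at the two examinations, > 0.
#' @param t1,t2 Examination times in days, t2 > t1.
#' @return VDT in days.
#' @export
vdt_between <- function(v1, v2, t1, t2) {
  stopifnot(all(v1 > 0), all(v2 > 0), all(t2 > t1))
  if (any(v1 == v2)) stop("volumes are equal; doubling time is undefined")
  (t2 - t1) * log(2) / log(v2 / v1)
}

#' Instantaneous volume doubling time
#'
#' The time for the tumor to reach twice its current size. Constant
#' (ln 2 / rate) under exponential growth; under Gompertz it shrinks as the
#' tumor shrinks, which is how the model accounts for repopulation.
#'
#' @param n Current cell number(s); `2 * n` must stay below capacity for the
#'   Gompertz model.
#' @inheritParams gompertz_solve
#' @return Doubling time(s) in days.
#' @export
vdt_instantaneous <- function(n, params,
                              cell_density = DEFAULT_CELL_DENSITY) {
  stopifnot(inherits(params, "growth_parameters"), all(n > 0))
  if (params$model_kind == "exponential")
    return(rep(log(2) / params$exp_rate, length(n)))
  kc <- diameter_to_cell_number(params$carrying_capacity_diameter,
                                cell_density)
  if (any(2 * n >= kc))
    stop("burden cannot double below the carrying capacity")
  .gomp_time_to(n, 2 * n, params$rho, kc)
}
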