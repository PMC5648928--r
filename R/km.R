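#' Kaplan-Meier survival curve on a monthly grid
#'
#' Product-limit estimator over death events with right censoring, evaluated
#' on an integer grid of months. `SF(m)` is the estimated probability of
#' surviving beyond month `m`; with censoring only at the follow-up horizon
#' it reduces to the empirical survival function.
#'
#' @param outcomes Outcome data frame (columns `survival_months` and `event`;
#'   any `event` other than `"censored"` counts as a death).
#' @param grid Integer months at which to evaluate the curve.
#' @return An object of classes `survival_curve`, `data.frame` with columns
#'   `month` and `survival_fraction` (non-increasing, in \[0, 1\]).
#' @export
km_curve <- function(outcomes, grid = 1:60) {
  stopifnot(is.data.frame(outcomes), nrow(outcomes) > 0)
  tt <- outcomes$survival_months
  dd <- outcomes$event != "censored"
  ut <- sort(unique(tt[dd]))
  if (length(ut)) {
    n_risk <- vapply(ut, function(x) sum(tt >= x), numeric(1))
    n_dead <- vapply(ut, function(x) sum(tt == x & dd), numeric(1))
    surv <- cumprod(1 - n_dead / n_risk)
    sf <- vapply(grid, function(m) {
      i <- findInterval(m, ut)
      if (i == 0) 1 else surv[i]
    }, numeric(1))
  } else {
    sf <- rep(1, length(grid))
  }
  structure(data.frame(month = grid, survival_fraction = sf),
            class = c("survival_curve", "data.frame"))
}

#' Survival fraction at given months
#'
#' @param curve A `survival_curve`.
#' @param months Months present on the curve's grid.
#' @return Numeric survival fractions.
#' @export
sf_at <- function(curve, months) {
  idx <- match(months, curve$month)
  if (anyNA(idx)) stop("month not on the curve grid")
  curve$survival_fraction[idx]
}

#' Sum-of-squares cost between model and observed curves
#'
#' The fitting objective: the sum over the monthly grid of squared
#' differences in survival fraction. For multi-curve fits, pass named lists;
#' stage-wise costs add with equal weight.
#'
#' @param model_curves A `survival_curve` or named list of them.
#' @param observed_curves Matching `survival_curve` or named list.
#' @return Non-negative scalar; zero iff the curves agree on the grid.
#' @export
km_cost <- function(model_curves, observed_curves) {
  if (inherits(model_curves, "survival_curve"))
    model_curves <- list(model_curves)
  if (inherits(observed_curves, "survival_curve"))
    observed_curves <- list(observed_curves)
  stopifnot(length(model_curves) == length(observed_curves))
  if (!is.null(names(model_curves)) && !is.null(names(observed_curves)))
    observed_curves <- observed_curves[names(model_curves)]
  total <- 0
  for (i in seq_along(model_curves)) {
    m <- model_curves[[i]]; o <- observed_curves[[i]]
    if (!identical(as.numeric(m$month), as.numeric(o$month)))
      stop("model and observed curves are on different month grids")
    total <- total + sum((m$survival_fraction - o$survival_fraction)^2)
  }
  total
}

#' Write / read a survival curve as CSV
#'
#' The exchange format is a two-column CSV with header
#' `month,survival_fraction` and a complete monthly grid. Reading validates
#' bounds and warns (without failing) on non-monotone fractions, since
#' digitized clinical curves may wobble.
#'
#' @param curve A `survival_curve`.
#' @param path File path.
#' @return `write_survival_csv` returns `path` invisibly; `read_survival_csv`
#'   returns a `survival_curve`.
#' @export
write_survival_csv <- function(curve, path) {
  stopifnot(inherits(curve, "survival_curve"))
  utils::write.csv(data.frame(month = curve$month,
                              survival_fraction = curve$survival_fraction),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_survival_csv
#' @export
read_survival_csv <- function(path, months = 1:60) {
  df <- utils::read.csv(path)
  if (!identical(names(df), c("month", "survival_fraction")))
    stop("expected header 'month,survival_fraction'")
  if (!identical(as.integer(df$month), as.integer(months)))
    stop("curve must cover months ", months[1], "..", months[length(months)],
         " completely")
  sf <- df$survival_fraction
  if (any(!is.finite(sf)) || any(sf < 0) || any(sf > 1))
    stop("survival fractions must lie in [0, 1]")
  if (any(diff(sf) > 1e-9))
    warning("survival fractions are not non-increasing")
  structure(data.frame(month = as.integer(df$month),
                       survival_fraction = sf),
            class = c("survival_curve", "data.frame"))
}
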