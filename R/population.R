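STAGES <- c("I", "II", "IIIA", "IIIB", "IV")

#' Population parameter distributions
#'
#' The full parameter set generating a virtual cohort: per-stage truncated
#' lognormal initial-diameter distributions, the growth-rate and
#' radiosensitivity normals with their correlation, the chemotherapy
#' cell-kill normal, the carrying capacity, and the diagnosis-to-treatment
#' delay window.
#'
#' Defaults are the fitted population values. Volume rows are the
#' location/scale of the underlying normal of `ln(diameter in cm)`, truncated
#' to `[lower, upper]` by rejection. The stage IIIA/IIIB/IV scales default to
#' 0.940/0.687/0.882: these reproduce the fitted population's stage-wise
#' median and mean diameters (5.06/8.74/9.68 and 5.63/8.54/9.26 cm) to three
#' significant figures, which the ten-fold larger printed values do not (they
#' imply ~2 cm medians for all three stages).
#'
#' @param volume Data frame with columns `stage`, `mu`, `sigma`, `lower`,
#'   `upper` (cm bounds; 5 cm cap for stage I, 13 cm elsewhere).
#' @param rho_mu,rho_sigma Growth-rate normal, per day.
#' @param alpha_mu,alpha_sigma Radiosensitivity normal, Gy^-1.
#' @param correlation Pearson correlation between the underlying alpha and
#'   rho normals, in (-1, 1).
#' @param beta_c_mu,beta_c_sigma Chemotherapy cell-kill normal, per mg/m^3.
#' @param carrying_capacity_diameter Carrying capacity, cm.
#' @param delay_min,delay_max Uniform window (days) between diagnosis and
#'   treatment start.
#' @return An object of class `population_distributions`.
#' @export
population_distributions <- function(
    volume = data.frame(
      stage = STAGES,
      mu    = c(1.72, 1.96, 1.91, 2.76, 3.86),
      sigma = c(4.70, 1.63, 0.940, 0.687, 0.882),
      lower = 0.3,
      upper = c(5, 13, 13, 13, 13)),
    rho_mu = 7.00e-5, rho_sigma = 7.23e-3,
    alpha_mu = 0.0398, alpha_sigma = 0.168,
    correlation = 0.87,
    beta_c_mu = 0.028, beta_c_sigma = 0.0007,
    carrying_capacity_diameter = 30,
    delay_min = 14, delay_max = 21) {
  stopifnot(all(c("stage", "mu", "sigma", "lower", "upper") %in%
                  names(volume)),
            all(volume$sigma > 0), all(volume$lower > 0),
            all(volume$lower < volume$upper),
            rho_sigma > 0, alpha_sigma > 0, beta_c_sigma > 0,
            correlation > -1, correlation < 1,
            carrying_capacity_diameter > 0,
            delay_min >= 0, delay_max >= delay_min)
  structure(list(volume = volume,
                 rho_mu = rho_mu, rho_sigma = rho_sigma,
                 alpha_mu = alpha_mu, alpha_sigma = alpha_sigma,
                 correlation = correlation,
                 beta_c_mu = beta_c_mu, beta_c_sigma = beta_c_sigma,
                 carrying_capacity_diameter = carrying_capacity_diameter,
                 delay_min = delay_min, delay_max = delay_max),
            class = "population_distributions")
}

#' @export
print.population_distributions <- function(x, ...) {
  cat("<population_distributions>\n")
  cat(sprintf("  rho ~ N(%.3g, %.3g)/day, alpha ~ N(%.3g, %.3g)/Gy, cor %.2f\n",
              x$rho_mu, x$rho_sigma, x$alpha_mu, x$alpha_sigma,
              x$correlation))
  cat(sprintf("  beta_c ~ N(%.3g, %.3g) per mg/m3, K = %g cm, delay %g-%g d\n",
              x$beta_c_mu, x$beta_c_sigma, x$carrying_capacity_diameter,
              x$delay_min, x$delay_max))
  print(x$volume, row.names = FALSE)
  invisible(x)
}

# Normal-scale truncation mass on the log scale.
.tln_mass <- function(mu, sigma, lower, upper) {
  pnorm((log(upper) - mu) / sigma) - pnorm((log(lower) - mu) / sigma)
}

#' Sample a truncated lognormal by rejection
#'
#' Draws `ln d ~ Normal(mu, sigma)` and accepts iff `lower <= d <= upper`.
#' Rejection (not clipping) is used so no probability mass accumulates at the
#' bounds.
#'
#' @param mu,sigma Location and scale of the underlying normal of `ln d`.
#' @param lower,upper Truncation bounds, same units as `d` (cm here).
#' @param n Number of samples.
#' @return Numeric vector of length `n`.
#' @export
sample_truncated_lognormal <- function(mu, sigma, lower, upper, n) {
  stopifnot(n >= 1, sigma > 0, lower < upper)
  mass <- .tln_mass(mu, sigma, lower, upper)
  if (mass < 1e-6)
    stop("truncation bounds carry less than 1e-6 probability mass; ",
         "rejection sampling is infeasible")
  out <- numeric(0)
  while (length(out) < n) {
    m <- ceiling((n - length(out)) / mass * 1.2) + 16
    d <- exp(rnorm(m, mu, sigma))
    out <- c(out, d[d >= lower & d <= upper])
  }
  out[seq_len(n)]
}

#' Analytic truncated-lognormal quantile
#'
#' Exact inverse CDF of the truncated lognormal, used as the independent
#' oracle for the rejection sampler.
#'
#' @inheritParams sample_truncated_lognormal
#' @param q Probability in (0, 1); vectorized.
#' @return Quantile(s) on the data scale.
#' @export
truncated_lognormal_quantile <- function(mu, sigma, lower, upper, q) {
  stopifnot(all(q > 0), all(q < 1), sigma > 0, lower < upper)
  plo <- pnorm((log(lower) - mu) / sigma)
  phi <- pnorm((log(upper) - mu) / sigma)
  if (phi - plo <= 0) stop("truncation bounds carry no probability mass")
  exp(mu + sigma * qnorm(plo + q * (phi - plo)))
}

#' Analytic truncated-lognormal mean
#'
#' Closed form: `exp(mu + sigma^2/2) * (Phi(b - sigma) - Phi(a - sigma)) /
#' (Phi(b) - Phi(a))` with `a`, `b` the standardized log bounds.
#'
#' @inheritParams sample_truncated_lognormal
#' @return The mean on the data scale.
#' @export
truncated_lognormal_mean <- function(mu, sigma, lower, upper) {
  stopifnot(sigma > 0, lower < upper)
  a <- (log(lower) - mu) / sigma
  b <- (log(upper) - mu) / sigma
  z <- pnorm(b) - pnorm(a)
  if (z <= 0) stop("truncation bounds carry no probability mass")
  exp(mu + sigma^2 / 2) * (pnorm(b - sigma) - pnorm(a - sigma)) / z
}

#' Jointly sample radiosensitivity and growth rate
#'
#' Draws `(alpha, rho)` from the bivariate normal with the population
#' marginals and the stated correlation on the underlying normals, jointly
#' rejecting any draw with `alpha <= 0` or `rho <= 0`. The faster-growing,
#' more radiosensitive corner of the distribution is therefore over-selected
#' relative to the marginal truncations, which is the biology the correlation
#' encodes.
#'
#' @param n Number of accepted pairs.
#' @param dists A [population_distributions()] object.
#' @return Data frame with columns `alpha` (Gy^-1) and `rho` (per day).
#' @export
sample_alpha_rho <- function(n, dists = population_distributions()) {
  stopifnot(n >= 1)
  r <- dists$correlation
  alpha <- rho <- numeric(0)
  while (length(alpha) < n) {
    m <- ceiling((n - length(alpha)) * 2.5) + 16
    z1 <- rnorm(m)
    z2 <- r * z1 + sqrt(1 - r^2) * rnorm(m)
    a <- dists$alpha_mu + dists$alpha_sigma * z1
    p <- dists$rho_mu + dists$rho_sigma * z2
    keep <- a > 0 & p > 0
    alpha <- c(alpha, a[keep]); rho <- c(rho, p[keep])
  }
  data.frame(alpha = alpha[seq_len(n)], rho = rho[seq_len(n)])
}

# Positive-truncated normal via rejection.
.sample_trunc_normal_pos <- function(n, mu, sigma) {
  out <- numeric(0)
  mass <- max(1 - pnorm(0, mu, sigma), 1e-3)
  while (length(out) < n) {
    x <- rnorm(ceiling((n - length(out)) / mass * 1.2) + 16, mu, sigma)
    out <- c(out, x[x > 0])
  }
  out[seq_len(n)]
}

#' Sample a virtual patient cohort
#'
#' Assembles patients: stage by multinomial over `stage_mix`, initial
#' diameter from the stage's truncated lognormal, `(alpha, rho)` from the
#' correlated joint sampler (or `rho` alone from its positive-truncated
#' marginal for untreated cohorts), `beta_c` from its positive-truncated
#' normal, and the diagnosis-to-treatment delay uniform on the delay window.
#'
#' @param dists A [population_distributions()] object.
#' @param stage_mix Named proportions over stages (subset of
#'   `I, II, IIIA, IIIB, IV`), summing to 1.
#' @param n Cohort size (0 allowed, returning an empty cohort).
#' @param alpha_sampling `"joint"` samples `(alpha, rho)` together with the
#'   positivity-truncated correlation structure; `"none"` samples `rho` from
#'   its own positive-truncated marginal and leaves `alpha` as `NA`
#'   (appropriate for untreated cohorts, where no radiosensitivity enters).
#' @param seed Optional integer seed applied before sampling.
#' @return Data frame (one row per patient) with columns `id`, `stage`,
#'   `diameter`, `rho`, `alpha`, `beta_c`, `delay`.
#' @export
sample_cohort <- function(dists, stage_mix, n,
                          alpha_sampling = c("joint", "none"),
                          seed = NULL) {
  alpha_sampling <- match.arg(alpha_sampling)
  stopifnot(inherits(dists, "population_distributions"),
            all(names(stage_mix) %in% STAGES),
            abs(sum(stage_mix) - 1) < 1e-8, n >= 0)
  if (!is.null(seed)) set.seed(seed)
  if (n == 0)
    return(data.frame(id = integer(0), stage = character(0),
                      diameter = numeric(0), rho = numeric(0),
                      alpha = numeric(0), beta_c = numeric(0),
                      delay = numeric(0)))
  stage <- sample(names(stage_mix), n, replace = TRUE, prob = stage_mix)
  diameter <- numeric(n)
  for (s in unique(stage)) {
    row <- dists$volume[dists$volume$stage == s, ]
    idx <- which(stage == s)
    diameter[idx] <- sample_truncated_lognormal(row$mu, row$sigma, row$lower,
                                                row$upper, length(idx))
  }
  if (alpha_sampling == "joint") {
    ar <- sample_alpha_rho(n, dists)
    alpha <- ar$alpha; rho <- ar$rho
  } else {
    alpha <- rep(NA_real_, n)
    rho <- .sample_trunc_normal_pos(n, dists$rho_mu, dists$rho_sigma)
  }
  beta_c <- .sample_trunc_normal_pos(n, dists$beta_c_mu, dists$beta_c_sigma)
  delay <- runif(n, dists$delay_min, dists$delay_max)
  data.frame(id = seq_len(n), stage = stage, diameter = diameter,
             rho = rho, alpha = alpha, beta_c = beta_c, delay = delay)
}

#' Partition a cohort by empirical growth-rate percentiles
#'
#' Splits at the cohort's own empirical `rho` quantiles, so the subgroups
#' partition the cohort exactly (every patient in exactly one subgroup).
#'
#' @param cohort A cohort data frame from [sample_cohort()].
#' @param breaks Probabilities in (0, 1) defining the cut points; `0.5` gives
#'   a below/above-median split, `0.75` isolates the top quartile.
#' @return Named list of cohort subsets, ordered from slowest- to
#'   fastest-growing.
#' @export
stratify_by_rho <- function(cohort, breaks = 0.5) {
  stopifnot(nrow(cohort) > 0, all(breaks > 0), all(breaks < 1))
  breaks <- sort(unique(breaks))
  cuts <- c(-Inf, quantile(cohort$rho, breaks, names = FALSE), Inf)
  grp <- cut(cohort$rho, cuts, right = FALSE, labels = FALSE)
  pct <- c(0, breaks * 100, 100)
  out <- lapply(seq_len(length(cuts) - 1), function(i)
    cohort[grp == i, , drop = FALSE])
  names(out) <- sprintf("rho_pct_%g_%g", pct[-length(pct)], pct[-1])
  out
}
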