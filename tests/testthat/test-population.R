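test_that("truncated lognormal sampler matches its analytic distribution", {
  set.seed(1)
  # degenerate scale collapses to the geometric center
  d <- sample_truncated_lognormal(log(2), 1e-8, 0.3, 13, 100)
  expect_equal(d, rep(2, 100), tolerance = 1e-6)
  # stage II parameters: empirical quantiles vs analytic inverse CDF
  d <- sample_truncated_lognormal(1.96, 1.63, 0.3, 13, 4e4)
  expect_true(all(d >= 0.3 & d <= 13))
  for (q in c(0.25, 0.5, 0.9))
    expect_equal(unname(quantile(d, q)),
                 truncated_lognormal_quantile(1.96, 1.63, 0.3, 13, q),
                 tolerance = 0.05)
  # Kolmogorov-Smirnov against the analytic truncated CDF
  cdf <- function(x) {
    a <- pnorm((log(0.3) - 1.96) / 1.63); b <- pnorm((log(13) - 1.96) / 1.63)
    (pnorm((log(x) - 1.96) / 1.63) - a) / (b - a)
  }
  expect_gt(ks.test(d, cdf)$p.value, 0.01)
  expect_error(sample_truncated_lognormal(30, 0.1, 0.3, 13, 10), "mass")
})

test_that("analytic truncated-lognormal quantile and mean are exact", {
  # symmetric-in-log window centered on mu: median = geometric mean of bounds
  expect_equal(truncated_lognormal_quantile(log(2), 0.7, 1, 4, 0.5), 2)
  # numeric-integration oracle for the mean
  mu <- 1.96; sg <- 1.63
  z <- pnorm((log(13) - mu) / sg) - pnorm((log(0.3) - mu) / sg)
  num <- integrate(function(x) x * dnorm((log(x) - mu) / sg) / (x * sg) / z,
                   0.3, 13)$value
  expect_equal(truncated_lognormal_mean(mu, sg, 0.3, 13), num,
               tolerance = 1e-6)
})

test_that("default volume rows reproduce the fitted population's stage medians", {
  # the fitted population's median/mean diameters by stage:
  # I 1.23/1.66, II 3.53/4.49, IIIA 5.06/5.63, IIIB 8.74/8.54, IV 9.68/9.26
  vol <- population_distributions()$volume
  med <- c(1.23, 3.53, 5.06, 8.74, 9.68)
  mea <- c(1.66, 4.49, 5.63, 8.54, 9.26)
  for (i in 2:5) {  # stage I is known to sit ~6% off; see the vignette
    expect_equal(truncated_lognormal_quantile(vol$mu[i], vol$sigma[i],
                                              vol$lower[i], vol$upper[i],
                                              0.5),
                 med[i], tolerance = 0.01, info = vol$stage[i])
    expect_equal(truncated_lognormal_mean(vol$mu[i], vol$sigma[i],
                                          vol$lower[i], vol$upper[i]),
                 mea[i], tolerance = 0.01, info = vol$stage[i])
  }
  expect_equal(truncated_lognormal_quantile(vol$mu[1], vol$sigma[1], 0.3, 5,
                                            0.5), 1.23, tolerance = 0.07)
})

test_that("joint alpha-rho sampler reproduces the truncated bivariate normal", {
  skip_if_not_installed("MASS")
  dists <- table_dists()
  set.seed(7)
  ar <- sample_alpha_rho(5e4, dists)
  expect_true(all(ar$alpha > 0), all(ar$rho > 0))
  # independent oracle: MASS::mvrnorm draws with the same joint rejection
  set.seed(8)
  sig <- matrix(c(dists$alpha_sigma^2,
                  dists$correlation * dists$alpha_sigma * dists$rho_sigma,
                  dists$correlation * dists$alpha_sigma * dists$rho_sigma,
                  dists$rho_sigma^2), 2)
  z <- MASS::mvrnorm(2e5, c(dists$alpha_mu, dists$rho_mu), sig)
  z <- z[z[, 1] > 0 & z[, 2] > 0, ]
  expect_equal(cor(ar$alpha, ar$rho), cor(z[, 1], z[, 2]), tolerance = 0.05)
  expect_equal(median(ar$alpha), median(z[, 1]), tolerance = 0.01)
  # zero correlation: accepted marginals decorrelate
  d0 <- population_distributions(correlation = 0)
  set.seed(9)
  ar0 <- sample_alpha_rho(5e4, d0)
  expect_lt(abs(cor(ar0$alpha, ar0$rho)), 0.02)
})

test_that("cohort assembly respects the stage mix and marginal moments", {
  dists <- table_dists()
  expect_equal(nrow(sample_cohort(dists, c(I = 1), 0)), 0)
  co <- sample_cohort(dists, c(II = 1), 5000, seed = 3)
  expect_true(all(co$stage == "II"))
  # diameter mean vs analytic truncated-lognormal mean (3 SE)
  m <- truncated_lognormal_mean(1.96, 1.63, 0.3, 13)
  se <- sd(co$diameter) / sqrt(nrow(co))
  expect_lt(abs(mean(co$diameter) - m), 3 * se)
  # delay uniform on [14, 21]
  expect_true(all(co$delay >= 14 & co$delay <= 21))
  expect_lt(abs(mean(co$delay) - 17.5), 3 * (7 / sqrt(12)) / sqrt(nrow(co)))
  # beta_c positive with the population mean (3 SE; truncation negligible)
  expect_lt(abs(mean(co$beta_c) - 0.028), 3 * 0.0007 / sqrt(nrow(co)))
  # untreated sampling leaves alpha unset and uses the rho marginal
  cu <- sample_cohort(dists, c(II = 1), 5000, alpha_sampling = "none",
                      seed = 4)
  expect_true(all(is.na(cu$alpha)))
  expect_true(all(cu$rho > 0))
  # joint truncation with positive correlation enriches fast growers
  expect_gt(median(co$rho), median(cu$rho))
})

test_that("growth-rate stratification partitions the cohort exactly", {
  co <- small_stageIII_cohort(401)
  halves <- stratify_by_rho(co, 0.5)
  expect_equal(abs(nrow(halves[[1]]) - nrow(halves[[2]])) <= 1, TRUE)
  top <- stratify_by_rho(co, 0.75)
  expect_equal(nrow(top[[2]]), ceiling(401 / 4))
  ids <- sort(unname(unlist(lapply(halves, `[[`, "id"))))
  expect_equal(ids, sort(co$id))          # exact partition
  three <- stratify_by_rho(co, c(0.5, 0.75))
  expect_equal(sum(vapply(three, nrow, 0L)), nrow(co))
  expect_true(max(three[[1]]$rho) <= min(three[[3]]$rho))
})
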