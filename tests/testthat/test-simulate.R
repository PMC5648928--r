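test_that("Poisson control draw has the right acceptance probability", {
  expect_true(all(tumor_control_draw(rep(0, 50))))
  expect_true(tumor_control_draw(log(2), u = 0.49))
  expect_false(tumor_control_draw(log(2), u = 0.51))
  set.seed(2)
  expect_equal(mean(tumor_control_draw(rep(log(2), 2e4))), 0.5,
               tolerance = 3 * 0.5 / sqrt(2e4))
  expect_false(tumor_control_draw(23, u = 1e-9))  # e^-23 ~ 1e-10
})

test_that("natural death reproduces the annual life-table reduction", {
  expect_equal(natural_death_time(5, sim_config(natural_death_annual = 0)),
               rep(Inf, 5))
  set.seed(3)
  t <- natural_death_time(2e5, sim_config())
  s1 <- mean(t > 12)
  s5 <- mean(t > 60)
  expect_equal(s1, 1 - 0.0148, tolerance = 3 * sqrt(0.0148 / 2e5))
  expect_equal(s5, (1 - 0.0148)^5, tolerance = 3 * sqrt(0.07 / 2e5))
})

test_that("death-diameter crossing time matches root finding", {
  cfg <- sim_config()
  p <- growth_parameters(rho = 5e-3, carrying_capacity_diameter = 30)
  nd <- diameter_to_cell_number(13)
  expect_lt(time_to_death_diameter(nd * (1 - 1e-9), p, cfg), 1e-3)
  n0 <- diameter_to_cell_number(4)
  t_cf <- time_to_death_diameter(n0, p, cfg)
  t_root <- uniroot(function(t) gompertz_solve(n0, p, t) - nd,
                    c(0, 1e5), tol = 1e-8)$root
  expect_equal(t_cf, t_root, tolerance = 1e-4)
  pe <- growth_parameters(1, model_kind = "exponential", exp_rate = 8.7e-3)
  expect_equal(time_to_death_diameter(n0, pe, cfg), log(nd / n0) / 8.7e-3)
  pl <- growth_parameters(rho = 5e-3, carrying_capacity_diameter = 12)
  expect_error(time_to_death_diameter(n0, pl, cfg), "never")
})

test_that("untreated simulation reduces to growth plus the natural-death race", {
  co <- small_stageIII_cohort(300)
  cfg <- sim_config()
  out <- simulate_cohort(co, NULL, growth_model(), cfg, seed = 5)
  nd <- diameter_to_cell_number(13)
  kc <- diameter_to_cell_number(30)
  t_gr <- vapply(seq_len(nrow(co)), function(i)
    time_to_death_diameter(diameter_to_cell_number(co$diameter[i]),
                           growth_parameters(co$rho[i]), cfg), 0) / (365 / 12)
  tum <- out$event == "death_tumor"
  expect_equal(out$survival_months[tum], t_gr[tum])
  expect_true(all(out$survival_months[!tum] <= t_gr[!tum]))
  expect_true(all(out$survival_months > 0 & out$survival_months <= 60))
  expect_true(all(out$survival_months[out$event == "censored"] == 60))
  expect_false(any(out$controlled))
})

test_that("treated burden stays positive and survival times step-converge", {
  co <- small_stageIII_cohort(150)
  s <- build_rtog9410_sequential()
  out1 <- simulate_cohort(co, s, growth_model(), sim_config(step_days = 1),
                          seed = 6)
  out2 <- simulate_cohort(co, s, growth_model(), sim_config(step_days = 0.1),
                          seed = 6)
  expect_true(all(out2$nadir_cells > 0))
  expect_true(all(out2$end_of_treatment_cells > 0, na.rm = TRUE))
  # shrinking the step from 1.0 to 0.1 day moves no survival time by > 1 day
  expect_lt(max(abs(out1$survival_months - out2$survival_months)),
            1 / (365 / 12) + 1e-9)
  expect_equal(out1$event, out2$event)
})

test_that("concurrent delivery reaches a nadir no higher than sequential", {
  co <- small_stageIII_cohort(300)
  for (kind in c("gompertz", "gompertz_with_kickoff")) {
    g <- growth_model(kind)
    nc <- simulate_cohort(co, build_rtog9410_concurrent(), g, seed = 7)
    ns <- simulate_cohort(co, build_rtog9410_sequential(), g, seed = 7)
    expect_true(all(nc$nadir_cells <= ns$nadir_cells * (1 + 1e-9)))
  }
})

test_that("the example patient is salvaged by concurrent but not sequential CRT", {
  co <- fig8_cohort()
  out_c <- simulate_cohort(co, build_rtog9410_concurrent(), growth_model(),
                           seed = 1)
  out_s <- simulate_cohort(co, build_rtog9410_sequential(), growth_model(),
                           seed = 1)
  # concurrent drives the burden below one cell: control is the likely draw
  expect_lt(out_c$nadir_cells, 1)
  expect_gt(exp(-out_c$nadir_cells), 0.5)
  # sequential leaves a macroscopic burden that regrows to the death diameter
  expect_gt(out_s$nadir_cells, 1)
  expect_equal(out_s$event, "death_tumor")
  expect_false(out_s$controlled)
  # with the favorable control draw the concurrent patient is controlled
  expect_true(tumor_control_draw(out_c$nadir_cells, u = 0.4))
})

test_that("extreme radiosensitivity sterilizes the tumor", {
  co <- fig8_cohort()
  co$alpha <- 50
  out <- simulate_cohort(co, build_rt_only_60gy(0), growth_model(), seed = 2)
  expect_lt(out$nadir_cells, 1e-12)
  expect_true(out$controlled)
  expect_true(out$event %in% c("censored", "death_natural"))
})

test_that("patients near the death boundary die untreated within months", {
  co <- data.frame(id = 1, stage = "IV", diameter = 12.9, rho = 5e-3,
                   alpha = 0.2, beta_c = 0.028, delay = 14)
  out <- simulate_cohort(co, NULL, growth_model(), seed = 3)
  expect_equal(out$event, "death_tumor")
  expect_lt(out$survival_months, 6)
})

test_that("single-patient wrapper and outcome CSV round trip", {
  pat <- virtual_patient("IIIA", 5, growth_parameters(0.008),
                         radiation_parameters(0.3), beta_c = 0.03,
                         delay = 14)
  out <- simulate_patient(pat, build_rtog9410_sequential(), seed = 4)
  expect_equal(nrow(out), 1)
  path <- withr::local_tempfile(fileext = ".csv")
  write_outcomes_csv(out, path)
  back <- read_outcomes_csv(path)
  expect_equal(back$survival_months, out$survival_months)
  expect_equal(back$event, out$event)
  expect_equal(back$nadir_cells, out$nadir_cells)
  expect_error(virtual_patient("I", 6, growth_parameters(0.008),
                               radiation_parameters(0.3), 0.03))
})

test_that("schedules extending past the follow-up horizon are rejected", {
  co <- small_stageIII_cohort(5)
  late <- treatment_schedule(data.frame(time = 1900, dose = 2))
  expect_error(simulate_cohort(co, late, growth_model(), seed = 1),
               "horizon")
})
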