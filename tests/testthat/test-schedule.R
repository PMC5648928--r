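test_that("linear-quadratic kill follows alpha d + beta d^2", {
  rad <- radiation_parameters(alpha = 0.3, alpha_beta_ratio = 10)
  expect_equal(lq_ln_kill(rad, 0), 0)
  expect_equal(lq_ln_kill(rad, 2), 0.72)
  expect_equal(exp(-lq_ln_kill(rad, 2)), 0.4868, tolerance = 1e-4)
  # with ratio 10, each 2 Gy fraction kills exactly 2.4 * alpha
  for (a in c(0.05, 0.16, 0.4))
    expect_equal(lq_ln_kill(radiation_parameters(a), 2), 2.4 * a)
  # fractions multiply: order invariance of the total course survival
  doses <- rep(2, 30)
  expect_equal(exp(-sum(lq_ln_kill(rad, doses))),
               prod(exp(-lq_ln_kill(rad, sample(doses)))))
  expect_error(lq_ln_kill(rad, -1))
})

test_that("schedule construction validates and sorts events", {
  expect_error(treatment_schedule(data.frame(time = 0, dose = 12)),
               "10 Gy")
  expect_error(treatment_schedule(data.frame(time = -1, dose = 2)))
  s <- treatment_schedule(data.frame(time = c(5, 1), dose = 2))
  expect_equal(s$fractions$time, c(1, 5))
})

test_that("drug concentration decays, superposes, and is right-continuous", {
  adm <- data.frame(drug = "cisplatin", time = 2, cmax = 100,
                    half_life_hours = 24)
  s <- treatment_schedule(administrations = adm)
  expect_equal(concentration_at(s, c(0, 1.99)), c(0, 0))
  expect_equal(concentration_at(s, 2), 100)     # right-continuous at dosing
  expect_equal(concentration_at(s, 3), 50)      # one 24 h half-life
  two <- treatment_schedule(administrations = rbind(adm, adm))
  expect_equal(concentration_at(two, 3), 100)   # linear superposition
  expect_true(all(concentration_at(two, seq(0, 30, by = 0.25)) >= 0))
})

test_that("analytic chemo exposure integral matches quadrature", {
  s <- build_rtog9410_sequential()
  expect_equal(chemo_ln_kill_integral(s, 0, 0, 100), 0)
  # single dose integrated to infinity: beta_c * cmax / lambda
  one <- treatment_schedule(administrations = data.frame(
    drug = "cisplatin", time = 0, cmax = 100, half_life_hours = 24))
  expect_equal(chemo_ln_kill_integral(one, 0.028, 0, Inf),
               0.028 * 100 / log(2), tolerance = 1e-12)
  # interval additivity
  expect_equal(chemo_ln_kill_integral(s, 0.03, 0, 90),
               chemo_ln_kill_integral(s, 0.03, 0, 45) +
                 chemo_ln_kill_integral(s, 0.03, 45, 90),
               tolerance = 1e-10)
  # trapezoid oracle at 0.001-day resolution, segmented at the dosing
  # discontinuities
  brk <- sort(unique(c(0, s$administrations$time, 60)))
  trap <- 0
  for (i in seq_len(length(brk) - 1)) {
    tt <- seq(brk[i], brk[i + 1], by = 0.001)
    # left limit at the segment end: the next dose belongs to the next segment
    cc <- concentration_at(s, c(tt[-length(tt)], tt[length(tt)] - 1e-9))
    trap <- trap + sum((cc[-1] + cc[-length(cc)]) / 2 * diff(tt))
  }
  expect_equal(chemo_ln_kill_integral(s, 1, 0, 60) / trap, 1,
               tolerance = 1e-6)
  expect_error(chemo_ln_kill_integral(s, 0.03, 10, 5))
})

test_that("radiation-only course delivers 60 Gy over six weekday weeks", {
  s <- build_rt_only_60gy(0)
  expect_equal(nrow(s$fractions), 30)
  expect_equal(sum(s$fractions$dose), 60)
  expect_equal(max(s$fractions$time), 39)
  s7 <- build_rt_only_60gy(7)
  expect_equal(range(s7$fractions$time), c(7, 46))
  # consecutive-day switch
  expect_equal(max(build_rt_only_60gy(0, weekday_spacing = FALSE)$fractions$time),
               29)
})

test_that("trial-arm presets share drugs and differ only in RT start", {
  sq <- build_rtog9410_sequential()
  cc <- build_rtog9410_concurrent()
  for (s in list(sq, cc)) {
    expect_equal(sum(s$administrations$drug == "cisplatin"), 2)
    expect_equal(sum(s$administrations$drug == "vinblastine"), 5)
    expect_equal(nrow(s$fractions), 30)
  }
  expect_equal(sq$administrations, cc$administrations)
  expect_equal(min(sq$fractions$time), 49)  # protocol day 50
  expect_equal(min(cc$fractions$time), 0)   # protocol day 1
  # cisplatin on protocol days 1 and 29, vinblastine weekly for 5 weeks
  expect_equal(sq$administrations$time[sq$administrations$drug == "cisplatin"],
               c(0, 28))
})

test_that("chemo-only doublet builds the requested cycles", {
  s <- build_chemo_only(4, 28)
  expect_equal(sum(s$administrations$drug == "cisplatin"), 4)
  expect_equal(nrow(s$fractions), 0)
  expect_equal(s$administrations$time[s$administrations$drug == "cisplatin"],
               c(0, 28, 56, 84))
  expect_equal(nrow(build_chemo_only(1)$administrations), 3)
})

test_that("schedules round-trip through the text serialization", {
  for (s in list(build_rtog9410_sequential(), build_chemo_only(2),
                 build_rt_only_60gy(5))) {
    path <- withr::local_tempfile(fileext = ".yaml")
    write_schedule_yaml(s, path)
    s2 <- read_schedule_yaml(path)
    expect_equal(s2$fractions, s$fractions)
    expect_equal(s2$administrations, s$administrations)
    expect_equal(s2$label, s$label)
  }
})
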