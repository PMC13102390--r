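m <- excavation_model()

test_that("target area follows the fitted line and clamps at zero", {
  expect_equal(target_area(0, target_line()), 11.22)
  expect_equal(target_area(40, target_line()), 11.22 - 0.032 * 40)  # 9.94
  expect_equal(target_area(400, target_line()), 0)
  expect_equal(target_area(c(0, 500), constant_target(11.6)), c(11.6, 11.6))
})

test_that("per-ant rate is basal at empty nest, zero at/after the target", {
  expect_equal(per_ant_rate(0, 40, m), 2.2)
  a40 <- target_area(40, m$target)
  expect_equal(per_ant_rate(a40, 40, m), 0)
  expect_equal(per_ant_rate(2 * a40, 40, m), 0)      # rectified
  expect_equal(per_ant_rate(0, 3, m), 0)             # immature
  expect_equal(per_ant_rate(0, 400, m), 0)           # zero target
  norect <- excavation_model(rectify = FALSE)
  expect_lt(per_ant_rate(2 * a40, 40, norect), 0)
})

test_that("per-ant rate never exceeds the basal constant", {
  set.seed(1)
  a <- runif(500, 0, 30)
  age <- runif(500, 0, 400)
  expect_true(all(per_ant_rate(a, age, m) <= m$r + 1e-12))
  expect_true(all(per_ant_rate(a, age, m) >= 0))
})

test_that("colony rate sums per-ant terms at the shared density", {
  expect_equal(colony_rate(0, rep(40, 10), m), 22)
  # area per ant above every target: nobody digs
  expect_equal(colony_rate(10 * 12, rep(40, 10), m), 0)
  # mixed ages: only ants whose target exceeds A/N contribute
  ages <- c(20, 100, 300)          # targets 10.58, 8.02, 1.62
  A <- 3 * 9                        # a = 9
  expected <- sum(per_ant_rate(9, ages, m))
  expect_equal(colony_rate(A, ages, m), expected)
  expect_equal(expected, 2.2 * (1 - 9 / 10.58), tolerance = 1e-12)
  expect_error(colony_rate(5, numeric(0), m), "at least one ant")
})

test_that("closed form has the right endpoints and half-life", {
  expect_equal(closed_form_single_cohort(0, 10, 40, a0 = 2, model = m), 20)
  expect_equal(closed_form_single_cohort(1e6, 10, 40, model = m),
               10 * target_area(40, m$target))
  a40 <- target_area(40, m$target)
  t_half <- a40 / m$r * log(2)
  expect_equal(closed_form_single_cohort(t_half, 10, 40, model = m),
               10 * a40 / 2)
  # zero target: constant at N * a0
  expect_equal(closed_form_single_cohort(c(0, 5), 4, 400, a0 = 1, model = m),
               c(4, 4))
})

test_that("simulation matches the closed-form oracle for uniform cohorts", {
  tl <- uniform_cohort(16, 40)
  sim <- simulate_excavation(tl, m)
  oracle <- closed_form_single_cohort(sim$grid_days, 16, 40, model = m)
  expect_lt(max(abs(sim$grid_area[-1] - oracle[-1]) / oracle[-1]), 1e-3)
})

test_that("Euler integration converges to the oracle as dt shrinks", {
  tl <- uniform_cohort(16, 40)
  errs <- vapply(c(0.2, 0.1, 0.05), function(dt) {
    sim <- simulate_excavation(tl, m, dt = dt, method = "euler")
    oracle <- closed_form_single_cohort(sim$grid_days, 16, 40, model = m)
    max(abs(sim$grid_area - oracle)) / max(oracle)
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[2], 1e-2)
})

test_that("area is non-decreasing between events and fixed points hold", {
  tl <- synth_maturation_colony(generator_config(seed = 5))
  sim <- simulate_excavation(tl, m, queen_area = 23.8)
  expect_true(all(diff(sim$grid_area) >= -1e-9))
  # digging has ceased only once A/N matches the oldest *young* target
  sim2 <- simulate_excavation(uniform_cohort(12, 60, duration = 60), m)
  expect_equal(tail(sim2$area, 1) / 12, target_area(60, m$target),
               tolerance = 1e-4)
})

test_that("queen-alone maturation colony keeps only the founding area", {
  ants <- data.frame(ant_id = "q", caste = "queen",
                     eclosion_day = -365, death_day = NA_real_)
  tl <- colony_timeline(ants, 100, "maturation")
  sim <- simulate_excavation(tl, m)
  expect_equal(tail(sim$area, 1), 23.8)
  expect_equal(max(abs(diff(sim$area[40:100]))), 0)  # flat after founding
})

test_that("collapse removes the stated fraction and the ledger balances", {
  expect_equal(induce_collapse(100, 0.30), 70)
  expect_equal(induce_collapse(100, 0.25), 75)
  expect_equal(induce_collapse(0, 0.28), 0)
  expect_error(collapse_event(10, 0.5), "protocol band")
  ev <- collapse_event(20, 0.28)
  sim <- simulate_excavation(uniform_cohort(11, 40, duration = 50), m,
                             events = ev)
  # ledger total equals final area plus realised collapse loss
  expect_equal(sum(sim$ledger), tail(sim$area, 1) + sim$events$loss,
               tolerance = 1e-8)
  # area drops by the fraction at the event day
  i <- match(20, sim$days)
  expect_equal(sim$area[i] / sim$area[i - 1], 0.72, tolerance = 0.03)
  expect_error(simulate_excavation(uniform_cohort(5, 40), m,
                                   events = collapse_event(99, 0.28)),
               "duration")
})

test_that("saturation area detects plateaus and their levels", {
  sim <- simulate_excavation(uniform_cohort(15, 40, duration = 40), m)
  expect_equal(as.numeric(saturation_area(sim)),
               15 * target_area(40, m$target), tolerance = 0.01)
  # constant series is its own plateau
  const <- data.frame(day = 0:20, area_cm2 = 7)
  expect_equal(as.numeric(saturation_area(const)), 7)
  # age-independent null model: N * a_star
  null <- excavation_model(target = constant_target(11.6))
  simn <- simulate_excavation(uniform_cohort(10, 40, duration = 40), null)
  expect_equal(as.numeric(saturation_area(simn)), 116, tolerance = 0.01)
  rising <- data.frame(day = 0:20, area_cm2 = (0:20) * 5)
  expect_error(saturation_area(rising), "no plateau")
})

test_that("null model and line model coincide when the line is flat", {
  flat <- excavation_model(target = target_line(slope = 0, intercept = 11.6))
  null <- excavation_model(target = constant_target(11.6))
  tl <- uniform_cohort(8, 120, duration = 40)
  s1 <- simulate_excavation(tl, flat)
  s2 <- simulate_excavation(tl, null)
  expect_equal(s1$area, s2$area)
})

test_that("excavated area is attributed to queen, young and old correctly", {
  # single young cohort: no old-age digging
  sim <- simulate_excavation(uniform_cohort(10, 40), m)
  ab <- attribute_by_group(sim, 56)
  expect_equal(unname(ab["old"]), 0)
  # fixed colony: no founding credit, the queen's share is what she dug
  expect_equal(unname(ab["queen"]), unname(sim$ledger["queen"]))
  expect_equal(sum(ab), sum(sim$ledger), tolerance = 1e-9)

  # maturation colony: queen share is exactly the founding area
  tl <- synth_maturation_colony(generator_config(seed = 3))
  simm <- simulate_excavation(tl, m, queen_area = 23.8)
  abm <- attribute_by_group(simm, 56)
  expect_equal(unname(abm["queen"]), 23.8, tolerance = 1e-9)
  expect_equal(sum(abm), tail(simm$area, 1), tolerance = 1e-6)

  # ants digging past the threshold land in the old bucket
  simo <- simulate_excavation(uniform_cohort(10, 100), m)
  abo <- attribute_by_group(simo, 56)
  expect_equal(unname(abo["young"]), 0)
  expect_gt(unname(abo["old"]), 0)
})

test_that("old ants dig a negligible share during normal colony growth", {
  set.seed(10)
  shares <- vapply(1:12, function(i) {
    tl <- synth_maturation_colony(generator_config())
    sim <- simulate_excavation(tl, m, queen_area = 23.8)
    ab <- attribute_by_group(sim, 56)
    unname(ab["old"] / (ab["young"] + ab["old"]))
  }, numeric(1))
  expect_lt(mean(shares), 0.10)
})

test_that("per-ant statistics compute area-weighted band fractions", {
  s <- fake_sim_with_ledger(c(2, 8, 10))
  st <- per_ant_stats(s, band = c(5, 13))
  expect_equal(st$band_area_fraction, 18 / 20)
  expect_equal(st$mean, mean(c(2, 8, 10)))
  s8 <- fake_sim_with_ledger(rep(8, 6))
  st8 <- per_ant_stats(s8)
  expect_equal(st8$band_area_fraction, 1)
  expect_equal(st8$sd, 0)
  expect_error(per_ant_stats(fake_sim_with_ledger(numeric(0))), "no workers")
  expect_error(per_ant_stats(fake_sim_with_ledger(c(0, 0))), "zero")
})

test_that("observation adds multiplicative noise only at sampling days", {
  sim <- simulate_excavation(uniform_cohort(10, 40), m)
  ob0 <- observe_trajectory(sim, sampling_days = c(0, 10, 20, 30),
                            noise_sd_frac = 0, seed = 1)
  expect_equal(ob0$area_cm2, approx(sim$grid_days, sim$grid_area,
                                    xout = c(0, 10, 20, 30))$y)
  ob1 <- observe_trajectory(sim, noise_sd_frac = 0.05, seed = 1)
  ob2 <- observe_trajectory(sim, noise_sd_frac = 0.05, seed = 1)
  expect_identical(ob1, ob2)
  expect_true(all(ob1$area_cm2 >= 0))
})

test_that("model predictions expose targets and rates per age", {
  pr <- predict(m, age = c(0, 40), area_per_ant = 0)
  expect_equal(pr$target_cm2, c(11.22, 9.94))
  expect_equal(pr$rate_cm2_per_day[2], 2.2)  # age 40 at empty nest
  expect_equal(pr$rate_cm2_per_day[1], 0)    # age 0 is immature
})
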