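test_that("growth simulation is byte-identical under a repeated seed", {
  cfg <- growth_sim_config(n_per_cohort = 25L, n_eval_per_cohort = 5L,
                           seed = 123)
  s1 <- simulate_growth_cohorts(cfg)
  s2 <- simulate_growth_cohorts(cfg)
  expect_identical(s1$training, s2$training)
  expect_identical(s1$evaluation, s2$evaluation)
  s3 <- simulate_growth_cohorts(growth_sim_config(n_per_cohort = 25L,
                                                  n_eval_per_cohort = 5L,
                                                  seed = 124))
  expect_false(identical(s1$training$length, s3$training$length))
})

test_that("a noiseless config lies exactly on the mean curve with exact stages", {
  cfg <- growth_sim_config(cohort_ages = c(12, 30, 60, 95),
                           n_per_cohort = 3L, individual_sd = 0,
                           measurement_sd = 0, boundary_jitter_sd = 0,
                           seed = 7)
  td <- simulate_growth_cohorts(cfg)$training
  expect_equal(td$length, mean_growth_curve(cfg, td$condition),
               tolerance = 1e-12)
  expect_equal(td$width, 0.22 * mean_growth_curve(cfg, td$condition),
               tolerance = 1e-12)
  # boundaries at 18, 36, 90: 12 -> first stage, 30 -> second, 60 -> third,
  # 95 -> fourth
  expect_identical(unique(td$stage[td$condition == 12]), "instar1")
  expect_identical(unique(td$stage[td$condition == 30]), "instar2")
  expect_identical(unique(td$stage[td$condition == 60]), "instar3")
  expect_identical(unique(td$stage[td$condition == 95]), "pupa")
})

test_that("large cohorts match the mean curve at the inflection point", {
  # at the logistic inflection the curve is locally odd, so the rate
  # multiplier adds no first- or second-order bias to the cohort mean
  cfg <- growth_sim_config(cohort_ages = 36, n_per_cohort = 5000L, seed = 99)
  td <- simulate_growth_cohorts(cfg)$training
  se <- sd(td$length) / sqrt(5000)
  expect_lt(abs(mean(td$length) - mean_growth_curve(cfg, 36)), 3 * se)
})

test_that("the quadratic-spline family peaks where told and floors at zero", {
  cfg <- growth_sim_config(mean_curve = list(family = "rise_then_fall",
                                             asymptote = 10, rate = 0.01,
                                             decline_onset = 50,
                                             decline_rate = 0.004),
                           seed = 1)
  ages <- seq(0, 120, by = 1)
  y <- mean_growth_curve(cfg, ages)
  expect_equal(max(y), 10)
  expect_identical(ages[which.max(y)], 50)
  expect_identical(y[1], 0)  # floored rise far from the peak
  expect_true(all(diff(y[ages <= 50]) >= 0) && all(diff(y[ages >= 50]) <= 0))
})

test_that("succession simulation is reproducible and respects windows", {
  spp <- list(early = list(onset_mean = 1, onset_sd = 0,
                           departure_mean = 20, departure_sd = 0))
  cfg <- succession_sim_config(spp, n_carcasses = 6L,
                               observation_times = c(2, 5, 9), seed = 5)
  sim <- simulate_succession(cfg)
  expect_true(all(sim$observations$early == 1L))
  expect_identical(unique(sim$observations$category), "1")
  expect_identical(sim$scheme$c, 2L)
  expect_identical(simulate_succession(cfg)$observations, sim$observations)
})

test_that("empirical presence probability matches the truncated-normal closed form", {
  sp <- list(onset_mean = 3, onset_sd = 1, departure_mean = 9,
             departure_sd = 2)
  cfg <- succession_sim_config(list(sp1 = sp), n_carcasses = 10000L,
                               observation_times = c(2, 4, 7, 10), seed = 17)
  sim <- simulate_succession(cfg)
  # P(onset <= t <= departure | departure >= onset); the event already
  # implies departure >= onset, so only the denominator needs the condition
  denom <- pnorm((sp$departure_mean - sp$onset_mean) /
                   sqrt(sp$onset_sd^2 + sp$departure_sd^2))
  for (t in cfg$observation_times) {
    p_true <- pnorm(t, sp$onset_mean, sp$onset_sd) *
      (1 - pnorm(t, sp$departure_mean, sp$departure_sd)) / denom
    p_hat <- mean(sim$observations$sp1[sim$observations$time == t])
    expect_lt(abs(p_hat - p_true), 3 * sqrt(p_true * (1 - p_true) / 10000),
              label = sprintf("t = %g", t))
  }
})

test_that("two species give the full four-category presence scheme", {
  spp <- list(a = list(onset_mean = 2, onset_sd = 1, departure_mean = 8,
                       departure_sd = 2),
              b = list(onset_mean = 6, onset_sd = 1, departure_mean = 14,
                       departure_sd = 2))
  sim <- simulate_succession(succession_sim_config(spp, n_carcasses = 50L,
                                                   observation_times = 1:14,
                                                   seed = 3))
  expect_identical(sim$scheme$c, 4L)
  expect_setequal(sim$scheme$labels, c("00", "01", "10", "11"))
  expect_true(all(sim$observations$category %in% sim$scheme$labels))
})

test_that("under-replicated succession data can never reject any interval", {
  spp <- list(sp = list(onset_mean = 3, onset_sd = 1.5, departure_mean = 10,
                        departure_sd = 2))
  sim <- simulate_succession(succession_sim_config(spp, n_carcasses = 5L,
                                                   observation_times = 1:10,
                                                   seed = 21))
  dat <- data.frame(specimen_id = sim$observations$carcass_id,
                    condition = sim$observations$time,
                    category = sim$observations$category)
  tab <- pivot_categorical(dat, sim$scheme)
  for (lbl in sim$scheme$labels) {
    cs <- categorical_confidence_set(tab, lbl)
    expect_identical(cs$members, tab$conditions)
  }
})

test_that("configs refuse degenerate inputs", {
  expect_error(growth_sim_config(seed = NULL), "mandatory")
  expect_error(growth_sim_config(), "mandatory")
  expect_error(growth_sim_config(cohort_ages = c(5, 5), seed = 1))
  expect_error(succession_sim_config(
    list(x = list(onset_mean = 5, onset_sd = 1, departure_mean = 4,
                  departure_sd = 1)), seed = 1), "degenerate")
})
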