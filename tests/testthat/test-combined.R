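six_stage_table <- function(n_per_age, ages = seq(12, 72, by = 12)) {
  sch <- category_scheme(c("egg", "instar1", "instar2", "instar3",
                           "pupa", "adult"))
  # put all specimens in a stage that advances with age
  counts <- t(vapply(seq_along(ages), function(i) {
    v <- integer(6); v[min(i, 6)] <- as.integer(n_per_age); v
  }, integer(6)))
  categorical_training_table(ages, counts, sch)
}

test_that("model combos validate their components and split", {
  expect_error(model_combo(character(), use_stage = FALSE), "at least one")
  expect_error(model_combo("width", FALSE, alpha_split = c(0.02, 0.03)),
               "alpha_cat must be 0")
  cmb <- model_combo("width", TRUE)
  expect_identical(pmical:::resolve_split(cmb, 0.05), c(0.025, 0.025))
  expect_identical(pmical:::resolve_split(model_combo("width", FALSE), 0.05),
                   c(0, 0.05))
})

test_that("stage alone below the six-category minimum never rejects", {
  tab <- six_stage_table(36)   # 36 < 37, the six-stage minimum
  cs <- combined_confidence_set(cat_table = tab, ms = list(stage = "instar2"),
                                combo = model_combo(character(), TRUE))
  expect_identical(cs$members, tab$conditions)
  # at 37 the zero-match ages drop at full alpha
  cs37 <- combined_confidence_set(cat_table = six_stage_table(37),
                                  ms = list(stage = "instar2"),
                                  combo = model_combo(character(), TRUE))
  expect_lt(length(cs37$members), 6L)
})

test_that("a continuous-only combo degenerates to the continuous set", {
  set.seed(31)
  t <- rep(seq(12, 96, by = 12), each = 5)
  w <- 0.4 + 0.03 * t + rnorm(length(t), 0, 0.12)
  m <- fit_growth_model(t, cbind(width = w), degree = 1)
  grid <- condition_grid(m, n = 101)
  ms <- list(y_star = c(width = 1.6))
  combined <- combined_confidence_set(growth_model = m, ms = ms,
                                      combo = model_combo("width", FALSE),
                                      grid = grid)
  direct <- continuous_confidence_set(m, 1.6, grid)
  expect_identical(combined$members, direct$members)
})

test_that("the Bonferroni union matches running the components separately", {
  set.seed(77)
  ages <- seq(12, 96, by = 12)
  t <- rep(ages, each = 40)
  w <- 0.4 + 0.03 * t + rnorm(length(t), 0, 0.15)
  m <- fit_growth_model(t, cbind(width = w), degree = 1)
  sch <- category_scheme(c("instar1", "instar2", "instar3"))
  counts <- t(vapply(seq_along(ages), function(i) {
    v <- integer(3); v[findInterval(ages[i], c(0, 40, 70))] <- 40L; v
  }, integer(3)))
  tab <- categorical_training_table(ages, counts, sch)
  ms <- list(y_star = c(width = 1.1), stage = "instar2")
  combo <- model_combo("width", TRUE)
  cs <- combined_confidence_set(tab, m, ms, combo, grid = ages, alpha = 0.05)
  # oracle: run each component at its split level and intersect the members
  mem_cat <- categorical_confidence_set(tab, "instar2", 0.025)$members
  mem_cont <- continuous_confidence_set(m, 1.1, ages, 0.025)$members
  expect_identical(cs$members, intersect(mem_cat, mem_cont))
  # combined set is a subset of each component's set
  expect_true(all(cs$members %in% mem_cat))
  expect_true(all(cs$members %in% mem_cont))
})

test_that("combined inference keeps the nominal level under joint simulation", {
  reps <- 800
  true_age <- 60
  rejected <- logical(reps)
  for (r in seq_len(reps)) {
    sim <- simulate_growth_cohorts(growth_sim_config(
      n_per_cohort = 30L, n_eval_per_cohort = 1L, seed = 10000 + r))
    td <- sim$training
    m <- fit_growth_model(td$condition, cbind(length = td$length), degree = 2)
    tab <- pivot_categorical(
      data.frame(specimen_id = td$specimen_id, condition = td$condition,
                 category = td$stage),
      category_scheme(sim$config$stage_labels))
    ms_row <- sim$evaluation[sim$evaluation$condition == true_age, ][1, ]
    cs <- combined_confidence_set(tab, m,
                                  list(y_star = c(length = ms_row$length),
                                       stage = ms_row$stage),
                                  model_combo("length", TRUE),
                                  grid = sim$config$cohort_ages)
    rejected[r] <- !true_age %in% cs$members
  }
  mc_err <- sqrt(0.05 * 0.95 / reps)
  expect_lte(mean(rejected), 0.05 + 3 * mc_err)
})

test_that("set-width summaries report hulls and order by width", {
  grid <- seq(10, 100, by = 5)
  fake_set <- function(members) {
    per <- data.frame(condition = grid, rejected = !grid %in% members)
    pmical:::new_confidence_set(0.05, members, per, "categorical")
  }
  s <- set_width_summary(list(wide = fake_set(seq(30, 70, 5)),
                              narrow = fake_set(c(50, 55)),
                              empty = fake_set(numeric())))
  expect_identical(s$model, c("empty", "narrow", "wide"))
  expect_identical(s$hull_width[s$model == "narrow"], 5)
  expect_identical(s$n_members[s$model == "narrow"], 2L)
  expect_true(s$empty[s$model == "empty"])
  lines <- render_asterisk_rows(list(narrow = fake_set(c(50, 55))))
  expect_length(lines, 2L)
  expect_match(lines[2], "\\*")
})
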