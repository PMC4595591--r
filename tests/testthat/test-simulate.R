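test_that("simulated behaviour is reproducible and respects the error rate", {
  set.seed(10)
  ex <- make_experiment(order = default_run_order())
  set.seed(42)
  a <- simulate_subject(ex, grid = small_grid())
  set.seed(42)
  b <- simulate_subject(ex, grid = small_grid())
  expect_identical(a, b)

  # accuracy within the binomial 95% interval around 94.2%
  acc <- mean(a$correct)
  half <- 1.96 * sqrt(0.942 * 0.058 / 768)
  expect_true(abs(acc - 0.942) < half + 1e-12)
  expect_true(all(is.na(a$rt[!a$correct])))
  expect_true(all(a$rs[a$correct] >= 0.1))
  expect_equal(a$rs[a$correct], 1 / a$rt[a$correct])
})

test_that("a noise-free flat emission produces constant RS per congruency", {
  ex <- make_experiment(seed = 3)
  hyper <- hyperparameters(b_con = 0, b_inc = 0,
                           sigma_con = 1e-12, sigma_inc = 1e-12)
  set.seed(4)
  tab <- simulate_subject(ex, generator_params(hyper = hyper, error_rate = 0,
                                               outlier_rate = 0),
                          grid = small_grid())
  expect_equal(as.numeric(tapply(tab$rs, tab$congruency, sd)), c(0, 0),
               tolerance = 1e-9)
  expect_lt(max(abs(tab$rs[tab$congruency == 0] - hyper$a_con)), 1e-6)
  expect_lt(max(abs(tab$rs[tab$congruency == 1] - hyper$a_inc)), 1e-6)
})

test_that("cohorts carry per-subject designs, parameters and traces", {
  coh <- simulate_cohort(3, seed = 5, grid = small_grid())
  expect_length(coh, 3)
  ids <- vapply(coh, `[[`, "", "subject_id")
  expect_equal(ids, c("s01", "s02", "s03"))
  tab <- cohort_trials(coh)
  expect_equal(nrow(tab), 3 * 768)
  # jittered emission parameters differ across subjects
  a_con <- vapply(coh, function(s) s$hyper$a_con, numeric(1))
  expect_gt(max(a_con) - min(a_con), 0)
  # same seed, same cohort
  coh2 <- simulate_cohort(3, seed = 5, grid = small_grid())
  expect_identical(cohort_trials(coh2), tab)
})

test_that("trial tables round-trip through CSV with RT in milliseconds", {
  coh <- simulate_cohort(1, seed = 6, grid = small_grid())
  tab <- apply_exclusions(coh[[1]]$trials)
  path <- tempfile(fileext = ".csv")
  write_trials(tab, path)
  back <- read_trials(path)
  expect_equal(back$rs, tab$rs, tolerance = 1e-9)
  expect_equal(back$rt, tab$rt, tolerance = 1e-9)
  expect_equal(back$congruency, tab$congruency)
  expect_equal(back$exclusion_reason, tab$exclusion_reason)
  raw <- read.csv(path)
  expect_true(all(c("subject_id", "rt_ms", "rs", "excluded",
                    "exclusion_reason") %in% names(raw)))
  expect_equal(raw$rt_ms, tab$rt * 1000, tolerance = 1e-6)
})

test_that("study configurations round-trip through YAML and JSON", {
  cfg <- study_config(seed = 9, n_subjects = 4, mc_samples = 1e4)
  for (ext in c(".yaml", ".json")) {
    path <- tempfile(fileext = ext)
    write_config(cfg, path)
    back <- read_config(path)
    expect_equal(unclass(back), unclass(cfg), tolerance = 1e-12)
  }
  expect_match(config_hash(cfg), "^[0-9a-f]{8}$")
  expect_false(config_hash(cfg) == config_hash(study_config(seed = 10)))
})
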