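toy_trials <- function() {
  # 12 analysis trials (block 2), rt in seconds; trial 5 error, trial 9 outlier
  rt <- rep(0.45, 12)
  rt[9] <- 2.5
  correct <- rep(TRUE, 12)
  correct[5] <- FALSE
  rt[5] <- NA
  data.frame(subject_id = "s", block_index = 2L, trial_index = 1:12,
             congruency = rep(c(0L, 1L), 6), correct = correct, rt = rt,
             rs = 1 / rt)
}

test_that("exclusion rules mark errors, outliers and their successors", {
  tab <- apply_exclusions(toy_trials())
  expect_equal(which(tab$excluded), c(5L, 6L, 9L, 10L))
  expect_equal(tab$exclusion_reason[5], "error")
  expect_equal(tab$exclusion_reason[6], "post_error")
  expect_equal(tab$exclusion_reason[9], "outlier")
  expect_equal(tab$exclusion_reason[10], "post_outlier")

  clean <- toy_trials()
  clean$correct <- TRUE
  clean$rt <- 0.45 + 0.001 * (1:12)
  clean$rs <- 1 / clean$rt
  expect_true(all(!apply_exclusions(clean)$excluded))
})

test_that("burn-in trials are excluded and reasons follow the priority order", {
  tab <- toy_trials()
  tab$block_index <- c(1L, 1L, rep(2L, 10))
  out <- apply_exclusions(tab)
  expect_equal(out$exclusion_reason[1:2], c("burn_in", "burn_in"))
  # an error inside the burn-in is reported as an error, not as burn-in
  tab$correct[2] <- FALSE
  tab$rt[2] <- NA
  tab$rs[2] <- NA
  out2 <- apply_exclusions(tab)
  expect_equal(out2$exclusion_reason[2], "error")
  expect_equal(out2$exclusion_reason[3], "post_error")
})

test_that("outlier statistics are computed over correct-response RTs only", {
  tab <- toy_trials()
  # a wild RT on the error trial must not perturb the outlier threshold
  tab$rt[5] <- 99
  tab$rs[5] <- 1 / 99
  out <- apply_exclusions(tab)
  expect_equal(which(out$excluded), c(5L, 6L, 9L, 10L))
  expect_equal(out$exclusion_reason[9], "outlier")
})

test_that("the design matrix has seven standardized regressors plus a constant", {
  set.seed(1)
  ex <- make_experiment(order = random_order())
  tab <- simulate_subject(ex, grid = small_grid())
  tab <- apply_exclusions(tab)
  trace <- filter_subject(tab, grid = small_grid())
  X <- build_design(trace, tab$congruency, !tab$excluded)
  expect_equal(ncol(X), 8)
  for (col in c("lr", "conflict", "congruency", "conflict_x_congruency")) {
    expect_equal(mean(X[, col]), 0, tolerance = 1e-10)
    expect_equal(sd(X[, col]), 1, tolerance = 1e-10)
  }
  expect_true(all(X[, "constant"] == 1))
  # lr and conflict are not orthogonalized against each other, only reported
  expect_gt(abs(cor(X[, "lr"], X[, "conflict"])), 0)
  expect_error(build_design(trace, rep(1L, nrow(trace)), !tab$excluded),
               "zero-variance")
})

test_that("residualized effects satisfy the Frisch-Waugh-Lovell identity", {
  set.seed(2)
  for (i in 1:25) {
    n <- 60
    X <- cbind(a = rnorm(n), b = rnorm(n), c = rnorm(n), constant = 1)
    y <- rnorm(n, X[, "a"] * 0.5 - X[, "b"])
    beta_full <- lm.fit(X, y)$coefficients[["a"]]
    expect_equal(residualized_effect(y, X, "a"), beta_full, tolerance = 1e-8)
  }
  # orthogonal test column: equals the simple regression slope
  n <- 200
  X <- cbind(a = rep(c(-1, 1), n / 2), b = rep(c(-1, -1, 1, 1), n / 4),
             constant = 1)
  y <- rnorm(n, X[, "a"])
  expect_equal(residualized_effect(y, X, "a"),
               sum(X[, "a"] * y) / sum(X[, "a"]^2), tolerance = 1e-10)
  expect_error(residualized_effect(y, cbind(X, a2 = X[, "a"]), "a"),
               "rank deficient")
})

test_that("a pure-noise response yields a near-zero residualized effect", {
  set.seed(3)
  n <- 1e4
  X <- cbind(a = rnorm(n), b = rnorm(n), constant = 1)
  y <- rnorm(n)
  beta <- residualized_effect(y, X, "a")
  se <- 1 / sqrt(n)
  expect_lt(abs(beta / se), 3)
})

test_that("the group t-test matches hand-computed values", {
  out <- group_ttest(c(1, 2, 3))
  expect_equal(out$t, 2 * sqrt(3), tolerance = 1e-12)
  expect_equal(out$df, 2L)
  expect_equal(out$p, 2 * pt(-2 * sqrt(3), 2), tolerance = 1e-12)
  flipped <- group_ttest(-c(1, 2, 3))
  expect_equal(flipped$t, -out$t)
  expect_equal(flipped$p, out$p)
  expect_warning(zero <- group_ttest(rep(0, 5)), "zero variance")
  expect_equal(zero$t, 0)
  expect_equal(zero$p, 1)
})

test_that("the KS normality screen is calibrated and detects violations", {
  pass <- vapply(1:50, function(sd) {
    set.seed(sd)
    x <- rnorm(300, 2.3, 0.25)
    ks_normality(x, rep("c", 300))$normal
  }, logical(1))
  expect_gte(mean(pass), 0.9)
  # strongly skewed reaction speeds are flagged
  set.seed(99)
  skew <- 1 / (0.2 + rexp(300, 2))
  expect_false(ks_normality(skew, rep("c", 300))$normal)
  # identical data in two conditions give identical statistics
  x <- rnorm(100, 2, 0.3)
  res <- ks_normality(c(x, x), rep(c("a", "b"), each = 100))
  expect_equal(res$statistic[1], res$statistic[2])
  expect_equal(res$p[1], res$p[2])
  expect_warning(ks_normality(rnorm(10), rep("tiny", 10)), "fewer than")
})
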