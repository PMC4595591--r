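test_that("the delta rule iterates as specified", {
  expect_equal(rw_trace(c(1L, 1L), 0.5), c(0.5, 0.75))
  # one more incongruent trial would predict 0.875
  expect_equal(rw_trace(c(1L, 1L, 1L), 0.5), c(0.5, 0.75, 0.875))
  o <- rbinom(50, 1, 0.5)
  expect_equal(rw_trace(o, 1 - 1e-12)[-1], as.numeric(o[-50]),
               tolerance = 1e-9)
  expect_equal(rw_trace(o, 1e-12, f0 = 0.3), rep(0.3, 50), tolerance = 1e-9)
  set.seed(1)
  for (i in 1:20) {
    f <- rw_trace(rbinom(80, 1, runif(1)), runif(1, 0.01, 0.99))
    expect_true(all(f >= 0 & f <= 1))
  }
})

test_that("the default search grid has 491 candidates", {
  expect_equal(length(lr_grid()), 491)
  expect_equal(lr_grid()[1], 0.01)
  expect_equal(lr_grid()[491], 0.5, tolerance = 1e-12)
  expect_error(lr_grid(0.5, 0.01, 0.001))
})

test_that("exhaustive search equals an independent brute-force oracle", {
  set.seed(7)
  o <- rbinom(200, 1, rep(c(0.8, 0.2), each = 100))
  rs <- rnorm(200, 2.3 + 0.3 * o, 0.25)
  trials <- data.frame(congruency = o, rs = rs,
                       run_type = rep(c("stable", "volatile"), each = 100))
  coarse <- lr_grid(0.01, 0.5, 0.01)

  brute <- vapply(coarse, function(lr) {
    f <- rw_trace(o, lr)
    res <- numeric(0)
    for (cc in 0:1) {
      sel <- o == cc
      res <- c(res, lm(rs[sel] ~ f[sel])$residuals)
    }
    c(bic_rs(res, 1L), bic_congruency(f, o, 1L))
  }, numeric(2))

  fit_rs <- search_fixed_lr(trials, 1L, "rs", grid = coarse)
  fit_cg <- search_fixed_lr(trials, 1L, "congruency", grid = coarse)
  expect_equal(unname(fit_rs$lrs), coarse[which.min(brute[1, ])])
  expect_equal(unname(fit_cg$lrs), coarse[which.min(brute[2, ])])
  expect_equal(fit_rs$bic_rs, min(brute[1, ]), tolerance = 1e-9)
  expect_equal(fit_cg$bic_cong, min(brute[2, ]), tolerance = 1e-9)
})

test_that("the two-LR model with tied rates reproduces the one-LR fit", {
  set.seed(8)
  ex <- make_experiment(order = random_order())
  tab <- simulate_subject(ex, grid = small_grid())
  g <- lr_grid(0.05, 0.3, 0.05)
  one <- search_fixed_lr(tab, 1L, "rs", grid = g)
  two <- search_fixed_lr(tab, 2L, "rs", grid = g)
  # diagonal of the two-LR grid equals the one-LR objective up to the
  # parameter-count term of the BIC
  n <- sum(!is.na(tab$rs))
  expect_equal(diag(two$bic_grid_rs), as.vector(one$bic_grid_rs) + log(n),
               tolerance = 1e-9)
  # the free two-LR fit can only improve on the tied fit's likelihood term
  expect_lte(min(two$bic_grid_rs), min(diag(two$bic_grid_rs)) + 1e-9)
})

test_that("ties break towards the smallest learning rate", {
  # constant congruency with f0 = 1: every lr is equally good
  trials <- data.frame(congruency = rep(1L, 30),
                       rs = rnorm(30, 2, 0.1))
  g <- lr_grid(0.1, 0.3, 0.1)
  fit <- search_fixed_lr(trials, 1L, "congruency", grid = g, f0 = 1)
  expect_equal(unname(fit$lrs), 0.1)
})
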