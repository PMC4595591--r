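test_that("the filter matches the explicit operation-by-operation composition", {
  set.seed(1)
  grid <- small_grid()
  hyper <- hyperparameters()
  o <- rbinom(30, 1, 0.7)
  rs <- rnorm(30, 2.3, 0.25)
  rs[c(5, 17)] <- NA
  tr <- filter_trials(o, rs, hyper, grid)
  b <- grid
  fh <- ah <- un <- numeric(30)
  for (i in 1:30) {
    b <- transition_alpha(b, hyper$k_stay)
    b <- propagate_f(b)
    fh[i] <- f_hat(b)
    ah[i] <- alpha_hat(b)
    un[i] <- estimation_uncertainty(b)
    b <- update_congruency(b, o[i])
    b <- update_rs(b, rs[i], o[i], hyper)
  }
  expect_equal(tr$f_hat, fh, tolerance = 1e-12)
  expect_equal(tr$alpha_hat, ah, tolerance = 1e-12)
  expect_equal(tr$est_uncertainty, un, tolerance = 1e-12)
  expect_equal(attr(tr, "belief")$mass, b$mass, tolerance = 1e-12)
})

test_that("trace bookkeeping: one row per trial, bounded summaries", {
  set.seed(2)
  o <- rbinom(120, 1, 0.5)
  tr <- filter_trials(o, grid = small_grid())
  expect_equal(nrow(tr), 120)
  expect_true(all(tr$f_hat > 0 & tr$f_hat < 1))
  expect_true(all(tr$alpha_hat > 0 & tr$alpha_hat < 1))
  expect_true(all(tr$est_uncertainty >= 0 & tr$est_uncertainty <= 0.5))
  expect_true(all(tr$cpe >= 0 & tr$cpe <= 1))
  expect_equal(tr$cpe, abs(o - tr$f_hat))
  expect_error(filter_trials(integer(0)), "empty")
})

test_that("congruency-only belief updates have the reinforcement-learning form", {
  # sign of each prediction change matches the sign of the prediction error
  set.seed(3)
  ex <- make_experiment(order = random_order())
  tr <- filter_trials(ex$congruency, grid = init_grid())
  d_f <- diff(tr$f_hat)
  pe <- (ex$congruency - tr$f_hat)[-nrow(tr)]
  expect_identical(mean(sign(d_f) == sign(pe)), 1)
  # prediction changes scale positively with alpha-weighted prediction error
  slope <- coef(lm(d_f ~ 0 + I(tr$alpha_hat[-1] * pe)))
  expect_gt(slope, 0)
  expect_lt(slope, 1.5)
})

test_that("the conflict prediction is stable under grid refinement", {
  set.seed(4)
  o <- rbinom(250, 1, 0.7)
  tr1 <- filter_trials(o, grid = init_grid(50, 50))
  tr2 <- filter_trials(o, grid = init_grid(100, 100))
  expect_lt(sqrt(mean((tr1$f_hat - tr2$f_hat)^2)), 0.02)
})

test_that("filter_subject consumes trial tables with and without RS", {
  set.seed(5)
  ex <- make_experiment(order = random_order())
  tab <- simulate_subject(ex, grid = small_grid())
  tr_rs <- filter_subject(tab, grid = small_grid())
  tr_o <- filter_subject(tab, grid = small_grid(), use_rs = FALSE)
  expect_equal(nrow(tr_rs), nrow(tab))
  # RS carries information: the two traces must differ
  expect_gt(max(abs(tr_rs$f_hat - tr_o$f_hat)), 1e-4)
  expect_true(all(is.na(tr_o$loglik_rs)))
  expect_error(filter_subject(tab[0, ], grid = small_grid()))
})
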