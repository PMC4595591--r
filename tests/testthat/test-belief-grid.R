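test_that("the initial grid is a normalized uniform prior", {
  g <- init_grid(50, 50)
  expect_equal(sum(g$mass), 1, tolerance = 1e-12)
  expect_equal(f_hat(g), 0.5, tolerance = 1e-12)
  expect_equal(alpha_hat(g), 0.5, tolerance = 1e-12)
  expect_true(all(diff(g$alpha) > 0) && all(diff(g$f) > 0))
  expect_true(all(g$alpha > 0 & g$alpha < 1))
  expect_error(init_grid(50, 50, s_alpha = function(a) rep(1.5, length(a))),
               "must exceed 2")
})

test_that("the LR transition mixes towards uniform and preserves the f-marginal", {
  g <- init_grid(10, 12)
  # point mass at one (alpha, f) node
  g$mass[] <- 0
  g$mass[4, 7] <- 1
  near_identity <- transition_alpha(g, 1 - 1e-12)
  expect_equal(near_identity$mass, g$mass, tolerance = 1e-9)
  mixed <- transition_alpha(g, 0.9)
  expect_equal(mixed$mass[4, 7], 0.9 + 0.1 / 10, tolerance = 1e-12)
  expect_equal(sum(mixed$mass[, 7]), 1, tolerance = 1e-12)
  full_mix <- transition_alpha(g, 1e-12)
  expect_equal(rowSums(full_mix$mass), rep(0.1, 10), tolerance = 1e-9)
  # f-marginal untouched in all cases
  expect_equal(colSums(mixed$mass), colSums(g$mass), tolerance = 1e-12)
  expect_error(transition_alpha(g, 1.2), "k_stay")
})

test_that("conflict propagation widens with the volatility belief, mode preserved", {
  g <- init_grid(10, 50)
  j <- which.min(abs(g$f - 0.7))
  g$mass[] <- 0
  g$mass[, j] <- 1 / 10  # f fixed at node j for every alpha slice
  prop <- propagate_f(g)
  # per-alpha-slice variance of propagated f increases with alpha
  vars <- apply(prop$mass, 1, function(m) {
    m <- m / sum(m)
    sum(m * g$f^2) - sum(m * g$f)^2
  })
  expect_true(all(diff(vars) > 0))
  # kernel rows peak at the origin node (mode = f_old)
  for (a in c(1, 5, 10)) {
    expect_equal(unname(which.max(g$kernel[j, , a])), j)
  }
  # low-alpha (huge parameter sum) limit: kernel approaches identity
  expect_equal(unname(prop$mass[1, ] / sum(prop$mass[1, ])),
               as.numeric(g$f == g$f[j]), tolerance = 1e-3)
})

test_that("congruency updates follow Bayes on the f-marginal", {
  g <- init_grid(10, 200)
  up <- update_congruency(g, 1L)
  expect_gt(f_hat(up), f_hat(g))
  # uniform prior + one incongruent observation -> Beta(2, 1), mean 2/3
  expect_equal(f_hat(up), 2 / 3, tolerance = 0.01)
  down <- update_congruency(g, 0L)
  expect_equal(f_hat(down), 1 / 3, tolerance = 0.01)
  # likelihood products commute when no propagation intervenes
  ab <- update_congruency(update_congruency(g, 0L), 1L)
  ba <- update_congruency(update_congruency(g, 1L), 0L)
  expect_equal(ab$mass, ba$mass, tolerance = 1e-12)
})

test_that("RS updates respond to the emission slope and skip missing trials", {
  g <- init_grid(15, 60)
  hyper <- hyperparameters()
  expect_identical(update_rs(g, NA_real_, 1L, hyper)$mass, g$mass)
  flat <- hyperparameters(b_con = 0, b_inc = 0)
  expect_equal(update_rs(g, 2.1, 1L, flat)$mass, g$mass, tolerance = 1e-12)
  wide <- hyperparameters(sigma_con = 1e4, sigma_inc = 1e4)
  expect_equal(update_rs(g, 2.1, 1L, wide)$mass, g$mass, tolerance = 1e-6)
  # b_inc > 0 and a fast RS on an incongruent trial raises predicted conflict
  fast <- update_rs(g, hyper$a_inc + hyper$b_inc + 0.3, 1L, hyper)
  expect_gt(f_hat(fast), f_hat(g))
  slow <- update_rs(g, hyper$a_inc - 0.3, 1L, hyper)
  expect_lt(f_hat(slow), f_hat(g))
})

test_that("estimation uncertainty is the s.d. of the conflict marginal", {
  g <- init_grid(10, 200)
  expect_equal(estimation_uncertainty(g), sqrt(1 / 12), tolerance = 0.005)
  point <- g
  point$mass[] <- 0
  point$mass[3, 120] <- 1
  expect_equal(estimation_uncertainty(point), 0)
  set.seed(4)
  for (i in 1:20) {
    r <- g
    r$mass[] <- runif(length(r$mass))
    r$mass <- r$mass / sum(r$mass)
    u <- estimation_uncertainty(r)
    expect_true(u >= 0 && u <= 0.5)
  }
})

test_that("every grid operation preserves normalization to 1e-10", {
  g <- init_grid(12, 12)
  hyper <- hyperparameters()
  set.seed(9)
  for (i in 1:25) {
    g <- transition_alpha(g, hyper$k_stay)
    g <- propagate_f(g)
    g <- update_congruency(g, rbinom(1, 1, 0.7))
    g <- update_rs(g, rnorm(1, 2.2, 0.3), rbinom(1, 1, 0.5), hyper)
    expect_equal(sum(g$mass), 1, tolerance = 1e-10)
    expect_true(all(g$mass >= 0))
  }
})
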