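#' Discrete joint belief grid over (flexible learning rate, predicted conflict)
#'
#' The model maintains a joint probability mass over the flexible learning
#' rate `alpha` (the volatility belief) and the predicted conflict level `f`
#' (the believed probability that the upcoming trial is incongruent), both on
#' open-interval (0, 1) grids of midpoint nodes. All filter operations act on
#' and return a normalized grid.
#'
#' `propagate_f()` spreads the conflict belief through a beta kernel whose
#' mode is the current `f` and whose parameter sum `s(alpha)` shrinks as the
#' volatility belief grows (a higher sum gives a narrower beta distribution),
#' so a volatile world makes conflict predictions more diffuse. The mapping
#' `s(alpha)` is a configuration hook; see [s_alpha_inverse()] and
#' [s_alpha_inverse_sq()].
#'
#' @param n_alpha,n_f Number of grid nodes per dimension (>= 10).
#' @param s_alpha Function mapping `alpha` nodes to the beta parameter sum;
#'   must return values > 2 (otherwise the mode is undefined). Default
#'   [s_alpha_map()].
#' @return An object of class `belief_grid`: list with `alpha` and `f` node
#'   vectors, `mass` (an `n_alpha` x `n_f` matrix summing to 1), `s` (the
#'   parameter sums per alpha node) and `kernel` (the precomputed f-propagation
#'   kernels, an `n_f` x `n_f` x `n_alpha` array of row-normalized transition
#'   rows).
#' @examples
#' g <- init_grid(20, 20)
#' sum(g$mass) # 1
#' @export
init_grid <- function(n_alpha = 50L, n_f = 50L, s_alpha = s_alpha_map()) {
  stopifnot(n_alpha >= 10L, n_f >= 10L)
  n_alpha <- as.integer(n_alpha)
  n_f <- as.integer(n_f)
  alpha <- (seq_len(n_alpha) - 0.5) / n_alpha
  f <- (seq_len(n_f) - 0.5) / n_f
  s <- s_alpha(alpha)
  if (any(s <= 2)) {
    stop("s(alpha) must exceed 2 everywhere for the beta mode to be defined")
  }
  kernel <- array(0, dim = c(n_f, n_f, n_alpha))
  for (a in seq_len(n_alpha)) {
    # rows: f_old; columns: f_new; mode-parameterized beta, renormalized on grid
    for (j in seq_len(n_f)) {
      shape1 <- f[j] * (s[a] - 2) + 1
      shape2 <- (1 - f[j]) * (s[a] - 2) + 1
      row <- stats::dbeta(f, shape1, shape2)
      kernel[j, , a] <- row / sum(row)
    }
  }
  structure(
    list(alpha = alpha, f = f,
         mass = matrix(1 / (n_alpha * n_f), n_alpha, n_f),
         s = s, kernel = kernel),
    class = "belief_grid"
  )
}

#' Beta parameter-sum mapping for conflict propagation
#'
#' The family `s(alpha) = 2 + gain / alpha^exponent`, strictly decreasing in
#' `alpha` so that a stronger volatility belief always yields a wider (more
#' diffuse) conflict propagation. The parameter sum acts like the effective
#' memory of a slice's conflict tracker: nodes with large `s` integrate the
#' congruency history over hundreds of trials, nodes with small `s` over just
#' a handful. The default (`gain = 4`, `exponent = 3`) spreads the 50-node
#' grid so that roughly a quarter of the nodes hold slow, precise trackers
#' (`s > 300`) while the upper half reacts within a few trials; this
#' calibration gives both close tracking of a stationary conflict rate and a
#' reliable volatile-over-stable separation of the learning rate. See the
#' methods vignette for the calibration analysis.
#'
#' @param gain Positive scale of the mapping.
#' @param exponent Positive exponent of the decay in `alpha`.
#' @return A function of `alpha` returning the parameter sum.
#' @export
s_alpha_map <- function(gain = 4, exponent = 3) {
  stopifnot(gain > 0, exponent > 0)
  force(gain)
  force(exponent)
  function(alpha) 2 + gain / alpha^exponent
}

normalize_grid <- function(belief) {
  tot <- sum(belief$mass)
  if (!is.finite(tot) || tot <= 0) {
    stop("belief mass degenerated (total ", tot, ")")
  }
  belief$mass <- belief$mass / tot
  belief
}

#' Transition the learning-rate belief
#'
#' The flexible LR most likely stays at its previous value; with probability
#' `1 - k_stay` it jumps to a uniformly chosen node. Applied independently
#' within each f-slice, so the f-marginal is unchanged.
#'
#' @param belief A [init_grid()] object.
#' @param k_stay Stickiness in (0, 1).
#' @return Updated `belief_grid`.
#' @export
transition_alpha <- function(belief, k_stay) {
  stopifnot(inherits(belief, "belief_grid"))
  if (!(k_stay > 0 && k_stay < 1)) {
    stop("k_stay must lie strictly inside (0, 1)")
  }
  n_alpha <- length(belief$alpha)
  f_slice_tot <- colSums(belief$mass)
  belief$mass <- k_stay * belief$mass +
    (1 - k_stay) * matrix(f_slice_tot / n_alpha, n_alpha, length(belief$f),
                          byrow = TRUE)
  normalize_grid(belief)
}

#' Propagate the conflict belief through the volatility-scaled beta kernel
#'
#' @param belief A `belief_grid`.
#' @return Updated `belief_grid`.
#' @export
propagate_f <- function(belief) {
  stopifnot(inherits(belief, "belief_grid"))
  for (a in seq_along(belief$alpha)) {
    belief$mass[a, ] <- belief$mass[a, , drop = FALSE] %*% belief$kernel[, , a]
  }
  normalize_grid(belief)
}

#' Update the belief with the observed trial congruency
#'
#' Multiplies the mass at each `(alpha, f)` node by the Bernoulli likelihood
#' `f^o * (1 - f)^(1 - o)` and renormalizes.
#'
#' @param belief A `belief_grid`.
#' @param o Observed congruency, 0 (congruent) or 1 (incongruent).
#' @return Updated `belief_grid`.
#' @export
update_congruency <- function(belief, o) {
  stopifnot(inherits(belief, "belief_grid"), o %in% c(0L, 1L))
  lik <- if (o == 1L) belief$f else 1 - belief$f
  belief$mass <- sweep(belief$mass, 2L, lik, `*`)
  normalize_grid(belief)
}

#' Update the belief with the observed reaction speed
#'
#' Multiplies the mass by the Gaussian emission likelihood of `rs` under the
#' congruency-specific mean `a_c + b_c * f` and s.d. `sigma_c`. A missing
#' `rs` (error or no-response trial) leaves the belief unchanged: only the
#' congruency observation informs the model on such trials.
#'
#' @param belief A `belief_grid`.
#' @param rs Reaction speed (1/s) or `NA`.
#' @param o Trial congruency (selects the emission parameter set).
#' @param hyper A [hyperparameters()] object.
#' @return Updated `belief_grid`.
#' @export
update_rs <- function(belief, rs, o, hyper) {
  stopifnot(inherits(belief, "belief_grid"), inherits(hyper, "flex_hyper"))
  if (is.na(rs)) {
    return(belief)
  }
  p <- emission_pars(hyper, o)
  lik <- dnorm(rs, mean = p[["a"]] + p[["b"]] * belief$f, sd = p[["sigma"]])
  # guard against total underflow for extreme outliers
  if (sum(lik) <= 0) {
    return(belief)
  }
  belief$mass <- sweep(belief$mass, 2L, lik, `*`)
  normalize_grid(belief)
}

#' Posterior summaries of the belief grid
#'
#' `f_hat()` and `alpha_hat()` are the posterior means of predicted conflict
#' and of the flexible LR; `estimation_uncertainty()` is the s.d. of the
#' marginal distribution of predicted conflict.
#'
#' @param belief A `belief_grid`.
#' @return A scalar.
#' @export
f_hat <- function(belief) {
  sum(colSums(belief$mass) * belief$f)
}

#' @rdname f_hat
#' @export
alpha_hat <- function(belief) {
  sum(rowSums(belief$mass) * belief$alpha)
}

#' @rdname f_hat
#' @export
estimation_uncertainty <- function(belief) {
  p <- colSums(belief$mass)
  m <- sum(p * belief$f)
  sqrt(max(sum(p * belief$f^2) - m^2, 0))
}
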