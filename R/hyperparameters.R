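#' Reaction-speed emission hyperparameters
#'
#' The model links the latent predicted conflict level `f` to observed
#' reaction speed (RS = 1/RT, in 1/s) through congruency-specific Gaussian
#' emissions: on a trial of congruency `c`, `RS ~ Normal(a_c + b_c * f,
#' sigma_c)`. `k_stay` is the stickiness of the learning-rate transition (the
#' probability that the flexible LR keeps its value from one trial to the
#' next; otherwise it jumps uniformly).
#'
#' The defaults encode slower responding under conflict and a negative
#' modulation of control prediction error `|o - f|` on RS: at `f = 0.5` they
#' imply RT of about 417 ms on congruent and 455 ms on incongruent trials,
#' and RS decreases as `|o - f|` grows in both conditions (`b_con < 0`,
#' `b_inc > 0`).
#'
#' @param a_con,a_inc RS intercepts (1/s) for congruent/incongruent trials.
#' @param b_con,b_inc RS slopes on `f` (1/s).
#' @param sigma_con,sigma_inc RS noise s.d. (1/s), strictly positive.
#' @param k_stay Learning-rate transition stickiness, in (0, 1).
#' @return Object of class `flex_hyper` (a named list).
#' @export
hyperparameters <- function(a_con = 2.6, a_inc = 2.0,
                            b_con = -0.4, b_inc = 0.4,
                            sigma_con = 0.25, sigma_inc = 0.25,
                            k_stay = 0.993) {
  stopifnot(sigma_con > 0, sigma_inc > 0, k_stay > 0, k_stay < 1)
  structure(
    list(a_con = a_con, a_inc = a_inc, b_con = b_con, b_inc = b_inc,
         sigma_con = sigma_con, sigma_inc = sigma_inc, k_stay = k_stay),
    class = "flex_hyper"
  )
}

#' @export
print.flex_hyper <- function(x, ...) {
  cat("RS emission hyperparameters (RS = a_c + b_c * f + noise):\n")
  cat(sprintf("  congruent:   a = %+.4f  b = %+.4f  sigma = %.4f\n",
              x$a_con, x$b_con, x$sigma_con))
  cat(sprintf("  incongruent: a = %+.4f  b = %+.4f  sigma = %.4f\n",
              x$a_inc, x$b_inc, x$sigma_inc))
  cat(sprintf("  LR transition stickiness k_stay = %.4f\n", x$k_stay))
  invisible(x)
}

# per-congruency views used by the filter and the generator
emission_pars <- function(hyper, o) {
  if (o == 1L) {
    c(a = hyper$a_inc, b = hyper$b_inc, sigma = hyper$sigma_inc)
  } else {
    c(a = hyper$a_con, b = hyper$b_con, sigma = hyper$sigma_con)
  }
}

#' Jitter hyperparameters to create between-subject variability
#'
#' Multiplies each emission parameter by an independent uniform factor in
#' `1 +/- amount`, leaving `k_stay` untouched. Used by the cohort simulator so
#' that simulated subjects differ realistically in their RS mapping.
#'
#' @param hyper A [hyperparameters()] object.
#' @param amount Half-width of the relative jitter (default 0.1, i.e. +/-10%).
#' @return A new `flex_hyper` object.
#' @export
jitter_hyperparameters <- function(hyper, amount = 0.1) {
  stopifnot(inherits(hyper, "flex_hyper"), amount >= 0, amount < 1)
  jit <- function(x) x * runif(1L, 1 - amount, 1 + amount)
  hyperparameters(
    a_con = jit(hyper$a_con), a_inc = jit(hyper$a_inc),
    b_con = jit(hyper$b_con), b_inc = jit(hyper$b_inc),
    sigma_con = jit(hyper$sigma_con), sigma_inc = jit(hyper$sigma_inc),
    k_stay = hyper$k_stay
  )
}
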