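#' BIC from reaction-speed residuals
#'
#' `BIC = n * ln(sigma2_hat) + n_params * ln(n)`, where `sigma2_hat` is the
#' mean squared residual of the model's RS predictions: the standard
#' large-sample approximation of `-2 ln L` by `n ln(error variance)` for a
#' Gaussian error model. The free-parameter count includes only the learning
#' rates (0 for the flexible model, 1 and 2 for the fixed-LR comparators);
#' the RS-emission parameters are profiled out identically in all models.
#'
#' @param residuals RS prediction errors over the analysed trials.
#' @param n_params Number of free parameters.
#' @return BIC value.
#' @examples
#' bic_rs(rep(1, 100), n_params = 2) # 2 * log(100)
#' @export
bic_rs <- function(residuals, n_params = 0L) {
  n <- length(residuals)
  stopifnot(n >= 2L, n_params >= 0L)
  sigma2 <- mean(residuals^2)
  if (sigma2 < 1e-12) {
    warning("zero residual variance; floored at 1e-12")
    sigma2 <- 1e-12
  }
  n * log(sigma2) + n_params * log(n)
}

#' BIC from trial-wise congruency predictions
#'
#' Uses the per-trial likelihood `1 - |o_i - f_i|`: a prediction of conflict
#' level 0.8 assigns likelihood 0.8 to an incongruent trial and 0.2 to a
#' congruent one. `BIC = -2 * sum(ln lik) + n_params * ln(n)`, with per-trial
#' likelihoods floored at 1e-12.
#'
#' @param f_seq Predicted conflict levels in `[0, 1]` (pre-update, aligned
#'   with the trials).
#' @param o_seq Observed congruency (0/1).
#' @param n_params Number of free parameters.
#' @return BIC value.
#' @export
bic_congruency <- function(f_seq, o_seq, n_params = 0L) {
  stopifnot(length(f_seq) == length(o_seq), all(f_seq >= 0), all(f_seq <= 1),
            n_params >= 0L)
  lik <- pmax(1 - abs(o_seq - f_seq), 1e-12)
  -2 * sum(log(lik)) + n_params * log(length(o_seq))
}
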