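#' Random-effects group-level Bayesian model selection
#'
#' Treats the model identity of each subject as a random effect drawn from a
#' population multinomial with Dirichlet-distributed frequencies, and
#' estimates the posterior over frequencies by the standard variational
#' scheme: starting from a uniform Dirichlet(1, ..., 1) prior, subject-level
#' model responsibilities proportional to `exp(log-evidence + digamma(alpha_k)
#' - digamma(sum(alpha)))` and the Dirichlet counts are iterated to
#' convergence. Log model evidence is approximated by `-BIC/2`. Exceedance
#' probabilities (the posterior belief that a model is the most frequent one
#' in the population) are estimated by Monte-Carlo sampling from the
#' posterior Dirichlet.
#'
#' @param bic Subjects x models matrix of BIC values (finite; >= 2 models).
#'   Column names label the models.
#' @param mc_samples Number of Monte-Carlo Dirichlet samples for the
#'   exceedance estimate.
#' @param seed Optional seed for the Monte-Carlo step.
#' @param prior_alpha Dirichlet prior count per model.
#' @param tol,max_iter Convergence controls for the variational iteration.
#' @return List of class `bms_result`: `dirichlet_alpha`,
#'   `expected_frequencies`, `exceedance`, `responsibilities` (subjects x
#'   models), `mc_samples`, `n_iter`, `converged`.
#' @examples
#' b <- matrix(c(0, 10, 0, 10, 0, 10), nrow = 3, byrow = TRUE,
#'             dimnames = list(NULL, c("m1", "m2")))
#' group_bms(b, mc_samples = 1e4, seed = 1)$exceedance
#' @export
group_bms <- function(bic, mc_samples = 1e5, seed = NULL, prior_alpha = 1,
                      tol = 1e-6, max_iter = 1e4) {
  bic <- as.matrix(bic)
  n_sub <- nrow(bic)
  n_mod <- ncol(bic)
  stopifnot(n_mod >= 2L, n_sub >= 1L, all(is.finite(bic)), prior_alpha > 0)
  labels <- colnames(bic)
  if (is.null(labels)) {
    labels <- paste0("model", seq_len(n_mod))
  }
  lme <- -bic / 2

  alpha0 <- rep(prior_alpha, n_mod)
  alpha <- alpha0
  g <- matrix(1 / n_mod, n_sub, n_mod)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    logu <- sweep(lme, 2L, digamma(alpha) - digamma(sum(alpha)), `+`)
    logu <- logu - apply(logu, 1L, max)
    u <- exp(logu)
    g <- u / rowSums(u)
    alpha_new <- alpha0 + colSums(g)
    if (max(abs(alpha_new - alpha)) < tol) {
      alpha <- alpha_new
      converged <- TRUE
      break
    }
    alpha <- alpha_new
  }
  if (!converged) {
    warning("group BMS did not converge after ", max_iter,
            " iterations (last max alpha change ",
            signif(max(abs(alpha_new - alpha)), 3), ")")
  }

  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  draws <- matrix(rgamma(mc_samples * n_mod, shape = rep(alpha, each = mc_samples)),
                  nrow = mc_samples)
  xp <- tabulate(max.col(draws, ties.method = "first"), nbins = n_mod) /
    mc_samples

  structure(
    list(
      dirichlet_alpha = setNames(alpha, labels),
      expected_frequencies = setNames(alpha / sum(alpha), labels),
      exceedance = setNames(xp, labels),
      responsibilities = `colnames<-`(g, labels),
      mc_samples = mc_samples,
      n_iter = iter,
      converged = converged
    ),
    class = "bms_result"
  )
}

#' @export
print.bms_result <- function(x, ...) {
  cat("Random-effects group model selection (", nrow(x$responsibilities),
      " subjects, ", length(x$exceedance), " models)\n", sep = "")
  tab <- rbind(
    `Dirichlet alpha` = x$dirichlet_alpha,
    `Expected frequency` = x$expected_frequencies,
    `Exceedance probability` = x$exceedance
  )
  print(round(tab, 4))
  invisible(x)
}
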