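#' Behaviour generator settings
#'
#' Packages the settings used to simulate subject behaviour: the emission
#' hyperparameters (shared with the model), the error rate, and the injected
#' slow-outlier process. The default error rate of 0.058 matches a mean
#' accuracy of 94.2%; outliers multiply RT by `outlier_scale` on a fraction
#' `outlier_rate` of correct trials so that the downstream >2.5 s.d. outlier
#' filter has genuine work to do.
#'
#' @param hyper A [hyperparameters()] object.
#' @param error_rate Probability of an error trial (no RT), in `[0, 1]`.
#' @param outlier_rate Fraction of correct trials receiving an RT outlier.
#' @param outlier_scale RT multiplier for outlier trials.
#' @param rs_floor Lower truncation (1/s) of simulated reaction speed,
#'   keeping RT finite.
#' @return Object of class `generator_params`.
#' @export
generator_params <- function(hyper = hyperparameters(),
                             error_rate = 0.058,
                             outlier_rate = 0.01,
                             outlier_scale = 3,
                             rs_floor = 0.1) {
  stopifnot(inherits(hyper, "flex_hyper"),
            error_rate >= 0, error_rate <= 1,
            outlier_rate >= 0, outlier_rate <= 1,
            outlier_scale > 0, rs_floor > 0)
  structure(
    list(hyper = hyper, error_rate = error_rate, outlier_rate = outlier_rate,
         outlier_scale = outlier_scale, rs_floor = rs_floor),
    class = "generator_params"
  )
}

#' Simulate one subject's behaviour on a congruency table
#'
#' Latent conflict predictions are produced by the congruency-only
#' belief-update variant of the grid filter; observed reaction speed is then
#' drawn from the congruency-specific Gaussian emission
#' `RS ~ Normal(a_c + b_c * f_hat, sigma_c)`, truncated below at
#' `params$rs_floor`. Errors are injected i.i.d. at `params$error_rate`
#' (error trials carry no RT); RT outliers are injected by multiplying RT by
#' `params$outlier_scale` on a random `params$outlier_rate` fraction of
#' correct trials.
#'
#' @param trials Congruency table from [make_experiment()] (or any data frame
#'   with `congruency` plus design columns).
#' @param params A [generator_params()] object.
#' @param subject_id Identifier stored in the output.
#' @param grid Belief grid used for the latent predictions.
#' @return Trial table: design columns plus `subject_id`, `correct` (logical),
#'   `rt` (seconds, `NA` on errors), `rs` (1/s, `NA` on errors). The latent
#'   prediction trace is attached as attribute `"trace"` and the generating
#'   parameters as `"params"`.
#' @export
simulate_subject <- function(trials, params = generator_params(),
                             subject_id = "s01", grid = init_grid()) {
  stopifnot(inherits(params, "generator_params"))
  hyper <- params$hyper
  trace <- filter_subject(trials, hyper = hyper, grid = grid, use_rs = FALSE)
  n <- nrow(trials)
  correct <- runif(n) >= params$error_rate
  ab <- cbind(
    a = ifelse(trials$congruency == 1L, hyper$a_inc, hyper$a_con),
    b = ifelse(trials$congruency == 1L, hyper$b_inc, hyper$b_con),
    s = ifelse(trials$congruency == 1L, hyper$sigma_inc, hyper$sigma_con)
  )
  rs <- pmax(rnorm(n, ab[, "a"] + ab[, "b"] * trace$f_hat, ab[, "s"]),
             params$rs_floor)
  outlier <- correct & (runif(n) < params$outlier_rate)
  rs[outlier] <- pmax(rs[outlier] / params$outlier_scale, params$rs_floor)
  rs[!correct] <- NA_real_
  out <- cbind(
    subject_id = subject_id,
    trials,
    correct = correct,
    rt = 1 / rs,
    rs = rs
  )
  rownames(out) <- NULL
  attr(out, "trace") <- trace
  attr(out, "params") <- params
  out
}

#' Simulate a cohort of subjects on the full task design
#'
#' Each subject receives a freshly randomized counterbalanced run order and
#' emission hyperparameters jittered around the cohort defaults (+/-10% by
#' default), then behaves per [simulate_subject()]. A single seed makes the
#' whole cohort reproducible.
#'
#' @param n_subjects Number of subjects (the study modelled 21).
#' @param seed Integer seed for the whole cohort.
#' @param params Cohort-level [generator_params()].
#' @param jitter Relative half-width of the per-subject hyperparameter jitter.
#' @param grid Belief grid used for the latent predictions.
#' @return List of class `cohort`; one element per subject with fields
#'   `subject_id`, `trials` (the simulated trial table), `hyper` (the
#'   subject's true emission parameters) and `trace` (the latent generator
#'   trace).
#' @export
simulate_cohort <- function(n_subjects = 21L, seed = 1L,
                            params = generator_params(),
                            jitter = 0.1, grid = init_grid()) {
  stopifnot(n_subjects >= 1L)
  set.seed(seed)
  labels <- c("s20", "s80", "v20", "v80")
  subjects <- lapply(seq_len(n_subjects), function(s) {
    id <- sprintf("s%02d", s)
    order <- sample(rep(labels, 2L))
    design <- make_experiment(order = order)
    hyper_s <- jitter_hyperparameters(params$hyper, jitter)
    params_s <- params
    params_s$hyper <- hyper_s
    tab <- simulate_subject(design, params = params_s, subject_id = id,
                            grid = grid)
    list(subject_id = id, trials = tab, hyper = hyper_s,
         trace = attr(tab, "trace"))
  })
  structure(subjects, class = "cohort")
}

#' Bind a cohort's trial tables into one data frame
#'
#' @param cohort A [simulate_cohort()] result.
#' @return A single trial table with all subjects stacked.
#' @export
cohort_trials <- function(cohort) {
  out <- do.call(rbind, lapply(cohort, function(s) {
    tab <- s$trials
    attr(tab, "trace") <- NULL
    attr(tab, "params") <- NULL
    tab
  }))
  rownames(out) <- NULL
  out
}
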