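#' Run the flexible control filter over a trial sequence
#'
#' Processes a chronological congruency (and optionally reaction-speed)
#' sequence with the grid filter. On every trial the belief is first passed
#' through the learning-rate transition and the volatility-scaled conflict
#' propagation; the *pre-stimulus* posterior summaries (`alpha_hat`, `f_hat`,
#' `est_uncertainty`) are recorded at that point. The observed congruency and
#' (when present) reaction speed are then applied as likelihood updates in
#' anticipation of the next trial. The belief is carried across run
#' boundaries without reset; the burn-in blocks of the task design perform
#' the baseline-resetting role.
#'
#' @param congruency Integer vector of 0/1 observations, chronological order.
#' @param rs Optional numeric vector of reaction speeds (1/s), `NA` for
#'   trials without a response; `NULL` runs the congruency-only belief-update
#'   variant (used by the behaviour generator).
#' @param hyper A [hyperparameters()] object (supplies `k_stay` and, when
#'   `rs` is given, the RS emission).
#' @param grid A [init_grid()] object giving the discretization and the
#'   `s(alpha)` mapping; consumed as the prior for trial 1.
#' @return A data.frame of class `model_trace` with one row per trial:
#'   `trial`, `congruency`, `alpha_hat`, `f_hat`, `est_uncertainty`,
#'   `cpe` (`|o - f_hat|`, the control prediction error), `pc_x_cong`
#'   (`f_hat * o`, the raw predicted-conflict-by-congruency product) and
#'   `loglik_rs` (the one-step-ahead predictive log-density of the trial's
#'   RS, `NA` when RS is absent). The final belief is attached as attribute
#'   `"belief"` and the summed RS predictive log-likelihood as
#'   `attr(, "loglik_rs")`.
#' @examples
#' tr <- filter_trials(rbinom(50, 1, 0.8), grid = init_grid(15, 15))
#' nrow(tr) # 50
#' @export
filter_trials <- function(congruency, rs = NULL,
                          hyper = hyperparameters(),
                          grid = init_grid()) {
  n <- length(congruency)
  if (n == 0L) {
    stop("empty trial sequence")
  }
  stopifnot(all(congruency %in% c(0L, 1L)))
  use_rs <- !is.null(rs)
  if (use_rs) {
    stopifnot(length(rs) == n)
  }
  a_hat <- f_h <- unc <- ll <- numeric(n)
  # fast inner loop in f-major layout (f on rows, alpha on columns) so that
  # f-likelihoods recycle down columns without copies; mathematically
  # identical to composing transition_alpha/propagate_f/update_* per trial
  k_stay <- hyper$k_stay
  if (!(k_stay > 0 && k_stay < 1)) {
    stop("k_stay must lie strictly inside (0, 1)")
  }
  n_a <- length(grid$alpha)
  n_fn <- length(grid$f)
  f_nodes <- grid$f
  f_sq <- f_nodes^2
  alpha_nodes <- grid$alpha
  tkern <- lapply(seq_len(n_a), function(a) t(grid$kernel[, , a]))
  M <- t(grid$mass)  # n_f x n_alpha
  for (i in seq_len(n)) {
    # LR transition: sticky identity + uniform jump, per f-slice
    M <- k_stay * M + ((1 - k_stay) / n_a) * rowSums(M)
    # conflict propagation through the per-alpha beta kernel
    for (a in seq_len(n_a)) {
      M[, a] <- tkern[[a]] %*% M[, a]
    }
    M <- M / sum(M)
    # pre-stimulus summaries
    p_f <- rowSums(M)
    f_h[i] <- sum(p_f * f_nodes)
    a_hat[i] <- sum(colSums(M) * alpha_nodes)
    unc[i] <- sqrt(max(sum(p_f * f_sq) - f_h[i]^2, 0))
    o <- congruency[i]
    if (use_rs && !is.na(rs[i])) {
      pars <- emission_pars(hyper, o)
      dens <- dnorm(rs[i], pars[["a"]] + pars[["b"]] * f_nodes,
                    pars[["sigma"]])
      ll[i] <- log(max(sum(p_f * dens), 1e-300))
      if (sum(dens) > 0) {
        M <- M * dens
      }
    } else {
      ll[i] <- NA_real_
    }
    M <- M * (if (o == 1L) f_nodes else 1 - f_nodes)
    M <- M / sum(M)
  }
  belief <- grid
  belief$mass <- t(M)
  out <- data.frame(
    trial = seq_len(n),
    congruency = as.integer(congruency),
    alpha_hat = a_hat,
    f_hat = f_h,
    est_uncertainty = unc,
    cpe = abs(congruency - f_h),
    pc_x_cong = f_h * congruency,
    loglik_rs = ll
  )
  class(out) <- c("model_trace", "data.frame")
  attr(out, "belief") <- belief
  attr(out, "loglik_rs") <- sum(ll, na.rm = TRUE)
  out
}

#' Filter a subject's trial table
#'
#' Convenience wrapper around [filter_trials()] for trial tables produced by
#' [simulate_subject()] or read with [read_trials()]. All trials enter the
#' filter (exclusions are applied only by the downstream behavioural GLM);
#' runs are concatenated in chronological order without belief reset.
#'
#' @param trials Trial table with columns `congruency` and (unless
#'   `use_rs = FALSE`) `rs`.
#' @param hyper,grid Passed to [filter_trials()].
#' @param use_rs If `FALSE`, run the congruency-only belief-update variant.
#' @return A `model_trace`; see [filter_trials()].
#' @export
filter_subject <- function(trials, hyper = hyperparameters(),
                           grid = init_grid(), use_rs = TRUE) {
  stopifnot(is.data.frame(trials), nrow(trials) > 0L,
            "congruency" %in% names(trials))
  rs <- if (use_rs) {
    if (!"rs" %in% names(trials)) stop("trials table has no 'rs' column")
    trials$rs
  } else {
    NULL
  }
  filter_trials(trials$congruency, rs = rs, hyper = hyper, grid = grid)
}
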