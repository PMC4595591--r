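#' Fit the RS-emission hyperparameters by expectation-maximization
#'
#' Alternates between (E) running the grid filter under the current emission
#' hyperparameters to obtain the trial-wise conflict predictions `f_hat`, and
#' (M) refitting, per congruency, the least-squares regression of observed
#' reaction speed on `f_hat` to update the intercept `a_c`, slope `b_c` and
#' residual s.d. `sigma_c`. Iteration stops when the largest absolute
#' parameter change drops below `tol` or after `max_iter` iterations. The
#' per-iteration objective is the one-step-ahead predictive log-likelihood of
#' the RS sequence under the filter; because the E-step re-filters the whole
#' sequence this is an approximate (generalized) EM scheme, monitored rather
#' than guaranteed monotone.
#'
#' The initial hyperparameters use per-congruency RS means with zero slope,
#' which makes the first E-step identical to the congruency-only filter.
#'
#' @param trials Trial table with `congruency` and `rs` (NA on error trials);
#'   at least two valid-RS trials per congruency are required.
#' @param grid A [init_grid()] object (re-used as prior for every E-step).
#' @param k_stay LR transition stickiness.
#' @param tol Convergence tolerance on the parameters.
#' @param max_iter Maximum EM iterations.
#' @param sigma_floor Lower bound for the fitted noise s.d.
#' @return List of class `flex_fit`: `hyper` (fitted [hyperparameters()]),
#'   `trace` (final `model_trace` under the fitted parameters), `objective`
#'   (per-iteration predictive log-likelihood), `n_iter`, `converged`.
#' @export
fit_flexible_em <- function(trials, grid = init_grid(), k_stay = 0.993,
                            tol = 1e-4, max_iter = 100L,
                            sigma_floor = 1e-3) {
  stopifnot(is.data.frame(trials), all(c("congruency", "rs") %in% names(trials)))
  o <- as.integer(trials$congruency)
  rs <- trials$rs
  valid <- !is.na(rs)
  for (cc in c(0L, 1L)) {
    if (sum(valid & o == cc) < 2L) {
      stop("need at least 2 valid-RS trials per congruency to fit the emission")
    }
  }

  m_step <- function(f_seq) {
    pars <- lapply(c(0L, 1L), function(cc) {
      sel <- valid & o == cc
      y <- rs[sel]
      x <- f_seq[sel]
      if (var(y) < 1e-12) {
        warning("degenerate RS (zero variance) for congruency ", cc,
                "; slope set to 0")
        b <- 0
        a <- mean(y)
      } else if (var(x) < 1e-12) {
        b <- 0
        a <- mean(y)
      } else {
        fit <- lm.fit(cbind(1, x), y)
        a <- fit$coefficients[1L]
        b <- fit$coefficients[2L]
      }
      res <- y - (a + b * x)
      c(a = unname(a), b = unname(b),
        sigma = max(sqrt(mean(res^2)), sigma_floor))
    })
    hyperparameters(
      a_con = pars[[1L]][["a"]], a_inc = pars[[2L]][["a"]],
      b_con = pars[[1L]][["b"]], b_inc = pars[[2L]][["b"]],
      sigma_con = pars[[1L]][["sigma"]], sigma_inc = pars[[2L]][["sigma"]],
      k_stay = k_stay
    )
  }

  par_vec <- function(h) {
    c(h$a_con, h$a_inc, h$b_con, h$b_inc, h$sigma_con, h$sigma_inc)
  }

  hyper <- hyperparameters(
    a_con = mean(rs[valid & o == 0L]), a_inc = mean(rs[valid & o == 1L]),
    b_con = 0, b_inc = 0,
    sigma_con = max(sd(rs[valid & o == 0L]), sigma_floor),
    sigma_inc = max(sd(rs[valid & o == 1L]), sigma_floor),
    k_stay = k_stay
  )

  objective <- numeric(0)
  converged <- FALSE
  iter <- 0L
  trace <- NULL
  while (iter < max_iter) {
    iter <- iter + 1L
    trace <- filter_trials(o, rs = rs, hyper = hyper, grid = grid)
    objective <- c(objective, attr(trace, "loglik_rs"))
    hyper_new <- m_step(trace$f_hat)
    delta <- max(abs(par_vec(hyper_new) - par_vec(hyper)))
    hyper <- hyper_new
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  trace <- filter_trials(o, rs = rs, hyper = hyper, grid = grid)
  structure(
    list(hyper = hyper, trace = trace, objective = objective,
         n_iter = iter, converged = converged),
    class = "flex_fit"
  )
}
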