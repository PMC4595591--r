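#' Fixed learning-rate Rescorla-Wagner trace
#'
#' The delta rule `f_{i+1} = f_i + lr * (o_i - f_i)` applied to a binary
#' congruency sequence. The returned values are the *pre-update* predictions:
#' `f[i]` is the predicted conflict level going into trial `i`, before `o_i`
#' is observed.
#'
#' @param o Binary congruency sequence.
#' @param lr Learning rate(s): either a scalar in (0, 1) or a vector of
#'   per-trial learning rates (used by the two-LR model, where the rate
#'   depends on the trial's run type).
#' @param f0 Initial prediction (default 0.5, the burn-in baseline).
#' @return Numeric vector of predictions, same length as `o`.
#' @examples
#' rw_trace(c(1, 1), lr = 0.5) # 0.50 0.75
#' @export
rw_trace <- function(o, lr, f0 = 0.5) {
  n <- length(o)
  stopifnot(n >= 1L, all(o %in% c(0L, 1L)), all(lr > 0), all(lr < 1),
            f0 >= 0, f0 <= 1)
  lr <- rep_len(lr, n)
  f <- numeric(n)
  f[1L] <- f0
  for (i in seq_len(n - 1L)) {
    f[i + 1L] <- f[i] + lr[i] * (o[i] - f[i])
  }
  f
}

#' Candidate learning-rate grid for the exhaustive search
#'
#' @param from,to,by Grid limits and step; defaults 0.01 to 0.5 in steps of
#'   0.001 (491 candidate values).
#' @return Numeric vector of learning rates.
#' @export
lr_grid <- function(from = 0.01, to = 0.5, by = 0.001) {
  g <- seq(from, to, by = by)
  if (length(g) == 0L) stop("empty learning-rate grid")
  g
}

#' Exhaustive search for the best fixed-LR model
#'
#' Fits the one-LR (whole task) or two-LR (one rate for stable runs, one for
#' volatile runs; run type known to the model) Rescorla-Wagner comparator by
#' exhaustive search over a learning-rate grid, minimizing either the
#' reaction-speed BIC (per-congruency least-squares emission of RS on the
#' predicted conflict, parameters profiled out, as in the flexible model) or
#' the congruency BIC (per-trial likelihood `1 - |o - f|`). For the two-LR
#' model the full product grid is searched. Ties are broken towards the
#' smallest learning rate (lexicographically for the two-LR model).
#'
#' @param trials Trial table with `congruency`, `rs`, and (for `n_lrs = 2`)
#'   `run_type`.
#' @param n_lrs 1 or 2 learning rates.
#' @param objective `"rs"` or `"congruency"`: the BIC minimized by the
#'   search (the paper re-selects the fixed-LR models per objective).
#' @param grid Candidate learning rates, see [lr_grid()].
#' @param f0 Initial prediction of the concatenated sequence.
#' @return List of class `fixed_lr_fit`: `lrs` (named vector; `lr` or
#'   `lr_stable`/`lr_volatile`), `objective`, `n_params`, `f_seq` (pre-update
#'   predictions at the selected rates), `rs_residual_variance`, `bic_rs`,
#'   `bic_cong` (both objectives evaluated at the selected rates).
#' @export
search_fixed_lr <- function(trials, n_lrs = 1L,
                            objective = c("rs", "congruency"),
                            grid = lr_grid(), f0 = 0.5) {
  objective <- match.arg(objective)
  stopifnot(n_lrs %in% c(1L, 2L), is.data.frame(trials),
            all(c("congruency", "rs") %in% names(trials)))
  o <- as.integer(trials$congruency)
  rs <- trials$rs
  valid <- !is.na(rs)
  if (n_lrs == 2L) {
    if (!"run_type" %in% names(trials)) {
      stop("two-LR model needs a run_type column")
    }
    is_vol <- trials$run_type == "volatile"
  } else {
    is_vol <- rep(FALSE, length(o))
  }
  ev <- lr_grid_evaluate(o, ifelse(valid, rs, 0), valid, is_vol,
                         grid, grid, f0, n_lrs == 1L, n_lrs)
  target <- if (objective == "rs") ev$bic_rs else ev$bic_cong
  idx <- arrayInd(which.min(target), dim(target))
  if (n_lrs == 1L) {
    lrs <- c(lr = grid[idx[2L]])
    lr_trial <- rep(lrs, length(o))
  } else {
    lrs <- c(lr_stable = grid[idx[2L]], lr_volatile = grid[idx[1L]])
    lr_trial <- ifelse(is_vol, lrs[["lr_volatile"]], lrs[["lr_stable"]])
  }
  f_seq <- rw_trace(o, lr_trial, f0 = f0)
  res <- profiled_rs_residuals(rs[valid], f_seq[valid], o[valid])
  structure(
    list(
      lrs = lrs, objective = objective, n_params = n_lrs,
      f_seq = f_seq,
      rs_residual_variance = mean(res^2),
      bic_rs = ev$bic_rs[idx[1L], idx[2L]],
      bic_cong = ev$bic_cong[idx[1L], idx[2L]],
      bic_grid_rs = ev$bic_rs, bic_grid_cong = ev$bic_cong,
      lr_grid = grid
    ),
    class = "fixed_lr_fit"
  )
}

# residuals of RS after the per-congruency least-squares emission on f
profiled_rs_residuals <- function(rs, f, o) {
  res <- numeric(length(rs))
  for (cc in c(0L, 1L)) {
    sel <- o == cc
    y <- rs[sel]
    x <- f[sel]
    if (sum(sel) < 2L || var(x) < 1e-12) {
      res[sel] <- y - mean(y)
    } else {
      fit <- lm.fit(cbind(1, x), y)
      res[sel] <- fit$residuals
    }
  }
  res
}
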