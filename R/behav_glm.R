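#' Trial exclusion rules for the behavioural analyses
#'
#' Marks error trials, post-error trials, RT outliers (RT deviating more than
#' `sd_threshold` standard deviations from the subject's grand mean, computed
#' over correct-response RTs only), post-outlier trials and burn-in trials.
#' When several rules apply to one trial a single reason is recorded with
#' priority error > post_error > outlier > post_outlier > burn_in. Applied
#' per subject on the chronologically ordered concatenated sequence.
#'
#' @param trials Trial table with `correct`, `rt`, `block_index` and
#'   optionally `subject_id` columns, chronological within subject.
#' @param sd_threshold Outlier cut-off in subject-level s.d. units.
#' @return The table with `excluded` (logical) and `exclusion_reason`
#'   (`"none"`, `"error"`, `"post_error"`, `"outlier"`, `"post_outlier"`,
#'   `"burn_in"`) columns added/overwritten.
#' @export
apply_exclusions <- function(trials, sd_threshold = 2.5) {
  stopifnot(is.data.frame(trials),
            all(c("correct", "rt", "block_index") %in% names(trials)))
  ids <- if ("subject_id" %in% names(trials)) trials$subject_id else "s"
  reason <- rep("none", nrow(trials))
  for (id in unique(ids)) {
    sel <- which(ids == id)
    correct <- trials$correct[sel]
    rt <- trials$rt[sel]
    err <- !correct
    rt_ok <- rt[correct & !is.na(rt)]
    mu <- mean(rt_ok)
    sdv <- sd(rt_ok)
    out <- correct & !is.na(rt) & abs(rt - mu) > sd_threshold * sdv
    post_err <- c(FALSE, err[-length(err)])
    post_out <- c(FALSE, out[-length(out)])
    burn <- trials$block_index[sel] == 1L
    r <- rep("none", length(sel))
    r[burn] <- "burn_in"
    r[post_out] <- "post_outlier"
    r[out] <- "outlier"
    r[post_err] <- "post_error"
    r[err] <- "error"
    reason[sel] <- r
  }
  trials$excluded <- reason != "none"
  trials$exclusion_reason <- reason
  if (all(trials$excluded)) {
    stop("all trials excluded")
  }
  trials
}

#' Build the seven-regressor design matrix
#'
#' On the retained trials, the flexible LR (`alpha_hat`), predicted conflict
#' (`f_hat`) and congruency vectors are standardized (mean 0, s.d. 1), and
#' combined into seven variable vectors plus a constant. The
#' conflict-by-congruency interaction — the control-prediction-error
#' regressor — is computed as the standardized unsigned prediction error
#' `|o - f_hat|`, and the three-way interaction as the product of
#' standardized LR and standardized `|o - f_hat|`; this CPE-aligned
#' parameterization spans the same column space as plain products of the
#' standardized mains while giving the interaction coefficients the
#' prediction-error sign convention (slower responses under larger control
#' prediction error appear as a negative effect). The remaining two-way
#' interactions are plain products of the standardized mains. Standardization
#' happens after exclusion; excluded trials' model estimates are discarded,
#' not re-estimated.
#'
#' @param trace A `model_trace` aligned with the subject's trials.
#' @param congruency Observed congruency vector (same length as the trace).
#' @param retain Logical vector of retained (non-excluded) trials.
#' @return Numeric matrix with 8 columns: `lr`, `conflict`, `congruency`,
#'   `lr_x_conflict`, `lr_x_congruency`, `conflict_x_congruency`,
#'   `lr_x_conflict_x_congruency`, `constant`.
#' @export
build_design <- function(trace, congruency, retain) {
  stopifnot(nrow(trace) == length(congruency),
            length(retain) == length(congruency))
  z <- function(x, label) {
    s <- sd(x)
    if (!is.finite(s) || s < 1e-12) {
      stop("zero-variance column in design matrix: ", label)
    }
    (x - mean(x)) / s
  }
  a <- z(trace$alpha_hat[retain], "lr")
  f <- z(trace$f_hat[retain], "conflict")
  o <- z(congruency[retain], "congruency")
  cpe <- z(abs(congruency[retain] - trace$f_hat[retain]),
           "conflict_x_congruency")
  X <- cbind(
    lr = a,
    conflict = f,
    congruency = o,
    lr_x_conflict = a * f,
    lr_x_congruency = a * o,
    conflict_x_congruency = cpe,
    lr_x_conflict_x_congruency = a * cpe,
    constant = 1
  )
  X
}

#' Residualized single-regressor effect
#'
#' Regresses the test column on all other design columns (constant included),
#' then fits the response on the residual together with the other columns as
#' nuisance effects, returning the residual's coefficient. By the
#' Frisch-Waugh-Lovell identity this equals the test variable's coefficient
#' in the full joint least-squares fit.
#'
#' @param y Response vector (retained-trial reaction speeds).
#' @param X Design matrix from [build_design()]; must have full column rank.
#' @param test_label Name of the column to test.
#' @return The fitted coefficient (scalar).
#' @export
residualized_effect <- function(y, X, test_label) {
  stopifnot(test_label %in% colnames(X), length(y) == nrow(X))
  if (qr(X)$rank < ncol(X)) {
    stop("design matrix is rank deficient")
  }
  j <- match(test_label, colnames(X))
  others <- X[, -j, drop = FALSE]
  r <- lm.fit(others, X[, j])$residuals
  fit <- lm.fit(cbind(resid = r, others), y)
  unname(fit$coefficients["resid"])
}

#' One-sample group t-test on per-subject coefficients
#'
#' @param coefficients Per-subject fitted coefficients.
#' @return List with `mean`, `t`, `df`, `p` (two-sided).
#' @export
group_ttest <- function(coefficients) {
  n <- length(coefficients)
  stopifnot(n >= 2L)
  m <- mean(coefficients)
  s <- sd(coefficients)
  if (s < 1e-15) {
    warning("zero variance across subjects")
    if (abs(m) < 1e-15) {
      return(list(mean = m, t = 0, df = n - 1L, p = 1))
    }
    return(list(mean = m, t = sign(m) * Inf, df = n - 1L, p = 0))
  }
  t_stat <- m / (s / sqrt(n))
  list(mean = m, t = t_stat, df = n - 1L,
       p = 2 * pt(-abs(t_stat), df = n - 1L))
}

#' Group-level residualized GLM over a cohort of fitted subjects
#'
#' For each subject: apply the exclusion rules, build the seven-regressor
#' design on retained trials, and estimate each regressor's residualized
#' coefficient on the retained reaction speeds; then test each coefficient
#' against zero across subjects.
#'
#' @param subjects List with one element per subject, each containing
#'   `trials` (trial table) and `trace` (aligned `model_trace`) — e.g. a
#'   [simulate_cohort()] with fitted traces substituted.
#' @param sd_threshold Outlier cut-off passed to [apply_exclusions()].
#' @return List of class `glm_effects`: `effects` (data frame with `label`,
#'   `mean_beta`, `t`, `df`, `p` per regressor) and `coefficients`
#'   (subjects x regressors matrix).
#' @export
glm_group_effects <- function(subjects, sd_threshold = 2.5) {
  labels <- c("lr", "conflict", "congruency", "lr_x_conflict",
              "lr_x_congruency", "conflict_x_congruency",
              "lr_x_conflict_x_congruency")
  coefs <- t(vapply(subjects, function(s) {
    tab <- apply_exclusions(s$trials, sd_threshold = sd_threshold)
    retain <- !tab$excluded
    X <- build_design(s$trace, tab$congruency, retain)
    y <- tab$rs[retain]
    vapply(labels, function(l) residualized_effect(y, X, l), numeric(1))
  }, numeric(length(labels))))
  tests <- lapply(labels, function(l) group_ttest(coefs[, l]))
  effects <- data.frame(
    label = labels,
    mean_beta = vapply(tests, `[[`, numeric(1), "mean"),
    t = vapply(tests, `[[`, numeric(1), "t"),
    df = vapply(tests, `[[`, numeric(1), "df"),
    p = vapply(tests, `[[`, numeric(1), "p")
  )
  structure(list(effects = effects, coefficients = coefs),
            class = "glm_effects")
}

#' Kolmogorov-Smirnov normality check of reaction speed by condition
#'
#' One-sample KS tests of each condition's RS against a Gaussian with the
#' sample's own mean and s.d., with Benjamini-Hochberg correction over
#' conditions. Conditions with fewer than `min_n` observations are skipped
#' with a warning.
#'
#' @param rs Reaction-speed vector (NA allowed, dropped).
#' @param condition Condition labels aligned with `rs`.
#' @param alpha Significance level applied to the adjusted p values.
#' @param min_n Minimum observations per condition.
#' @return Data frame with `condition`, `n`, `statistic`, `p`, `p_adj`,
#'   `normal` (TRUE when the adjusted p exceeds `alpha`).
#' @export
ks_normality <- function(rs, condition, alpha = 0.05, min_n = 20L) {
  keep <- !is.na(rs)
  rs <- rs[keep]
  condition <- condition[keep]
  levels <- unique(condition)
  rows <- lapply(levels, function(l) {
    x <- rs[condition == l]
    if (length(x) < min_n) {
      warning("condition ", l, " has fewer than ", min_n,
              " observations; skipped")
      return(data.frame(condition = l, n = length(x), statistic = NA_real_,
                        p = NA_real_))
    }
    kt <- suppressWarnings(ks.test(x, "pnorm", mean(x), sd(x)))
    data.frame(condition = l, n = length(x),
               statistic = unname(kt$statistic), p = kt$p.value)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- p.adjust(out$p, method = "BH")
  out$normal <- out$p_adj > alpha
  out
}
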