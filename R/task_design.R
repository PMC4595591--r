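#' Run designs for the volatility-manipulated conflict task
#'
#' A run consists of a 16-trial burn-in block with a 0.5 proportion of
#' incongruent trials, followed by four 20-trial blocks. In a *stable* run the
#' post-burn-in proportion of incongruent trials is fixed at 0.2 or 0.8; in a
#' *volatile* run it alternates between 0.2 and 0.8 every block. Averaged over
#' a counterbalanced set of runs the overall incidence of incongruent trials
#' is exactly 0.5 in both run classes.
#'
#' @param run_type `"stable"` or `"volatile"`.
#' @param start_high Logical; if `TRUE` the first post-burn-in block uses an
#'   incongruent proportion of 0.8 (and a stable run stays at 0.8), otherwise
#'   0.2.
#' @return An object of class `run_design`: a list with `run_type`,
#'   `start_high`, `block_props` (length 5, burn-in first) and
#'   `trials_per_block` (length 5).
#' @examples
#' run_design("volatile", start_high = TRUE)$block_props # 0.5 0.8 0.2 0.8 0.2
#' @export
run_design <- function(run_type = c("stable", "volatile"), start_high = TRUE) {
  run_type <- match.arg(run_type)
  hi <- 0.8
  lo <- 0.2
  first <- if (start_high) hi else lo
  other <- if (start_high) lo else hi
  props <- if (run_type == "stable") {
    rep(first, 4)
  } else {
    c(first, other, first, other)
  }
  structure(
    list(
      run_type = run_type,
      start_high = start_high,
      block_props = c(0.5, props),
      trials_per_block = c(16L, rep(20L, 4L))
    ),
    class = "run_design"
  )
}

#' Generate one block of trial congruencies
#'
#' Blocks use an exact-count composition: a block of `n_trials` trials at
#' incongruent proportion `p_incongruent` contains exactly
#' `n_trials * p_incongruent` incongruent trials, in uniformly shuffled order.
#'
#' @param n_trials Positive integer number of trials.
#' @param p_incongruent Proportion of incongruent trials in `[0, 1]`;
#'   `n_trials * p_incongruent` must be a whole number.
#' @return Integer vector of 0 (congruent) / 1 (incongruent), length
#'   `n_trials`.
#' @examples
#' set.seed(1)
#' sum(make_block(20, 0.8)) # 16
#' @export
make_block <- function(n_trials, p_incongruent) {
  stopifnot(length(n_trials) == 1L, n_trials >= 1, n_trials == round(n_trials),
            length(p_incongruent) == 1L,
            p_incongruent >= 0, p_incongruent <= 1)
  n_inc <- n_trials * p_incongruent
  if (abs(n_inc - round(n_inc)) > 1e-9) {
    stop("n_trials * p_incongruent = ", n_inc,
         " is not a whole number; the block design uses exact counts")
  }
  n_inc <- as.integer(round(n_inc))
  sample(rep(c(1L, 0L), c(n_inc, n_trials - n_inc)))
}

#' Generate the congruency sequence of one run
#'
#' @param design A [run_design()] object.
#' @return A data frame with one row per trial: `block_index` (1 = burn-in),
#'   `trial_index` (within run), `congruency` (0/1) and `block_prop`.
#' @export
make_run <- function(design) {
  stopifnot(inherits(design, "run_design"))
  o <- unlist(lapply(seq_along(design$block_props), function(b) {
    make_block(design$trials_per_block[b], design$block_props[b])
  }))
  n <- length(o)
  data.frame(
    block_index = rep(seq_along(design$block_props), design$trials_per_block),
    trial_index = seq_len(n),
    congruency = as.integer(o),
    block_prop = rep(design$block_props, design$trials_per_block)
  )
}

#' Default counterbalanced run order
#'
#' Eight runs: two stable at 20%, two stable at 80%, and two volatile runs per
#' starting direction, interleaved so that both halves of the session contain
#' two volatile and two stable runs (one per proportion).
#'
#' @return Character vector of length 8 with labels among
#'   `"s20"`, `"s80"`, `"v20"`, `"v80"`.
#' @export
default_run_order <- function() {
  c("v80", "s20", "v20", "s80", "v20", "s80", "v80", "s20")
}

run_label_design <- function(label) {
  switch(label,
    s20 = run_design("stable", start_high = FALSE),
    s80 = run_design("stable", start_high = TRUE),
    v20 = run_design("volatile", start_high = FALSE),
    v80 = run_design("volatile", start_high = TRUE),
    stop("unknown run label: ", label)
  )
}

#' Generate a full experiment's congruency table
#'
#' Eight runs of 96 trials each (16-trial burn-in + 4 x 20), counterbalanced
#' so that the post-burn-in incongruent proportion is exactly 0.5 within the
#' stable-run set and within the volatile-run set.
#'
#' @param seed Optional integer seed; if given, the R RNG is seeded locally so
#'   identical seeds yield identical tables.
#' @param order Permutation of the 8 run labels; must contain each of
#'   `"s20"`, `"s80"`, `"v20"`, `"v80"` exactly twice.
#' @return Data frame with one row per trial (768 rows): `run_index`,
#'   `run_type`, `block_index`, `trial_index`, `congruency`, `block_prop`.
#' @examples
#' ex <- make_experiment(seed = 1)
#' nrow(ex) # 768
#' @export
make_experiment <- function(seed = NULL, order = default_run_order()) {
  counts <- table(factor(order, levels = c("s20", "s80", "v20", "v80")))
  if (length(order) != 8L || any(counts != 2L)) {
    stop("order must contain each of s20, s80, v20, v80 exactly twice")
  }
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  runs <- lapply(seq_along(order), function(r) {
    d <- run_label_design(order[r])
    tab <- make_run(d)
    cbind(run_index = r, run_type = d$run_type, tab)
  })
  out <- do.call(rbind, runs)
  rownames(out) <- NULL
  out
}
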