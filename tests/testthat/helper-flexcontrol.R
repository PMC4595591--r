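# shared fixtures: built lazily once per test run and cached, because the
# 21-subject study and the 20-seed recovery suite are reused by several tests
.cache <- new.env(parent = emptyenv())

small_grid <- function(n = 20L) init_grid(n, n)

# canonical synthetic study at the design's full size
acceptance_study <- function() {
  if (is.null(.cache$study)) {
    .cache$study <- run_study(study_config(seed = 1L), progress = FALSE)
  }
  .cache$study
}

# EM parameter recovery over 20 cohort seeds (shared by acceptance tests)
em_recovery <- function(n_seeds = 20L) {
  if (is.null(.cache$recovery)) {
    grid <- init_grid()
    .cache$recovery <- t(vapply(seq_len(n_seeds), function(sd) {
      set.seed(1000 + sd)
      hyper <- jitter_hyperparameters(hyperparameters(), 0.1)
      ex <- make_experiment(order = sample(rep(c("s20", "s80", "v20", "v80"), 2)))
      tab <- simulate_subject(ex, generator_params(hyper = hyper), grid = grid)
      fit <- fit_flexible_em(tab, grid = grid)
      c(a_con = abs(fit$hyper$a_con - hyper$a_con) / abs(hyper$a_con),
        a_inc = abs(fit$hyper$a_inc - hyper$a_inc) / abs(hyper$a_inc),
        b_con = abs(fit$hyper$b_con - hyper$b_con) / abs(hyper$b_con),
        b_inc = abs(fit$hyper$b_inc - hyper$b_inc) / abs(hyper$b_inc))
    }, numeric(4)))
  }
  .cache$recovery
}

# random counterbalanced order
random_order <- function() sample(rep(c("s20", "s80", "v20", "v80"), 2))
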