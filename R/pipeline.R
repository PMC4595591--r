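#' Study configuration
#'
#' Collects every setting of the simulate -> fit -> compare -> GLM pipeline
#' in one serializable list: seeds, cohort size, grid resolution, transition
#' stickiness, the `s(alpha)` propagation mapping, generator settings, the
#' fixed-LR search grid and the group model-selection controls.
#'
#' @param seed Master seed for the cohort simulation.
#' @param n_subjects Cohort size (the study modelled 21).
#' @param n_alpha,n_f Belief-grid resolution.
#' @param k_stay LR transition stickiness.
#' @param s_gain,s_exponent Parameters of the propagation mapping
#'   `s(alpha) = 2 + s_gain / alpha^s_exponent`, see [s_alpha_map()].
#' @param error_rate,outlier_rate,outlier_scale,rs_floor Generator settings,
#'   see [generator_params()].
#' @param jitter Per-subject hyperparameter jitter half-width.
#' @param lr_from,lr_to,lr_by Fixed-LR search grid.
#' @param mc_samples Monte-Carlo samples for exceedance probabilities.
#' @param em_tol,em_max_iter EM controls.
#' @return List of class `study_config`.
#' @export
study_config <- function(seed = 1L, n_subjects = 21L,
                         n_alpha = 50L, n_f = 50L, k_stay = 0.993,
                         s_gain = 4, s_exponent = 3,
                         error_rate = 0.058, outlier_rate = 0.01,
                         outlier_scale = 3, rs_floor = 0.1,
                         jitter = 0.1,
                         lr_from = 0.01, lr_to = 0.5, lr_by = 0.001,
                         mc_samples = 1e5,
                         em_tol = 1e-4, em_max_iter = 100L) {
  structure(
    list(seed = seed, n_subjects = n_subjects, n_alpha = n_alpha, n_f = n_f,
         k_stay = k_stay, s_gain = s_gain, s_exponent = s_exponent,
         error_rate = error_rate, outlier_rate = outlier_rate,
         outlier_scale = outlier_scale, rs_floor = rs_floor,
         jitter = jitter, lr_from = lr_from, lr_to = lr_to, lr_by = lr_by,
         mc_samples = mc_samples, em_tol = em_tol,
         em_max_iter = em_max_iter),
    class = "study_config"
  )
}

#' Read a study configuration from YAML or JSON
#'
#' Fields present in the file override the [study_config()] defaults.
#'
#' @param path File path ending in `.yaml`, `.yml` or `.json`.
#' @return A `study_config`.
#' @export
read_config <- function(path) {
  vals <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  do.call(study_config, vals)
}

#' @rdname read_config
#' @param config A `study_config` to write.
#' @export
write_config <- function(config, path) {
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(unclass(config), path)
  } else {
    jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Short polynomial hash of a configuration (used to tag output files)
#'
#' @param config A `study_config`.
#' @return 8-character hexadecimal string.
#' @export
config_hash <- function(config) {
  txt <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
  h <- 17
  for (b in utf8ToInt(as.character(txt))) {
    h <- (h * 31 + b) %% 2147483647
  }
  sprintf("%08x", h)
}

config_grid <- function(config) {
  init_grid(config$n_alpha, config$n_f,
            s_alpha = s_alpha_map(config$s_gain, config$s_exponent))
}

config_generator <- function(config) {
  generator_params(
    hyper = hyperparameters(k_stay = config$k_stay),
    error_rate = config$error_rate,
    outlier_rate = config$outlier_rate,
    outlier_scale = config$outlier_scale,
    rs_floor = config$rs_floor
  )
}

#' Run the full synthetic study
#'
#' Simulates a cohort on the volatility-manipulated design, fits the flexible
#' control model (EM over the RS emission) and the one- and two-LR fixed
#' comparators to every subject, computes per-subject BICs under both the
#' reaction-speed and the congruency objectives (re-selecting the fixed-LR
#' models per objective), runs the random-effects group model selection for
#' each objective, and estimates the group-level residualized behavioural
#' GLM.
#'
#' @param config A [study_config()].
#' @param out_dir Optional directory; when given, the configuration, the BIC
#'   table, the model-selection summaries and the GLM effects are written
#'   there as JSON/CSV, each file tagged with the configuration hash and
#'   seed.
#' @param progress Print per-stage progress to stderr.
#' @return List of class `study_result` with elements `config`, `hash`,
#'   `subjects` (per-subject fits: flexible hyperparameters, fixed LRs,
#'   BICs), `bic_rs` and `bic_cong` (subjects x models matrices),
#'   `bms_rs`, `bms_cong` ([group_bms()] results), `glm`
#'   ([glm_group_effects()] result) and `cohort` (the simulated subjects
#'   with fitted traces attached).
#' @export
run_study <- function(config = study_config(), out_dir = NULL,
                      progress = interactive()) {
  t0 <- Sys.time()
  say <- function(...) {
    if (progress) {
      message(sprintf("[%5.1fs] ", as.numeric(Sys.time() - t0, units = "secs")),
              ...)
    }
  }
  hash <- config_hash(config)
  grid <- config_grid(config)
  gen <- config_generator(config)
  lrs <- lr_grid(config$lr_from, config$lr_to, config$lr_by)

  say("simulating ", config$n_subjects, " subjects (seed ", config$seed, ")")
  cohort <- simulate_cohort(config$n_subjects, seed = config$seed,
                            params = gen, jitter = config$jitter, grid = grid)

  models <- c("flexible", "fixed_1lr", "fixed_2lr")
  bic_rs_mat <- bic_cong_mat <- matrix(
    NA_real_, length(cohort), length(models),
    dimnames = list(vapply(cohort, `[[`, "", "subject_id"), models)
  )
  subjects <- vector("list", length(cohort))
  for (i in seq_along(cohort)) {
    sub <- cohort[[i]]
    say("fitting subject ", sub$subject_id)
    fit <- fit_flexible_em(sub$trials, grid = grid, k_stay = config$k_stay,
                           tol = config$em_tol,
                           max_iter = config$em_max_iter)
    valid <- !is.na(sub$trials$rs)
    res <- profiled_rs_residuals(sub$trials$rs[valid],
                                 fit$trace$f_hat[valid],
                                 sub$trials$congruency[valid])
    bic_rs_mat[i, "flexible"] <- bic_rs(res, n_params = 0L)
    bic_cong_mat[i, "flexible"] <- bic_congruency(
      fit$trace$f_hat, sub$trials$congruency, n_params = 0L)

    f1_rs <- search_fixed_lr(sub$trials, 1L, "rs", grid = lrs)
    f2_rs <- search_fixed_lr(sub$trials, 2L, "rs", grid = lrs)
    f1_cg <- search_fixed_lr(sub$trials, 1L, "congruency", grid = lrs)
    f2_cg <- search_fixed_lr(sub$trials, 2L, "congruency", grid = lrs)
    bic_rs_mat[i, "fixed_1lr"] <- f1_rs$bic_rs
    bic_rs_mat[i, "fixed_2lr"] <- f2_rs$bic_rs
    bic_cong_mat[i, "fixed_1lr"] <- f1_cg$bic_cong
    bic_cong_mat[i, "fixed_2lr"] <- f2_cg$bic_cong

    cohort[[i]]$trace <- fit$trace
    subjects[[i]] <- list(
      subject_id = sub$subject_id,
      flexible = list(hyper = fit$hyper, n_iter = fit$n_iter,
                      converged = fit$converged,
                      objective = fit$objective),
      fixed_1lr = list(rs = f1_rs$lrs, congruency = f1_cg$lrs),
      fixed_2lr = list(rs = f2_rs$lrs, congruency = f2_cg$lrs)
    )
  }

  say("group model selection")
  bms_rs <- group_bms(bic_rs_mat, mc_samples = config$mc_samples,
                      seed = config$seed + 1L)
  bms_cong <- group_bms(bic_cong_mat, mc_samples = config$mc_samples,
                        seed = config$seed + 2L)

  say("behavioural GLM")
  glm <- glm_group_effects(cohort)

  result <- structure(
    list(config = config, hash = hash, subjects = subjects,
         bic_rs = bic_rs_mat, bic_cong = bic_cong_mat,
         bms_rs = bms_rs, bms_cong = bms_cong, glm = glm,
         cohort = cohort),
    class = "study_result"
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    tag <- sprintf("%s_seed%d", hash, config$seed)
    write_config(config, file.path(out_dir, sprintf("config_%s.json", tag)))
    write.csv(data.frame(subject_id = rownames(bic_rs_mat),
                         bic_rs_mat,
                         `colnames<-`(bic_cong_mat,
                                      paste0(models, "_cong"))),
              file.path(out_dir, sprintf("bic_%s.csv", tag)),
              row.names = FALSE)
    jsonlite::write_json(
      list(
        rs = list(exceedance = as.list(bms_rs$exceedance),
                  expected_frequencies = as.list(bms_rs$expected_frequencies)),
        congruency = list(
          exceedance = as.list(bms_cong$exceedance),
          expected_frequencies = as.list(bms_cong$expected_frequencies))
      ),
      file.path(out_dir, sprintf("model_comparison_%s.json", tag)),
      auto_unbox = TRUE, digits = NA)
    write.csv(glm$effects,
              file.path(out_dir, sprintf("glm_effects_%s.csv", tag)),
              row.names = FALSE)
  }
  say("done")
  result
}

#' @export
print.study_result <- function(x, ...) {
  cat("Synthetic study (", x$config$n_subjects, " subjects, seed ",
      x$config$seed, ", config ", x$hash, ")\n\n", sep = "")
  cat("Exceedance probabilities (RS objective):\n")
  print(round(x$bms_rs$exceedance, 4))
  cat("Exceedance probabilities (congruency objective):\n")
  print(round(x$bms_cong$exceedance, 4))
  cat("\nGroup GLM effects on reaction speed:\n")
  print(x$glm$effects, row.names = FALSE, digits = 3)
  invisible(x)
}
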