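#' Read and write trial tables
#'
#' Trial tables are exchanged as UTF-8 CSV with columns `subject_id`,
#' `run_index`, `run_type`, `block_index`, `trial_index`, `congruency`,
#' `correct`, `rt_ms`, `rs`, `excluded`, `exclusion_reason`. RT is stored in
#' milliseconds on disk and as seconds (`rt`) in memory; RS is in 1/s.
#'
#' @param trials In-memory trial table (e.g. from [simulate_subject()]).
#' @param path File path.
#' @return `write_trials()` returns `path` invisibly; `read_trials()` returns
#'   the trial table with `rt` in seconds.
#' @export
write_trials <- function(trials, path) {
  out <- data.frame(
    subject_id = trials$subject_id,
    run_index = trials$run_index,
    run_type = trials$run_type,
    block_index = trials$block_index,
    trial_index = trials$trial_index,
    congruency = trials$congruency,
    correct = trials$correct,
    rt_ms = round(trials$rt * 1000, 6),
    rs = trials$rs,
    excluded = if ("excluded" %in% names(trials)) trials$excluded else FALSE,
    exclusion_reason = if ("exclusion_reason" %in% names(trials)) {
      trials$exclusion_reason
    } else {
      "none"
    }
  )
  write.csv(out, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  tab <- read.csv(path, fileEncoding = "UTF-8")
  tab$rt <- tab$rt_ms / 1000
  tab$rt_ms <- NULL
  tab
}

#' Write a model trace as CSV
#'
#' @param trace A `model_trace` from [filter_trials()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  keep <- c("trial", "congruency", "alpha_hat", "f_hat", "est_uncertainty",
            "cpe", "pc_x_cong")
  write.csv(as.data.frame(trace)[, keep], path, row.names = FALSE,
            fileEncoding = "UTF-8")
  invisible(path)
}
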