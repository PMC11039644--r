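#' Export trial-by-trial prediction errors as modulator event files
#'
#' Computes the prediction-error trajectory of a session under fitted
#' parameters and formats it as an events table for a first-level
#' neuroimaging model: one `feedback` row per answered trial with onset
#' at feedback presentation, duration equal to the feedback duration,
#' and the prediction error as parametric modulator; plus one
#' `no_response` row per missed trial with an empty modulator (these
#' feed the separate regressor of no interest). Modulators are
#' mean-centered across feedback rows by default.
#'
#' @param session an `rl_session` with feedback onsets.
#' @param spec the fitted `rl_model_spec`.
#' @param params the session's fitted `rl_params`.
#' @param mean_center center the modulator column to zero mean.
#' @param path optional output path; if given, the table is written as a
#'   tab-separated events file (`n/a` for empty modulators).
#' @return an object of class `pe_events`: a data frame with columns
#'   onset, duration, trial_type, modulator, trial, and attributes
#'   `subject_id`, `session_label`, `model`, `params`, `mean_centered`.
#' @export
export_pe_events <- function(session, spec, params, mean_center = TRUE,
                             path = NULL) {
  tr <- session$trials
  if (any(!is.finite(tr$onset_feedback)))
    stop("session lacks feedback onsets", call. = FALSE)
  traj <- session_loglik(spec, params, session)
  ans <- !is.na(tr$choice)
  mod <- traj$trajectory$pe[ans]
  if (mean_center) mod <- mod - mean(mod)
  ev <- data.frame(onset = tr$onset_feedback[ans],
                   duration = session$config$feedback_duration,
                   trial_type = "feedback",
                   modulator = mod,
                   trial = tr$trial[ans],
                   stringsAsFactors = FALSE)
  if (any(!ans)) {
    ev <- rbind(ev, data.frame(onset = tr$onset_feedback[!ans],
                               duration = session$config$feedback_duration,
                               trial_type = "no_response",
                               modulator = NA_real_,
                               trial = tr$trial[!ans],
                               stringsAsFactors = FALSE))
    ev <- ev[order(ev$onset), ]
    rownames(ev) <- NULL
  }
  attr(ev, "subject_id") <- session$subject_id
  attr(ev, "session_label") <- session$session_label
  attr(ev, "model") <- spec$name
  attr(ev, "params") <- constrain_params(spec, params)
  attr(ev, "mean_centered") <- mean_center
  class(ev) <- c("pe_events", "data.frame")
  if (!is.null(path)) write_pe_events(ev, path)
  ev
}

#' Write an events table to a tab-separated file
#'
#' @param events a `pe_events` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pe_events <- function(events, path) {
  out <- as.data.frame(events)
  out$onset <- sprintf("%.6f", out$onset)
  out$duration <- sprintf("%.6f", out$duration)
  out$modulator <- ifelse(is.na(out$modulator), "n/a",
                          sprintf("%.10f", out$modulator))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export events files for every fitted session of a cohort
#'
#' @param sessions list of `rl_session`.
#' @param fit an `em_fit` of the chosen model covering the sessions.
#' @param dir output directory; files are named
#'   `<subject_id>_<session_label>_events.tsv`.
#' @param mean_center passed to [export_pe_events()].
#' @return invisible character vector of written paths.
#' @export
export_cohort_events <- function(sessions, fit, dir, mean_center = TRUE) {
  stopifnot(inherits(fit, "em_fit"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  key <- paste(vapply(fit$subject_fits, `[[`, "", "subject_id"),
               vapply(fit$subject_fits, `[[`, "", "session_label"))
  paths <- vapply(sessions, function(s) {
    i <- match(paste(s$subject_id, s$session_label), key)
    if (is.na(i)) stop("no fit for session ", s$subject_id, "/",
                       s$session_label, call. = FALSE)
    p <- file.path(dir, paste0(s$subject_id, "_", s$session_label,
                               "_events.tsv"))
    export_pe_events(s, fit$spec, fit$subject_fits[[i]]$params,
                     mean_center = mean_center, path = p)
    p
  }, "")
  invisible(paths)
}
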