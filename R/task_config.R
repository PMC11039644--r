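#' Task configuration for the probabilistic reversal-learning task
#'
#' Bundles every structural constant of the task: trial count, reward
#' contingency, the learning criterion that arms the reversal hazard, the
#' hazard itself, feedback amounts, payout clamp, and presentation timing.
#' Defaults reproduce the in-scanner task: 200 trials, 80/20 dependent
#' contingencies, a 5-of-6 learning criterion, a 20% per-trial reversal
#' hazard once armed, +/-10 SEK feedback, payout clamped to 30--300 SEK,
#' 1.5 s stimulus window, 1 s feedback, and a jittered inter-trial
#' interval drawn from a truncated exponential on 1.5--6.5 s.
#'
#' @param n_trials number of trials per session.
#' @param p_reward_good probability that choosing the currently good
#'   stimulus yields a win (the other stimulus wins with its complement).
#' @param criterion_hits,criterion_window the learning criterion:
#'   `criterion_hits` correct choices among the last `criterion_window`
#'   answered trials arms the reversal hazard.
#' @param reversal_hazard per-trial probability of a contingency reversal
#'   while the criterion is armed.
#' @param win_amount,loss_amount feedback amounts in SEK.
#' @param payout_min,payout_max clamp applied to the session's summed
#'   winnings, in SEK.
#' @param stim_duration,feedback_duration presentation durations in
#'   seconds; `stim_duration` is also the response window.
#' @param iti_range lower and upper bound (seconds) of the inter-trial
#'   interval.
#' @param iti_rate rate (1/s) of the exponential from which the ITI is
#'   drawn before truncation to `iti_range`.
#' @param miss_probability per-trial probability that a simulated agent
#'   fails to respond in time. Missed trials produce no outcome, no value
#'   update, and do not enter the criterion window.
#'
#' @return an object of class `task_config` (a validated named list).
#' @examples
#' cfg <- task_config()
#' cfg$n_trials
#' @export
task_config <- function(n_trials = 200L,
                        p_reward_good = 0.8,
                        criterion_hits = 5L,
                        criterion_window = 6L,
                        reversal_hazard = 0.2,
                        win_amount = 10,
                        loss_amount = -10,
                        payout_min = 30,
                        payout_max = 300,
                        stim_duration = 1.5,
                        feedback_duration = 1.0,
                        iti_range = c(1.5, 6.5),
                        iti_rate = 1.0,
                        miss_probability = 0) {
  cfg <- list(n_trials = as.integer(n_trials),
              p_reward_good = p_reward_good,
              criterion_hits = as.integer(criterion_hits),
              criterion_window = as.integer(criterion_window),
              reversal_hazard = reversal_hazard,
              win_amount = win_amount,
              loss_amount = loss_amount,
              payout_min = payout_min,
              payout_max = payout_max,
              stim_duration = stim_duration,
              feedback_duration = feedback_duration,
              iti_range = as.numeric(iti_range),
              iti_rate = iti_rate,
              miss_probability = miss_probability)
  class(cfg) <- "task_config"
  validate_task_config(cfg)
}

validate_task_config <- function(cfg) {
  if (!is.numeric(cfg$n_trials) || cfg$n_trials < 1)
    stop("task config: n_trials must be a positive count", call. = FALSE)
  if (!(cfg$p_reward_good > 0 && cfg$p_reward_good < 1))
    stop("task config: p_reward_good must lie strictly in (0, 1)", call. = FALSE)
  if (cfg$criterion_hits > cfg$criterion_window || cfg$criterion_hits < 1)
    stop("task config: need 1 <= criterion_hits <= criterion_window", call. = FALSE)
  if (cfg$reversal_hazard < 0 || cfg$reversal_hazard > 1)
    stop("task config: reversal_hazard must be a probability", call. = FALSE)
  if (cfg$payout_min > cfg$payout_max)
    stop("task config: payout_min must not exceed payout_max", call. = FALSE)
  if (length(cfg$iti_range) != 2 || cfg$iti_range[1] >= cfg$iti_range[2])
    stop("task config: iti_range must be an increasing pair", call. = FALSE)
  if (cfg$stim_duration <= 0 || cfg$feedback_duration <= 0 || cfg$iti_rate <= 0)
    stop("task config: durations and iti_rate must be positive", call. = FALSE)
  if (cfg$miss_probability < 0 || cfg$miss_probability >= 1)
    stop("task config: miss_probability must lie in [0, 1)", call. = FALSE)
  cfg
}

#' @export
print.task_config <- function(x, ...) {
  cat("Probabilistic reversal-learning task configuration\n")
  cat(sprintf("  %d trials; P(win | correct) = %.2f\n", x$n_trials, x$p_reward_good))
  cat(sprintf("  criterion %d of last %d arms a %.0f%% per-trial reversal hazard\n",
              x$criterion_hits, x$criterion_window, 100 * x$reversal_hazard))
  cat(sprintf("  feedback %+g / %+g SEK, payout clamped to [%g, %g] SEK\n",
              x$win_amount, x$loss_amount, x$payout_min, x$payout_max))
  cat(sprintf("  stimulus %.1f s, feedback %.1f s, ITI trunc-exp(%.1f) on [%.1f, %.1f] s\n",
              x$stim_duration, x$feedback_duration, x$iti_rate,
              x$iti_range[1], x$iti_range[2]))
  invisible(x)
}

#' Read or write a task configuration as a key: value text file
#'
#' @param path file path.
#' @param cfg a [task_config()] object.
#' @return `read_task_config` returns a `task_config`; `write_task_config`
#'   returns `path` invisibly.
#' @export
read_task_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, ":", fixed = TRUE)
  keys <- vapply(kv, function(x) trimws(x[[1]]), "")
  vals <- lapply(kv, function(x) {
    v <- trimws(paste(x[-1], collapse = ":"))
    as.numeric(strsplit(v, ",", fixed = TRUE)[[1]])
  })
  names(vals) <- keys
  do.call(task_config, vals)
}

#' @rdname read_task_config
#' @export
write_task_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "task_config"))
  lines <- vapply(names(unclass(cfg)), function(k) {
    paste0(k, ": ", paste(format(cfg[[k]], scientific = FALSE), collapse = ", "))
  }, "")
  writeLines(lines, path)
  invisible(path)
}
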