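#' Reversal state machine: one per-trial transition
#'
#' The learning criterion arms the reversal hazard once at least
#' `criterion_hits` of the last `criterion_window` answered trials were
#' correct; the criterion is evaluable only once a full window of
#' answered trials exists. While armed, a reversal fires with probability
#' `reversal_hazard` on each trial; a fired reversal disarms the state,
#' and the armed state is otherwise re-evaluated every trial from the
#' sliding window (so losing the criterion also disarms it).
#'
#' This is a pure function: `armed` is the state entering the current
#' trial, `recent_correct` holds the correctness flags of all answered
#' trials up to and including the current one, and `draw` is the uniform
#' variate consumed by the hazard.
#'
#' @param recent_correct logical vector of correctness flags of all
#'   answered trials so far.
#' @param armed logical; hazard state entering the current trial.
#' @param config a [task_config()].
#' @param draw a uniform(0,1) variate.
#' @return list with `reverse_now` (did a reversal fire before this
#'   trial) and `armed` (state entering the next trial).
#' @examples
#' cfg <- task_config()
#' update_reversal_state(c(1, 0, 1, 1, 1, 1) == 1, FALSE, cfg, 0.9)$armed
#' @export
update_reversal_state <- function(recent_correct, armed, config, draw) {
  reverse_now <- isTRUE(armed) && draw < config$reversal_hazard
  n <- length(recent_correct)
  w <- config$criterion_window
  criterion_met <- n >= w &&
    sum(recent_correct[(n - w + 1L):n]) >= config$criterion_hits
  list(reverse_now = reverse_now, armed = criterion_met && !reverse_now)
}

# Inverse-CDF draw from an exponential truncated to [lo, hi].
sample_iti <- function(config, u) {
  lo <- config$iti_range[1]
  hi <- config$iti_range[2]
  r <- config$iti_rate
  lo - log(1 - u * (1 - exp(-r * (hi - lo)))) / r
}

#' Simulate one session of the reversal-learning task
#'
#' Plays a Q-learning agent (or a scripted policy) through the task.
#' Each trial: while the criterion is armed, the contingency reverses
#' with probability `reversal_hazard`; the agent chooses by softmax over
#' its current Q-values (or misses with probability `miss_probability`);
#' choosing the currently good stimulus wins with probability
#' `p_reward_good`, the other stimulus with its complement; the agent
#' then updates its values and the criterion window is re-evaluated.
#'
#' @param config a [task_config()].
#' @param spec an `rl_model_spec` describing the agent (ignored for
#'   scripted policies).
#' @param params an `rl_params` with the agent's natural-space
#'   parameters (ignored for scripted policies).
#' @param seed integer seed; the session is deterministic given it.
#' @param subject_id,session_label identifiers stored with the session.
#' @param policy `"model"` for a Q-learning agent; `"good"` for a
#'   scripted agent that always chooses the currently good stimulus
#'   (used for contingency audits); `"random"` for unbiased coin-flip
#'   choices.
#' @return an object of class `rl_session`: a list with `subject_id`,
#'   `session_label`, `config` and a `trials` data frame (trial,
#'   good_stimulus, choice, outcome, correct, criterion_armed, reversal,
#'   onset_stim, onset_feedback, iti). Missed trials have `NA` choice,
#'   outcome and correct.
#' @export
generate_session <- function(config, spec = model_spec(), params = NULL,
                             seed = NULL,
                             subject_id = "sim01",
                             session_label = "synthetic",
                             policy = c("model", "good", "random")) {
  policy <- match.arg(policy)
  validate_task_config(config)
  if (policy == "model") {
    if (is.null(params)) stop("a model agent needs params", call. = FALSE)
    stopifnot(inherits(spec, "rl_model_spec"), inherits(params, "rl_params"))
    params <- constrain_params(spec, params)
    if (!all(vapply(params, is.finite, TRUE)))
      stop("agent parameters must be finite", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)

  n <- config$n_trials
  good <- character(n); choice <- character(n); outcome <- character(n)
  correct <- logical(n); armed_rec <- logical(n); reversal <- logical(n)
  onset_stim <- numeric(n); onset_feedback <- numeric(n); iti <- numeric(n)

  cur_good <- sample(c("A", "B"), 1L)
  armed <- FALSE
  flags <- logical(0)
  q <- if (policy == "model") c(params$q_init, 0) else c(0, 0)
  t_clock <- 0

  for (t in seq_len(n)) {
    draw_rev <- runif(1)
    draw_miss <- runif(1)
    draw_choice <- runif(1)
    draw_out <- runif(1)
    draw_iti <- runif(1)

    reverse_now <- armed && draw_rev < config$reversal_hazard
    if (reverse_now) cur_good <- if (cur_good == "A") "B" else "A"
    armed_rec[t] <- armed
    reversal[t] <- reverse_now
    good[t] <- cur_good

    missed <- draw_miss < config$miss_probability
    if (missed) {
      choice[t] <- NA_character_; outcome[t] <- NA_character_
      correct[t] <- NA
    } else {
      ch <- switch(policy,
                   model  = simulate_choice(q, draw_choice),
                   good   = cur_good,
                   random = if (draw_choice < 0.5) "A" else "B")
      is_correct <- ch == cur_good
      p_win <- if (is_correct) config$p_reward_good else 1 - config$p_reward_good
      out <- if (draw_out < p_win) "win" else "loss"
      choice[t] <- ch; outcome[t] <- out; correct[t] <- is_correct
      if (policy == "model") q <- ql_step(q, ch, out, params, spec)
      flags <- c(flags, is_correct)
    }

    st <- update_reversal_state(flags, armed, config, draw_rev)
    armed <- st$armed

    onset_stim[t] <- t_clock
    onset_feedback[t] <- t_clock + config$stim_duration
    iti[t] <- sample_iti(config, draw_iti)
    t_clock <- onset_feedback[t] + config$feedback_duration + iti[t]
  }

  structure(list(
    subject_id = subject_id,
    session_label = session_label,
    config = config,
    trials = data.frame(trial = seq_len(n), good_stimulus = good,
                        choice = choice, outcome = outcome,
                        correct = correct, criterion_armed = armed_rec,
                        reversal = reversal, onset_stim = onset_stim,
                        onset_feedback = onset_feedback, iti = iti,
                        stringsAsFactors = FALSE)),
    class = "rl_session")
}

#' @export
print.rl_session <- function(x, ...) {
  tr <- x$trials
  cat(sprintf("rl_session %s / %s: %d trials, %d answered, %d reversals\n",
              x$subject_id, x$session_label, nrow(tr),
              sum(!is.na(tr$choice)), sum(tr$reversal)))
  invisible(x)
}

#' Session payout in SEK
#'
#' Sums the per-trial feedback amounts and clamps the total to the
#' configured payout bounds.
#'
#' @param session an `rl_session`.
#' @return payout in SEK.
#' @export
compute_payout <- function(session) {
  cfg <- session$config
  out <- session$trials$outcome
  raw <- sum(out == "win", na.rm = TRUE) * cfg$win_amount +
    sum(out == "loss", na.rm = TRUE) * cfg$loss_amount
  min(max(raw, cfg$payout_min), cfg$payout_max)
}

#' Default group-level generating distribution of the synthetic cohort
#'
#' Inference-space means and standard deviations of the simulated
#' population: mean learning-rate logit -0.85 (learning rate about
#' 0.30), reward sensitivity 2.0 and punishment sensitivity -1.0
#' (matching the scale of group means observed in healthy volunteers on
#' this task), initial-value bias 0; SDs (0.8, 0.87, 0.5, 0.3).
#'
#' @return list with `mean` and `sd`, named inference-space vectors.
#' @export
default_population <- function() {
  list(mean = c(a = -0.85, b_rew = 2.0, b_pun = -1.0, q0 = 0),
       sd   = c(a = 0.8, b_rew = 0.87, b_pun = 0.5, q0 = 0.3))
}

#' Simulate a two-session within-subject cohort
#'
#' Emulates the crossover design: each subject contributes one session
#' per label, with session-level parameters drawn independently from the
#' group Gaussian in inference space and mapped to natural space. The
#' generating (true) parameters are returned alongside for parameter-
#' recovery studies.
#'
#' @param n_subjects number of subjects (>= 2).
#' @param group_mean,group_sd named inference-space vectors over the
#'   model's active coordinates; defaults from [default_population()].
#' @param spec agent model variant (default: the full double-update,
#'   separate-sensitivity, free-initial-value model).
#' @param config a [task_config()].
#' @param seed integer seed.
#' @param session_labels labels of the two sessions.
#' @return an object of class `rl_cohort`: list with `sessions` (list of
#'   `rl_session`) and `true_params` (data frame: subject_id,
#'   session_label, alpha, beta_rew, beta_pun, q_init and the
#'   inference-space draws).
#' @export
generate_cohort <- function(n_subjects = 30L,
                            group_mean = default_population()$mean,
                            group_sd = default_population()$sd,
                            spec = model_spec(),
                            config = task_config(),
                            seed = 1L,
                            session_labels = c("placebo", "ghrelin")) {
  if (n_subjects < 2) stop("need at least 2 subjects", call. = FALSE)
  ap <- active_params(spec)
  group_mean <- group_mean[ap]; group_sd <- group_sd[ap]
  if (any(is.na(group_mean)) || any(is.na(group_sd)))
    stop("group_mean/group_sd must cover the model's active parameters",
         call. = FALSE)
  if (any(group_sd <= 0))
    stop("group_sd must be positive elementwise", call. = FALSE)
  set.seed(seed)

  sessions <- list(); rows <- list(); k <- 0L
  for (i in seq_len(n_subjects)) {
    sid <- sprintf("sub%02d", i)
    for (lab in session_labels) {
      v <- rnorm(length(ap), group_mean, group_sd); names(v) <- ap
      pars <- to_natural(spec, v)
      sess_seed <- sample.int(.Machine$integer.max, 1L)
      k <- k + 1L
      sessions[[k]] <- generate_session(config, spec, pars, seed = sess_seed,
                                        subject_id = sid, session_label = lab)
      rows[[k]] <- data.frame(subject_id = sid, session_label = lab,
                              alpha = pars$alpha, beta_rew = pars$beta_rew,
                              beta_pun = pars$beta_pun, q_init = pars$q_init,
                              t(v), stringsAsFactors = FALSE)
    }
  }
  structure(list(sessions = sessions,
                 true_params = do.call(rbind, rows),
                 spec = spec, config = config),
            class = "rl_cohort")
}

#' Read and write session tables
#'
#' Sessions are stored as a tab-separated table with one row per trial
#' and columns subject_id, session_label, trial, good_stimulus, choice,
#' outcome, correct, reversal, onset_stim, onset_feedback, iti. Missed
#' trials carry `NA` in choice/outcome/correct.
#'
#' @param sessions a list of `rl_session` objects or an `rl_cohort`.
#' @param path file path.
#' @param config the [task_config()] to attach on reading.
#' @return `write_sessions` returns `path` invisibly; `read_sessions`
#'   returns a list of `rl_session` objects.
#' @export
write_sessions <- function(sessions, path) {
  if (inherits(sessions, "rl_cohort")) sessions <- sessions$sessions
  if (inherits(sessions, "rl_session")) sessions <- list(sessions)
  tab <- do.call(rbind, lapply(sessions, function(s) {
    tr <- s$trials
    data.frame(subject_id = s$subject_id, session_label = s$session_label,
               trial = tr$trial, good_stimulus = tr$good_stimulus,
               choice = tr$choice, outcome = tr$outcome,
               correct = tr$correct, reversal = tr$reversal,
               onset_stim = sprintf("%.6f", tr$onset_stim),
               onset_feedback = sprintf("%.6f", tr$onset_feedback),
               iti = sprintf("%.6f", tr$iti), stringsAsFactors = FALSE)
  }))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sessions
#' @export
read_sessions <- function(path, config = task_config()) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "session_label", "trial", "good_stimulus",
            "choice", "outcome", "correct", "reversal",
            "onset_stim", "onset_feedback", "iti")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols))
    stop("session table lacks columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  keys <- unique(tab[c("subject_id", "session_label")])
  lapply(seq_len(nrow(keys)), function(i) {
    sub <- tab[tab$subject_id == keys$subject_id[i] &
                 tab$session_label == keys$session_label[i], ]
    sub <- sub[order(sub$trial), ]
    structure(list(
      subject_id = keys$subject_id[i],
      session_label = keys$session_label[i],
      config = config,
      trials = data.frame(trial = sub$trial,
                          good_stimulus = sub$good_stimulus,
                          choice = sub$choice, outcome = sub$outcome,
                          correct = as.logical(sub$correct),
                          criterion_armed = NA,
                          reversal = as.logical(sub$reversal),
                          onset_stim = as.numeric(sub$onset_stim),
                          onset_feedback = as.numeric(sub$onset_feedback),
                          iti = as.numeric(sub$iti),
                          stringsAsFactors = FALSE)),
      class = "rl_session")
  })
}

#' Write the true-parameter sidecar table of a synthetic cohort
#'
#' @param cohort an `rl_cohort`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_true_params <- function(cohort, path) {
  stopifnot(inherits(cohort, "rl_cohort"))
  cols <- c("subject_id", "session_label", "alpha", "beta_rew",
            "beta_pun", "q_init")
  write.table(cohort$true_params[cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
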