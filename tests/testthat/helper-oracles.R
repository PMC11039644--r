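# Independent oracles and scripted-session builders used across tests.
# The likelihood oracle is a literal per-trial loop over the model
# equations, deliberately sharing no code with the package internals.

naive_loglik <- function(double_update, separate_sensitivities, free_q_init,
                         alpha, beta_rew, beta_pun, q_init,
                         choice, outcome) {
  if (!separate_sensitivities) beta_pun <- -beta_rew
  if (!free_q_init) q_init <- 0
  q <- c(q_init, 0)
  ll <- 0
  for (t in seq_along(choice)) {
    if (is.na(choice[t])) next
    pA <- exp(q[1]) / (exp(q[1]) + exp(q[2]))
    p <- if (choice[t] == "A") pA else 1 - pA
    ll <- ll + log(p)
    R <- if (outcome[t] == "win") beta_rew else beta_pun
    i <- if (choice[t] == "A") 1L else 2L
    u <- 3L - i
    q[i] <- q[i] + alpha * (R - q[i])
    if (double_update) q[u] <- q[u] + alpha * (-R - q[u])
  }
  ll
}

# Build an rl_session from scripted choice/outcome vectors.
scripted_session <- function(choice, outcome,
                             good = rep("A", length(choice)),
                             reversal = rep(FALSE, length(choice)),
                             subject_id = "scripted",
                             session_label = "synthetic",
                             config = task_config(n_trials = length(choice))) {
  n <- length(choice)
  onset_stim <- (seq_len(n) - 1) * 6
  structure(list(
    subject_id = subject_id, session_label = session_label, config = config,
    trials = data.frame(
      trial = seq_len(n), good_stimulus = good, choice = choice,
      outcome = outcome,
      correct = ifelse(is.na(choice), NA, choice == good),
      criterion_armed = FALSE, reversal = reversal,
      onset_stim = onset_stim,
      onset_feedback = onset_stim + config$stim_duration,
      iti = rep(2, n), stringsAsFactors = FALSE)),
    class = "rl_session")
}

# Random scripted session (choices and outcomes unconstrained by the
# task's contingencies; sufficient for likelihood evaluation).
random_session <- function(n = 200, p_miss = 0) {
  miss <- runif(n) < p_miss
  choice <- ifelse(miss, NA, ifelse(runif(n) < 0.5, "A", "B"))
  outcome <- ifelse(miss, NA, ifelse(runif(n) < 0.5, "win", "loss"))
  scripted_session(choice, outcome)
}

random_params <- function() {
  parameter_set(alpha = runif(1, 0.05, 0.95),
                beta_rew = rnorm(1, 2, 1),
                beta_pun = rnorm(1, -1, 1),
                q_init = rnorm(1, 0, 0.5))
}
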