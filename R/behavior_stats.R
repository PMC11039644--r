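#' Model-free behavioral summary of one session
#'
#' Counts are computed over answered trials only: percent correct
#' (choosing the currently good stimulus), number of switches (a choice
#' differing from the previous answered trial's choice), number of
#' reversals reached, and number of missed trials.
#'
#' @param session an `rl_session`.
#' @return data frame with one row: subject_id, session_label,
#'   pct_correct, n_switches, n_reversals, n_missed, n_answered.
#' @export
summarize_session <- function(session) {
  tr <- session$trials
  ans <- !is.na(tr$choice)
  if (!any(ans)) stop("session has no answered trials", call. = FALSE)
  ch <- tr$choice[ans]
  data.frame(subject_id = session$subject_id,
             session_label = session$session_label,
             pct_correct = 100 * mean(tr$correct[ans]),
             n_switches = sum(ch[-1] != ch[-length(ch)]),
             n_reversals = sum(tr$reversal),
             n_missed = sum(!ans),
             n_answered = sum(ans),
             stringsAsFactors = FALSE)
}

#' Exclude subjects with too few reversals
#'
#' A subject is removed (both sessions) if any of their sessions reached
#' fewer than `min_reversals` reversals.
#'
#' @param sessions list of `rl_session`, two per subject, or an
#'   `rl_cohort`.
#' @param min_reversals exclusion threshold (sessions with
#'   `n_reversals < min_reversals` fail).
#' @return list with `kept` (list of sessions), `excluded` (subject
#'   ids), and `log` (data frame of per-session reversal counts with an
#'   `excluded` flag).
#' @export
apply_exclusion <- function(sessions, min_reversals = 5L) {
  if (inherits(sessions, "rl_cohort")) sessions <- sessions$sessions
  summ <- do.call(rbind, lapply(sessions, summarize_session))
  bad_rows <- summ$n_reversals < min_reversals
  excluded <- unique(summ$subject_id[bad_rows])
  summ$excluded <- summ$subject_id %in% excluded
  keep <- vapply(sessions, function(s) !(s$subject_id %in% excluded), TRUE)
  list(kept = sessions[keep], excluded = excluded, log = summ)
}

#' Paired t test with the within-subject effect size
#'
#' Classic paired t on the differences `x - y`, with a two-sided p-value
#' on `n - 1` degrees of freedom and the paired-design effect size
#' Cohen's d = t / sqrt(n).
#'
#' @param x,y paired per-subject values of equal length >= 2.
#' @return data frame with one row: test, statistic (t), df, p_value,
#'   cohen_d, n.
#' @export
paired_t <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  d <- x - y
  n <- length(d)
  sdd <- sd(d)
  if (sdd == 0) {
    if (all(d == 0))
      return(data.frame(test = "paired_t", statistic = 0, df = n - 1,
                        p_value = 1, cohen_d = 0, n = n))
    stop("zero variance of nonzero differences: t undefined", call. = FALSE)
  }
  t_stat <- mean(d) / (sdd / sqrt(n))
  data.frame(test = "paired_t", statistic = t_stat, df = n - 1,
             p_value = 2 * pt(-abs(t_stat), df = n - 1),
             cohen_d = t_stat / sqrt(n), n = n)
}

#' Cohen's d for a paired design from the t statistic
#'
#' @param t_stat paired t statistic.
#' @param n number of pairs.
#' @return d = t / sqrt(n).
#' @export
cohen_d_paired <- function(t_stat, n) t_stat / sqrt(n)

#' Wilcoxon signed-rank test (normal approximation)
#'
#' Signed-rank test on paired differences with the conventions: zero
#' differences dropped, mid-ranks for tied absolute differences, normal
#' approximation with tie correction and no continuity correction, so
#' the statistic is reported as a z value.
#'
#' @param x,y paired values; alternatively pass the differences as `x`
#'   and leave `y` missing.
#' @return data frame with one row: test, statistic (z), W (sum of
#'   positive-signed ranks), p_value, n (non-zero pairs).
#' @export
wilcoxon_signed_rank <- function(x, y = NULL) {
  d <- if (is.null(y)) x else x - y
  d <- d[d != 0]
  n <- length(d)
  if (n < 1) stop("all differences are zero: W undefined", call. = FALSE)
  r <- rank(abs(d))
  w_pos <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  ties <- table(r)
  sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  z <- if (sig2 > 0) (w_pos - mu) / sqrt(sig2) else 0
  data.frame(test = "wilcoxon_signed_rank", statistic = z, W = w_pos,
             p_value = if (sig2 > 0) 2 * pnorm(-abs(z)) else 1, n = n)
}

#' Pearson correlation with a two-sided p-value
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return data frame with one row: test, r, df, p_value, n.
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (sd(x) == 0 || sd(y) == 0)
    stop("zero variance: correlation undefined", call. = FALSE)
  n <- length(x)
  r <- cor(x, y)
  t_stat <- r * sqrt((n - 2) / (1 - r^2))
  data.frame(test = "pearson", r = r, df = n - 2,
             p_value = if (abs(r) == 1) 0 else 2 * pt(-abs(t_stat), n - 2),
             n = n)
}

# Per-session switch probabilities after win and after loss feedback,
# over consecutive answered trials (missed trials break the chain).
session_switch_probs <- function(session) {
  tr <- session$trials
  ans <- which(!is.na(tr$choice))
  prev <- ans[-length(ans)]
  cur <- ans[-1]
  consecutive <- (cur - prev) == 1
  prev <- prev[consecutive]; cur <- cur[consecutive]
  switched <- tr$choice[cur] != tr$choice[prev]
  after_win <- tr$outcome[prev] == "win"
  data.frame(subject_id = session$subject_id,
             session_label = session$session_label,
             p_switch_after_win = if (any(after_win))
               mean(switched[after_win]) else NA_real_,
             p_switch_after_loss = if (any(!after_win))
               mean(switched[!after_win]) else NA_real_,
             stringsAsFactors = FALSE)
}

#' Change in switch behavior after wins versus after losses
#'
#' Exploratory feedback-sensitivity analysis for the crossover design:
#' per session, the probability of switching stimulus on the trial after
#' a win and after a loss; per subject, the session-contrast deltas
#' (second label minus first label) of both probabilities; and a paired
#' test contrasting the loss-delta against the win-delta. Subjects
#' lacking a cell (e.g. no answered post-loss trials) are dropped from
#' the contrast with a log entry.
#'
#' @param sessions list of `rl_session` covering both labels for each
#'   subject.
#' @param labels length-2 character vector giving the order of the
#'   contrast: deltas are `labels[2]` minus `labels[1]`.
#' @return list with `per_session` (switch probabilities), `per_subject`
#'   (delta_win, delta_loss), `contrast` (paired test of delta_loss vs
#'   delta_win), and `dropped` (subject ids excluded from the contrast).
#' @export
switch_feedback_analysis <- function(sessions,
                                     labels = c("placebo", "ghrelin")) {
  per <- do.call(rbind, lapply(sessions, session_switch_probs))
  a <- per[per$session_label == labels[1], ]
  b <- per[per$session_label == labels[2], ]
  common <- intersect(a$subject_id, b$subject_id)
  a <- a[match(common, a$subject_id), ]
  b <- b[match(common, b$subject_id), ]
  per_subject <- data.frame(
    subject_id = common,
    delta_win = b$p_switch_after_win - a$p_switch_after_win,
    delta_loss = b$p_switch_after_loss - a$p_switch_after_loss,
    stringsAsFactors = FALSE)
  ok <- stats::complete.cases(per_subject)
  dropped <- per_subject$subject_id[!ok]
  contrast <- paired_t(per_subject$delta_loss[ok], per_subject$delta_win[ok])
  list(per_session = per, per_subject = per_subject[ok, ],
       contrast = contrast, dropped = dropped)
}

#' Full behavioral and sensitivity comparison battery for a crossover
#' cohort
#'
#' Computes, per session label, means and SEMs of the behavioral
#' summaries and (if estimates are supplied) of the fitted
#' sensitivities, and compares labels within subject: paired t for
#' percent correct, percent switches, reward and punishment sensitivity;
#' Wilcoxon signed-rank for the number of reversals; Pearson
#' correlations between reward and punishment sensitivity within label
#' and of each sensitivity across labels.
#'
#' @param sessions list of `rl_session` (after exclusion), both labels
#'   per subject.
#' @param estimates optional per-session parameter table as in
#'   `em_fit$estimates`.
#' @param labels the two session labels, contrast `labels[2] - labels[1]`.
#' @return list with `descriptives` (long data frame: measure,
#'   session_label, mean, sem, n), `tests` (long data frame of paired
#'   comparisons), and `correlations` (data frame of Pearson results).
#' @export
behavior_battery <- function(sessions, estimates = NULL,
                             labels = c("placebo", "ghrelin")) {
  summ <- do.call(rbind, lapply(sessions, summarize_session))
  summ$pct_switches <- 100 * summ$n_switches / pmax(summ$n_answered - 1, 1)
  if (!is.null(estimates))
    summ <- merge(summ, estimates, by = c("subject_id", "session_label"),
                  sort = FALSE)
  measures <- c("pct_correct", "pct_switches", "n_reversals",
                intersect(c("beta_rew", "beta_pun", "alpha"), names(summ)))

  wide <- function(m) {
    a <- summ[summ$session_label == labels[1], c("subject_id", m)]
    b <- summ[summ$session_label == labels[2], c("subject_id", m)]
    common <- intersect(a$subject_id, b$subject_id)
    cbind(a[match(common, a$subject_id), m, drop = FALSE],
          stats::setNames(b[match(common, b$subject_id), m, drop = FALSE],
                          paste0(m, "_2")))
  }

  desc <- do.call(rbind, lapply(measures, function(m) {
    do.call(rbind, lapply(labels, function(l) {
      v <- summ[summ$session_label == l, m]
      data.frame(measure = m, session_label = l, mean = mean(v),
                 sem = sd(v) / sqrt(length(v)), n = length(v))
    }))
  }))

  tests <- do.call(rbind, lapply(measures, function(m) {
    w <- wide(m)
    x <- w[[2]]; y <- w[[1]]  # contrast labels[2] - labels[1]
    res <- if (m == "n_reversals") {
      r <- wilcoxon_signed_rank(x, y)
      data.frame(measure = m, test = r$test, statistic = r$statistic,
                 df = NA_real_, p_value = r$p_value, effect_size = NA_real_)
    } else {
      r <- paired_t(x, y)
      data.frame(measure = m, test = r$test, statistic = r$statistic,
                 df = r$df, p_value = r$p_value, effect_size = r$cohen_d)
    }
    res
  }))

  correlations <- NULL
  if (!is.null(estimates)) {
    within_label <- do.call(rbind, lapply(labels, function(l) {
      s <- summ[summ$session_label == l, ]
      r <- pearson_r(s$beta_rew, s$beta_pun)
      data.frame(pair = "beta_rew~beta_pun", session_label = l, r = r$r,
                 p_value = r$p_value, n = r$n)
    }))
    across <- do.call(rbind, lapply(c("beta_rew", "beta_pun"), function(m) {
      w <- wide(m)
      r <- pearson_r(w[[1]], w[[2]])
      data.frame(pair = paste0(m, ": ", labels[1], "~", labels[2]),
                 session_label = "both", r = r$r, p_value = r$p_value,
                 n = r$n)
    }))
    correlations <- rbind(within_label, across)
  }
  list(descriptives = desc, tests = tests, correlations = correlations)
}
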