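test_that("session summaries count over answered trials only", {
  # perfectly performing agent under a zero hazard: all correct, no switches
  s <- generate_session(task_config(reversal_hazard = 0), seed = 131,
                        policy = "good")
  summ <- summarize_session(s)
  expect_equal(summ$pct_correct, 100)
  expect_equal(summ$n_switches, 0L)
  expect_equal(summ$n_reversals, 0L)
  # strict alternation: every consecutive pair is a switch
  alt <- scripted_session(rep(c("A", "B"), 100), rep("win", 200))
  expect_equal(summarize_session(alt)$n_switches, 199L)
  # scripted 10-trial session with 7 correct choices
  s10 <- scripted_session(c("A", "A", "B", "A", "A", "A", "B", "A", "B", "A"),
                          rep(c("win", "loss"), 5))
  expect_equal(summarize_session(s10)$pct_correct, 70)
  expect_error(summarize_session(
    scripted_session(rep(NA_character_, 3), rep(NA_character_, 3))),
    "no answered")
})

test_that("summaries are stable under relabeling of the stimuli", {
  s <- generate_session(task_config(), model_spec(),
                        parameter_set(0.3, 2, -1, 0), seed = 132)
  flip <- function(x) chartr("AB", "BA", x)
  s2 <- s
  s2$trials$choice <- flip(s2$trials$choice)
  s2$trials$good_stimulus <- flip(s2$trials$good_stimulus)
  expect_equal(summarize_session(s2)[-(1:2)], summarize_session(s)[-(1:2)])
})

test_that("subjects failing the reversal criterion are excluded with both sessions", {
  mk <- function(id, lab, n_rev) {
    s <- scripted_session(rep(c("A", "B"), 20), rep("win", 40),
                          subject_id = id, session_label = lab)
    s$trials$reversal <- c(rep(TRUE, n_rev), rep(FALSE, 40 - n_rev))
    s
  }
  sessions <- c(
    list(mk("s1", "placebo", 1), mk("s1", "ghrelin", 3)),    # excluded
    list(mk("s2", "placebo", 5), mk("s2", "ghrelin", 5)),    # boundary: kept
    list(mk("s3", "placebo", 12), mk("s3", "ghrelin", 4)))   # one bad session
  res <- apply_exclusion(sessions)
  expect_setequal(res$excluded, c("s1", "s3"))
  expect_length(res$kept, 2L)
  expect_identical(unique(vapply(res$kept, `[[`, "", "subject_id")), "s2")
  expect_identical(nrow(res$log), 6L)
})

test_that("the paired t statistic, p and effect size follow the classic formulas", {
  # printed-value identity of the paired effect size
  expect_equal(round(cohen_d_paired(-2.448, 29), 3), -0.455)
  # differences (1, 2, 3): t = mean/sd * sqrt(3) = 2 * sqrt(3)
  r <- paired_t(c(2, 4, 6), c(1, 2, 3))
  expect_equal(r$statistic, 2 * sqrt(3), tolerance = 1e-12)
  expect_equal(r$df, 2)
  expect_equal(r$p_value, 2 * pt(-2 * sqrt(3), 2), tolerance = 1e-12)
  expect_equal(r$cohen_d, r$statistic / sqrt(3), tolerance = 1e-12)
  # equal pairs: t = 0, p = 1
  r0 <- paired_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r0$statistic, 0); expect_equal(r0$p_value, 1)
  # agreement with the stock implementation on random data
  set.seed(141)
  x <- rnorm(20); y <- rnorm(20)
  ref <- t.test(x, y, paired = TRUE)
  mine <- paired_t(x, y)
  expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12)
  expect_error(paired_t(c(1, 2), c(0, 1)), "zero variance")
})

test_that("paired t is invariant to adding a common constant to both members", {
  set.seed(142)
  x <- rnorm(15); y <- rnorm(15); shift <- rnorm(15)
  a <- paired_t(x, y)
  b <- paired_t(x + shift, y + shift)
  expect_equal(a$statistic, b$statistic, tolerance = 1e-9)
  expect_equal(a$p_value, b$p_value, tolerance = 1e-9)
})

test_that("the signed-rank z agrees with exact sign-permutation enumeration", {
  d <- c(3.2, -1.5, 0.7, 2.8, -0.3, 1.1, -2.0, 0.9)
  res <- wilcoxon_signed_rank(d)
  r <- rank(abs(d))
  expect_equal(res$W, sum(r[d > 0]))
  # exact null distribution of W+ over all 2^8 sign assignments
  signs <- expand.grid(rep(list(c(0, 1)), 8))
  w_all <- as.matrix(signs) %*% r
  mu <- 8 * 9 / 4
  p_exact <- mean(abs(w_all - mu) >= abs(res$W - mu) - 1e-9)
  p_mid <- mean(abs(w_all - mu) > abs(res$W - mu) + 1e-9) +
    0.5 * mean(abs(abs(w_all - mu) - abs(res$W - mu)) < 1e-9)
  # without a continuity correction the normal approximation tracks the
  # exact mid-p and undershoots the conservative exact tail at n = 8
  expect_lt(abs(res$p_value - p_mid), 0.03)
  expect_lte(res$p_value, p_exact)
  expect_equal(res$statistic, (res$W - mu) / sqrt(8 * 9 * 17 / 24),
               tolerance = 1e-12)
})

test_that("signed-rank conventions: antisymmetry, zeros dropped, tie correction", {
  set.seed(143)
  x <- rnorm(12); y <- rnorm(12)
  a <- wilcoxon_signed_rank(x, y)
  b <- wilcoxon_signed_rank(y, x)
  expect_equal(a$statistic, -b$statistic, tolerance = 1e-12)
  # a (+1, -1) pair balances exactly
  expect_equal(wilcoxon_signed_rank(c(1, -1))$statistic, 0)
  # zero differences are dropped before ranking
  expect_equal(wilcoxon_signed_rank(c(0, 0, 1, -1))$n, 2L)
  expect_error(wilcoxon_signed_rank(c(0, 0)), "undefined")
  # six tied absolute differences: mid-ranks all 3.5, W+ = 17.5,
  # mu = 10.5, var = 6*7*13/24 - (6^3 - 6)/48 = 18.375
  tied <- wilcoxon_signed_rank(c(1, 1, 1, 1, 1, -1))
  expect_equal(tied$W, 17.5)
  expect_equal(tied$statistic, 7 / sqrt(18.375), tolerance = 1e-12)
})

test_that("Pearson correlation matches the closed form and handles sign", {
  x <- c(0.3, 1.9, 2.2, 3.1, 4.8)
  expect_equal(pearson_r(x, 2 * x + 1)$r, 1, tolerance = 1e-12)
  expect_equal(pearson_r(x, -x)$r, -1, tolerance = 1e-12)
  y <- c(1.2, 0.7, 2.9, 2.1, 4.4)
  got <- pearson_r(x, y)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(got$r, r_hand, tolerance = 1e-12)
  ref <- cor.test(x, y)
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-10)
  expect_error(pearson_r(c(1, 1, 1), c(1, 2, 3)), "zero variance")
})

test_that("switch probabilities after wins and losses match a hand count", {
  # choices A A B B A A; outcomes win loss win win loss win
  # transitions after win: t1->t2 stay, t3->t4 stay, t4->t5 switch  (1/3)
  # transitions after loss: t2->t3 switch, t5->t6 stay              (1/2)
  s <- scripted_session(c("A", "A", "B", "B", "A", "A"),
                        c("win", "loss", "win", "win", "loss", "win"))
  per <- revlearn:::session_switch_probs(s)
  expect_equal(per$p_switch_after_win, 1 / 3)
  expect_equal(per$p_switch_after_loss, 1 / 2)
  # an agent that always switches after loss and never after win
  ch <- character(30); ch[1] <- "A"
  out <- rep(c("win", "win", "loss"), 10)
  for (t in 2:30) ch[t] <- if (out[t - 1] == "loss")
    setdiff(c("A", "B"), ch[t - 1]) else ch[t - 1]
  wsls <- revlearn:::session_switch_probs(scripted_session(ch, out))
  expect_equal(wsls$p_switch_after_win, 0)
  expect_equal(wsls$p_switch_after_loss, 1)
})

test_that("missed trials break the switch chain", {
  s <- scripted_session(c("A", NA, "B", "B"),
                        c("win", NA, "win", "loss"))
  per <- revlearn:::session_switch_probs(s)
  # only t3->t4 is a consecutive answered pair (after a win): stay
  expect_equal(per$p_switch_after_win, 0)
  expect_true(is.na(per$p_switch_after_loss))
})

test_that("identical sessions across labels yield zero deltas and a zero contrast", {
  mk <- function(id, lab) scripted_session(
    c("A", "A", "B", "B", "A", "A"),
    c("win", "loss", "win", "win", "loss", "win"),
    subject_id = id, session_label = lab)
  sessions <- unlist(lapply(c("s1", "s2", "s3"), function(id)
    list(mk(id, "placebo"), mk(id, "ghrelin"))), recursive = FALSE)
  res <- switch_feedback_analysis(sessions)
  expect_equal(res$per_subject$delta_win, rep(0, 3))
  expect_equal(res$per_subject$delta_loss, rep(0, 3))
  expect_equal(res$contrast$statistic, 0)
  expect_equal(res$contrast$p_value, 1)
})

test_that("the full battery runs on a simulated crossover cohort", {
  co <- generate_cohort(n_subjects = 8, seed = 151)
  fit <- run_em(model_spec(), co$sessions, seed = 10, max_iter = 4)
  kept <- apply_exclusion(co)$kept
  bat <- behavior_battery(kept, estimates = fit$estimates)
  expect_setequal(unique(bat$descriptives$session_label),
                  c("placebo", "ghrelin"))
  expect_true(all(c("pct_correct", "n_reversals", "beta_pun") %in%
                    bat$tests$measure))
  expect_identical(bat$tests$test[bat$tests$measure == "n_reversals"],
                   "wilcoxon_signed_rank")
  expect_true(all(bat$tests$p_value >= 0 & bat$tests$p_value <= 1))
  expect_identical(nrow(bat$correlations), 4L)
  expect_true(all(abs(bat$correlations$r) <= 1))
})
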