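#' Assemble a session-by-model log-evidence matrix
#'
#' @param fits a named list of `em_fit` objects (one per model variant),
#'   all fitted to the same sessions in the same order.
#' @return numeric matrix, rows = sessions, columns = models.
#' @export
evidence_matrix <- function(fits) {
  cols <- lapply(fits, function(f)
    vapply(f$subject_fits, `[[`, 0, "log_evidence"))
  n <- unique(vapply(cols, length, 0L))
  if (length(n) != 1)
    stop("fits cover different numbers of sessions", call. = FALSE)
  keys <- lapply(fits, function(f)
    paste(vapply(f$subject_fits, `[[`, "", "subject_id"),
          vapply(f$subject_fits, `[[`, "", "session_label")))
  if (length(unique(keys)) != 1)
    stop("fits cover different sessions or orderings", call. = FALSE)
  m <- do.call(cbind, cols)
  colnames(m) <- names(fits)
  rownames(m) <- keys[[1]]
  m
}

#' Random-effects Bayesian model selection for groups
#'
#' Treats the model identity of each session as a random effect with a
#' Dirichlet population distribution and infers the Dirichlet posterior
#' from session-wise log evidences by the standard variational scheme:
#' responsibilities `g[i,k]` proportional to
#' `exp(logev[i,k] + digamma(alpha[k]) - digamma(sum(alpha)))`, then
#' `alpha = alpha0 + colSums(g)`, iterated to convergence. Exceedance
#' probabilities (the posterior probability that a model is the most
#' frequent in the population) are estimated by Monte-Carlo sampling
#' from the Dirichlet posterior.
#'
#' @param evidence session-by-model matrix of log evidences (see
#'   [evidence_matrix()]).
#' @param alpha0 symmetric Dirichlet prior count per model.
#' @param n_samples Monte-Carlo samples for the exceedance estimate.
#' @param seed integer seed for the Monte-Carlo step.
#' @param tol convergence tolerance on the change in `alpha`.
#' @return an object of class `bms_result`: list with `dirichlet_alpha`,
#'   `expected_frequencies`, `exceedance_prob`, `assignments` (the
#'   session-by-model responsibility matrix) and `n_iterations`.
#' @export
bms <- function(evidence, alpha0 = 1, n_samples = 1e5, seed = 1L,
                tol = 1e-6) {
  evidence <- as.matrix(evidence)
  if (ncol(evidence) < 2 || nrow(evidence) < 2)
    stop("need >= 2 models and >= 2 sessions", call. = FALSE)
  if (!all(is.finite(evidence)))
    stop("non-finite log evidences", call. = FALSE)
  K <- ncol(evidence)
  alpha <- rep(alpha0, K)
  g <- NULL
  for (it in 1:500) {
    u <- sweep(evidence, 2, digamma(alpha) - digamma(sum(alpha)), `+`)
    u <- u - apply(u, 1, max)
    g <- exp(u) / rowSums(exp(u))
    alpha_new <- alpha0 + colSums(g)
    if (max(abs(alpha_new - alpha)) < tol) {
      alpha <- alpha_new
      break
    }
    alpha <- alpha_new
  }
  set.seed(seed)
  draws <- matrix(rgamma(n_samples * K, shape = rep(alpha, each = n_samples)),
                  ncol = K)
  xp <- tabulate(max.col(draws, ties.method = "random"), K) / n_samples
  structure(list(dirichlet_alpha = stats::setNames(alpha, colnames(evidence)),
                 expected_frequencies =
                   stats::setNames(alpha / sum(alpha), colnames(evidence)),
                 exceedance_prob = stats::setNames(xp, colnames(evidence)),
                 assignments = g, n_iterations = it),
            class = "bms_result")
}

#' @export
print.bms_result <- function(x, ...) {
  tab <- data.frame(model = names(x$dirichlet_alpha),
                    alpha = round(x$dirichlet_alpha, 3),
                    expected_freq = round(x$expected_frequencies, 3),
                    exceedance = round(x$exceedance_prob, 4))
  cat("Random-effects Bayesian model selection\n")
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Integrated BIC of a fitted model family member
#'
#' Fixed-effects companion criterion to [bms()]: minus twice the summed
#' session log evidence, penalized by the number of group-level
#' hyperparameters (a mean and a variance per active dimension) times
#' the log of the total answered-trial count.
#'
#' @param fit an `em_fit`.
#' @return the iBIC value (smaller is better).
#' @export
ibic <- function(fit) {
  stopifnot(inherits(fit, "em_fit"))
  lev <- sum(vapply(fit$subject_fits, `[[`, 0, "log_evidence"))
  n_total <- sum(vapply(fit$subject_fits, `[[`, 0L, "n_answered"))
  p_prior <- 2 * length(fit$prior$mu)
  -2 * lev + p_prior * log(n_total)
}

#' Model selection across the two crossover sessions
#'
#' Runs [bms()] separately per session label and on the pooled evidence
#' matrix. The winning model is the pooled winner, with a flag recording
#' whether the same model also wins (highest expected frequency) in each
#' session label separately.
#'
#' @param evidence session-by-model log-evidence matrix with row names
#'   `"<subject_id> <session_label>"` as produced by [evidence_matrix()].
#' @param labels character vector of session labels, one per row of
#'   `evidence`.
#' @param ... passed to [bms()].
#' @return list with `pooled` (a `bms_result`), `per_label` (named list
#'   of `bms_result`), `winner` (model name) and `consistent` (logical:
#'   does the pooled winner win within every label).
#' @export
select_model <- function(evidence, labels, ...) {
  stopifnot(nrow(evidence) == length(labels))
  pooled <- bms(evidence, ...)
  per_label <- lapply(split(seq_along(labels), labels), function(idx)
    bms(evidence[idx, , drop = FALSE], ...))
  winner <- names(which.max(pooled$expected_frequencies))
  label_winners <- vapply(per_label, function(b)
    names(which.max(b$expected_frequencies)), "")
  list(pooled = pooled, per_label = per_label, winner = winner,
       consistent = all(label_winners == winner))
}

#' Write a model-selection summary table
#'
#' @param bms_result a `bms_result`.
#' @param ibic_values optional named vector of [ibic()] values.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_bms <- function(bms_result, path, ibic_values = NULL) {
  tab <- data.frame(model = names(bms_result$dirichlet_alpha),
                    dirichlet_alpha = bms_result$dirichlet_alpha,
                    expected_frequency = bms_result$expected_frequencies,
                    exceedance_probability = bms_result$exceedance_prob)
  if (!is.null(ibic_values)) tab$ibic <- ibic_values[tab$model]
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
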