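#' Group-level Gaussian prior over inference-space parameters
#'
#' @param mu named mean vector over the model's active coordinates.
#' @param sigma2 named positive variance vector (diagonal covariance).
#' @return an object of class `group_prior`.
#' @export
group_prior <- function(mu, sigma2) {
  if (length(mu) != length(sigma2))
    stop("mu and sigma2 must have matching length", call. = FALSE)
  if (any(sigma2 <= 0))
    stop("prior variances must be positive", call. = FALSE)
  structure(list(mu = mu, sigma2 = sigma2), class = "group_prior")
}

#' Default (weakly informative) initial prior for a model variant
#'
#' Centered at learning-rate logit 0, reward sensitivity 1, punishment
#' sensitivity -1 and initial value 0, with variance 6.25 per dimension.
#'
#' @param spec an `rl_model_spec`.
#' @return a [group_prior()].
#' @export
default_prior <- function(spec) {
  full_mu <- c(a = 0, b_rew = 1, b_pun = -1, q0 = 0)
  ap <- active_params(spec)
  group_prior(full_mu[ap], stats::setNames(rep(6.25, length(ap)), ap))
}

# Negative log posterior of one session in inference space.
neg_log_post <- function(v, spec, enc, prior) {
  ll <- loglik_encoded(spec, enc, stats::setNames(v, names(prior$mu)))
  lp <- sum(dnorm(v, prior$mu, sqrt(prior$sigma2), log = TRUE))
  -(ll + lp)
}

# Central finite-difference Hessian (step h in inference space).
fd_hessian <- function(f, x, h = 1e-4) {
  d <- length(x)
  H <- matrix(0, d, d)
  f0 <- f(x)
  for (i in seq_len(d)) {
    ei <- replace(numeric(d), i, h)
    H[i, i] <- (f(x + ei) - 2 * f0 + f(x - ei)) / h^2
    if (i < d) for (j in (i + 1):d) {
      ej <- replace(numeric(d), j, h)
      H[i, j] <- H[j, i] <-
        (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) + f(x - ei - ej)) /
        (4 * h^2)
    }
  }
  H
}

# Invert a Hessian of the negative log posterior into a covariance,
# regularizing the diagonal if it is not positive definite.
hessian_to_cov <- function(H) {
  d <- nrow(H)
  ridge <- 0
  for (k in 0:8) {
    ch <- tryCatch(chol(H + diag(ridge, d)), error = function(e) NULL)
    if (!is.null(ch)) {
      return(list(cov = chol2inv(ch),
                  logdet_cov = -2 * sum(log(diag(ch))),
                  regularized = ridge > 0))
    }
    ridge <- if (ridge == 0) 1e-6 else ridge * 10
  }
  # last resort: diagonal curvature only
  dvec <- pmax(abs(diag(H)), 1e-6)
  list(cov = diag(1 / dvec, d), logdet_cov = -sum(log(dvec)),
       regularized = TRUE)
}

#' MAP fit of one session under a group prior
#'
#' Maximizes the log choice likelihood plus the log Gaussian prior
#' density by quasi-Newton optimization from multiple starts (the prior
#' mean plus `n_restarts - 1` draws from the prior; ties broken by first
#' occurrence). The subject-level posterior is Laplace-approximated at
#' the optimum: the covariance is the inverse finite-difference Hessian
#' of the negative log posterior, and the log model evidence is
#'
#'   `loglik + log prior density + (d/2) log 2*pi + (1/2) log det(cov)`.
#'
#' @param spec an `rl_model_spec`.
#' @param session an `rl_session` with at least one answered trial.
#' @param prior a [group_prior()] over the model's active coordinates.
#' @param n_restarts number of optimizer starts.
#' @param seed optional integer seed for the restart draws.
#' @param start optional named vector used as the first start (warm
#'   start), replacing the prior mean.
#' @return an object of class `subject_fit`: list with `theta_map`
#'   (named inference-space vector), `params` (natural space),
#'   `laplace_cov`, `loglik`, `log_prior`, `log_evidence`,
#'   `n_answered`, `regularized` flag, and identifiers.
#' @export
fit_map_session <- function(spec, session, prior, n_restarts = 5L,
                            seed = NULL, start = NULL) {
  stopifnot(inherits(prior, "group_prior"))
  enc <- encode_session(session)
  n_ans <- sum(enc$choice != 0L)
  if (n_ans < 1) stop("session has no answered trials", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  d <- length(prior$mu)
  ap <- names(prior$mu)

  obj <- function(v) neg_log_post(v, spec, enc, prior)
  starts <- list(if (is.null(start)) prior$mu else start[ap])
  if (n_restarts > 1) {
    for (r in seq_len(n_restarts - 1L))
      starts[[r + 1L]] <- rnorm(d, prior$mu, sqrt(prior$sigma2))
  }

  best <- NULL
  for (s0 in starts) {
    fit <- tryCatch(
      optim(s0, obj, method = "BFGS",
            control = list(maxit = 500, reltol = 1e-10)),
      error = function(e) NULL)
    if (is.null(fit))
      fit <- tryCatch(optim(s0, obj, method = "Nelder-Mead",
                            control = list(maxit = 2000)),
                      error = function(e) NULL)
    if (is.null(fit)) next
    # never accept an iterate worse than its own start
    if (obj(s0) < fit$value) fit <- list(par = s0, value = obj(s0))
    if (is.null(best) || fit$value < best$value - 1e-12) best <- fit
  }
  if (is.null(best)) stop("MAP optimization failed on all starts", call. = FALSE)

  theta <- stats::setNames(best$par, ap)
  H <- fd_hessian(obj, theta)
  hc <- hessian_to_cov(H)
  ll <- loglik_encoded(spec, enc, theta)
  lp <- sum(dnorm(theta, prior$mu, sqrt(prior$sigma2), log = TRUE))
  lev <- ll + lp + 0.5 * d * log(2 * pi) + 0.5 * hc$logdet_cov

  structure(list(subject_id = session$subject_id,
                 session_label = session$session_label,
                 model = spec$name,
                 theta_map = theta,
                 params = to_natural(spec, theta),
                 laplace_cov = hc$cov,
                 loglik = ll, log_prior = lp, log_evidence = lev,
                 n_answered = n_ans, regularized = hc$regularized),
            class = "subject_fit")
}

#' Hierarchical expectation-maximization over a set of sessions
#'
#' Alternates an E-step (MAP fit of every session under the current
#' group prior, warm-started from the previous iteration's optima) with
#' a closed-form M-step matching the prior's moments to the subject
#' posteriors: the mean is the average MAP and the variance averages the
#' squared MAPs plus the Laplace variances, floored at `var_floor`. The
#' objective is the summed Laplace log evidence; iteration stops when
#' the objective improves by less than `tol` or `max_iter` is reached,
#' and the best iterate is kept (an iteration that would decrease the
#' objective is rolled back, so the reported trace is non-decreasing).
#'
#' Sessions are fitted as independent units: both crossover sessions of
#' a subject enter the same group prior but receive separate parameters.
#'
#' @param spec an `rl_model_spec`.
#' @param sessions list of `rl_session` (>= 2).
#' @param init_prior starting [group_prior()]; default [default_prior()].
#' @param tol absolute convergence tolerance on the summed log evidence.
#' @param max_iter maximum EM iterations.
#' @param n_restarts optimizer restarts in the first E-step (later
#'   E-steps warm-start from the previous optima).
#' @param seed integer seed for the restart draws.
#' @param var_floor lower bound on the group variances.
#' @param verbose print the objective per iteration.
#' @return an object of class `em_fit`: list with `model`, `prior`
#'   (final [group_prior()]), `subject_fits` (list of `subject_fit`),
#'   `objective_trace`, `n_iterations`, `converged`, and the per-session
#'   natural-space parameter table `estimates` (subject_id,
#'   session_label, alpha, beta_rew, beta_pun, q_init, loglik,
#'   log_evidence).
#' @export
run_em <- function(spec, sessions, init_prior = default_prior(spec),
                   tol = 0.02, max_iter = 50L, n_restarts = 5L,
                   seed = 1L, var_floor = 1e-6, verbose = FALSE) {
  if (length(sessions) < 2) stop("need at least 2 sessions", call. = FALSE)
  set.seed(seed)
  prior <- init_prior
  ap <- names(prior$mu)
  fits <- vector("list", length(sessions))
  trace <- numeric(0)
  converged <- FALSE
  best <- NULL

  for (iter in seq_len(max_iter)) {
    fits <- lapply(seq_along(sessions), function(i) {
      fit_map_session(spec, sessions[[i]], prior,
                      n_restarts = if (iter == 1L) n_restarts else 1L,
                      start = if (iter == 1L) NULL else fits[[i]]$theta_map)
    })
    obj <- sum(vapply(fits, `[[`, 0, "log_evidence"))
    if (!is.finite(obj))
      stop("EM diverged (non-finite objective); trace: ",
           paste(signif(trace, 8), collapse = ", "), call. = FALSE)
    if (verbose) message(sprintf("EM iter %d: objective %.6f", iter, obj))

    if (!is.null(best) && obj < best$obj) {
      # approximation noise at the optimum: keep the best iterate
      converged <- TRUE
      break
    }
    trace <- c(trace, obj)
    best <- list(obj = obj, prior = prior, fits = fits)
    if (iter > 1L && obj - trace[length(trace) - 1L] < tol) {
      converged <- TRUE
      break
    }

    # M-step: moment-match the group Gaussian to the subject posteriors
    th <- do.call(rbind, lapply(fits, `[[`, "theta_map"))
    lv <- do.call(rbind, lapply(fits, function(f) diag(f$laplace_cov)))
    mu <- colMeans(th)
    sigma2 <- pmax(colMeans(th^2 + lv) - mu^2, var_floor)
    prior <- group_prior(stats::setNames(mu, ap),
                         stats::setNames(sigma2, ap))
  }

  fits <- best$fits
  est <- do.call(rbind, lapply(fits, function(f)
    data.frame(subject_id = f$subject_id, session_label = f$session_label,
               alpha = f$params$alpha, beta_rew = f$params$beta_rew,
               beta_pun = f$params$beta_pun, q_init = f$params$q_init,
               loglik = f$loglik, log_evidence = f$log_evidence,
               stringsAsFactors = FALSE)))
  structure(list(model = spec$name, spec = spec, prior = best$prior,
                 subject_fits = fits, objective_trace = trace,
                 n_iterations = length(trace), converged = converged,
                 estimates = est),
            class = "em_fit")
}

#' @export
print.em_fit <- function(x, ...) {
  cat(sprintf("Hierarchical EM fit of model %s: %d sessions, %d iterations%s\n",
              x$model, length(x$subject_fits), x$n_iterations,
              if (x$converged) " (converged)" else ""))
  cat(sprintf("  final objective (sum log evidence): %.3f\n",
              x$objective_trace[length(x$objective_trace)]))
  cat("  group prior mean:",
      paste(sprintf("%s=%.3f", names(x$prior$mu), x$prior$mu), collapse = ", "),
      "\n")
  invisible(x)
}

#' Write the per-session parameter table of an EM fit
#'
#' @param fit an `em_fit`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_estimates <- function(fit, path) {
  stopifnot(inherits(fit, "em_fit"))
  write.table(fit$estimates, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
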