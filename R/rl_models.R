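#' Specify a Q-learning model variant
#'
#' The model family is the 2 x 2 x 2 factorial crossing of three binary
#' choices: whether the unchosen option is updated toward the opposite
#' outcome (double update, exploiting the dependent contingencies),
#' whether reinforcement sensitivity is estimated separately for wins and
#' losses, and whether the initial Q-value of option A is a free
#' parameter (a bias to initially prefer one stimulus). Names follow the
#' pattern `DU`/`SU` (double/single update), `SS`/`CS` (separate/common
#' sensitivities), `Qi`/`Q0` (free/fixed initial value); the full model
#' is `"DU-SS-Qi"`.
#'
#' @param double_update logical; update the unchosen option toward the
#'   opposite reinforcement.
#' @param separate_sensitivities logical; if `FALSE`, the punishment
#'   sensitivity is constrained to `-beta_rew`.
#' @param free_q_init logical; if `FALSE`, `q_init` is fixed at 0.
#' @return an object of class `rl_model_spec`.
#' @examples
#' model_spec(TRUE, TRUE, TRUE)$name
#' @export
model_spec <- function(double_update = TRUE,
                       separate_sensitivities = TRUE,
                       free_q_init = TRUE) {
  spec <- list(double_update = isTRUE(double_update),
               separate_sensitivities = isTRUE(separate_sensitivities),
               free_q_init = isTRUE(free_q_init))
  spec$name <- paste0(if (spec$double_update) "DU" else "SU", "-",
                      if (spec$separate_sensitivities) "SS" else "CS", "-",
                      if (spec$free_q_init) "Qi" else "Q0")
  class(spec) <- "rl_model_spec"
  spec
}

#' All eight model variants
#'
#' @return a named list of [model_spec()] objects covering the factorial
#'   family, in a fixed order.
#' @export
model_family <- function() {
  grid <- expand.grid(du = c(FALSE, TRUE), ss = c(FALSE, TRUE),
                      qi = c(FALSE, TRUE))
  specs <- lapply(seq_len(nrow(grid)), function(i)
    model_spec(grid$du[i], grid$ss[i], grid$qi[i]))
  names(specs) <- vapply(specs, `[[`, "", "name")
  specs
}

#' Look up a model variant by name
#'
#' @param name a model name such as `"DU-SS-Qi"`, or an `rl_model_spec`
#'   (returned unchanged).
#' @return an `rl_model_spec`.
#' @export
get_model <- function(name) {
  if (inherits(name, "rl_model_spec")) return(name)
  fam <- model_family()
  if (!name %in% names(fam))
    stop("unknown model '", name, "'; available: ",
         paste(names(fam), collapse = ", "), call. = FALSE)
  fam[[name]]
}

#' Inference-space parameter names active under a model variant
#'
#' The unconstrained inference space has coordinates `a` (logit of the
#' learning rate), `b_rew`, `b_pun` (identity-mapped sensitivities) and
#' `q0` (identity-mapped initial value). Restricted variants drop the
#' inactive coordinates.
#'
#' @param spec an `rl_model_spec`.
#' @return character vector of active coordinate names.
#' @export
active_params <- function(spec) {
  stopifnot(inherits(spec, "rl_model_spec"))
  c("a", "b_rew",
    if (spec$separate_sensitivities) "b_pun",
    if (spec$free_q_init) "q0")
}

#' Construct a natural-space parameter set
#'
#' @param alpha learning rate, strictly inside (0, 1).
#' @param beta_rew reward sensitivity (reinforcement magnitude of a win).
#' @param beta_pun punishment sensitivity (reinforcement magnitude of a
#'   loss; typically negative, not constrained).
#' @param q_init initial Q-value of option A (option B starts at 0).
#' @return an object of class `rl_params`.
#' @export
parameter_set <- function(alpha, beta_rew, beta_pun = -beta_rew,
                          q_init = 0) {
  vals <- c(alpha = alpha, beta_rew = beta_rew, beta_pun = beta_pun,
            q_init = q_init)
  if (!all(is.finite(vals)))
    stop("parameters must be finite", call. = FALSE)
  if (alpha <= 0 || alpha >= 1)
    stop("alpha must lie strictly inside (0, 1)", call. = FALSE)
  structure(as.list(vals), class = "rl_params")
}

# Apply a variant's equality constraints to a full parameter set.
constrain_params <- function(spec, params) {
  if (!spec$separate_sensitivities) params$beta_pun <- -params$beta_rew
  if (!spec$free_q_init) params$q_init <- 0
  params
}

#' Map between inference space and natural parameter space
#'
#' The learning rate is logistic-transformed (`alpha = plogis(a)`) so the
#' group-level Gaussian prior lives on an unconstrained space; the
#' sensitivities and initial value map by identity. Coordinates inactive
#' under `spec` are fixed by the variant's constraints.
#'
#' @param spec an `rl_model_spec`.
#' @param v named numeric vector over `active_params(spec)`.
#' @param params an `rl_params` object.
#' @return `to_natural` returns an `rl_params`; `from_natural` returns a
#'   named inference-space vector. The two are mutually inverse on the
#'   active coordinates.
#' @examples
#' sp <- model_spec(TRUE, TRUE, TRUE)
#' to_natural(sp, c(a = 0, b_rew = 2, b_pun = -1, q0 = 0))$alpha  # 0.5
#' @export
to_natural <- function(spec, v) {
  ap <- active_params(spec)
  v <- v[ap]
  if (any(!is.finite(v)))
    stop("non-finite inference-space vector", call. = FALSE)
  p <- parameter_set(
    alpha    = plogis(v[["a"]]),
    beta_rew = v[["b_rew"]],
    beta_pun = if (spec$separate_sensitivities) v[["b_pun"]] else -v[["b_rew"]],
    q_init   = if (spec$free_q_init) v[["q0"]] else 0)
  p
}

#' @rdname to_natural
#' @export
from_natural <- function(spec, params) {
  full <- c(a = log(params$alpha / (1 - params$alpha)),
            b_rew = params$beta_rew,
            b_pun = params$beta_pun,
            q0 = params$q_init)
  full[active_params(spec)]
}

# Session -> integer encoding for the C++ core.
encode_session <- function(session) {
  tr <- session$trials
  choice <- ifelse(is.na(tr$choice), 0L, ifelse(tr$choice == "A", 1L, 2L))
  outcome <- ifelse(is.na(tr$outcome), 0L, ifelse(tr$outcome == "win", 1L, -1L))
  if (any(choice != 0L & outcome == 0L))
    stop("answered trial without an outcome: corrupt session data", call. = FALSE)
  if (any(choice == 0L & outcome != 0L))
    stop("missed trial carrying an outcome: corrupt session data", call. = FALSE)
  list(choice = as.integer(choice), outcome = as.integer(outcome))
}

#' Trial-wise likelihood and latent trajectory of a session
#'
#' Runs the Rescorla-Wagner pass: Q-values start at `(q_init, 0)`, the
#' choice probability is a unit-temperature softmax of the Q-difference,
#' the experienced reinforcement is `beta_rew` on a win and `beta_pun` on
#' a loss, the prediction error is reinforcement minus the chosen
#' option's Q-value, and the chosen option moves toward the
#' reinforcement by fraction `alpha`. Under a double-update variant the
#' unchosen option simultaneously moves toward the opposite
#' reinforcement. Missed trials contribute no likelihood and no update.
#'
#' @param spec an `rl_model_spec`.
#' @param params an `rl_params`; constraints of restricted variants are
#'   enforced before evaluation.
#' @param session an `rl_session` (see [generate_session()]).
#' @return an object of class `ql_trajectory`: a list with `trajectory`
#'   (data frame: trial, qA, qB, p_choice, pe) and `loglik` (sum of log
#'   choice probabilities over answered trials).
#' @export
session_loglik <- function(spec, params, session) {
  stopifnot(inherits(spec, "rl_model_spec"), inherits(params, "rl_params"))
  params <- constrain_params(spec, params)
  enc <- encode_session(session)
  out <- ql_trajectory_cpp(enc$choice, enc$outcome, params$alpha,
                           params$beta_rew, params$beta_pun, params$q_init,
                           spec$double_update)
  structure(list(
    trajectory = data.frame(trial = seq_along(enc$choice),
                            qA = out$qA, qB = out$qB,
                            p_choice = out$p_choice, pe = out$pe),
    loglik = out$loglik,
    model = spec$name),
    class = "ql_trajectory")
}

# Fast loglik from an encoded session and an inference-space vector.
loglik_encoded <- function(spec, enc, v) {
  p <- to_natural(spec, v)
  ql_loglik_cpp(enc$choice, enc$outcome, p$alpha, p$beta_rew, p$beta_pun,
                p$q_init, spec$double_update)
}

#' Softmax choice probability and agent choice draw
#'
#' @param q_pair numeric length-2 vector `(Q(A), Q(B))`.
#' @param draw a uniform(0,1) variate.
#' @return `softmax_pA` returns P(choose A); `simulate_choice` returns
#'   `"A"` iff `draw < softmax_pA(q_pair)`, else `"B"`.
#' @export
softmax_pA <- function(q_pair) {
  stopifnot(all(is.finite(q_pair)), length(q_pair) == 2)
  plogis(q_pair[1] - q_pair[2])
}

#' @rdname softmax_pA
#' @export
simulate_choice <- function(q_pair, draw) {
  if (draw < softmax_pA(q_pair)) "A" else "B"
}

# One agent-side learning step; mirrors the C++ update exactly.
ql_step <- function(q, choice, outcome, params, spec) {
  R <- if (outcome == "win") params$beta_rew else params$beta_pun
  i <- if (choice == "A") 1L else 2L
  u <- 3L - i
  q[i] <- q[i] + params$alpha * (R - q[i])
  if (spec$double_update) q[u] <- q[u] + params$alpha * (-R - q[u])
  q
}

#' Write a fitted session's latent trajectory to a TSV file
#'
#' @param traj a `ql_trajectory` from [session_loglik()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "ql_trajectory"))
  write.table(traj$trajectory, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
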