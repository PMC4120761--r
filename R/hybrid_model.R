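#' Parameters of the hybrid model-free/model-based learner
#'
#' The seven-parameter hybrid learner combines SARSA(lambda) model-free
#' values with model-based values computed from the true transition
#' structure; `omega` mixes the two at the first stage and is the quantity
#' of primary scientific interest.
#'
#' @param beta1,beta2 Softmax inverse temperatures for stage 1 and 2
#'   (non-negative).
#' @param alpha1,alpha2 Learning rates per stage, in \[0, 1\].
#' @param lam Stage-skipping eligibility weight lambda in \[0, 1\]: how
#'   strongly the second-stage prediction error also updates the chosen
#'   first-stage value.
#' @param omega Model-based weight in \[0, 1\] (0 = purely model-free,
#'   1 = purely model-based).
#' @param rho Perseveration bonus added to the value of repeating the
#'   previous first-stage choice (any real).
#' @return A classed named numeric vector (`hybrid_params`) in the
#'   canonical order beta1, beta2, alpha1, alpha2, lam, omega, rho.
#' @examples
#' hybrid_params(omega = 1, lam = 0)
#' @export
hybrid_params <- function(beta1 = 1, beta2 = 1, alpha1 = 0.5, alpha2 = 0.5,
                          lam = 0.5, omega = 0.5, rho = 0) {
  p <- c(beta1 = beta1, beta2 = beta2, alpha1 = alpha1, alpha2 = alpha2,
         lam = lam, omega = omega, rho = rho)
  if (anyNA(p) || !is.numeric(p)) stop("parameters must be numeric")
  if (beta1 < 0 || beta2 < 0) stop("`beta1`/`beta2` must be non-negative")
  for (nm in LOGISTIC_PARS) {
    if (p[[nm]] < 0 || p[[nm]] > 1) {
      stop(sprintf("`%s` must lie in [0, 1]", nm))
    }
  }
  structure(p, class = "hybrid_params")
}

#' @export
print.hybrid_params <- function(x, ...) {
  cat("<hybrid_params>\n")
  print(round(unclass(x), 4))
  invisible(x)
}

#' Q-value container for the hybrid learner
#'
#' Holds the model-free values: `q1` for the two first-stage actions and
#' `q2`, a 2 x 2 matrix with rows indexing the second-stage state (0, 1)
#' and columns the action (0, 1). All values start at 0.
#'
#' @param q1 Numeric length-2 first-stage values.
#' @param q2 2 x 2 numeric matrix of second-stage values.
#' @return An object of class `q_values`.
#' @export
q_values <- function(q1 = c(0, 0), q2 = matrix(0, 2, 2)) {
  stopifnot(length(q1) == 2, is.matrix(q2), all(dim(q2) == c(2, 2)))
  structure(list(q1 = as.numeric(q1), q2 = q2), class = "q_values")
}

#' Model-based first-stage values
#'
#' Prospective values computed from the true transition probabilities:
#' for each first-stage action, the probability-weighted best second-stage
#' value, `p_common * max_a Q(s_common, a) + (1 - p_common) *
#' max_a Q(s_rare, a)`. Transition probabilities are fixed to the task's
#' true values, not learned.
#'
#' @param q A [q_values()] object.
#' @param structure A [transition_structure()].
#' @return Numeric length-2 vector of model-based values for actions 0, 1.
#' @examples
#' q <- q_values(q2 = matrix(c(0.6, 0.3, 0.2, 0.1), 2, 2))
#' mb_values(q, transition_structure())  # 0.51 0.39
#' @export
mb_values <- function(q, structure) {
  maxs <- c(max(q$q2[1, ]), max(q$q2[2, ]))
  p <- structure$p_common
  vapply(0:1, function(a) {
    cs <- structure$common_map[a + 1L]
    p * maxs[cs + 1L] + (1 - p) * maxs[2L - cs]
  }, numeric(1))
}

#' Net (hybrid) first-stage values
#'
#' Mixture `omega * Q_MB + (1 - omega) * Q_MF` of model-based and
#' model-free first-stage values. At the second stage the two systems
#' coincide, so no mixing is needed there.
#'
#' @inheritParams mb_values
#' @param omega Model-based weight in \[0, 1\].
#' @return Numeric length-2 vector of net values for actions 0, 1.
#' @export
net_values <- function(q, structure, omega) {
  if (!is.numeric(omega) || omega < 0 || omega > 1) {
    stop("`omega` must lie in [0, 1]")
  }
  omega * mb_values(q, structure) + (1 - omega) * q$q1
}

#' Softmax choice probabilities with perseveration
#'
#' `p(a)` proportional to `exp(beta * (Q(a) + rho * rep(a)))`, where
#' `rep(a) = 1` iff `a` equals the previous first-stage action. At the
#' second stage (or on the first trial) pass `prev_action = NULL` so the
#' perseveration term vanishes. Stabilized by max-subtraction before
#' exponentiation.
#'
#' @param values Numeric length-2 action values.
#' @param beta Inverse temperature, non-negative.
#' @param rho Perseveration bonus (default 0).
#' @param prev_action Previous first-stage action (0/1) or `NULL`.
#' @return Numeric length-2 probability vector summing to 1.
#' @examples
#' choice_probs(c(0.51, 0.39), beta = 1)  # ~ 0.530 0.470
#' @export
choice_probs <- function(values, beta, rho = 0, prev_action = NULL) {
  if (!is.numeric(beta) || beta < 0) stop("`beta` must be non-negative")
  rep_ind <- if (is.null(prev_action)) c(0, 0) else as.numeric(0:1 == prev_action)
  x <- beta * (values + rho * rep_ind)
  e <- exp(x - max(x))
  e / sum(e)
}

#' Apply one trial's SARSA(lambda) updates
#'
#' Computes both prediction errors from the pre-update values -- `delta1 =
#' Q(s2, a2) - Q(sA, a1)` (no reward at stage 1) and `delta2 = r -
#' Q(s2, a2)` (terminal stage) -- then updates the chosen second-stage
#' value by `alpha2 * delta2` and the chosen first-stage value by
#' `alpha1 * delta1 + alpha1 * lam * delta2` (the stage-skipping update).
#' Unchosen values are untouched.
#'
#' @param q A [q_values()] object.
#' @param trial A list or one-row data.frame with `a1`, `s2`, `a2`, `r`.
#' @param params A [hybrid_params()] object.
#' @return List with the updated `q` and `comp` (fields `delta1`, `delta2`).
#' @export
apply_trial_updates <- function(q, trial, params) {
  a1 <- trial$a1 + 1L
  s2 <- trial$s2 + 1L
  a2 <- trial$a2 + 1L
  delta1 <- q$q2[s2, a2] - q$q1[a1]
  delta2 <- trial$r - q$q2[s2, a2]
  q$q2[s2, a2] <- q$q2[s2, a2] + params[["alpha2"]] * delta2
  q$q1[a1] <- q$q1[a1] + params[["alpha1"]] * delta1 +
    params[["alpha1"]] * params[["lam"]] * delta2
  list(q = q, comp = list(delta1 = delta1, delta2 = delta2))
}

#' Log-likelihood of a two-step session under the hybrid model
#'
#' Iterates the trials in order, accumulating `log p(a1)` (net first-stage
#' values, beta1, perseveration toward the previous trial's choice) and
#' `log p(a2)` (second-stage values, beta2, no perseveration), then applies
#' the trial's updates. All Q values start at 0. Per-trial probabilities
#' are floored at 1e-300 before the log to keep extreme inverse
#' temperatures finite.
#'
#' @param session A [twostep_session()].
#' @param params A [hybrid_params()] object.
#' @param details If `TRUE` (default) also return the per-trial
#'   computations (prediction errors, repeat indicator, choice
#'   probabilities of the taken actions).
#' @return List with `loglik` and, if requested, a data.frame `trials`
#'   with columns `delta1`, `delta2`, `rep1`, `p_a1`, `p_a2`.
#' @export
session_loglik <- function(session, params, details = TRUE) {
  if (!inherits(session, "twostep_session")) {
    stop("`session` must be a twostep_session")
  }
  tr <- session$trials
  if (nrow(tr) == 0) stop("session has no trials")
  validate_twostep_trials(tr)
  st <- session$structure
  res <- hybrid_session_pass(as.integer(tr$a1), as.integer(tr$s2),
                             as.integer(tr$a2), as.numeric(tr$r),
                             as.numeric(params)[1:7],
                             st$p_common, st$common_map)
  out <- list(loglik = res$loglik)
  if (details) {
    out$trials <- data.frame(t = tr$t, delta1 = res$delta1,
                             delta2 = res$delta2, rep1 = res$rep1,
                             p_a1 = res$p_a1, p_a2 = res$p_a2)
  }
  out
}

#' Simulate a hybrid agent on the two-step task
#'
#' Generative use of the hybrid learner: on each trial choices are sampled
#' from [choice_probs()] at both stages, the environment is stepped via
#' [step_twostep()], and the values updated via [apply_trial_updates()].
#'
#' @param params A [hybrid_params()] object.
#' @param structure A [transition_structure()].
#' @param walk Optional [generate_reward_walk()]; generated fresh (inside
#'   the seeded stream) when `NULL`.
#' @param n_trials Number of trials (default 201, one standard session).
#' @param seed Optional integer seed; the full session is deterministic
#'   given the seed.
#' @param subject_id Identifier stored in the session.
#' @return A [twostep_session()].
#' @examples
#' s <- simulate_agent(hybrid_params(beta1 = 3, omega = 1), seed = 1)
#' mean(s$trials$transition == "common")
#' @export
simulate_agent <- function(params, structure = transition_structure(),
                           walk = NULL, n_trials = 201, seed = NULL,
                           subject_id = "agent") {
  n_trials <- as.integer(n_trials)
  with_seed_or_stream(seed, function() {
    if (is.null(walk)) {
      walk <- generate_reward_walk(n_trials)
    }
    if (n_trials > nrow(walk$probs)) {
      stop("`n_trials` exceeds the reward walk's length")
    }
    q <- q_values()
    prev <- NULL
    a1v <- s2v <- a2v <- rv <- integer(n_trials)
    trv <- character(n_trials)
    beta2 <- params[["beta2"]]
    for (t in seq_len(n_trials)) {
      v <- net_values(q, structure, params[["omega"]])
      p1 <- choice_probs(v, params[["beta1"]], params[["rho"]], prev)
      a1 <- if (runif(1) < p1[1]) 0L else 1L
      trial <- step_twostep(a1, t, structure, walk, function(s2) {
        p2 <- choice_probs(q$q2[s2 + 1L, ], beta2)
        if (runif(1) < p2[1]) 0L else 1L
      })
      q <- apply_trial_updates(q, trial, params)$q
      a1v[t] <- trial$a1
      s2v[t] <- trial$s2
      a2v[t] <- trial$a2
      rv[t] <- trial$r
      trv[t] <- trial$transition
      prev <- a1
    }
    twostep_session(subject_id,
                    data.frame(t = seq_len(n_trials), a1 = a1v, s2 = s2v,
                               a2 = a2v, r = rv, transition = trv,
                               stringsAsFactors = FALSE),
                    walk = walk, structure = structure)
  })
}
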