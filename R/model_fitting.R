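#' Map hybrid parameters to the unconstrained scale and back
#'
#' Fitting operates on an unconstrained 7-vector `y`: the learning rates,
#' lambda and omega are logit-transformed, the inverse temperatures
#' log-transformed, and rho is left on its natural scale. Group priors are
#' Gaussian on this scale, so the back-transformed parameters follow
#' logistic/log-normal group distributions.
#'
#' @param params A [hybrid_params()] object. Bounded parameters sitting
#'   exactly on 0 or 1 are clipped into the open interval (with a warning)
#'   so the transform stays finite.
#' @return Named numeric 7-vector on the unconstrained scale.
#' @examples
#' y <- transform_params(hybrid_params(omega = 0.43))
#' inverse_transform_params(y)[["omega"]]
#' @export
transform_params <- function(params) {
  p <- as.numeric(params)
  names(p) <- PAR_NAMES
  for (nm in LOGISTIC_PARS) {
    if (p[[nm]] <= 0 || p[[nm]] >= 1) {
      warning(sprintf("`%s` on the boundary; clipping into (0, 1)", nm))
      p[[nm]] <- min(max(p[[nm]], 1e-9), 1 - 1e-9)
    }
  }
  if (any(p[EXP_PARS] <= 0)) {
    warning("inverse temperature on the boundary; clipping above 0")
    p[EXP_PARS] <- pmax(p[EXP_PARS], 1e-12)
  }
  y <- p
  y[EXP_PARS] <- log(p[EXP_PARS])
  y[LOGISTIC_PARS] <- qlogis(p[LOGISTIC_PARS])
  y
}

#' @rdname transform_params
#' @param y Named or ordered numeric 7-vector on the unconstrained scale.
#' @export
inverse_transform_params <- function(y) {
  y <- as.numeric(y)
  if (length(y) != 7) stop("`y` must have length 7")
  names(y) <- PAR_NAMES
  p <- y
  p[EXP_PARS] <- exp(pmin(y[EXP_PARS], 50))  # cap keeps exp() finite
  p[LOGISTIC_PARS] <- plogis(y[LOGISTIC_PARS])
  hybrid_params(beta1 = p[["beta1"]], beta2 = p[["beta2"]],
                alpha1 = p[["alpha1"]], alpha2 = p[["alpha2"]],
                lam = p[["lam"]], omega = p[["omega"]], rho = p[["rho"]])
}

#' Gaussian group-prior moments on the unconstrained scale
#'
#' @param mu Numeric 7-vector of prior means.
#' @param sigma2 Numeric 7-vector of prior variances (floored at 1e-4 by
#'   the EM routine to prevent collapse).
#' @return An object of class `prior_moments`.
#' @export
prior_moments <- function(mu, sigma2) {
  stopifnot(length(mu) == 7, length(sigma2) == 7, all(sigma2 > 0))
  mu <- as.numeric(mu)
  sigma2 <- as.numeric(sigma2)
  names(mu) <- names(sigma2) <- PAR_NAMES
  structure(list(mu = mu, sigma2 = sigma2), class = "prior_moments")
}

# penalized negative log posterior on the unconstrained scale
neg_log_post <- function(y, session, prior) {
  make_neg_log_post(session, prior)(y)
}

# closure with the trial vectors pre-extracted: the optimizer evaluates
# this thousands of times per subject, so it must skip per-call
# validation and object construction
make_neg_log_post <- function(session, prior) {
  tr <- session$trials
  validate_twostep_trials(tr)
  a1 <- as.integer(tr$a1)
  s2 <- as.integer(tr$s2)
  a2 <- as.integer(tr$a2)
  r <- as.numeric(tr$r)
  st <- session$structure
  mu <- prior$mu
  sig <- sqrt(prior$sigma2)
  exp_idx <- match(EXP_PARS, PAR_NAMES)
  log_idx <- match(LOGISTIC_PARS, PAR_NAMES)
  function(y) {
    p <- y
    p[exp_idx] <- exp(pmin(y[exp_idx], 50))
    p[log_idx] <- plogis(y[log_idx])
    ll <- hybrid_session_loglik(a1, s2, a2, r, p, st$p_common,
                                st$common_map)
    lp <- sum(dnorm(y, mu, sig, log = TRUE))
    -(ll + lp)
  }
}

# central-difference diagonal Hessian
hessian_diag <- function(f, y, h_rel = 1e-3) {
  f0 <- f(y)
  vapply(seq_along(y), function(k) {
    h <- h_rel * (1 + abs(y[k]))
    e <- numeric(length(y))
    e[k] <- h
    (f(y + e) - 2 * f0 + f(y - e)) / h^2
  }, numeric(1))
}

#' Per-subject MAP estimate under a Gaussian prior
#'
#' Maximizes the penalized log-likelihood `log p(choices | theta) +
#' log Normal(y; mu, sigma2)` over the unconstrained parameters by BFGS
#' from multiple seeded restarts (the hybrid model's likelihood surface is
#' multimodal). Approximate posterior variances come from the inverse of
#' the numerically differentiated diagonal Hessian at the optimum (Laplace
#' approximation); coordinates where the curvature is not positive fall
#' back to the prior variance.
#'
#' @param session A [twostep_session()].
#' @param prior A [prior_moments()] object.
#' @param n_restarts Number of optimizer restarts drawn from the prior
#'   (the prior mean, and `init` when given, are always tried as well).
#' @param seed Optional integer seed for the restart draws.
#' @param init Optional unconstrained 7-vector used as a warm start.
#' @param maxit BFGS iteration cap per restart.
#' @return An object of class `subject_fit`: `subject_id`, `y_map`,
#'   `params_map`, `laplace_var`, `log_post` (penalized log-likelihood at
#'   the optimum) and `n_restarts_used`.
#' @export
map_fit <- function(session, prior, n_restarts = 10, seed = NULL,
                    init = NULL, maxit = 500) {
  obj <- make_neg_log_post(session, prior)
  starts <- with_seed_or_stream(seed, function() {
    s <- list(prior$mu)
    if (!is.null(init)) s <- c(s, list(as.numeric(init)))
    if (n_restarts > 0) {
      draws <- replicate(n_restarts,
                         rnorm(7, prior$mu, sqrt(prior$sigma2)),
                         simplify = FALSE)
      s <- c(s, draws)
    }
    s
  })
  best <- NULL
  for (y0 in starts) {
    fit <- tryCatch(optim(y0, obj, method = "BFGS",
                          control = list(maxit = maxit)),
                    error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$value)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) {
    stop("all optimizer restarts failed for subject ", session$subject_id)
  }
  h <- hessian_diag(obj, best$par)
  lv <- ifelse(is.finite(h) & h > 1e-8, 1 / pmax(h, 1e-8), prior$sigma2)
  y <- best$par
  names(y) <- PAR_NAMES
  names(lv) <- PAR_NAMES
  structure(list(subject_id = session$subject_id, y_map = y,
                 params_map = inverse_transform_params(y),
                 laplace_var = lv, log_post = -best$value,
                 n_restarts_used = length(starts)),
            class = "subject_fit")
}

#' Hierarchical empirical-Bayes fit of a cohort
#'
#' Expectation-Maximization over a Gaussian group prior on the
#' unconstrained parameters. E-step: [map_fit()] per subject under the
#' current prior (warm-started at the previous optimum). M-step: moment
#' matching including the Laplace posterior uncertainty, `mu <- mean(y)`
#' and `sigma2 <- mean(y^2 + laplace_var) - mu^2` (floored at 1e-4).
#' Iteration stops when the summed per-subject penalized log-likelihood
#' improves by less than `tol`, or at `max_iter`. `max_iter = 1`
#' reproduces a set-once prior (single pooled E-step, no prior update).
#'
#' @param sessions List of at least two [twostep_session()] objects.
#' @param max_iter Maximum EM iterations (default 50).
#' @param tol Convergence tolerance on the summed penalized objective
#'   (default 1e-3).
#' @param n_restarts Optimizer restarts per subject per E-step.
#' @param seed Integer seed controlling all restart draws.
#' @param prior_init Optional starting [prior_moments()]; defaults to a
#'   broad zero-centered prior (variance 5 per coordinate).
#' @param verbose Print per-iteration objective values.
#' @return An object of class `group_fit`: `prior`, `subjects` (list of
#'   `subject_fit`), `em_iterations`, `converged` and `trajectory` (the
#'   per-iteration summed penalized objective).
#' @export
em_fit <- function(sessions, max_iter = 50, tol = 1e-3, n_restarts = 10,
                   seed = 1, prior_init = NULL, verbose = FALSE) {
  if (length(sessions) < 2) stop("need at least 2 sessions")
  prior <- prior_init %||% prior_moments(rep(0, 7), rep(5, 7))
  fits <- vector("list", length(sessions))
  traj <- numeric(0)
  converged <- FALSE
  it <- 0
  for (it in seq_len(max_iter)) {
    for (i in seq_along(sessions)) {
      sub_seed <- (as.integer(seed) + 7919L * it + 104729L * i) %%
        2147483646L + 1L
      fits[[i]] <- map_fit(sessions[[i]], prior, n_restarts = n_restarts,
                           seed = sub_seed,
                           init = if (is.null(fits[[i]])) NULL
                                  else fits[[i]]$y_map)
    }
    total <- sum(vapply(fits, `[[`, numeric(1), "log_post"))
    traj <- c(traj, total)
    if (verbose) {
      message(sprintf("EM iteration %d: objective %.4f", it, total))
    }
    if (it > 1 && total - traj[it - 1] < tol) {
      converged <- TRUE
      break
    }
    if (it == max_iter) break
    Y <- vapply(fits, `[[`, numeric(7), "y_map")
    V <- vapply(fits, `[[`, numeric(7), "laplace_var")
    mu <- rowMeans(Y)
    sigma2 <- pmax(rowMeans(Y^2 + V) - mu^2, 1e-4)
    prior <- prior_moments(mu, sigma2)
  }
  structure(list(prior = prior, subjects = fits, em_iterations = it,
                 converged = converged, trajectory = traj),
            class = "group_fit")
}

#' @export
print.group_fit <- function(x, ...) {
  cat(sprintf("<group_fit> %d subjects, %d EM iterations (%s)\n",
              length(x$subjects), x$em_iterations,
              if (x$converged) "converged" else "not converged"))
  cat("group-prior means (back-transformed):\n")
  print(round(unclass(inverse_transform_params(x$prior$mu)), 3))
  invisible(x)
}

#' Per-subject parameter table of a group fit
#'
#' @param fit A `group_fit`.
#' @return data.frame with one row per subject: the seven back-transformed
#'   MAP parameters plus `log_post`.
#' @export
group_fit_table <- function(fit) {
  rows <- lapply(fit$subjects, function(s) {
    data.frame(subject_id = s$subject_id,
               as.list(round(as.numeric(s$params_map), 6)) |>
                 stats::setNames(PAR_NAMES),
               log_post = s$log_post, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
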