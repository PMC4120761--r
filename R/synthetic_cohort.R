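# group-level defaults on the unconstrained scale; centers are the
# empirically observed medians for this task family, spreads derived from
# the reported interquartile ranges (IQR / 1.349 under normality)
default_hybrid_mu <- function() {
  c(beta1 = log(6.55), beta2 = log(2.42), alpha1 = qlogis(0.56),
    alpha2 = qlogis(0.58), lam = qlogis(0.70), omega = qlogis(0.43),
    rho = 0.20)
}

default_hybrid_sd <- function() {
  iqr <- c(beta1 = log(7.55) - log(4.57),
           beta2 = log(4.35) - log(1.53),
           alpha1 = qlogis(0.76) - qlogis(0.28),
           alpha2 = qlogis(0.69) - qlogis(0.40),
           lam = qlogis(0.85) - qlogis(0.44),
           omega = qlogis(0.54) - qlogis(0.34),
           rho = 0.26 - 0.15)
  iqr / 1.349
}

#' Configuration of a synthetic two-task cohort
#'
#' Each synthetic subject carries a latent standard-normal
#' "goal-directedness" trait `g` that shifts both the two-step model-based
#' weight omega (on the logit scale) and the devaluation agent's
#' goal-directed weight `w` by `trait_coupling_k * g`; all other
#' parameters are sampled independently. `trait_coupling_k = 0` decouples
#' the tasks (the null of the construct-validity analysis). The default
#' `k = 3` sits near the saturation point of the expected cross-task
#' correlation: trial-sampling noise in the two interaction scores caps
#' the expected Spearman rho near 0.5 regardless of coupling strength, so
#' stronger defaults buy almost nothing (see the methods vignette).
#'
#' @param n_subjects Cohort size (default 18, the study-scale preset;
#'   presets of 50 or 200 are useful for power analyses).
#' @param trait_coupling_k Coupling strength k >= 0 on the logit scale.
#' @param mu_hybrid,sd_hybrid Group means/SDs of the hybrid parameters on
#'   the unconstrained scale (named 7-vectors).
#' @param mu_w,sd_w Group mean/SD of `logit(w)` for the devaluation agent.
#' @param mu_log_beta_d,sd_log_beta_d Group moments of `log(beta_d)`.
#' @param mu_logit_alpha_h,sd_logit_alpha_h Group moments of
#'   `logit(alpha_h)`.
#' @param n_trials_twostep Trials per two-step session (default 201).
#' @param seed Integer seed; the whole cohort is reproducible from it.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 18, trait_coupling_k = 3,
                          mu_hybrid = default_hybrid_mu(),
                          sd_hybrid = default_hybrid_sd(),
                          mu_w = 0, sd_w = 1,
                          mu_log_beta_d = log(8), sd_log_beta_d = 0.2,
                          mu_logit_alpha_h = qlogis(0.15),
                          sd_logit_alpha_h = 0.3,
                          n_trials_twostep = 201, seed = 1) {
  if (n_subjects < 4) stop("`n_subjects` must be at least 4")
  if (trait_coupling_k < 0) stop("`trait_coupling_k` must be non-negative")
  stopifnot(length(mu_hybrid) == 7, length(sd_hybrid) == 7,
            all(sd_hybrid >= 0), sd_w >= 0)
  structure(list(n_subjects = as.integer(n_subjects),
                 trait_coupling_k = trait_coupling_k,
                 mu_hybrid = stats::setNames(as.numeric(mu_hybrid), PAR_NAMES),
                 sd_hybrid = stats::setNames(as.numeric(sd_hybrid), PAR_NAMES),
                 mu_w = mu_w, sd_w = sd_w,
                 mu_log_beta_d = mu_log_beta_d,
                 sd_log_beta_d = sd_log_beta_d,
                 mu_logit_alpha_h = mu_logit_alpha_h,
                 sd_logit_alpha_h = sd_logit_alpha_h,
                 n_trials_twostep = as.integer(n_trials_twostep),
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Sample one synthetic subject's parameters
#'
#' Draws the latent trait `g ~ N(0, 1)`, then `logit(omega) = mu_omega +
#' k g + noise` and `logit(w) = mu_w + k g + noise` (noise SDs are the
#' configured group SDs), with all remaining hybrid and dual-controller
#' parameters sampled independently from their group distributions on the
#' unconstrained scale and back-transformed. Uses the current RNG stream.
#'
#' @param config A [cohort_config()].
#' @return List with `hybrid` ([hybrid_params()]), `dual`
#'   ([dual_controller_params()]) and the latent trait `g`.
#' @export
sample_subject <- function(config) {
  k <- config$trait_coupling_k
  g <- rnorm(1)
  y <- stats::setNames(rnorm(7, config$mu_hybrid, config$sd_hybrid),
                       PAR_NAMES)
  y[["omega"]] <- config$mu_hybrid[["omega"]] + k * g +
    rnorm(1, 0, config$sd_hybrid[["omega"]])
  hybrid <- inverse_transform_params(y)
  w <- plogis(config$mu_w + k * g + rnorm(1, 0, config$sd_w))
  beta_d <- exp(rnorm(1, config$mu_log_beta_d, config$sd_log_beta_d))
  alpha_h <- plogis(rnorm(1, config$mu_logit_alpha_h,
                          config$sd_logit_alpha_h))
  dual <- dual_controller_params(w = w, alpha_h = alpha_h, beta_d = beta_d)
  list(hybrid = hybrid, dual = dual, g = g)
}

#' Generate a coupled two-task cohort
#'
#' For every subject, samples parameters via [sample_subject()], simulates
#' a two-step session ([simulate_agent()], fresh reward walk per subject)
#' and a devaluation session ([simulate_dual_controller()]), and applies
#' the 75% training learning criterion; failing subjects are recorded as
#' excluded. Everything is deterministic given `config$seed`.
#'
#' @param config A [cohort_config()].
#' @return An object of class `cohort`: `config`, `subjects` (each with
#'   `subject_id`, `params`, `twostep`, `deval`, `g`, `included`) and the
#'   vector `excluded` of failing subject ids.
#' @export
generate_cohort <- function(config) {
  withr::with_seed(config$seed, {
    subjects <- lapply(seq_len(config$n_subjects), function(i) {
      id <- sprintf("sub%03d", i)
      pars <- sample_subject(config)
      ts <- simulate_agent(pars$hybrid, n_trials = config$n_trials_twostep,
                           subject_id = id)
      dv <- simulate_dual_controller(pars$dual, subject_id = id)
      crit <- training_criterion_met(dv)
      list(subject_id = id, params = pars, twostep = ts, deval = dv,
           g = pars$g, included = attr(crit, "overall"))
    })
    excluded <- vapply(subjects, function(s) !s$included, logical(1))
    structure(list(config = config, subjects = subjects,
                   excluded = vapply(subjects[excluded], `[[`, character(1),
                                     "subject_id")),
              class = "cohort")
  })
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d subjects (k = %.2f, seed %d); %d excluded by training criterion\n",
              length(x$subjects), x$config$trait_coupling_k,
              x$config$seed, length(x$excluded)))
  invisible(x)
}

#' End-to-end construct-validity analysis of a cohort
#'
#' On the subjects passing the training criterion: computes the per-subject
#' score pair (devaluation interaction score, two-step model-based
#' interaction score) and the per-subject main effect of reward, the group
#' stay-probability contrasts, and the one-tailed Spearman correlations
#' rho(deval, mb) plus the specificity check rho(deval, main effect of
#' reward). Optionally fits the hybrid model by [em_fit()] and adds
#' rho(deval, omega_MAP).
#'
#' @param cohort A [generate_cohort()] result.
#' @param fit_omega Also run the hierarchical fit and correlate the
#'   devaluation score with the fitted omega (slower).
#' @param literal_formula Passed to [deval_interaction_score()].
#' @param window Analysis window per condition (default 10).
#' @param fit_args List of extra arguments for [em_fit()].
#' @return An object of class `cv_report`: `scores` (data.frame with
#'   `subject_id`, `deval_score`, `mb_score`, `main_effect`, optional
#'   `omega_map`), `rho_deval_mb`, `rho_deval_main`, optional
#'   `rho_deval_omega` (each a [spearman_onetailed()] result),
#'   `contrasts`, `n_included`, `n_excluded`.
#' @export
run_construct_validity <- function(cohort, fit_omega = FALSE,
                                   literal_formula = FALSE, window = 10,
                                   fit_args = list()) {
  inc <- Filter(function(s) s$included, cohort$subjects)
  if (length(inc) < 4) stop("need at least 4 included subjects")
  tables <- lapply(inc, function(s) stay_table(s$twostep))
  ok <- vapply(tables, function(tb) !anyNA(tb$p_stay), logical(1))
  if (any(!ok)) {
    warning(sprintf("dropping %d subject(s) with unobserved stay-table cells",
                    sum(!ok)))
    inc <- inc[ok]
    tables <- tables[ok]
  }
  scores <- data.frame(
    subject_id = vapply(inc, `[[`, character(1), "subject_id"),
    deval_score = vapply(inc, function(s) {
      deval_interaction_score(deval_choice_counts(s$deval, window),
                              literal_formula = literal_formula)
    }, numeric(1)),
    mb_score = vapply(tables, mb_interaction_score, numeric(1)),
    main_effect = vapply(tables, function(tb) {
      p <- tb$p_stay
      mean(p["rewarded", ]) - mean(p["unrewarded", ])
    }, numeric(1)),
    stringsAsFactors = FALSE
  )
  out <- list(scores = scores,
              rho_deval_mb = spearman_onetailed(scores$deval_score,
                                                scores$mb_score),
              rho_deval_main = spearman_onetailed(scores$deval_score,
                                                  scores$main_effect),
              contrasts = reward_and_interaction_contrasts(tables),
              n_included = nrow(scores),
              n_excluded = length(cohort$subjects) - length(inc))
  if (fit_omega) {
    sessions <- lapply(inc, `[[`, "twostep")
    fit <- do.call(em_fit, c(list(sessions = sessions), fit_args))
    omega_map <- vapply(fit$subjects, function(s) s$params_map[["omega"]],
                        numeric(1))
    out$scores$omega_map <- omega_map
    out$rho_deval_omega <- spearman_onetailed(out$scores$deval_score,
                                              omega_map)
    out$fit <- fit
  }
  structure(out, class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %d subjects analyzed (%d excluded)\n",
              x$n_included, x$n_excluded))
  cat(sprintf("  rho(deval, mb)   = %.3f (one-tailed p = %.4f)\n",
              x$rho_deval_mb$rho, x$rho_deval_mb$p))
  cat(sprintf("  rho(deval, main) = %.3f (one-tailed p = %.4f)\n",
              x$rho_deval_main$rho, x$rho_deval_main$p))
  if (!is.null(x$rho_deval_omega)) {
    cat(sprintf("  rho(deval, omega) = %.3f (one-tailed p = %.4f)\n",
                x$rho_deval_omega$rho, x$rho_deval_omega$p))
  }
  print(x$contrasts$main_effect)
  print(x$contrasts$interaction)
  invisible(x)
}
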