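test_that("transforms are exact closed forms and round-trip", {
  y <- transform_params(hybrid_params(beta1 = 1, beta2 = 1, alpha1 = 0.5,
                                      alpha2 = 0.5, lam = 0.5, omega = 0.5,
                                      rho = 0))
  expect_equal(unname(y), rep(0, 7))
  y2 <- transform_params(hybrid_params(omega = 0.43))
  expect_equal(y2[["omega"]], log(0.43 / 0.57), tolerance = 1e-12)
  expect_equal(inverse_transform_params(y2)[["omega"]], 0.43,
               tolerance = 1e-12)
  # 1000 random draws round-trip to 1e-12
  set.seed(8)
  for (i in 1:1000) {
    p <- hybrid_params(beta1 = exp(rnorm(1)), beta2 = exp(rnorm(1)),
                       alpha1 = runif(1, .01, .99), alpha2 = runif(1, .01, .99),
                       lam = runif(1, .01, .99), omega = runif(1, .01, .99),
                       rho = rnorm(1))
    back <- inverse_transform_params(transform_params(p))
    expect_equal(as.numeric(back), as.numeric(p), tolerance = 1e-12)
  }
})

test_that("boundary parameters are clipped with a warning", {
  expect_warning(y <- transform_params(hybrid_params(omega = 0)), "omega")
  expect_true(is.finite(y[["omega"]]))
})

test_that("a tight prior dominates an uninformative likelihood", {
  # beta1 = beta2 = 0 makes choices independent of the parameters
  s <- simulate_agent(hybrid_params(beta1 = 0, beta2 = 0), seed = 41,
                      n_trials = 60)
  mu <- transform_params(median_params())
  prior <- prior_moments(mu, rep(1e-6, 7))
  fit <- map_fit(s, prior, n_restarts = 2, seed = 1)
  expect_true(all(abs(fit$y_map - mu) < 0.01))
  expect_true(all(fit$laplace_var > 0))
  expect_true(is.finite(fit$log_post))
})

test_that("MAP under a flat prior agrees with an independent grid search", {
  gen <- median_params(omega = 0.6)
  s <- simulate_agent(gen, seed = 42, n_trials = 400)
  flat <- prior_moments(rep(0, 7), rep(1e6, 7))
  # grid over (omega, beta1) with the other parameters fixed at truth
  grid_ll <- function(omega, beta1) {
    p <- hybrid_params(beta1 = beta1, beta2 = gen[["beta2"]],
                       alpha1 = gen[["alpha1"]], alpha2 = gen[["alpha2"]],
                       lam = gen[["lam"]], omega = omega,
                       rho = gen[["rho"]])
    session_loglik(s, p, details = FALSE)$loglik
  }
  omegas <- seq(0.05, 0.95, length.out = 11)
  betas <- seq(1, 11, length.out = 11)
  ll <- outer(omegas, betas, Vectorize(grid_ll))
  best <- which(ll == max(ll), arr.ind = TRUE)
  # optimize only (omega, beta1) through the same objective for comparability
  obj <- function(th) -grid_ll(plogis(th[1]), exp(th[2]))
  opt <- optim(c(0, log(6)), obj, method = "BFGS")
  expect_lt(abs(plogis(opt$par[1]) - omegas[best[1]]),
            diff(omegas[1:2]) + 1e-9)
  expect_lt(abs(exp(opt$par[2]) - betas[best[2]]), diff(betas[1:2]) + 1e-9)
})

test_that("MAP recovers omega from a long session under a broad prior", {
  gen <- median_params(omega = 0.35)
  s <- simulate_agent(gen, seed = 43, n_trials = 2000)
  prior <- prior_moments(rep(0, 7), rep(100, 7))
  fit <- map_fit(s, prior, n_restarts = 6, seed = 2)
  expect_lt(abs(fit$params_map[["omega"]] - 0.35), 0.1)
  # local optimality: no nearby point beats the optimum
  obj <- function(y) dualcontrol:::neg_log_post(y, s, prior)
  f0 <- obj(fit$y_map)
  set.seed(3)
  nearby <- replicate(100, fit$y_map + rnorm(7, 0, 0.05))
  expect_true(all(apply(nearby, 2, obj) >= f0 - 1e-6))
})

test_that("EM shrinks the prior on a homogeneous cohort and is monotone", {
  gen <- median_params()
  sessions <- lapply(1:6, function(i) {
    simulate_agent(gen, seed = 50 + i, n_trials = 150,
                   subject_id = paste0("s", i))
  })
  fit <- em_fit(sessions, max_iter = 8, n_restarts = 3, seed = 4)
  expect_true(all(diff(fit$trajectory) > -1e-3))
  expect_equal(length(fit$subjects), 6)
  # prior variance shrinks from its broad start on every coordinate
  expect_true(all(fit$prior$sigma2 < 5))
  expect_true(is.finite(fit$prior$mu[["omega"]]))
})

test_that("em_fit flags non-convergence instead of erroring", {
  sessions <- lapply(1:3, function(i) {
    simulate_agent(median_params(), seed = 60 + i, n_trials = 60,
                   subject_id = paste0("s", i))
  })
  fit <- em_fit(sessions, max_iter = 2, n_restarts = 2, seed = 5)
  expect_false(fit$converged)
  expect_equal(fit$em_iterations, 2)
  expect_error(em_fit(sessions[1]), "at least 2")
})
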