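test_that("parameter constructor enforces bounds", {
  expect_error(hybrid_params(beta1 = -1), "non-negative")
  expect_error(hybrid_params(omega = 1.2), "omega")
  p <- hybrid_params()
  expect_named(p, c("beta1", "beta2", "alpha1", "alpha2", "lam", "omega",
                    "rho"))
})

test_that("model-based values weight the better second-stage option by the true transition probabilities", {
  ts <- transition_structure()
  q <- q_values(q2 = matrix(c(0.6, 0.3, 0.2, 0.1), 2, 2))  # QB=(.6,.2), QC=(.3,.1)
  expect_equal(mb_values(q, ts), c(0.51, 0.39))
  # all second-stage values equal -> both MB values collapse to that value
  qc <- q_values(q2 = matrix(0.37, 2, 2))
  expect_equal(mb_values(qc, ts), c(0.37, 0.37))
})

test_that("net values interpolate between model-free and model-based", {
  ts <- transition_structure()
  q <- q_values(q1 = c(0.2, 0.4), q2 = matrix(c(0.6, 0.3, 0.2, 0.1), 2, 2))
  expect_equal(net_values(q, ts, 0), c(0.2, 0.4))
  expect_equal(net_values(q, ts, 1), mb_values(q, ts))
  expect_equal(net_values(q, ts, 0.5), c(0.355, 0.395))
  expect_error(net_values(q, ts, 1.5), "omega")
})

test_that("softmax choice rule matches its logistic closed form", {
  expect_equal(choice_probs(c(5, -3), 0), c(0.5, 0.5))
  p <- choice_probs(c(0.51, 0.39), 1)
  expect_equal(p[1], 1 / (1 + exp(-0.12)), tolerance = 1e-12)
  expect_equal(sum(p), 1, tolerance = 1e-12)
  # perseveration shifts choice toward repeating
  pr <- choice_probs(c(0.3, 0.3), 1, rho = 0.2, prev_action = 0)
  expect_equal(pr[1], 1 / (1 + exp(-0.2)), tolerance = 1e-12)
  # extreme values do not overflow
  expect_equal(choice_probs(c(1e6, 0), 10), c(1, 0))
})

test_that("softmax probabilities are monotone in the value difference", {
  diffs <- seq(-2, 2, length.out = 21)
  p0 <- vapply(diffs, function(d) choice_probs(c(d, 0), 3)[1], numeric(1))
  expect_true(all(diff(p0) > 0))
  expect_true(all(abs(p0 + rev(p0) - 1) < 1e-12))
})

test_that("trial updates implement the stage-skipping SARSA rule", {
  p <- hybrid_params(alpha1 = 0.4, alpha2 = 0.5, lam = 0.5)
  q <- q_values(q1 = c(0.2, 0), q2 = matrix(c(0.4, 0, 0, 0), 2, 2))
  out <- apply_trial_updates(q, list(a1 = 0, s2 = 0, a2 = 0, r = 1), p)
  expect_equal(out$comp$delta1, 0.2)
  expect_equal(out$comp$delta2, 0.6)
  expect_equal(out$q$q2[1, 1], 0.7)                   # 0.4 + 0.5 * 0.6
  expect_equal(out$q$q1[1], 0.2 + 0.4 * 0.2 + 0.4 * 0.5 * 0.6)
  # zero learning rates leave values untouched but still report errors
  p0 <- hybrid_params(alpha1 = 0, alpha2 = 0, lam = 0.5)
  out0 <- apply_trial_updates(q, list(a1 = 0, s2 = 0, a2 = 0, r = 1), p0)
  expect_equal(out0$q$q1, q$q1)
  expect_equal(out0$q$q2, q$q2)
  expect_equal(out0$comp$delta2, 0.6)
})

test_that("first-trial likelihood is uniform over both stages", {
  s <- make_session(a1 = 0, s2 = 1, a2 = 1, r = 1)
  ll <- session_loglik(s, median_params())
  expect_equal(ll$loglik, 2 * log(0.5), tolerance = 1e-12)
  expect_equal(ll$trials$rep1, 0L)
})

test_that("likelihood matches the step-wise oracle on all 64 three-trial configurations", {
  pars <- list(beta1 = 2, beta2 = 2, alpha1 = 0.5, alpha2 = 0.5,
               lam = 0.5, omega = 0.5, rho = 0.1)
  hp <- do.call(hybrid_params, pars)
  configs <- expand.grid(a11 = 0:1, s21 = 0:1, a21 = 0:1, r1 = 0:1,
                         a12 = 0:1, r2 = 0:1)[1:64, ]
  for (i in seq_len(nrow(configs))) {
    cf <- configs[i, ]
    trials <- data.frame(a1 = c(cf$a11, cf$a12, 1),
                         s2 = c(cf$s21, 1 - cf$s21, 0),
                         a2 = c(cf$a21, cf$a12, 1),
                         r = c(cf$r1, cf$r2, 1))
    s <- make_session(trials$a1, trials$s2, trials$a2, trials$r)
    expect_equal(session_loglik(s, hp)$loglik,
                 oracle_loglik(trials, pars), tolerance = 1e-10)
  }
})

test_that("likelihood equals the sum of per-trial log contributions", {
  s <- simulate_agent(median_params(), seed = 21, n_trials = 150)
  ll <- session_loglik(s, median_params())
  expect_equal(ll$loglik, sum(log(ll$trials$p_a1)) + sum(log(ll$trials$p_a2)),
               tolerance = 1e-10)
})

test_that("a purely model-free learner is blind to the transition labeling", {
  p_mf <- median_params(omega = 0)
  s <- simulate_agent(p_mf, seed = 13)
  swapped <- transition_structure(common_map = c(1L, 0L))
  tr <- s$trials
  tr$transition <- ifelse(tr$transition == "common", "rare", "common")
  s_swap <- twostep_session(s$subject_id, tr, structure = swapped)
  expect_equal(session_loglik(s, p_mf)$loglik,
               session_loglik(s_swap, p_mf)$loglik, tolerance = 1e-12)
})

test_that("second-stage values stay within [0, 1] for binary rewards", {
  s <- simulate_agent(median_params(), seed = 31)
  q <- q_values()
  p <- median_params()
  for (i in seq_len(nrow(s$trials))) {
    q <- apply_trial_updates(q, s$trials[i, ], p)$q
    expect_true(all(q$q2 >= 0 & q$q2 <= 1))
  }
})

test_that("a zero-temperature agent chooses at random", {
  s <- simulate_agent(hybrid_params(beta1 = 0, beta2 = 0), seed = 17,
                      n_trials = 2000)
  expect_lt(abs(mean(s$trials$a1) - 0.5), 0.03)
})

test_that("malformed trial sequences are rejected with the offending index", {
  s <- make_session(a1 = c(0, 1), s2 = c(0, 1), a2 = c(0, 0), r = c(1, 0))
  s$trials$s2[2] <- 5
  expect_error(session_loglik(s, median_params()), "trial 2")
})
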