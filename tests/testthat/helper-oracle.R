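# Independent step-wise likelihood oracle, written directly from the
# update equations with naive bookkeeping. Deliberately shares no code
# with the package implementation.
#
# pars: list with beta1, beta2, alpha1, alpha2, lam, omega, rho
# trials: data.frame with a1, s2, a2, r (0/1 coding)
# p_common, common_map as in transition_structure()
oracle_loglik <- function(trials, pars, p_common = 0.7,
                          common_map = c(0L, 1L)) {
  QB <- c(0, 0)  # second-stage state 0
  QC <- c(0, 0)  # second-stage state 1
  QA <- c(0, 0)  # first-stage model-free
  prev_a1 <- NA
  ll <- 0
  for (i in seq_len(nrow(trials))) {
    a1 <- trials$a1[i]
    s2 <- trials$s2[i]
    a2 <- trials$a2[i]
    r <- trials$r[i]
    # model-based values from true transition probabilities
    qmb <- numeric(2)
    for (a in 0:1) {
      pB <- if (common_map[a + 1] == 0) p_common else 1 - p_common
      qmb[a + 1] <- pB * max(QB) + (1 - pB) * max(QC)
    }
    qnet <- pars$omega * qmb + (1 - pars$omega) * QA
    bonus <- c(0, 0)
    if (!is.na(prev_a1)) bonus[prev_a1 + 1] <- pars$rho
    z1 <- exp(pars$beta1 * (qnet + bonus))
    p1 <- z1 / sum(z1)
    q2 <- if (s2 == 0) QB else QC
    z2 <- exp(pars$beta2 * q2)
    p2 <- z2 / sum(z2)
    ll <- ll + log(p1[a1 + 1]) + log(p2[a2 + 1])
    # prediction errors from pre-update values
    d1 <- q2[a2 + 1] - QA[a1 + 1]
    d2 <- r - q2[a2 + 1]
    if (s2 == 0) {
      QB[a2 + 1] <- QB[a2 + 1] + pars$alpha2 * d2
    } else {
      QC[a2 + 1] <- QC[a2 + 1] + pars$alpha2 * d2
    }
    QA[a1 + 1] <- QA[a1 + 1] + pars$alpha1 * d1 +
      pars$alpha1 * pars$lam * d2
    prev_a1 <- a1
  }
  ll
}

# build a twostep_session from bare vectors under the default structure
make_session <- function(a1, s2, a2, r, id = "t",
                         structure = transition_structure()) {
  transition <- ifelse(s2 == structure$common_map[a1 + 1], "common", "rare")
  twostep_session(id, data.frame(t = seq_along(a1), a1 = a1, s2 = s2,
                                 a2 = a2, r = r, transition = transition,
                                 stringsAsFactors = FALSE),
                  structure = structure)
}

# hybrid parameters at the empirically observed group medians
median_params <- function(omega = 0.43, lam = 0.70) {
  hybrid_params(beta1 = 6.55, beta2 = 2.42, alpha1 = 0.56, alpha2 = 0.58,
                lam = lam, omega = omega, rho = 0.20)
}
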