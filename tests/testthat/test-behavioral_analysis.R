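test_that("stay tables tally a hand-built sequence correctly", {
  # a1 = 0,0,1; predecessors: (rewarded, common) stayed; (unrewarded, rare) switched
  s <- make_session(a1 = c(0, 0, 1), s2 = c(0, 1, 0), a2 = c(0, 0, 1),
                    r = c(1, 0, 1))
  tb <- stay_table(s)
  expect_equal(tb$p_stay["rewarded", "common"], 1)
  expect_equal(tb$p_stay["unrewarded", "rare"], 0)
  expect_true(is.na(tb$p_stay["rewarded", "rare"]))
  expect_true(is.na(tb$p_stay["unrewarded", "common"]))
  expect_equal(sum(tb$n), 2)
  expect_error(stay_table(make_session(0, 0, 0, 1)), "2 trials")
})

test_that("constant and alternating choosers bracket the stay probabilities", {
  n <- 40
  set.seed(1)
  s2 <- sample(0:1, n, replace = TRUE)
  r <- sample(0:1, n, replace = TRUE)
  s_const <- make_session(rep(0, n), s2, rep(0, n), r)
  expect_true(all(stay_table(s_const)$p_stay == 1, na.rm = TRUE))
  s_alt <- make_session(rep(c(0, 1), n / 2), s2, rep(0, n), r)
  expect_true(all(stay_table(s_alt)$p_stay == 0, na.rm = TRUE))
})

test_that("group contrasts equal the within-subject ANOVA computed independently", {
  cells <- rbind(c(0.9, 0.6, 0.7, 0.8),
                 c(0.8, 0.5, 0.6, 0.6),
                 c(0.7, 0.7, 0.5, 0.9),
                 c(0.95, 0.4, 0.65, 0.7))  # RC, RR, UC, UR
  tables <- apply(cells, 1, function(x) {
    structure(list(p_stay = matrix(x, 2, 2, byrow = TRUE,
                                   dimnames = list(c("rewarded", "unrewarded"),
                                                   c("common", "rare"))),
                   n = matrix(10, 2, 2)), class = "stay_table")
  })
  res <- reward_and_interaction_contrasts(tables)
  # independent route: base aov with within-subject error strata
  long <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    data.frame(subject = factor(i),
               reward = factor(c("R", "R", "U", "U")),
               trans = factor(c("C", "R", "C", "R")),
               p = cells[i, ])
  }))
  fit <- stats::aov(p ~ reward * trans + Error(subject / (reward * trans)),
                    data = long)
  sm <- summary(fit)
  f_main <- sm[["Error: subject:reward"]][[1]]["reward", "F value"]
  f_int <- sm[["Error: subject:reward:trans"]][[1]]["reward:trans", "F value"]
  expect_equal(res$main_effect$F, f_main, tolerance = 1e-8)
  expect_equal(res$interaction$F, f_int, tolerance = 1e-8)
  expect_equal(res$main_effect$F, res$main_effect$t^2, tolerance = 1e-10)
  expect_equal(res$interaction$F, res$interaction$t^2, tolerance = 1e-10)
})

test_that("identical null tables give zero contrasts and F", {
  tb <- structure(list(p_stay = matrix(0.6, 2, 2,
                                       dimnames = list(c("rewarded", "unrewarded"),
                                                       c("common", "rare"))),
                       n = matrix(10, 2, 2)), class = "stay_table")
  res <- reward_and_interaction_contrasts(list(tb, tb, tb, tb))
  expect_equal(res$main_effect$mean, 0)
  expect_equal(res$main_effect$F, 0)
  expect_equal(res$interaction$F, 0)
})

test_that("subjects with missing cells are dropped from group contrasts", {
  full <- structure(list(p_stay = matrix(c(0.9, 0.5, 0.6, 0.8), 2, 2,
                                         dimnames = list(c("rewarded", "unrewarded"),
                                                         c("common", "rare"))),
                         n = matrix(10, 2, 2)), class = "stay_table")
  holey <- full
  holey$p_stay["rewarded", "rare"] <- NA
  expect_warning(res <- reward_and_interaction_contrasts(
    list(full, full, full, holey)), "dropping 1")
  expect_equal(res$main_effect$df[2], 2)
})

test_that("the model-based interaction score isolates the interaction", {
  mk <- function(rc, rr, uc, ur) {
    structure(list(p_stay = matrix(c(rc, uc, rr, ur), 2, 2,
                                   dimnames = list(c("rewarded", "unrewarded"),
                                                   c("common", "rare"))),
                   n = matrix(5, 2, 2)), class = "stay_table")
  }
  expect_equal(mb_interaction_score(mk(0.9, 0.6, 0.6, 0.9)), 0.6)
  expect_equal(mb_interaction_score(mk(0.5, 0.5, 0.5, 0.5)), 0)
  # a pure main effect of reward yields zero
  expect_equal(mb_interaction_score(mk(0.8, 0.8, 0.4, 0.4)), 0)
  # invariant to adding a constant to every cell
  expect_equal(mb_interaction_score(mk(0.7, 0.4, 0.4, 0.7)),
               mb_interaction_score(mk(0.9, 0.6, 0.6, 0.9)))
  # swapping transition labels flips the sign
  expect_equal(mb_interaction_score(mk(0.6, 0.9, 0.9, 0.6)), -0.6)
  bad <- mk(0.9, NA, 0.6, 0.9)
  expect_error(mb_interaction_score(bad), "missing")
})

test_that("devaluation choice counts use the pre/post analysis windows", {
  s <- simulate_dual_controller(dual_controller_params(w = 1, beta_d = 50),
                                seed = 11)
  # near-deterministic agent: ceiling pre, floor post in devalued condition
  cnt <- deval_choice_counts(s)
  expect_equal(dim(cnt), c(2, 3))
  expect_true(all(cnt >= 0 & cnt <= 10))
  expect_equal(cnt["pre", "valued"], 10)
  expect_error(deval_choice_counts(s, window = 60), "fewer than")

  # hand-tallied fixture: known alternating choices in one condition
  idx_tr <- which(s$trials$phase == "training" & s$trials$condition == "neutral")
  s$trials$choice[tail(idx_tr, 10)] <- rep(c("high", "low"), 5)
  expect_equal(deval_choice_counts(s)["pre", "neutral"], 5)
})

test_that("the devaluation score orientation makes higher mean more goal-directed", {
  cnt <- matrix(c(9, 2, 8, 8, 7, 7), 2, 3,
                dimnames = list(c("pre", "post"),
                                c("devalued", "valued", "neutral")))
  expect_equal(deval_interaction_score(cnt), 7)
  expect_equal(deval_interaction_score(cnt, literal_formula = TRUE), -7)
  # no change anywhere, or equal drops, cancel to zero
  null_cnt <- matrix(8, 2, 3, dimnames = dimnames(cnt))
  expect_equal(deval_interaction_score(null_cnt), 0)
  eq_drop <- matrix(c(9, 5, 9, 5, 8, 8), 2, 3, dimnames = dimnames(cnt))
  expect_equal(deval_interaction_score(eq_drop), 0)
})

test_that("spearman correlation is exact for small n and calibrated for larger n", {
  res <- spearman_onetailed(1:5, c(10, 20, 21, 40, 100))
  expect_equal(res$rho, 1)
  expect_equal(res$p, 1 / 120)
  res_neg <- spearman_onetailed(1:5, 5:1)
  expect_equal(res_neg$rho, -1)
  expect_gt(res_neg$p, 0.99)
  expect_error(spearman_onetailed(rep(1, 5), 1:5), "constant")
  expect_error(spearman_onetailed(1:3, 1:3), "at least 4")
})

test_that("spearman rho is invariant under monotone transforms and matches cor.test", {
  set.seed(2)
  x <- rnorm(13)
  y <- 0.5 * x + rnorm(13)
  a <- spearman_onetailed(x, y)
  b <- spearman_onetailed(exp(x), y)
  cc <- spearman_onetailed(x, y^3 + 10 * y)
  expect_equal(a$rho, b$rho)
  expect_equal(a$rho, cc$rho)
  ct <- stats::cor.test(x, y, method = "spearman", alternative = "greater",
                        exact = FALSE)
  expect_equal(a$rho, unname(ct$estimate))
  expect_equal(a$p, ct$p.value, tolerance = 0.02)
})

test_that("one-tailed p-values are uniform under independence", {
  set.seed(5)
  p <- replicate(4000, spearman_onetailed(rnorm(13), rnorm(13))$p)
  expect_lt(abs(mean(p < 0.05) - 0.05), 0.015)
  expect_lt(abs(mean(p < 0.5) - 0.5), 0.03)
})
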