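#' Design of the selective outcome-devaluation paradigm
#'
#' Three interleaved instrumental conditions (two food conditions -- one
#' later devalued, one staying valued -- and a neutral water condition),
#' each a choice between a high- and a low-probability stimulus. During
#' training the high-probability stimulus of a food condition delivers its
#' food with p = 0.5 and the common fruit-tea outcome with p = 0.25; the
#' low-probability stimulus delivers only tea with p = 0.25. The neutral
#' condition delivers water with p = 0.75 (high) or p = 0.25 (low). In the
#' post-devaluation extinction test the foods are withheld and tea is
#' delivered with p = 0.3 for either stimulus of the food conditions; the
#' neutral condition continues as in training.
#'
#' @param n_training,n_extinction Total trials per phase (default 150,
#'   i.e. 50 per condition).
#' @param analysis_window Trials per condition entering the pre/post
#'   comparison (default 10).
#' @return An object of class `deval_design` holding the per-phase,
#'   per-condition, per-stimulus outcome distributions (remaining mass is
#'   "none").
#' @export
deval_design <- function(n_training = 150, n_extinction = 150,
                         analysis_window = 10) {
  food_training <- list(high = c(food = 0.5, tea = 0.25, none = 0.25),
                        low = c(tea = 0.25, none = 0.75))
  neutral_training <- list(high = c(water = 0.75, none = 0.25),
                           low = c(water = 0.25, none = 0.75))
  food_extinction <- list(high = c(tea = 0.3, none = 0.7),
                          low = c(tea = 0.3, none = 0.7))
  probs <- list(
    training = list(devalued = food_training, valued = food_training,
                    neutral = neutral_training),
    extinction = list(devalued = food_extinction, valued = food_extinction,
                      neutral = neutral_training)
  )
  for (ph in probs) for (cond in ph) for (p in cond) {
    stopifnot(sum(p) <= 1 + 1e-12)
  }
  structure(list(probs = probs,
                 conditions = c("devalued", "valued", "neutral"),
                 n_training = as.integer(n_training),
                 n_extinction = as.integer(n_extinction),
                 analysis_window = as.integer(analysis_window)),
            class = "deval_design")
}

#' Sample one trial outcome of the devaluation paradigm
#'
#' Draws from the design's categorical outcome distribution for the given
#' condition, stimulus and phase. Food is never delivered in extinction by
#' construction of the design. Uses the current RNG stream.
#'
#' @param condition `"devalued"`, `"valued"` or `"neutral"`.
#' @param choice `"high"` or `"low"` probability stimulus.
#' @param phase `"training"` or `"extinction"`.
#' @param design A [deval_design()].
#' @return Character scalar: `"food"`, `"tea"`, `"water"` or `"none"`.
#' @export
sample_outcome <- function(condition, choice, phase, design = deval_design()) {
  ph <- design$probs[[phase]]
  if (is.null(ph)) stop("unknown phase: ", phase)
  cond <- ph[[condition]]
  if (is.null(cond)) stop("unknown condition: ", condition)
  p <- cond[[choice]]
  if (is.null(p)) stop("unknown choice: ", choice)
  full <- c(p, none = max(0, 1 - sum(p)))
  full <- tapply(full, names(full), sum)  # merge duplicate "none" mass
  sample(names(full), 1L, prob = full)
}

#' Parameters of the dual-controller devaluation agent
#'
#' A synthetic stand-in for a human subject in the devaluation paradigm:
#' choices mix a goal-directed value `G` (expected current utility of each
#' stimulus under the true training contingencies) and a habit value `H`
#' (running average of delivered-outcome utility) with weight `w`, passed
#' through a softmax. Devaluation changes only the utility entering `G`;
#' `H` is insensitive to it until new outcomes are experienced.
#'
#' @param w Goal-directed weight in \[0, 1\].
#' @param alpha_h Habit learning rate in \[0, 1\] (running-average step).
#' @param beta_d Choice inverse temperature, non-negative.
#' @param utilities Named utilities of the four outcomes before
#'   devaluation.
#' @param u_deval Utility of the devalued food after satiety. The default
#'   -0.25 encodes that the sated food becomes mildly aversive (subjects
#'   typically rate it unpleasant), not merely neutral.
#' @return An object of class `dual_controller_params`.
#' @export
dual_controller_params <- function(w = 0.5, alpha_h = 0.15, beta_d = 8,
                                   utilities = c(food = 1, tea = 0.5,
                                                 water = 0.5, none = 0),
                                   u_deval = -0.25) {
  if (w < 0 || w > 1) stop("`w` must lie in [0, 1]")
  if (alpha_h < 0 || alpha_h > 1) stop("`alpha_h` must lie in [0, 1]")
  if (beta_d < 0) stop("`beta_d` must be non-negative")
  if (!all(c("food", "tea", "water", "none") %in% names(utilities))) {
    stop("`utilities` must name food, tea, water and none")
  }
  if (any(!is.finite(utilities)) || !is.finite(u_deval)) {
    stop("utilities must be finite")
  }
  structure(list(w = w, alpha_h = alpha_h, beta_d = beta_d,
                 utilities = utilities, u_deval = u_deval),
            class = "dual_controller_params")
}

# expected utility of each stimulus under the design's true training
# contingencies; `food_utility` lets the caller devalue one condition's food
goal_values <- function(design, utilities, condition, food_utility) {
  u <- utilities
  u[["food"]] <- food_utility
  vapply(c("high", "low"), function(ch) {
    p <- design$probs$training[[condition]][[ch]]
    sum(p * u[names(p)])
  }, numeric(1))
}

#' Simulate a dual-controller agent through the devaluation paradigm
#'
#' Training: on each trial (condition order fully randomized) the agent
#' chooses by softmax over `w * G + (1 - w) * H`, where `G` uses the true
#' contingencies and current utilities and `H` tracks delivered utility by
#' a running average. Devaluation: the devalued condition's food utility is
#' set to `u_deval`; `G` is recomputed, `H` is left untouched. Extinction:
#' choices are read out from the frozen values (the 10-trial analysis
#' windows are too short for appreciable relearning, so no updating is
#' applied in this phase); outcomes are sampled from the extinction
#' contingencies.
#'
#' @param params A [dual_controller_params()].
#' @param design A [deval_design()].
#' @param seed Optional integer seed (deterministic given the seed).
#' @param subject_id Identifier stored in the session.
#' @param devalued_food Which food is devalued, `"chocolate"` or
#'   `"tomato"`; sampled at random when `NULL`.
#' @return An object of class `deval_session`: `subject_id`,
#'   `devalued_condition`, a `trials` data.frame (`phase`, `t`,
#'   `condition`, `choice`, `outcome`) and the `design`.
#' @examples
#' s <- simulate_dual_controller(dual_controller_params(w = 1), seed = 1)
#' table(s$trials$phase)
#' @export
simulate_dual_controller <- function(params, design = deval_design(),
                                     seed = NULL, subject_id = "agent",
                                     devalued_food = NULL) {
  conds <- design$conditions
  n_tr <- design$n_training
  n_ex <- design$n_extinction
  stopifnot(n_tr %% length(conds) == 0, n_ex %% length(conds) == 0)
  with_seed_or_stream(seed, function() {
    dev_food <- devalued_food %||% sample(c("chocolate", "tomato"), 1L)
    u0 <- params$utilities
    G <- vapply(conds, function(cn) goal_values(design, u0, cn, u0[["food"]]),
                numeric(2))  # 2 x 3, rows high/low
    H <- matrix(0, 2, length(conds), dimnames = list(c("high", "low"), conds))
    order_tr <- sample(rep(conds, n_tr / length(conds)))
    choice <- character(n_tr)
    outcome <- character(n_tr)
    for (t in seq_len(n_tr)) {
      cn <- order_tr[t]
      j <- match(cn, conds)
      v <- params$w * G[, j] + (1 - params$w) * H[, j]
      p_high <- 1 / (1 + exp(-params$beta_d * (v[1] - v[2])))
      ch <- if (runif(1) < p_high) "high" else "low"
      o <- sample_outcome(cn, ch, "training", design)
      i <- if (ch == "high") 1L else 2L
      H[i, j] <- H[i, j] + params$alpha_h * (u0[[o]] - H[i, j])
      choice[t] <- ch
      outcome[t] <- o
    }
    # devaluation event: only the devalued condition's food loses utility
    G_post <- G
    G_post[, "devalued"] <- goal_values(design, u0, "devalued",
                                        params$u_deval)
    order_ex <- sample(rep(conds, n_ex / length(conds)))
    choice_ex <- character(n_ex)
    outcome_ex <- character(n_ex)
    for (t in seq_len(n_ex)) {
      cn <- order_ex[t]
      j <- match(cn, conds)
      v <- params$w * G_post[, j] + (1 - params$w) * H[, j]
      p_high <- 1 / (1 + exp(-params$beta_d * (v[1] - v[2])))
      ch <- if (runif(1) < p_high) "high" else "low"
      choice_ex[t] <- ch
      outcome_ex[t] <- sample_outcome(cn, ch, "extinction", design)
    }
    trials <- data.frame(
      phase = rep(c("training", "extinction"), c(n_tr, n_ex)),
      t = c(seq_len(n_tr), seq_len(n_ex)),
      condition = c(order_tr, order_ex),
      choice = c(choice, choice_ex),
      outcome = c(outcome, outcome_ex),
      stringsAsFactors = FALSE
    )
    structure(list(subject_id = as.character(subject_id),
                   devalued_condition = dev_food, trials = trials,
                   design = design),
              class = "deval_session")
  })
}

#' @export
print.deval_session <- function(x, ...) {
  tr <- x$trials
  cat(sprintf("<deval_session> subject %s (devalued food: %s)\n",
              x$subject_id, x$devalued_condition))
  cat(sprintf("  %d training + %d extinction trials; training high-prob rate %.3f\n",
              sum(tr$phase == "training"), sum(tr$phase == "extinction"),
              mean(tr$choice[tr$phase == "training"] == "high")))
  invisible(x)
}

#' Training learning criterion
#'
#' Whether the fraction of high-probability-stimulus choices during
#' training reaches the criterion in each condition (default 75%, the
#' standard exclusion rule; the comparison is inclusive, so exactly 75%
#' passes).
#'
#' @param session A `deval_session`.
#' @param threshold Criterion fraction, default 0.75.
#' @return Named logical vector (one entry per condition) with attribute
#'   `overall`, `TRUE` iff every condition passes.
#' @export
training_criterion_met <- function(session, threshold = 0.75) {
  tr <- session$trials[session$trials$phase == "training", ]
  if (nrow(tr) == 0) stop("session has no training phase")
  res <- vapply(session$design$conditions, function(cn) {
    sub <- tr[tr$condition == cn, ]
    if (nrow(sub) == 0) stop("no training trials for condition ", cn)
    mean(sub$choice == "high") >= threshold
  }, logical(1))
  attr(res, "overall") <- all(res)
  res
}
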