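#' Transition structure of the two-step task
#'
#' Each of the two first-stage actions leads "commonly" (with probability
#' `p_common`, 0.7 in the standard task) to one of the two second-stage
#' states and "rarely" (probability `1 - p_common`) to the other. The two
#' actions must map to distinct common states so that the transition
#' structure is informative.
#'
#' @param common_map Integer vector of length 2: `common_map[a + 1]` is the
#'   common second-stage state (0 or 1) for first-stage action `a`
#'   (actions and states are 0-indexed).
#' @param p_common Probability of the common transition, in (0.5, 1].
#' @return An object of class `transition_structure`.
#' @examples
#' ts <- transition_structure()
#' ts$p_common
#' @export
transition_structure <- function(common_map = c(0L, 1L), p_common = 0.7) {
  common_map <- as.integer(common_map)
  if (length(common_map) != 2L || !all(common_map %in% 0:1) ||
      common_map[1] == common_map[2]) {
    stop("`common_map` must map the two first-stage actions to distinct ",
         "second-stage states coded 0/1")
  }
  if (!is.numeric(p_common) || length(p_common) != 1L ||
      p_common <= 0.5 || p_common > 1) {
    stop("`p_common` must be a single probability in (0.5, 1]")
  }
  structure(list(common_map = common_map, p_common = p_common),
            class = "transition_structure")
}

# fold values back across violated bounds; a single fold suffices for
# innovations much smaller than the bound width, the loop guards
# pathological step sizes
reflect_bounds <- function(x, lower, upper) {
  repeat {
    below <- x < lower
    above <- x > upper
    if (!any(below) && !any(above)) {
      return(x)
    }
    x[below] <- 2 * lower - x[below]
    x[above] <- 2 * upper - x[above]
  }
}

#' Drifting reward probabilities for the four second-stage stimuli
#'
#' Generates independent Gaussian random walks with reflecting boundaries,
#' one per second-stage stimulus (2 states x 2 actions). Column
#' `2 * s2 + a2 + 1` holds the reward probability of action `a2` in
#' second-stage state `s2` (both 0-indexed). The walks drift slowly so that
#' second-stage values must be updated continuously throughout a session.
#'
#' @param n_trials Number of trials (rows), a positive integer.
#' @param sd_innovation Standard deviation of the per-trial Gaussian
#'   increments. The default 0.025 keeps drift slow relative to a
#'   201-trial session.
#' @param bounds Length-2 numeric, the reflecting boundaries (default
#'   `c(0.25, 0.75)`).
#' @param seed Optional integer seed; the walk is deterministic given the
#'   seed. With `seed = NULL` the current RNG stream is used.
#' @return An object of class `reward_walk`: a list with `probs`
#'   (`n_trials` x 4 matrix), `sd_innovation` and `bounds`.
#' @examples
#' w <- generate_reward_walk(201, seed = 1)
#' range(w$probs)
#' @export
generate_reward_walk <- function(n_trials, sd_innovation = 0.025,
                                 bounds = c(0.25, 0.75), seed = NULL) {
  if (!is.numeric(n_trials) || length(n_trials) != 1L || n_trials < 1) {
    stop("`n_trials` must be a positive integer")
  }
  n_trials <- as.integer(n_trials)
  if (!is.numeric(sd_innovation) || sd_innovation <= 0) {
    stop("`sd_innovation` must be positive")
  }
  if (length(bounds) != 2L || bounds[1] >= bounds[2] ||
      bounds[1] <= 0 || bounds[2] >= 1) {
    stop("`bounds` must satisfy 0 < lower < upper < 1")
  }
  probs <- with_seed_or_stream(seed, function() {
    p <- matrix(NA_real_, n_trials, 4)
    p[1, ] <- runif(4, bounds[1], bounds[2])
    if (n_trials > 1) {
      for (t in seq_len(n_trials - 1)) {
        p[t + 1, ] <- reflect_bounds(p[t, ] + rnorm(4, 0, sd_innovation),
                                     bounds[1], bounds[2])
      }
    }
    p
  })
  structure(list(probs = probs, sd_innovation = sd_innovation,
                 bounds = bounds),
            class = "reward_walk")
}

#' Execute one two-step trial
#'
#' Samples the second-stage state from the transition structure, obtains the
#' second-stage choice from a supplied callback (an agent's policy, or a
#' constant for forced choices) and samples the binary reward from the walk
#' probability of the chosen stimulus at trial `t`. Randomness is drawn from
#' the current RNG stream; seed callers that need reproducibility.
#'
#' @param a1 First-stage action, 0 or 1.
#' @param t Trial index (1-based) into the reward walk.
#' @param structure A [transition_structure()].
#' @param walk A [generate_reward_walk()] object.
#' @param a2_supplier Function of the second-stage state returning the
#'   second-stage action (0 or 1).
#' @return A list with fields `t`, `a1`, `s2`, `a2`, `r` and `transition`
#'   (`"common"` or `"rare"`).
#' @export
step_twostep <- function(a1, t, structure, walk, a2_supplier) {
  n <- nrow(walk$probs)
  if (t < 1 || t > n) {
    stop(sprintf("trial index %d outside the walk's range 1..%d", t, n))
  }
  a1 <- as.integer(a1)
  common <- structure$common_map[a1 + 1L]
  s2 <- if (runif(1) < structure$p_common) common else 1L - common
  a2 <- as.integer(a2_supplier(s2))
  p_r <- walk$probs[t, 2L * s2 + a2 + 1L]
  r <- as.integer(runif(1) < p_r)
  list(t = as.integer(t), a1 = a1, s2 = s2, a2 = a2, r = r,
       transition = if (s2 == common) "common" else "rare")
}

validate_twostep_trials <- function(trials) {
  needed <- c("t", "a1", "s2", "a2", "r", "transition")
  missing_cols <- setdiff(needed, names(trials))
  if (length(missing_cols)) {
    stop("trial table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (!all(trials$t == seq_len(nrow(trials)))) {
    stop("trial indices must be consecutive from 1")
  }
  for (col in c("a1", "s2", "a2")) {
    bad <- which(!trials[[col]] %in% 0:1)
    if (length(bad)) {
      stop(sprintf("trial %d: `%s` must be 0 or 1", bad[1], col))
    }
  }
  bad_r <- which(!trials$r %in% 0:1)
  if (length(bad_r)) {
    stop(sprintf("trial %d: `r` must be 0 or 1", bad_r[1]))
  }
  bad_tr <- which(!trials$transition %in% c("common", "rare"))
  if (length(bad_tr)) {
    stop(sprintf("trial %d: `transition` must be \"common\" or \"rare\"",
                 bad_tr[1]))
  }
  invisible(trials)
}

#' Bundle two-step trials into a session
#'
#' @param subject_id Subject identifier.
#' @param trials data.frame with columns `t`, `a1`, `s2`, `a2`, `r`,
#'   `transition`; trial indices must run consecutively from 1.
#' @param walk Optional [generate_reward_walk()] used to generate the
#'   trials (not needed for likelihood evaluation).
#' @param structure The [transition_structure()] of the task.
#' @return An object of class `twostep_session`.
#' @export
twostep_session <- function(subject_id, trials,
                            walk = NULL,
                            structure = transition_structure()) {
  trials <- as.data.frame(trials)
  validate_twostep_trials(trials)
  if (!is.null(walk) && nrow(walk$probs) < nrow(trials)) {
    stop("reward walk shorter than the trial sequence")
  }
  structure(list(subject_id = as.character(subject_id), trials = trials,
                 walk = walk, structure = structure),
            class = "twostep_session")
}

#' @export
print.twostep_session <- function(x, ...) {
  cat(sprintf("<twostep_session> subject %s: %d trials, p_common = %.2f\n",
              x$subject_id, nrow(x$trials), x$structure$p_common))
  cat(sprintf("  common transitions: %.3f, reward rate: %.3f\n",
              mean(x$trials$transition == "common"), mean(x$trials$r)))
  invisible(x)
}
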