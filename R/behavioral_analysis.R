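#' Stay-probability table of a two-step session
#'
#' For every trial from the second onward, the stay indicator (did the
#' first-stage choice repeat the previous trial's?) is binned by the
#' previous trial's reward (rewarded/unrewarded) and transition
#' (common/rare); cell means are the stay probabilities. The first trial
#' contributes only as a predecessor. Cells never visited are `NA`
#' (missing), not 0.
#'
#' @param session A [twostep_session()] with at least 2 trials.
#' @return An object of class `stay_table`: `p_stay` (2 x 2 matrix, rows
#'   rewarded/unrewarded, columns common/rare) and `n` (counts per cell).
#' @examples
#' s <- simulate_agent(hybrid_params(beta1 = 3), seed = 1)
#' stay_table(s)
#' @export
stay_table <- function(session) {
  tr <- session$trials
  n <- nrow(tr)
  if (n < 2) stop("stay probabilities need at least 2 trials")
  stay <- as.numeric(tr$a1[-1] == tr$a1[-n])
  rew <- factor(ifelse(tr$r[-n] == 1, "rewarded", "unrewarded"),
                levels = c("rewarded", "unrewarded"))
  trans <- factor(tr$transition[-n], levels = c("common", "rare"))
  p <- tapply(stay, list(rew, trans), mean)
  counts <- as.matrix(unclass(table(rew, trans)))
  dimnames(p) <- dimnames(counts) <- list(c("rewarded", "unrewarded"),
                                          c("common", "rare"))
  structure(list(p_stay = p, n = counts), class = "stay_table")
}

#' @export
print.stay_table <- function(x, ...) {
  cat("<stay_table> stay probabilities (previous reward x transition):\n")
  print(round(x$p_stay, 3))
  invisible(x)
}

contrast_result <- function(effect, contrasts) {
  n <- length(contrasts)
  m <- mean(contrasts)
  s <- sd(contrasts)
  tstat <- if (s == 0) {
    if (m == 0) 0 else sign(m) * Inf
  } else {
    m / (s / sqrt(n))
  }
  p <- if (is.infinite(tstat)) 0 else 2 * pt(-abs(tstat), df = n - 1)
  structure(list(effect = effect, mean = m, t = tstat, F = tstat^2,
                 df = c(1, n - 1), p = p, n = n),
            class = "contrast_result")
}

#' @export
print.contrast_result <- function(x, ...) {
  cat(sprintf("%s: mean %.4f, F(1, %d) = %.3f, p = %.4f\n",
              x$effect, x$mean, x$df[2], x$F, x$p))
  invisible(x)
}

#' Group contrasts on stay probabilities
#'
#' The 2 x 2 within-subject analysis of stay behavior reduced to paired
#' contrasts: per subject, the main effect of reward is the mean of the
#' rewarded cells minus the mean of the unrewarded cells, and the
#' reward-by-transition interaction is `(RC - RR) - (UC - UR)`. Each
#' contrast is tested against 0 with a one-sample t test across subjects;
#' `F = t^2` with df (1, n - 1) is exactly the 2 x 2 within-subject ANOVA
#' F. Subjects missing any cell are dropped with a warning
#' (complete-case).
#'
#' @param tables List of [stay_table()] objects, at least 3 complete.
#' @return List with `main_effect` and `interaction`, each a
#'   `contrast_result` (fields `mean`, `t`, `F`, `df`, `p`).
#' @export
reward_and_interaction_contrasts <- function(tables) {
  cells <- t(vapply(tables, function(tb) {
    p <- tb$p_stay
    c(RC = p["rewarded", "common"], RR = p["rewarded", "rare"],
      UC = p["unrewarded", "common"], UR = p["unrewarded", "rare"])
  }, numeric(4)))
  complete <- stats::complete.cases(cells)
  if (any(!complete)) {
    warning(sprintf("dropping %d subject(s) with missing stay-table cells",
                    sum(!complete)))
    cells <- cells[complete, , drop = FALSE]
  }
  if (nrow(cells) < 3) stop("need at least 3 subjects with all 4 cells")
  main <- (cells[, "RC"] + cells[, "RR"]) / 2 -
    (cells[, "UC"] + cells[, "UR"]) / 2
  inter <- (cells[, "RC"] - cells[, "RR"]) - (cells[, "UC"] - cells[, "UR"])
  list(main_effect = contrast_result("main effect of reward", main),
       interaction = contrast_result("reward x transition interaction",
                                     inter))
}

#' Model-based interaction score of a stay table
#'
#' `(RC - RR) - (UC - UR)` on stay probabilities: positive when subjects
#' preferentially stay after rewards that followed common transitions and
#' after omissions that followed rare ones -- the model-based signature.
#' Pure main effects of reward cancel out.
#'
#' @param table A [stay_table()] with all four cells observed.
#' @return Numeric score in \[-2, 2\].
#' @export
mb_interaction_score <- function(table) {
  p <- table$p_stay
  if (anyNA(p)) stop("interaction score undefined: missing stay-table cell")
  (p["rewarded", "common"] - p["rewarded", "rare"]) -
    (p["unrewarded", "common"] - p["unrewarded", "rare"])
}

#' High-probability choice counts around devaluation
#'
#' Counts choices of the high-probability stimulus per condition in the
#' last `window` training trials and the first `window` extinction trials
#' of that condition -- the two analysis windows of the pre/post
#' comparison.
#'
#' @param session A `deval_session`.
#' @param window Window length per condition (default 10).
#' @return 2 x 3 integer matrix, rows `pre`/`post`, columns the
#'   conditions.
#' @export
deval_choice_counts <- function(session, window = 10) {
  tr <- session$trials
  conds <- session$design$conditions
  out <- matrix(NA_integer_, 2, length(conds),
                dimnames = list(c("pre", "post"), conds))
  for (cn in conds) {
    tt <- tr[tr$phase == "training" & tr$condition == cn, ]
    te <- tr[tr$phase == "extinction" & tr$condition == cn, ]
    if (nrow(tt) < window || nrow(te) < window) {
      stop(sprintf("condition %s has fewer than %d trials in a phase",
                   cn, window))
    }
    out["pre", cn] <- sum(tail(tt$choice, window) == "high")
    out["post", cn] <- sum(head(te$choice, window) == "high")
  }
  out
}

#' Devaluation interaction score
#'
#' Condition-specific drop in high-probability choices after devaluation:
#' by default `(devalued_pre - devalued_post) - (valued_pre -
#' valued_post)`, oriented so that a higher score means more goal-directed
#' behavior (the devalued stimulus is abandoned while the valued one is
#' retained); condition-nonspecific extinction cancels.
#' `literal_formula = TRUE` returns the opposite orientation,
#' `(valued_pre - valued_post) - (devalued_pre - devalued_post)`.
#'
#' @param counts Matrix from [deval_choice_counts()].
#' @param literal_formula Flip to the valued-minus-devalued orientation.
#' @return Numeric score (units: choices out of the analysis window).
#' @export
deval_interaction_score <- function(counts, literal_formula = FALSE) {
  score <- (counts["pre", "devalued"] - counts["post", "devalued"]) -
    (counts["pre", "valued"] - counts["post", "valued"])
  if (literal_formula) -score else score
}

# all permutations of 1..n as an n! x n integer matrix
all_perms <- function(n) {
  if (n == 1L) {
    return(matrix(1L))
  }
  sub <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- setdiff(seq_len(n), k)
    cbind(rep(k, nrow(sub)),
          matrix(rest[sub], nrow(sub), n - 1L))
  }))
}

#' One-tailed Spearman correlation
#'
#' Rank correlation (average ranks for ties) with a one-tailed p-value for
#' the directed hypothesis of a *positive* association. For n up to
#' `exact_max_n` the p-value is exact, from full enumeration of all n!
#' rank permutations; beyond that a t approximation with n - 2 degrees of
#' freedom is used.
#'
#' @param x,y Numeric vectors of equal length, n >= 4, neither constant.
#' @param exact_max_n Largest n for exact enumeration (default 9;
#'   9! = 362,880 permutations).
#' @return List with `rho`, `p` (one-tailed, positive direction), `n` and
#'   `method`.
#' @examples
#' spearman_onetailed(1:5, c(2, 3, 5, 8, 9))  # rho = 1, p = 1/120
#' @export
spearman_onetailed <- function(x, y, exact_max_n = 9L) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length")
  n <- length(x)
  if (n < 4) stop("need at least 4 paired observations")
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    stop("rho undefined: constant input vector")
  }
  rx <- rank(x)
  ry <- rank(y)
  rho <- cor(rx, ry)
  if (n <= exact_max_n) {
    P <- all_perms(n)
    rxc <- rx - mean(rx)
    ryc <- ry - mean(ry)
    rho_perm <- as.vector(matrix(ryc[P], nrow(P)) %*% rxc) /
      sqrt(sum(rxc^2) * sum(ryc^2))
    p <- mean(rho_perm >= rho - 1e-12)
    method <- "exact permutation"
  } else {
    tstat <- rho * sqrt((n - 2) / max(1 - rho^2, 1e-12))
    p <- pt(tstat, df = n - 2, lower.tail = FALSE)
    method <- "t approximation"
  }
  list(rho = rho, p = p, n = n, method = method)
}
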