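# Trial logs travel as plain TSV (UTF-8, Unix newlines, no quoting);
# parameters and reports as flat JSON/YAML.

write_tsv_plain <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8", eol = "\n")
  invisible(path)
}

#' Read and write two-step trial logs
#'
#' TSV with header `subject_id, trial, a1, s2, a2, reward, transition`.
#' A multi-subject file is split on `subject_id` when reading.
#'
#' @param session A [twostep_session()].
#' @param path File path.
#' @return `write_twostep_tsv` returns the path invisibly;
#'   `read_twostep_tsv` returns a single `twostep_session` (or a list of
#'   them if the file holds several subjects).
#' @param structure [transition_structure()] assumed for the read
#'   sessions.
#' @export
write_twostep_tsv <- function(session, path) {
  tr <- session$trials
  write_tsv_plain(data.frame(subject_id = session$subject_id,
                             trial = tr$t, a1 = tr$a1, s2 = tr$s2,
                             a2 = tr$a2, reward = tr$r,
                             transition = tr$transition), path)
}

#' @rdname write_twostep_tsv
#' @export
read_twostep_tsv <- function(path, structure = transition_structure()) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  needed <- c("subject_id", "trial", "a1", "s2", "a2", "reward",
              "transition")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols)) {
    stop(sprintf("%s: missing column(s) %s", path,
                 paste(missing_cols, collapse = ", ")))
  }
  sessions <- lapply(split(df, df$subject_id), function(d) {
    d <- d[order(d$trial), ]
    twostep_session(d$subject_id[1],
                    data.frame(t = d$trial, a1 = d$a1, s2 = d$s2,
                               a2 = d$a2, r = d$reward,
                               transition = d$transition,
                               stringsAsFactors = FALSE),
                    structure = structure)
  })
  if (length(sessions) == 1) sessions[[1]] else sessions
}

#' Read and write reward walks
#'
#' TSV with the four per-stimulus probability columns.
#'
#' @param walk A [generate_reward_walk()] object.
#' @param path File path.
#' @export
write_reward_walk_tsv <- function(walk, path) {
  df <- as.data.frame(walk$probs)
  names(df) <- c("s0_a0", "s0_a1", "s1_a0", "s1_a1")
  write_tsv_plain(df, path)
}

#' @rdname write_reward_walk_tsv
#' @param sd_innovation,bounds Metadata to attach to the read walk.
#' @export
read_reward_walk_tsv <- function(path, sd_innovation = 0.025,
                                 bounds = c(0.25, 0.75)) {
  m <- as.matrix(read.delim(path))
  if (ncol(m) != 4) stop(path, ": a reward walk must have 4 columns")
  structure(list(probs = unname(m), sd_innovation = sd_innovation,
                 bounds = bounds),
            class = "reward_walk")
}

#' Read and write devaluation trial logs
#'
#' TSV with header `subject_id, phase, trial, condition, choice, outcome`;
#' session metadata (the devalued food) lives in a JSON sidecar
#' `<path>.json`.
#'
#' @param session A `deval_session`.
#' @param path File path for the TSV (sidecar written next to it).
#' @export
write_deval_tsv <- function(session, path) {
  tr <- session$trials
  write_tsv_plain(data.frame(subject_id = session$subject_id,
                             phase = tr$phase, trial = tr$t,
                             condition = tr$condition, choice = tr$choice,
                             outcome = tr$outcome), path)
  jsonlite::write_json(list(subject_id = session$subject_id,
                            devalued_condition = session$devalued_condition),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_deval_tsv
#' @param design The [deval_design()] assumed for the read session.
#' @export
read_deval_tsv <- function(path, design = deval_design()) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  needed <- c("subject_id", "phase", "trial", "condition", "choice",
              "outcome")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols)) {
    stop(sprintf("%s: missing column(s) %s", path,
                 paste(missing_cols, collapse = ", ")))
  }
  sidecar <- paste0(path, ".json")
  devalued <- if (file.exists(sidecar)) {
    jsonlite::read_json(sidecar)$devalued_condition
  } else {
    NA_character_
  }
  structure(list(subject_id = as.character(df$subject_id[1]),
                 devalued_condition = devalued,
                 trials = data.frame(phase = df$phase, t = df$trial,
                                     condition = df$condition,
                                     choice = df$choice,
                                     outcome = df$outcome,
                                     stringsAsFactors = FALSE),
                 design = design),
            class = "deval_session")
}

#' Serialize hybrid parameters
#'
#' Flat key-value block with the seven canonical names; YAML or JSON by
#' file extension.
#'
#' @param params A [hybrid_params()] object.
#' @param path File path ending in `.yaml`, `.yml` or `.json`.
#' @export
write_hybrid_params <- function(params, path) {
  lst <- as.list(stats::setNames(as.numeric(params), PAR_NAMES))
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(lst, path)
  } else {
    jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_hybrid_params
#' @export
read_hybrid_params <- function(path) {
  lst <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path)
  }
  do.call(hybrid_params, lst[PAR_NAMES])
}

#' Serialize a group fit
#'
#' JSON with the prior moments, per-subject estimates and diagnostics.
#'
#' @param fit A `group_fit`.
#' @param path Output JSON path.
#' @export
write_group_fit_json <- function(fit, path) {
  out <- list(
    prior = list(mu = as.list(fit$prior$mu),
                 sigma2 = as.list(fit$prior$sigma2)),
    em_iterations = fit$em_iterations,
    converged = fit$converged,
    trajectory = fit$trajectory,
    subjects = lapply(fit$subjects, function(s) {
      list(subject_id = s$subject_id,
           params_map = as.list(stats::setNames(as.numeric(s$params_map),
                                                PAR_NAMES)),
           y_map = as.list(s$y_map),
           laplace_var = as.list(s$laplace_var),
           log_post = s$log_post)
    })
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
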