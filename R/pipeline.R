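# Pipeline entry points used by the command-line wrapper in
# inst/cli/dualcontrol. Every run writes a manifest recording the seed,
# the configuration (with an md5 hash) and the package version.

write_manifest <- function(out_dir, config) {
  cfg_path <- file.path(out_dir, "config.json")
  jsonlite::write_json(config, cfg_path, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  manifest <- list(package = "dualcontrol",
                   version = as.character(packageVersion("dualcontrol")),
                   created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   seed = config$seed,
                   config_md5 = unname(tools::md5sum(cfg_path)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(manifest)
}

#' Simulate and write two-step sessions
#'
#' Simulates `n_subjects` hybrid agents (each with its own reward walk)
#' and writes one trial-log TSV per subject plus a manifest.
#'
#' @param out_dir Output directory (created if missing).
#' @param n_subjects Number of agents.
#' @param n_trials Trials per session (default 201).
#' @param seed Integer seed for the whole run.
#' @param params A [hybrid_params()] object shared by all agents, or
#'   `NULL` to sample each agent from the default group distribution.
#' @return Invisibly, the vector of written TSV paths.
#' @export
run_simulate_twostep <- function(out_dir, n_subjects = 18, n_trials = 201,
                                 seed = 1, params = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(n_subjects), function(i) {
      id <- sprintf("sub%03d", i)
      p <- params %||%
        inverse_transform_params(rnorm(7, default_hybrid_mu(),
                                       default_hybrid_sd()))
      s <- simulate_agent(p, n_trials = n_trials, subject_id = id)
      path <- file.path(out_dir, paste0(id, "_twostep.tsv"))
      write_twostep_tsv(s, path)
      write_reward_walk_tsv(s$walk, file.path(out_dir,
                                              paste0(id, "_walk.tsv")))
      path
    }, character(1))
  })
  write_manifest(out_dir, list(command = "simulate-twostep",
                               n_subjects = n_subjects,
                               n_trials = n_trials, seed = seed,
                               shared_params = !is.null(params)))
  invisible(paths)
}

#' Simulate and write devaluation sessions
#'
#' @inheritParams run_simulate_twostep
#' @param w Goal-directed weight shared by all agents, or `NULL` to sample
#'   per agent from the default group distribution.
#' @return Invisibly, the vector of written TSV paths.
#' @export
run_simulate_deval <- function(out_dir, n_subjects = 18, seed = 1,
                               w = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(n_subjects), function(i) {
      id <- sprintf("sub%03d", i)
      wi <- w %||% plogis(rnorm(1))
      s <- simulate_dual_controller(dual_controller_params(w = wi),
                                    subject_id = id)
      path <- file.path(out_dir, paste0(id, "_deval.tsv"))
      write_deval_tsv(s, path)
      path
    }, character(1))
  })
  write_manifest(out_dir, list(command = "simulate-deval",
                               n_subjects = n_subjects, seed = seed,
                               shared_w = !is.null(w)))
  invisible(paths)
}

#' Generate and write a coupled two-task cohort
#'
#' Writes one two-step and one devaluation TSV per subject, the cohort
#' manifest (configuration, seed, exclusions) as YAML, and the run
#' manifest.
#'
#' @param out_dir Output directory.
#' @param config A [cohort_config()].
#' @return The generated [generate_cohort()] object, invisibly.
#' @export
run_cohort <- function(out_dir, config = cohort_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- generate_cohort(config)
  for (s in cohort$subjects) {
    write_twostep_tsv(s$twostep,
                      file.path(out_dir, paste0(s$subject_id,
                                                "_twostep.tsv")))
    write_deval_tsv(s$deval,
                    file.path(out_dir, paste0(s$subject_id, "_deval.tsv")))
  }
  yaml::write_yaml(list(n_subjects = config$n_subjects,
                        trait_coupling_k = config$trait_coupling_k,
                        n_trials_twostep = config$n_trials_twostep,
                        seed = config$seed,
                        excluded = as.list(cohort$excluded)),
                   file.path(out_dir, "cohort.yaml"))
  write_manifest(out_dir, list(command = "cohort",
                               n_subjects = config$n_subjects,
                               trait_coupling_k = config$trait_coupling_k,
                               seed = config$seed))
  invisible(cohort)
}

read_cohort_sessions <- function(in_dir) {
  ts_files <- sort(list.files(in_dir, pattern = "_twostep\\.tsv$",
                              full.names = TRUE))
  if (!length(ts_files)) {
    stop("no *_twostep.tsv trial logs found in ", in_dir)
  }
  lapply(ts_files, read_twostep_tsv)
}

#' Fit the hybrid model to a directory of two-step logs
#'
#' Runs [em_fit()] on every `*_twostep.tsv` in `in_dir` and writes the
#' group fit as JSON plus a per-subject parameter TSV.
#'
#' @param in_dir Directory of two-step trial logs.
#' @param out_dir Output directory.
#' @param em_iterations Maximum EM iterations; 1 reproduces a set-once
#'   prior.
#' @param n_restarts Optimizer restarts per subject per E-step.
#' @param seed Integer seed.
#' @return The `group_fit`, invisibly.
#' @export
run_fit <- function(in_dir, out_dir, em_iterations = 50, n_restarts = 10,
                    seed = 1) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sessions <- read_cohort_sessions(in_dir)
  fit <- em_fit(sessions, max_iter = em_iterations,
                n_restarts = n_restarts, seed = seed)
  write_group_fit_json(fit, file.path(out_dir, "group_fit.json"))
  write_tsv_plain(group_fit_table(fit),
                  file.path(out_dir, "parameters.tsv"))
  write_manifest(out_dir, list(command = "fit", in_dir = in_dir,
                               em_iterations = em_iterations,
                               n_restarts = n_restarts, seed = seed))
  invisible(fit)
}

#' Behavioral analysis of a cohort directory
#'
#' Reads the paired trial logs written by [run_cohort()], computes the
#' per-subject score pairs and group statistics, and writes `scores.tsv`
#' plus `report.json` (contrasts, correlations, exclusions).
#'
#' @param in_dir Cohort directory.
#' @param out_dir Output directory.
#' @param literal_formula Use the valued-minus-devalued orientation of the
#'   devaluation score.
#' @param window Analysis window per condition.
#' @return The report list, invisibly.
#' @export
run_analyze <- function(in_dir, out_dir, literal_formula = FALSE,
                        window = 10) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ts_files <- sort(list.files(in_dir, pattern = "_twostep\\.tsv$",
                              full.names = TRUE))
  dv_files <- sort(list.files(in_dir, pattern = "_deval\\.tsv$",
                              full.names = TRUE))
  if (!length(ts_files) || !length(dv_files)) {
    stop("cohort directory ", in_dir,
         " must contain *_twostep.tsv and *_deval.tsv logs")
  }
  if (length(ts_files) != length(dv_files)) {
    stop("unpaired trial logs in ", in_dir)
  }
  subjects <- lapply(seq_along(ts_files), function(i) {
    dv <- read_deval_tsv(dv_files[i])
    list(subject_id = dv$subject_id,
         twostep = read_twostep_tsv(ts_files[i]), deval = dv,
         included = attr(training_criterion_met(dv), "overall"))
  })
  cohort <- structure(list(config = list(seed = NA), subjects = subjects,
                           excluded = vapply(
                             Filter(function(s) !s$included, subjects),
                             `[[`, character(1), "subject_id")),
                      class = "cohort")
  report <- run_construct_validity(cohort,
                                   literal_formula = literal_formula,
                                   window = window)
  write_tsv_plain(report$scores, file.path(out_dir, "scores.tsv"))
  jsonlite::write_json(
    list(n_included = report$n_included, n_excluded = report$n_excluded,
         rho_deval_mb = report$rho_deval_mb,
         rho_deval_main = report$rho_deval_main,
         main_effect = unclass(report$contrasts$main_effect),
         interaction = unclass(report$contrasts$interaction)),
    file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
  write_manifest(out_dir, list(command = "analyze", in_dir = in_dir,
                               literal_formula = literal_formula,
                               window = window, seed = NA))
  invisible(report)
}
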