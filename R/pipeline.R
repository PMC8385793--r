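# End-to-end orchestration: simulate (or load) -> eligibility -> timeline
# -> z-scores -> conditional variables -> ASQ scoring -> risk models ->
# balance table, as one seeded, logged, reproducible run.

#' Assemble a pipeline run configuration
#'
#' @param n_children Cohort size when simulating (overrides the simulation
#'   config's own `n_children`).
#' @param seed Integer seed for the whole run.
#' @param simulation Simulation configuration ([default_config()]).
#' @param cohort_path Optional CSV of an existing cohort; when given, no
#'   simulation is performed.
#' @param reference_path Optional LMS reference CSV; default uses
#'   [synthetic_lms_reference()].
#' @param target_ages Postnatal target ages in days.
#' @param window_days Admissibility window of [build_timeline()].
#' @param prorate_asq Missing-item rule of [score_asq()].
#' @param out_dir Optional directory; when given, every stage output is
#'   materialised as CSV plus a YAML config and manifest.
#' @return A validated configuration list of class `cg_run_config`.
#' @export
pipeline_config <- function(n_children = 10000, seed = 1L,
                            simulation = default_config(),
                            cohort_path = NULL, reference_path = NULL,
                            target_ages = default_target_ages(),
                            window_days = 45, prorate_asq = FALSE,
                            out_dir = NULL) {
  if (!is.null(cohort_path) && !file.exists(cohort_path))
    stop_config("cohort_path '%s' does not exist", cohort_path)
  if (!is.null(reference_path) && !file.exists(reference_path))
    stop_config("reference_path '%s' does not exist", reference_path)
  simulation$n_children <- n_children
  cfg <- list(seed = as.integer(seed), simulation = simulation,
              cohort_path = cohort_path, reference_path = reference_path,
              target_ages = target_ages, window_days = window_days,
              prorate_asq = prorate_asq, out_dir = out_dir)
  class(cfg) <- "cg_run_config"
  cfg
}

#' Apply the cohort eligibility filters
#'
#' In order: live singleton birth; term window (gestational age >= 37 and
#' < 42 weeks); complete basic information (parity, sex, birth length,
#' birth weight); exclusion of malformation/severe disease.  Filters whose
#' columns are absent are skipped with a zero-exclusion log entry.
#'
#' @param cohort Cohort tibble.
#' @return List with `cohort` (the filtered tibble) and `log`, a tibble of
#'   per-step counts satisfying n_out = n_in - n_excluded.
#' @export
apply_eligibility <- function(cohort) {
  steps <- list(
    singleton = function(d)
      if ("singleton" %in% names(d)) !is.na(d$singleton) & d$singleton
      else rep(TRUE, nrow(d)),
    term_birth = function(d)
      !is.na(d$gestational_age) & d$gestational_age >= 37 &
        d$gestational_age < 42,
    complete_basic_information = function(d)
      !is.na(d$parity) & !is.na(d$sex) & !is.na(d$birth_length_cm) &
        !is.na(d$birth_weight_g),
    no_malformation = function(d)
      if ("malformation" %in% names(d)) !is.na(d$malformation) & !d$malformation
      else rep(TRUE, nrow(d)))
  log <- list()
  for (nm in names(steps)) {
    keep <- steps[[nm]](cohort)
    log[[length(log) + 1]] <- tibble::tibble(
      step = nm, n_in = nrow(cohort), n_excluded = sum(!keep),
      n_out = sum(keep))
    cohort <- cohort[keep, , drop = FALSE]
  }
  list(cohort = cohort, log = dplyr::bind_rows(log))
}

#' Run the full analysis pipeline
#'
#' Executes all stages in order on a simulated or loaded cohort and
#' returns every intermediate product.  Deterministic and idempotent for a
#' fixed configuration: two runs with the same config yield identical
#' outputs and manifests.  ASQ cutoffs are derived from all children with
#' questionnaire data *before* the eligibility filter, emulating the use
#' of the full available population as the normative reference.
#'
#' @param config A [pipeline_config()].
#' @return List of class `cg_run`: `cohort` (analyzed), `eligibility_log`,
#'   `timeline`, `zscores`, `cutoffs`, `scores6`/`scores12`,
#'   `flags6`/`flags12`, `models`, `balance`, `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (!inherits(config, "cg_run_config"))
    stop_config("config must come from pipeline_config()")
  ref <- if (is.null(config$reference_path)) synthetic_lms_reference()
         else read_lms_reference(config$reference_path)
  full <- if (is.null(config$cohort_path)) {
    simulate_cohort(config$simulation, seed = config$seed, reference = ref)
  } else {
    read_cohort(config$cohort_path)
  }

  # normative cutoffs from the pre-exclusion population
  scores6_all <- score_asq(full, 6, prorate = config$prorate_asq)
  scores12_all <- score_asq(full, 12, prorate = config$prorate_asq)
  cutoffs <- dplyr::bind_rows(derive_cutoffs(scores6_all),
                              derive_cutoffs(scores12_all))

  elig <- apply_eligibility(full)
  cohort <- elig$cohort
  timeline <- build_timeline(cohort, target_ages = config$target_ages,
                             window = config$window_days)
  zscores <- zscore_anthro(timeline, ref = ref,
                           target_ages = config$target_ages)
  scores6 <- scores6_all[scores6_all$child_id %in% cohort$child_id, ]
  scores12 <- scores12_all[scores12_all$child_id %in% cohort$child_id, ]
  flags6 <- flag_delay(scores6, cutoffs[cutoffs$outcome_age == 6, ])
  flags12 <- flag_delay(scores12, cutoffs[cutoffs$outcome_age == 12, ])
  models <- run_delay_models(cohort, zscores, flags6, flags12)

  bal_cohort <- cohort |>
    dplyr::left_join(stats::setNames(flags6[c("child_id", "any_delay")],
                                     c("child_id", "delay6")),
                     by = "child_id") |>
    dplyr::left_join(stats::setNames(flags12[c("child_id", "any_delay")],
                                     c("child_id", "delay12")),
                     by = "child_id")
  balance <- balance_table(bal_cohort, has_complete_anthro(timeline))

  manifest <- list(
    package = "condgrowth",
    version = as.character(utils::packageVersion("condgrowth")),
    seed = config$seed,
    config_hash = rlang::hash(config),
    n_simulated = nrow(full),
    n_analyzed = nrow(cohort),
    eligibility = as.data.frame(elig$log),
    n_models = nrow(unique(models[c("sex", "outcome_age", "variant")])))

  run <- list(cohort = cohort, eligibility_log = elig$log,
              timeline = timeline, zscores = zscores, cutoffs = cutoffs,
              scores6 = scores6, scores12 = scores12,
              flags6 = flags6, flags12 = flags12,
              models = models, balance = balance, manifest = manifest)
  class(run) <- "cg_run"

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(x, f) readr::write_csv(x, file.path(config$out_dir, f),
                                          na = "")
    wr(full, "cohort.csv")
    wr(elig$log, "eligibility_log.csv")
    wr(timeline, "timeline.csv")
    wr(zscores, "zscores.csv")
    wr(cutoffs, "cutoffs.csv")
    wr(dplyr::bind_rows(scores6, scores12), "asq_scores.csv")
    wr(dplyr::bind_rows(flags6, flags12), "delay_flags.csv")
    wr(models, "models.csv")
    wr(balance, "balance.csv")
    cfg_out <- config
    cfg_out$simulation$growth_corr <-
      apply(config$simulation$growth_corr, 1, as.list, simplify = FALSE)
    yaml::write_yaml(unclass(cfg_out), file.path(config$out_dir, "config.yaml"))
    yaml::write_yaml(manifest, file.path(config$out_dir, "manifest.yaml"))
  }
  run
}

#' @export
print.cg_run <- function(x, ...) {
  cat("<condgrowth pipeline run>\n")
  cat(sprintf("  analyzed children: %d (of %d simulated/loaded)\n",
              x$manifest$n_analyzed, x$manifest$n_simulated))
  cat(sprintf("  model tables: %d; result rows: %d\n",
              x$manifest$n_models, nrow(x$models)))
  invisible(x)
}
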