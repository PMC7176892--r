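# End-to-end orchestration: simulate (or read) responses, validate,
# phenotype, derive risks, tabulate, and write a QC report and a manifest.
# Outputs are plain delimited text and JSON; with a fixed seed and config
# the artifact bytes are identical across runs (the manifest deliberately
# carries no timestamps).

#' Run the full pipeline
#'
#' Stages: load instrument and ruleset; simulate a synthetic cohort (or
#' read existing responses); validate responses against the instrument;
#' classify every syndrome and derive mood groups; derive risk profiles;
#' write the requested summary tables; write a QC report (completion
#' counts, unassessable counts per syndrome, validation violations) and a
#' manifest with versions, seed and md5 checksums of every artifact.
#'
#' @param config A list or path to a YAML file with fields: `out_dir`
#'   (required); `seed`; `n`; `instrument` and `ruleset` (paths or
#'   `"default"`); `responses` (path to an existing wide response file --
#'   when set, simulation is skipped and the manifest records the input
#'   provenance); `tables` (subset of `"comorbidity"`, `"diagnoses"`,
#'   `"characteristics"`, `"mood"`, `"sex"`); `cohort` (overrides passed to
#'   [cohort_config()]).
#' @param seed Optional override of the config seed.
#' @return The manifest (list), invisibly. Artifacts are written under
#'   `out_dir`.
#' @export
run_pipeline <- function(config, seed = NULL) {
  if (is.character(config)) {
    if (!file.exists(config)) abort(sprintf("config file not found: %s", config))
    config <- yaml::read_yaml(config)
  }
  if (is.null(config$out_dir)) abort("config error: 'out_dir' is required")
  for (field in c("instrument", "ruleset")) {
    p <- config[[field]] %||% "default"
    if (!identical(p, "default") && !file.exists(p)) {
      abort(sprintf("config error: %s file not found: %s", field, p))
    }
  }
  if (!is.null(config$responses) && !file.exists(config$responses)) {
    abort(sprintf("config error: responses file not found: %s",
                  config$responses))
  }
  seed <- seed %||% config$seed %||% 1L
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  spec <- read_instrument(config$instrument %||% "default")
  ruleset <- read_ruleset(config$ruleset %||% "default")
  tables <- config$tables %||%
    c("comorbidity", "diagnoses", "characteristics", "mood", "sex")
  artifacts <- character()
  emit <- function(df, name) {
    path <- file.path(out_dir, name)
    readr::write_tsv(df, path, progress = FALSE)
    artifacts[[length(artifacts) + 1L]] <<- path
    path
  }

  if (is.null(config$responses)) {
    cc_args <- config$cohort %||% list()
    cc_args$n <- config$n %||% cc_args$n %||% 1000L
    cc_args$seed <- seed
    cohort <- do.call(cohort_config, cc_args) |>
      generate_cohort(spec, ruleset)
    responses <- cohort$responses
    emit(responses, "responses.tsv")
    emit(cohort$truth, "truth.tsv")
    provenance <- "simulated"
  } else {
    responses <- read_responses(config$responses, spec)
    provenance <- config$responses
  }

  violations <- validate_responses(responses, spec)
  completion <- completion_status(responses, spec)
  phen <- classify_all(responses, spec, ruleset)
  risks <- derive_risk_profiles(responses, spec, ruleset)
  emit(phen, "phenotypes.tsv")
  emit(risks, "risk_profiles.tsv")
  emit(data_dictionary(spec), "data_dictionary.tsv")

  if ("comorbidity" %in% tables) {
    emit(tidy(comorbidity_crosstab(phen)), "table_comorbidity.tsv")
  }
  if ("diagnoses" %in% tables) {
    emit(diagnosis_prevalence(phen), "table_diagnoses.tsv")
  }
  if ("characteristics" %in% tables) {
    emit(characteristics_by_stratum(phen, risks, "syndrome"),
         "table_characteristics.tsv")
  }
  if ("mood" %in% tables) {
    emit(characteristics_by_stratum(phen, risks, "mood"), "table_mood.tsv")
  }
  if ("sex" %in% tables) {
    emit(stratify_by_sex(phen, risks), "table_sex.tsv")
  }

  qc <- bind_rows(
    count(completion, .data$completion, .drop = FALSE) |>
      mutate(metric = paste0("completion_", .data$completion)) |>
      select("metric", "n"),
    tibble(metric = "validation_violations", n = nrow(violations)),
    purrr::map(c(SYNDROMES, "bipolar"), function(s) {
      tibble(metric = paste0("unassessable_", s),
             n = sum(phen[[s]] == "unassessable"))
    }) |> bind_rows(),
    tibble(metric = "mood_group_undefined", n = sum(is.na(phen$mood_group)))
  )
  emit(qc, "qc_report.tsv")

  manifest <- list(
    package = as.character(utils::packageVersion("mhqtools")),
    instrument_version = spec$version,
    ruleset_version = ruleset$version,
    seed = seed,
    responses_provenance = provenance,
    n_respondents = nrow(responses),
    artifacts = lapply(artifacts, function(p) {
      list(file = basename(p), md5 = unname(tools::md5sum(p)))
    })
  )
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(manifest)
}
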