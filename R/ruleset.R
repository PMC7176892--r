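# The ruleset holds every operational-criteria threshold and the binding of
# criteria roles to instrument item ids. Keeping it in an editable,
# versioned structured-text file means a revised transcription of the
# criteria can be dropped in without touching classifier code.

#' The default operational-criteria ruleset
#'
#' Encodes the case definitions used throughout the package: DSM-IV style
#' CIDI-SF lifetime depression (core feature most of the day nearly every
#' day for at least two weeks, at least five symptoms in total, with
#' impairment; episode count separates single from recurrent), CIDI-SF
#' lifetime generalised anxiety (at least six months of excessive,
#' hard-to-control worry plus at least three associated symptoms), lifetime
#' hypomania/mania (core elated or irritable period, at least three
#' associated symptoms, duration at least one week), AUDIT total score of
#' at least 8 for past-year hazardous/harmful drinking, the six-item PTSD
#' checklist with a default sum cut-off of 14 for current post-traumatic
#' stress, any lifetime unusual experience, lifetime self-harm regardless
#' of suicidal intent, and single-item self-reported addiction. Risk-factor
#' screens (childhood trauma screener, adult adversity, trauma triggers,
#' loneliness, social isolation) and demographic recodes are bound here too.
#'
#' @return A `mhq_ruleset` list.
#' @export
default_ruleset <- function() {
  rs <- list(
    version = "ruleset_default-1.0",
    depression = list(
      screen_mood = "dep_screen_mood",
      screen_anh = "dep_screen_anh",
      symptom_anh = "dep_sym_anh",
      symptom_items = c("dep_sym_tired", "dep_sym_appetite", "dep_sym_sleep",
                        "dep_sym_conc", "dep_sym_worth", "dep_sym_death"),
      most_day = "dep_most_day",
      duration = "dep_dur_weeks",
      impairment = "dep_impair",
      episodes = "dep_episodes",
      min_symptoms = 5L,
      min_duration_weeks = 2L,
      recurrent_min_episodes = 2L
    ),
    mania = list(
      screen_elated = "man_screen_elated",
      screen_irritable = "man_screen_irrit",
      symptom_items = c("man_sym_active", "man_sym_talk", "man_sym_sleep",
                        "man_sym_ideas"),
      duration = "man_dur_days",
      min_symptoms = 3L,
      min_duration_days = 7L
    ),
    gad = list(
      screen = "gad_screen",
      duration = "gad_dur_months",
      excessive = "gad_excess",
      control = "gad_control",
      symptom_items = c("gad_sym_restless", "gad_sym_keyed", "gad_sym_tired",
                        "gad_sym_irrit", "gad_sym_sleep", "gad_sym_conc"),
      min_symptoms = 3L,
      min_duration_months = 6L
    ),
    alcohol = list(items = sprintf("audit_%d", 1:10), cutoff = 8L),
    ptsd = list(items = sprintf("pcl_%d", 1:6), cutoff = 14L),
    unusual_experiences = list(
      items = c("ue_vision", "ue_voice", "ue_conspiracy", "ue_signal")
    ),
    self_harm = list(item = "sh_ever"),
    addiction = list(item = "addict_ever"),
    diagnoses = list(
      item = "dx_mhp",
      categories = c(depression = 1L, anxiety_nerves = 2L, bipolar = 3L,
                     psychosis = 4L, eating_disorder = 5L, other = 6L)
    ),
    childhood_trauma = list(
      items = sprintf("cts_%d", 1:5),
      # frequency code (0 never .. 4 very often) at or above which the item
      # counts as possible abuse or neglect
      item_cutoffs = c(3L, 3L, 3L, 3L, 3L)
    ),
    adult_adversity = list(items = c("aa_confide", "aa_abuse", "aa_money")),
    trauma_exposure = list(items = sprintf("tr_trig_%d", 1:6), min_count = 1L),
    loneliness = list(
      lonely = "lonely_often", confide = "confide_freq",
      confide_max = 1L, min_score = 2L
    ),
    social_isolation = list(
      live_alone = "live_alone", visits = "visit_freq",
      visits_min_code = 4L, group = "group_activity", min_score = 2L
    ),
    demographics = list(
      age = "age_years", age_band_cut = 65L, sex = "sex",
      degree = "edu_degree", townsend = "townsend_q", tenure = "tenure",
      renter_codes = c(3L, 4L), illness = "longstanding_illness",
      smoked = "smoked_ever", cannabis = "cannabis_ever",
      activity = "activity_met", neuroticism = "neuroticism"
    )
  )
  structure(rs, class = "mhq_ruleset")
}

#' @export
print.mhq_ruleset <- function(x, ...) {
  cat(sprintf("<mhq_ruleset '%s': %d criteria blocks>\n",
              x$version, length(x) - 1L))
  invisible(x)
}

#' Read / write a criteria ruleset
#'
#' @param path YAML file, or `"default"` for the bundled ruleset.
#' @return A `mhq_ruleset`.
#' @export
read_ruleset <- function(path) {
  if (identical(path, "default")) return(default_ruleset())
  if (!file.exists(path)) abort(sprintf("ruleset file not found: %s", path))
  raw <- yaml::read_yaml(path)
  if (is.null(raw$version)) {
    abort(sprintf("ruleset file %s: missing field 'version'", path))
  }
  base <- unclass(default_ruleset())
  merged <- utils::modifyList(base, raw)
  # yaml scalarises; restore vector fields
  for (blk in names(merged)) {
    if (is.list(merged[[blk]])) {
      merged[[blk]] <- lapply(merged[[blk]], function(v) {
        if (is.list(v)) unlist(v) else v
      })
    }
  }
  if (!is.null(merged$diagnoses$categories)) {
    merged$diagnoses$categories <-
      setNames(as.integer(merged$diagnoses$categories),
               names(merged$diagnoses$categories))
  }
  structure(merged, class = "mhq_ruleset")
}

#' @rdname read_ruleset
#' @param ruleset A `mhq_ruleset`.
#' @export
write_ruleset <- function(ruleset, path) {
  namify <- function(x) {
    if (is.list(x)) {
      lapply(x, namify)
    } else if (is.atomic(x) && !is.null(names(x))) {
      as.list(x)
    } else {
      x
    }
  }
  yaml::write_yaml(namify(unclass(ruleset)), path)
  invisible(path)
}
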