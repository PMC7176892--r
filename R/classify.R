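# Tri-state classification uses Kleene three-valued logic over criterion
# values: an item that was presented but declined or left blank is NA, a
# rule-skipped item contributes "criterion not endorsed" (0), and the
# criterion expression evaluates to TRUE (met), FALSE (not met) or NA
# (unassessable). NA propagates exactly when the missing answer could still
# change the decision, which is the spec of "unassessable": a negative
# screen decides the outcome no matter what the skipped detail would have
# said, while a declined screen leaves it open.

tv_status <- function(x) {
  factor(ifelse(is.na(x), "unassessable", ifelse(x, "met", "not_met")),
         levels = TRI_LEVELS)
}

status_true <- function(status) !is.na(status) & status == "met"
status_known <- function(status) !is.na(status) & status != "unassessable"

# Three-valued "at least k of these indicator columns are endorsed":
# TRUE once the observed endorsements reach k, FALSE once even endorsing
# every missing item cannot reach k, otherwise NA.
tv_count_ge <- function(ind, k) {
  ones <- rowSums(ind == 1, na.rm = TRUE)
  nas <- rowSums(is.na(ind))
  ifelse(ones >= k, TRUE, ifelse(ones + nas < k, FALSE, NA))
}

tv_any <- function(ind) tv_count_ge(ind, 1L)

#' Classify lifetime depression (CIDI-SF style)
#'
#' Met when a core feature (depressed mood or anhedonia) was present most of
#' the day nearly every day for at least `min_duration_weeks` weeks, the
#' total symptom count (core features plus associated symptoms) reaches
#' `min_symptoms`, and the episode interfered with life. The episode count
#' separates single-episode from recurrent depression.
#'
#' @param responses Wide response tibble.
#' @param spec An `mhq_instrument`.
#' @param ruleset A `mhq_ruleset`.
#' @return A tibble with `respondent_id`, tri-state `status`, logical
#'   `screen_endorsed` (either screen positive; NA when undecidable),
#'   `symptom_count`, `duration_weeks`, `episode_count`.
#' @export
classify_depression <- function(responses, spec = default_instrument(),
                                ruleset = default_ruleset()) {
  cv <- crit_values(spec, responses)
  b <- ruleset$depression
  core_mood <- cv[, b$screen_mood] == 1
  core_anh <- cv[, b$screen_anh] == 1 | cv[, b$symptom_anh] == 1
  core <- core_mood | core_anh
  sym_ind <- cbind(core_mood, core_anh,
                   cv[, b$symptom_items, drop = FALSE] == 1)
  n_sym <- tv_count_ge(sym_ind, b$min_symptoms)
  met <- core &
    cv[, b$most_day] == 1 &
    cv[, b$duration] >= b$min_duration_weeks &
    n_sym &
    cv[, b$impairment] == 1
  symptom_count <- rowSums(sym_ind == 1, na.rm = TRUE)
  symptom_count[is.na(n_sym) & is.na(met)] <- NA_integer_
  tibble(
    respondent_id = responses$respondent_id,
    status = tv_status(met),
    screen_endorsed = unname(core),
    symptom_count = as.integer(unname(symptom_count)),
    duration_weeks = unname(ifelse(is.na(cv[, b$duration]), NA_integer_,
                                   as.integer(cv[, b$duration]))),
    episode_count = unname(ifelse(is.na(cv[, b$episodes]), NA_integer_,
                                  as.integer(cv[, b$episodes])))
  )
}

#' Classify lifetime hypomania/mania
#'
#' Met when a period of elated or irritable mood carried at least
#' `min_symptoms` associated symptoms and lasted at least
#' `min_duration_days` days (one week by default).
#'
#' @inheritParams classify_depression
#' @return A tibble `respondent_id`, `status`, `duration_days`.
#' @export
classify_mania <- function(responses, spec = default_instrument(),
                           ruleset = default_ruleset()) {
  cv <- crit_values(spec, responses)
  b <- ruleset$mania
  core <- cv[, b$screen_elated] == 1 | cv[, b$screen_irritable] == 1
  met <- core &
    tv_count_ge(cv[, b$symptom_items, drop = FALSE] == 1, b$min_symptoms) &
    cv[, b$duration] >= b$min_duration_days
  tibble(
    respondent_id = responses$respondent_id,
    status = tv_status(met),
    duration_days = unname(ifelse(is.na(cv[, b$duration]), NA_integer_,
                                  as.integer(cv[, b$duration])))
  )
}

#' Classify lifetime generalised anxiety disorder (CIDI-SF style)
#'
#' Met when worry lasted at least `min_duration_months` months, was
#' excessive and hard to control, and carried at least `min_symptoms`
#' associated symptoms.
#'
#' @inheritParams classify_depression
#' @return A tibble `respondent_id`, `status`, `duration_months`.
#' @export
classify_gad <- function(responses, spec = default_instrument(),
                         ruleset = default_ruleset()) {
  cv <- crit_values(spec, responses)
  b <- ruleset$gad
  met <- cv[, b$screen] == 1 &
    cv[, b$duration] >= b$min_duration_months &
    cv[, b$excessive] == 1 &
    cv[, b$control] == 1 &
    tv_count_ge(cv[, b$symptom_items, drop = FALSE] == 1, b$min_symptoms)
  tibble(
    respondent_id = responses$respondent_id,
    status = tv_status(met),
    duration_months = unname(ifelse(is.na(cv[, b$duration]), NA_integer_,
                                    as.integer(cv[, b$duration])))
  )
}

#' Classify past-year hazardous/harmful alcohol use (AUDIT)
#'
#' The AUDIT total is the plain sum of the ten items (0-40); met at or above
#' the cut-off (8 by default). Items skipped because the respondent never
#' drinks contribute zero; a declined or absent item makes the total -- and
#' hence the classification -- unassessable (no proration).
#'
#' @inheritParams classify_depression
#' @return A tibble `respondent_id`, `status`, `audit_score`.
#' @export
classify_alcohol <- function(responses, spec = default_instrument(),
                             ruleset = default_ruleset()) {
  cv <- crit_values(spec, responses)
  b <- ruleset$alcohol
  score <- rowSums(cv[, b$items, drop = FALSE])
  tibble(
    respondent_id = responses$respondent_id,
    status = tv_status(score >= b$cutoff),
    audit_score = ifelse(is.na(score), NA_integer_, as.integer(score))
  )
}

#' Classify current post-traumatic stress (six-item checklist)
#'
#' Sum of the six items (each 1-5, total 6-30); met at or above the
#' configured cut-off (14 by default). Any missing item makes the score
#' unassessable.
#'
#' @inheritParams classify_depression
#' @return A tibble `respondent_id`, `status`, `pcl_score`.
#' @export
classify_ptsd <- function(responses, spec = default_instrument(),
                          ruleset = default_ruleset()) {
  cv <- crit_values(spec, responses)
  b <- ruleset$ptsd
  vals <- cv[, b$items, drop = FALSE]
  vals[vals == 0] <- NA  # checklist items have no rule-skip route; floor is 1
  score <- rowSums(vals)
  tibble(
    respondent_id = responses$respondent_id,
    status = tv_status(score >= b$cutoff),
    pcl_score = ifelse(is.na(score), NA_integer_, as.integer(score))
  )
}

#' Classify lifetime unusual experiences
#'
#' Met when any lifetime psychotic-like experience item is endorsed; a
#' phenomenon, not a diagnosis.
#'
#' @inheritParams classify_depression
#' @return A tibble `respondent_id`, `status`.
#' @export
classify_unusual_experiences <- function(responses,
                                         spec = default_instrument(),
                                         ruleset = default_ruleset()) {
  cv <- crit_values(spec, responses)
  met <- tv_any(cv[, ruleset$unusual_experiences$items, drop = FALSE] == 1)
  tibble(respondent_id = responses$respondent_id, status = tv_status(met))
}

#' Classify lifetime self-harm
#'
#' Met when lifetime self-harm is endorsed, irrespective of suicidal intent.
#'
#' @inheritParams classify_depression
#' @return A tibble `respondent_id`, `status`.
#' @export
classify_self_harm <- function(responses, spec = default_instrument(),
                               ruleset = default_ruleset()) {
  cv <- crit_values(spec, responses)
  met <- cv[, ruleset$self_harm$item] == 1
  tibble(respondent_id = responses$respondent_id, status = tv_status(met))
}

#' Classify self-reported addiction
#'
#' Met when the single addiction/dependence item is endorsed; defined by
#' self-report alone, with no professional-diagnosis requirement.
#'
#' @inheritParams classify_depression
#' @return A tibble `respondent_id`, `status`.
#' @export
classify_addiction <- function(responses, spec = default_instrument(),
                               ruleset = default_ruleset()) {
  cv <- crit_values(spec, responses)
  met <- cv[, ruleset$addiction$item] == 1
  tibble(respondent_id = responses$respondent_id, status = tv_status(met))
}

#' Count self-reported professional diagnoses
#'
#' Tick-all-that-apply; the count is the number of distinct categories
#' ticked (zero when the item was declined or left blank, with
#' `dx_answered` recording whether it was answered so prevalence tables can
#' use explicit denominators).
#'
#' @inheritParams classify_depression
#' @return A tibble `respondent_id`, `n_diagnoses`, `dx_answered`, and one
#'   logical column `dx_<category>` per roster category.
#' @export
count_self_reported_diagnoses <- function(responses,
                                          spec = default_instrument(),
                                          ruleset = default_ruleset()) {
  b <- ruleset$diagnoses
  n <- nrow(responses)
  x <- item_column(responses, b$item, n)
  if (!is.character(x)) x <- as.character(x)
  answered <- answered_cells(x)
  sets <- parse_multi(ifelse(answered, x, NA_character_))
  out <- tibble(
    respondent_id = responses$respondent_id,
    n_diagnoses = purrr::map_int(sets, ~ length(setdiff(.x, 0L))),
    dx_answered = answered
  )
  for (cat in names(b$categories)) {
    code <- b$categories[[cat]]
    out[[paste0("dx_", cat)]] <- ifelse(
      answered, purrr::map_lgl(sets, ~ code %in% .x), NA
    )
  }
  out
}

#' Gate likely bipolar affective disorder on depression history
#'
#' Screening a general population for mania alone over-identifies bipolar
#' disorder, so the likely bipolar label requires lifetime depression and
#' lifetime mania together. Kleene conjunction gives the missing-data rule:
#' either input not met decides not met; otherwise an unassessable input
#' leaves the conjunction unassessable.
#'
#' @param depression,mania Tri-state status vectors (factors or characters).
#' @return A tri-state factor.
#' @export
derive_bipolar <- function(depression, mania) {
  d <- ifelse(depression == "unassessable", NA, depression == "met")
  m <- ifelse(mania == "unassessable", NA, mania == "met")
  tv_status(d & m)
}

#' Derive the five-level mood-disorder group
#'
#' Precedence: bipolar affective disorder, then recurrent depression, then
#' single-episode depression, then subthreshold depressive symptoms (a
#' depression screen endorsed but full criteria unmet), then no depression.
#' Respondents whose depression status (or, where it decides the group,
#' episode count or mania status) is unassessable get `NA` and are counted
#' in quality-control output rather than mood tables.
#'
#' @param depression Tri-state depression status.
#' @param episode_count Integer episode count (NA when unknown).
#' @param screen_endorsed Logical: either depression screen endorsed.
#' @param bipolar Tri-state bipolar status from [derive_bipolar()].
#' @param recurrent_min_episodes Episodes at or above which depression is
#'   recurrent.
#' @return A factor over the five mood groups, NA when undefined.
#' @export
derive_mood_group <- function(depression, episode_count, screen_endorsed,
                              bipolar, recurrent_min_episodes = 2L) {
  dep_met <- ifelse(depression == "unassessable", NA, depression == "met")
  bip_met <- ifelse(bipolar == "unassessable", NA, bipolar == "met")
  grp <- dplyr::case_when(
    bip_met ~ "bipolar_affective_disorder",
    is.na(bip_met) & (is.na(dep_met) | dep_met) ~ NA_character_,
    dep_met & !is.na(episode_count) &
      episode_count >= recurrent_min_episodes ~ "recurrent_depression",
    dep_met & !is.na(episode_count) ~ "single_episode_depression",
    dep_met ~ NA_character_,  # depression met, episode count missing
    is.na(dep_met) ~ NA_character_,
    screen_endorsed ~ "subthreshold",
    !screen_endorsed ~ "no_depression",
    .default = NA_character_
  )
  factor(grp, levels = MOOD_GROUPS)
}

#' Apply every case definition to a cohort
#'
#' Runs all syndrome classifiers, the diagnosis-report counter, bipolar
#' gating and the mood-group derivation, returning one row per respondent.
#' `any_syndrome` is the OR over the seven operationally defined syndromes
#' (self-reported addiction tabulated separately), treating unassessable
#' components as not met; `any_unassessable` flags rows where that happened.
#'
#' @inheritParams classify_depression
#' @return An `mhq_phenotypes` tibble.
#' @export
classify_all <- function(responses, spec = default_instrument(),
                         ruleset = default_ruleset()) {
  if (nrow(responses) == 0L) {
    return(structure(tibble(respondent_id = character()),
                     class = c("mhq_phenotypes", class(tibble()))))
  }
  dep <- classify_depression(responses, spec, ruleset)
  man <- classify_mania(responses, spec, ruleset)
  gad <- classify_gad(responses, spec, ruleset)
  alc <- classify_alcohol(responses, spec, ruleset)
  pts <- classify_ptsd(responses, spec, ruleset)
  ue <- classify_unusual_experiences(responses, spec, ruleset)
  sh <- classify_self_harm(responses, spec, ruleset)
  add <- classify_addiction(responses, spec, ruleset)
  dxs <- count_self_reported_diagnoses(responses, spec, ruleset)

  bipolar <- derive_bipolar(dep$status, man$status)
  mood_group <- derive_mood_group(
    dep$status, dep$episode_count, dep$screen_endorsed, bipolar,
    recurrent_min_episodes = ruleset$depression$recurrent_min_episodes
  )

  status_tbl <- tibble(
    depression = dep$status, mania = man$status, gad = gad$status,
    unusual_experiences = ue$status, self_harm = sh$status,
    alcohol = alc$status, ptsd = pts$status, addiction = add$status
  )
  met_mat <- sapply(status_tbl[ANY_SYNDROME_SET], status_true)
  unk_mat <- sapply(status_tbl[ANY_SYNDROME_SET], \(s) !status_known(s))
  if (nrow(responses) == 1L) {
    met_mat <- matrix(met_mat, nrow = 1L)
    unk_mat <- matrix(unk_mat, nrow = 1L)
  }

  out <- bind_cols(
    tibble(respondent_id = responses$respondent_id),
    status_tbl,
    tibble(
      bipolar = bipolar,
      mood_group = mood_group,
      screen_endorsed = dep$screen_endorsed,
      symptom_count = dep$symptom_count,
      episode_count = dep$episode_count,
      audit_score = alc$audit_score,
      pcl_score = pts$pcl_score,
      any_syndrome = rowSums(met_mat) > 0L,
      any_unassessable = rowSums(unk_mat) > 0L
    ),
    dxs |> select(-"respondent_id")
  )
  structure(out, class = c("mhq_phenotypes", class(out)))
}
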