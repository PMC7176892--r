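# Risk-factor and characteristics derivation: the exposure screens asked in
# the questionnaire (childhood trauma screener, adult adversity, trauma
# triggers) and baseline-style recodes (deprivation, tenure, loneliness,
# social isolation, health behaviours). The same tri-state convention as
# the syndrome classifiers applies: declined or absent answers on a
# required presented item make the screen unassessable, rule-skipped items
# count as not endorsed.

#' Childhood trauma screen
#'
#' Met when any of the five screener items reaches its configured frequency
#' cut-off (possible abuse or neglect).
#'
#' @inheritParams classify_depression
#' @return A tibble `respondent_id`, tri-state `status`.
#' @export
screen_childhood_trauma <- function(responses, spec = default_instrument(),
                                    ruleset = default_ruleset()) {
  cv <- crit_values(spec, responses)
  b <- ruleset$childhood_trauma
  ind <- sapply(seq_along(b$items),
                function(k) cv[, b$items[[k]]] >= b$item_cutoffs[[k]])
  if (nrow(responses) == 1L) ind <- matrix(ind, nrow = 1L)
  tibble(respondent_id = responses$respondent_id,
         status = tv_status(tv_any(ind)))
}

#' Adult adversity screen
#'
#' Met when any of the three adult adversity domains (lack of a confiding
#' relationship, abusive relationship, serious money problems) is endorsed.
#'
#' @inheritParams classify_depression
#' @return A tibble `respondent_id`, tri-state `status`.
#' @export
screen_adult_adversity <- function(responses, spec = default_instrument(),
                                   ruleset = default_ruleset()) {
  cv <- crit_values(spec, responses)
  met <- tv_any(cv[, ruleset$adult_adversity$items, drop = FALSE] == 1)
  tibble(respondent_id = responses$respondent_id, status = tv_status(met))
}

#' Trauma-trigger exposure screen
#'
#' Met when at least `min_count` of the six situations known to trigger
#' trauma-related disorders are reported.
#'
#' @inheritParams classify_depression
#' @return A tibble `respondent_id`, tri-state `status`.
#' @export
screen_trauma_exposure <- function(responses, spec = default_instrument(),
                                   ruleset = default_ruleset()) {
  cv <- crit_values(spec, responses)
  b <- ruleset$trauma_exposure
  met <- tv_count_ge(cv[, b$items, drop = FALSE] == 1, b$min_count)
  tibble(respondent_id = responses$respondent_id, status = tv_status(met))
}

recode_or_fail <- function(responses, spec, item_id) {
  n <- nrow(responses)
  x <- item_column(responses, item_id, n)
  ans <- answered_cells(x)
  legal <- legal_codes(spec, item_id)
  bad <- ans & !(x %in% legal)
  if (any(bad)) {
    abort(sprintf("unknown code %s for field %s",
                  paste(unique(x[bad]), collapse = ", "), item_id))
  }
  ifelse(ans, as.integer(x), NA_integer_)
}

#' Derive the full risk/characteristics profile
#'
#' Combines the three questionnaire screens with deterministic recodes of
#' baseline-style fields: age band (45-64 / 65+), sex, degree, Townsend
#' quintile, renting (social or private rent; other tenures excluded),
#' long-standing illness, smoking, cannabis, physical activity, loneliness
#' (often lonely plus infrequent confiding at baseline) and social
#' isolation (living alone, infrequent visits, no weekly group activity).
#' Unknown codes on a recoded field fail loudly, naming the field.
#'
#' @inheritParams classify_depression
#' @param baseline Optional tibble of baseline covariates joined on
#'   `respondent_id`; its columns override same-named response columns.
#' @return An `mhq_risk` tibble, one row per respondent.
#' @export
derive_risk_profiles <- function(responses, spec = default_instrument(),
                                 ruleset = default_ruleset(),
                                 baseline = NULL) {
  if (!is.null(baseline)) {
    keep <- setdiff(names(responses), setdiff(names(baseline), "respondent_id"))
    responses <- left_join(responses[keep], baseline, by = "respondent_id")
  }
  cv <- crit_values(spec, responses)
  d <- ruleset$demographics
  lo <- ruleset$loneliness
  si <- ruleset$social_isolation

  age <- recode_or_fail(responses, spec, d$age)
  sex_code <- recode_or_fail(responses, spec, d$sex)
  tenure <- recode_or_fail(responses, spec, d$tenure)

  tri_item <- function(id) tv_status(cv[, id] == 1)
  lonely_met <- tv_count_ge(
    cbind(cv[, lo$lonely] == 1, cv[, lo$confide] <= lo$confide_max),
    lo$min_score
  )
  isol_met <- tv_count_ge(
    cbind(cv[, si$live_alone] == 1, cv[, si$visits] >= si$visits_min_code,
          cv[, si$group] == 0),
    si$min_score
  )

  out <- tibble(
    respondent_id = responses$respondent_id,
    childhood_adversity = screen_childhood_trauma(responses, spec, ruleset)$status,
    adult_adversity = screen_adult_adversity(responses, spec, ruleset)$status,
    trauma_exposure = screen_trauma_exposure(responses, spec, ruleset)$status,
    loneliness = tv_status(lonely_met),
    social_isolation = tv_status(isol_met),
    ever_smoked = tri_item(d$smoked),
    ever_cannabis = tri_item(d$cannabis),
    physical_activity_met = tri_item(d$activity),
    longstanding_illness = tri_item(d$illness),
    age_band = factor(
      ifelse(is.na(age), NA_character_,
             ifelse(age >= d$age_band_cut,
                    sprintf("%d+", d$age_band_cut),
                    sprintf("45-%d", d$age_band_cut - 1L))),
      levels = c(sprintf("45-%d", d$age_band_cut - 1L),
                 sprintf("%d+", d$age_band_cut))
    ),
    sex = factor(ifelse(is.na(sex_code), NA_character_,
                        ifelse(sex_code == 1L, "male", "female")),
                 levels = c("female", "male")),
    degree_holder = unname(cv[, d$degree] == 1),
    townsend_quintile = unname(ifelse(is.na(cv[, d$townsend]), NA_integer_,
                                      as.integer(cv[, d$townsend]))),
    renter = tenure %in% d$renter_codes & !is.na(tenure),
    neuroticism_score = unname(ifelse(is.na(cv[, d$neuroticism]), NA_integer_,
                                      as.integer(cv[, d$neuroticism])))
  )
  out$renter[is.na(tenure)] <- NA
  structure(out, class = c("mhq_risk", class(out)))
}
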