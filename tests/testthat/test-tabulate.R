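# A tiny phenotype table built by hand: statuses are set directly so the
# tabulations can be checked against pencil-and-paper counts.
toy_phenotypes <- function(rows) {
  tri <- function(x) factor(x, levels = c("met", "not_met", "unassessable"))
  df <- purrr::imap(rows, function(r, i) {
    defaults <- list(
      depression = "not_met", mania = "not_met", gad = "not_met",
      unusual_experiences = "not_met", self_harm = "not_met",
      alcohol = "not_met", ptsd = "not_met", addiction = "not_met",
      bipolar = "not_met", mood_group = "no_depression",
      any_syndrome = FALSE, any_unassessable = FALSE,
      n_diagnoses = 0L, dx_answered = TRUE,
      dx_depression = FALSE, dx_anxiety_nerves = FALSE, dx_bipolar = FALSE,
      dx_psychosis = FALSE, dx_eating_disorder = FALSE, dx_other = FALSE
    )
    c(list(respondent_id = sprintf("t%d", i)), utils::modifyList(defaults, r))
  }) |> purrr::map(tibble::as_tibble) |> dplyr::bind_rows()
  for (s in c("depression", "mania", "gad", "unusual_experiences",
              "self_harm", "alcohol", "ptsd", "addiction", "bipolar")) {
    df[[s]] <- tri(df[[s]])
  }
  df$mood_group <- factor(df$mood_group, levels = c(
    "no_depression", "subthreshold", "single_episode_depression",
    "recurrent_depression", "bipolar_affective_disorder"))
  structure(df, class = c("mhq_phenotypes", class(df)))
}

test_that("cross-tab counts and row percentages match hand enumeration", {
  # respondents: {depression+gad}, {depression}, {gad}, {neither}
  ph <- toy_phenotypes(list(
    list(depression = "met", gad = "met"),
    list(depression = "met"),
    list(gad = "met"),
    list()
  ))
  ct <- comorbidity_crosstab(ph, syndromes = c("depression", "gad"))
  expect_identical(ct$counts["depression", "gad"], 1L)
  expect_identical(ct$counts["gad", "depression"], 1L)
  expect_identical(ct$row_totals[["depression"]], 2L)
  expect_equal(ct$row_pct["depression", "gad"], 50)
  expect_equal(ct$row_pct["gad", "depression"], 50)
  expect_equal(ct$row_pct["depression", "depression"], 100)
  # tidy() carries the same cells in long form
  td <- tidy(ct)
  expect_equal(
    td$pct[td$row_syndrome == "depression" & td$col_syndrome == "gad"], 50)
})

test_that("cross-tab handles unassessable statuses pairwise and empty rows", {
  ph <- toy_phenotypes(list(
    list(depression = "met", gad = "unassessable"),
    list(depression = "met", gad = "met"),
    list(depression = "not_met", gad = "met")
  ))
  ct <- comorbidity_crosstab(ph, syndromes = c("depression", "gad", "ptsd"))
  # the unassessable gad row drops from the depression/gad cell only
  expect_identical(ct$denominators["depression", "gad"], 1L)
  expect_identical(ct$denominators["depression", "depression"], 2L)
  # empty stratum: no ptsd cases, percentages undefined
  expect_true(all(is.na(ct$row_pct["ptsd", ])))
  # all-met cohort: every row percentage is 100
  ph2 <- toy_phenotypes(list(
    list(depression = "met", gad = "met"),
    list(depression = "met", gad = "met")
  ))
  ct2 <- comorbidity_crosstab(ph2, syndromes = c("depression", "gad"))
  expect_true(all(ct2$row_pct == 100))
})

test_that("pair counts are symmetric and conserved on simulated cohorts", {
  co <- default_cohort()
  ph <- classify_all(co$responses)
  ct <- comorbidity_crosstab(ph)
  expect_identical(ct$counts, t(ct$counts))
  # a pair count can never exceed either marginal count
  for (i in seq_along(ct$syndromes)) {
    for (j in seq_along(ct$syndromes)) {
      expect_lte(ct$counts[i, j], ct$denominators[i, j])
    }
  }
  # diagonal percentages are 100 wherever the row is populated
  pop <- diag(ct$denominators) > 0
  expect_true(all(diag(ct$row_pct)[pop] == 100))
})

test_that("diagnosis prevalence includes cumulative rows with explicit denominators", {
  ph <- toy_phenotypes(list(
    list(n_diagnoses = 2L, dx_depression = TRUE, dx_anxiety_nerves = TRUE),
    list(n_diagnoses = 1L, dx_depression = TRUE),
    list(n_diagnoses = 0L),
    list(n_diagnoses = 0L, dx_answered = FALSE)
  ))
  tab <- diagnosis_prevalence(ph)
  expect_identical(tab$denominator[1], 3L)  # one respondent never answered
  expect_identical(tab$n[tab$category == "depression"], 2L)
  expect_equal(tab$pct[tab$category == "one_or_more"], 100 * 2 / 3)
  expect_equal(tab$pct[tab$category == "two_or_more"], 100 * 1 / 3)
  # every respondent ticks exactly one
  ph2 <- toy_phenotypes(list(
    list(n_diagnoses = 1L, dx_depression = TRUE),
    list(n_diagnoses = 1L, dx_other = TRUE)
  ))
  tab2 <- diagnosis_prevalence(ph2)
  expect_equal(tab2$pct[tab2$category == "one_or_more"], 100)
  expect_equal(tab2$pct[tab2$category == "two_or_more"], 0)
})

test_that("characteristics tables use per-cell complete-case denominators", {
  ph <- toy_phenotypes(list(
    list(depression = "met"),
    list(depression = "met"),
    list()
  ))
  tri <- function(x) factor(x, levels = c("met", "not_met", "unassessable"))
  risks <- tibble::tibble(
    respondent_id = c("t1", "t2", "t3"),
    childhood_adversity = tri(c("met", "unassessable", "not_met")),
    adult_adversity = tri(rep("not_met", 3)),
    trauma_exposure = tri(rep("not_met", 3)),
    loneliness = tri(rep("not_met", 3)),
    social_isolation = tri(rep("not_met", 3)),
    ever_smoked = tri(rep("not_met", 3)),
    ever_cannabis = tri(rep("not_met", 3)),
    physical_activity_met = tri(rep("met", 3)),
    longstanding_illness = tri(rep("not_met", 3)),
    age_band = factor(c("45-64", "65+", "65+"), levels = c("45-64", "65+")),
    sex = factor(c("female", "male", "female"), levels = c("female", "male")),
    degree_holder = c(TRUE, FALSE, NA),
    townsend_quintile = c(5L, 1L, 2L),
    renter = c(TRUE, TRUE, FALSE),
    neuroticism_score = c(10L, 4L, 2L)
  )
  st <- characteristics_by_stratum(ph, risks, "syndrome")
  dep <- st[st$stratum == "depression", ]
  # the unassessable childhood screen drops from its cell denominator
  cell <- dep[dep$characteristic == "childhood_adversity", ]
  expect_identical(cell$n_used, 1L)
  expect_equal(cell$value, 100)
  expect_equal(dep$value[dep$characteristic == "renter"], 100)
  expect_equal(dep$value[dep$characteristic == "neuroticism_mean"], 7)
  # the none-of-the-above stratum exists and excludes the depression cases
  expect_identical(unique(st$n_stratum[st$stratum == "none_of_the_above"]), 1L)
  # empty stratum reports undefined cells, not errors
  expect_true(all(is.na(st$value[st$stratum == "gad"])))
})

test_that("mood-group stratification covers the five groups", {
  co <- perfect_cohort()
  ph <- classify_all(co$responses)
  rk <- derive_risk_profiles(co$responses)
  st <- characteristics_by_stratum(ph, rk, "mood")
  expect_setequal(unique(st$stratum), c(
    "no_depression", "subthreshold", "single_episode_depression",
    "recurrent_depression", "bipolar_affective_disorder"))
  # stratum sizes agree with the mood-group table
  sizes <- dplyr::distinct(st, stratum, n_stratum)
  tab <- table(ph$mood_group)
  for (g in names(tab)) {
    expect_identical(sizes$n_stratum[sizes$stratum == g], as.integer(tab[[g]]))
  }
})

test_that("sex stratification recovers the configured direction of effects", {
  co <- perfect_cohort(n = 6000, seed = 404)
  ph <- classify_all(co$responses)
  rk <- derive_risk_profiles(co$responses)
  st <- stratify_by_sex(ph, rk)
  pick <- function(sx, s) st$pct[st$stratum == sx & st$syndrome == s]
  # alcohol tilts male, depression tilts female in the default model
  expect_gt(pick("male", "alcohol"), pick("female", "alcohol"))
  expect_gt(pick("female", "depression"), pick("male", "depression"))
  # single-sex cohort: the other column is empty
  rk_f <- rk[rk$sex == "female", ]
  ph_f <- ph[ph$respondent_id %in% rk_f$respondent_id, ]
  st_f <- stratify_by_sex(ph_f, rk_f)
  expect_true(all(st_f$n_assessable[st_f$stratum == "male"] == 0))
})

test_that("external comparison joins by label and reports mismatches", {
  internal <- diagnosis_prevalence(toy_phenotypes(list(
    list(n_diagnoses = 1L, dx_depression = TRUE)
  )))
  external <- tibble::tibble(
    category = c("Depression", "anxiety_nerves", "phobia"),
    pct = c(21, 8, 2)
  )
  j <- join_external_comparison(internal, external)
  mm <- attr(j, "mismatches")
  # case-insensitive match on depression; phobia only external
  expect_false("depression" %in% mm$internal_only)
  expect_true("phobia" %in% mm$external_only)
  expect_true("one_or_more" %in% mm$internal_only)
  # nothing silently dropped
  expect_true("phobia" %in% tolower(j$category))
  # empty external table: passthrough plus a full mismatch list
  j2 <- join_external_comparison(internal,
                                 tibble::tibble(category = character(),
                                                pct = numeric()))
  expect_identical(nrow(j2), nrow(internal))
  expect_setequal(attr(j2, "mismatches")$internal_only,
                  tolower(internal$category))
})

test_that("plot and summary methods return well-formed objects", {
  co <- default_cohort()
  ph <- classify_all(co$responses)
  g <- glance(ph)
  expect_identical(g$n, nrow(ph))
  expect_true(all(!is.na(g[paste0("pct_", c("depression", "alcohol"))])))
  expect_s3_class(autoplot(comorbidity_crosstab(ph)), "ggplot")
  expect_s3_class(autoplot(ph), "ggplot")
  expect_s3_class(plot_mood_groups(ph), "ggplot")
  rk <- derive_risk_profiles(co$responses)
  expect_s3_class(autoplot(stratify_by_sex(ph, rk)), "ggplot")
  expect_s3_class(autoplot(characteristics_by_stratum(ph, rk)), "ggplot")
})
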