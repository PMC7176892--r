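# A full depression case as a baseline record; individual tests perturb it.
dep_case <- function(...) {
  base <- list(
    dep_screen_mood = 1L, dep_sym_anh = 1L, dep_sym_tired = 1L,
    dep_sym_appetite = 1L, dep_sym_sleep = 0L, dep_sym_conc = 0L,
    dep_sym_worth = 0L, dep_sym_death = 0L, dep_most_day = 1L,
    dep_dur_weeks = 2L, dep_impair = 1L, dep_episodes = 1L
  )
  do.call(resp, utils::modifyList(base, list(...)))
}

test_that("depression requires core, duration, five symptoms and impairment", {
  # mood + anhedonia + 3 further symptoms, 2 weeks, impairment -> met
  r <- classify_depression(dep_case(dep_sym_sleep = 1L))
  expect_identical(as.character(r$status), "met")
  expect_identical(r$symptom_count, 5L)
  # only 4 symptoms in total -> not met
  expect_identical(as.character(classify_depression(dep_case())$status),
                   "not_met")
  # short duration fails
  expect_identical(
    as.character(classify_depression(
      dep_case(dep_sym_sleep = 1L, dep_dur_weeks = 1L))$status),
    "not_met")
  # both screens negative: detail ignored, decided not met
  r2 <- classify_depression(resp(dep_screen_mood = 0L, dep_screen_anh = 0L))
  expect_identical(as.character(r2$status), "not_met")
  expect_false(r2$screen_endorsed)
  # declined screen leaves the outcome open
  r3 <- classify_depression(resp(dep_screen_mood = -818L,
                                 dep_screen_anh = NA_integer_))
  expect_identical(as.character(r3$status), "unassessable")
})

test_that("mania needs a core period, three symptoms and at least one week", {
  man_case <- function(dur) resp(
    man_screen_elated = 1L, man_sym_active = 1L, man_sym_talk = 1L,
    man_sym_sleep = 1L, man_sym_ideas = 0L, man_dur_days = dur
  )
  expect_identical(as.character(classify_mania(man_case(14L))$status), "met")
  expect_identical(as.character(classify_mania(man_case(7L))$status), "met")
  # three days is below the one-week rule
  expect_identical(as.character(classify_mania(man_case(3L))$status),
                   "not_met")
  # no core endorsement
  expect_identical(
    as.character(classify_mania(
      resp(man_screen_elated = 0L, man_screen_irrit = 0L))$status),
    "not_met")
  # core endorsed but duration declined -> unassessable
  r <- classify_mania(resp(man_screen_elated = 1L, man_sym_active = 1L,
                           man_sym_talk = 1L, man_sym_sleep = 1L,
                           man_dur_days = -818L))
  expect_identical(as.character(r$status), "unassessable")
})

test_that("generalised anxiety requires six months of uncontrollable worry", {
  gad_case <- function(months) resp(
    gad_screen = 1L, gad_dur_months = months, gad_excess = 1L,
    gad_control = 1L, gad_sym_restless = 1L, gad_sym_keyed = 1L,
    gad_sym_tired = 1L, gad_sym_irrit = 0L, gad_sym_sleep = 0L,
    gad_sym_conc = 0L
  )
  expect_identical(as.character(classify_gad(gad_case(12L))$status), "met")
  expect_identical(as.character(classify_gad(gad_case(3L))$status), "not_met")
  expect_identical(
    as.character(classify_gad(resp(gad_screen = 0L))$status), "not_met")
})

test_that("AUDIT sums the ten items with the printed cut-off at eight", {
  audit_case <- function(a1, a2) {
    args <- c(list(audit_1 = a1, audit_2 = a2),
              setNames(as.list(rep(0L, 8)), sprintf("audit_%d", 3:10)))
    do.call(resp, args)
  }
  r8 <- classify_alcohol(audit_case(4L, 4L))
  expect_identical(as.character(r8$status), "met")
  expect_identical(r8$audit_score, 8L)
  r7 <- classify_alcohol(audit_case(3L, 4L))
  expect_identical(as.character(r7$status), "not_met")
  expect_identical(r7$audit_score, 7L)
  # never drinks: remaining items rule-skipped, score 0
  r0 <- classify_alcohol(resp(audit_1 = 0L))
  expect_identical(r0$audit_score, 0L)
  expect_identical(as.character(r0$status), "not_met")
  # a declined item forbids the sum (no proration)
  rna <- classify_alcohol(audit_case(4L, -818L))
  expect_identical(as.character(rna$status), "unassessable")
  expect_true(is.na(rna$audit_score))
})

test_that("PTSD checklist score spans 6-30 with the configured cut-off", {
  pcl_case <- function(v) do.call(resp, setNames(as.list(rep(v, 6)),
                                                 sprintf("pcl_%d", 1:6)))
  r_floor <- classify_ptsd(pcl_case(1L))
  expect_identical(r_floor$pcl_score, 6L)
  expect_identical(as.character(r_floor$status), "not_met")
  r_ceil <- classify_ptsd(pcl_case(5L))
  expect_identical(r_ceil$pcl_score, 30L)
  expect_identical(as.character(r_ceil$status), "met")
  # exactly at the default cut-off of 14
  args <- setNames(as.list(c(3L, 3L, 3L, 3L, 1L, 1L)), sprintf("pcl_%d", 1:6))
  r_cut <- classify_ptsd(do.call(resp, args))
  expect_identical(r_cut$pcl_score, 14L)
  expect_identical(as.character(r_cut$status), "met")
  # a raised cut-off via the ruleset flips the same record
  rs <- default_ruleset()
  rs$ptsd$cutoff <- 15L
  expect_identical(
    as.character(classify_ptsd(do.call(resp, args), ruleset = rs)$status),
    "not_met")
})

test_that("single-item and any-item syndromes follow the tri-state convention", {
  # one endorsed unusual-experience item suffices
  expect_identical(
    as.character(classify_unusual_experiences(
      resp(ue_vision = 1L, ue_voice = 0L, ue_conspiracy = 0L,
           ue_signal = 0L))$status), "met")
  expect_identical(
    as.character(classify_unusual_experiences(
      resp(ue_vision = 0L, ue_voice = 0L, ue_conspiracy = 0L,
           ue_signal = 0L))$status), "not_met")
  expect_identical(
    as.character(classify_unusual_experiences(
      resp(ue_vision = -818L, ue_voice = -818L, ue_conspiracy = -818L,
           ue_signal = -818L))$status), "unassessable")
  # a single "no" with the rest declined is still open
  expect_identical(
    as.character(classify_unusual_experiences(
      resp(ue_vision = 0L, ue_voice = -818L, ue_conspiracy = -818L,
           ue_signal = -818L))$status), "unassessable")
  # self-harm regardless of intent; declined -> unassessable
  expect_identical(as.character(classify_self_harm(resp(sh_ever = 1L))$status),
                   "met")
  expect_identical(as.character(classify_self_harm(resp(sh_ever = 0L))$status),
                   "not_met")
  expect_identical(
    as.character(classify_self_harm(resp(sh_ever = -818L))$status),
    "unassessable")
  # addiction is self-report alone
  expect_identical(
    as.character(classify_addiction(resp(addict_ever = 1L))$status), "met")
  expect_identical(
    as.character(classify_addiction(resp(addict_ever = NA_integer_))$status),
    "unassessable")
})

test_that("self-reported diagnosis counts come from the tick-all item", {
  r <- count_self_reported_diagnoses(resp(dx_mhp = "1;2"))
  expect_identical(r$n_diagnoses, 2L)
  expect_true(r$dx_depression && r$dx_anxiety_nerves)
  expect_false(r$dx_bipolar)
  r0 <- count_self_reported_diagnoses(resp(dx_mhp = "0"))
  expect_identical(r0$n_diagnoses, 0L)
  expect_true(r0$dx_answered)
  rall <- count_self_reported_diagnoses(resp(dx_mhp = "1;2;3;4;5;6"))
  expect_identical(rall$n_diagnoses, 6L)
  rd <- count_self_reported_diagnoses(resp(dx_mhp = "-818"))
  expect_identical(rd$n_diagnoses, 0L)
  expect_false(rd$dx_answered)
})

test_that("bipolar is gated on depression history", {
  tri <- function(x) factor(x, levels = c("met", "not_met", "unassessable"))
  expect_identical(
    as.character(derive_bipolar(tri("met"), tri("met"))), "met")
  # mania without depression never yields bipolar
  expect_identical(
    as.character(derive_bipolar(tri("not_met"), tri("met"))), "not_met")
  expect_identical(
    as.character(derive_bipolar(tri("not_met"), tri("not_met"))), "not_met")
  expect_identical(
    as.character(derive_bipolar(tri("unassessable"), tri("met"))),
    "unassessable")
  expect_identical(
    as.character(derive_bipolar(tri("unassessable"), tri("not_met"))),
    "not_met")
})

test_that("mood groups follow the stated precedence and subthreshold rule", {
  full <- function(...) {
    args <- utils::modifyList(list(
      dep_screen_mood = 1L, dep_sym_anh = 1L, dep_sym_tired = 1L,
      dep_sym_appetite = 1L, dep_sym_sleep = 1L, dep_sym_conc = 0L,
      dep_sym_worth = 0L, dep_sym_death = 0L, dep_most_day = 1L,
      dep_dur_weeks = 4L, dep_impair = 1L, dep_episodes = 3L,
      man_screen_elated = 0L, man_screen_irrit = 0L
    ), list(...))
    ph <- classify_all(do.call(resp, args))
    as.character(ph$mood_group)
  }
  # recurrent depression plus mania -> bipolar affective disorder
  expect_identical(
    full(man_screen_elated = 1L, man_sym_active = 1L, man_sym_talk = 1L,
         man_sym_sleep = 1L, man_dur_days = 14L),
    "bipolar_affective_disorder")
  expect_identical(full(), "recurrent_depression")
  expect_identical(full(dep_episodes = 1L), "single_episode_depression")
  # screen endorsed, criteria unmet -> subthreshold
  expect_identical(full(dep_impair = 0L), "subthreshold")
  # screens negative throughout -> no depression
  expect_identical(full(dep_screen_mood = 0L, dep_screen_anh = 0L),
                   "no_depression")
  # unassessable depression leaves the group undefined
  expect_true(is.na(classify_all(
    resp(dep_screen_mood = -818L))$mood_group))
})

test_that("classifiers agree with brute force over exhaustively enumerated patterns", {
  spec <- default_instrument()
  rs <- default_ruleset()
  # mania: every full assignment over the enumeration domains
  g <- full_grid(spec, c("man_screen_elated", "man_screen_irrit",
                         rs$mania$symptom_items, rs$mania$duration))
  got <- classify_mania(grid_to_responses(g), spec, rs)
  expect_identical(as.integer(got$status == "met"), oracle_mania(g))
  # gad
  g2 <- full_grid(spec, c(rs$gad$screen, rs$gad$duration, rs$gad$excessive,
                          rs$gad$control, rs$gad$symptom_items))
  got2 <- classify_gad(grid_to_responses(g2), spec, rs)
  expect_identical(as.integer(got2$status == "met"), oracle_gad(g2))
  # unusual experiences
  g3 <- full_grid(spec, rs$unusual_experiences$items)
  got3 <- classify_unusual_experiences(grid_to_responses(g3), spec, rs)
  expect_identical(as.integer(got3$status == "met"), oracle_ue(g3))
})

test_that("empty and degenerate cohorts classify cleanly", {
  ph <- classify_all(tibble::tibble(respondent_id = character()))
  expect_identical(nrow(ph), 0L)
  # one all-declined record: everything unassessable, any_syndrome FALSE
  spec <- default_instrument()
  ids <- spec$items$item_id
  rec <- tibble::tibble(respondent_id = "r1")
  for (id in ids) rec[[id]] <- if (id == "dx_mhp") "-818" else -818L
  ph1 <- classify_all(rec, spec)
  for (s in c("depression", "mania", "gad", "unusual_experiences",
              "self_harm", "alcohol", "ptsd", "addiction")) {
    expect_identical(as.character(ph1[[s]]), "unassessable")
  }
  expect_false(ph1$any_syndrome)
  expect_true(ph1$any_unassessable)
})
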