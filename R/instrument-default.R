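# The bundled MHQ-like instrument. It is a faithful skeleton of the study
# questionnaire's branching structure -- screens, symptom items, durations,
# impairment, standard screening scales -- sufficient to drive every case
# definition. Prompts are placeholders: criteria logic binds to item ids,
# and the deployed item bank is held on the study's public showcase rather
# than reproduced here.

yn <- c(no = 0L, yes = 1L)
freq04 <- c(never = 0L, rarely = 1L, sometimes = 2L, often = 3L, very_often = 4L)

#' The bundled default MHQ-like instrument
#'
#' Sections: baseline-linked demographics and wellbeing items, CIDI-SF style
#' lifetime depression (two screens routing into a detailed block), lifetime
#' hypomania/mania, CIDI-SF style lifetime generalised anxiety, lifetime
#' unusual (psychotic-like) experiences, lifetime self-harm, the ten-item
#' AUDIT for the past year, the six-item PTSD checklist for the past month,
#' trauma triggers, the five-item childhood trauma screener, an adult
#' adversity screen, a tick-all professional-diagnosis item and a single
#' self-reported addiction item.
#'
#' Branching follows the screening convention: a positive first screen
#' routes straight into the detailed block (the second screen is then not
#' presented); a negative second screen skips the detailed block. Never
#' drinking skips the remaining alcohol items.
#'
#' @return A validated `mhq_instrument`.
#' @export
default_instrument <- function() {
  items <- bind_rows(
    # -- demographics / baseline-linked ------------------------------------
    mhq_item("age_years", "demographics_link", "Age at questionnaire (years)",
             "integer", min = 45, max = 82),
    mhq_item("sex", "demographics_link", "Sex", "single_choice",
             coding = c(female = 0L, male = 1L)),
    mhq_item("edu_degree", "demographics_link", "Holds a university degree",
             "single_choice", coding = yn),
    mhq_item("townsend_q", "demographics_link",
             "Townsend deprivation quintile (1 least - 5 most deprived)",
             "single_choice",
             coding = c(q1_least = 1L, q2 = 2L, q3 = 3L, q4 = 4L, q5_most = 5L)),
    mhq_item("tenure", "demographics_link", "Housing tenure", "single_choice",
             coding = c(own_outright = 1L, own_mortgage = 2L, rent_social = 3L,
                        rent_private = 4L, other = 5L)),
    mhq_item("longstanding_illness", "demographics_link",
             "Long-standing illness or disability (baseline)", "single_choice",
             coding = yn),
    mhq_item("smoked_ever", "demographics_link", "Ever smoked (baseline)",
             "single_choice", coding = yn),
    mhq_item("cannabis_ever", "demographics_link", "Ever used cannabis",
             "single_choice", coding = yn),
    mhq_item("activity_met", "demographics_link",
             "Meets recommended physical activity level (baseline)",
             "single_choice", coding = yn),
    mhq_item("live_alone", "demographics_link", "Lives alone (baseline)",
             "single_choice", coding = yn),
    mhq_item("visit_freq", "demographics_link",
             "Frequency of friend/family visits (baseline)", "single_choice",
             coding = c(daily = 1L, weekly = 2L, monthly = 3L,
                        few_times_year = 4L, never = 5L)),
    mhq_item("group_activity", "demographics_link",
             "Weekly group activity (baseline)", "single_choice", coding = yn),
    mhq_item("confide_freq", "wellbeing",
             "How often able to confide in someone close (baseline)",
             "single_choice", coding = freq04),
    mhq_item("lonely_often", "wellbeing", "Often feels lonely",
             "single_choice", coding = yn),
    mhq_item("neuroticism", "wellbeing",
             "Neuroticism score (baseline scale, supplied)", "integer",
             min = 0, max = 12),

    # -- lifetime depression (CIDI-SF style) -------------------------------
    mhq_item("dep_screen_mood", "depression",
             "Ever a period of >= 2 weeks feeling sad or depressed",
             "single_choice", coding = yn),
    mhq_item("dep_screen_anh", "depression",
             "Ever a period of >= 2 weeks losing interest in things",
             "single_choice", coding = yn),
    mhq_item("dep_sym_anh", "depression", "During worst period: lost interest",
             "single_choice", coding = yn),
    mhq_item("dep_sym_tired", "depression", "During worst period: tiredness",
             "single_choice", coding = yn),
    mhq_item("dep_sym_appetite", "depression",
             "During worst period: appetite/weight change", "single_choice",
             coding = yn),
    mhq_item("dep_sym_sleep", "depression", "During worst period: sleep change",
             "single_choice", coding = yn),
    mhq_item("dep_sym_conc", "depression",
             "During worst period: trouble concentrating", "single_choice",
             coding = yn),
    mhq_item("dep_sym_worth", "depression",
             "During worst period: feelings of worthlessness", "single_choice",
             coding = yn),
    mhq_item("dep_sym_death", "depression",
             "During worst period: thoughts of death", "single_choice",
             coding = yn),
    mhq_item("dep_most_day", "depression",
             "Symptoms most of the day, nearly every day", "single_choice",
             coding = yn),
    mhq_item("dep_dur_weeks", "depression", "Duration of worst period (weeks)",
             "duration", min = 0, max = 520,
             domain = c(0L, 1L, 2L, 3L, 4L, 8L, 26L)),
    mhq_item("dep_impair", "depression",
             "Symptoms interfered with life or activities", "single_choice",
             coding = yn),
    mhq_item("dep_episodes", "depression", "Number of such episodes in life",
             "integer", min = 0, max = 100, domain = c(1L, 2L, 3L, 5L)),

    # -- lifetime hypomania / mania ----------------------------------------
    mhq_item("man_screen_elated", "mania",
             "Ever a period feeling high or elated", "single_choice",
             coding = yn),
    mhq_item("man_screen_irrit", "mania",
             "Ever a period extremely irritable", "single_choice", coding = yn),
    mhq_item("man_sym_active", "mania", "During that period: more active",
             "single_choice", coding = yn),
    mhq_item("man_sym_talk", "mania", "During that period: more talkative",
             "single_choice", coding = yn),
    mhq_item("man_sym_sleep", "mania", "During that period: needed less sleep",
             "single_choice", coding = yn),
    mhq_item("man_sym_ideas", "mania", "During that period: thoughts racing",
             "single_choice", coding = yn),
    mhq_item("man_dur_days", "mania", "Longest such period (days)",
             "duration", min = 0, max = 3650, domain = c(1L, 3L, 7L, 14L)),

    # -- lifetime generalised anxiety (CIDI-SF style) ----------------------
    mhq_item("gad_screen", "anxiety",
             "Ever a period of a month or more feeling worried or anxious",
             "single_choice", coding = yn),
    mhq_item("gad_dur_months", "anxiety", "Longest such period (months)",
             "duration", min = 0, max = 600, domain = c(1L, 3L, 6L, 12L)),
    mhq_item("gad_excess", "anxiety", "Worry stronger than in most people",
             "single_choice", coding = yn),
    mhq_item("gad_control", "anxiety", "Worry difficult to control",
             "single_choice", coding = yn),
    mhq_item("gad_sym_restless", "anxiety", "When worried: restless",
             "single_choice", coding = yn),
    mhq_item("gad_sym_keyed", "anxiety", "When worried: keyed up or on edge",
             "single_choice", coding = yn),
    mhq_item("gad_sym_tired", "anxiety", "When worried: easily tired",
             "single_choice", coding = yn),
    mhq_item("gad_sym_irrit", "anxiety", "When worried: irritable",
             "single_choice", coding = yn),
    mhq_item("gad_sym_sleep", "anxiety", "When worried: trouble sleeping",
             "single_choice", coding = yn),
    mhq_item("gad_sym_conc", "anxiety", "When worried: trouble concentrating",
             "single_choice", coding = yn),

    # -- lifetime unusual experiences --------------------------------------
    mhq_item("ue_vision", "psychotic_experiences",
             "Ever saw something not really there", "single_choice",
             coding = yn),
    mhq_item("ue_voice", "psychotic_experiences",
             "Ever heard a voice others could not hear", "single_choice",
             coding = yn),
    mhq_item("ue_conspiracy", "psychotic_experiences",
             "Ever believed in an unjust plot against them", "single_choice",
             coding = yn),
    mhq_item("ue_signal", "psychotic_experiences",
             "Ever believed a special sign or message was sent to them",
             "single_choice", coding = yn),

    # -- lifetime self-harm ------------------------------------------------
    mhq_item("sh_ever", "self_harm",
             "Ever self-harmed, whether or not meaning to end life",
             "single_choice", coding = yn),

    # -- AUDIT, past year --------------------------------------------------
    mhq_item("audit_1", "alcohol", "Frequency of drinking", "single_choice",
             coding = c(never = 0L, monthly_or_less = 1L, two_four_month = 2L,
                        two_three_week = 3L, four_plus_week = 4L)),
    purrr::map(2:8, function(k) {
      mhq_item(sprintf("audit_%d", k), "alcohol",
               sprintf("AUDIT item %d (0-4)", k), "single_choice",
               coding = setNames(0:4, c("c0", "c1", "c2", "c3", "c4")),
               domain = c(0L, 2L, 4L))
    }) |> bind_rows(),
    purrr::map(9:10, function(k) {
      mhq_item(sprintf("audit_%d", k), "alcohol",
               sprintf("AUDIT item %d (0/2/4)", k), "single_choice",
               coding = c(no = 0L, yes_not_last_year = 2L, yes_last_year = 4L))
    }) |> bind_rows(),

    # -- PTSD checklist (6-item short form), past month; trauma exposure;
    #    childhood and adult adversity screens -----------------------------
    purrr::map(1:6, function(k) {
      mhq_item(sprintf("pcl_%d", k), "trauma_ptsd",
               sprintf("PTSD checklist item %d (1-5)", k), "single_choice",
               coding = c(not_at_all = 1L, a_little = 2L, moderately = 3L,
                          quite_a_bit = 4L, extremely = 5L))
    }) |> bind_rows(),
    purrr::map(1:6, function(k) {
      mhq_item(sprintf("tr_trig_%d", k), "trauma_ptsd",
               sprintf("Experienced trauma-trigger situation %d", k),
               "single_choice", coding = yn)
    }) |> bind_rows(),
    purrr::map(1:5, function(k) {
      mhq_item(sprintf("cts_%d", k), "trauma_ptsd",
               sprintf("Childhood trauma screener item %d (frequency)", k),
               "single_choice", coding = freq04)
    }) |> bind_rows(),
    mhq_item("aa_confide", "trauma_ptsd",
             "As an adult: lacked a confiding relationship", "single_choice",
             coding = yn),
    mhq_item("aa_abuse", "trauma_ptsd",
             "As an adult: abusive relationship", "single_choice", coding = yn),
    mhq_item("aa_money", "trauma_ptsd",
             "As an adult: serious money problems", "single_choice",
             coding = yn),

    # -- self-reported diagnoses and addiction -----------------------------
    mhq_item("dx_mhp", "diagnoses",
             "Professional mental-health diagnoses ever received (tick all)",
             "multi_choice",
             coding = c(none = 0L, depression = 1L, anxiety_nerves = 2L,
                        bipolar = 3L, psychosis = 4L, eating_disorder = 5L,
                        other = 6L)),
    mhq_item("addict_ever", "addiction",
             "Ever addicted to or dependent on substances or behaviours",
             "single_choice", coding = yn)
  )

  rules <- list(
    # positive first depression screen routes into detail (second screen
    # not presented); negative second screen skips the detailed block
    skip_rule("dep_screen_mood", 1L, "dep_screen_anh"),
    skip_rule("dep_screen_anh", 0L,
              c("dep_sym_anh", "dep_sym_tired", "dep_sym_appetite",
                "dep_sym_sleep", "dep_sym_conc", "dep_sym_worth",
                "dep_sym_death", "dep_most_day", "dep_dur_weeks",
                "dep_impair", "dep_episodes")),
    skip_rule("man_screen_elated", 1L, "man_screen_irrit"),
    skip_rule("man_screen_irrit", 0L,
              c("man_sym_active", "man_sym_talk", "man_sym_sleep",
                "man_sym_ideas", "man_dur_days")),
    skip_rule("gad_screen", 0L,
              c("gad_dur_months", "gad_excess", "gad_control",
                "gad_sym_restless", "gad_sym_keyed", "gad_sym_tired",
                "gad_sym_irrit", "gad_sym_sleep", "gad_sym_conc")),
    # never drinks: remaining alcohol items not presented
    skip_rule("audit_1", 0L, sprintf("audit_%d", 2:10))
  )

  mhq_instrument(items, rules, version = "mhq_default-1.0")
}
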