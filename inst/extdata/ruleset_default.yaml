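version: ruleset_default-1.0
depression:
  screen_mood: dep_screen_mood
  screen_anh: dep_screen_anh
  symptom_anh: dep_sym_anh
  symptom_items:
  - dep_sym_tired
  - dep_sym_appetite
  - dep_sym_sleep
  - dep_sym_conc
  - dep_sym_worth
  - dep_sym_death
  most_day: dep_most_day
  duration: dep_dur_weeks
  impairment: dep_impair
  episodes: dep_episodes
  min_symptoms: 5
  min_duration_weeks: 2
  recurrent_min_episodes: 2
mania:
  screen_elated: man_screen_elated
  screen_irritable: man_screen_irrit
  symptom_items:
  - man_sym_active
  - man_sym_talk
  - man_sym_sleep
  - man_sym_ideas
  duration: man_dur_days
  min_symptoms: 3
  min_duration_days: 7
gad:
  screen: gad_screen
  duration: gad_dur_months
  excessive: gad_excess
  control: gad_control
  symptom_items:
  - gad_sym_restless
  - gad_sym_keyed
  - gad_sym_tired
  - gad_sym_irrit
  - gad_sym_sleep
  - gad_sym_conc
  min_symptoms: 3
  min_duration_months: 6
alcohol:
  items:
  - audit_1
  - audit_2
  - audit_3
  - audit_4
  - audit_5
  - audit_6
  - audit_7
  - audit_8
  - audit_9
  - audit_10
  cutoff: 8
ptsd:
  items:
  - pcl_1
  - pcl_2
  - pcl_3
  - pcl_4
  - pcl_5
  - pcl_6
  cutoff: 14
unusual_experiences:
  items:
  - ue_vision
  - ue_voice
  - ue_conspiracy
  - ue_signal
self_harm:
  item: sh_ever
addiction:
  item: addict_ever
diagnoses:
  item: dx_mhp
  categories:
    depression: 1
    anxiety_nerves: 2
    bipolar: 3
    psychosis: 4
    eating_disorder: 5
    other: 6
childhood_trauma:
  items:
  - cts_1
  - cts_2
  - cts_3
  - cts_4
  - cts_5
  item_cutoffs:
  - 3
  - 3
  - 3
  - 3
  - 3
adult_adversity:
  items:
  - aa_confide
  - aa_abuse
  - aa_money
trauma_exposure:
  items:
  - tr_trig_1
  - tr_trig_2
  - tr_trig_3
  - tr_trig_4
  - tr_trig_5
  - tr_trig_6
  min_count: 1
loneliness:
  lonely: lonely_often
  confide: confide_freq
  confide_max: 1
  min_score: 2
social_isolation:
  live_alone: live_alone
  visits: visit_freq
  visits_min_code: 4
  group: group_activity
  min_score: 2
demographics:
  age: age_years
  age_band_cut: 65
  sex: sex
  degree: edu_degree
  townsend: townsend_q
  tenure: tenure
  renter_codes:
  - 3
  - 4
  illness: longstanding_illness
  smoked: smoked_ever
  cannabis: cannabis_ever
  activity: activity_met
  neuroticism: neuroticism
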