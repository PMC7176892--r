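# mhqtools

Computable phenotyping for a branching online mental-health questionnaire,
plus a synthetic-cohort generator to validate the whole pipeline without
access to restricted survey data.

Large cohort studies increasingly characterise lifetime mental-health
phenotypes with self-completed online questionnaires built from established
screening instruments: CIDI-SF style lifetime depression and generalised
anxiety modules with screening questions and skip rules, a hypomania/mania
module, the ten-item AUDIT for past-year hazardous/harmful drinking, a
six-item PTSD checklist, and single items for lifetime unusual
(psychotic-like) experiences, self-harm and self-reported addiction. The
study data behind such questionnaires are typically access-controlled, so
analysis code is hard to test end to end. `mhqtools` is aimed at
epidemiologists and methodologists who need that pipeline as reusable,
tested code: the questionnaire model, the operational case definitions, the
descriptive tables, and a generator of synthetic cohorts with known latent
truth to validate everything against.

## What it implements

**Instrument model.** A questionnaire is an ordered list of coded items plus
skip rules (`trigger item x answered with code c suppresses later items`).
The bundled default instrument (`default_instrument()`, also shipped as
`inst/extdata/mhq_default.yaml`) encodes the branching skeleton of a
composite mental-health questionnaire: a positive first depression screen
routes straight into the detailed block, a negative second screen skips it,
never-drinkers skip the remaining alcohol items, and so on. Respondent
answers live in a wide tibble with explicit sentinels: `-818` = prefer not
to answer, `-121` = do not know, blank = absent (or rule-skipped, derived
from the instrument).

**Case definitions.** Each syndrome classifier is a deterministic tri-state
function (met / not met / unassessable) over a response table:

- *Lifetime depression* (CIDI-SF style): a core feature (depressed mood or
  anhedonia) most of the day nearly every day for >= 2 weeks, total symptom
  count >= 5, with impairment; the episode count separates single-episode
  from recurrent depression.
- *Lifetime hypomania/mania*: elated or irritable period, >= 3 associated
  symptoms, duration >= 1 week.
- *Lifetime generalised anxiety*: >= 6 months of excessive, hard-to-control
  worry with >= 3 associated symptoms.
- *Past-year hazardous/harmful alcohol use*: AUDIT total >= 8 (no
  proration of missing items).
- *Current post-traumatic stress*: six-item checklist sum (6-30), default
  cut-off 14 (configurable).
- *Unusual experiences*, *self-harm* (irrespective of suicidal intent) and
  *self-reported addiction*: single/any-item endorsements.

Missing data follow Kleene three-valued logic: a rule-skipped item counts
as "criterion not endorsed" (screening out *decides* the outcome), while a
declined or absent answer on an item that could still change the decision
makes the classification unassessable. A likely *bipolar affective
disorder* label is gated on depression history (depression AND mania), and
the cohort is partitioned into five mood groups with precedence
`bipolar > recurrent > single episode > subthreshold > no depression`.
Every threshold and item binding lives in an editable, versioned ruleset
(`default_ruleset()`, `inst/extdata/ruleset_default.yaml`).

**Risk factors and tables.** Childhood trauma screener, adult adversity,
trauma-trigger exposure, loneliness and social isolation composites,
deprivation/tenure/education recodes; row-conditional comorbidity
cross-tabs with pairwise complete-case denominators, self-reported
diagnosis prevalence with cumulative rows, characteristics by syndrome
stratum or mood group, sex stratification, and a label-matched join against
user-supplied external prevalence tables.

**Synthetic cohorts.** Latent syndrome indicators follow a pairwise-tilted
multivariate Bernoulli (Ising model): the joint mass of states
`x in {0,1}^8` is proportional to
`exp(sum_i alpha_i x_i + sum_{i<j} beta_ij x_i x_j)`, with the fields
`alpha` calibrated by Newton iteration on the exact 2^8 enumeration so the
realized marginals match configured prevalences (defaults: depression 24%,
alcohol 21%, GAD 7%, PTSD 6%, addiction 6%, unusual experiences 5%,
self-harm 4%, mania 2%) under positive comorbidity tilts. Responses are
emitted in two stages per scored construct -- a sensitivity/specificity coin
for the classification outcome, then a uniform draw from the enumerated
response patterns consistent with that outcome and the skip rules --
followed by configurable refusal and abandonment censoring. With fidelity 1
and no censoring, classification recovers the latent truth exactly, which
is the backbone of the test suite.

## Worked example

```r
library(mhqtools)

cohort <- generate_cohort(cohort_config(n = 5000, seed = 42))
phen   <- classify_all(cohort$responses)
round(glance(phen), 1)
#>      n pct_depression pct_mania pct_gad pct_unusual_experiences pct_self_harm
#> 1 5000           23.4       4.9     9.3                     7.9           6.8
#>   pct_alcohol pct_ptsd pct_addiction pct_bipolar pct_any_syndrome n_any_unassessable
#> 1        19.8      7.8           8.5         1.7             49.9                834
```

Classified prevalence sits near `p*se + (1-p)(1-sp)` of the configured
prevalences because the default generator emits with sensitivity 0.9 and
specificity 0.97; 834 respondents have at least one syndrome that could not
be assessed because of simulated refusals or abandonment. The comorbidity
table conditions on the row syndrome:

```r
comorbidity_crosstab(phen)
#> Comorbidity cross-tab (5000 respondents)
#> Row percentages (share of row syndrome also meeting column):
#>                     depression mania   gad ... bipolar
#> depression               100.0   7.3  23.8 ...     7.3
#> gad                       60.1   8.0 100.0 ...     5.7
#> ptsd                      53.9   7.9  31.0 ...     4.2
#> bipolar                  100.0 100.0  31.3 ...   100.0
```

Note the built-in gating: every bipolar case meets both depression and
mania by construction. Self-reported professional diagnoses and the
five-group mood partition:

```r
diagnosis_prevalence(phen)
#>          category    n denominator  pct
#> 1      depression 1041        4813 21.6
#> ...
#> 7     one_or_more 1543        4813 32.1
#> 8     two_or_more  241        4813  5.0

table(phen$mood_group, useNA = "ifany")
#>              no_depression               subthreshold  single_episode_depression
#>                        966                       2749                        418
#>       recurrent_depression bipolar_affective_disorder                       <NA>
#>                        621                         83                        163
```

The `NA` mood groups are respondents whose depression status (or episode
count) was unassessable; they are counted in the pipeline's QC report
rather than mood tables. `autoplot()` methods exist for phenotype tables,
cross-tabs and stratified tables, and `run_pipeline()` orchestrates
simulate -> validate -> phenotype -> tabulate with a manifest and QC report
(`inst/cli/mhq.R` wraps it for shell use).

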