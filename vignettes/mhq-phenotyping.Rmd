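---
title: "Phenotyping a branching mental-health questionnaire: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phenotyping a branching mental-health questionnaire}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mhqtools)
```

This vignette is the package's account of its science: the questionnaire
model, the operational case definitions and their missing-data semantics,
the synthetic-cohort generator, and the design decisions taken where more
than one reasonable choice existed.

## The instrument model and skip semantics

An instrument is an ordered list of coded items plus *skip rules*: when a
trigger item is answered with one of its trigger codes, a stated set of
later items is not presented. This is the branching device of screening
instruments -- a negative screen routes the respondent past the detailed
block -- and it is what makes "missing" ambiguous in the raw data: an empty
cell can mean *rule-skipped* (legitimately never asked), *absent*
(abandoned or unreached), or, with explicit sentinels, *declined* (`-818`)
or *do not know* (`-121`).

Two semantic choices deserve explanation.

**Screen pairs are encoded as sequential flow.** The depression module
skips its detailed block only when *both* screens (low mood; anhedonia) are
negative. A skip rule has a single trigger, so the conjunction is encoded
the way the source instruments themselves administer it: a positive first
screen routes straight into detail (the second screen is then rule-skipped
and the corresponding symptom is collected inside the detail block); a
negative second screen skips the detail block. The mania module follows the
same pattern.

**Unanswered triggers fire no rule.** `presented_items()` treats an item as
presented unless a *triggered* rule suppressed it. A respondent who
declines a screen therefore still "faces" the detail items; a respondent
who abandons the questionnaire leaves later presented items absent. This is
what makes `completion_status()` well defined: *complete* means every
presented item carries a response (a refusal counts as responding --
voluntary skipping was an explicit affordance of the survey), *partial*
means some presented item is blank, *not started* means nothing was
answered. The alternative reading -- unanswered gates hide their blocks --
would make every abandoned questionnaire look complete and would make
"answered inside a skip" unverifiable, so it was rejected.

## Case definitions and three-valued logic

Every classifier is a deterministic function from a response table to
`met / not_met / unassessable`, with all thresholds and item bindings in an
editable, versioned ruleset (`default_ruleset()`); a later, more faithful
transcription of any criterion is a configuration change, not a code
change. Defaults:

| construct | rule | default | unit |
|---|---|---|---|
| depression | core + most-of-day + duration + symptoms + impairment | >= 5 symptoms, >= 2 weeks | count, weeks |
| depression recurrence | episode count | >= 2 episodes | count |
| hypomania/mania | core + symptoms + duration | >= 3 symptoms, >= 7 days | count, days |
| generalised anxiety | worry + excessive + uncontrollable + symptoms | >= 6 months, >= 3 symptoms | months, count |
| alcohol (AUDIT) | item sum, 0-40 | >= 8 | score |
| PTSD (6-item checklist) | item sum, 6-30 | >= 14 | score |
| childhood trauma screener | any item at frequency cut-off | code >= 3 ("often") per item | 0-4 code |
| trauma exposure | situations reported | >= 1 of 6 | count |
| loneliness | often lonely + infrequent confiding | both (score 2 of 2) | -- |
| social isolation | lives alone, infrequent visits, no group activity | >= 2 of 3 | -- |

The depression, anxiety and mania modules are DSM-IV operationalisations
of the named instruments; the alcohol cut-off and the one-week mania rule
are fixed by the instruments' published conventions. The six-item PTSD
checklist has no single canonical short-form threshold, so 14 (a published
convention for the 6-item sum) is the default and is exposed in the
ruleset, as are the per-item childhood-screener cut-offs. The loneliness
and social-isolation composites are two- and three-item conventions for
baseline cohort items; the named construct is fixed, the thresholds are
configuration.

Missing data follow Kleene three-valued logic over *criterion values*:
an answered item contributes its code; a rule-skipped item contributes
"criterion not endorsed" (zero); a presented-but-missing item contributes
`NA`. The criterion expression then evaluates to `TRUE`, `FALSE` or `NA`,
and `NA` propagates exactly when the missing answer could still change the
decision. Consequences worth spelling out:

- Screening out *decides*: both screens negative gives `not_met` no matter
  what the (never-asked) detail items would have said.
- A declined screen leaves the classification `unassessable` even if some
  detail answers exist.
- Symptom counts use an interval argument: "at least k" is `TRUE` once
  observed endorsements reach k, `FALSE` once even endorsing every missing
  item could not reach k, `NA` otherwise.
- Score sums (AUDIT, PTSD checklist) are never prorated: one declined item
  makes the sum, and hence the classification, unassessable. The cut-off
  semantics of a partial sum are undefined, so the package refuses to
  invent them.

The likely bipolar-affective-disorder label is the Kleene conjunction of
depression and mania: population screening for mania alone over-identifies
bipolar disorder, so the label is restricted to respondents with a
depression history. The five mood groups apply the precedence
`bipolar > recurrent > single episode > subthreshold > no depression`,
where *subthreshold* means a depression screen was endorsed but full
criteria were not met. The boundary between "no depression" and
"subthreshold" is set at screen endorsement; a defensible alternative
(partial criteria) exists, which is why the screen-endorsement flag is
returned alongside the status. A respondent whose depression status,
episode count or (where it decides the label) mania status is unassessable
gets an undefined mood group and is reported in the QC count, never
silently dropped into a group.

`any_syndrome` is the OR over the seven operationally defined syndromes
(self-reported addiction is tabulated separately); unassessable components
count as not met, and the row is flagged so tables can report how often
that convention was exercised.

## The synthetic-cohort generator

The generator's defaults are the study conditions the package is validated
under; they are set once and are not tuning knobs.

**Latent layer.** The eight syndrome indicators follow a pairwise-tilted
multivariate Bernoulli (an Ising model): the probability of state
$x \in \{0,1\}^8$ is proportional to
$\exp(\sum_i \alpha_i x_i + \sum_{i<j} \beta_{ij} x_i x_j)$. This is the
simplest joint distribution that matches configurable marginals *and*
pairwise associations, which is exactly the information a row-conditional
comorbidity table carries. The tilt matrix defaults encode the qualitative
published pattern: anxiety, self-harm, mania and current PTSD cluster
strongly with depression (the depression-anxiety tilt of 2.3 log-odds
makes most anxiety cases also depression cases), PTSD raises everything,
hazardous drinking adds little. The fields $\alpha$ are calibrated by
Newton iteration on the exact $2^8$ enumeration (the Jacobian of the
marginals is the covariance of the indicators), with a step-halving line
search, to tolerance $10^{-10}$; marginals pinned to 0 or 1 are rejected
as infeasible rather than approximated. Depression cases split into
single-episode and recurrent with a configurable recurrent share
(default 0.6 -- the split is not published, and this value simply makes
both groups well populated).

**Covariates.** Binary covariates are drawn conditionally on the latent
states by logistic models, $P(\text{cov}\mid x) =
\mathrm{logit}^{-1}(\beta_0 + \sum_i \delta_i x_i)$, with offsets encoding
the *direction* of the published associations (depression and anxiety more
common in women, alcohol and addiction in men, every syndrome rarer over
65, deprivation and renting raised with addiction and mania, neuroticism
raised with mood and anxiety syndromes); the magnitudes are the package's
own choices, since the real magnitudes are functions of the restricted
data. Age is uniform within bands with 53% at 65 or over (range 45-82);
sex is 57% female; the Townsend quintile is categorical with an
exponential deprivation tilt per syndrome.

**Emission.** Each scored construct is emitted in two stages. First a
classification-consistency coin: a true case yields a criteria-satisfying
record with probability `sensitivity`, a true non-case with probability
`1 - specificity` (defaults 0.9 / 0.97 -- plausible screen accuracy; the
test suite exercises 1/1 and 0.9/0.95 explicitly). Second, a concrete
response pattern is drawn *uniformly* from the enumerated set of full
assignments whose classification under the skip rules equals that outcome.
Enumeration domains for integer items are small, stated supports (e.g.
durations {0,1,2,3,4,8,26} weeks; AUDIT items 2-10 restricted to
{0,2,4}), which keeps every section at or below about $10^5$ patterns.
Uniform sampling within a class guarantees the perfect-fidelity identity
without pretending to model item psychometrics; its cost is that the
*composition within* a class is arbitrary -- for example, the share of
non-cases with an endorsed screen (hence "subthreshold") reflects the
pattern count, not an epidemiological estimate. Quantities conditioned on
meeting or not meeting criteria are meaningful; quantities about the fine
structure inside a class are not.

Patterns retain values for rule-skipped items ("shadow" values). They are
not written to the record -- unless censoring strikes a trigger: a declined
screen no longer fires its rule, the detail block becomes presented, and
the shadow values are revealed. This keeps every emitted record
skip-consistent under any censoring configuration (`validate_responses()`
returns zero violations by construction). Refusal censoring declines each
presented item independently with `decline_rate` (default 0.01);
abandonment makes a respondent partial with `partial_rate` (default 0.03)
by blanking everything from a uniformly drawn cut position onward. At
`decline_rate = 1` every classification is unassessable, as it should be.

**Randomness.** Generation is fully vectorised under one seeded stream
(`set.seed` on the config seed); identical config and seed give
byte-identical cohorts and pipeline artifacts (the manifest carries no
timestamps for this reason). Per-respondent counter-derived substreams
were considered and rejected: they buy order-independence the vectorised
implementation already has, at the cost of a hand-rolled RNG protocol.

**What the generator does not emulate.** Item-response-theory style item
correlations within a section; nonresponse driven by the latent state
(selection bias -- deliberately, since the motivating surveys cannot
estimate prevalence for exactly that reason); recall bias; free-text.
Passing tests therefore demonstrate that the *pipeline logic* is correct
-- classifiers invert the emission exactly at fidelity 1, attenuate as
$p \cdot se + (1-p)(1-sp)$ under imperfect fidelity, and handle censoring
per the stated conventions -- not that any real cohort has these
prevalences. The headline percentages of the motivating literature are
computed on restricted, self-selected samples and are explicitly not
prevalence estimates; they are reproduced here only as generator settings.

## Tabulation conventions

Comorbidity tables are row-conditional: the cell (i, j) is the percentage
of respondents with syndrome i who also meet j, among respondents
assessable on *both* (pairwise complete case; whether the source tables
excluded listwise or pairwise is not stated, so the denominators are
explicit in the output). Pair counts are symmetric; denominators are not.
Characteristics tables use per-cell complete-case denominators with
reported `n_used`; counts always accompany percentages; empty strata
produce undefined markers, never errors. The none-of-the-above stratum is
defined as criteria not met (and assessable) for depression, generalised
anxiety, unusual experiences and addiction. The external-comparison join
is label-matched and keeps unmatched categories on both sides, listing
them in a mismatch attribute. Confidence intervals are omitted by design
at these sample sizes; exact binomial intervals are a line of code away
from the reported numerators and denominators.

The adult-adversity screen and the loneliness composite both involve a
confiding relationship, but over different windows (adult lifetime versus
at baseline); they are two distinct items in the instrument, each feeding
exactly one construct, so no single answer is double-counted.

## Numerical choices and degenerate inputs

- Ising calibration: Newton with line search, tolerance $10^{-10}$,
  maximum 500 iterations; non-convergence and boundary prevalences raise
  configuration errors.
- Threshold comparisons are all "at or above" (`>=`), matching the printed
  "score of 8 or more" style conventions; boundary tests pin 7 vs 8
  (AUDIT), 13 vs 14 (PTSD checklist), 3 days vs 1 week (mania), 3 vs 6
  months (anxiety), 4 vs 5 symptoms (depression).
- Empty cohorts, all-declined records, single-sex cohorts and empty strata
  are all legal inputs with defined outputs (empty tables, unassessable
  statuses, undefined markers).
- Percentages are computed from explicit denominators and printed to one
  decimal in displays; underlying tibbles keep full precision.

## Problem sizes used in validation

The test suite enumerates every section's full response-pattern space
(up to ~$10^5$ patterns for the alcohol module) against independent
brute-force oracles, and runs cohorts of 5 000 (perfect-fidelity
identity), 20 000 (attenuation) and 100 000 (latent calibration within
$3\sqrt{p(1-p)/n}$). These sizes give the stochastic checks comfortable
3-standard-error margins while keeping a full run to about a minute; the
acceptance script uses 20 000 respondents for the same reason.

## Known limitations

The bundled instrument is a faithful *skeleton*: item wording is
placeholder, and the deployed item bank's exact codings live behind the
study's data showcase, so the default ruleset is marked provisional in the
same sense -- the computational contract is the criteria logic, not the
prose. Classification from self-report cannot rule out better explanations
for symptoms, and the package deliberately labels outcomes "likely"
syndromes, not diagnoses. Cross-construct skip rules (a rule in one
section gating another section's items) are supported by the instrument
model but not by the emission enumerator, which enumerates per section.
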