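# cogtrainr

An engine for delivering multidomain computerized cognitive training (CCT)
at home, built for digital trials where thousands of older adults train
unsupervised and adherence — not exercise content — is the scarce resource.
It is aimed at researchers running or simulating adaptive cognitive
interventions: it plans what each participant trains and when, scores and
feeds back performance relative to the cohort, and triages limited trainer
time with rule-based monitoring. A seeded virtual-participant simulator
drives every component, so the whole pipeline is testable without any
participant data.

## What it implements

**Cognitive profile.** Seven cognitive domains are assessed at intake
(verbal memory, visual attention, visual memory, verbal executive, visual
executive, working memory, processing speed). Each baseline test score *x*
is standardized against a normative reference, *z* = (*x* − μ) / σ, domains
are ranked from strength (highest *z*) to weakness (lowest *z*), and the
ranking is partitioned into 2 strength / 2 mid / 3 weakness tiers.

**"Sandwich" sessions.** Each of the 30 sessions in a 10-week module holds
17 exercises: 6 easy (drawn from strength domains), 4 medium (mid domains),
and 7 hard (weakness domains), in a fixed positional pattern that opens,
re-centers, and closes each session with easy work
(`E E M M M H H H E E M H H H H E E`). Selection within a tier is
pseudorandom without within-session repetition, and fully reproducible from
a seed. Sessions cannot be skipped; after the module, boosters run monthly
for up to 3 years.

**Adaptive refresh.** At sessions 13, 19 and 25 the profile is rebuilt from
the participant's own exercise results over the preceding session range:
each raw score is standardized against the cohort's per-exercise
distribution and averaged per domain, so strengths and weaknesses track
observed training performance.

**Comparable scoring and feedback.** Cohort z-standardization makes scores
comparable across exercises; per-domain means feed a feedback board with a
target zone at the cohort's 75th percentile (the "top performing 25%").

**Adherence monitoring.** Red flags for poor performance (more incorrect
than correct, zero correct, below a predefined level, a ≥10% decline across
consecutive attempts of the same exercise); orange flags for poor adherence
(session > 90 min, ≥72 h absent between sessions); three oranges escalate
to a red. Red flags open trainer tickets (open → assigned → resolved, with
handover); automatic participant emails are capped at 1 per 72 hours;
up to five CheerSquad members receive milestone notifications.

## Worked example

```r
library(cogtrainr)
catalog <- load_catalog()                                  # 35 exercises, 7 domains
cohort  <- generate_normative_cohort(catalog, n = 100, seed = 42)

scores <- c(logos_verbal_memory = 68, cogstate_identification = 55,
            visual_memory_composite = 52, cbs_grammatical_reasoning = 49,
            cbs_spatial_search = 44, cogstate_one_back = 39,
            cogstate_detection = 33)
profile <- build_baseline_profile(scores, cohort$norms, catalog, "p001")
profile
#> cognitive_profile for p001 at epoch baseline
#>   1. VerbalMemory     z = +0.98  [strength]
#>   2. VisualAttention  z = +0.23  [strength]
#>   3. VisualMemory     z = +0.08  [mid]
#>   4. VerbalExecutive  z = -0.21  [mid]
#>   5. WorkingMemory    z = -0.52  [weakness]
#>   6. VisualExecutive  z = -0.57  [weakness]
#>   7. ProcessingSpeed  z = -1.23  [weakness]
```

The z-scores standardize p001's raw test scores against the simulated
normative cohort; the two highest-ranked domains become this participant's
strengths. The first session then opens with exercises from those strength
domains before moving into medium and hard territory:

```r
plan <- make_session_plan(profile, catalog, session_index = 1, seed = 42)
head(as.data.frame(plan), 8)
#>   slot difficulty   exercise_id          domain
#> 1    1       easy     memo_pair    VerbalMemory
#> 2    2       easy       memobox VisualAttention
#> 3    3     medium     symbolism    VisualMemory
#> 4    4     medium   domino_word VerbalExecutive
#> 5    5     medium      restorer    VisualMemory
#> 6    6       hard alphabet_soup ProcessingSpeed
#> 7    7       hard   color_craze VisualExecutive
#> 8    8       hard  missing_link VisualExecutive
```

`simulate_module()` plays out a complete 30-session module for a virtual
participant — intake, planning, attempts, refreshes, flags, tickets,
throttled emails — and returns the full log. A command-line interface
(`inst/cli/cogtrain`, or `run_cli()` from R) exposes `intake`, `plan`,
`advance`, `simulate` and `report` subcommands over the same functions.

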