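---
title: "Adaptive delivery of multidomain cognitive training: models, rules, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive delivery of multidomain cognitive training}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cogtrainr)
```

## The problem

Home-based computerized cognitive training (CCT) suffers from attrition and
low fidelity compared with supervised, center-based delivery. This package
implements a delivery engine built around three ideas: (1) personalize
*which* exercises a participant trains and *in what order* from a
standardized cognitive profile, so that hard material is cushioned by easy
material; (2) make performance comparable across heterogeneous exercises so
that feedback, adaptation, and monitoring all share one scale; and
(3) replace continuous human supervision with rule-based flags that triage
scarce trainer attention toward the participants who need it.

All components operate on seven cognitive domains; `cognitive_domains()`
returns them in canonical order, which doubles as the deterministic
tie-break order everywhere domains are ranked.

## The cognitive profile

Intake standardizes each baseline assessment score against a normative
reference, $z = (x - \mu)/\sigma$, and aggregates to one $z$ per domain
(averaging when a domain has several assessments; the packaged catalog maps
one assessment score per domain, with the two visual-memory instruments
treated as a single composite). Domains are ranked from highest to lowest
$z$ and partitioned into tiers: ranks 1–2 are strengths, 3–4 mid, 5–7
weaknesses.

The 2/2/3 split is a design choice the delivery rules leave open. We fix it
because (a) the session structure needs three tiers, (b) six easy slots
must be fillable without within-session repetition even when the strengths
are the two smallest domains (3 + 3 = 6 exercises in the packaged catalog),
and (c) seven hard slots are always fillable from any three domains
(minimum 3 + 3 + 4 = 10). Ties in the ranking break by canonical domain
order so that profiles, and everything downstream of them, are
reproducible.

## The sandwich session

A session holds 17 exercise slots: 6 easy, 4 medium, 7 hard. The published
description fixes the opening (two easy, three medium, three hard) and
requires easy material at the beginning, middle, and end; we complete the
under-specified remainder as the single canonical pattern

```
E E M M M H H H E E M H H H H E E
```

which satisfies every stated constraint. Easy slots draw pseudorandomly
from the strength-tier domains' exercises, medium from mid, hard from
weakness, all without within-session repetition — feasible for every
profile with the packaged catalog, and guarded with an explicit scheduling
error otherwise. Selection across sessions is independent draws with no
balancing memory; a round-robin exposure balancer would be a reasonable
alternative but is not implemented.

A module is 30 sessions over 10 weeks. Sessions 1–12 use the baseline
profile; at sessions 13, 19, and 25 the profile refreshes from the
preceding range's training results (below). Sessions cannot be skipped: the
lowest uncompleted session stays allocated until completed or until the
module window closes. We anchor the window at exactly 70 days from the
participant's module start, since the 10-week length is stated but the
anchoring is not. After the module, one booster session per calendar month
is offered for up to three years; booster composition reuses the last
refreshed profile.

## Comparable scores, refresh, and feedback

The engine has one shared scoring primitive: a raw exercise score
standardized against the comparison cohort's per-exercise distribution,
$z_e = (x - \mu_e)/\sigma_e$. The delivery rules require "comparable scores
across exercises" aggregated at the domain level but state no formula;
cohort z-standardization is chosen because it simultaneously serves the
profile refresh (which must judge performance "in comparison to the other
participants"), the feedback board, and the adherence rules, making the
refreshed profile literally a re-ranking of the same quantity participants
see fed back.

**Refresh rule.** At refresh point $r \in \{13, 19, 25\}$, the new domain
$z$ is the mean of the cohort-standardized scores of the participant's own
attempts in the preceding session range (1–12, 13–18, 19–24), aggregated
per domain; domains without attempts in the range carry their previous $z$
forward. Ranking and tiers are recomputed as at baseline. The exact
weighting between cohort-relative level and improvement is not specified by
the source rules; this level-based rule is our documented choice, and it
responds to improvement because later-range attempts reflect practice
gains. We interpret the refresh points as session indices (the session
ranges are the operational statement; the alternative week-based reading
conflicts with three-sessions-per-week arithmetic).

**Feedback target zone.** The feedback board reports, per domain, the
participant's score, the cohort's 75th percentile as the target-zone lower
bound, and an in-zone indicator. Percentile convention: linear-interpolation
quantile (R type 7), with in-zone meaning score ≥ bound. Under this pinned
convention a cohort of $n$ distinct scores always places
$\lfloor 0.25 n \rfloor$ or $\lceil 0.25 n \rceil$ participants in the
zone. Feedback requires at least 20 cohort members per domain (configurable)
so the percentile is not driven by a handful of scores.

## Adherence rules and their boundaries

Performance (red) flags per exercise attempt: more incorrect than correct
responses; zero correct responses; raw score below a predefined
per-exercise level; and a decline of ≥ 10% relative to the previous attempt
of the same exercise across sessions. The predefined level is per-exercise
configuration; its default is 10% of the exercise's maximum attainable
score (10 on the 0–100 native scale used throughout), since no value is
specified. The decrease rule compares raw scores on the exercise's native
scale and its boundary is inclusive: a decline of exactly 10% flags.

Adherence (orange) flags per session: duration strictly greater than
90 minutes, and an inter-session gap of at least 72 hours (the phrasings
"longer than 90 minutes" and "absent for 72 hours" fix the exclusive and
inclusive boundaries respectively). Three orange flags escalate to one red
`adherence_escalation` flag, and the counter resets, so $k$ oranges yield
$\lfloor k/3 \rfloor$ escalations.

Red flags open trainer tickets; orange flags only notify until escalated —
an inference from the rules (tickets are raised by red flags; oranges
escalate at three), recorded as such. The ticket lifecycle is a closed
state machine: open → assigned → resolved, with assigned → assigned
reassignment/handover and idempotent re-assignment to the current owner;
all other transitions error.

Automatic participant emails are capped at 1 per 72 hours, per participant:
an email is emitted only if none was emitted in the preceding 72 hours, so
an email exactly 72 hours after the last is allowed, and sliding windows
are counted half-open, $[t, t+72)$. The cap applies to automatic emails;
help-request acknowledgements are not throttled. Emails are modeled as
events in an outbox log, never sent. CheerSquads hold at most five members,
each notified once per milestone; the milestone set defaults to completing
sessions 1, 10, 20, and 30 (configurable; the source rules leave milestones
undefined).

## The virtual-participant simulator

The simulator stands in for both real participants and the black-box
exercise content. An attempt's latent performance is

$$\theta = a_d + \ell_d\,(k - 1) + \varepsilon,\qquad
  \varepsilon \sim N(0, \sigma^2_\text{noise}),$$

with $a_d$ the latent ability in the exercise's domain (population SD
units), $\ell_d$ a per-attempt learning gain, and $k$ the attempt number.
The within-exercise staircase adaptivity of the real content belongs to the
exercise vendor's black box and is deliberately not modeled; the learning
term abstracts practice effects instead. Latent performance maps to a
bounded 0–100 native score ($50 + 15\theta$, clamped), correct responses
are binomial over 20 trials with success probability
$\mathrm{logit}^{-1}(1.5 + \theta)$ — exercises are tuned so an average
trainee answers about 82% of trials correctly, and the correct fraction
rises with the score — and durations average 150 s per exercise, giving
sessions near the intended 45 minutes.

Defaults are fixed once as realistic study conditions: attempt and test
noise SD 0.5 (test–retest reliability around 0.8); learning rate 0.02 SD
per attempt (a modest practice effect over a 30-session module); session
cadence 56 ± 8 h (three sessions per week), with non-lapse gaps capped just
below the 72-hour absence limit so that lapses are governed solely by
`lapse_prob`; the normative cohort defaults to $n = 100$, mirroring a pilot
cohort of that size. All randomness flows from one root seed through named
substreams (`derive_seed()`), so logs are byte-identical under identical
parameters and seeds, and module simulation composes the real profile,
scheduler, scoring, and adherence code rather than shadow implementations.

What the simulator does not emulate: real psychometrics of the assessment
battery (assessments are abstract Gaussian score sources), exercise-specific
native scales and difficulty staircases, correlated multi-domain loadings
of single exercises, non-Gaussian ability distributions, and time-of-day or
device effects. Passing tests therefore demonstrate the engine's logic and
its statistical conventions, not fidelity to any real trial population.

## Numerical choices and degenerate inputs

Quantiles are type 7; in-zone is ≥ the bound. Ranking ties break by
canonical domain order. Cohort standardization refuses zero-variance
exercise distributions rather than dividing by zero. Refresh with no
attempts in the preceding range is an error (nothing to adapt from), while
individual domains without attempts carry forward. Session plans error if a
tier's pool is smaller than its slot count. State files are versioned JSON
with ISO 8601 UTC timestamps; loading a truncated or version-mismatched
file errors without touching state. Seeds are kept below $2^{31}$.

Problem sizes used by the test suite were chosen to make the statistical
checks sharp at interactive runtimes: the feedback-zone check uses a
simulated cohort of 10,000 (the quartile fraction is then exact to within
±1 point by construction), profile parameter recovery averages Kendall's
$\tau$ over 200 simulated participants with 1-SD-separated abilities, and
flag-boundary checks probe the rules directly, including by bisection.

## Known limitations

The exercise-to-domain mapping is consensus-based and single-label; the
engine inherits that simplification. The refresh weighting and several
operational details (tier sizes, the full slot pattern, milestone sets,
booster composition, the orange-flags-do-not-ticket reading) are documented
choices where the delivery rules are silent; all are centralized in
`engine_config()` and `adherence_config()` so alternatives are one
configuration away. The catalog ships 35 exercises as enumerated by the
published domain table, noting the accompanying prose's count of 34; the
discrepancy is recorded in the catalog header rather than resolved by
guessing.
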