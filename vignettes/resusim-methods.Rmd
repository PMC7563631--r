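---
title: "resusim: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{resusim: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(resusim)
```

## The guidance model

`resusim` encodes a PALS-style pediatric cardiac-arrest decision flow
as a finite-state machine over a *declarative* flow graph: screens
(nodes) hold either an ordered list of sequential action buttons or a
mutually exclusive set of alternative choices, and edges say where each
screen leads. A screen with sequential buttons advances only once every
button has been tapped — the checklist discipline that distinguishes
this class of cognitive aid from a passive algorithm card — while a
choice button advances immediately along its edge. The graph is data
(`inst/extdata/flow_graph.yaml`), not code: validation enforces that
every edge target exists, every node is reachable from the start node,
the advance rule matches the button layout, and that both the
shockable and nonshockable rhythm pathways are tagged.

The bundled graph has a shared entry screen (recognize the arrest, call
for help, start CPR, attach the monitor), a rhythm-choice screen, a
nonshockable branch (resume CPR, vascular access) and a shockable
branch (charge, clear, shock), which re-join on shared epinephrine
preparation/administration screens — preparation deliberately separate
from administration — then reversible causes, airway management, and
back to the rhythm check. An organized rhythm with a pulse exits to
post-resuscitation care.

Assumptions worth stating: the engine models the *team leader's
interaction with the aid*, not patient physiology; a tap means "this
action was read and (we assume) performed"; and the screen contents are
a faithful reconstruction of the described pathways rather than a
pixel-level clone of any particular product.

### Time, timers and priority

Time is injected through `tick(state, dt_s)`; the engine never reads a
wall clock, so identical inputs give identical logs. Two countdowns
matter clinically:

* **Rhythm check**, 120 s, repeating. Each firing logs `TIMER_FIRED`
  plus `ALERT_RAISED`, re-arms the countdown and increments the
  completed-cycle counter whether or not the user responds; unanswered
  alerts persist until acknowledged (selecting a rhythm acknowledges
  them implicitly).
* **Medication**, default 180 s (configurable 180–300 s), armed at the
  first epinephrine administration by default (`start: first_epi`;
  `case_start` is available, since either reading of "countdown for
  medications" is defensible). 180 s is the conservative lower bound of
  the usual 3–5 minute repeat-dosing interval.

Timer-triggered medication actions have priority: the medication timer
carries a lower `priority_rank` than the rhythm check, pending alerts
are kept sorted by rank, and when both countdowns expire at the same
instant the medication alert is raised first. `tick()` processes
firings at their exact instants inside the step, so one large step
fires a repeating timer `floor(dt/period)` times — the
timer-conservation property the tests assert over random tick
partitions. A tolerance of 1e-9 s absorbs floating-point drift when a
partition lands exactly on a firing boundary. The CPR and ROSC
overlays are openable from every screen and never stop timers or move
the underlying node.

### Dosing and energies

All clinical constants live in `inst/extdata/engine_config.yaml`, never
in code: epinephrine 0.01 mg/kg (max 1 mg/dose) at 0.1 mg/mL
(1:10,000), defibrillation 2 J/kg then 4 J/kg (subsequent shocks
4 J/kg), clamped to min(10 J/kg × weight, 360 J), metronome bounds
100–120/min. Dose mass is `min(weight × per_kg, max_total)` — so it is
nondecreasing in weight and constant at the cap — and the
`DOSE_COMPUTED` log entry records both the recommendation and what the
team actually drew up, so the checklist can compare them.

### The event log

Every action appends one `(t_s, event, payload)` entry; entries are
strictly ordered in time with ties broken by insertion order.
Timestamps are canonicalized to 6 decimal places *at creation*, which
makes the JSONL serialization exact: `read_log(export_log(x))` is the
identity and re-exporting is byte-identical. Reading enforces the
ordering invariant and reports the offending line on malformed input.

## The scenario simulator

The simulator models team behaviour at the event-log level only — no
physiology — because every scored quantity downstream is a function of
actions and their times. A scripted agent walks the current screen's
buttons with lognormal latencies (chosen for positivity and the right
skew of human response times; parameterized by median and log-sd),
waits for the 2-minute reminder before re-checking the rhythm,
administers the first epinephrine dose at recognition time plus the
policy's epinephrine latency, and repeats doses when the medication
alert fires. Rhythm transitions come from the scenario's declarative
rules; the default scenario is a 10 kg infant (a reconstruction — the
original scenario script is not published) in asystole for up to
600 s, converting to an organized rhythm with a pulse once two
epinephrine doses have been given and at least 360 s have elapsed.

Study conditions are fixed once in `default_policy()`: 5 control and
11 intervention teams; control epinephrine latency median 165 s
(log-sd 0.25) with fault probabilities 0.2 / 0.2 / 0.4 for incorrect
compression ratio, dose error and reversible-causes omission;
intervention median 254 s (log-sd 0.3) with a 0.18 reversible-causes
omission rate and no ratio/dose faults. These are the observed
arm-level rates of the pilot study the package emulates.

Control teams run against the same flow graph with completion
enforcement relaxed (`advance_node(force = TRUE)` past screens with
omitted actions): taps represent performed actions, not screen
interactions, and the arm label itself never changes an engine rule —
only the policy differs. Per-team seeds derive from the master seed via
a Lehmer-style integer hash (`derive_seed()`), exact in doubles, so
cohorts are reproducible and any team can be regenerated in isolation.

What the simulator does *not* emulate: teamwork and communication
quality, partial/incorrect performance that a video reviewer would
catch but a log cannot show, physiologic feedback, and rater noise.
Passing tests therefore demonstrate correctness of the pipeline on
log-expressible behaviour, not validity against real resuscitations.

## Scoring instruments

The published 16-item deviation checklist and the asystole
clinical-performance section are not reproduced verbatim in the source
text, so the bundled instruments are reconstructions (each item flagged
`reconstructed: true`) built from the named deviations — compression
ratio, epinephrine dose/dilution, reversible causes including
hypovolemia, timeliness — padded with standard resuscitation criteria.
Two structural properties drove the design: each of the 16 items is
anchored on a *distinct* log event, so (a) a log with every required
action absent scores the full 16 and (b) for every item there is a
single fault that fails exactly that item (the bijection the tests
check). Timeliness windows (e.g. first epinephrine within 300 s of
recognition, recognition within 60 s) are configuration values in the
instrument files, never code literals. Performance tasks score 0 when
absent, full credit (2, or 1 for the reassessment task) when all
criteria hold, and full-minus-one when present but late or incorrect;
the bundled totals are 0–16 and 0–13.

Recognition of cardiac arrest is an explicit log marker (the
recognition tap) rather than something inferred; time to epinephrine is
the first administration tap minus that marker, absent when the drug
was never given, and an error if the ordering is impossible.

## Questionnaire scoring

UEQ: 26 items on −3..+3 partitioned into six scales; a respondent's
scale score is the mean of polarity-adjusted items. The bundled scale
map ships with all polarities +1 — the convention that responses are
already recoded to "higher is better", as in the instrument's analysis
sheet — while the scorer fully supports −1 flags for raw
direction-alternating data. Cohort summaries use the sample (n−1) SD
and the normal interval mean ± 1.96·sd/√n; the normal multiplier (not
a t quantile) is deliberate, because with n = 11 respondents it exactly
reproduces the published usability table's intervals, which is also the
arithmetic evidence that the respondents were the 11 intervention team
leaders. Cronbach's α uses the standard coefficient-alpha formula and
is reported as `NA` (never NaN) when the total score has zero
variance. Scale scores above 0.8 are a positive evaluation, below −0.8
negative, the closed band between them neutral.

NASA RTLX: the overall workload is the plain average of six 0–100
subscales on a 5-point grid (off-grid values are rejected), banded
low (<40), moderate (40–60, inclusive at both ends — "between 40 and
60" is read inclusively), high (>60).

The questionnaire generator draws a respondent-level latent scale score
from a truncated normal, adds item-level noise (default item sd = half
the scale sd, so zero scale sd collapses every item to the mean), and
discretizes onto the instrument grid. The latent-plus-noise structure
gives scales a realistic positive internal consistency; discretization
biases means by at most a few hundredths, which the recovery tests
allow for.

## Group comparisons

The exact Mann–Whitney test enumerates all `choose(n+m, n)` assignments
of the pooled mid-ranks (ties handled exactly) and defines the
two-sided p-value as the total probability of splits whose U lies at
least as far from the null mean `nm/2` as observed — a symmetric-
distance rule that reduces to tail-doubling for tie-free data. Exact
mode is used up to a combined n of 20 (≤ 184 756 splits); beyond that
the normal approximation with tie-corrected variance and a 0.5
continuity correction takes over. Fisher's 2×2 test sums hypergeometric
probabilities of tables "as or less probable" than the observed one
(relative tolerance 1e-7 for ties in probability), which reproduces the
published two-sided values.

Report tables show categorical variables as `count (percent)` with
percentages rounded half-up to integers, compared by Fisher's exact
test when any expected cell is below 5 and chi-squared otherwise (the
test used is labelled per row, since the source analysis did not state
the per-variable choice); continuous variables appear as
`median (Q1–Q3)` using Tukey hinges — a convention chosen and
documented here because none was stated — with Mann–Whitney p-values.
No multiplicity correction is applied, matching the original analysis.
Single-arm input yields summaries without p-values plus a warning.

## Problem sizes and numerical choices

The parameter-recovery check simulates 200 teams per latency setting
(medians 254 s and 165 s) and verifies that the scored median time to
epinephrine falls inside a 2000-replicate bootstrap 95% interval of the
sample median — sizes chosen to make the check sharp while keeping the
whole suite comfortably fast on one core. Observed study medians
(time-to-epinephrine 254/165 s, RTLX 67.5/66.7, deviation total 6,
performance total 9) derive from participant-level data that was never
published; they serve here only as simulator parameter settings and
formatting fixtures, not as quantities the package claims to
reproduce.

Other numerical conventions: timestamps canonicalized to 6 decimals
(exact JSONL round trips); timer boundary tolerance 1e-9 s;
simultaneous timer expiry broken by priority rank (medication first);
log ties broken by insertion order; untagged toy graphs are exempt from
the two-pathway tag requirement so a single-node graph validates.

## Known limitations

* The flow graph and instruments are reconstructions, suitable for
  methodological work, not clinical deployment.
* Checklist predicates see only the log: quality-of-performance
  deviations (e.g. compression depth) are out of reach by design.
* The engine is single-session and purely functional; there is no
  concurrency or persistence layer.
* The exact Mann–Whitney enumerator is O(choose(n+m, n)) and
  intentionally refuses combined samples above 20.
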