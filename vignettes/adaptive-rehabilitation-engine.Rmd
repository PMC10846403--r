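---
title: "An adaptive cognitive rehabilitation engine: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An adaptive cognitive rehabilitation engine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cogrehab)
```

`cogrehab` implements the computational core of an adaptive
neurorehabilitation workflow: profile a patient from a heterogeneous
neuropsychological battery, select and parameterize training tasks, keep
in-session difficulty inside a challenge band, and revise the profile by
minimal change after every session. This vignette explains each model, the
parameters that matter, and the choices we made where the design was
genuinely open.

## Profiles and the constraint language

A profile is an ordered tuple of per-domain values. Formal treatments of
profile dynamics take values in the naturals; training scales in the field,
however, run 1–10 in half steps. We reconcile the two by attaching an
explicit `(min, max, step)` grid to every label (`profile_schema()`), with
integer steps as the default. Atom constants are consequently allowed to be
non-integers — 7.5 is a legitimate boundary on a half-step scale.

The language over profiles has terms (labels, unary minus, sums), atoms
comparing a term to a constant, and the classical connectives. Since no
authoritative surface syntax exists, the package fixes an ASCII one (`&`,
`|`, `!`, `->`, `<->`, `>=`, `<=`) and desugars derived connectives to
negation and conjunction at parse time; `<=`/`>=` are kept as primitive
comparators with their obvious semantics, which the test suite checks
against their negation-based definitions. Categorical labels ("single /
married / …") are mapped to grid integers at schema construction; the
semantics never sees them.

Model enumeration walks the full Cartesian product of the label grids and is
guarded by a configurable cap (default 250 000 grid points) — the language is
only ever evaluated over small training schemas, and an explicit
state-space error beats a silent multi-minute enumeration.

Profile distance is weighted L1, `sum(w_i * |p_i - q_i|)`. An L1 form makes
per-domain moves additive, which is what the one-step revision semantics
below needs; the test suite property-checks nonnegativity, symmetry and the
triangle inequality.

## Building the assessed profile

Every instrument subscore is min–max normalized to 0–100 from its published
bounds — the only normalization the field's simplified scoring scheme
instantiates, so we use it uniformly. Reverse-scored instruments
(depression inventories, functional-incapacity and rating scales where
higher raw scores mean worse functioning) carry a `higher_is_better = FALSE`
flag in the registry and are flipped at normalization; without this the
weighted aggregation would mix directions incoherently.

The domain weight table ships verbatim as raw percentages and is
renormalized at load so each domain's weights sum to 1. Two printed
renormalized percentages in the source table are rounding artifacts (a
half-case rounded down, and a row forced to sum to exactly 100); the package
reports the arithmetically correct fractions and the tests document the two
cells explicitly.

Missing data follow one rule: renormalize over the subscores that are
present. A domain with no scorable entry is reported absent — never imputed,
never zeroed. The cognitive-status step inherits the same rule: the
SDI-expected score for a domain is computed over the instruments that
actually contributed to that domain's ACP.

Cognitive status anchors the ACP against normative strata selected by the
patient's age and education bands. The default backend implements the
cross-multiplication rule `CS_k = 100 * ACP_k / (2 * expected_k)` so that a
patient exactly at the group average scores 50; we clip to [0, 100] because
the rule is otherwise unbounded for patients far above average. The exact
percentile semantics of the normative comparison is underdetermined, so a
second backend (`method = "zscore"`) reports the normal percentile of the
ACP within the stratum, with the stratum sd pooled on the normalized scale;
the mean-anchored rule is the default. The shipped normative table is
synthetic (and labelled as such in its filename and header): it has the
right stratified structure for the method, but its means and sds are
plausible values, not published population norms.

## Task selection and parameterization

Each training task model declares coverage ranges on the CS axis, training
weights, ADL contexts, parameter bounds and a nominal duration. The
selection distance is a per-domain variant of a Hamming distance computed on
a 0–10 axis (CS/10): 0 inside the covered range, the gap to the nearest
endpoint outside it, and 10 — the stated maximum — when the domain is not
covered at all. Whether near-miss gaps should also be capped at 10 is
ambiguous; we cap both, which only matters for pathological ranges. How
per-domain distances combine is likewise unstated; we use a
priority-weighted sum over the objective's target domains, which keeps the
ranking a single comparable score and is overridable by supplying different
priorities. Ties break by lexicographic task id so plans are deterministic.

Context filtering keeps tasks whose contexts intersect the preferred ADLs
(an empty preference set is a no-op) and truncates to the session budget
using each task's nominal duration, defaulting to 11 minutes — the only play
duration reported for this family of tasks — and configurable per task.

Initial difficulty for a task is the training-weight-weighted mean of the
profile values over its trained domains, snapped to the half-step grid.
Parameters interpolate their bounds linearly at `(d - 1) / 9`: the scale
minimum 1 must map to the parameter minimum (a floor-ability patient gets
the 2-step sequencing task, not a harder one) and 10 to the maximum, which
an interpolation at `d / 10` cannot satisfy. Count-valued bounds round to
integers; `initial_parameters()` output always passes
`validate_task_parameters()`, which additionally enforces the per-kind hard
limits (search: 1–12 targets, ≤20 elements per section, ≤8 sections;
sequencing: 2–12 steps; categorization: 2–60 items, ≤4 containers).

## The difficulty controller

The controller is a one-step threshold rule per task: performance below the
low threshold drops difficulty by 0.5, above the high threshold raises it by
0.5, otherwise it holds. The published descriptions of the band disagree
slightly on its edges (50–70 vs 51–70 vs >71); we resolve them with strict
inequalities at both ends and defaults low = 50, high = 71, which reproduces
every printed example and decides the edge values deterministically. Both
thresholds are clinician-configurable, and the narrower the band the more
the difficulty fluctuates. The flow target often quoted as 50–70% and the
50/71 controller thresholds are kept as separate configurable values rather
than conflated. Saturation at the grid bounds (difficulty 1 and 10) is our
addition — the sources never discuss it, and clamping is the only behaviour
that keeps the trajectory on the grid.

Adaptation is per task within a session — the stated refinement over older
session-global designs — with `per_task = FALSE` available as a legacy mode
that adapts a single shared difficulty from the running session mean.

## Profile revision

After a session, per-domain performance is aggregated as the
training-weight-weighted mean over the plays of tasks training that domain
(how much each of several tasks should move a shared domain is unspecified;
weighting by training weight before thresholding is the least-surprising
choice). The sentence builder then emits one atom per trained domain:
`domain > v` above the high threshold, `domain < v` below the low one,
`domain = v` inside the band. Strict atoms make the minimal-change revision
move exactly one grid step, consistent with the worked 7 → 7.5 example; a
domain already at a grid bound that cannot move further emits an equality
instead of an unsatisfiable atom. Alternative builders can be swapped in by
constructing any sentence of the language.

Revision itself minimizes L1 distance over the grid models of the sentence.
Ties in distance prefer the candidate whose change concentrates on the
domains with the higher tiebreak weight (the session's combined training
weights), compared lexicographically over domains in descending weight
order; remaining ties take the lexicographically smallest value vector, so
revision is a function, not a relation. Pure conjunctions of single-label
atoms — the sentences the default builder produces — are revised
coordinate-wise, each label moving to its nearest feasible grid value; this
is provably equivalent to the exhaustive search on that fragment and is
property-tested against an independent full-grid oracle. Unsatisfiable
sentences raise an explicit inconsistency error rather than clamping. The
intermediary profile fed to the next session and the predicted profile
compared against the next assessment are treated as the same object.

Divergence between predicted and assessed profiles is reported
descriptively: signed per-domain differences, the aggregate weighted
distance, and flags above a configurable threshold (default 0.5, one half
step). Attribution of divergence to its causes is out of scope.

## The synthetic patient

The simulator exists so the whole loop is testable without clinical data; it
makes no claim to cognitive-science fidelity. A patient has latent
per-domain abilities on 0–100, and performance on a task follows a logistic
curve in the gap between effective ability (training-weight-weighted mean
ability, rescaled to the 1–10 difficulty axis) and task difficulty:
`100 * plogis(slope * (ability10 - difficulty))` plus Gaussian noise,
clipped to [0, 100]. The logistic is the simplest monotone mechanism with
the 50% midpoint the controller's band assumes; defaults are slope 1 and
noise sd 5 percentage points, chosen so that one half-step of difficulty
moves expected performance by roughly 12 points — large enough for the
controller to matter, small enough that the band is attainable. Severity
presets draw abilities uniformly from mild 50–85, moderate 30–65, severe
10–45. Training effects add `learning_rate` ability points per play
training a domain, capped at 100, with a stationary default
(`learning_rate = 0`).

All randomness flows through an explicitly seeded generator
(`run_program(seed = )`, `generate_patient(seed = )`); nothing depends on
ambient RNG state, and fixed seeds give byte-identical session logs.

What the simulator does *not* emulate: fatigue and day-to-day variability,
domain interactions (each ability is independent), floor/ceiling artifacts
of real instruments, or non-monotone responses to difficulty. Tests passing
against it show the engine's control and revision logic is coherent — not
that real patients behave this way.

## Problem sizes and numerical choices

The test suite exercises revision equivalence on randomly drawn schemas of
up to 3 labels and 21 grid points per label (the exhaustive oracle stays
below ~1500 grid profiles per case, a hundred cases in seconds), and the
closed loop on 20 synthetic patients at 12 sessions of 4 plays — the session
count of the intended one-month program — which recovers the rank order of
latent abilities (Spearman ≥ 0.8, pooled over patients) and beats a
fixed-difficulty baseline on time-in-band over 200 plays. Equality
comparisons on grid values use a 1e-9 tolerance throughout; half-step
snapping uses round-half-even via `round()`, and the state-space cap
defaults to 250 000 grid points.

## Known limitations

The engine treats the weight table as ground truth; recalibrating weights
from accumulating patient data is explicitly out of scope, as are the
training tasks' interactive content, emotional-profile inputs, and any
machine-learned attribution of predicted-vs-assessed divergence. The
shipped normative table is synthetic; real deployments must supply
population norms in the same stratified format. Sentences beyond
conjunctions over a few labels fall back to exhaustive enumeration, which
the cap bounds but does not make fast.
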