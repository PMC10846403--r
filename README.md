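# cogrehab

Adaptive cognitive rehabilitation asks for a closed loop: assess a patient's
cognition with a battery of neuropsychological tests, pick the training tasks
that target the impaired domains, keep each task's difficulty in a challenge
band during the session, and carry what the session revealed back into the
patient's cognitive profile before the next one. `cogrehab` implements that
loop as a reusable R engine for computational neuropsychology: clinicians and
methods researchers can drive it from real score files and session logs, or
run it end to end against a built-in synthetic-patient simulator.

## The model

**Profiles and the profile language.** A cognitive profile is a tuple
⟪v₁, …, vₙ⟫ of per-domain values on finite grids (integers by default, the
half-step 1–10 scale for training profiles). Constraints over profiles are
sentences of a small propositional language — atoms compare terms (labels,
negation, sums) against constants with `=`, `<`, `>`, `<=`, `>=`, combined
with `!`, `&`, `|`, `->`, `<->` — with classical semantics, bounded model
enumeration, and a weighted L1 distance d(p, q) = Σᵢ wᵢ·|pᵢ − qᵢ|.

**Assessed Cognitive Profile (ACP).** Raw test subscores are min–max
normalized to 0–100 and aggregated per domain k as

    ACP_k = Σ_ij Norm(score_ij) · W_kij,

where the weights `W` come from an expert consensus table shipped with the
package (raw percentages stored verbatim, renormalized within each domain to
sum to 1 — and renormalized again over whatever subscores are actually
available, so missing data shrink the basis instead of zeroing a domain).

**Cognitive Status (CS).** The ACP is anchored against demographically
stratified normative data: with expected_k the weighted normalized stratum
mean, CS_k = 100 · ACP_k / (2 · expected_k), clipped to [0, 100], so a
patient at the group average sits at the 50th-percentile anchor. A
normal-percentile backend (`method = "zscore"`) is available behind the same
interface.

**Task selection.** Each cognitive training task (CTT) carries a model:
coverage ranges on the CS axis, training weights over domains, ADL contexts,
and difficulty-parameter bounds. Tasks are ranked by a per-domain coverage
distance on a 0–10 axis (0 in range, gap to the nearest endpoint otherwise,
10 when uncovered), summed with objective priorities, then filtered by
context and session budget, and parameterized by interpolating each
parameter's bounds along the profile-derived difficulty.

**In-session adaptation.** Performance below 50% lowers a task's difficulty
by 0.5 points, above 71% raises it by 0.5, in between it holds (thresholds
configurable); medals reward performance bands (≥50 copper, >70 silver,
>90 gold) and hints halve the points.

**Profile revision.** A session is summarized into a sentence of the profile
language — per trained domain, `domain > v` above the band, `domain < v`
below it, `domain = v` inside — and the profile is revised by *minimal
change*: among the grid profiles satisfying the sentence, the one closest in
L1 distance to the current profile, ties broken toward the domains the
session trained hardest. A patient holding memory 7/10 who outperforms the
band therefore moves to exactly 7.5/10.

## Worked example

```r
library(cogrehab)

sc <- npa_scores("demo-01", data.frame(
  instrument = c("MoCA", "WAIS_III", "FCSRT", "FCSRT", "ToulousePieron"),
  subscore   = c("total", "digit_symbol_coding", "immediate_memory",
                 "delayed_recall", "total"),
  raw        = c(21, 38, 22, 8, 13)),
  sdi = list(age_band = "65-80", education_band = "5-12"))

sp <- compute_simple_profile(sc)   # five macro-domains on 0-10
tp <- as_training_profile(sp)      # snapped to the half-step 1-10 grid

ob <- training_objective(c(attention = 1, memory = 1, executive_functions = 1),
                         contexts = c("kitchen", "supermarket"))
ranked <- filter_by_context(rank_ctts(sp$values * 10, ob, read_ctt_repo()), ob)
task <- attr(ranked, "models")[[1]]

patient <- generate_patient(42, names(sp$values),
                            abilities = pmin(100, sp$values * 10 + 15))
plan <- data.frame(task_id = task$id,
                   difficulty = attr(initial_parameters(task, tp), "difficulty"))
rec <- run_session(plan[rep(1, 4), ],
                   function(tid, d, i) simulate_task_performance(patient, task, d))
sent <- summarize_to_sentence(rec, list(task), tp)
revise_profile(tp, sent, tiebreak_weights = task$training_weights)
```

With the full battery of the shipped registry this prints (abridged):

```
<simple_profile> patient demo-01 (0-10 scale)
  general_cognition         7.00
  memory                    4.21
  executive_functions       3.84
  attention                 3.23
  play            task_id difficulty performance  medal
1    1 search_kitchen        3.5    85.27130 silver
2    2 search_kitchen        4.0    68.33967 copper
3    3 search_kitchen        4.0    79.85118 silver
4    4 search_kitchen        4.5    64.79335 copper
sentence: ((attention > 3 & memory > 4) & executive_functions > 4)
<predicted_profile> moved 1.5 under "((attention > 3 & memory > 4) & executive_functions > 4)"
  ≪7, 4.5, 4.5, 4, 3.5≫
```

The screening-dominant profile sits around 4/10, the cancellation task in the
kitchen context is the best coverage match (selection score 0), its
difficulty starts at 3.5 on the 1–10 scale, the controller nudges it up as
the simulated patient outperforms, and the revision moves each trained
domain up by exactly one half-step.

A command-line interface wraps the same functions
(`exec/cogrehab profile|plan|run|compare`), reading and writing JSON
documents and CSV session logs with embedded seed and config hash.

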