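---
title: "Modeling predictive uncertainty in melodic expectation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling predictive uncertainty in melodic expectation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(melent)
```

## The model and its assumptions

`melent` treats melodic expectation as sequential probabilistic
prediction. For each note position the model produces a conditional
distribution over a pitch alphabet given the preceding notes; the
distribution's Shannon entropy is the model's predictive uncertainty
before the note, and the realized note's information content
(−log₂ p) is its unexpectedness. The core assumptions are:

- **Statistical learning.** Expectations reflect n-gram statistics
  internalized from exposure, nothing more. The long-term sub-model
  (LTM) is trained once on a corpus; the short-term sub-model (STM)
  starts empty for each melody and learns incrementally, capturing
  within-piece repetition. When both are active their distributions are
  merged with an entropy-weighted geometric mean.
- **Derived viewpoints.** Notes are encoded as linked symbols of pitch
  interval and chromatic scale degree (optionally extended by
  inter-onset-interval contour for rhythmic material). This buys
  transposition invariance: a melody and its transposition produce
  identical symbol sequences when the key moves with it. The first note
  of a melody has no interval, so it is encoded (and predicted) by scale
  degree alone; at prediction time, candidate pitches sharing a degree
  split that degree's probability equally.
- **No zero probabilities.** Smoothing terminates in a uniform
  1/|alphabet| floor, so IC and H are always finite, as the
  information-theoretic definitions require.

## Smoothing and the variable-order strategy

Counts are stored for every context length up to the order bound. A
prediction blends maximum-likelihood estimates at the longest usable
context with escape mass passed to successively shorter contexts
(interpolated smoothing; a strict backoff variant is available). The
escape estimator is method C by default — escape mass t/(N+t) for N
observations of t distinct symbols — with methods A, B and D selectable.
Update exclusion is on by default: during training, a count stops
propagating to shorter contexts once the symbol has already been seen at
a longer one.

For the `"variable"` order bound, the starting context is chosen
PPM*-style: the *shortest deterministic* matching context (one whose
continuation set has a single member), falling back to the longest
matching context when no deterministic one exists. We adopted this rule
after finding that naive longest-match selection is overconfident —
count-1 deep contexts dominate the blend and held-out log-probability on
first-order synthetic chains fell below even the order-0 model, while
the shortest-deterministic rule restores the expected ordering (variable
at least as good as low fixed orders). The unit tests pin the whole
recursion, including this selection rule, to an independently written
brute-force oracle at 1e-12.

Two numerical guards matter: normalized entropy is floored at 1e-6 when
used as a combination weight (a point-mass sub-model would otherwise get
infinite weight), and Fisher's z clamps |r| to 1 − 1e-16 (|z| ≈ 18.7)
so perfect simulated correlations stay finite.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `order_bound` | `"variable"` | Max context length in notes (0–4 or PPM*) |
| `configuration` | `"both"` | LTM, STM, or both combined |
| `escape_method` | `"c"` | PPM escape estimator |
| `smoothing` | `"interpolated"` | Blend vs. strict backoff |
| `update_exclusion` | `TRUE` | Count propagation rule in training |
| `bias` b | 1 | Entropy-weighting exponent in the combination |
| `include_ioi_contour` | `FALSE` | Third linked viewpoint for rhythm |
| `alphabet_policy` | `"corpus"` | Observed pitches vs. chromatic fill |

The combination bias and escape configuration are exposed because no
single published value fits every corpus; the defaults follow the
configuration the n-gram modeling literature reports as strongest
(escape C, interpolated, update exclusion). All parameters are recorded
in output provenance.

## Stimulus selection

The two-stage procedure mirrors a probe-tone design: (1) score every
corpus note by the entropy of its full-alphabet predictive distribution
and keep the k highest- and k lowest-entropy notes per style (default
k = 18, giving 72 candidates over two styles); (2) segment a candidate
context for each — the shortest prefix starting at a phrase boundary
with ≥ 1 complete phrase, ≥ 8 notes and ≥ 4 distinct pitches (targets
with fewer than 8 preceding notes are skipped up front, since no prefix
could qualify); (3) assign nine chromatically consecutive probe tones
centered on the context's median pitch (even-length medians round half
*down*; the window shifts minimally to include the true continuation);
(4) re-rank candidates by the entropy of the distribution renormalized
over the nine probes — now using the key *estimated from the context
itself* rather than the notated key, to approximate the key actually
induced in a listener — and keep the per-cell extremes, skipping
candidates whose note span overlaps an already selected stimulus from
the same melody. Defaults give 24 stimuli: 6 per style × entropy-class
cell. Where the procedure was underdetermined (median rounding, the
displacement rule, how 72 candidates reduce to 24), we fixed the
simplest deterministic rule and state it here; selection is bit-identical
across runs.

## Key finding

Key estimation correlates the duration-weighted pitch-class distribution
against all 24 rotated key profiles and takes the argmax, with a
deterministic tie-break (lowest tonic, major first). Both the
Krumhansl–Kessler probe-tone profiles and Temperley's modified profiles
ship in `inst/extdata/key_profiles.json` with provenance strings;
Temperley's values are the default for the selection stage. A
count-weighted variant is available.

## The rule-based baseline

The Implication–Realization regression uses three per-probe predictors:
proximity (12 − min(distance, 12)), pitch reversal (direction component
in {+1, 0, −1} gated at 6 semitones, plus a 1.5-point returning-proximity
bonus within 2 semitones of the implicative origin), and tonal hierarchy
(the key-profile value of the probe's degree). The exact constants are
collected in `ir_constants()` and overridable, since published
quantifications differ in detail; the tests pin the default coding to an
independent transcription of the rule table. Predictors enter an OLS
regression on participant-averaged ratings; the multiple correlation R
is the comparison statistic.

## Simulated listeners

The synthetic-data module generates (a) melodic corpora from first-order
Markov grammars with controllable conditional entropy — transition
weight decays exponentially with semitone distance, scaled by the key
profile and mixed with a uniform component — in two styles (isochronous
"simple", C4–F5; rhythmic "complex", A3–A5 with a wider uniform mix so
its entropy is higher); and (b) listeners whose unexpectedness ratings
are clip(round(affine(IC + noise))) on the 9-point scale, with the
affine map calibrated so the 5th/95th IC percentiles of the stimulus set
land on the scale ends (the instruction to "use the full range"), plus a
2% lapse rate. Expertise is operationalized purely as noise magnitude
(musicians 1 bit, non-musicians 2.5 bits by default): a lower-noise
rater tracks the generating model more faithfully, which is the
mechanism behind the expertise effects the analysis recovers. Explicit
uncertainty ratings are generated the same way from per-context entropy.

What the generator does *not* emulate: veridical familiarity and memory
for specific melodies (familiarity is uniformly false), closure and
phrase-final lengthening, rhythm-driven expectation, response times, and
any dependence of listener noise on the stimulus itself. Passing tests
therefore show that the analysis pipeline recovers known structure from
data *generated under the model's own assumptions* — they do not certify
the model against human listeners.

## Behavioral analysis

Inferred uncertainty is the normalized entropy of a participant's nine
normalized probe ratings per context (raw orientation by default; the
reversed, expectedness-weighted variant is provided and both are worth
reporting when they disagree). Explicit-uncertainty values from contexts
marked familiar are dropped cell-wise. Per dependent variable the
pipeline computes participant × condition means, excludes participants
by the 1.5 × IQR fence rule (strictly outside the fences, per condition,
values exactly on a fence retained), runs the classical mixed 2×2×2
ANOVA (`aov` with an `Error(participant/(complexity*entropy))` stratum)
on the retained set, and the Conover–Iman rank-transform ANOVA on the
full set as a non-parametric check. Reliability uses Cronbach's α with
participants as items and stimuli as cases. Per-participant model fits
are Pearson correlations, Fisher-z transformed for aggregation; Williams'
t compares dependent correlations sharing a variable; Welch, pooled-t and
χ² (no continuity correction) handle the demographics. p-values are
two-tailed with no multiplicity correction. The model-comparison grid
crosses order bounds {0–4, variable} with configurations {STM, LTM,
both}, correlating (Spearman) entropy with uncertainty measures and IC
with mean unexpectedness, per group and overall, alongside Schmuckler
difference scores (both the IC and the probability variant are
implemented, as the two appear in different places in the literature)
and the IR regression.

## Problem sizes and determinism

Default study conditions mirror the emulated design: 24 stimuli (6 per
cell), 9 probes, 17 simulated participants per group; the acceptance
analyses use 20 per group. Training corpora default to 40 melodies × 40
notes per style and stimulus corpora to 25 × 32, which we find ample for
stable selection; the unit-test fixtures are smaller (10–12 melodies,
3 per cell) to keep the suite fast, and the replicate-recovery property
uses 40 rating re-simulations on a fixed stimulus set. Chain-recovery
checks train on 10⁴ events from a 5-state grammar, where the analytic
stationary-averaged conditional entropy is matched within 0.05 bits and
KL to the generator rows decreases with training size. A single
top-level seed expands into fixed per-stage streams; every table the
pipeline writes is byte-identical across re-runs with the same config.

## Known limitations

- The model predicts pitch only; duration and onset are carried but not
  predicted, and the IOI-contour viewpoint is a single config switch
  rather than a general viewpoint system.
- Phrase boundaries in plain MIDI input are inferred from rest gaps
  (≥ 1 beat by default), a stand-in for explicit phrase encodings.
- Key finding is whole-segment; no modulation tracking.
- The mixed ANOVA requires a complete, balanced within-design per
  participant (as the emulated paradigm guarantees).
- Human-data correlation magnitudes are out of scope by design: the
  simulated-listener results validate the machinery, not the cognitive
  claim.
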