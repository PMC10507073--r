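---
title: "Predicting unplanned ICU readmission: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting unplanned ICU readmission: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the scientific choices behind ReadmitTA: the
cohort definition, the temporal-abstraction model, the sequence
classifier and training protocol, the synthetic-data generator used to
validate everything, and the places where the design was genuinely open
and a choice had to be made.

## Cohort definition

An index ICU stay enters the unplanned-readmission cohort when all of
the following hold, applied as conjunctive filters (the surviving set is
invariant to their order; the filter report records the counts in the
order below):

1. the patient is 18 or older at ICU admission (ages computed above 89
   are capped at 90, following the de-identification convention of
   age-shifted critical-care databases);
2. the ICU length of stay is between 1 and 30 days;
3. every one of the 12 laboratory concepts has at least one measurement
   and every one of the 5 chart concepts at least five, inside
   `[intime, outtime]`;
4. no death timestamp falls during the stay or within 30 days of
   hospital discharge.

The label is 1 iff another ICU stay of the same patient begins within
30 days after the index stay's *hospital* discharge. Three conventions
were open and are fixed as follows. The 30-day window is measured as
elapsed time (30 × 24 h) with an **inclusive** boundary: a gap of
exactly 30.0 days counts as a readmission. The death exclusion is
anchored on hospital discharge, matching the label's anchor. "First
stay per year" is implemented as a **rolling 365-day exclusion** — a
stay is kept only if no kept stay of the same patient began in the
preceding 365 days — rather than a calendar-year rule, since the
motivation is excluding recently hospitalized patients, not calendar
bookkeeping. A consequence is that later ICU stays inside the same
hospital admission are never index candidates but still count as
readmission targets.

Folds are assigned to *patients*, never stays, so no patient
contributes to both sides of a split; assignment is round-robin over a
shuffled ordering within each label stratum, which bounds the per-fold
positive count to within one of the proportional share. The validation
set is a stratified 12.5% of each fold's training patients — the
protocol needs a validation stream and this size keeps roughly 70/10/20
proportions. With five folds, the ±2-percentage-point stratification
guarantee is granularity-limited: it holds once cohorts have roughly
250+ patients, which is the scale the property suite exercises.

## Temporal abstraction

State abstraction maps each raw value to the state whose half-open
interval `[min, max)` contains it; intervals are lower-inclusive, which
matches the below/within/above phrasing of clinical guidelines and
fixes the boundary convention once. The bundled knowledge base defines
three states per concept (below / within / above the normal range) with
named exceptions — Hypothermia/Normal/Fever for body temperature,
Severe/Moderate/Mild for the Glasgow Coma Scale — and accepts up to six
states per concept from user-supplied files. The chloride normal range
is encoded 96–106 mEq/L.

Gradient abstraction labels each consecutive pair of observations
Increasing, Decreasing or Stable. The default `simple` mode is the pure
sign rule: it is invariant to adding a constant to the series and
equivariant under negation, properties the test suite checks. The
knowledge base also tabulates a per-concept significance threshold Δ
and a stable-trend window in hours that the sign rule itself does not
use; rather than guess how they were meant to combine, the package
exposes a second, `thresholded` mode — Stable whenever |Δx| ≤ Δ and the
gap is within the window — and keeps `simple` the default. Gradients
are defined from the second observation on (n − 1 symbols for n
observations); the first observation has no predecessor, so no symbol.

Temporal-linear interpolation aligns the 17 concepts on the union of
their observation timestamps. The implementation uses the standard
convention in which the *near* neighbour receives the large weight:

\[
x_i^{(\tau_t)} \;=\; x_i^{(\tau_{t-1})}\,
  \frac{\tau_{t+1}-\tau_t}{\tau_{t+1}-\tau_{t-1}}
  \;+\; x_i^{(\tau_{t+1})}\,
  \frac{\tau_t-\tau_{t-1}}{\tau_{t+1}-\tau_{t-1}},
\]

which is continuous at observed points (the far-neighbour-weighted
variant is not, and reproduces the observations only at exact grid
hits). Outside a concept's first/last observation the nearest observed
value is carried, so no grid row is dropped. The suite checks the
implementation against an independent two-point line-equation oracle to
1e-9 on a thousand random series.

Flattening merges all state (and optionally gradient) events into one
temporally ordered sequence of concept-qualified symbols
(`heart_rate:Tachycardia`, `wbc:Increasing`); ties at identical
timestamps break by knowledge-base concept order, states before
gradients. The vocabulary is enumerated from the knowledge base alone
(every concept × state plus gradients plus one pad symbol), so D is
identical across folds and runs and nothing leaks from test data.
Sequences longer than L are truncated from the *start* — the most
recent clinical trajectory is the informative part for a prediction
made at discharge — and padded at the end otherwise.

## Models

The sequence classifier embeds tokens into `floor(D^(1/4))` dimensions,
runs one GRU forward and one over the time-reversed sequence,
concatenates their per-timestep outputs, and pools with attention: a
single learned projection scores each timestep, a softmax over valid
(non-pad) positions normalizes the scores, and the output is the
weighted sum — a fixed-size vector. A pooled output (rather than a
weighted sequence) is forced by the affine classification layer that
follows. An all-pad sample falls back to uniform weights, so the model
is total. The optional extra-modality vector (demographics one-hot)
joins at the pre-classifier concatenation, consistent with how fusion
attaches additional modalities; per-timestep injection was considered
and rejected as redundant copies. Hidden width defaults to 64 per
direction; experiments here use 16, which is ample at synthetic scale.

Forward and backward passes are hand-implemented with vectorized matrix
algebra (no deep-learning framework is required); backpropagation is
verified against central-difference numerical gradients, and the
bidirectional symmetry (reversing the input and swapping the two GRUs'
parameters mirrors the pre-attention representation in time with the
direction blocks exchanged) is asserted as an architecture check.

Multimodal fusion concatenates each component's pre-classifier vector —
a sequence model's post-attention vector (2 × hidden), a text scorer's
aggregated probability as a 1-vector, a passthrough block such as the
demographics one-hot — and trains a single affine head jointly with all
trainable components. The tabular baseline is a seeded random forest on
the concatenated ICD-9 one-hot and demographics one-hot.

The text pathway defines a scorer contract (`scoreChunks`: note chunks
to probabilities in [0, 1], fine-tunable on labeled chunks). The
bundled reference implementation is a neural bag-of-words (mean-pooled
token embedding and logistic head): small enough to fine-tune at desk
scale while exercising the full chunking / fine-tuning / aggregation
path; a pretrained clinical encoder can be dropped in behind the same
contract. Notes are cleaned (lower-casing, removal of bracketed
de-identification placeholders, whitespace collapsing; digits kept),
tokenized by an injected tokenizer (tests use whitespace tokens), and
split into greedy fixed-length chunks — 318 content tokens by default,
leaving room for special tokens under a 512-token encoder limit. Chunk
probabilities combine as `(P_max + P_mean · n/2) / (1 + n/2)`, which
provably lies between the chunk mean and maximum; at training time each
chunk inherits its note's label.

## Training protocol

Binary cross-entropy is minimized with Adam (standard moments) in
batches of 64. Every 200 steps (50 in the scaled-down experiments
below) the validation AUPRC is computed — AUPRC rather than AUROC
because the positive class is rare (~11%) and the precision-recall
curve is the sensitive instrument there. If it improves on the best
seen, the parameters are checkpointed and the non-improvement counter
resets; otherwise the learning rate is multiplied by the decay (0.97;
0.9 with the text preset whose initial rate is 2e-5 instead of 1e-3)
and the counter increments. Training stops once the counter *exceeds*
the stop loss of 7 — i.e. on the 8th consecutive non-improvement — and
the last saved checkpoint is returned. Two conventions were open: the
learning rate never resets after an improvement (the decay is read as
monotone annealing; only the counter resets), and a `max_steps` safety
cap (default 20 epochs' worth) guards non-terminating runs. Class
imbalance is unhandled by default, with an optional positive-class loss
weight.

Per-fold experiments build every data-derived encoding from the fold's
training patients only: the ICD-9 vocabulary comes from training
admissions (codes seen only in test map to a reserved unknown index and
are counted), while the charts vocabulary is knowledge-base-derived and
fold-independent by construction. The decision threshold for
F1/precision/recall is chosen on validation predictions as the F1
maximizer over candidate cuts (midpoints between consecutive distinct
scores, plus the all-positive cut), lowest threshold on ties — the
"optimal threshold" needed a concrete criterion and maximizing the
reported F1 on held-out validation data is the natural one. AUROC is
computed as pairwise concordance with ties counted one half, AUPRC as
the step-wise precision-over-recall integral; fold aggregation reports
the sample mean and the (n−1) standard deviation. One model is called
conclusively better than another iff it is strictly higher on at least
three of the five metrics; note the rule is not antisymmetric in
general (with ties both directions can fail) and is applied at the same
aggregation level on both sides.

## The synthetic generator

The generator emulates the *structure* of a critical-care EHR, not its
clinical content: eight schema tables, demographics, hospital/ICU
admission-discharge timestamps, irregular per-concept sampling
(jittered-grid scheduling whose realised mean inter-event gap matches
the configured interval — hourly charts, daily labs — within 10% even
under in-stay truncation; 15% missingness), ICD-9 sequences over a
bundled 200-code vocabulary with invented-but-plausible titles,
sectioned discharge-summary-like notes with de-identification
placeholders, and a label mechanism that emits a follow-up ICU
admission within 30 days of hospital discharge for positives and at 45+
days (or never) for negatives — so the labeling rules can be audited
for exact recovery. All randomness flows from the single configured
seed; identical configurations are byte-identical.

Label-dependent signal is injected per modality and scaled by
`signal_strength`: a constant shift of the latent chart trajectories
toward each concept's abnormal direction (`chart_signal_target =
"state"`), over-sampling of 20 designated risk ICD-9 codes, and
risk-phrase injection into notes. Because the simple gradient rule is
invariant to constant shifts, a mean shift carries *no* gradient
signal; the `"gradient"` target therefore uses a separate mechanism —
measurement plateaus, where an observation repeats the previous reading
with probability `0.25 × signal` — which leaves the per-observation
value marginal (and hence the state abstraction) essentially unchanged
while surfacing as Stable gradient symbols. This separation lets the
test suite target each abstraction layer independently: under
gradient-targeted signal the states-only model scores at chance while
the states+gradients model recovers the signal.

What the generator does **not** emulate: real physiology (trajectories
are AR(1) noise around normal ranges), correlated comorbidity
structure, clinical language (notes are templated), waveforms, or
de-identification artifacts beyond bracketed placeholders. Passing
tests therefore demonstrate that the pipeline's mechanics — filtering,
labeling, abstraction, encoding, training, evaluation — are correct and
that injected signal of each kind is recoverable; they say nothing
about predictive performance on real patients.

Generator audits use a deliberately simple reference scorer: a logistic
model on four per-channel oracle composites (direction-aligned mean
chart deviation, mean up-fraction of consecutive differences, risk-code
count, risk-phrase count). At zero signal its held-out discrimination
is chance (the suite asserts AUROC in [0.45, 0.55] at n = 1500, a size
at which the null estimator noise fits that band); discrimination is
non-decreasing across a signal grid.

## Problem sizes and numerical choices

The end-to-end experiments run at desk scale, chosen once: 2,000
patients (state-signal arm) and 1,200 (gradient arm), charts signal
1.5, sequence length L = 128 most-recent tokens, hidden width 16,
evaluations every 50 steps with a 300–400 step cap, one of the five
folds. Observed held-out AUROC is ~0.97–0.99 for the state arm against
the ≥ 0.65 acceptance bound, and ~0.98–1.0 vs ~0.41–0.49 for the
gradient-vs-states comparison, so conclusions are insensitive to these
sizes. Other numerical conventions: probabilities are clamped by an
1e-12 epsilon inside the cross-entropy; attention masks use −Inf before
the softmax with a uniform fallback for all-pad rows; Adam uses
β = (0.9, 0.999), ε = 1e-8; parameter initialization is
uniform Glorot-style, embeddings ±0.1.

## Known limitations

* The pretrained clinical language models for the ICD-9-text and notes
  pathways are out of scope; the bundled scorer exercises the interface
  and aggregation but is not a clinical-language model.
* `runExperiment()` automates the charts / ICD-9 / demographics
  combinations; text pathways are composed from the exported functions
  directly.
* The thresholded gradient mode is provided but not the default; how
  the tabulated Δ and stable-window columns were originally meant to
  interact with the sign rule is left explicitly open.
* Synthetic validation bounds what the tests can claim about real EHR
  data (see above); the cohort builder accepts real MIMIC-III-schema
  extracts, but no real-data results are reported here.
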