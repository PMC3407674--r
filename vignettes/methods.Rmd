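---
title: "Streaming clinical decision support: model, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Streaming clinical decision support: model, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`streamcds` turns a continuous multivariate vital-sign stream into
actionable advice: an incremental decision tree classifies the patient's
current state, and every tree leaf indexes the historical medical records
that were classified there, so "similar past cases" are one pointer
dereference away. This vignette explains the model, its assumptions, the
parameters that matter, and the design decisions taken where the design was
genuinely open.

```{r setup}
library(streamcds)
```

## From stream to classifier input

A stream is a strictly time-ordered sequence of samples, one numeric
reading per monitor channel. Fixed-size windows of `unit_size` consecutive
samples form *data units*; an incomplete trailing window is carried over,
never emitted, so segmentation is an exact partition of the input. Each
unit is summarized per channel by its mean, least-squares slope, minimum
and maximum (`"mslmm"`). Mean and min/max capture the level of the signal,
the slope its direction over the window — the smallest set that
distinguishes "blood pressure is low" from "blood pressure is falling".
Timestamps order the samples but are treated as equispaced within a unit
for the slope fit; irregular sampling should be regularized upstream.
Missing channel readings are rejected, not imputed: a monitor that reports
at all is assumed to report completely, and silently invented
physiological values are worse than a skipped window.

`unit_size` defaults to 3. One caveat discovered in testing is worth
knowing: when malformed rows are dropped mid-stream, all later window
boundaries shift, and shifted windows can straddle a change in the
patient's state. Accuracy degrades gracefully, but data quality problems
are better fixed in whole-unit chunks.

An open question in the windowing design is whether the classifier should
see single time points or unit aggregates. This package classifies unit
feature vectors: a single reading cannot express a trend, and `unit_size =
1` recovers per-sample classification as a special case (the mean equals
the raw reading, the slope is 0).

## The Hoeffding tree

The classifier is a Very Fast Decision Tree: each labeled feature vector
is routed to a leaf, updates that leaf's statistics, and is discarded.
A leaf attempts a split every `grace_period` examples. Let `G1` and `G2`
be the information gains (in bits) of the two best candidate attributes,
and

\[ \varepsilon = \sqrt{\frac{R^2 \ln(1/\delta)}{2n}} \]

with `R = log2(#classes)` the gain range and `n` the examples at the leaf.
The leaf splits when `G1 − G2 > ε` (the best attribute is truly best with
confidence `1 − δ`) or when `ε < τ` (the top candidates are
indistinguishable and waiting longer is pointless). Defaults are
`δ = 1e-6`, `τ = 0.05`, `grace_period = 200` — conventional settings for
this family of learners. The model's "sensitivity" knob is exactly this
triple: smaller `δ` and `τ` make splits more conservative; a smaller grace
period checks more often.

Numeric attributes are summarized per class by running Gaussian estimators
(count, mean, variance via Welford updates) plus the observed min/max, so
leaf memory is fixed regardless of stream length. Candidate thresholds are
the midpoints between class means plus the interior deciles of the
observed range; the per-class mass on each side of a threshold is read off
the Gaussian CDF. Ties between equally good splits break deterministically
toward the lowest attribute index, then the lowest threshold, which makes
whole-model training a deterministic function of the input order.

One practical consequence of the feature scheme deserves emphasis: the
mean, min and max of the same separating channel are strongly correlated,
so their gains are nearly identical and the `G1 − G2 > ε` test almost
never resolves between them. Such splits go through the tie route, which
under the defaults requires roughly `R² ln(1/δ) / (2τ²)` examples at the
leaf — about 6,900 for three classes. This is the *incubation period*: the
engine needs on the order of 10⁴ initial records before the tree is fully
grown. It is a property of honest Hoeffding-bound splitting with
correlated features, not a defect; raising `τ` shortens incubation at the
cost of more speculative splits (the package's own small-corpus tests do
exactly that).

### Pointer lists and splits

Each leaf carries the pointer values of every record trained into it (the
*Adder*'s job), and the model remembers each pointed record's feature
vector. When a leaf splits, its pointers are re-distributed by re-routing
those stored features through the new split, and the child statistics are
rebuilt from them, so the leaf → similar-records mapping stays correct
after growth and child majorities stay consistent with their pointer sets.
What should happen to pointers at a split is genuinely open in this
design's lineage; re-routing was chosen because the alternative (freezing
pointers at the parent) silently decouples retrieval from classification
as the tree grows. Remembering pointed features costs one vector per
record — bounded by the store size, not the stream length — and an
optional per-leaf `pointer_cap` (keep-most-recent) restores strictly fixed
memory where required; it is off by default because dropping historical
cases silently is the worse default in a clinical setting.

## Record store and mapping table

Records live in an append-only JSON-lines file. Registration mints pointer
values sequentially from 1 — the first record `R1` gets pointer value 1 —
and appends a `(pointer, rid, address)` row to a TSV mapping table. The
"physical address" is the store file plus the record's byte offset
(printed as 16 hex digits), so `resolve()` seeks and reads one line
without scanning: a portable stand-in for raw memory addresses.
Pointer ↔ record ID is a bijection by construction; pointers are never
reused, records never amended (feedback only inserts). Reopening a store
directory reloads the mapping table exactly.

## Consensus extraction and the cache

Different doctors word the same advice differently, so exact-string
counting under-counts. Texts are normalized (lower case, punctuation
stripped), tokenized to sets, optionally passed through a user synonym
table, and grouped by single-linkage: two texts join when a chain of pairs
with token-set cosine similarity ≥ θ connects them. The group
representative is its most frequent exact string (ties lexicographic),
and the top `k` groups by size become the ranked output, formatted
`1.… 2.… 3.…`. Defaults `θ = 0.5`, `k = 3`. Token-set cosine with a
synonym table is a deterministic, testable proxy for sentence-level
semantic similarity; learned sentence embeddings are deliberately out of
scope, and the shared θ across the three text fields is a simplification
(nothing in the engine prevents per-field thresholds, but one knob is
easier to audit).

Extraction runs per leaf over only the records that leaf points to, so it
is cheap; it is still memoized. Each cache entry stores the leaf's
pointer-list *version stamp* — a counter the Adder bumps whenever a new
pointer lands on the leaf. An entry is served only if its stamp equals the
leaf's current version, so the cache is semantically transparent: a cached
answer is always identical to a from-scratch recomputation (this is
asserted property-style in the tests, across random operation
interleavings). Explicit `invalidate()` exists and is idempotent, but the
version guard alone already guarantees coherence; stamps avoid any global
locking.

The prognosis output is the most frequent illness-history description
among the retrieved records — the course that similar past cases took.

## Feedback: copy-train-swap

`ingest()` normalizes the event (lower case, collapsed whitespace —
idempotent), registers the record (store append *before* tree swap, so a
crash in between leaves at worst an orphaned record that `cdss_load()`
detects and re-trains on startup — a doctor's record is never lost),
clones the live tree, trains the clone with the new pointer, swaps the
clone in, invalidates the affected leaf's cache entry and, in the default
eager mode, re-extracts that leaf's consensus immediately. The
implementation is single-threaded with snapshot semantics rather than
concurrency primitives: the observable contract — every query is answered
by exactly one tree version, and queries issued before the swap see the
pre-ingest tree — is honored in deterministic replay and auditable through
the `.probe` hook, which runs between clone-training and swap.

## The quadratic-form distance baseline

`lsml_distance(x_i, x_j, P)` computes `(x_i − x_j)ᵀ P (x_i − x_j)` for a
positive semidefinite `P` (checked by symmetric eigendecomposition with
tolerance `1e-8`; identity by default). It represents the
metric-learning retrieval approach that requires an offline training pass
over the archive — the approach the leaf-pointer index replaces — and
serves as the baseline in retrieval sanity checks: records retrieved
through a leaf should be no farther from the query, on average, than
records of other classes. Learning `P` from data is out of scope.

## Synthetic study conditions

A `class_regime` is one illness class: per-channel Gaussian mean, noise
sd, within-unit drift slope, and phrase distributions for the three text
fields with a designated modal phrase each. Streams draw one regime
uniformly per unit (`value = mean + drift·s + N(0, sd)`, `s` the
within-unit index, so drift appears exactly as the slope feature);
records draw a regime, one synthesized unit for features, and the three
texts. Everything is a deterministic function of the seed.

`default_regimes()` defines the study conditions used throughout: three
classes (stable, cardiac, neuro) over four channels named for the
canonical monitors — systolic blood pressure (mmHg), heart rate (bpm), an
EEG burden index (a.u.), body temperature (°C) — with physiologically
plausible levels and class means at least 5 noise sd apart on at least one
channel. Each text field has its modal phrase at probability 0.45, a
distinct runner-up at 0.25, a third phrase at 0.15, and a paraphrase of
the mode sharing ≥ 80% of its tokens at 0.15, so grouping is genuinely
exercised (the paraphrase must merge into the modal group without
capturing the representative).

The manifest reports a Bayes-error bound for the per-sample channel
mixture: for two equal-covariance diagonal-Gaussian classes with equal
priors the Bayes error is exactly `pnorm(-Δ/2)` with `Δ` the Mahalanobis
separation of the means; for `K > 2` classes the pairwise union bound
`(1/K) Σ_{i≠j} pnorm(-Δ_ij/2)` is reported. It is an upper bound, and
unit-level features separate at least as well (the mean of `u` samples
shrinks the noise by `√u`). For the default regimes the bound is below
10⁻⁴ %.

What the generator does *not* emulate: waveform morphology, patient-level
longitudinal correlation (units are exchangeable given the regime),
sensor artifacts, label noise, and concept drift. Passing tests on this
data therefore demonstrate the engine's mechanics — windowing, bound-gated
splitting, pointer bookkeeping, cache coherence, consensus extraction —
not clinical validity on real monitors, where drift handling (explicitly
out of scope here) would matter.

## Problem sizes and numerical choices

The test suite and the reproduction script use: 5,000 samples for
root-split recovery against a brute-force batch information-gain oracle;
1,000 interleaved registrations/ingests (with `τ = 0.5`,
`grace_period = 50`, the short-incubation configuration) for pointer
conservation across ≥ 5 splits; 100 corpora of 1,500 records for
modal-phrase recovery; and a full study of 11,000 initial records plus
2,000 stream units — enough for the default configuration to complete its
incubation, including both tie-bound splits — for leaf purity and
prequential (test-then-train) accuracy over the final 1,000 units.

Smaller numerical choices, for the record: Gaussian per-class sd is
floored at `1e-9` when estimating threshold mass; a split requires
`G1 > 1e-12` (never split a pure leaf); class posteriors at a leaf are
Laplace-smoothed over all classes the model has seen; an empty leaf
answers with its parent's majority at split time; `max_depth` is
unbounded by default; and JSON serialization preserves full double
precision, so a serialize → deserialize round trip classifies
identically.

## Known limitations

- No concept-drift adaptation: a regime change after training requires
  enough new evidence to out-vote old leaf statistics.
- Numeric channels only; categorical attributes are not supported.
- The tie-route incubation described above makes cold starts slow under
  conservative defaults.
- Token-set similarity ignores word order and negation ("no surgery
  required" vs "surgery required" share most tokens); a curated synonym
  table mitigates, a real NLP similarity would be a drop-in replacement
  behind the same θ interface.
- Single-writer store; no access control or audit trail beyond the
  append-only files.
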