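# streamcds

Real-time clinical decision support by data-stream mining.

Bedside monitors emit continuous multivariate vital-sign streams (blood
pressure, ECG-derived heart rate, an EEG index, body temperature, ...).
Classical decision-support systems re-scan a static archive to refresh their
model, so they diagnose but cannot keep up with a stream. `streamcds`
implements an always-online alternative for clinicians and clinical
informaticians:

1. **Windowing.** Consecutive time points are grouped into fixed-size *data
   units* (`U1 = {T1,T2,T3}`, `U2 = {T4,T5,T6}`, ...); each unit is reduced
   to a per-channel (mean, slope, min, max) feature vector capturing the
   level and short-term trend of the patient's state.
2. **Incremental classification.** A Hoeffding tree (VFDT) consumes one
   feature vector at a time in constant time and memory. A leaf splits on
   attribute candidates only when the Hoeffding bound
   `ε = sqrt(R² ln(1/δ) / (2n))` guarantees, with confidence `1 − δ`, that
   the best candidate's information gain truly beats the runner-up
   (`G1 − G2 > ε`), or when the two are tied within `τ` and `ε < τ`.
3. **Pointer-augmented leaves.** During training, the *Adder* appends each
   record's pointer value to the leaf the record reaches. A *mapping table*
   (pointer → record ID → physical address, i.e. file + byte offset) lets a
   classified stream retrieve its similar historical cases directly — no
   offline clustering pass.
4. **Consensus extraction.** The retrieved records' free-text treatment,
   diagnosis, and illness-history fields are grouped as "same meaning,
   different expression" (single-linkage under token-set cosine similarity
   ≥ θ), and the most frequent groups become the ranked advice
   (`1.… 2.… 3.…`). Results are cached per leaf and invalidated by a
   version stamp the Adder bumps whenever a new pointer lands on the leaf.
5. **Feedback.** A doctor-confirmed diagnosis becomes a new record via
   copy-train-swap: the live tree is cloned, the clone is trained, and the
   clone atomically replaces the live tree, so classification is never
   blocked by an update.

A quadratic-form metric distance `d(x_i, x_j) = (x_i − x_j)ᵀ P (x_i − x_j)`
(PSD `P`; squared Euclidean for `P = I`) is included as the retrieval
baseline this design replaces.

A synthetic-data module generates labeled vital-sign streams and record
corpora from *class regimes* (per-channel Gaussian levels, drifts, and
phrase distributions with planted modal phrases), with a ground-truth
manifest including a closed-form Bayes-error bound, so every stage is
testable without patient data.

## Worked example

```r
library(streamcds)

regimes <- default_regimes()                 # 3 illness classes, 4 channels
eng <- cdss_engine(tempfile("cdss"))
run_initial_training(eng, generate_records(regimes, n = 11000, seed = 7))
print(eng$tree)
#> Hoeffding tree (VFDT): 3 leaves, 2 splits, depth 3
#>   trained on 11000 examples, 3 classes (cardiac, neuro, stable)
#>   11000 record pointers attached across leaves
leaf_purity(eng)
#> [1] 1

stream <- generate_stream(regimes, n_units = 200, unit_size = 3, seed = 9)
out <- run_stream(eng, stream)
out$summary$prequential_accuracy
#> [1] 1
print(out$results[[1]])
#> Prediction at leaf C5: class 'neuro'
#>   3609 similar records: R5, R13, R15, R21, R23, R24, R28, R34
#>   treatment: 1.load anticonvulsant and obtain urgent neurology consult 2.administer antipyretics and order head imaging 3.initiate seizure precautions and continuous eeg
#>   diagnosis: 1.encephalopathy with elevated eeg burden and fever 2.febrile state with abnormal cortical activity 3.possible central nervous system infection
#>   prognosis: 1.prior seizure activity controlled with anticonvulsants 2.recent febrile illness with confusion 3.longstanding epilepsy with good control
```

Each prediction names the reached leaf, the illness class, the similar
historical records retrieved through the leaf's pointer list, and the ranked
consensus texts: the treatment line is the advice, the diagnosis line the
system diagnosis, and the prognosis line the expected course, each ordered
by how many similar records' descriptions fell into that group. The second
prediction for an untouched leaf is served from the cache (`cache_hit`).

Doctor feedback folds in without blocking queries:

```r
ev <- feedback_event("cardiac",
                     treatment_text = "Administer beta blocker and monitor blood pressure closely",
                     diagnosis_text = "Acute cardiac decompensation",
                     illness_history_text = "Prior episodes of tachycardia",
                     unit = generate_stream(regimes, 1, 3, seed = 11)[, 1:5])
ingest(eng, ev)   # register -> clone -> train -> swap -> re-extract
```

A thin CLI wraps the same functions
(`inst/cli/streamcds simulate|train|stream|predict|feedback|inspect`).

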