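# harf

Hierarchical activity recognition from smartphone sensor streams, built
around a bounded-memory adaptive Gaussian naïve Bayes classifier.

## The problem

Life-logging applications want to label what a person is doing — walking,
sitting, standing, jogging, riding a car, waiting at the bus stop — from the
sensors a phone already carries (3-axis accelerometer, 3-axis gyroscope,
proximity sensor, GPS), in real time, on the device. Two things make the
naïve approach fail in practice:

1. **Memory.** Batch training of Gaussian class models wants all raw samples
   in memory; at 50 Hz over multiple channels that overflows a constrained
   device.
2. **Context.** The same physical motion means different things in different
   places, and a classifier asked to separate all activities at once from
   inertial features alone loses accuracy — a passenger in a slow-moving car
   looks exactly like someone sitting.

`harf` addresses both for anyone who wants a lightweight, fully inspectable
activity-recognition pipeline in R: an **adaptive naïve Bayes (A-NB)**
trainer with constant per-sample memory, and a **hierarchical recognition
framework** that decides location first and classifies second.

## The model

Classification is standard Gaussian naïve Bayes. For feature vector
F₁…Fₙ and class C,

    p(C | F₁,…,Fₙ) ∝ p(C) · Πᵢ p(Fᵢ | C),
    p(Fᵢ = v | C) = N(v; μ, σ²) per feature,

computed in log space with log-sum-exp normalization over the candidate set.

**A-NB training** never stores raw samples. Within each chunk of the stream
it maintains, per feature, the count N, running mean μ_N and running mean of
squares v_N:

    μ_N = (μ_{N−1}(N−1) + F_N) / N,   v_N = (v_{N−1}(N−1) + F_N²) / N,
    σ_N² = v_N − μ_N².

Every `chunk_size` vectors the chunk is finalized; the j finalized chunks
are combined into the class model as μ_m = mean(μ₁…μ_j) and
μ_v = mean(σ₁²…σ_j²) (the canonical unweighted rule, mode `"paper"`), or
exactly via the law of total variance (mode `"pooled"`, which reproduces
batch moments to machine precision for any chunking).

**Hierarchical routing** handles each 2-second window in order: match the
last GPS fix against a registry of geofenced venues (haversine distance);
a matched type-2 venue (bus stop, cafeteria, gym, park) returns its
location-based activity directly; a matched home/office restricts the
classifier's candidates to that area's walking/sitting/standing; anything
else is classified over the four outdoor activities, and a windowed mean
GPS speed strictly over 25 km/h compulsorily relabels the window as
*Riding a car*. The taxonomy has 15 activities (10 location-qualified
physical, 4 location-based, 1 heuristic).

## Worked example

```r
library(harf)

# Simulate a labeled 15-activity study (seeded, deterministic), train one
# Gaussian model per physical activity, and route every test window.
suite  <- generate_evaluation_suite(seed = 1)
res    <- run_suite(suite)
cm     <- build_confusion(res$results$truth, res$results$pred,
                          labels = activity_labels()$name)
macro_accuracy(cm)
#> [1] 99.29825

# The bundled 11-activity reference confusion matrix aggregates to the
# published summary figures:
ref <- reference_confusion_11()
macro_accuracy(ref)                                  # 11 activities
#> [1] 90.40091
macro_accuracy(ref, extra_diagonals = rep(100, 4))   # plus 4 location-based
#> [1] 92.96067
```

`macro_accuracy()` is the unweighted mean of per-class accuracies (diagonal
of the row-normalized confusion matrix), so 99.3% above means the average
test activity is recognized on 99.3% of its windows; the two reference
numbers are the same aggregation applied to a published 11-activity matrix,
without and with the four location-based activities counted as fully
recognized.

The same workflow is available file-based from a shell via the wrapper in
`inst/cli/`:

```sh
Rscript inst/cli/harf.R simulate  --out-dir run1 --seed 1
Rscript inst/cli/harf.R train     --out-dir run1
Rscript inst/cli/harf.R recognize --out-dir run1
Rscript inst/cli/harf.R evaluate  --out-dir run1   # writes confusion.csv + report.json
```

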