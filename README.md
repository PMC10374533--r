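# pamscape

Passive acoustic monitoring (PAM) pipeline for freshwater soundscapes:
from raw WAV recordings to CNN classification of dolphin echolocation
clicks, boat engine noise and rain, to ecological presence and
co-occurrence statistics.

Amazonian river dolphins echolocate almost continuously, so long-term
autonomous recorders can track their presence in flooded-forest habitats
that defeat visual surveys. The catch is scale and confusion: thousands of
hours of audio in which broadband clicks compete with boat cavitation,
rain, and walls of insect noise. `pamscape` implements the full analysis
chain for this problem and ships a ground-truthed synthetic soundscape
generator so that every stage is testable without field recordings.

## The method in brief

1. **Front end.** Recordings are resampled to 96 kHz and cut into 5-s
   segments. Each segment is Fourier-transformed (2048-sample Hamming
   window, 1112-sample overlap → 511 frames × 1024 bins), log-scaled,
   projected onto 128 Mel bands (0–48 kHz), padded to 512 frames, and
   median-equalized per band over time:
   `M[t, b] ← M[t, b] − median_t M[·, b]`,
   which strips time-constant insect tones.
2. **Classifier.** A CNN of five blocks — each two 3×3 convolutions
   (batch-norm before every convolution, ReLU) plus 2×2 max pooling, with
   32/64/96/128/160 filters — reduces the 512 × 128 image to a 16-step
   sequence, which a head of two 1×1 convolutions (256 filters) and a
   sigmoid layer maps to **16 output values per class per segment**
   (multi-label: click, boat, rain). Training minimizes binary
   cross-entropy summed over columns, classes and batch (Adam), with class
   oversampling and four on-the-fly spectrogram transforms per epoch.
3. **Scoring.** Per segment and class the 16 outputs are pooled by the
   **Q75 summary** — the mean of the values between the 75th and 100th
   percentile (the top 4 of 16) — which rewards sounds that repeat within
   the segment.
4. **Evaluation & thresholds.** Precision `PPV = TP/(TP+FP)`, recall
   `TPR = TP/(TP+FN)`, `TNR = TN/(TN+FP)`; average precision as the step
   sum `AP = Σ_t [TPR(t) − TPR(t+1)]·PPV(t)` with `TPR(T)=0, PPV(T)=1`;
   micro-mAP from the pooled multi-class curve. Per-site decision
   thresholds sit where precision equals recall, and a **posterior rain
   filter** re-attributes segments that exceed both the click and rain
   thresholds to rain.
5. **Ecology.** Daily acoustic presence (proportion of recorded time with
   detections — duty-cycle invariant), dolphin–boat co-occurrence minutes,
   and monthly day/night activity comparisons (Wilcoxon rank-sum on
   per-day rates scaled by period length).

The CNN backend is implemented in the package's own C++ (RcppArmadillo,
single precision over BLAS); all randomness flows from R seeds, so fits
are exactly reproducible.

## Worked example

Generate a labeled synthetic corpus, train the reduced classifier, and
evaluate on the held-out half:

```r
library(pamscape)

corp <- make_training_corpus(n_click = 200, n_boat = 60, n_rain = 40,
                             n_background = 300, seed = 101)
sp  <- split_train_test(data.frame(segment_id = corp$meta$segment_id),
                        "random", seed = 7)
tr  <- match(sp$train, corp$meta$segment_id)
te  <- match(sp$test,  corp$meta$segment_id)

fit <- fit_pam_cnn(corp$features[, , tr],
                   lapply(tr, function(i) corp$targets[i, , ]),
                   spec   = network_spec_small(),
                   epochs = 5, batch_size = 8, lr = 2e-3, swa_last = 3,
                   policy = augment_policy(min_labels_per_epoch = 100),
                   labels = corp$labels[tr], seed = 1)

scores <- segment_scores(fit, corp$features[, , te], classes = corp$classes)
eval_report(labels_to_matrix(corp$labels[te]), scores, corp$classes)
```

```
Model evaluation
  click  AP = 0.8900  (PPV=TPR threshold 0.262)
  boat   AP = 1.0000  (PPV=TPR threshold 1.000)
  rain   AP = 1.0000  (PPV=TPR threshold 1.000)
  micro mAP = 0.9276
```

Boat and rain separate perfectly on synthetic scenes; clicks — sparse
sub-millisecond transients — are the hard class, as in the field. The
selected thresholds are the precision = recall operating points used by
`classify_archive()`; `apply_rain_filter()` then clears click flags on
segments whose rain score also exceeds the site's rain-filter threshold.
Detections aggregate with `daily_presence()`, `cooccurrence_minutes()`
and `day_night_test()`.

A command-line wrapper around the same functions lives at
`inst/cli/pamscape.R`:

```sh
Rscript $(Rscript -e 'cat(system.file("cli/pamscape.R", package="pamscape"))') \
    all --config run.yml --seed 1
```

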