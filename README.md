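# ppght — hypertension risk stratification from PPG morphology

`ppght` is an R package for screening hypertension from short single-channel
fingertip photoplethysmogram (PPG) records. It is aimed at biosignal and
biostatistics researchers who want a fully reproducible, end-to-end pipeline
from raw samples to cross-validated classification metrics — including a
synthetic cohort generator, so every stage is testable without downloading
any recordings.

## The science in brief

Systolic blood pressure is shaped by the fusion of the forward (propulsion)
pressure wave with its reflection from the periphery: early, large reflection
accompanies higher BP. That fusion is visible in PPG morphology and — more
sharply — in its derivatives (VPG = dPPG/dt, APG = d²PPG/dt²). The pipeline:

1. **Quality gate** — of each subject's three 2.1 s records, keep the one
   with the highest skewness SQI, `S = m3 / m2^(3/2)`.
2. **Preprocess** — zero-phase 4th-order Chebyshev-II bandpass (0.5–10 Hz
   stopband edges), then derivative waveforms.
3. **Delineate** — per beat: O, S, N, D on the PPG; w, x, y, z on the VPG;
   a, b, c, d, e on the APG.
4. **Extract** — a 125-feature catalogue in seven families (time spans,
   amplitudes, VPG/APG amplitudes, curve areas, power areas, ratios, slopes),
   e.g. crest time `OS-`, the APG combination `(b−c−d)/a`, the VPG power
   ratio `S+1c-1}/O+1O+1}`.
5. **Rank** — six filter methods: |Spearman ρ|, ReliefF, information gain,
   χ², greedy mRMR, Gini impurity reduction.
6. **Classify** — per BP pairing (norm vs pre, norm vs hyp, norm+pre vs hyp),
   top-10 features, stratified 10-fold CV with per-fold refit of scaling and
   selection; four classifiers (LDA, logistic regression, cubic SVM, weighted
   KNN with K = 10). Reported per cell: pooled TP/FP/FN/TN and
   `SE = TP/(TP+FN)`, `PP = TP/(TP+FP)`, `F1 = 2·PP·SE/(PP+SE)` in percent.

BP classes follow the screening criteria: hypertensive if SBP ≥ 140 or
DBP ≥ 90; else prehypertensive if SBP ≥ 120 or DBP ≥ 80; else normotensive.

## Worked example

```r
library(ppght)

cohort   <- generate_cohort(48, 41, 35, seed = 17)   # 124 subjects, 372 records
features <- extract_cohort_features(cohort$records, cohort$meta)

head(correlation_report(features), 5)   # features vs SBP
#>              feature     r        p
#>   amp_D__over__amp_S 0.644 7.74e-12
#>                amp_D 0.631 2.67e-11
#>              amp_c-2 0.609 6.33e-14
#>          slope_O_c-2 0.597 2.49e-13
#>  comb_b-c-d__over__a 0.591 4.97e-13

stratified_10fold(features, "norm_vs_hyp", "relieff", "weighted_knn", seed = 17)
#>      pairing  method   classifier TP FP FN TN  PP    SE    F1
#>  norm_vs_hyp relieff weighted_knn 33  0  2 48 100 94.29 97.06
```

On this synthetic cohort the strongest SBP correlates are reflection-
sensitive features (c-wave amplitude and its PPG projection, the APG
combination `(b−c−d)/a`) — the generator plants its class effect on
reflected-wave timing/amplitude, and the ranking recovers it. The CV cell
reads: pooled over 10 folds, 33 of 35 hypertensives were detected (SE
94.3%), no normotensive was misflagged (PP 100%), F1 97.1%. Synthetic
cohorts overlap less than real ones; these numbers validate the pipeline,
not clinical performance. `run_experiment(features)` runs the full 3 × 6 × 4
grid and flags the best cell per pairing.

## Command line

A thin CLI ships in `inst/exec/ppght`:

```sh
ppght simulate --n-norm 48 --n-pre 41 --n-hyp 35 --seed 17 --out cohort/
ppght extract  --signals cohort/ --meta cohort/meta.csv --out features.csv
ppght classify --features features.csv --k 10 --seed 17 --out report.json
ppght run      --config config.json --out results/
```

Records travel as plain-text `<subject>_<k>.txt` files (one integer sample
per line, 1 kHz, 12-bit counts) next to a `meta.csv` — the layout of openly
deposited short-record PPG datasets.

## Documentation

The methods vignette (`vignettes/ppg-hypertension-methods.Rmd`) documents the
signal model, every tunable parameter with its default and rationale, what
the synthetic generator does and does not emulate, and the package's design
decisions (filter application direction, derivative smoothing, baseline and
aggregation conventions, per-fold selection refit).
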