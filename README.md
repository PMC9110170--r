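# mindfuse

Attention-weighted multimodal fusion for digital mental-health phenotyping.

Screening programmes increasingly record short behavioural streams — facial
landmarks and body-joint trajectories from a pose-estimation network, and a
little speech — and want a score for each dimension of an SCL-90-style
symptom checklist (somatization, obsessive-compulsive, interpersonal
sensitivity, depression, anxiety, hostility, dreadness, crankiness,
psychopathy, other). mindfuse is an R toolkit for that pipeline, end to end,
for researchers prototyping such assessment systems:

1. **Feature extraction.** Face (68 landmarks) and gait (18 joints) keypoint
   streams become per-landmark motion-magnitude channels (displacement from
   the temporal mean — translation-invariant); speech is Wiener-denoised,
   cut into 1 s segments, and reduced to 17 per-frame descriptors: short-time
   energy, cepstral pitch *PF*, LPC-root formants For1–3, and 12 MFCCs.
2. **Time-domain statistics.** Each channel is summarized by a configurable
   statistic set (default mean, std, skewness, kurtosis), giving matrices
   `F` (68×4), `V` (17×4), `G` (18×4).
3. **Attention fusion.** Modality descriptors are scored against their mean
   (cosine similarity by default; dot, bilinear `kᵀWq`, and scaled-dot
   `⟨q,k⟩/√d` available) and softmax-normalized into weights
   `(w₁, w₂, w₃)`; the fused feature is the weighted stack
   `Fus = [w₁·F; w₃·G; w₂·V]`, 103 channels × 4 statistics → a 412-vector.
4. **Classification.** Ten independent soft-margin SVMs (binary relevance),
   Gaussian kernel `K(x,z) = exp(−‖x−z‖²/2σ²)`, `C = 1`, kernel width from
   the scale rule `σ² = d·Var(X)/2`.
5. **Evaluation.** Stratified k-fold cross-validation per indicator;
   accuracy, precision, recall, F1 with zero-denominator conventions; a
   modality-ablation grid (F, V, G, pairs, tri-modal ± attention).

No subject data is bundled. A synthetic-cohort generator (source–filter
voice with planted f0/formants; oscillatory keypoint motion with
label-dependent amplitudes) makes every stage testable offline, with
controllable per-indicator, per-modality effect sizes.

## Worked example

```r
library(mindfuse)

spec    <- cohort_spec(n_subjects = 30, effects = 3, seed = 7)
cohort  <- generate_cohort(spec)           # labels + 3 streams per subject
dataset <- extract_cohort_features(cohort) # 68x4 / 17x4 / 18x4 per subject
report  <- cross_validate(dataset, k = 5, seed = 42)
print(report)
```

```
EvalReport [F+G+V+attention]: overall accuracy 0.7800, overall F1 0.7980 (k=5, seed=42)
                 indicator accuracy precision recall     F1
              somatization   0.7333    0.7500 0.5000 0.6000
      obsessive_compulsive   0.8667    0.8235 0.9333 0.8750
 interpersonal_sensitivity   0.7667    0.7857 0.7333 0.7586
                depression   0.9000    0.8333 1.0000 0.9091
                   anxiety   0.7000    0.7000 1.0000 0.8235
                 hostility   0.7333    0.6957 0.9412 0.8000
                 dreadness   0.5667    0.5556 0.6667 0.6061
                crankiness   0.8333    0.7826 1.0000 0.8780
               psychopathy   0.8000    0.7391 1.0000 0.8500
                     other   0.9000    1.0000 0.7857 0.8800
```

Each row is one indicator's pooled out-of-fold confusion summarized by the
four metrics; the header's overall numbers are macro-averages across the ten
indicators. With moderate planted effects (standardized shift 3) on a small
cohort the bank sits well above the 0.5 chance level without saturating.

The fused representation for one subject:

```r
s <- dataset$subjects[[1]]
fused <- fuse(s$face, s$voice, s$gait)
print(fused)
#> FusedFeature: 103 x 4 (face 68, gait 18, voice 17 rows)
#> weights: face 0.3130, voice 0.3601, gait 0.3269
```

103 = 68 face + 18 gait + 17 voice channels; the weights are this subject's
softmax attention over the three modality descriptors and sum to 1.

## Command line

```sh
Rscript inst/cli/mindfuse.R simulate --n 30 --seed 7 --out cohort_dir
Rscript inst/cli/mindfuse.R run      --data cohort_dir --out report_dir
Rscript inst/cli/mindfuse.R ablation --data cohort_dir --out report_dir
Rscript inst/cli/mindfuse.R extract  --in voice.wav --out features.csv
```

`run` writes `report.csv`, `summary.json`, the effective `config.yaml`, and
`run.log`; configuration is YAML (`--config`), covering `audio.*`,
`stats.set`, `fusion.*`, `svm.*`, `eval.*`.

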