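# anuracall

Temporally-aware classification of anuran (frog and toad) calls from noisy
field recordings.

Automatic call classification supports long-term acoustic monitoring of
anuran populations, whose calling activity tracks temperature and habitat
change. The practical obstacles are heavy ambient noise and tiny labelled
training sets. `anuracall` implements a complete frame-based pipeline:

1. recordings are cut into 10 ms frames (`frame_signal()`);
2. each frame gets 18 MPEG-7-style descriptors -- powers, spectral centroid
   and dispersion, flatness, three LPC formants with bandwidths, pitch and
   six harmonicity descriptors (`extract_features()`);
3. features are ranked by the Jensen-Shannon separability index
   Psi_j = (prod over class pairs of d_JS(f_ju, f_jv))^(1/B), the geometric
   mean of the pairwise Jensen-Shannon distances between class-conditional
   densities, and the top `r` are kept (`rank_features()`);
4. frames are classified against hand-picked labelled pattern frames
   (instance selection) by a pluggable classifier -- native minimum-distance
   and Gaussian maximum-likelihood, plus decision-tree, k-NN, SVM,
   logistic, neural-network, discriminant and naive-Bayes backends;
5. the sound is labelled by plurality vote over its non-silence frames.

Temporal context enters through a family of temporally-aware methods: LIQR (local interquartile
range features over a 10-frame window), SW (stacking the `w = 2d + 1`
frames around each frame), RSW (SW plus the previous `d` decisions fed
back), discrete left-right HMMs over an LBG vector-quantization codebook
(full-file, ROI-length and sliding-window segmentation), and VAR segment
models whose coefficient matrices (selected order by a weighted-AIC rule)
feed an ordinary frame classifier. Evaluation uses one-vs-rest confusion
metrics with the single-point AUC = (sensitivity + specificity)/2,
macro-averaging, and bootstrap resampling of test sounds for confidence
intervals and paired outperformance probabilities.

A seeded synthetic scene generator (`generate_dataset()`) emits labelled
WAV recordings -- pulsatile croak-like and tonal whistle-like calls over
band-limited habitat noise with per-frame ground truth -- so the entire
pipeline is testable without any audio assets.

## Worked example

Compare the frame-level baseline with a 7-frame sliding window on one
synthetic dataset (four call classes, 12 recordings each, 5 s at 20 dB
in-ROI SNR over 300-2000 Hz habitat noise; 2 recordings per class are
clean "pattern" recordings used for training):

```r
library(anuracall)

cfg <- experiment_config(methods = c("NTA", "SW"), r = 5, w = 7,
                         backend = "MinDis",
                         scene = scene_config(seed = 8, snr_db = 20),
                         n_per_class = 12, pattern_fraction = 0.17)
report <- run_experiment(cfg)
report
#> <experiment_report: test split, r = 5>
#>   NTA      macro AUC 0.7000  ACC 0.7750
#>   SW       macro AUC 1.0000  ACC 1.0000
```

Both methods share the dataset, the feature ranking and the split, so the
comparison is paired: here the baseline mislabels several croaks whose
frame features are perturbed by the in-band noise, while stacking 7 frames
(70 ms of context) averages that perturbation away. The macro AUC is the
mean over the four call classes of (sensitivity + specificity)/2; ACC is
the mean one-vs-rest accuracy. A paired bootstrap quantifies the gap:

```r
p_sw  <- report$results$SW$predictions
p_nta <- report$results$NTA$predictions
po <- prob_outperform(p_sw$true, p_sw$pred, p_nta$pred,
                      classes = c(unique(p_sw$true), "silence"),
                      n_boot = 1000, seed = 1)
round(po$o["AUC"], 3)
#> AUC
#>   1
```

so the sliding window beats the baseline on every paired resample of this
test set.

The command-line front end wraps the same functions:

```sh
Rscript inst/cli/anuracall generate --out data/demo --n-per-class 6 --seed 7
Rscript inst/cli/anuracall rank --data data/demo --out ranking.csv
Rscript inst/cli/anuracall evaluate --data data/demo --method SW --w 7 --r 5 --out report.json
Rscript inst/cli/anuracall compare --method1 SW --method2 NTA --w 7 --out cmp.json
```

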