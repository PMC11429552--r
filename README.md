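# hapticEEG

Band-limited EEG feature engineering and classification of haptic versus
non-haptic trials.

EEG recorded while a person performs a simulated motor task carries a
signature of whether force (haptic) feedback was present. This package
implements the full analysis chain for detecting that signature in epoched,
labeled EEG, for researchers studying sensory feedback in virtual-reality
and simulation paradigms:

* **Band decomposition** — zero-phase 4th-order Butterworth band-passes
  into low alpha (8–9.5 Hz), high alpha (10–13 Hz), low beta (13–21 Hz)
  and high beta (21–30 Hz) on nine channels (F3, Fz, F4, C3, Cz, C4, P3,
  Pz, P4).
* **Feature extraction** — per channel and band: Hjorth activity
  (variance σ²), mobility √(σ²_Δx/σ²_x), complexity; Welch band power;
  permutation entropy (order 3, bound log 3!); normalized spectral entropy;
  Higuchi fractal dimension (∈ [1, 2]); rescaled-range Hurst exponent
  H (∈ [0, 1]); skewness g₁; excess kurtosis g₂. 9 channels × 4 bands ×
  10 features = **360 features per epoch**.
* **Feature selection** — greedy MRMR ranking by the quotient
  F(x) / mean|r(x, selected)| of the one-way ANOVA F statistic to the mean
  absolute Pearson correlation with already-selected features, and a hybrid
  proposal that filters the MRMR top-20 with two-sided Mann–Whitney U tests
  (p < 0.05) and re-orders by ascending p.
* **Classification** — seven grid-searched classifiers (SGD, SVC, decision
  tree, Gaussian NB, KNN, random forest, MLP) on an 80/20 shuffle split,
  evaluated over nested feature subsets (5, 10, 15, 20, …, all).
* **Characterization** — per-channel class means of any feature/band,
  jointly min–max normalized for topographic display.
* **Synthetic EEG generator** — 1/f^β background noise with *planted*,
  mechanism-level class effects of known direction and intended Cohen's d,
  plus a ground-truth manifest and empirical verification of realized
  effect sizes. The generator stands in for the unreleased recordings of
  the emulated paradigm and makes every downstream stage testable by
  recovery.

## Worked example

Simulate a small cohort with the ten planted "strong" class effects,
verify what was realized, extract the 360-column feature table, select
features with the hybrid MRMR + Mann–Whitney proposal, and classify:

```r
library(hapticEEG)

cfg <- generator_config(n_participants = 4, trials_per_class = 50,
                        preset = "strong", seed = 7)
run <- generate_epochs(cfg)
run$epochs
#> <eeg_epochs> 400 epochs x 9 channels x 2048 samples @ 1024 Hz
#>   channels: F3, Fz, F4, C3, Cz, C4, P3, Pz, P4
#>   labels: haptic=200, non_haptic=200
#>   participants: 4

verify_manifest(run$epochs, run$manifest)
#> <ground_truth_manifest> 10 planted effect(s), seed 7
#>   Pz_13-21Hz_Hurst             non_haptic_higher  slope_tilt       d*=1.50 realized=+1.77
#>   Fz_13-21Hz_Hurst             non_haptic_higher  slope_tilt       d*=1.50 realized=+1.55
#>   Cz_13-21Hz_Hurst             non_haptic_higher  slope_tilt       d*=1.50 realized=+1.51
#>   P4_13-21Hz_Hurst             non_haptic_higher  slope_tilt       d*=1.50 realized=+1.40
#>   Cz_21-30Hz_Kurtosis          non_haptic_higher  burst_amplitude  d*=1.50 realized=+1.25
#>   Cz_21-30Hz_PSD               non_haptic_higher  band_gain        d*=1.50 realized=+1.43
#>   Cz_21-30Hz_Activity          non_haptic_higher  band_gain        d*=1.50 realized=+1.71
#>   C3_13-21Hz_Spectral_Ent      haptic_higher      slope_tilt       d*=1.50 realized=-1.35
#>   Cz_13-21Hz_Spectral_Ent      non_haptic_higher  slope_tilt       d*=1.50 realized=+1.76
#>   Pz_13-21Hz_Spectral_Ent      non_haptic_higher  slope_tilt       d*=1.50 realized=+1.56

tab <- extract_feature_table(band_decompose(run$epochs))
sel <- select_features(tab, "mrmr_mwu", k = 10)
sel
#> <selection_result> method = mrmr_mwu, 10 feature(s)
#>    1. Pz_13-21Hz_Kurtosis            p = 6.62e-62
#>    2. Cz_13-21Hz_Kurtosis            p = 1.23e-60
#>    3. Fz_13-21Hz_Kurtosis            p = 1.4e-60
#>    4. P4_13-21Hz_Kurtosis            p = 4.07e-58
#>    5. C3_13-21Hz_Complexity          p = 1.15e-45
#>    6. Cz_21-30Hz_Activity            p = 1.2e-43
#>    7. Cz_13-21Hz_Spectral_Ent        p = 1.48e-42
#>    8. Pz_13-21Hz_Hurst               p = 2.47e-42
#>    9. Cz_13-21Hz_Complexity          p = 9.71e-42
#>   10. Pz_13-21Hz_Spectral_Ent        p = 5.74e-38

evaluate_battery(tab, sel, sizes = c(5, 10),
                 models = default_model_specs()[c("KNN", "RF")], seed = 1)
#> <accuracy_report> selection = mrmr_mwu, seed = 1 (test accuracy %)
#>         5    10
#> KNN 100.0 100.0
#> RF   98.8  98.8
```

Reading the output: every planted effect realized a standardized class
difference close to its intended d = 1.5 (sign follows the planted
direction — negative for C3 low-beta spectral entropy, where the haptic
class is higher). The hybrid selection surfaces the perturbed low-beta and
high-beta cells; note that a planted mechanism legitimately moves several
features of its cell (the envelope modulation that raises Hurst also
produces heavy-tailed amplitudes, so low-beta kurtosis at the modulated
channels carries the contrast too). With 5–10 selected features the
held-out accuracy of KNN/RF sits near ceiling, exactly the regime the
planted d ≈ 1.5 × 10 features implies.

Per-channel class means for topographic display:

```r
class_mean_maps(tab, "Spectral_Ent", "low_beta")
#> <topo_map> Spectral_Ent, 13-21Hz
#>               F3    Fz    F4    C3    Cz    C4    P3    Pz    P4
#> haptic     0.882 0.913 0.934 0.909 0.012 1.000 0.895 0.000 0.870
#> non_haptic 0.941 0.862 0.910 0.192 0.928 0.809 0.874 0.863 0.774
```

(the direction reversal at C3 — haptic above non-haptic — against Cz/Pz is
the planted asymmetry; `plot()` renders the pair as scalp maps).

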