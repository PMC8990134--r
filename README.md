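# lfpdecode

Decoding bilateral hindlimb joint angles from multichannel intraspinal local
field potentials (LFP) recorded during treadmill locomotion.

Neural interfaces that aim to restore locomotion need kinematic information
from the nervous system. The dorsal columns (ascending sensory tracts) and
lateral columns (descending motor tracts) of the spinal cord both carry
signals that covary with the gait cycle, and band-limited LFP amplitude
recorded there can be regressed onto joint angles. `lfpdecode` is for
electrophysiologists and neural-engineering researchers who want a tested,
reusable implementation of that analysis chain — and a synthetic ground-truth
world to validate it against, since recordings of this kind are not publicly
deposited.

## What it implements

**Features.** 8-channel LFP at 500 Hz is notch-filtered (50/100/150 Hz,
4th-order Butterworth band-stop), split into six bands — δ (0.5–4 Hz),
θ (6–12 Hz), β (15–30 Hz), γ (40–80 Hz), high-γ (80–120 Hz),
ripple (150–210 Hz) — rectified, low-passed at 4 Hz and resampled to 10 Hz,
alongside a windowed average LFP amplitude (ALFP, 200 ms windows / 100 ms
step). Ten 100 ms lags give a channel × lag × feature tensor (8 × 10 × 7)
per time point.

**Decoders.** A 3D convolutional network per joint (70 filters of 7 × 6 × 8
by default, ReLU, 2 × 2 × 2 max-pool with stride 1, one hidden fully
connected layer, single linear output; SGD with momentum 0.75, L2 penalty
0.3, batches of 128, 10 epochs), plus PLS and Lasso baselines. Evaluation is
the coefficient of determination in percent,

    R²(%) = (1 − Σₙ(yₙ − ŷₙ)² / Σₙ(yₙ − ȳ)²) × 100,

under threefold cross-validation with contiguous temporal folds. Channel
subsets follow the electrode map: lateral columns {1, 4, 5, 8}, dorsal
columns {2, 3, 6, 7}, left side {3, 4, 7, 8}, right side {1, 2, 5, 6}.

**Analyses.** Gait-cycle-locked ERD/ERS maps (percent change of the band
envelope per phase bin), adaptive-partitioning (Darbellay–Vajda) mutual
information between every feature and joint angle, ANOVA + Tukey HSD group
comparisons, and a lower- vs higher-cadence (0.67 / 0.73 steps/s thresholds)
band-power comparison.

**Synthetic sessions.** `generate_session()` produces gait-periodic joint
angles and LFP whose band-limited components are amplitude-modulated by the
gait phase with known per-channel coupling (depth `m`, phase `ψ`), mains
interference, pink and white noise — deterministic under a seed, so decoding
and analysis results are exact parameter-recovery experiments.

## Worked example

```r
library(lfpdecode)

cfg <- synth_config(duration = 120, seed = 1,
                    gait = gait_model(cadence = 0.75),
                    coupling = coupling_spec(m = matrix(0.7, 8, 6)))
session <- generate_session(cfg)
prep <- preprocess_session(session)

res <- crossvalidate(prep, decoder = "pls")
round(mean_r2(res), 1)
#>  left_ankle    left_hip   left_knee right_ankle   right_hip  right_knee
#>        89.4        82.8        83.0        89.8        81.7        82.5

mi <- mi_matrix(prep$features, session$kinematics, session$kin_fs)
round(sort(apply(mi, 2, mean), decreasing = TRUE), 3)
#>      gamma high_gamma       alfp     ripple       beta      theta      delta
#>      0.507      0.455      0.453      0.422      0.397      0.262      0.130
```

Fold-averaged R² in the 80s per joint says the linear baseline recovers most
of the variance of this strongly coupled (m = 0.7) synthetic session; the
MI row ranks feature types by how much kinematic information they carry on
average (bits, averaged over channels and joints — here every band shares
the same modulation depth, so the fast bands with the most carrier cycles
per envelope sample read it out most cleanly).

The command-line interface drives the same pipeline:

```sh
Rscript inst/cli/lfpdecode.R simulate --out session.json --duration 120 --seed 1 --m 0.7
Rscript inst/cli/lfpdecode.R preprocess --in session.json --out features.json
Rscript inst/cli/lfpdecode.R decode --features features.json --decoder pls --subset lateral --out decode.csv
Rscript inst/cli/lfpdecode.R analyze mi --in session.json --out mi.csv
Rscript inst/cli/lfpdecode.R run --config config.json --out-dir results/
```

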