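# bikephase

Phase recognition for bicycle riding with a lower-limb prosthesis.

Active prosthetic knee joints need to know where the crank is in its
revolution: the knee motor should push hard in the pedaling phase, wind
down through the lower buffer, free-wheel in relaxation and re-engage in
the upper buffer. The crank angle itself cannot be measured on an ordinary
bicycle, so the phase must be recognized from wearable kinematics — knee
and ankle horizontal/vertical accelerations plus the knee-joint angle —
and those accelerometer channels are heavily contaminated by frame and
stump vibration.

`bikephase` implements the full recognition pipeline for researchers in
rehabilitation engineering and wearable-sensor activity recognition:

* **Simulator** (`sim_config()`, `generate_recording()`) — seeded,
  labeled crank-driven recordings. The knee angle is a smooth periodic
  curve through the phase-onset anchors observed in static experiments
  (pedaling 84–87°, lower buffer 106–108°, relaxation 95–98°, upper
  buffer 73–76°; midpoints by default); accelerations are crank harmonics;
  vibration is 5–20 Hz band-limited Gaussian noise at a chosen SNR.
* **Denoiser** (`denoise_recording()`) — wavelet-packet decomposition with
  the combined soft-hard threshold: for coefficient `g`, threshold `α` and
  mix factor `k ∈ [0, 1]`,

  `G = sign(g)·(|g| − k·α)` if `|g| > α`, else `0`,

  so `k = 0` is the hard threshold, `k = 1` the soft one, and the default
  `k = 0.5` the combination. `α = τ·sqrt(2·ln D)` is the universal
  threshold with noise scale `τ = median(|d₁|)/0.6745`. The knee angle is
  exempt (its sensor is interference-proof).
* **Features** (`extract_features()`) — per-sample 5-D vectors
  `P(x) = [kx, ky, hx, hy, a]`; the knee angle alone is ambiguous (each
  angle occurs twice per cycle), the accelerations disambiguate.
* **Classifier** (`train_tree()`, `predict_tree()`) — a binary tree of
  three kernel SVMs with decision function
  `f(P) = sgn(Σᵢ Qᵢ αᵢ* K(Pᵢ, P) + b*)`: SVM1 peels off pedaling, SVM2 the
  lower buffer, SVM3 relaxation; the remainder is the upper buffer.
* **Tuner** (`tune_tree_pso()`) — particle swarm optimization of the
  penalty `C` and RBF bandwidth `γ` (log-space), with adaptive per-particle
  inertia and ten-fold cross-validation accuracy
  `H = (1/K) Σ P_lr/(P_lr + P_lw)` as fitness. Swarm defaults: 20
  particles, 200 iterations, accelerations c₁ = 1.5, c₂ = 1.7.
* **Baselines** (`train_bp()`, `train_pso_bp()`) — a 5–6–4 sigmoid BP
  network (hidden size `round(sqrt(n + l)) + 3`, learning rate 0.7) and
  its PSO-initialized variant.
* **Evaluation** (`metrics_report()`, `compare_models()`) — recognition
  rate, per-node precision/recall, F1 `2PR/(P+R)`, G index `sqrt(P·R)`,
  precision average with population standard deviation, and the four-way
  BP / SVM / PSO-BP / PSO-SVM comparison on one shared cycle split.

## Worked example

```r
library(bikephase)

cfg    <- sim_config(n_cycles = 50, vibration_snr_db = 10, seed = 1)
rec    <- generate_recording(cfg)
rec_dn <- denoise_recording(rec, shrinkage_spec(k = 0.5))

ds    <- group_medians(extract_features(rec_dn))   # 200 groups, 4 per cycle
sp    <- split_cycles(ds, 25, 25, seed = 1)        # 100 train / 100 test
train <- standardize(sp$train)
test  <- apply_standardization(sp$test, train)

tuned <- tune_tree_pso(train, folds = 10,
                       swarm = pso_config(n_particles = 12, max_iter = 30,
                                          seed = 2))
tree  <- train_tree(train, C = tuned$C, gamma = tuned$gamma)
metrics_report(test$y, predict_tree(tree, test$x))
```

```
Recognition rate: 100.00% (100/100)
Per-phase correct: pedaling=25, lower buffer=25, relaxation=25, upper buffer=25
            precision recall  f1   g
classifier1       100    100 100 100
classifier2       100    100 100 100
classifier3       100    100 100 100
Precision average 100.00%, population sd 0.00%
```

The denoiser lifted the knee horizontal channel from 10.0 dB to 12.0 dB
before feature extraction, and the swarm settled on `C = 0.0549`,
`γ = 1.10` at CV fitness 1.000. All 100 test groups classify correctly:
synthetic recordings, even at 10 dB vibration, are considerably more
separable than real amputee data once each phase segment is collapsed to
its median feature vector — see the methods vignette
(`vignettes/phase-recognition.Rmd`) for what this does and does not say
about field performance.

A thin command-line wrapper ships in `inst/cli/bikephase`
(`simulate`, `denoise`, `train`, `predict`, `tune`, `evaluate`,
`compare`).

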