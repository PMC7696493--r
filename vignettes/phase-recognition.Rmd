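---
title: "Methods: cycling-phase recognition from prosthesis kinematics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cycling-phase recognition from prosthesis kinematics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bikephase)
```

## The problem and the model

A transfemoral prosthesis wearer riding a bicycle moves through four
mechanically distinct phases per crank revolution: **pedaling** (maximum
motor output, crank near horizontal-forward), **lower buffer** (output
winding down, knee at its largest angle), **relaxation** (damping-free
free-wheeling) and **upper buffer** (output ramping back up, knee at its
smallest angle). Phase-aware knee control needs these phases recognized
from body-worn sensors, because the crank angle $\varphi_c$ itself is not
measurable on an ordinary bicycle.

The recognizer is a binary tree of three soft-margin kernel SVMs over the
instantaneous 5-D feature vector $P(x) = [k_x, k_y, h_x, h_y, a]$ (knee
and ankle horizontal/vertical accelerations, knee angle). Each node
evaluates

$$f(P) = \operatorname{sgn}\Big(\sum_i Q_i \alpha_i^\ast K(P_i, P) + b^\ast\Big),$$

with the RBF kernel $K(u,v) = \exp(-\gamma\|u-v\|^2)$ by default; SVM1
separates pedaling from the rest, SVM2 the lower buffer from what
remains, SVM3 relaxation from the upper buffer, and a sample rejected
three times is the upper buffer. Peeling one phase at a time keeps every
node a one-against-rest problem, which is easier to separate in feature
space than any balanced two-against-two split (the `scheme = "secondary"`
alternative is retained only for comparison; its top split must divide
four clusters into two pairs and is measurably less accurate).

A decision value of exactly zero classifies as $+1$; the tie rule is
documented and tested. The quadratic program behind each node is solved
by libsvm via e1071 — an ordinary, well-tested solver; this package's
contribution is everything around it (kernels, decision evaluation, the
tree, the tuner, the metrics), and the decision values the package
reports are computed by its own explicit support-vector sum, checked
against the solver in the tests.

## Phase geometry and the simulator

Phases are quadrants of the crank angle: pedaling
$\varphi_c \in (-45^\circ, 45^\circ]$, upper buffer $(45^\circ, 135^\circ]$,
relaxation $(135^\circ, 225^\circ]$, and the lower buffer takes the
remaining quadrant $(225^\circ, 315^\circ]$ so the four tile the circle.
Under this geometric convention a forward-pedaling crank sweeps
$\varphi_c$ *downwards*; the simulator therefore integrates the crank
with direction $-1$, which is exactly what makes the labels cycle
pedaling → lower buffer → relaxation → upper buffer in time.
`crank_trajectory()` keeps direction $+1$ as its own default so that it
is the plain linear model $\varphi_c(t) = (6\,\mathrm{cadence}\,t +
\varphi_0) \bmod 360$.

The undeposited human-subject recordings are stood in for by a seeded
synthetic generator whose defaults are the study conditions:

| parameter | default | rationale |
|---|---|---|
| cadence | 60 rpm | leisurely stationary riding; 1 s period |
| sample rate | 100 Hz | typical wearable IMU rate |
| cycles | 50 | 50 riding cycles → 200 phase groups |
| knee-angle anchors | 85.5°, 107°, 96.5°, 74.5° | midpoints of the static-experiment onset ranges 84–87°, 106–108°, 95–98°, 73–76° |
| acceleration amplitude | 6.7 m/s² | centripetal acceleration of a 0.17 m pedal circle at 60 rpm |
| vibration SNR | 10 dB | heavy frame/stump vibration |

The knee angle is a monotone piecewise-cubic (PCHIP) curve through the
four anchors at their phase-onset crank angles, so its global maximum is
the lower-buffer anchor and its minimum the upper-buffer anchor, attained
exactly at the onsets; within-range anchor placement is unconstrained in
the source material, so the midpoints are used. The ankle rides the pedal
circle (pure first crank harmonic); the knee gets a smaller first plus
second harmonic (0.45 and 0.20 of the ankle amplitude, per-channel phase
offsets), a deliberately simple stand-in for a full linkage model that
still makes every channel phase-informative. Vibration is white Gaussian
noise band-passed to 5–20 Hz (4th-order Butterworth, zero-phase) and
scaled per channel to the requested SNR; it is added to the four
acceleration channels only, since the angle sensor fuses its own
nine-axis estimate and is treated as interference-proof.

**What the simulator does not emulate:** inter-subject variability, seat
height, pedaling-force asymmetry, sensor drift, non-stationary cadence
and the cross-phase similarity of real stump kinematics. Synthetic phases
are geometrically cleaner than real ones, so absolute accuracies here
exceed what field data yields; tests on this generator validate the
machinery (denoising gains, tuning dominance, metric identities), not
field-grade recognition rates.

## Denoising

Each acceleration channel is wavelet-packet decomposed (`db4`, level 3 by
default — a common choice for 100 Hz kinematics; at that rate level 3
gives 6.25 Hz subbands, so the 1–2 Hz crank harmonics stay in the
untouched approximation band while 5–20 Hz vibration lands in thresholded
subbands). All subbands except the all-lowpass path are shrunk by the
combined soft-hard rule

$$G = \begin{cases} \operatorname{sgn}(g)\,(|g| - k\alpha) & |g| > \alpha \\ 0 & |g| \le \alpha \end{cases}$$

with $k = 0.5$ by default ($k=0$ hard, $k=1$ soft; the "soft adjustment
factor" named $q$ in some accounts of this rule is the same quantity).
The threshold is the universal threshold $\alpha = \tau\sqrt{2\ln D}$
with $D$ the subband coefficient count and
$\tau = \mathrm{median}(|d_1|)/0.6745$ the MAD estimate of the noise
standard deviation from the first-level detail coefficients — the
estimator is unspecified in the source material, and $\tau$ only works
dimensionally as a standard deviation even where it is called a variance.
One global $\alpha$ from the finest subband is the default (simplest
reading of a single "threshold value"); `per_subband = TRUE` re-estimates
per subband. The knee angle is never denoised.

Numerical choices: the transform is a decimated orthogonal filter bank
with periodized boundaries whose synthesis is the exact transpose of
analysis, so full-tree reconstruction is exact to machine precision
(signals are symmetric-padded to a multiple of $2^{\text{level}}$ and
truncated back); reconstruction is from the full thresholded tree, not a
truncated one. With $\alpha = 0$ the denoiser is the identity to 1e-8,
which the tests assert.

## Features, groups and splits

Features are instantaneous channel values only — no sliding-window
statistics — because the recognizer is meant to fire within a phase, and
the listed eigenvalues are instantaneous. A **group** is one contiguous
phase segment of one cycle (50 cycles × 4 phases = 200 groups; 100
training and 100 testing at the default 25/25 cycle split). For
group-level training and evaluation each segment is represented by its
per-feature median, which reconciles group-counted evaluation with
continuous sampling; sample-level work can skip `group_medians()`.
Splits are drawn at cycle granularity so no cycle leaks across sets, and
standardization (zero mean, unit variance per feature; zero-variance
features get scale 1) is estimated on the training side only.

## PSO tuning

The tuner searches $C \in [10^{-2}, 10^2]$, $\gamma \in [10^{-3}, 10^1]$
in $\log_{10}$ coordinates (no bounds are given in the source material;
these cover the useful RBF regime for standardized 5-D features), with
velocity clamped to half the range per dimension. Velocity and position
updates are the classical

$$V^{k+1} = \omega V^k + c_1 r_1 (p^k - x^k) + c_2 r_2 (p_g^k - x^k),
\qquad x^{k+1} = x^k + V^k,$$

with $r_1, r_2$ drawn per dimension (standard practice; the source is
ambiguous), positions clamped to the box, ties between particles broken
by lower index, and the whole trajectory reproducible under a fixed seed.
Defaults: 20 particles, 200 iterations, $c_1 = 1.5$, $c_2 = 1.7$, early
stop after 30 iterations without a global-best improvement above $10^{-6}$.

The inertia weight is adapted per particle from its fitness $K$ relative
to the swarm's minimum and mean:

$$\omega = \begin{cases}
(\omega_{\max}-\omega_{\min})\dfrac{K - K_{\min}}{K_{avg} - K_{\min}} + \omega_{\min} & K \le K_{avg} \\
\omega_{\max} & K > K_{avg}
\end{cases}$$

with $\omega_{\max} = 0.9$, $\omega_{\min} = 0.4$ (conventional bounds;
the rule's source defines the form, not the bounds). This piecewise form
comes from the *minimization* literature, where $K \le K_{avg}$ means
*better* than average. Because this optimizer maximizes a CV accuracy,
applying the form literally hands the best particles the largest inertia
and measurably degrades final convergence (on the 2-D sphere benchmark,
3 of 5 seeds stall outside $10^{-3}$ per coordinate even at 200
iterations, versus ~$10^{-8}$ under the classical sense). The default
(`invert_inertia = TRUE` in `pso_config()`) therefore applies the rule in
its classical sense — good particles get the small inertia for fine
search — and `invert_inertia = FALSE` reproduces the literal direction.
`adaptive_inertia()` itself implements the printed piecewise rule
exactly, including branch continuity at $K = K_{avg}$ and the degenerate
$K_{avg} = K_{\min}$ case (returns $\omega_{\min}$).

The fitness is ten-fold stratified cross-validation accuracy of the full
tree, $H = \frac1K \sum_l P_{lr}/(P_{lr}+P_{lw})$, with one shared
$(C,\gamma)$ across the three nodes by default (`per_node = TRUE` tunes
each node's own binary subproblem). Fold assignment is fixed before the
search so the fitness is deterministic.

## Baselines

The BP network is $5\!-\!6\!-\!4$: hidden size from
$m = \operatorname{round}(\sqrt{n+l}) + \alpha$ with $\alpha = 3$ — the
only reading of the sizing rule consistent with the stated six hidden
nodes (the literal sum $n+l+\alpha = 12$ is available as
`rule = "sum"`). Sigmoid activations on both layers, squared-error
("global error") loss, full-batch gradient descent at the stated learning
rate 0.7, uniform $(-0.5, 0.5)$ seeded initialization, stopping at an
epoch cap or a target error.

PSO-BP searches the flattened 64-dimensional weight/threshold vector
($5\cdot6+6+6\cdot4+4$) maximizing training-set accuracy. (Formally the
fitness is described as CV accuracy, but cross-validating a *fixed*
weight vector — nothing is re-fit per fold — is arithmetically the
whole-set accuracy, so that is what is computed.) Two implementation
choices were driven by measured failures of the naive setup: the search
box is $\pm 1$ rather than a wide box, keeping pre-activations out of
sigmoid saturation where the accuracy fitness plateaus and gradients
vanish; and the swarm optimum is always polished by BP gradient descent —
the standard PSO-then-BP arrangement, without which the pure swarm
measurably underperforms plain BP and occasionally abandons a whole
phase. `polish = FALSE` gives the pure swarm result.

## Metrics

"Classifier $k$" is the $k$-th tree node, scored one-vs-rest on the full
test set: precision $100\,TP/(TP+FP)$, recall $100\,TP/(TP+FN)$ (so each
recall is the per-phase correct count over 25 test groups), F1
$= 2PR/(P+R)$ and G index $= \sqrt{PR}$ — the geometric mean, which
dominates the harmonic mean with equality iff $P = R$; it is the only
formula consistent with the published worked-example table this package
recomputes. The precision spread is the **population** standard deviation
(divisor 3), the only convention matching the published summary cells;
display rounding is half-up to 2 decimals. Two printed cells in the
source tables carry 0.01–0.02 rounding slips (one G-index cell and two
population-sd cells); the acceptance tests assert the recomputed values
and document the discrepancy where it occurs.

## Problem sizes used in the tests

The test suite exercises the pipeline at sizes chosen to keep the
full-pipeline checks meaningful while the suite stays quick: unit tests
use 2–10-cycle rides; the denoiser-efficacy property uses 20 seeds of
10-cycle rides at 10 dB; the $(C,\gamma)$-recovery check uses a
400-sample ride (4 cycles at 100 Hz), a 7×7 log-grid oracle and a
10-particle, 25-sweep swarm; the four-way comparison runs the canonical
50-cycle, 25/25-split benchmark with a 12-particle, 30-sweep tuning swarm
over 5 seeds. On the saturated synthetic benchmark the expected outcome
is ties at 100% rather than the published 72–93% spread — the ordering
(tuned ≥ untuned) is the meaningful, tested property.

## Known limitations

* Synthetic data only; no claim about recognition rates on real amputee
  recordings is made or testable here.
* The harmonic acceleration model omits limb dynamics; the anchors are
  fixed midpoints unless jittered by the caller.
* Per-sample features make boundary samples intrinsically ambiguous at
  high noise; the group-median representation sidesteps this by design.
* The PSO is the plain global-topology variant; no constriction factor,
  neighborhoods or multi-objective support.
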