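---
title: "Models and methods behind rungait"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind rungait}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(rungait)
```

`rungait` implements a complete wearable running-gait monitoring stack:
physics-based simulation of body-worn 9-axis inertial (IMU) and
ultra-wideband (UWB) sensor streams from articulated gait motion, error
modelling and calibration, loosely coupled IMU–UWB trajectory fusion,
skeletal kinematics, and a compact diffusion-transformer/LSTM (DiT-LSTM)
classifier for running-posture recognition. This vignette records the
models, the assumptions behind them, and the numerical and design choices a
maintainer would want to know.

## Skeletal kinematics

Body pose is a `SkeletonSequence`: 17 joints in the Human3.6M convention,
partitioned into five functional chains (trunk axis, two arm chains, two leg
chains). Orientations are unit quaternions in the Hamilton, scalar-first,
right-handed convention — the literature uses both conventions and the
choice is free, so it is fixed once here and used everywhere.

The joint flexion angle between a parent and child segment is read off the
scalar part of the relative rotation,

$$\theta = \arccos\!\big(2\,(q_\text{parent}\otimes q_\text{child}^{-1})_w^2-1\big),$$

which is the total relative rotation angle. It is *not* a signed anatomical
flexion/extension decomposition: the formula cannot distinguish flexion from
abduction for a ball joint. We implement it literally because it is
well-defined, symmetric, and invariant under a common left rotation of both
frames; a signed decomposition would require per-joint anatomical axes the
rest of the stack never needs. The `arccos` argument is clamped to
$[-1, 1]$ to absorb floating-point rounding.

The whole-body centre of mass is the unweighted joint mean after each
mounting point is corrected by its rotated fixed offset:
$p_\mathrm{CoM}(t) = \frac{1}{N}\sum_i [p_i(t) + R_i(t)\,r_i^\mathrm{CoM}]$
with $N = 17$. Equal weights keep the estimator free of anthropometric
assumptions; segment-mass weighting would be a one-line change.

Gait-phase segmentation uses dynamic time warping with the recurrence

$$D(i,j) = \min\{D(i-1,j)+d,\; D(i,j-1)+d,\; D(i-1,j-1)+2d\},$$

i.e. a *diagonal-weighted* symmetric step pattern. The boundary condition is
not implied by the recurrence alone; we initialize $D(1,1) = 2\,d(v_1,v_1)$
(the diagonal-entry convention, consistent with the weight of the step that
conceptually enters the first cell) and fill the first row and column with
weight-1 cumulative sums. The pointwise metric defaults to Euclidean; which
feature vector $v_i$ to align (raw joint coordinates, angles, model
features) is deliberately a caller choice, since nothing in the alignment
depends on it. Tests pin the implementation to exhaustive enumeration over
all monotone warping paths for every shape with $nm \le 30$.

## IMU error model and calibration

Each tri-axial sensor is corrupted by a diagonal scale-factor matrix, a
zero-bias vector and white Gaussian noise:
$\tilde{x} = \mathrm{diag}(S)\,x + b + \nu$. Bias instability (random-walk)
and temperature effects are intentionally out of scope — the fusion layer,
not the error model, is the package's subject, and white noise plus constant
bias is the regime in which its drift claims are stated.

Six-position calibration holds each axis up and down against gravity:
$S_k = (r_\text{up} - r_\text{down}) / 2g_\text{ref}$,
$b_k = (r_\text{up} + r_\text{down})/2$, an exact inversion of the model
when noiseless (tested to 1e-12) and a $1/\sqrt{n}$-consistent estimator
under noise.

Gyroscope Earth-rate compensation evaluates what an ideal gyro reports for a
body translating over the rotating Earth: in the local ENU navigation frame
$\omega_n = (-V_N/(R+h),\; \omega_{ie}\cos\phi + V_E/(R+h),\;
\omega_{ie}\sin\phi)$, rotated into the body frame and augmented with the
navigation-relative body rate. The defining contracts are the reduction
cases: at rest with identity attitude the result is
$(0, \omega_{ie}\cos\phi, \omega_{ie}\sin\phi)$ and its magnitude is
$\omega_{ie}$ at every latitude. The attitude matrix direction is
body←navigation, fixed here because conventions differ across texts.

Simulated IMU streams derive world acceleration from second-order central
differences of joint positions and body rates from the quaternion
derivative, $\omega_b = 2\,q^{-1}\otimes\dot q$. Gravity is
$(0,0,-9.80665)$ m/s² in ENU and the accelerometer outputs specific force,
so a stationary level sensor reads $+g$ on z. The magnetometer returns a
configurable constant reference field rotated into the body frame (no IGRF
model — heading observability, not geomagnetic fidelity, is what downstream
stages need).

## UWB ranging, SDS-TWR and multilateration

The pre-correction ranging model is
$\mathrm{TOF}_i = \lVert b_i - p\rVert/c + \Delta\tau + \delta_i + \nu_i$
with clock offset $\Delta\tau$, a *non-negative* NLOS/multipath delay
$\delta_i$ (path lengthening only; simulated as exponential, the simplest
positive-support choice), and Gaussian noise. Although the deployed protocol
is said to eliminate clock offset, the measurement model keeps
$\Delta\tau$ explicitly: it is the *pre-correction* model, and
`sdsTwrExchange()` models the correction. The symmetric double-sided
exchange simulates all four timestamps under a relative clock-rate error
$e$ — a delay programmed as $D$ ticks on a drifting clock lasts $D/(1+e)$
true seconds — and forms
$\hat{\tau} = (R_a R_b - D_1 D_2)/(R_a + R_b + D_1 + D_2)$,
which cancels the drift to first order; the single-sided estimator
$(R_a - D_1)/2$ is evaluated on the same exchange for comparison, and the
tests require a ≥10× error reduction at 20 ppm.

Multilateration solves the nonlinear least squares
$\min_p \sum_i (\lVert b_i - p\rVert - r_i)^2$ by Gauss–Newton from a
linearized closed-form initialization (range differences against the first
anchor), max 100 iterations, step tolerance 1e-10 m. Rank of the linearized
system is checked and near-coplanar geometries raise a diagnostic error
rather than returning a silently unstable fix. The default fixture is five
base stations (four corners at 2.5 m plus an elevated centre) and one tag.
NLOS gating is a rolling median/MAD gate with linear interpolation over
rejected samples — a deliberately simple front-end ahead of the smoother.

## Dead reckoning, Kalman filtering and RTS smoothing

The kinematic recursion is taken exactly as stated, with the acceleration
sample at the *end* of the step driving both updates:
$v_k = v_{k-1} + \Delta t\,a_k$,
$p_k = p_{k-1} + v_{k-1}\Delta t + \tfrac12\Delta t^2 a_k$.
This differs from the continuous-time $\tfrac12 a t^2$ law by a
discretization term, which the tests account for.

The filter state is position + velocity (6-D); attitude is handled upstream
by the IMU module's orientation track, so the transition model assembled
from the recursion is *linear* — the filter the printed equations define is
a linear Kalman filter, and it is implemented as such, with the nonlinear
observation hook documented rather than speculatively implemented. The
observation is the UWB-derived position (loose coupling; raw-range tight
coupling is a non-goal). Defaults: IMU at 100 Hz, UWB at 10 Hz applied at
the nearest IMU step without interpolation; observation noise
$R = (0.1\,\mathrm{m})^2 I$ matching 10 cm ranging accuracy; process noise
from the continuous-time white-acceleration discretization with
configurable spectral density. Numerics: covariance re-symmetrized each
step, Joseph-form update, positive semi-definiteness asserted in tests over
thousands of random steps.

The RTS smoother runs the standard backward recursion
$K_k = P_k^+ F^\top (P_{k+1}^-)^{-1}$,
$x_k^s = x_k^+ + K_k (x_{k+1}^s - x_{k+1}^-)$,
anchored at the final filtered state. The transpose on $F$ matters: only
this form satisfies the smoother-dominance property (smoothed RMSE never
above filtered RMSE on linear-Gaussian problems) that the acceptance suite
checks across 20 seeds × 3 noise levels.

## The synthetic gait cohort

The generator is sinusoid-superposition kinematics, not a biomechanical
simulation: the pelvis translates at cadence × stride length with a
vertical bounce at twice the cadence, legs swing antiphase at the cadence
with knee flexion, arms counter-swing, and ankle orientations carry
frontal-plane signatures. This is deterministic, fully parameterized, and
exercises every pipeline stage; what it does *not* emulate is ground
contact, impact transients, soft-tissue artefact, or inter-cycle
variability beyond smooth seeded perturbations. Passing tests therefore
certify the pipeline's mechanics and the model's capacity to separate
parameterized signatures — not field performance on real running data.

The seven posture classes are explicit parameter deltas against normal
running (the class names alone do not define kinematics, so the package
must): overstriding lengthens the stride and lowers cadence; foot
inversion/eversion add opposite-sign frontal ankle oscillations; forefoot
running pitches the ankle, raises cadence and flattens the bounce; seated
running lowers the pelvis and increases trunk lean; arm-swing
discoordination puts both arms in phase. Arm motion itself is invisible to
foot/tibia/femur sensors, so the generator models the physical pathway by
which real sensors see it: contralateral arm swing largely cancels the
legs' angular momentum, and synchronous arms leave it uncompensated, which
appears as markedly larger pelvis yaw and lateral sway — signals the lower
body IMUs and the UWB track do observe. Default cohort: 8 subjects with
mildly varying stature and noise level, 10 s sequences per subject × class
at 100 Hz, 6 train / 1 validation / 1 test subjects — subject-disjoint by
construction, with windows cut within sequences only (no temporal leakage).

Channels: 3 IMU placements (foot, tibia, femur — ankle, knee and hip mounts
on the right side) × 9 channels + 3 UWB-fused positions = 30. Windows are
256 steps (≈2.56 s) with stride 128, z-scored per channel with statistics
from the training split only, after channel concatenation (z-scoring before
vs after concatenation is equivalent per-channel; it is implemented once,
after).

## The DiT-LSTM recognizer

Every architectural quantity that is stated is used as stated: linear
$\beta$-schedule over 100 diffusion steps from 0.003 to 0.06; loss balance
$\lambda = 0.7$ on the diffusion MSE (the phrase order "diffusion loss and
classification loss" resolves which term gets 0.7; the config exposes it);
LSTM hidden 128; embedding dimension 256; 2×2 patches on the 256×256
pseudo-image (16384 tokens); sinusoidal positional encodings along time and
per-modality embeddings; gated fusion; Adam at learning rate 1e-4 with
weight decay 0.1 (L2-in-gradient form), batch 30, up to 300 epochs.

How the diffusion process serves *classification* is the one genuinely open
design question. The package's answer: a training-time auxiliary task.
Each window's token matrix is corrupted by the closed-form jump to a
uniformly sampled step $t$, a sinusoidal embedding of $t$ conditions the
tokens, a linear head on the final tokens predicts the injected noise
(MSE, weight $\lambda$), and the classifier reads the fused representation
of the same corrupted pass (cross-entropy, weight $1-\lambda$). Inference
is the clean forward pass — no sampling loop — which keeps latency at the
millisecond scale and uses every stated hyperparameter. Block count and
head count are not stated anywhere; defaults are 4 blocks / 4 heads.

The transformer itself is pre-LN: `x + Attn(LN(x))`, `x + MLP(LN(x))`,
with a final LayerNorm — the standard stability choice for small-depth
training from scratch. The whole network, including backpropagation and
Adam, is implemented in base R and verified against central finite
differences on every parameter tensor (relative error < 1e-4 in the test
suite; ~1e-7 typical).

**Desk-scale configuration.** Full scale (16384 tokens per window) is not
trainable in minutes on one CPU, so `scaledDownConfig()` shrinks the model
while preserving every mechanism: the pseudo-image is average-pooled to
16×16 before patching for the DiT branch (64 tokens), 2 blocks / 2 heads,
64-dim embeddings, LSTM hidden 32 reading every 4th row of the *unpooled*
temporal embedding (the LSTM branch, like its full-scale counterpart,
operates on the T×d embedding rows, not on the pooled grid), fusion
dropout 0.3, learning rate 3e-3, weight decay 1e-4, ≤60 epochs with early
stopping (patience 25, best checkpoint by validation accuracy with
cross-entropy tie-break). The printed fusion dropout of 0.9 is available in
the config and appropriate for large cohorts; at 300 training windows it
removes nearly the whole fused signal and is counterproductive, so the
desk-scale default is 0.3. These problem sizes — 8 subjects × 7 classes ×
10 s, the 16×16 pooled grid, 60 epochs — are the package's chosen
experiment scale; the acceptance suite trains three seeds at this scale and
requires test macro-F1 ≥ 0.85 and parity-or-better against a plain-LSTM
reference trained on the same windows.

The reference LSTM is the canonical temporal baseline: one LSTM (hidden
32) over the raw normalized window subsampled ×4, final hidden state into
a softmax, cross-entropy, Adam. It certifies that the synthetic set is
learnable and gates the DiT-LSTM comparison.

## Metrics and reporting

Classification: accuracy, per-class precision/recall/F1, macro averages
(macro is used for headline numbers throughout, and AUC is macro
one-vs-rest by rank statistic), confusion matrix. Positioning: per-axis
mean absolute error and RMSE, 3D Euclidean error mean ± sd, and the
empirical fraction of samples below a threshold (default 1.0 m).
Multi-seed results are reported as mean ± sd with a t-distribution 95% CI;
a two-sided paired t-test across seeds is available for model comparisons
and is reported, never used to gate anything automatically.

## Reproducibility

Every stochastic element — generator perturbations, sensor noise, UWB
draws, weight initialization, batch order, diffusion steps and noise,
dropout — flows from explicit integer seeds through R's global RNG, so a
stage re-run from its manifest (config + hash + seeds + package version) is
bit-identical; the test suite asserts this on the generator and the
pipeline asserts it per stage.

## Known limitations

* The gait generator's realism gap (no impacts, no contact dynamics) means
  classifier scores here do not transfer to field recordings.
* The joint angle is unsigned; anatomical flexion vs extension is not
  distinguished.
* The fusion filter assumes attitude is known well enough upstream that
  gravity compensation errors act as white noise — violated under fast
  attitude error growth.
* The NLOS gate is a heuristic front-end; a Bayesian outlier model would
  integrate more cleanly with the filter.
* File-based interfaces are plain text (CSV/YAML/JSON) throughout.
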