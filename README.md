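# rungait

Wearable running-gait analysis in R: sensor simulation, IMU–UWB fusion,
skeletal kinematics, and a diffusion-transformer/LSTM posture classifier.

## The problem

Body-worn inertial sensors (9-axis MEMS IMUs) are cheap and portable but
drift: integrating biased acceleration twice makes position error grow as
*t²*. Ultra-wideband (UWB) radio ranging gives absolute, drift-free — but
noisy and occasionally NLOS-corrupted — position fixes. A running-gait
monitoring system therefore needs three layers, and this package implements
all of them for researchers in human-movement science who want a fully
inspectable, simulation-backed reference stack:

1. **Sensor layer** — error models and calibration for the IMU
   (per-axis scale factors `S`, zero bias `b`, white noise:
   `x̃ = diag(S)x + b + ν`, six-position calibration recovering `S` and
   `b` in closed form), Earth-rate gyro compensation, UWB time-of-flight
   ranging `TOF = ‖b_i − p‖/c + Δτ + δ_NLOS + ν`, symmetric double-sided
   two-way ranging (SDS-TWR) that cancels clock drift to first order,
   Gauss–Newton multilateration, and median/MAD NLOS gating.
2. **Fusion layer** — kinematic dead reckoning
   (`v_k = v_{k−1} + Δt a_k`, `p_k = p_{k−1} + v_{k−1}Δt + ½Δt²a_k`),
   a position+velocity Kalman filter with UWB position observations, and
   a Rauch–Tung–Striebel backward smoother
   (`K_k = P_k⁺ Fᵀ (P_{k+1}⁻)⁻¹`), with drift-error reporting (per-axis
   mean error and RMSE, 3D error mean ± sd, fraction below 1 m).
3. **Recognition layer** — gait kinematics (quaternion joint angles
   `θ = arccos(2(q_p ⊗ q_c⁻¹)²_w − 1)`, centre-of-mass trajectories,
   DTW phase segmentation with weighted-diagonal recurrence) and a
   **DiT-LSTM** classifier: sensor windows (256 steps × 30 channels,
   z-scored) are linearly embedded into a 256×256 pseudo-image, cut into
   2×2 patches, corrupted during training by a linear-β diffusion process
   (100 steps, β: 0.003→0.06) whose injected noise the transformer must
   predict, while an LSTM branch reads the temporal embeddings; a sigmoid
   gate fuses both streams into a softmax over seven running-posture
   classes. Joint loss: `0.7·MSE(noise) + 0.3·CE(class)`, Adam.

No external dataset is needed: a seeded synthetic cohort generator renders
labelled running motions (normal running, overstriding, foot
inversion/eversion, forefoot running, seated running, arm-swing
discoordination) on a 17-joint skeleton, simulates the foot/tibia/femur
IMUs and the five-anchor UWB layout, and windows everything with
subject-disjoint train/val/test splits.

## A worked example

```r
library(rungait)

# simulate a runner with a biased foot IMU and noisy UWB fixes
frames <- generateGait("normal_running", syntheticSubject("S1", seed = 7),
                       duration = 10, rateHz = 100)
imu <- simulateImuStream(frames, "ankle_r",
                         model = imuErrorModel(bias = c(0.1, 0, 0)),
                         rateHz = 100, seed = 1)

# drift with and without UWB correction
accel <- matrix(rep(c(0.1, 0, 0), 1000), ncol = 3, byrow = TRUE)
dr <- deadReckon(c(0, 0, 0), c(0, 0, 0), accel, dt = 0.01)
tail(dr$position, 1)
#>          x y z
#> [1001,]  5 0 0        # 0.5 * 0.1 m/s^2 * (10 s)^2 = 5 m of drift

set.seed(1)
tU  <- seq(0.1, 10, by = 0.1)                      # 10 Hz UWB fixes
obs <- matrix(rnorm(300, 0, 0.1), ncol = 3)        # 10 cm accuracy
fz  <- fuseTrajectory(accel, tU, obs, truth = matrix(0, 1000, 3), dt = 0.01)
fz$report$mean3dError
#> [1] 0.0298824         # bounded at the UWB noise floor, not 5 m
fz$report$fractionBelow
#> [1] 1                 # every sample under 1 m
```

Ten seconds of a 0.1 m/s² accelerometer bias alone produce 5 m of position
drift; fusing 10 Hz UWB fixes with the Kalman filter + RTS smoother holds
the mean 3D error at ~3 cm.

Training the desk-scale classifier on the synthetic cohort:

```r
data  <- renderGaitDataset()                        # 8 subjects x 7 classes
model <- trainDitLstm(data, scaledDownConfig(), seed = 1)
evaluateModel(model, data, "test")[c("accuracy", "macroF1")]
```

## Command line

A thin CLI over the same functions lives at `inst/cli/rungait`
(`simulate`, `make-dataset`, `train`, `evaluate`, `report`); see
`vignettes/rungait-methods.Rmd` for the models, parameter choices, and
limitations.
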