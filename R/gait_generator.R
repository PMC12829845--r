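# Seeded generator of labelled multi-class running-gait motion and its
# sensor renderings. Gait synthesis is sinusoid-superposition kinematics on
# the 17-joint skeleton: deterministic, parameterized, and sufficient to
# exercise every downstream stage (it is not a biomechanical simulation).

#' Specifications of the seven running-posture classes
#'
#' Each class is defined by explicit kinematic parameter deltas against
#' normal running: cadence (stride frequency), stride length, per-chain
#' amplitude modifiers, ankle roll (inversion/eversion), pelvis height and
#' vertical bounce, trunk lean, and arm-swing phase. The class list covers
#' normal running, overstriding, foot inversion, foot eversion, forefoot
#' running, seated running, and arm-swing discoordination.
#'
#' @return Named list of class-spec lists.
#' @examples
#' names(gaitClassSpecs())
#' @export
gaitClassSpecs <- function() {
  base <- list(
    cadence = 1.4,        # stride frequency, Hz (per-leg cycle)
    strideLength = 2.0,   # m per stride
    legAmp = 0.55,        # hip swing amplitude, rad
    kneeAmp = 0.9,        # knee flexion amplitude, rad
    armAmp = 0.45,        # shoulder swing amplitude, rad
    armPhase = pi,        # arm swing phase relative to ipsilateral leg
    armSync = FALSE,      # TRUE: both arms swing in phase (discoordination)
    ankleRoll = 0,        # frontal-plane ankle oscillation, rad (+ = inversion)
    anklePitch = 0,       # static ankle pitch offset, rad
    bounceAmp = 0.045,    # vertical pelvis oscillation, m (at 2 x cadence)
    pelvisDrop = 0,       # static pelvis height change, m
    trunkLean = 0.08      # forward trunk pitch, rad
  )
  mod <- function(...) utils::modifyList(base, list(...))
  list(
    normal_running = base,
    overstriding = mod(strideLength = 2.7, cadence = 1.15, legAmp = 0.85,
                       kneeAmp = 0.6),
    foot_inversion = mod(ankleRoll = 0.45),
    foot_eversion = mod(ankleRoll = -0.45),
    forefoot_running = mod(anklePitch = 0.5, bounceAmp = 0.025,
                           cadence = 1.6, strideLength = 1.7),
    seated_running = mod(pelvisDrop = -0.25, trunkLean = 0.35,
                         bounceAmp = 0.02, legAmp = 0.4, kneeAmp = 1.2),
    arm_swing_discoordination = mod(armPhase = 0, armAmp = 0.7,
                                    armSync = TRUE)
  )
}

#' Synthetic subject descriptor
#'
#' @param subjectId Subject label.
#' @param scale Anthropometry scale factor (1 = 1.75 m reference stature).
#' @param noiseLevel Relative amplitude of the smooth per-subject motion
#'   perturbations.
#' @param seed Base RNG seed for this subject.
#' @return A list of class `SyntheticSubject`.
#' @export
syntheticSubject <- function(subjectId, scale = 1, noiseLevel = 0.05,
                             seed = 1L) {
  structure(list(subjectId = as.character(subjectId), scale = scale,
                 noiseLevel = noiseLevel, seed = as.integer(seed)),
            class = "SyntheticSubject")
}

#' Default synthetic cohort
#'
#' Eight subjects with mildly varying stature and motion-noise levels,
#' split 6 train / 1 val / 1 test downstream (subject-disjoint).
#'
#' @param seed Base seed; subject seeds are derived deterministically.
#' @return List of [syntheticSubject()] objects.
#' @export
defaultCohort <- function(seed = 20260101L) {
  scales <- c(0.94, 0.98, 1.0, 1.03, 1.06, 0.96, 1.02, 0.99)
  noise <- c(0.05, 0.06, 0.04, 0.05, 0.07, 0.05, 0.06, 0.05)
  lapply(1:8, function(i)
    syntheticSubject(sprintf("S%02d", i), scale = scales[i],
                     noiseLevel = noise[i], seed = seed + 1000L * i))
}

# smooth deterministic perturbation: sum of low-frequency sinusoids with
# seeded random phases/amplitudes
.smoothNoise <- function(t, level, nComp = 3L) {
  out <- numeric(length(t))
  for (k in seq_len(nComp)) {
    f <- stats::runif(1L, 0.1, 0.6)
    ph <- stats::runif(1L, 0, 2 * pi)
    a <- stats::rnorm(1L, 0, level / nComp)
    out <- out + a * sin(2 * pi * f * t + ph)
  }
  out
}

#' Generate a labelled running-gait motion
#'
#' Renders one subject performing one posture class as periodic
#' sinusoid-superposition joint trajectories on the 17-joint skeleton:
#' the pelvis translates forward at `cadence * strideLength` m/s with a
#' vertical bounce at twice the cadence; legs swing antiphase at the
#' cadence with knee flexion; arms counter-swing with a class-specific
#' phase; ankle orientations carry the class's frontal-plane
#' (inversion/eversion) and sagittal (forefoot) signatures. Smooth seeded
#' per-subject perturbations decorate every angle. Output is deterministic
#' given (subject, seed, spec).
#'
#' @param spec A class spec from [gaitClassSpecs()] or one of its names.
#' @param subject A [syntheticSubject()].
#' @param duration Sequence length, seconds (>= 3 gait cycles).
#' @param rateHz Frame rate, Hz.
#' @return A [SkeletonSequence-class].
#' @examples
#' frames <- generateGait("normal_running", syntheticSubject("S1"), 4, 50)
#' @export
generateGait <- function(spec, subject, duration = 10, rateHz = 100) {
  if (is.character(spec)) {
    specs <- gaitClassSpecs()
    if (!spec %in% names(specs))
      stop("unknown gait class '", spec, "'; known: ",
           paste(names(specs), collapse = ", "))
    spec <- specs[[spec]]
  }
  stopifnot(inherits(subject, "SyntheticSubject"))
  if (duration < 3 / spec$cadence)
    stop("duration must cover at least 3 gait cycles")
  set.seed(subject$seed)
  s <- subject$scale
  tm <- seq(0, duration, by = 1 / rateHz)
  nT <- length(tm)
  f <- spec$cadence
  w <- 2 * pi * f
  speed <- spec$cadence * spec$strideLength

  # segment lengths (m), scaled
  thigh <- 0.42 * s; shank <- 0.43 * s; hipW <- 0.10 * s
  trunkL <- 0.48 * s; neckL <- 0.10 * s; headL <- 0.12 * s
  shoulderW <- 0.19 * s; upperArm <- 0.30 * s; foreArm <- 0.27 * s
  hipH <- (thigh + shank) * 0.96 + spec$pelvisDrop

  nz <- function() .smoothNoise(tm, subject$noiseLevel)
  # joint angle signals (rad); right leg phase 0, left leg phase pi
  hipR <- spec$legAmp * sin(w * tm) + nz()
  hipL <- spec$legAmp * sin(w * tm + pi) + nz()
  kneeR <- spec$kneeAmp * (0.5 - 0.5 * cos(w * tm + 0.4)) + nz()
  kneeL <- spec$kneeAmp * (0.5 - 0.5 * cos(w * tm + pi + 0.4)) + nz()
  ankRollR <- spec$ankleRoll * sin(w * tm + 0.2) + nz()
  ankRollL <- spec$ankleRoll * sin(w * tm + pi + 0.2) + nz()
  contra <- if (isTRUE(spec$armSync)) 0 else pi
  armR <- spec$armAmp * sin(w * tm + spec$armPhase) + nz()
  armL <- spec$armAmp * sin(w * tm + spec$armPhase + contra) + nz()
  elbR <- 0.9 + 0.25 * sin(w * tm + spec$armPhase) + nz()
  elbL <- 0.9 + 0.25 * sin(w * tm + spec$armPhase + contra) + nz()
  trunkPitch <- spec$trunkLean + 0.03 * sin(2 * w * tm) + nz()
  # trunk counter-rotation: contralateral arm swing largely cancels the
  # legs' angular momentum; synchronous (discoordinated) arms leave it
  # uncompensated, so pelvis yaw and lateral sway grow markedly
  yawAmp <- (if (isTRUE(spec$armSync)) 0.32 else 0.06) * spec$armAmp
  swayAmp <- 0.02 * s + (if (isTRUE(spec$armSync)) 0.05 else 0)
  pelvisYaw <- yawAmp * sin(w * tm + 0.3) + nz()

  rootX <- speed * tm
  rootZ <- hipH + spec$bounceAmp * sin(2 * w * tm)
  rootY <- swayAmp * sin(w * tm) + 0.2 * nz()

  pos <- array(0, c(nT, 17L, 3L))
  ori <- array(0, c(nT, 17L, 4L)); ori[, , 1L] <- 1
  # joint indices per skeletonTopology()
  PELV <- 1L; HIP_R <- 2L; KNEE_R <- 3L; ANK_R <- 4L
  HIP_L <- 5L; KNEE_L <- 6L; ANK_L <- 7L
  SPINE <- 8L; NECK <- 9L; NOSE <- 10L; HEAD <- 11L
  SH_L <- 12L; EL_L <- 13L; WR_L <- 14L
  SH_R <- 15L; EL_R <- 16L; WR_R <- 17L

  Ry <- function(a) quatFromAxisAngle(c(0, 1, 0), a)
  Rx <- function(a) quatFromAxisAngle(c(1, 0, 0), a)

  Rz <- function(a) quatFromAxisAngle(c(0, 0, 1), a)

  for (k in seq_len(nT)) {
    root <- c(rootX[k], rootY[k], rootZ[k])
    qYaw <- Rz(pelvisYaw[k])
    pos[k, PELV, ] <- root
    ori[k, PELV, ] <- quatMultiply(qYaw, Ry(trunkPitch[k] * 0.3))

    legFK <- function(side, hipA, kneeA, roll) {
      hip <- root + quatRotate(qYaw, c(0, side * hipW, 0))
      qThigh <- quatMultiply(qYaw, Ry(hipA))
      knee <- hip + quatRotate(qThigh, c(0, 0, -thigh))
      qShank <- quatMultiply(qYaw, Ry(hipA + kneeA))
      ank <- knee + quatRotate(qShank, c(0, 0, -shank))
      qFoot <- quatMultiply(qYaw,
                            quatMultiply(Ry(hipA + kneeA + spec$anklePitch),
                                         Rx(roll)))
      list(hip = hip, knee = knee, ank = ank,
           qThigh = qThigh, qShank = qShank, qFoot = qFoot)
    }
    R <- legFK(-1, hipR[k], kneeR[k], ankRollR[k])
    L <- legFK(+1, hipL[k], kneeL[k], ankRollL[k])
    pos[k, HIP_R, ] <- R$hip; pos[k, KNEE_R, ] <- R$knee
    pos[k, ANK_R, ] <- R$ank
    ori[k, HIP_R, ] <- R$qThigh; ori[k, KNEE_R, ] <- R$qShank
    ori[k, ANK_R, ] <- R$qFoot
    pos[k, HIP_L, ] <- L$hip; pos[k, KNEE_L, ] <- L$knee
    pos[k, ANK_L, ] <- L$ank
    ori[k, HIP_L, ] <- L$qThigh; ori[k, KNEE_L, ] <- L$qShank
    ori[k, ANK_L, ] <- L$qFoot

    qTrunk <- quatMultiply(qYaw, Ry(trunkPitch[k]))
    spine <- root + quatRotate(qTrunk, c(0, 0, trunkL * 0.5))
    neck <- root + quatRotate(qTrunk, c(0, 0, trunkL))
    head <- neck + quatRotate(qTrunk, c(0, 0, neckL + headL))
    nose <- neck + quatRotate(qTrunk, c(0.06 * s, 0, neckL + headL * 0.6))
    pos[k, SPINE, ] <- spine; pos[k, NECK, ] <- neck
    pos[k, HEAD, ] <- head; pos[k, NOSE, ] <- nose
    ori[k, SPINE, ] <- qTrunk; ori[k, NECK, ] <- qTrunk
    ori[k, NOSE, ] <- qTrunk; ori[k, HEAD, ] <- qTrunk

    armFK <- function(side, shA, elA) {
      sh <- neck + c(0, side * shoulderW, 0)
      qUp <- Ry(shA)
      el <- sh + quatRotate(qUp, c(0, 0, -upperArm))
      qLo <- Ry(shA - elA)
      wr <- el + quatRotate(qLo, c(0, 0, -foreArm))
      list(sh = sh, el = el, wr = wr, qUp = qUp, qLo = qLo)
    }
    AR <- armFK(-1, armR[k], elbR[k])
    AL <- armFK(+1, armL[k], elbL[k])
    pos[k, SH_R, ] <- AR$sh; pos[k, EL_R, ] <- AR$el; pos[k, WR_R, ] <- AR$wr
    ori[k, SH_R, ] <- AR$qUp; ori[k, EL_R, ] <- AR$qLo; ori[k, WR_R, ] <- AR$qLo
    pos[k, SH_L, ] <- AL$sh; pos[k, EL_L, ] <- AL$el; pos[k, WR_L, ] <- AL$wr
    ori[k, SH_L, ] <- AL$qUp; ori[k, EL_L, ] <- AL$qLo; ori[k, WR_L, ] <- AL$qLo
  }

  # small fixed segment-CoM offsets
  offs <- matrix(0, 17L, 3L)
  offs[c(KNEE_R, KNEE_L), 3L] <- 0.2 * thigh
  offs[c(ANK_R, ANK_L), 1L] <- 0.05 * s
  offs[c(EL_R, EL_L, WR_R, WR_L), 3L] <- 0.1 * upperArm
  SkeletonSequence(time = tm, positions = pos, orientations = ori,
                   comOffsets = offs)
}

#' Sliding-window segmentation
#'
#' @param x `T0 x C` channel matrix.
#' @param width Window length in samples (default 256, about 2.56 s at
#'   100 Hz).
#' @param stride Hop between window starts (default 128).
#' @return `N x width x C` array of windows (N = floor((T0-width)/stride)+1).
#' @export
slidingWindows <- function(x, width = 256L, stride = 128L) {
  x <- as.matrix(x)
  T0 <- nrow(x)
  if (width > T0) stop("window longer than the series")
  n <- (T0 - width) %/% stride + 1L
  out <- array(0, c(n, width, ncol(x)))
  for (i in seq_len(n)) {
    a <- (i - 1L) * stride + 1L
    out[i, , ] <- x[a:(a + width - 1L), ]
  }
  out
}

#' Render the full windowed sensor dataset for a cohort
#'
#' For each subject x class, generates the gait motion, simulates the three
#' IMU placements (foot, tibia, femur: ankle, knee and hip mounts on the
#' right side) and the UWB-derived fused 3D pelvis positions, resamples all
#' channels to a common rate, concatenates them into a `T0 x C` matrix
#' (C = 3 placements x 9 IMU channels + 3 UWB = 30), cuts sliding windows
#' of `window` steps with stride `stride` *within each sequence only*, and
#' z-scores every channel with statistics from the training split alone.
#' The subject split is disjoint by construction.
#'
#' @param specs Class list (default all seven from [gaitClassSpecs()]).
#' @param subjects Cohort list (default [defaultCohort()]); >= 2 subjects.
#' @param config List of options: `duration` (s), `rateHz`, `window`,
#'   `stride`, `imuNoiseSd`, `uwbNoiseSd` (m), `uwbRateHz`, `placements`,
#'   `nTrain`, `nVal` (the remaining subjects form the test split), `seed`.
#' @return A [WindowedGaitData-class].
#' @export
renderGaitDataset <- function(specs = gaitClassSpecs(),
                              subjects = defaultCohort(),
                              config = list()) {
  cfg <- utils::modifyList(list(
    duration = 10, rateHz = 100, window = 256L, stride = 128L,
    imuNoiseSd = 0.05, uwbNoiseSd = 0.10, uwbRateHz = 10,
    placements = c(foot = "ankle_r", tibia = "knee_r", femur = "hip_r"),
    nTrain = NULL, nVal = 1L, seed = 1L
  ), config)
  if (length(subjects) < 2L)
    stop("need >= 2 subjects for a subject-independent split")
  if (is.null(cfg$nTrain))
    cfg$nTrain <- max(1L, length(subjects) - cfg$nVal - 1L)
  nS <- length(subjects)
  if (cfg$nTrain + cfg$nVal >= nS)
    stop("split leaves no test subject")
  splitOf <- c(rep("train", cfg$nTrain), rep("val", cfg$nVal),
               rep("test", nS - cfg$nTrain - cfg$nVal))

  anchors <- defaultAnchorLayout()
  allW <- list(); allLab <- character(); allSub <- character()
  allSplit <- character()
  for (si in seq_along(subjects)) {
    sub <- subjects[[si]]
    for (ci in seq_along(specs)) {
      cls <- names(specs)[ci]
      seqSeed <- sub$seed + ci
      subC <- syntheticSubject(sub$subjectId, sub$scale, sub$noiseLevel,
                               seed = seqSeed)
      frames <- generateGait(specs[[ci]], subC, duration = cfg$duration,
                             rateHz = cfg$rateHz)
      chan <- .renderChannels(frames, anchors, cfg, seed = seqSeed)
      win <- slidingWindows(chan, cfg$window, cfg$stride)
      allW[[length(allW) + 1L]] <- win
      n <- dim(win)[1L]
      allLab <- c(allLab, rep(cls, n))
      allSub <- c(allSub, rep(sub$subjectId, n))
      allSplit <- c(allSplit, rep(splitOf[si], n))
    }
  }
  W <- do.call(function(...) {
    mats <- list(...)
    n <- sum(vapply(mats, function(m) dim(m)[1L], 0L))
    out <- array(0, c(n, dim(mats[[1L]])[2L], dim(mats[[1L]])[3L]))
    at <- 1L
    for (m in mats) {
      k <- dim(m)[1L]
      out[at:(at + k - 1L), , ] <- m
      at <- at + k
    }
    out
  }, allW)

  # z-score from training statistics only, reused for val/test
  trIdx <- which(allSplit == "train")
  C <- dim(W)[3L]
  mu <- numeric(C); sdv <- numeric(C)
  for (c in seq_len(C)) {
    v <- as.numeric(W[trIdx, , c])
    mu[c] <- mean(v)
    sdv[c] <- stats::sd(v)
    if (sdv[c] < 1e-12) sdv[c] <- 1
    W[, , c] <- (W[, , c] - mu[c]) / sdv[c]
  }
  channels <- c(t(outer(names(cfg$placements),
                        c("ax", "ay", "az", "gx", "gy", "gz",
                          "mx", "my", "mz"), paste, sep = "_")),
                c("uwb_x", "uwb_y", "uwb_z"))
  new("WindowedGaitData",
      windows = W,
      labels = factor(allLab, levels = names(specs)),
      subject = allSub,
      split = factor(allSplit, levels = c("train", "val", "test")),
      channelNames = channels,
      normStats = list(mean = mu, sd = sdv))
}

# one sequence -> T0 x 30 channel matrix (3 IMUs + fused UWB positions)
.renderChannels <- function(frames, anchors, cfg, seed) {
  model <- imuErrorModel(noiseSd = cfg$imuNoiseSd)
  imus <- lapply(seq_along(cfg$placements), function(i)
    simulateImuStream(frames, cfg$placements[[i]], model = model,
                      rateHz = cfg$rateHz, seed = seed + 10L * i))
  tOut <- imus[[1L]]@time
  # UWB: noisy multilateration fixes on the pelvis at the UWB rate,
  # upsampled to the IMU rate
  set.seed(seed + 99L)
  tUwb <- seq(tOut[1L], tOut[length(tOut)], by = 1 / cfg$uwbRateHz)
  pelvis <- frames@positions[, 1L, ]
  pTrue <- apply(pelvis, 2L, function(col)
    stats::approx(frames@time, col, xout = tUwb, rule = 2L)$y)
  fixes <- matrix(0, length(tUwb), 3L)
  for (i in seq_along(tUwb)) {
    d <- sqrt(rowSums(sweep(as.matrix(anchors[, c("x", "y", "z")]),
                            2L, pTrue[i, ], "-")^2))
    r <- d + stats::rnorm(length(d), 0, cfg$uwbNoiseSd)
    fixes[i, ] <- multilaterate(anchors, r)$position
  }
  uwb <- apply(fixes, 2L, function(col)
    stats::approx(tUwb, col, xout = tOut, rule = 2L)$y)
  cbind(do.call(cbind, lapply(imus, streamData)), uwb)
}
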