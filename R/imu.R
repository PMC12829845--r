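# MEMS IMU error modelling: per-axis scale factors, zero bias, white noise,
# six-position calibration, and Earth-rate/transport-rate gyro compensation.

EARTH_RATE <- 7.2921150e-5   # rad/s
EARTH_RADIUS <- 6.371e6      # m, mean radius
GRAVITY <- 9.80665           # m/s^2

#' IMU error model (scale factors, zero bias, white noise)
#'
#' The deterministic part maps a true reading `x` to `diag(S) x + b`; white
#' Gaussian noise with per-axis standard deviation `noiseSd` is added on top.
#'
#' @param scale Length-3 vector of strictly positive per-axis scale factors
#'   (dimensionless).
#' @param bias Length-3 zero-bias vector, sensor units.
#' @param noiseSd Length-3 (or scalar) noise standard deviation, sensor units.
#' @return A list of class `ImuErrorModel`.
#' @examples
#' imuErrorModel()  # identity model
#' @export
imuErrorModel <- function(scale = c(1, 1, 1), bias = c(0, 0, 0), noiseSd = 0) {
  scale <- rep_len(as.numeric(scale), 3L)
  bias <- rep_len(as.numeric(bias), 3L)
  noiseSd <- rep_len(as.numeric(noiseSd), 3L)
  if (any(!is.finite(scale)) || any(scale <= 0))
    stop("scale factors must be finite and strictly positive")
  if (any(!is.finite(bias)) || any(!is.finite(noiseSd)) || any(noiseSd < 0))
    stop("bias must be finite and noiseSd non-negative")
  structure(list(scale = scale, bias = bias, noiseSd = noiseSd),
            class = "ImuErrorModel")
}

#' Apply an IMU error model to true readings
#'
#' Corrupts true tri-axial readings with the scale-factor and zero-bias
#' models plus seeded white Gaussian noise:
#' `out = diag(S) x + b + nu`, `nu ~ N(0, noiseSd^2)`.
#' With `noiseSd = 0` the mapping is the deterministic scale/bias
#' composition.
#'
#' @param trueReading Length-3 vector or `T x 3` matrix of true values.
#' @param model An [imuErrorModel()].
#' @param seed Integer RNG seed for the noise draw (ignored when noise is 0).
#' @return Corrupted reading(s), same shape as `trueReading`.
#' @export
applyImuErrors <- function(trueReading, model, seed = NULL) {
  stopifnot(inherits(model, "ImuErrorModel"))
  vec <- is.null(dim(trueReading))
  x <- if (vec) matrix(trueReading, ncol = 3L) else as.matrix(trueReading)
  if (ncol(x) != 3L) stop("trueReading must have 3 axes")
  if (!all(is.finite(x))) stop("trueReading has non-finite values")
  out <- sweep(x, 2L, model$scale, "*")
  out <- sweep(out, 2L, model$bias, "+")
  if (any(model$noiseSd > 0)) {
    if (!is.null(seed)) set.seed(as.integer(seed))
    noise <- matrix(stats::rnorm(length(x)), nrow(x), 3L)
    out <- out + sweep(noise, 2L, model$noiseSd, "*")
  }
  if (vec) as.numeric(out) else out
}

#' Invert an IMU error model (known parameters, noiseless correction)
#'
#' @param reading Corrupted reading(s), vector or `T x 3` matrix.
#' @param model The error model to remove.
#' @return Corrected reading(s): `diag(S)^-1 (reading - b)`.
#' @export
removeImuErrors <- function(reading, model) {
  stopifnot(inherits(model, "ImuErrorModel"))
  vec <- is.null(dim(reading))
  x <- if (vec) matrix(reading, ncol = 3L) else as.matrix(reading)
  out <- sweep(sweep(x, 2L, model$bias, "-"), 2L, model$scale, "/")
  if (vec) as.numeric(out) else out
}

#' Six-position accelerometer calibration
#'
#' Recovers per-axis scale factor and zero bias from static readings taken
#' with each sensor axis pointing up and down against gravity. With
#' `r_up = S*g + b` and `r_down = -S*g + b` for an axis, the closed forms are
#' `S = (r_up - r_down) / (2 g_ref)` and `b = (r_up + r_down) / 2`,
#' inverting the scale/bias model exactly in the noiseless case.
#'
#' @param staticReadings Named list of mean 3-vectors for the six
#'   axis-aligned orientations; names `"+x","-x","+y","-y","+z","-z"`
#'   denote which sensor axis points up.
#' @param gRef Reference gravity magnitude, default standard gravity.
#' @return An [imuErrorModel()] with the estimated `scale` and `bias`
#'   (noiseSd is set to 0; it is not identifiable from means).
#' @export
calibrateScaleBias <- function(staticReadings, gRef = GRAVITY) {
  need <- c("+x", "-x", "+y", "-y", "+z", "-z")
  if (!is.list(staticReadings) || !all(need %in% names(staticReadings)))
    stop("staticReadings must contain the six orientations: ",
         paste(setdiff(need, names(staticReadings)), collapse = ", "))
  scale <- numeric(3L); bias <- numeric(3L)
  axes <- c("x", "y", "z")
  for (k in 1:3) {
    up <- staticReadings[[paste0("+", axes[k])]][k]
    down <- staticReadings[[paste0("-", axes[k])]][k]
    scale[k] <- (up - down) / (2 * gRef)
    bias[k] <- (up + down) / 2
  }
  imuErrorModel(scale = scale, bias = bias, noiseSd = 0)
}

#' Simulate six-position static calibration readings
#'
#' Convenience generator for [calibrateScaleBias()] tests: for each of the
#' six axis-aligned orientations, draws `n` noisy static accelerometer
#' samples under a given error model and returns the per-orientation means.
#'
#' @param model True [imuErrorModel()].
#' @param n Samples averaged per orientation.
#' @param gRef Gravity magnitude.
#' @param seed RNG seed.
#' @return Named list of mean 3-vectors keyed by orientation.
#' @export
simulateSixPosition <- function(model, n = 1L, gRef = GRAVITY, seed = 1L) {
  set.seed(as.integer(seed))
  dirs <- list("+x" = c(1, 0, 0), "-x" = c(-1, 0, 0),
               "+y" = c(0, 1, 0), "-y" = c(0, -1, 0),
               "+z" = c(0, 0, 1), "-z" = c(0, 0, -1))
  lapply(dirs, function(d) {
    truth <- matrix(rep(d * gRef, each = n), n, 3L)
    colMeans(applyImuErrors(truth, model, seed = NULL))
  })
}

#' Geodetic state for gyroscope Earth-rate compensation
#'
#' @param latitude Geodetic latitude, radians, in `[-pi/2, pi/2]`.
#' @param altitude Altitude above the reference sphere, meters.
#' @param vN,vE North and east velocity, m/s.
#' @param attitude Body orientation as a unit quaternion (navigation-to-body
#'   rotation applied via its matrix transpose) or a 3x3 rotation matrix
#'   `R_b_n` mapping navigation-frame vectors into the body frame.
#' @param omegaNb Angular velocity of the navigation frame relative to the
#'   body, expressed in body coordinates (rad/s 3-vector).
#' @param earthRate Earth rotation rate, rad/s.
#' @param earthRadius Earth radius, meters.
#' @return A list of class `GeodeticState`.
#' @export
geodeticState <- function(latitude = 0, altitude = 0, vN = 0, vE = 0,
                          attitude = diag(3), omegaNb = c(0, 0, 0),
                          earthRate = EARTH_RATE, earthRadius = EARTH_RADIUS) {
  if (!is.finite(latitude) || abs(latitude) > pi / 2)
    stop("latitude must lie in [-pi/2, pi/2]")
  if (is.numeric(attitude) && length(attitude) == 4L)
    attitude <- t(quatToRotmat(attitude))  # body <- navigation
  if (!is.matrix(attitude) || !identical(dim(attitude), c(3L, 3L)))
    stop("attitude must be a unit quaternion or 3x3 matrix")
  structure(list(latitude = latitude, altitude = altitude, vN = vN, vE = vE,
                 Rbn = attitude, omegaNb = rep_len(omegaNb, 3L),
                 earthRate = earthRate, earthRadius = earthRadius),
            class = "GeodeticState")
}

#' Earth-rate and transport-rate gyroscope compensation term
#'
#' Evaluates the angular velocity a perfect gyroscope reports for a body that
#' is attitude-stationary over the rotating Earth while translating over its
#' curved surface: the Earth-rate plus transport-rate vector in the local
#' ENU navigation frame,
#' `omega_n = ( -V_N/(R+h), omega_ie*cos(lat) + V_E/(R+h),
#'              omega_ie*sin(lat) )`,
#' rotated into the body frame and augmented with the navigation-relative
#' body rate: `omega_b_ib = R_b_n * omega_n + omega_n_nb`. At rest with
#' identity attitude this reduces to `(0, omega_ie*cos(lat),
#' omega_ie*sin(lat))`, whose magnitude is always `omega_ie`.
#'
#' @param state A [geodeticState()].
#' @return Length-3 angular rate, rad/s, body frame.
#' @export
earthRateCompensation <- function(state) {
  stopifnot(inherits(state, "GeodeticState"))
  Rh <- state$earthRadius + state$altitude
  omegaN <- c(-state$vN / Rh,
              state$earthRate * cos(state$latitude) + state$vE / Rh,
              state$earthRate * sin(state$latitude))
  as.numeric(state$Rbn %*% omegaN) + state$omegaNb
}

#' Simulate an IMU stream from a skeleton sequence
#'
#' Renders the 9 channels of a body-mounted MEMS IMU (tri-axial
#' accelerometer, gyroscope, magnetometer) at a chosen joint. World-frame
#' linear acceleration comes from second-order central differences of the
#' joint position; the accelerometer reports specific force
#' `f_b = R_b^T (a_world - g)` with gravity `(0, 0, -9.80665)` m/s^2 (ENU),
#' so a stationary, level sensor reads `(0, 0, +g)`. Angular rate comes from
#' the quaternion derivative (`omega = 2 * qdot (x) q^-1`, central
#' differences, body frame). The magnetometer reports the reference field
#' rotated into the body frame. All channels are resampled to `rateHz` and
#' passed through the error model.
#'
#' @param frames A [SkeletonSequence-class] (at least 3 frames).
#' @param placement Joint name from [skeletonTopology()].
#' @param model An [imuErrorModel()] applied to each channel triple.
#' @param rateHz Output sampling rate, Hz.
#' @param magRef Reference magnetic field vector in the navigation frame
#'   (arbitrary units).
#' @param seed RNG seed for the error-model noise.
#' @return A [SensorStream-class] with channels
#'   `ax, ay, az, gx, gy, gz, mx, my, mz`.
#' @export
simulateImuStream <- function(frames, placement, model = imuErrorModel(),
                              rateHz = 100, magRef = c(0.2, 0.05, -0.4),
                              seed = 1L) {
  stopifnot(is(frames, "SkeletonSequence"))
  if (rateHz <= 0) stop("rateHz must be positive")
  topo <- skeletonTopology()
  j <- match(placement, topo$joints)
  if (is.na(j)) stop("unknown placement '", placement, "'")
  nT <- nFrames(frames)
  if (nT < 3L) stop("need at least 3 frames to differentiate")
  tm <- frames@time
  pos <- frames@positions[, j, , drop = TRUE]
  qs <- frames@orientations[, j, , drop = TRUE]

  # world-frame acceleration by central second differences (interior frames)
  aw <- matrix(0, nT, 3L)
  for (t in 2:(nT - 1L)) {
    dt1 <- tm[t] - tm[t - 1L]; dt2 <- tm[t + 1L] - tm[t]
    aw[t, ] <- 2 * (dt1 * pos[t + 1L, ] - (dt1 + dt2) * pos[t, ] +
                    dt2 * pos[t - 1L, ]) / (dt1 * dt2 * (dt1 + dt2))
  }
  aw[1L, ] <- aw[2L, ]; aw[nT, ] <- aw[nT - 1L, ]

  # body angular rate from quaternion central differences: omega_b = 2 q^-1 qdot
  gw <- matrix(0, nT, 3L)
  for (t in 2:(nT - 1L)) {
    dq <- (qs[t + 1L, ] - qs[t - 1L, ]) / (tm[t + 1L] - tm[t - 1L])
    wq <- 2 * quatMultiply(quatInverse(quatNormalize(qs[t, ])), dq)
    gw[t, ] <- wq[2L:4L]
  }
  gw[1L, ] <- gw[2L, ]; gw[nT, ] <- gw[nT - 1L, ]

  g <- c(0, 0, -GRAVITY)
  acc <- matrix(0, nT, 3L)
  mag <- matrix(0, nT, 3L)
  for (t in seq_len(nT)) {
    Rb <- quatToRotmat(qs[t, ])      # body -> world
    acc[t, ] <- as.numeric(t(Rb) %*% (aw[t, ] - g))
    mag[t, ] <- as.numeric(t(Rb) %*% magRef)
  }

  # resample all channels to the requested uniform rate
  tOut <- seq(tm[1L], tm[nT], by = 1 / rateHz)
  resamp <- function(x) apply(x, 2L, function(col)
    stats::approx(tm, col, xout = tOut, rule = 2L)$y)
  acc <- resamp(acc); gyr <- resamp(gw); mag <- resamp(mag)

  acc <- applyImuErrors(acc, model, seed = seed)
  gyr <- applyImuErrors(gyr, model, seed = if (is.null(seed)) NULL else seed + 1L)
  mag <- applyImuErrors(mag, model, seed = if (is.null(seed)) NULL else seed + 2L)

  data <- cbind(acc, gyr, mag)
  colnames(data) <- c("ax", "ay", "az", "gx", "gy", "gz",
                      "mx", "my", "mz")
  SensorStream(time = tOut, data = data, rate = rateHz, placement = placement,
               meta = list(model = model, seed = seed, magRef = magRef))
}

#' Read/write a SensorStream as CSV
#'
#' Columns: `time_s` followed by the channel columns.
#'
#' @param x A [SensorStream-class].
#' @param path File path.
#' @param rate,placement Stream metadata used on read.
#' @return `readSensorCsv` returns a `SensorStream`; `writeSensorCsv`
#'   returns `path` invisibly.
#' @export
writeSensorCsv <- function(x, path) {
  stopifnot(is(x, "SensorStream"))
  df <- data.frame(time_s = x@time, x@data, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeSensorCsv
#' @export
readSensorCsv <- function(path, rate = NULL, placement = "unknown") {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"time_s" %in% names(df)) stop("sensor CSV must have a time_s column")
  tm <- df$time_s
  dat <- as.matrix(df[setdiff(names(df), "time_s")])
  if (is.null(rate))
    rate <- if (length(tm) > 1L) 1 / stats::median(diff(tm)) else 1
  SensorStream(time = tm, data = dat, rate = rate, placement = placement)
}
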