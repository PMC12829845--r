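test_that("identity error model returns the input unchanged", {
  m <- imuErrorModel()
  x <- c(0.3, -1.2, 9.8)
  expect_identical(applyImuErrors(x, m), x)
})

test_that("scale/bias composition follows the error equations", {
  m <- imuErrorModel(scale = c(2, 2, 2), bias = c(1, 0, 0))
  expect_equal(applyImuErrors(c(1, 1, 1), m), c(3, 2, 2))
})

test_that("seeded noise has the modelled mean (law of large numbers)", {
  m <- imuErrorModel(scale = c(1.1, 0.9, 1.0), bias = c(0.2, -0.1, 0),
                     noiseSd = 0.1)
  n <- 1e4
  x <- matrix(rep(c(1, 2, 3), each = n), n, 3L)
  out <- applyImuErrors(x, m, seed = 7L)
  resid <- out - sweep(sweep(x, 2L, m$scale, "*"), 2L, m$bias, "+")
  tol <- 4 * 0.1 / sqrt(n)
  expect_true(all(abs(colMeans(resid)) < tol))
})

test_that("applying then removing a known error model is the identity", {
  set.seed(151)
  m <- imuErrorModel(scale = c(1.05, 0.93, 1.2), bias = c(0.4, -0.2, 0.1))
  x <- matrix(stats::rnorm(30), 10L, 3L)
  expect_equal(removeImuErrors(applyImuErrors(x, m), m), x,
               tolerance = 1e-12)
})

test_that("error model rejects non-positive scale factors", {
  expect_error(imuErrorModel(scale = c(1, 0, 1)), "positive")
  expect_error(imuErrorModel(scale = c(1, -2, 1)), "positive")
})

test_that("six-position calibration inverts the simulator exactly when noiseless", {
  truth <- imuErrorModel(scale = c(1.02, 0.98, 1.01),
                         bias = c(0.05, -0.03, 0.10))
  est <- calibrateScaleBias(simulateSixPosition(truth, n = 1L))
  expect_equal(est$scale, truth$scale, tolerance = 1e-12)
  expect_equal(est$bias, truth$bias, tolerance = 1e-12)
  # identity truth -> identity estimate
  estI <- calibrateScaleBias(simulateSixPosition(imuErrorModel(), n = 1L))
  expect_equal(estI$scale, c(1, 1, 1), tolerance = 1e-12)
  expect_equal(estI$bias, c(0, 0, 0), tolerance = 1e-12)
})

test_that("calibration recovers parameters within 1% from noisy data", {
  truth <- imuErrorModel(scale = c(1.02, 0.98, 1.01),
                         bias = c(0.05, -0.03, 0.10), noiseSd = 0.01)
  est <- calibrateScaleBias(simulateSixPosition(truth, n = 200L, seed = 9L))
  expect_true(all(abs(est$scale - truth$scale) / truth$scale < 0.01))
  expect_true(all(abs(est$bias - truth$bias) < 0.01))
})

test_that("calibration error decreases with the per-orientation sample count", {
  truth <- imuErrorModel(scale = c(1.05, 0.95, 1.02),
                         bias = c(0.1, -0.05, 0.02), noiseSd = 0.05)
  rmse <- vapply(c(10L, 100L, 1000L), function(n) {
    errs <- vapply(1:8, function(s) {
      est <- calibrateScaleBias(simulateSixPosition(truth, n = n,
                                                    seed = 1000L + s))
      sqrt(mean(c(est$scale - truth$scale, est$bias - truth$bias)^2))
    }, numeric(1L))
    mean(errs)
  }, numeric(1L))
  expect_true(all(diff(rmse) < 0))
})

test_that("calibration demands all six orientations", {
  r <- simulateSixPosition(imuErrorModel(), n = 1L)
  expect_error(calibrateScaleBias(r[-1L]), "six")
})

test_that("earth-rate compensation at the pole and equator", {
  pole <- geodeticState(latitude = pi / 2)
  expect_equal(earthRateCompensation(pole), c(0, 0, 7.2921150e-5),
               tolerance = 1e-18)
  eq <- geodeticState(latitude = 0)
  expect_equal(earthRateCompensation(eq), c(0, 7.2921150e-5, 0),
               tolerance = 1e-18)
})

test_that("earth-rate compensation matches a term-by-term transcription", {
  set.seed(161)
  for (k in 1:50) {
    lat <- stats::runif(1L, -pi / 2, pi / 2)
    st <- geodeticState(latitude = lat, altitude = stats::runif(1L, 0, 2000),
                        vN = stats::rnorm(1L, 0, 5), vE = stats::rnorm(1L, 0, 5),
                        attitude = randomUnitQuat(),
                        omegaNb = stats::rnorm(3L, 0, 0.1))
    # independent transcription of the compensation formula
    Rh <- st$earthRadius + st$altitude
    expected <- as.numeric(st$Rbn %*% c(-st$vN / Rh,
                                        st$earthRate * cos(lat) + st$vE / Rh,
                                        st$earthRate * sin(lat))) + st$omegaNb
    expect_equal(earthRateCompensation(st), expected, tolerance = 1e-15)
  }
})

test_that("at rest the compensation magnitude is the Earth rate at any latitude", {
  for (lat in seq(-pi / 2, pi / 2, length.out = 10L)) {
    st <- geodeticState(latitude = lat, attitude = randomUnitQuat())
    expect_equal(sqrt(sum(earthRateCompensation(st)^2)), 7.2921150e-5,
                 tolerance = 1e-12)
  }
})

test_that("latitude outside [-pi/2, pi/2] is rejected", {
  expect_error(geodeticState(latitude = 2), "latitude")
})

staticFrames <- function(nT, dt = 0.01) {
  pos <- array(0, c(nT, 17L, 3L))
  pos[, , 3L] <- 1  # all joints at 1 m, no motion
  SkeletonSequence(time = (seq_len(nT) - 1L) * dt, positions = pos)
}

test_that("stationary level IMU reads +g on z and zero gyro", {
  st <- simulateImuStream(staticFrames(50L), "pelvis",
                          model = imuErrorModel(), seed = 1L)
  d <- streamData(st)
  expect_equal(max(abs(d[, c("ax", "ay")])), 0, tolerance = 1e-6)
  expect_equal(unname(d[10L, "az"]), 9.80665, tolerance = 1e-6)
  expect_equal(max(abs(d[, c("gx", "gy", "gz")])), 0, tolerance = 1e-6)
})

test_that("uniform rotation about z reproduces the spin rate on the gyro", {
  nT <- 201L; dt <- 0.005
  Omega <- 3  # rad/s
  tm <- (seq_len(nT) - 1L) * dt
  ori <- array(0, c(nT, 17L, 4L))
  for (t in seq_len(nT)) {
    q <- quatFromAxisAngle(c(0, 0, 1), Omega * tm[t])
    for (j in 1:17) ori[t, j, ] <- q
  }
  fr <- SkeletonSequence(time = tm, positions = array(0, c(nT, 17L, 3L)),
                         orientations = ori)
  st <- simulateImuStream(fr, "pelvis", rateHz = 200, seed = 1L)
  gz <- streamData(st)[, "gz"]
  mid <- seq(20L, length(gz) - 20L)
  expect_true(all(abs(gz[mid] - Omega) < 1e-3 * Omega))
})

test_that("constant world acceleration appears as specific force", {
  nT <- 101L; dt <- 0.01
  a <- c(0.7, 0, 0)
  tm <- (seq_len(nT) - 1L) * dt
  pos <- array(0, c(nT, 17L, 3L))
  for (t in seq_len(nT)) pos[t, , 1L] <- 0.5 * a[1L] * tm[t]^2
  fr <- SkeletonSequence(time = tm, positions = pos)
  st <- simulateImuStream(fr, "wrist_l", rateHz = 100, seed = 1L)
  d <- streamData(st)
  mid <- seq(10L, nrow(d) - 10L)
  expect_equal(unname(stats::median(d[mid, "ax"])), a[1L], tolerance = 1e-6)
  expect_equal(unname(stats::median(d[mid, "az"])), 9.80665,
               tolerance = 1e-6)
})

test_that("sensor stream CSV round-trips", {
  st <- simulateImuStream(staticFrames(20L), "pelvis", seed = 2L)
  path <- withr::local_tempfile(fileext = ".csv")
  writeSensorCsv(st, path)
  back <- readSensorCsv(path, rate = 100, placement = "pelvis")
  expect_equal(streamData(back), streamData(st), tolerance = 1e-6)
})

test_that("too-short sequences are rejected", {
  expect_error(simulateImuStream(staticFrames(2L), "pelvis"), "3 frames")
  expect_error(simulateImuStream(staticFrames(10L), "no_such_joint"),
               "placement")
})
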