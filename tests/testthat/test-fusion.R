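test_that("dead reckoning: zero acceleration holds position", {
  dr <- deadReckon(c(1, 2, 3), c(0, 0, 0),
                   matrix(0, 10L, 3L), dt = 0.1)
  expect_true(all(dr$position == rep(c(1, 2, 3), each = 11L)))
})

test_that("dead reckoning matches an independent loop of the recursion", {
  a <- matrix(rep(c(1, 0, 0), 10L), ncol = 3L, byrow = TRUE)
  dr <- deadReckon(c(0, 0, 0), c(0, 0, 0), a, dt = 0.1)
  # independent transcription: v_k = v_{k-1} + dt a_k;
  # p_k = p_{k-1} + v_{k-1} dt + 0.5 dt^2 a_k  (a_k at the step end)
  v <- 0; p <- 0
  for (k in 1:10) {
    pNew <- p + v * 0.1 + 0.5 * 0.01 * 1
    v <- v + 0.1 * 1
    p <- pNew
  }
  expect_equal(unname(dr$position[11L, 1L]), p, tolerance = 1e-12)
  expect_equal(unname(dr$velocity[11L, 1L]), v, tolerance = 1e-12)
})

test_that("a constant accelerometer bias drifts quadratically", {
  b <- 0.1; Tend <- 10; dt <- 0.01
  a <- matrix(rep(c(b, 0, 0), Tend / dt), ncol = 3L, byrow = TRUE)
  dr <- deadReckon(c(0, 0, 0), c(0, 0, 0), a, dt)
  expect_equal(unname(dr$position[nrow(dr$position), 1L]),
               0.5 * b * Tend^2, tolerance = 0.02)
})

test_that("dead reckoning rejects non-finite acceleration", {
  expect_error(deadReckon(c(0, 0, 0), c(0, 0, 0),
                          matrix(c(NA, 0, 0), 1L), 0.1), "non-finite")
})

scalarModel <- function(dt = 1, q = 0, r = 1) {
  list(F = matrix(1), B = matrix(0), C = matrix(1), Q = matrix(q),
       R = matrix(r), dt = dt)
}

test_that("scalar update: equal prior and observation variance halves it", {
  st <- list(x = matrix(5), P = matrix(1))
  out <- ekfStep(st, scalarModel(q = 0, r = 1), u = 0, z = 5)
  expect_equal(out$P[1L, 1L], 0.5, tolerance = 1e-12)
  expect_equal(out$x[1L, 1L], 5, tolerance = 1e-12)
})

test_that("predict-only steps never shrink the covariance when Q >= 0", {
  st <- list(x = matrix(0), P = matrix(1))
  tr <- numeric(10L)
  for (k in 1:10) {
    st <- ekfStep(st, scalarModel(q = 0.1), u = 0, z = NULL)
    tr[k] <- st$P[1L, 1L]
  }
  expect_true(all(diff(c(1, tr)) >= 0))
})

test_that("filtering beats the raw observations on tracking RMSE", {
  set.seed(221)
  K <- 200L; dt <- 0.1
  model <- fusionModel(dt, qAccel = 0.05, rObs = 0.5^2)
  a <- matrix(stats::rnorm(K * 3, 0, 0.05), K, 3L)
  truth <- deadReckon(c(0, 0, 0), c(0.5, 0, 0), a, dt)$position[-1L, ]
  obs <- truth + matrix(stats::rnorm(K * 3, 0, 0.5), K, 3L)
  fwd <- runForwardFilter(c(0, 0, 0, 0.5, 0, 0), diag(1e-2, 6L), model, a,
                          obs)
  est <- t(vapply(fwd, function(s) as.numeric(s$x)[1:3], numeric(3L)))
  rmse <- function(x) sqrt(mean(rowSums((x - truth)^2)))
  expect_lt(rmse(est), rmse(obs))
})

test_that("covariances stay symmetric PSD over many random steps", {
  set.seed(231)
  model <- fusionModel(0.01, qAccel = 1, rObs = 0.01)
  st <- list(x = matrix(0, 6L), P = diag(0.1, 6L))
  minEig <- Inf
  for (k in 1:2000) {
    z <- if (k %% 10 == 0) stats::rnorm(3L) else NULL
    st <- ekfStep(st, model, u = stats::rnorm(3L), z = z)
    expect_equal(st$P, t(st$P))
    minEig <- min(minEig, min(eigen(st$P, symmetric = TRUE,
                                    only.values = TRUE)$values))
  }
  expect_gt(minEig, -1e-10)
})

test_that("final filtered state matches batch least squares (information form)", {
  set.seed(241)
  K <- 25L
  model <- scalarModel(q = 0, r = 0.5^2)
  obs <- matrix(stats::rnorm(K, 3, 0.5), K, 1L)
  st <- list(x = matrix(0), P = matrix(100))
  for (k in seq_len(K)) st <- ekfStep(st, model, u = 0, z = obs[k, ])
  # information-form batch solution for a static state
  info <- 1 / 100 + K / 0.25
  xBatch <- (0 / 100 + sum(obs) / 0.25) / info
  expect_equal(st$x[1L, 1L], xBatch, tolerance = 1e-8)
  expect_equal(st$P[1L, 1L], 1 / info, tolerance = 1e-8)
})

test_that("RTS boundary: smoothed final state equals filtered final state", {
  set.seed(251)
  model <- fusionModel(0.1, qAccel = 0.1, rObs = 0.1)
  a <- matrix(stats::rnorm(30L), 10L, 3L)
  obs <- matrix(stats::rnorm(30L), 10L, 3L)
  fwd <- runForwardFilter(rep(0, 6L), diag(1, 6L), model, a, obs)
  sm <- rtsSmooth(fwd)
  expect_equal(sm$x[10L, ], as.numeric(fwd[[10L]]$x), tolerance = 1e-12)
  expect_equal(sm$P[[10L]], fwd[[10L]]$P, tolerance = 1e-12)
})

test_that("smoothed variance never exceeds filtered variance", {
  set.seed(261)
  model <- fusionModel(0.05, qAccel = 0.5, rObs = 0.2)
  K <- 50L
  a <- matrix(stats::rnorm(K * 3), K, 3L)
  obs <- matrix(stats::rnorm(K * 3, 0, 0.4), K, 3L)
  obs[sample(K, 20L), ] <- NA    # intermittent observations
  fwd <- runForwardFilter(rep(0, 6L), diag(1, 6L), model, a, obs)
  sm <- rtsSmooth(fwd)
  for (k in seq_len(K))
    expect_lte(sum(diag(sm$P[[k]])), sum(diag(fwd[[k]]$P)) + 1e-12)
})

test_that("two-step scalar RTS matches hand-computed gain and state", {
  # hand-set forward pass: P1+ = 2, P2- = 5, F = 1.5
  model <- scalarModel()
  model$F <- matrix(1.5)
  fwd <- list(
    list(x = matrix(1.0), P = matrix(2.0), xPred = matrix(0.8),
         PPred = matrix(3.0)),
    list(x = matrix(2.2), P = matrix(1.1), xPred = matrix(1.9),
         PPred = matrix(5.0))
  )
  attr(fwd, "model") <- model
  sm <- rtsSmooth(fwd)
  # K1 = P1+ F' (P2-)^-1 = 2 * 1.5 / 5 = 0.6
  expect_equal(sm$gain[[1L]][1L, 1L], 0.6, tolerance = 1e-12)
  # x1s = x1+ + K1 (x2s - x2-) = 1.0 + 0.6 * (2.2 - 1.9) = 1.18
  expect_equal(sm$x[1L, 1L], 1.18, tolerance = 1e-12)
  # P1s = P1+ + K1 (P2s - P2-) K1 = 2 + 0.36 * (1.1 - 5) = 0.596
  expect_equal(sm$P[[1L]][1L, 1L], 0.596, tolerance = 1e-12)
})

test_that("smoothing never hurts: RMSE(RTS) <= RMSE(EKF) on 20 seeds", {
  for (seed in 1:20) {
    set.seed(seed)
    K <- 60L; dt <- 0.1
    qAccel <- 0.2
    model <- fusionModel(dt, qAccel = qAccel, rObs = 0.3^2)
    aCmd <- matrix(stats::rnorm(K * 3, 0, 0.3), K, 3L)
    aTrue <- aCmd + matrix(stats::rnorm(K * 3, 0, sqrt(qAccel)), K, 3L)
    truth <- deadReckon(c(0, 0, 0), c(0, 0, 0), aTrue, dt)$position[-1L, ]
    obs <- truth + matrix(stats::rnorm(K * 3, 0, 0.3), K, 3L)
    fwd <- runForwardFilter(rep(0, 6L), diag(0.01, 6L), model, aCmd, obs)
    est <- t(vapply(fwd, function(s) as.numeric(s$x)[1:3], numeric(3L)))
    sm <- rtsSmooth(fwd)$x[, 1:3]
    rmse <- function(x) sqrt(mean(rowSums((x - truth)^2)))
    expect_lte(rmse(sm), rmse(est) + 1e-9)
  }
})

test_that("fusion bounds the drift a biased IMU accumulates", {
  set.seed(271)
  K <- 1000L; dt <- 0.01
  truth <- matrix(0, K, 3L)
  accel <- matrix(rep(c(0.1, 0, 0), K), ncol = 3L, byrow = TRUE)  # bias only
  tU <- seq(0.1, K * dt, by = 0.1)
  obs <- matrix(stats::rnorm(length(tU) * 3L, 0, 0.1), ncol = 3L)
  fz <- fuseTrajectory(accel, tU, obs, config = list(smooth = TRUE),
                       truth = truth, dt = dt)
  terminal <- sqrt(sum(as.numeric(
    fz$trajectory[nrow(fz$trajectory), c("px", "py", "pz")])^2))
  expect_lt(terminal, 3 * 0.1)
  # while pure dead reckoning has drifted ~ 0.5 * b * T^2 = 5 m
  dr <- deadReckon(c(0, 0, 0), c(0, 0, 0), accel, dt)
  expect_gt(sqrt(sum(dr$position[K + 1L, ]^2)), 4.5)
})

test_that("perfect sensors reproduce the truth through the fusion chain", {
  K <- 200L; dt <- 0.01
  tm <- dt * seq_len(K)
  a <- cbind(1 * cos(tm), 0 * tm, 0 * tm)   # known smooth acceleration
  truth <- deadReckon(c(0, 0, 0), c(0, 0, 0), a, dt)$position[-1L, ]
  fz <- fuseTrajectory(a, tm, truth,
                       config = list(smooth = FALSE, rObs = 1e-12,
                                     P0 = diag(1e-12, 6L)),
                       truth = truth, dt = dt)
  expect_lt(fz$report$mean3dError, 1e-6)
})

test_that("fusion rejects non-overlapping streams", {
  a <- matrix(0, 100L, 3L)
  expect_error(fuseTrajectory(a, uwbTime = c(100, 101),
                              uwbPositions = matrix(0, 2L, 3L), dt = 0.01),
               "overlap")
})

test_that("the error report reproduces a known constant offset", {
  truth <- matrix(stats::rnorm(300L), 100L, 3L)
  est <- truth + rep(c(0.3, 0.4, 0), each = 100L)
  rep <- positioningErrorReport(est, truth)
  expect_equal(rep$mean3dError, 0.5, tolerance = 1e-12)
  expect_equal(rep$sd3dError, 0, tolerance = 1e-12)
  expect_equal(rep$fractionBelow, 1.0)
  expect_equal(rep$perAxis$mean_error_m, c(0.3, 0.4, 0), tolerance = 1e-12)
})
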