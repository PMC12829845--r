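# MEMS-UWB trajectory fusion: constant-acceleration-input dead reckoning,
# linear Kalman predict/update on a position+velocity state, and the
# Rauch-Tung-Striebel backward smoother.

#' Inertial dead reckoning
#'
#' Integrates gravity-compensated acceleration with the discrete recursion
#' `v_k = v_{k-1} + dt * a_k` and
#' `p_k = p_{k-1} + v_{k-1} dt + 0.5 dt^2 a_k`
#' (the acceleration sample at the *end* of the step drives both updates).
#'
#' @param p0,v0 Initial position and velocity (3-vectors, m and m/s).
#' @param accel `K x 3` matrix of gravity-compensated accelerations
#'   (m/s^2), one row per step.
#' @param dt Step length, seconds.
#' @return A list with `position` and `velocity`, `(K+1) x 3` matrices
#'   including the initial state in row 1.
#' @examples
#' deadReckon(c(0, 0, 0), c(0, 0, 0), matrix(rep(c(1, 0, 0), 10),
#'            ncol = 3, byrow = TRUE), dt = 0.1)
#' @export
deadReckon <- function(p0, v0, accel, dt) {
  if (dt <= 0) stop("dt must be positive")
  accel <- as.matrix(accel)
  if (ncol(accel) != 3L) stop("accel must be K x 3")
  if (!all(is.finite(accel))) stop("accel has non-finite values")
  K <- nrow(accel)
  p <- matrix(0, K + 1L, 3L); v <- matrix(0, K + 1L, 3L)
  p[1L, ] <- p0; v[1L, ] <- v0
  for (k in seq_len(K)) {
    v[k + 1L, ] <- v[k, ] + dt * accel[k, ]
    p[k + 1L, ] <- p[k, ] + v[k, ] * dt + 0.5 * dt^2 * accel[k, ]
  }
  colnames(p) <- colnames(v) <- c("x", "y", "z")
  list(position = p, velocity = v)
}

#' Construct the constant-acceleration-input filter model
#'
#' State is `x = [p; v]` (6D). The transition pair
#' `F = [[I, dt I], [0, I]]`, `B = [[0.5 dt^2 I], [dt I]]` reproduces the
#' dead-reckoning recursion exactly; `C` observes the position block.
#' Process noise uses the white-acceleration discretization
#' `Q = q * [[dt^4/4 I, dt^3/2 I], [dt^3/2 I, dt^2 I]]` with spectral
#' density `q` ((m/s^2)^2 / Hz).
#'
#' @param dt Step length, seconds.
#' @param qAccel Process-noise spectral density.
#' @param rObs Observation noise variance per axis (m^2); default `0.1^2`
#'   matching 10 cm UWB ranging accuracy.
#' @return A list with matrices `F`, `B`, `C`, `Q`, `R` and `dt`.
#' @export
fusionModel <- function(dt, qAccel = 0.5, rObs = 0.1^2) {
  I3 <- diag(3)
  Fm <- rbind(cbind(I3, dt * I3), cbind(matrix(0, 3, 3), I3))
  Bm <- rbind(0.5 * dt^2 * I3, dt * I3)
  Cm <- cbind(I3, matrix(0, 3, 3))
  Qm <- qAccel * rbind(cbind(dt^4 / 4 * I3, dt^3 / 2 * I3),
                       cbind(dt^3 / 2 * I3, dt^2 * I3))
  Rm <- diag(rep(rObs, 3L))
  list(F = Fm, B = Bm, C = Cm, Q = Qm, R = Rm, dt = dt)
}

#' One Kalman predict(/update) step
#'
#' Predict: `x <- F x + B u`, `P <- F P F' + Q`. If an observation `z`
#' (position 3-vector) is supplied, the standard gain/update follows with
#' `C` and `R`. The covariance is re-symmetrized after every step and the
#' update uses the Joseph form for positive semi-definiteness.
#'
#' @param state List with `x` (state vector) and `P` (covariance).
#' @param model A [fusionModel()] (or any list with conformable
#'   `F, B, C, Q, R`).
#' @param u Control input (gravity-compensated acceleration 3-vector).
#' @param z Optional position observation; `NULL` for predict-only.
#' @return The updated state list, with `xPred`/`PPred` (a-priori) and
#'   `x`/`P` (a-posteriori) both retained for smoothing.
#' @export
ekfStep <- function(state, model, u = c(0, 0, 0), z = NULL) {
  x <- model$F %*% state$x + model$B %*% u
  P <- model$F %*% state$P %*% t(model$F) + model$Q
  P <- (P + t(P)) / 2
  xPred <- x; PPred <- P
  if (!is.null(z)) {
    S <- model$C %*% P %*% t(model$C) + model$R
    if (rcond(S) < .Machine$double.eps)
      stop("innovation covariance is numerically singular")
    Kg <- P %*% t(model$C) %*% solve(S)
    x <- x + Kg %*% (as.numeric(z) - model$C %*% x)
    IKC <- diag(nrow(P)) - Kg %*% model$C
    P <- IKC %*% P %*% t(IKC) + Kg %*% model$R %*% t(Kg)
    P <- (P + t(P)) / 2
  }
  list(x = x, P = P, xPred = xPred, PPred = PPred)
}

#' Run the forward Kalman filter over an acceleration/observation sequence
#'
#' @param x0 Initial state (6-vector `[p; v]`).
#' @param P0 Initial covariance (6x6).
#' @param model A [fusionModel()].
#' @param accel `K x 3` control inputs.
#' @param obs `K x 3` matrix of position observations with `NA` rows where
#'   no observation is available, or `NULL` for pure prediction.
#' @return A list of per-step records (`x`, `P`, `xPred`, `PPred`), plus
#'   the initial state as attribute `init`.
#' @export
runForwardFilter <- function(x0, P0, model, accel, obs = NULL) {
  K <- nrow(accel)
  state <- list(x = matrix(x0, ncol = 1L), P = P0)
  steps <- vector("list", K)
  for (k in seq_len(K)) {
    z <- if (!is.null(obs) && !anyNA(obs[k, ])) obs[k, ] else NULL
    state <- ekfStep(state, model, u = accel[k, ], z = z)
    steps[[k]] <- state
  }
  attr(steps, "init") <- list(x = matrix(x0, ncol = 1L), P = P0)
  attr(steps, "model") <- model
  steps
}

#' Rauch-Tung-Striebel backward smoother
#'
#' Runs the backward recursion over a stored forward pass:
#' `K_k = P_k^+ F' (P_{k+1}^-)^{-1}`,
#' `x_k^s = x_k^+ + K_k (x_{k+1}^s - x_{k+1}^-)`,
#' `P_k^s = P_k^+ + K_k (P_{k+1}^s - P_{k+1}^-) K_k'`,
#' anchored at the final filtered state (which the smoother leaves
#' unchanged).
#'
#' @param forward Output of [runForwardFilter()].
#' @return A list with `x` (K x n matrix of smoothed states), `P` (list of
#'   smoothed covariances), and `gain` (list of smoother gains).
#' @export
rtsSmooth <- function(forward) {
  K <- length(forward)
  if (K == 0L) stop("empty forward pass")
  model <- attr(forward, "model")
  if (is.null(model)) stop("forward pass is missing its model attribute")
  for (s in forward)
    if (is.null(s$PPred) || is.null(s$xPred))
      stop("forward pass must store a-priori state and covariance per step")
  n <- length(forward[[K]]$x)
  xs <- matrix(0, K, n)
  Ps <- vector("list", K)
  gains <- vector("list", K)
  xs[K, ] <- forward[[K]]$x
  Ps[[K]] <- forward[[K]]$P
  if (K > 1L) {
    for (k in (K - 1L):1L) {
      Pplus <- forward[[k]]$P
      Pminus1 <- forward[[k + 1L]]$PPred
      Ks <- Pplus %*% t(model$F) %*% solve(Pminus1)
      xs[k, ] <- as.numeric(forward[[k]]$x) +
        as.numeric(Ks %*% (xs[k + 1L, ] - as.numeric(forward[[k + 1L]]$xPred)))
      Ps[[k]] <- Pplus + Ks %*% (Ps[[k + 1L]] - Pminus1) %*% t(Ks)
      Ps[[k]] <- (Ps[[k]] + t(Ps[[k]])) / 2
      gains[[k]] <- Ks
    }
  }
  list(x = xs, P = Ps, gain = gains)
}

#' Fuse an IMU stream with UWB positions into a drift-corrected trajectory
#'
#' Loose coupling: the IMU's gravity-compensated acceleration drives the
#' constant-acceleration-input prediction at the IMU rate, and each UWB
#' position fix (typically at a lower rate) is applied as a position
#' observation at the nearest IMU step. Optionally the RTS smoother refines
#' the filtered track, and an error report against ground truth is produced.
#'
#' @param imu A [SensorStream-class] whose first three channels are
#'   gravity-compensated world-frame acceleration, or a plain `K x 3`
#'   acceleration matrix with attribute-free timing given by `dt`.
#' @param uwbTime,uwbPositions UWB fix times (s) and `M x 3` positions (m);
#'   `NULL` for pure dead reckoning.
#' @param config List of options: `qAccel`, `rObs`, `smooth` (logical),
#'   `x0`, `P0`.
#' @param truth Optional `K x 3` ground-truth positions (at IMU steps) for
#'   the error report.
#' @param dt IMU step, seconds (taken from the stream when given one).
#' @return A list with `trajectory` (data frame: time_s, px..vz, source),
#'   `report` (see [positioningErrorReport()]; `NULL` without truth), and
#'   `forward` (the stored filter pass).
#' @export
fuseTrajectory <- function(imu, uwbTime = NULL, uwbPositions = NULL,
                           config = list(), truth = NULL, dt = NULL) {
  if (is(imu, "SensorStream")) {
    accel <- imu@data[, 1:3, drop = FALSE]
    tSteps <- imu@time          # sample k closes the step ending at time k
    dt <- 1 / imu@rate
  } else {
    accel <- as.matrix(imu)
    if (is.null(dt)) stop("dt required for matrix input")
    tSteps <- dt * seq_len(nrow(accel))
  }
  K <- nrow(accel)
  cfg <- utils::modifyList(list(qAccel = 0.5, rObs = 0.1^2, smooth = TRUE,
                                x0 = rep(0, 6L), P0 = diag(1e-4, 6L)), config)
  model <- fusionModel(dt, qAccel = cfg$qAccel, rObs = cfg$rObs)
  obs <- NULL
  if (!is.null(uwbPositions)) {
    uwbPositions <- as.matrix(uwbPositions)
    if (is.null(uwbTime) || length(uwbTime) != nrow(uwbPositions))
      stop("uwbTime must align with uwbPositions")
    if (max(uwbTime) < tSteps[1L] || min(uwbTime) > tSteps[K])
      stop("IMU and UWB records do not overlap in time")
    obs <- matrix(NA_real_, K, 3L)
    idx <- vapply(uwbTime, function(tt) which.min(abs(tSteps - tt)), 0L)
    obs[idx, ] <- uwbPositions
  }
  forward <- runForwardFilter(cfg$x0, cfg$P0, model, accel, obs)
  xf <- t(vapply(forward, function(s) as.numeric(s$x), numeric(6L)))
  est <- xf[, 1:3, drop = FALSE]
  source <- "filtered"
  if (isTRUE(cfg$smooth)) {
    sm <- rtsSmooth(forward)
    est <- sm$x[, 1:3, drop = FALSE]
    xf <- sm$x
    source <- "smoothed"
  }
  trajectory <- data.frame(time_s = tSteps, px = xf[, 1L], py = xf[, 2L],
                           pz = xf[, 3L], vx = xf[, 4L], vy = xf[, 5L],
                           vz = xf[, 6L], source = source)
  report <- if (!is.null(truth)) positioningErrorReport(est, truth) else NULL
  list(trajectory = trajectory, report = report, forward = forward)
}

#' Write a fused trajectory as CSV
#'
#' @param trajectory Data frame from [fuseTrajectory()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
writeTrajectoryCsv <- function(trajectory, path) {
  utils::write.csv(trajectory, path, row.names = FALSE)
  invisible(path)
}
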