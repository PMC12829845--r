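# UWB ranging: time-of-flight measurement model with clock offset, NLOS bias
# and Gaussian noise; symmetric double-sided two-way ranging; nonlinear
# least-squares multilateration; median/MAD outlier gating.

SPEED_OF_LIGHT <- 299792458  # m/s

#' UWB anchor set
#'
#' @param positions Numeric `K x 3` matrix of anchor coordinates (meters),
#'   optionally with rownames as anchor ids.
#' @return A data frame with columns `id, x, y, z`.
#' @examples
#' defaultAnchorLayout()
#' @export
uwbAnchors <- function(positions) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 3L) stop("anchor positions must be K x 3")
  ids <- rownames(positions)
  if (is.null(ids)) ids <- paste0("A", seq_len(nrow(positions)))
  data.frame(id = ids, x = positions[, 1L], y = positions[, 2L],
             z = positions[, 3L], row.names = NULL)
}

#' @describeIn uwbAnchors The default five-base-station layout: four corner
#'   anchors at 2.5 m height around a 10 x 10 m area plus one elevated
#'   central anchor, with a single mobile tag.
#' @export
defaultAnchorLayout <- function() {
  uwbAnchors(matrix(c(
    0, 0, 2.5,
    10, 0, 2.5,
    10, 10, 2.5,
    0, 10, 2.5,
    5, 5, 3.5
  ), ncol = 3L, byrow = TRUE))
}

#' Read/write anchor layouts as YAML
#'
#' The YAML schema is a list of `{id, x, y, z}` entries.
#'
#' @param anchors Data frame from [uwbAnchors()].
#' @param path File path.
#' @return `readAnchorLayout` returns the anchor data frame;
#'   `writeAnchorLayout` returns `path` invisibly.
#' @export
writeAnchorLayout <- function(anchors, path) {
  entries <- lapply(seq_len(nrow(anchors)), function(i)
    list(id = anchors$id[i], x = anchors$x[i], y = anchors$y[i],
         z = anchors$z[i]))
  yaml::write_yaml(list(anchors = entries), path)
  invisible(path)
}

#' @rdname writeAnchorLayout
#' @export
readAnchorLayout <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$anchors)) stop("anchor YAML must have an 'anchors' list")
  pos <- t(vapply(y$anchors, function(a) c(a$x, a$y, a$z), numeric(3L)))
  rownames(pos) <- vapply(y$anchors, function(a) as.character(a$id), "")
  uwbAnchors(pos)
}

#' Simulate a single time-of-flight measurement
#'
#' The pre-correction ranging model:
#' `TOF = ||b - p|| / c + clockOffset + delta_NLOS + nu`,
#' with `c` the speed of light, a non-negative NLOS/multipath delay
#' (path lengthening only), and Gaussian noise `nu ~ N(0, noiseSd^2)`.
#'
#' @param anchor One row of an anchor data frame (or a list with x, y, z).
#' @param tagPosition 3-vector tag position, meters.
#' @param clockOffset Residual clock offset, seconds.
#' @param nlos NLOS delay in seconds: 0 for line-of-sight, or a positive
#'   fixed bias, or `"random"` for an exponential draw with mean `nlosMean`.
#' @param noiseSd Gaussian noise standard deviation, seconds.
#' @param nlosMean Mean of the exponential NLOS delay when `nlos="random"`.
#' @param seed RNG seed.
#' @return A list with `anchorId, tof, range, clockOffset, nlosError,
#'   noise, isNlos`.
#' @export
simulateTof <- function(anchor, tagPosition, clockOffset = 0, nlos = 0,
                        noiseSd = 0, nlosMean = 1e-9, seed = NULL) {
  if (noiseSd < 0) stop("noiseSd must be non-negative")
  b <- as.numeric(c(anchor$x, anchor$y, anchor$z))
  if (length(b) != 3L || length(tagPosition) != 3L)
    stop("anchor and tag must be 3D points")
  if (!is.null(seed)) set.seed(as.integer(seed))
  delta <- if (identical(nlos, "random")) stats::rexp(1L, 1 / nlosMean)
           else as.numeric(nlos)
  if (delta < 0) stop("NLOS delay must be non-negative (path lengthening)")
  nu <- if (noiseSd > 0) stats::rnorm(1L, 0, noiseSd) else 0
  trueTof <- sqrt(sum((b - tagPosition)^2)) / SPEED_OF_LIGHT
  tof <- trueTof + clockOffset + delta + nu
  list(anchorId = if (!is.null(anchor$id)) anchor$id else NA_character_,
       tof = tof, range = tof * SPEED_OF_LIGHT, clockOffset = clockOffset,
       nlosError = delta, noise = nu, isNlos = delta > 0)
}

#' Symmetric double-sided two-way ranging exchange
#'
#' Simulates the four-timestamp SDS-TWR exchange between a tag and an anchor
#' whose clocks run at relative drift `e` (ppm): two interleaved round trips
#' with response delays `D1` (anchor side) and `D2` (tag side). The
#' double-sided estimator
#' `tof = (Ra * Rb - D1 * D2) / (Ra + Rb + D1 + D2)`
#' cancels the clock-drift error to first order, whereas the single-sided
#' estimator `tof = (Ra - D1) / 2` inherits it in full; both are evaluated
#' on the same exchange for comparison.
#'
#' @param trueRange True tag-anchor distance, meters (non-negative).
#' @param clockDriftPpm Relative tag clock drift in parts per million.
#' @param responseDelays Length-2 vector `(D1, D2)` of response delays,
#'   seconds (both positive).
#' @param timestampNoiseSd Gaussian jitter on each measured interval,
#'   seconds.
#' @param seed RNG seed for the jitter.
#' @return A list with `rangeSds`, `rangeSs` (single-sided), `errorSds`,
#'   `errorSs` (meters).
#' @export
sdsTwrExchange <- function(trueRange, clockDriftPpm = 0,
                           responseDelays = c(5e-4, 5e-4),
                           timestampNoiseSd = 0, seed = NULL) {
  if (trueRange < 0) stop("trueRange must be non-negative")
  if (any(responseDelays <= 0)) stop("response delays must be positive")
  tof <- trueRange / SPEED_OF_LIGHT
  D1 <- responseDelays[1L]; D2 <- responseDelays[2L]
  eA <- 0                          # anchor clock taken as reference
  eB <- clockDriftPpm * 1e-6       # tag clock rate error
  if (!is.null(seed)) set.seed(as.integer(seed))
  jit <- function() if (timestampNoiseSd > 0)
    stats::rnorm(1L, 0, timestampNoiseSd) else 0
  # round trip 1 measured on the tag clock; the anchor's programmed delay D1
  # elapses D1/(1+eA) true seconds on its own (drifting) clock
  Ra <- (2 * tof + D1 / (1 + eA)) * (1 + eB) + jit()
  # round trip 2 measured on the anchor clock; tag delay D2 likewise
  Rb <- (2 * tof + D2 / (1 + eB)) * (1 + eA) + jit()
  D1m <- D1; D2m <- D2             # delays as known to each responder
  tofSds <- (Ra * Rb - D1m * D2m) / (Ra + Rb + D1m + D2m)
  tofSs <- (Ra - D1m) / 2
  list(rangeSds = tofSds * SPEED_OF_LIGHT,
       rangeSs = tofSs * SPEED_OF_LIGHT,
       errorSds = tofSds * SPEED_OF_LIGHT - trueRange,
       errorSs = tofSs * SPEED_OF_LIGHT - trueRange)
}

#' Multilateration by nonlinear least squares
#'
#' Recovers the tag position minimizing `sum_i (||b_i - p|| - r_i)^2` by
#' Gauss-Newton iteration, initialized from the anchor centroid refined by a
#' linearized closed-form solve. Requires at least four anchors in
#' non-degenerate (non-coplanar) geometry for a unique 3D fix.
#'
#' @param anchors Anchor data frame ([uwbAnchors()]), >= 4 rows.
#' @param ranges Numeric vector of measured ranges (meters), one per anchor.
#' @param maxIter Maximum Gauss-Newton iterations.
#' @param tol Step-norm convergence tolerance, meters.
#' @return A list with `position` (3-vector), `residual` (RMS range
#'   residual, meters), `iterations`, and `converged`.
#' @export
multilaterate <- function(anchors, ranges, maxIter = 100L, tol = 1e-10) {
  B <- as.matrix(anchors[, c("x", "y", "z")])
  K <- nrow(B)
  if (K < 4L) stop("need at least 4 anchors for 3D multilateration")
  if (length(ranges) != K || !all(is.finite(ranges)))
    stop("ranges must be finite, one per anchor")
  # linearized closed form (differences against the first anchor)
  A <- 2 * sweep(B[-1L, , drop = FALSE], 2L, B[1L, ], "-")
  rhs <- (rowSums(B[-1L, , drop = FALSE]^2) - sum(B[1L, ]^2)) -
    (ranges[-1L]^2 - ranges[1L]^2)
  sv <- svd(A)
  if (min(sv$d) < 1e-8 * max(sv$d))
    stop("degenerate anchor geometry (linearized system rank-deficient, ",
         sprintf("condition %.3g)", max(sv$d) / max(min(sv$d), .Machine$double.xmin)))
  p <- as.numeric(sv$v %*% ((t(sv$u) %*% rhs) / sv$d))
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(maxIter)) {
    diffs <- sweep(B, 2L, p, "-")
    dists <- sqrt(rowSums(diffs^2))
    resid <- dists - ranges
    J <- -diffs / pmax(dists, 1e-12)     # d dist / d p
    step <- tryCatch(qr.solve(J, -resid), error = function(e) NULL)
    if (is.null(step)) stop("degenerate anchor geometry in Gauss-Newton step")
    p <- p + step
    if (sqrt(sum(step^2)) < tol) { converged <- TRUE; break }
  }
  diffs <- sweep(B, 2L, p, "-")
  resid <- sqrt(rowSums(diffs^2)) - ranges
  list(position = p, residual = sqrt(mean(resid^2)), iterations = iter,
       converged = converged)
}

#' NLOS outlier gating on a range time series
#'
#' Flags samples deviating from a rolling median by more than `gate` times
#' the rolling median absolute deviation (MAD) and replaces them (and any
#' NaN/NA samples) by linear interpolation from the surviving neighbours.
#'
#' @param ranges Numeric vector of range samples (meters); may contain NA.
#' @param window Rolling window width in samples (>= 5).
#' @param gate Outlier gate as a multiple of the MAD.
#' @return A list with `cleaned` (the gated, interpolated series) and
#'   `mask` (logical vector, `TRUE` where a sample was rejected).
#' @export
rejectNlos <- function(ranges, window = 15L, gate = 5) {
  n <- length(ranges)
  if (window < 5L) stop("window must be at least 5 samples")
  if (window > n) stop("window larger than the series")
  half <- window %/% 2L
  mask <- logical(n)
  med <- numeric(n); madv <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    w <- ranges[lo:hi]
    med[i] <- stats::median(w, na.rm = TRUE)
    madv[i] <- stats::mad(w, na.rm = TRUE)
  }
  dev <- abs(ranges - med)
  # a zero MAD (locally constant series) gates any deviation at all
  mask <- is.na(ranges) | dev > gate * pmax(madv, .Machine$double.eps)
  cleaned <- ranges
  cleaned[mask] <- NA_real_
  if (all(is.na(cleaned))) stop("all samples rejected; nothing to interpolate from")
  idx <- which(!is.na(cleaned))
  cleaned <- stats::approx(idx, cleaned[idx], xout = seq_len(n), rule = 2L)$y
  list(cleaned = cleaned, mask = mask)
}

#' Write/read a range log as CSV
#'
#' Columns: `time_s, anchor_id, range_m, is_nlos`.
#'
#' @param log Data frame with those columns.
#' @param path File path.
#' @return `readRangeLog` returns the data frame; `writeRangeLog` returns
#'   `path` invisibly.
#' @export
writeRangeLog <- function(log, path) {
  utils::write.csv(log[, c("time_s", "anchor_id", "range_m", "is_nlos")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeRangeLog
#' @export
readRangeLog <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
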