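#' @import methods
NULL

#' SkeletonSequence: a timed sequence of 17-joint body poses
#'
#' Container for articulated body motion sampled at discrete times. The 17
#' joints follow the Human3.6M convention (pelvis root, spine/neck/head axis,
#' two arm chains, two leg chains) and are partitioned into five kinematic
#' chains; see [skeletonTopology()].
#'
#' @slot time Numeric vector of frame times in seconds, strictly increasing.
#' @slot positions `T x 17 x 3` array of joint positions (meters).
#' @slot orientations `T x 17 x 4` array of unit joint quaternions
#'   (scalar-first).
#' @slot comOffsets `17 x 3` matrix of fixed offsets (meters) from each
#'   sensor mounting point to its segment centre of mass, expressed in the
#'   segment frame.
#'
#' @seealso [comTrajectory()], [simulateImuStream()], [generateGait()]
#' @export
setClass("SkeletonSequence",
  representation(
    time = "numeric",
    positions = "array",
    orientations = "array",
    comOffsets = "matrix"
  )
)

setValidity("SkeletonSequence", function(object) {
  msg <- character()
  nT <- length(object@time)
  dp <- dim(object@positions)
  dq <- dim(object@orientations)
  if (length(dp) != 3L || dp[2L] != 17L || dp[3L] != 3L)
    msg <- c(msg, "positions must be a T x 17 x 3 array")
  if (length(dq) != 3L || dq[2L] != 17L || dq[3L] != 4L)
    msg <- c(msg, "orientations must be a T x 17 x 4 array")
  if (length(dp) == 3L && dp[1L] != nT)
    msg <- c(msg, "positions first dimension must match length(time)")
  if (length(dq) == 3L && dq[1L] != nT)
    msg <- c(msg, "orientations first dimension must match length(time)")
  if (!identical(dim(object@comOffsets), c(17L, 3L)))
    msg <- c(msg, "comOffsets must be a 17 x 3 matrix")
  if (nT > 1L && any(diff(object@time) <= 0))
    msg <- c(msg, "time must be strictly increasing")
  if (length(dq) == 3L && dq[1L] > 0L) {
    n2 <- sqrt(apply(object@orientations^2, c(1L, 2L), sum))
    if (any(abs(n2 - 1) > 1e-6))
      msg <- c(msg, "orientations must be unit quaternions (tol 1e-6)")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a SkeletonSequence
#'
#' @param time Frame times (seconds), strictly increasing.
#' @param positions `T x 17 x 3` array, meters.
#' @param orientations `T x 17 x 4` array of unit quaternions; defaults to
#'   identity orientations.
#' @param comOffsets `17 x 3` matrix of per-joint CoM offsets (meters);
#'   defaults to zero.
#' @return A [SkeletonSequence-class] object.
#' @export
SkeletonSequence <- function(time, positions, orientations = NULL,
                             comOffsets = matrix(0, 17L, 3L)) {
  nT <- length(time)
  if (is.null(orientations)) {
    orientations <- array(0, c(nT, 17L, 4L))
    orientations[, , 1L] <- 1
  }
  new("SkeletonSequence", time = as.numeric(time), positions = positions,
      orientations = orientations, comOffsets = comOffsets)
}

#' @describeIn SkeletonSequence Number of frames.
#' @param x A `SkeletonSequence`.
#' @export
nFrames <- function(x) length(x@time)

setMethod("show", "SkeletonSequence", function(object) {
  nT <- nFrames(object)
  dur <- if (nT > 1L) diff(range(object@time)) else 0
  cat(sprintf("SkeletonSequence: %d frames, 17 joints, %.2f s\n", nT, dur))
})

#' SensorStream: a timestamped multichannel sensor record
#'
#' Holds synchronously sampled sensor channels (e.g. the nine IMU axes
#' ax..mz, or fused UWB positions) with placement and provenance metadata.
#'
#' @slot time Numeric sample times, seconds.
#' @slot data Numeric matrix, one row per sample, named columns per channel.
#' @slot rate Nominal sampling rate, Hz.
#' @slot placement Body placement label (e.g. `"foot_r"`, `"tibia_r"`).
#' @slot meta List of free-form metadata (error-model parameters, seed, ...).
#' @export
setClass("SensorStream",
  representation(
    time = "numeric",
    data = "matrix",
    rate = "numeric",
    placement = "character",
    meta = "list"
  )
)

setValidity("SensorStream", function(object) {
  msg <- character()
  if (nrow(object@data) != length(object@time))
    msg <- c(msg, "data rows must match length(time)")
  if (is.null(colnames(object@data)))
    msg <- c(msg, "data columns must be named")
  if (length(object@rate) != 1L || object@rate <= 0)
    msg <- c(msg, "rate must be a positive scalar")
  if (length(msg)) msg else TRUE
})

#' Construct a SensorStream
#'
#' @param time Sample times, seconds.
#' @param data Matrix of channel values with column names.
#' @param rate Sampling rate, Hz.
#' @param placement Placement label.
#' @param meta Metadata list.
#' @return A [SensorStream-class] object.
#' @export
SensorStream <- function(time, data, rate, placement = "unknown", meta = list()) {
  new("SensorStream", time = as.numeric(time), data = as.matrix(data),
      rate = rate, placement = placement, meta = meta)
}

setMethod("show", "SensorStream", function(object) {
  cat(sprintf("SensorStream [%s]: %d samples x %d channels @ %g Hz\n",
              object@placement, nrow(object@data), ncol(object@data),
              object@rate))
  cat("  channels:", paste(colnames(object@data), collapse = ", "), "\n")
})

#' @describeIn SensorStream Channel matrix accessor.
#' @param x A `SensorStream`.
#' @export
streamData <- function(x) x@data

#' @describeIn SensorStream Sample-time accessor.
#' @export
streamTime <- function(x) x@time

#' WindowedGaitData: normalized sliding windows with labels and splits
#'
#' The training-ready representation of a sensor recording campaign:
#' fixed-length windows (rows of `T` time steps by `C` channels), one class
#' label and subject id per window, a subject-disjoint train/val/test split,
#' and the training-split z-score statistics used to normalize all splits.
#'
#' @slot windows `N x T x C` numeric array of z-scored windows.
#' @slot labels Factor of class labels, length `N`.
#' @slot subject Character vector of subject ids, length `N`.
#' @slot split Factor with levels `train`, `val`, `test`, length `N`.
#' @slot channelNames Character vector of length `C`.
#' @slot normStats List with numeric vectors `mean` and `sd` (length `C`),
#'   computed on the training split only.
#' @export
setClass("WindowedGaitData",
  representation(
    windows = "array",
    labels = "factor",
    subject = "character",
    split = "factor",
    channelNames = "character",
    normStats = "list"
  )
)

setValidity("WindowedGaitData", function(object) {
  msg <- character()
  d <- dim(object@windows)
  if (length(d) != 3L) msg <- c(msg, "windows must be an N x T x C array")
  n <- d[1L]
  if (length(object@labels) != n) msg <- c(msg, "labels length must be N")
  if (length(object@subject) != n) msg <- c(msg, "subject length must be N")
  if (length(object@split) != n) msg <- c(msg, "split length must be N")
  if (!all(levels(object@split) %in% c("train", "val", "test")))
    msg <- c(msg, "split levels must be within train/val/test")
  if (length(object@channelNames) != d[3L])
    msg <- c(msg, "channelNames length must be C")
  tr <- intersect(unique(object@subject[object@split == "train"]),
                  unique(object@subject[object@split == "test"]))
  if (length(tr))
    msg <- c(msg, "train and test splits share subjects (split must be subject-disjoint)")
  if (length(msg)) msg else TRUE
})

setMethod("show", "WindowedGaitData", function(object) {
  d <- dim(object@windows)
  cat(sprintf("WindowedGaitData: %d windows (T=%d, C=%d), %d classes, %d subjects\n",
              d[1L], d[2L], d[3L], nlevels(object@labels),
              length(unique(object@subject))))
  print(table(split = object@split))
})

#' @describeIn WindowedGaitData Number of windows.
#' @param x A `WindowedGaitData`.
#' @export
nWindows <- function(x) dim(x@windows)[1L]

#' @describeIn WindowedGaitData Window array accessor.
#' @export
windowArray <- function(x) x@windows

#' @describeIn WindowedGaitData Label accessor.
#' @export
windowLabels <- function(x) x@labels

#' @describeIn WindowedGaitData Split accessor.
#' @export
windowSplit <- function(x) x@split

#' Subset a WindowedGaitData by split
#'
#' @param x A [WindowedGaitData-class].
#' @param split One of `"train"`, `"val"`, `"test"`.
#' @return A `WindowedGaitData` restricted to the requested split.
#' @export
subsetSplit <- function(x, split = c("train", "val", "test")) {
  split <- match.arg(split)
  keep <- which(x@split == split)
  new("WindowedGaitData",
      windows = x@windows[keep, , , drop = FALSE],
      labels = x@labels[keep],
      subject = x@subject[keep],
      split = droplevels(x@split[keep]),
      channelNames = x@channelNames,
      normStats = x@normStats)
}
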