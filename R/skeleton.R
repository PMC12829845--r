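#' 17-joint skeleton topology and kinematic chains
#'
#' The joint set and parent map follow the Human3.6M 17-joint convention:
#' a pelvis root, the trunk axis (spine, neck, head), and four limb chains.
#' The joints are partitioned into five functional chains used throughout
#' the package: left arm, trunk axis, right arm, left leg, right leg.
#'
#' @return A list with elements `joints` (character vector of 17 names),
#'   `parent` (integer vector; 0 marks the root), and `chains` (named list of
#'   joint-index vectors partitioning 1..17 into the five chains).
#' @examples
#' topo <- skeletonTopology()
#' topo$chains$trunk_axis
#' @export
skeletonTopology <- function() {
  joints <- c("pelvis", "hip_r", "knee_r", "ankle_r",
              "hip_l", "knee_l", "ankle_l",
              "spine", "neck", "nose", "head",
              "shoulder_l", "elbow_l", "wrist_l",
              "shoulder_r", "elbow_r", "wrist_r")
  parent <- c(0L, 1L, 2L, 3L,
              1L, 5L, 6L,
              1L, 8L, 9L, 10L,
              9L, 12L, 13L,
              9L, 15L, 16L)
  chains <- list(
    left_arm = c(12L, 13L, 14L),
    trunk_axis = c(1L, 8L, 9L, 10L, 11L),
    right_arm = c(15L, 16L, 17L),
    left_leg = c(5L, 6L, 7L),
    right_leg = c(2L, 3L, 4L)
  )
  list(joints = joints, parent = parent, chains = chains)
}

#' Whole-body centre-of-mass trajectory
#'
#' Estimates the body CoM at each frame as the unweighted mean over the N=17
#' joints of the sensor position corrected by the rotated fixed CoM offset:
#' `p_CoM(t) = (1/N) * sum_i [ p_i(t) + R_i(t) r_i^CoM ]`,
#' where `R_i(t)` is the rotation matrix of joint i's orientation quaternion
#' and `r_i^CoM` the fixed offset from the mounting point to the segment CoM.
#'
#' @param frames A [SkeletonSequence-class].
#' @return A `T x 3` matrix of CoM positions (meters).
#' @export
comTrajectory <- function(frames) {
  stopifnot(is(frames, "SkeletonSequence"))
  nT <- nFrames(frames)
  out <- matrix(0, nT, 3L)
  off <- frames@comOffsets
  for (t in seq_len(nT)) {
    acc <- c(0, 0, 0)
    for (i in 1:17) {
      R <- quatToRotmat(frames@orientations[t, i, ])
      acc <- acc + frames@positions[t, i, ] + as.numeric(R %*% off[i, ])
    }
    out[t, ] <- acc / 17
  }
  colnames(out) <- c("x", "y", "z")
  out
}

#' Read/write skeleton sequences as long-format CSV
#'
#' The CSV layout is one row per (frame, joint) with columns
#' `frame, time_s, joint, x, y, z, qw, qx, qy, qz`.
#'
#' @param x A [SkeletonSequence-class].
#' @param path File path.
#' @return `readSkeletonCsv` returns a `SkeletonSequence`;
#'   `writeSkeletonCsv` returns `path` invisibly.
#' @export
writeSkeletonCsv <- function(x, path) {
  stopifnot(is(x, "SkeletonSequence"))
  nT <- nFrames(x)
  topo <- skeletonTopology()
  df <- data.frame(
    frame = rep(seq_len(nT), each = 17L),
    time_s = rep(x@time, each = 17L),
    joint = rep(topo$joints, times = nT),
    x = as.vector(t(x@positions[, , 1L])),
    y = as.vector(t(x@positions[, , 2L])),
    z = as.vector(t(x@positions[, , 3L])),
    qw = as.vector(t(x@orientations[, , 1L])),
    qx = as.vector(t(x@orientations[, , 2L])),
    qy = as.vector(t(x@orientations[, , 3L])),
    qz = as.vector(t(x@orientations[, , 4L]))
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeSkeletonCsv
#' @export
readSkeletonCsv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("frame", "time_s", "joint", "x", "y", "z", "qw", "qx", "qy", "qz")
  if (!all(need %in% names(df)))
    stop("skeleton CSV missing columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  topo <- skeletonTopology()
  frames <- sort(unique(df$frame))
  nT <- length(frames)
  pos <- array(NA_real_, c(nT, 17L, 3L))
  ori <- array(NA_real_, c(nT, 17L, 4L))
  tm <- numeric(nT)
  df$jidx <- match(df$joint, topo$joints)
  if (anyNA(df$jidx)) stop("unknown joint names in skeleton CSV")
  df$fidx <- match(df$frame, frames)
  for (r in seq_len(nrow(df))) {
    f <- df$fidx[r]; j <- df$jidx[r]
    pos[f, j, ] <- c(df$x[r], df$y[r], df$z[r])
    ori[f, j, ] <- c(df$qw[r], df$qx[r], df$qy[r], df$qz[r])
    tm[f] <- df$time_s[r]
  }
  SkeletonSequence(time = tm, positions = pos, orientations = ori)
}
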