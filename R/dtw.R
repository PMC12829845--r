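#' Dynamic time warping with a weighted diagonal step
#'
#' Fills the accumulated-cost matrix by the recurrence
#' `D(i,j) = min( D(i-1,j) + d, D(i,j-1) + d, D(i-1,j-1) + 2*d )`
#' with `d = d(v_i, v_j)` the pointwise distance between frame feature
#' vectors, and recovers the optimal monotone alignment path by backtracking.
#' The diagonal step carries weight 2 (symmetric step weighting), so the
#' boundary cell is initialized as `D(1,1) = 2*d(v_1, v_1)` and the first
#' row/column accumulate with weight 1.
#'
#' @param test Numeric matrix, one row per frame (a numeric vector is treated
#'   as a single-feature sequence).
#' @param template Same layout as `test`.
#' @param dist Pointwise metric, `"euclidean"` or `"absolute"` (L1).
#' @return A list with `cost` (the n x m accumulated matrix), `totalCost`
#'   (`D(n,m)`), and `path` (two-column matrix of aligned (i, j) index pairs
#'   from (1,1) to (n,m)).
#' @examples
#' a <- matrix(sin(seq(0, 2 * pi, length.out = 20)))
#' dtwAccumulate(a, a)$totalCost  # 0 for identical sequences
#' @export
dtwAccumulate <- function(test, template, dist = c("euclidean", "absolute")) {
  dist <- match.arg(dist)
  test <- .asFeatureMatrix(test, "test")
  template <- .asFeatureMatrix(template, "template")
  if (ncol(test) != ncol(template))
    stop("test and template must have the same feature dimension")
  n <- nrow(test); m <- nrow(template)
  d <- .pointwiseDist(test, template, dist)
  D <- matrix(0, n, m)
  D[1L, 1L] <- 2 * d[1L, 1L]
  if (n > 1L) for (i in 2:n) D[i, 1L] <- D[i - 1L, 1L] + d[i, 1L]
  if (m > 1L) for (j in 2:m) D[1L, j] <- D[1L, j - 1L] + d[1L, j]
  if (n > 1L && m > 1L) {
    for (i in 2:n) {
      for (j in 2:m) {
        D[i, j] <- min(D[i - 1L, j] + d[i, j],
                       D[i, j - 1L] + d[i, j],
                       D[i - 1L, j - 1L] + 2 * d[i, j])
      }
    }
  }
  # backtrack; diagonal preferred on ties for the shortest path
  path <- matrix(0L, n + m, 2L)
  i <- n; j <- m; k <- 1L
  path[k, ] <- c(i, j)
  while (i > 1L || j > 1L) {
    if (i == 1L) {
      j <- j - 1L
    } else if (j == 1L) {
      i <- i - 1L
    } else {
      cand <- c(D[i - 1L, j - 1L], D[i - 1L, j], D[i, j - 1L])
      which <- which.min(cand)
      if (which == 1L) { i <- i - 1L; j <- j - 1L }
      else if (which == 2L) i <- i - 1L
      else j <- j - 1L
    }
    k <- k + 1L
    path[k, ] <- c(i, j)
  }
  path <- path[k:1, , drop = FALSE]
  colnames(path) <- c("i", "j")
  list(cost = D, totalCost = D[n, m], path = path)
}

.asFeatureMatrix <- function(x, arg) {
  if (is.vector(x) && is.numeric(x)) x <- matrix(x, ncol = 1L)
  if (!is.matrix(x) || nrow(x) == 0L)
    stop(sprintf("'%s' must be a non-empty numeric matrix or vector", arg))
  if (!all(is.finite(x))) stop(sprintf("'%s' has non-finite values", arg))
  x
}

.pointwiseDist <- function(a, b, dist) {
  n <- nrow(a); m <- nrow(b)
  d <- matrix(0, n, m)
  for (j in seq_len(m)) {
    diff <- sweep(a, 2L, b[j, ], "-")
    d[, j] <- if (dist == "euclidean") sqrt(rowSums(diff^2)) else rowSums(abs(diff))
  }
  d
}

#' Gait-phase segmentation by template alignment
#'
#' Labels every frame of a feature sequence with the gait phase whose
#' template aligns to it at minimum accumulated cost: each phase template is
#' DTW-aligned against the full sequence and each frame takes the phase of
#' the template whose alignment covers it most cheaply (per-frame cost of
#' the warping path, normalized by path length).
#'
#' @param features Numeric matrix of per-frame feature vectors.
#' @param templates Named list of phase templates (matrices with the same
#'   feature dimension).
#' @param dist Pointwise metric, see [dtwAccumulate()].
#' @return Character vector of per-frame phase labels.
#' @export
segmentGaitPhases <- function(features, templates,
                              dist = c("euclidean", "absolute")) {
  dist <- match.arg(dist)
  features <- .asFeatureMatrix(features, "features")
  if (!is.list(templates) || length(templates) < 1L ||
      is.null(names(templates)) || any(names(templates) == ""))
    stop("'templates' must be a non-empty named list")
  n <- nrow(features)
  # per-frame, per-phase alignment cost from the warping path
  costPerFrame <- matrix(Inf, n, length(templates))
  for (p in seq_along(templates)) {
    al <- dtwAccumulate(features, .asFeatureMatrix(templates[[p]], "template"),
                        dist = dist)
    d <- .pointwiseDist(features,
                        .asFeatureMatrix(templates[[p]], "template"), dist)
    # mean matched distance per test frame along the optimal path
    agg <- rep(0, n); cnt <- rep(0L, n)
    for (k in seq_len(nrow(al$path))) {
      i <- al$path[k, 1L]; j <- al$path[k, 2L]
      agg[i] <- agg[i] + d[i, j]
      cnt[i] <- cnt[i] + 1L
    }
    costPerFrame[, p] <- agg / pmax(cnt, 1L)
  }
  if (all(!is.finite(costPerFrame)))
    stop("no finite-cost alignment for any template")
  labels <- names(templates)[apply(costPerFrame, 1L, which.min)]
  # enforce contiguous runs via a short majority smoothing pass
  labels <- .majoritySmooth(labels, width = 5L)
  labels
}

.majoritySmooth <- function(labels, width = 5L) {
  n <- length(labels)
  if (n <= width) return(labels)
  half <- width %/% 2L
  out <- labels
  for (i in seq_len(n)) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    tab <- table(labels[lo:hi])
    out[i] <- names(tab)[which.max(tab)]
  }
  out
}
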