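# Shared fixtures, built once per test run and cached.

.fixtureEnv <- new.env(parent = emptyenv())

# small 3-subject cohort (all 7 classes, 6 s sequences): enough windows to
# exercise windowing, splits and learnability without the full-cohort cost
tinyGaitData <- function() {
  if (is.null(.fixtureEnv$tiny)) {
    subjects <- defaultCohort(seed = 424242L)[1:3]
    .fixtureEnv$tiny <- renderGaitDataset(
      subjects = subjects,
      config = list(duration = 6, nTrain = 1L, nVal = 1L, seed = 5L))
  }
  .fixtureEnv$tiny
}

randomUnitQuat <- function() quatNormalize(stats::rnorm(4L))

# independent 16-term Hamilton-product expansion (basis-table oracle)
hamiltonOracle <- function(a, b) {
  # multiplication table for (1, i, j, k); entries: (sign, target index)
  tab <- list(
    list(c(1, 1), c(1, 2), c(1, 3), c(1, 4)),
    list(c(1, 2), c(-1, 1), c(1, 4), c(-1, 3)),
    list(c(1, 3), c(-1, 4), c(-1, 1), c(1, 2)),
    list(c(1, 4), c(1, 3), c(-1, 2), c(-1, 1))
  )
  out <- numeric(4L)
  for (i in 1:4) for (j in 1:4) {
    e <- tab[[i]][[j]]
    out[e[2L]] <- out[e[2L]] + e[1L] * a[i] * b[j]
  }
  out
}

# exhaustive DTW over all monotone warping paths with diagonal weight 2
dtwBruteForce <- function(d) {
  n <- nrow(d); m <- ncol(d)
  best <- new.env(parent = emptyenv())
  best$val <- Inf
  recurse <- function(i, j, acc) {
    if (acc >= best$val) return(invisible())
    if (i == n && j == m) { best$val <- acc; return(invisible()) }
    if (i < n) recurse(i + 1L, j, acc + d[i + 1L, j])
    if (j < m) recurse(i, j + 1L, acc + d[i, j + 1L])
    if (i < n && j < m) recurse(i + 1L, j + 1L, acc + 2 * d[i + 1L, j + 1L])
  }
  recurse(1L, 1L, 2 * d[1L, 1L])
  best$val
}
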