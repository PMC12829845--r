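test_that("time-of-flight model: zero at the anchor, exact at 3 ns", {
  an <- uwbAnchors(matrix(c(0, 0, 0), 1L))[1L, ]
  expect_equal(simulateTof(an, c(0, 0, 0))$tof, 0)
  d <- 299792458 * 3e-9
  expect_equal(simulateTof(an, c(d, 0, 0))$tof, 3e-9, tolerance = 1e-20)
})

test_that("ToF noise matches the requested standard deviation", {
  an <- uwbAnchors(matrix(c(0, 0, 0), 1L))[1L, ]
  set.seed(171)
  tofs <- vapply(1:10000, function(i)
    simulateTof(an, c(5, 0, 0), noiseSd = 2e-9)$tof, numeric(1L))
  expect_equal(stats::sd(tofs), 2e-9, tolerance = 0.05)
})

test_that("NLOS delays are strictly non-negative and flagged", {
  an <- uwbAnchors(matrix(c(0, 0, 0), 1L))[1L, ]
  m <- simulateTof(an, c(3, 0, 0), nlos = 2e-9)
  expect_true(m$isNlos)
  expect_gte(m$nlosError, 0)
  expect_error(simulateTof(an, c(3, 0, 0), nlos = -1e-9), "non-negative")
  set.seed(181)
  draws <- vapply(1:50, function(i)
    simulateTof(an, c(3, 0, 0), nlos = "random")$nlosError, numeric(1L))
  expect_true(all(draws >= 0))
})

test_that("SDS-TWR is exact with zero drift and noise", {
  ex <- sdsTwrExchange(12.5, clockDriftPpm = 0)
  expect_equal(ex$rangeSds, 12.5, tolerance = 1e-9)
  expect_equal(ex$errorSds, 0, tolerance = 1e-9)
})

test_that("SDS-TWR beats single-sided TWR by >= 10x under 20 ppm drift", {
  ex <- sdsTwrExchange(10, clockDriftPpm = 20,
                       responseDelays = c(5e-4, 5e-4))
  expect_lt(abs(ex$errorSds), abs(ex$errorSs) / 10)
})

test_that("drift sweep: SDS-TWR error grows much slower than single-sided", {
  drifts <- c(5, 10, 20)
  errs <- t(vapply(drifts, function(d) {
    ex <- sdsTwrExchange(10, clockDriftPpm = d)
    c(sds = abs(ex$errorSds), ss = abs(ex$errorSs))
  }, numeric(2L)))
  # single-sided error is linear in drift; the double-sided residual stays
  # orders of magnitude below it across the sweep
  ratioSs <- errs[3L, "ss"] / errs[1L, "ss"]
  expect_equal(unname(ratioSs), 4, tolerance = 0.01)   # 20/5 linear growth
  expect_true(all(errs[, "sds"] < errs[, "ss"] / 10))
})

test_that("multilateration inverts exact ranges on the default layout", {
  an <- defaultAnchorLayout()
  p <- c(0.3, 0.4, 0.2) * 10
  r <- sqrt(rowSums(sweep(as.matrix(an[, c("x", "y", "z")]), 2L, p, "-")^2))
  fit <- multilaterate(an, r)
  expect_lt(sqrt(sum((fit$position - p)^2)), 1e-6)
  expect_lt(fit$residual, 1e-6)
})

test_that("multilateration identity holds over 50 random geometries", {
  set.seed(191)
  for (k in 1:50) {
    pos <- matrix(stats::runif(15L, -10, 10), 5L, 3L)
    # keep geometry well-conditioned: reject near-coplanar draws
    while (kappa(sweep(pos[-1L, ], 2L, pos[1L, ])) > 50)
      pos <- matrix(stats::runif(15L, -10, 10), 5L, 3L)
    an <- uwbAnchors(pos)
    p <- stats::runif(3L, -5, 5)
    r <- sqrt(rowSums(sweep(pos, 2L, p, "-")^2))
    fit <- multilaterate(an, r)
    expect_lt(sqrt(sum((fit$position - p)^2)), 1e-6)
  }
})

test_that("tag coincident with an anchor is recovered", {
  an <- defaultAnchorLayout()
  p <- as.numeric(an[1L, c("x", "y", "z")])
  r <- sqrt(rowSums(sweep(as.matrix(an[, c("x", "y", "z")]), 2L, p, "-")^2))
  fit <- multilaterate(an, r)
  expect_lt(sqrt(sum((fit$position - p)^2)), 1e-6)
})

test_that("noisy multilateration keeps the median error well-bounded", {
  an <- defaultAnchorLayout()
  p <- c(3, 4, 1.2)
  d <- sqrt(rowSums(sweep(as.matrix(an[, c("x", "y", "z")]), 2L, p, "-")^2))
  set.seed(201)
  errs <- vapply(1:500, function(i) {
    fit <- multilaterate(an, d + stats::rnorm(5L, 0, 0.1))
    sqrt(sum((fit$position - p)^2))
  }, numeric(1L))
  expect_lt(stats::median(errs), 0.25)
})

test_that("an NLOS bias on one anchor cannot decrease the residual", {
  an <- defaultAnchorLayout()
  p <- c(2, 7, 1.0)
  r <- sqrt(rowSums(sweep(as.matrix(an[, c("x", "y", "z")]), 2L, p, "-")^2))
  clean <- multilaterate(an, r)$residual
  for (bias in c(0.5, 1, 3)) {
    rb <- r; rb[2L] <- rb[2L] + bias
    expect_gte(multilaterate(an, rb)$residual, clean)
  }
})

test_that("degenerate (collinear) anchor geometry is diagnosed", {
  pos <- cbind(1:5, 2 * (1:5), 3 * (1:5))   # collinear
  expect_error(multilaterate(uwbAnchors(pos), rep(1, 5L)), "degenerate")
  expect_error(multilaterate(defaultAnchorLayout()[1:3, ], rep(1, 3L)),
               "4 anchors")
})

test_that("NLOS gating flags an injected spike and nothing else", {
  set.seed(211)
  r <- 5 + 0.02 * sin(seq_len(200L) / 10) + stats::rnorm(200L, 0, 0.01)
  r[87L] <- r[87L] + 3
  out <- rejectNlos(r, window = 15L, gate = 5)
  expect_true(out$mask[87L])
  expect_equal(sum(out$mask), 1L)
  expect_lt(abs(out$cleaned[87L] - 5), 0.2)
})

test_that("clean series passes the gate untouched; NaN is filled", {
  r <- rep(2.5, 50L)
  out <- rejectNlos(r, window = 9L, gate = 5)
  expect_false(any(out$mask))
  expect_identical(out$cleaned, r)
  r[20L] <- NA
  out2 <- rejectNlos(r, window = 9L, gate = 5)
  expect_true(out2$mask[20L])
  expect_equal(out2$cleaned[20L], 2.5)
})

test_that("gating rejects invalid windows", {
  expect_error(rejectNlos(rep(1, 10L), window = 3L), "at least 5")
  expect_error(rejectNlos(rep(1, 4L), window = 8L), "larger")
})

test_that("anchor layout YAML round-trips", {
  an <- defaultAnchorLayout()
  path <- withr::local_tempfile(fileext = ".yaml")
  writeAnchorLayout(an, path)
  back <- readAnchorLayout(path)
  expect_equal(back$x, an$x)
  expect_equal(back$id, an$id)
  # the shipped example layout matches the in-code default
  shipped <- readAnchorLayout(system.file("extdata",
                                          "anchors_default.yaml",
                                          package = "rungait"))
  expect_equal(shipped[, c("x", "y", "z")], an[, c("x", "y", "z")])
})
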