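test_that("attention with a single key-value pair returns the value row", {
  q <- matrix(stats::rnorm(6), 2L, 3L)
  k <- matrix(c(1, 0, 0), 1L)
  v <- matrix(c(5, -2), 1L)
  out <- attention(q, k, v)
  expect_equal(unname(out[, ]), matrix(c(5, -2), 2L, 2L, byrow = TRUE),
               ignore_attr = TRUE)
})

test_that("attention weights approach one-hot at large scale", {
  Q <- diag(4) * 100
  out <- attention(Q, Q, diag(4), dk = 4)
  expect_equal(unname(out[, ]), diag(4), tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("attention matches the naive two-loop softmax computation", {
  set.seed(281)
  for (rep in 1:60) {
    Q <- matrix(stats::rnorm(32), 4L, 8L)
    K <- matrix(stats::rnorm(48), 6L, 8L)
    V <- matrix(stats::rnorm(30), 6L, 5L)
    out <- attention(Q, K, V)
    naive <- matrix(0, 4L, 5L)
    for (i in 1:4) {
      s <- numeric(6L)
      for (j in 1:6) s[j] <- sum(Q[i, ] * K[j, ]) / sqrt(8)
      w <- exp(s) / sum(exp(s))
      for (j in 1:6) naive[i, ] <- naive[i, ] + w[j] * V[j, ]
    }
    expect_equal(unname(out)[, ], naive, tolerance = 1e-6)
    expect_equal(unname(rowSums(attr(out, "weights"))), rep(1, 4L),
                 tolerance = 1e-6)
  }
})

test_that("attention rejects bad dimensions", {
  expect_error(attention(diag(2), diag(3), diag(3)), "dimensions")
  expect_error(attention(diag(2), diag(2), diag(2), dk = 0), "positive")
})

test_that("diffusion schedule: linear betas, strictly decreasing alphaBar", {
  sch <- diffusionSchedule()
  expect_length(sch$betas, 100L)
  expect_equal(sch$betas[1L], 0.003)
  expect_equal(sch$betas[100L], 0.06)
  expect_equal(diff(sch$betas), rep(diff(sch$betas)[1L], 99L))
  expect_true(all(diff(sch$alphaBar) < 0))
  expect_gt(sch$alphaBar[100L], 0)
  expect_error(diffusionSchedule(betaStart = 0.5, betaEnd = 0.1), "betaStart")
})

test_that("diffusion step with zero noise is the deterministic decay", {
  sch <- diffusionSchedule()
  x <- stats::rnorm(10L)
  expect_equal(diffuseStep(x, 7L, sch, noise = rep(0, 10L)),
               sqrt(1 - sch$betas[7L]) * x, tolerance = 1e-12)
  expect_error(diffuseStep(x, 0L, sch), "out of range")
  expect_error(diffuseStep(x, 101L, sch), "out of range")
})

test_that("a single diffusion step preserves unit variance", {
  sch <- diffusionSchedule()
  set.seed(291)
  x <- stats::rnorm(1e5)
  for (t in c(1L, 50L, 100L)) {
    xt <- diffuseStep(x, t, sch, seed = 300L + t)
    expect_equal(stats::var(xt), 1, tolerance = 0.02)
  }
})

test_that("composed steps match the closed-form jump in distribution", {
  sch <- diffusionSchedule()
  set.seed(301)
  x0 <- stats::rnorm(1e4)
  t <- 40L
  xt <- x0
  for (s in 1:t) xt <- diffuseStep(xt, s, sch)
  jump <- diffuseTo(x0, t, sch)$xt
  expect_equal(mean(xt), mean(jump), tolerance = 0.02)
  expect_equal(stats::var(xt), stats::var(jump), tolerance = 0.02)
  expect_equal(stats::var(xt), 1, tolerance = 0.02)
})

zeroLstmCell <- function(d, p) {
  list(Wf = matrix(0, d, d + p), Wi = matrix(0, d, d + p),
       Wc = matrix(0, d, d + p), Wo = matrix(0, d, d + p),
       bf = numeric(d), bi = numeric(d), bc = numeric(d), bo = numeric(d))
}

test_that("LSTM cell with zero weights: gates 0.5, half-retained cell", {
  cell <- zeroLstmCell(3L, 2L)
  cPrev <- c(1, -2, 0.5)
  out <- lstmCellStep(c(0.3, -0.1), rep(0, 3L), cPrev, cell)
  expect_equal(out$f, rep(0.5, 3L))
  expect_equal(out$i, rep(0.5, 3L))
  expect_equal(out$c, 0.5 * cPrev)
  expect_equal(out$h, 0.5 * tanh(0.5 * cPrev))
})

test_that("a saturated forget gate retains the cell state", {
  cell <- zeroLstmCell(2L, 1L)
  cell$bf <- c(50, 50)
  cPrev <- c(0.7, -0.3)
  out <- lstmCellStep(0.2, c(0, 0), cPrev, cell)
  # f ~ 1: cell keeps C_prev plus the (half-open) input contribution
  expect_equal(out$f, c(1, 1), tolerance = 1e-6)
  expect_equal(out$c, cPrev + out$i * out$g, tolerance = 1e-6)
})

test_that("LSTM cell matches an element-wise transcription of the gates", {
  set.seed(311)
  sig <- function(x) 1 / (1 + exp(-x))
  for (rep in 1:50) {
    d <- 4L; p <- 3L
    cell <- list(Wf = matrix(stats::rnorm(d * (d + p)), d),
                 Wi = matrix(stats::rnorm(d * (d + p)), d),
                 Wc = matrix(stats::rnorm(d * (d + p)), d),
                 Wo = matrix(stats::rnorm(d * (d + p)), d),
                 bf = stats::rnorm(d), bi = stats::rnorm(d),
                 bc = stats::rnorm(d), bo = stats::rnorm(d))
    x <- stats::rnorm(p); h0 <- stats::rnorm(d); c0 <- stats::rnorm(d)
    out <- lstmCellStep(x, h0, c0, cell)
    hx <- c(h0, x)
    f <- sig(cell$Wf %*% hx + cell$bf)
    i <- sig(cell$Wi %*% hx + cell$bi)
    g <- tanh(cell$Wc %*% hx + cell$bc)
    cN <- f * c0 + i * g
    o <- sig(cell$Wo %*% hx + cell$bo)
    expect_equal(out$c, as.numeric(cN), tolerance = 1e-7)
    expect_equal(out$h, as.numeric(o * tanh(cN)), tolerance = 1e-7)
    expect_true(all(abs(out$h) <= 1))
  }
})

test_that("patch embedding: token count, zero-window, and locality", {
  set.seed(321)
  Tn <- 16L; C <- 5L; dEmb <- 8L
  proj <- matrix(stats::rnorm(Tn * C), Tn, C)
  tokenProj <- matrix(stats::rnorm(dEmb * 4L), dEmb, 4L)
  win <- matrix(stats::rnorm(Tn * C), Tn, C)
  tok <- patchEmbed(win, proj, tokenProj, patch = 2L)
  expect_equal(nrow(tok), (Tn / 2L)^2)      # (T/p) x (dImg/p) tokens
  expect_equal(ncol(tok), dEmb)
  # reference scale arithmetic: 256 x 256 image, 2x2 patches -> 16384 tokens
  expect_equal((256L / 2L) * (256L / 2L), 16384L)
  # zero window: tokens are exactly the positional (+modality) encodings
  tok0 <- patchEmbed(matrix(0, Tn, C), proj, tokenProj, patch = 2L)
  grid <- attr(tok0, "grid")
  pe <- rungait:::.sinusoidalPE(grid[1L], dEmb)
  expect_equal(unname(tok0[, ]), pe[rep(seq_len(grid[1L]), each = grid[2L]), ],
               tolerance = 1e-12)
  # locality: permuting two time steps only changes the touched patch rows
  win2 <- win; win2[c(1L, 9L), ] <- win[c(9L, 1L), ]
  tok2 <- patchEmbed(win2, proj, tokenProj, patch = 2L)
  changed <- which(rowSums(abs(tok2 - tok)) > 1e-12)
  rows <- unique((changed - 1L) %/% grid[2L] + 1L)  # patched time rows
  expect_true(all(rows %in% c(1L, 5L)))   # steps 1 and 9 -> patch rows 1, 5
})

test_that("patch embedding enforces divisibility", {
  expect_error(patchEmbed(matrix(0, 15L, 3L), matrix(0, 15L, 3L),
                          matrix(0, 4L, 4L), patch = 2L), "divisible")
})

test_that("gated fusion: neutral gate averages, saturated gate selects", {
  d <- 4L
  hd <- stats::rnorm(d); hl <- stats::rnorm(d)
  fused <- gatedFuse(hd, hl, Wg = matrix(0, d, 2L * d), bg = numeric(d))
  expect_equal(as.numeric(fused), 0.5 * (hd + hl), tolerance = 1e-12)
  sat <- gatedFuse(hd, hl, Wg = matrix(0, d, 2L * d), bg = rep(50, d))
  expect_equal(as.numeric(sat), hd, tolerance = 1e-6)
})

test_that("fusion dropout only acts in training mode", {
  d <- 8L
  hd <- stats::rnorm(d); hl <- stats::rnorm(d)
  Wg <- matrix(stats::rnorm(2 * d * d, 0, 0.1), d, 2L * d)
  e1 <- gatedFuse(hd, hl, Wg, numeric(d), dropout = 0.9, training = FALSE)
  e2 <- gatedFuse(hd, hl, Wg, numeric(d), dropout = 0.9, training = FALSE)
  expect_identical(as.numeric(e1), as.numeric(e2))
  set.seed(331)
  tr <- gatedFuse(hd, hl, Wg, numeric(d), dropout = 0.9, training = TRUE)
  expect_false(identical(as.numeric(tr), as.numeric(e1)))
})

test_that("joint loss: limits and a hand-computed mixed case", {
  # perfect noise prediction at lambda = 1
  expect_equal(as.numeric(jointLoss(1:4, 1:4, c(0, 0), 1L, lambda = 1)), 0)
  # pure cross-entropy with uniform logits over 7 classes
  expect_equal(as.numeric(jointLoss(0, 1, rep(0, 7L), 3L, lambda = 0)),
               log(7), tolerance = 1e-12)
  # hand-set small tensors at lambda = 0.7
  np <- c(0.5, -0.5); nt <- c(0, 0)
  logits <- c(2, 1, 0)
  mse <- mean((np - nt)^2)                       # 0.25
  ce <- -(2 - log(sum(exp(logits - 2))) - 2 + 2) # via log-softmax
  ce <- -(logits[1L] - max(logits) - log(sum(exp(logits - max(logits)))))
  expect_equal(as.numeric(jointLoss(np, nt, logits, 1L, lambda = 0.7)),
               0.7 * mse + 0.3 * ce, tolerance = 1e-12)
  expect_error(jointLoss(0, 0, c(1, 0), 1L, lambda = 1.2), "lambda")
})
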