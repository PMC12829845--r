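# The DiT-LSTM running-posture recognizer, trained from scratch in R:
# patch-embedded pseudo-image tokens -> diffusion corruption at a sampled
# step (training only) -> pre-LN transformer blocks with a noise-prediction
# head -> mean-pooled DiT representation, fused through a sigmoid gate with
# the final hidden state of an LSTM branch over the temporal embeddings ->
# softmax classifier. Joint loss: lambda * diffusion MSE +
# (1 - lambda) * cross-entropy. Optimizer: Adam with L2 weight decay.

#' DiT-LSTM model configuration
#'
#' Defaults mirror the reference training setup: a linear beta schedule
#' with 100 diffusion steps from 0.003 to 0.06, loss balance
#' `lambda = 0.7`, LSTM hidden size 128, embedding dimension 256, gated
#' fusion dropout 0.9, 2x2 patches on the 256 x 256 pseudo-image, Adam
#' with learning rate 1e-4 and weight decay 0.1, batch 30, up to 300
#' epochs. Every value is overridable; `poolTo` average-pools the
#' pseudo-image to a `poolTo x poolTo` grid before patching for
#' CPU-scale runs (`NULL` = full scale).
#'
#' @param ... Named overrides of any configuration field.
#' @return A list of class `DitLstmConfig`.
#' @examples
#' scaledDownConfig()
#' @export
ditlstmConfig <- function(...) {
  cfg <- list(
    diffusionSteps = 100L, betaStart = 0.003, betaEnd = 0.06,
    lambda = 0.7, lstmHidden = 128L, dEmb = 256L, dImg = 256L,
    dropoutFusion = 0.9, patch = 2L, T = 256L,
    learningRate = 1e-4, weightDecay = 0.1, batch = 30L, maxEpochs = 300L,
    nBlocks = 4L, nHeads = 4L, mlpMult = 2L, poolTo = NULL,
    lstmSubsample = 1L, patience = 20L, nModalities = 3L
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown config fields: ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(cfg, over)
  if (!(cfg$betaStart > 0 && cfg$betaStart < cfg$betaEnd && cfg$betaEnd < 1))
    stop("require 0 < betaStart < betaEnd < 1")
  if (cfg$lambda < 0 || cfg$lambda > 1) stop("lambda must be in [0, 1]")
  if (cfg$T %% cfg$patch != 0L) stop("T must be divisible by the patch size")
  if (cfg$dEmb %% cfg$nHeads != 0L)
    stop("dEmb must be divisible by nHeads")
  structure(cfg, class = "DitLstmConfig")
}

#' @describeIn ditlstmConfig The desk-scale configuration used by the
#'   package's own experiments: 2 blocks, 2 heads, 64-dim embeddings,
#'   16 x 16 pooled pseudo-image for the DiT branch, LSTM hidden 32 over
#'   every 4th temporal embedding, fusion dropout 0.3, learning rate 3e-3,
#'   weight decay 1e-4, up to 60 epochs.
#' @export
scaledDownConfig <- function(...) {
  ditlstmConfig(nBlocks = 2L, nHeads = 2L, dEmb = 64L, dImg = 64L,
                poolTo = 16L, lstmHidden = 32L, lstmSubsample = 4L,
                dropoutFusion = 0.3, learningRate = 3e-3,
                weightDecay = 1e-4, maxEpochs = 60L, patience = 25L, ...)
}

# ---- parameter initialization -------------------------------------------

.glorot <- function(nOut, nIn) {
  matrix(stats::rnorm(nOut * nIn, 0, sqrt(2 / (nIn + nOut))), nOut, nIn)
}

.initParams <- function(cfg, nChannels, nClasses) {
  d <- cfg$dEmb
  h <- cfg$lstmHidden
  mh <- cfg$mlpMult * d
  lstmIn <- cfg$dImg   # the LSTM branch reads the unpooled temporal embeddings
  p <- list(
    Wproj = .glorot(cfg$dImg, nChannels),
    tokenProj = .glorot(d, cfg$patch^2),
    modalityEmb = matrix(stats::rnorm(d * cfg$nModalities, 0, 0.02),
                         d, cfg$nModalities),
    Wnoise = .glorot(d, d), bnoise = numeric(d),
    Wd = .glorot(h, d), bd = numeric(h),
    Wlstm = .glorot(4L * h, h + lstmIn), blstm = numeric(4L * h),
    Wg = .glorot(h, 2L * h), bg = numeric(h),
    Wcls = .glorot(nClasses, h), bcls = numeric(nClasses),
    lnFg = rep(1, d), lnFb = numeric(d)
  )
  # forget-gate bias starts at 1 (standard LSTM initialization)
  p$blstm[seq_len(h)] <- 1
  for (b in seq_len(cfg$nBlocks)) {
    p[[paste0("Wq", b)]] <- .glorot(d, d)
    p[[paste0("Wk", b)]] <- .glorot(d, d)
    p[[paste0("Wv", b)]] <- .glorot(d, d)
    p[[paste0("Wo", b)]] <- .glorot(d, d)
    p[[paste0("ln1g", b)]] <- rep(1, d); p[[paste0("ln1b", b)]] <- numeric(d)
    p[[paste0("ln2g", b)]] <- rep(1, d); p[[paste0("ln2b", b)]] <- numeric(d)
    p[[paste0("W1", b)]] <- .glorot(mh, d); p[[paste0("b1", b)]] <- numeric(mh)
    p[[paste0("W2", b)]] <- .glorot(d, mh); p[[paste0("b2", b)]] <- numeric(d)
  }
  p
}

# ---- layer forward/backward helpers -------------------------------------

.lnForward <- function(X, g, b, eps = 1e-5) {
  mu <- rowMeans(X)
  xc <- X - mu
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  list(y = sweep(xhat, 2L, g, "*") + matrix(b, nrow(X), ncol(X), byrow = TRUE),
       xhat = xhat, inv = inv)
}

.lnBackward <- function(dy, cache, g) {
  n <- ncol(dy)
  xhat <- cache$xhat; inv <- cache$inv
  dxhat <- sweep(dy, 2L, g, "*")
  # dX = inv/n * (n*dxhat - rowSums(dxhat) - xhat * rowSums(dxhat * xhat))
  dX <- inv * (dxhat - rowSums(dxhat) / n - xhat * rowSums(dxhat * xhat) / n)
  list(dX = dX, dg = colSums(dy * xhat), db = colSums(dy))
}

.blockForward <- function(X, p, b, nHeads) {
  d <- ncol(X)
  dh <- d %/% nHeads
  ln1 <- .lnForward(X, p[[paste0("ln1g", b)]], p[[paste0("ln1b", b)]])
  Xn <- ln1$y
  Q <- Xn %*% t(p[[paste0("Wq", b)]])
  K <- Xn %*% t(p[[paste0("Wk", b)]])
  V <- Xn %*% t(p[[paste0("Wv", b)]])
  O <- matrix(0, nrow(X), d)
  Wlist <- vector("list", nHeads)
  for (hd in seq_len(nHeads)) {
    cols <- ((hd - 1L) * dh + 1L):(hd * dh)
    S <- Q[, cols, drop = FALSE] %*% t(K[, cols, drop = FALSE]) / sqrt(dh)
    Wt <- .softmaxRows(S)
    O[, cols] <- Wt %*% V[, cols, drop = FALSE]
    Wlist[[hd]] <- Wt
  }
  att <- O %*% t(p[[paste0("Wo", b)]])
  X1 <- X + att
  ln2 <- .lnForward(X1, p[[paste0("ln2g", b)]], p[[paste0("ln2b", b)]])
  H1pre <- ln2$y %*% t(p[[paste0("W1", b)]]) +
    matrix(p[[paste0("b1", b)]], nrow(X), length(p[[paste0("b1", b)]]),
           byrow = TRUE)
  H1 <- pmax(H1pre, 0)
  mlp <- H1 %*% t(p[[paste0("W2", b)]]) +
    matrix(p[[paste0("b2", b)]], nrow(X), d, byrow = TRUE)
  X2 <- X1 + mlp
  list(out = X2, X = X, ln1 = ln1, Xn = Xn, Q = Q, K = K, V = V,
       Wlist = Wlist, O = O, X1 = X1, ln2 = ln2, H1 = H1)
}

.blockBackward <- function(dX2, cache, p, b, nHeads, grads) {
  d <- ncol(dX2)
  dh <- d %/% nHeads
  # MLP path
  dmlp <- dX2
  dH1 <- dmlp %*% p[[paste0("W2", b)]]
  grads[[paste0("W2", b)]] <- grads[[paste0("W2", b)]] + t(dmlp) %*% cache$H1
  grads[[paste0("b2", b)]] <- grads[[paste0("b2", b)]] + colSums(dmlp)
  dH1pre <- dH1 * (cache$H1 > 0)
  grads[[paste0("W1", b)]] <- grads[[paste0("W1", b)]] +
    t(dH1pre) %*% cache$ln2$y
  grads[[paste0("b1", b)]] <- grads[[paste0("b1", b)]] + colSums(dH1pre)
  dln2y <- dH1pre %*% p[[paste0("W1", b)]]
  ln2b <- .lnBackward(dln2y, cache$ln2, p[[paste0("ln2g", b)]])
  grads[[paste0("ln2g", b)]] <- grads[[paste0("ln2g", b)]] + ln2b$dg
  grads[[paste0("ln2b", b)]] <- grads[[paste0("ln2b", b)]] + ln2b$db
  dX1 <- dX2 + ln2b$dX
  # attention path
  datt <- dX1
  dO <- datt %*% p[[paste0("Wo", b)]]
  grads[[paste0("Wo", b)]] <- grads[[paste0("Wo", b)]] + t(datt) %*% cache$O
  dQ <- matrix(0, nrow(dX2), d); dK <- matrix(0, nrow(dX2), d)
  dV <- matrix(0, nrow(dX2), d)
  for (hd in seq_len(nHeads)) {
    cols <- ((hd - 1L) * dh + 1L):(hd * dh)
    Wt <- cache$Wlist[[hd]]
    dOh <- dO[, cols, drop = FALSE]
    Vh <- cache$V[, cols, drop = FALSE]
    dW <- dOh %*% t(Vh)
    dV[, cols] <- t(Wt) %*% dOh
    dS <- Wt * (dW - rowSums(dW * Wt))
    dQ[, cols] <- dS %*% cache$K[, cols, drop = FALSE] / sqrt(dh)
    dK[, cols] <- t(dS) %*% cache$Q[, cols, drop = FALSE] / sqrt(dh)
  }
  dXn <- dQ %*% p[[paste0("Wq", b)]] + dK %*% p[[paste0("Wk", b)]] +
    dV %*% p[[paste0("Wv", b)]]
  grads[[paste0("Wq", b)]] <- grads[[paste0("Wq", b)]] + t(dQ) %*% cache$Xn
  grads[[paste0("Wk", b)]] <- grads[[paste0("Wk", b)]] + t(dK) %*% cache$Xn
  grads[[paste0("Wv", b)]] <- grads[[paste0("Wv", b)]] + t(dV) %*% cache$Xn
  ln1b <- .lnBackward(dXn, cache$ln1, p[[paste0("ln1g", b)]])
  grads[[paste0("ln1g", b)]] <- grads[[paste0("ln1g", b)]] + ln1b$dg
  grads[[paste0("ln1b", b)]] <- grads[[paste0("ln1b", b)]] + ln1b$db
  list(dX = dX1 + ln1b$dX, grads = grads)
}

# token embedding of one window (mirrors patchEmbed(); caches for backprop)
.embedForward <- function(window, p, cfg) {
  img <- window %*% t(p$Wproj)
  imgDim <- dim(img)
  imgFull <- img
  if (!is.null(cfg$poolTo)) img <- .avgPool2d(img, cfg$poolTo)
  Tg <- nrow(img); Dg <- ncol(img)
  patch <- cfg$patch
  nR <- Tg %/% patch; nC <- Dg %/% patch
  tiles <- matrix(0, nR * nC, patch * patch)
  k <- 1L
  for (r in seq_len(nR)) {
    rows <- ((r - 1L) * patch + 1L):(r * patch)
    for (cc in seq_len(nC)) {
      tiles[k, ] <- as.numeric(img[rows, ((cc - 1L) * patch + 1L):(cc * patch)])
      k <- k + 1L
    }
  }
  tok <- tiles %*% t(p$tokenProj)
  pe <- .sinusoidalPE(nR, ncol(tok))
  tok <- tok + pe[rep(seq_len(nR), each = nC), , drop = FALSE]
  blockMod <- rep(seq_len(cfg$nModalities), length.out = nC)
  tok <- tok + t(p$modalityEmb)[rep(blockMod, times = nR), , drop = FALSE]
  list(tok = tok, tiles = tiles, img = img, imgFull = imgFull,
       imgDim = imgDim, nR = nR, nC = nC, blockMod = blockMod)
}

.embedBackward <- function(dtok, cache, window, p, cfg, grads) {
  grads$tokenProj <- grads$tokenProj + t(dtok) %*% cache$tiles
  modIdx <- rep(cache$blockMod, times = cache$nR)
  for (m in seq_len(cfg$nModalities)) {
    sel <- which(modIdx == m)
    if (length(sel))
      grads$modalityEmb[, m] <- grads$modalityEmb[, m] +
        colSums(dtok[sel, , drop = FALSE])
  }
  dtiles <- dtok %*% p$tokenProj
  patch <- cfg$patch
  dimg <- matrix(0, nrow(cache$img), ncol(cache$img))
  k <- 1L
  for (r in seq_len(cache$nR)) {
    rows <- ((r - 1L) * patch + 1L):(r * patch)
    for (cc in seq_len(cache$nC)) {
      cols <- ((cc - 1L) * patch + 1L):(cc * patch)
      dimg[rows, cols] <- dimg[rows, cols] +
        matrix(dtiles[k, ], patch, patch)
      k <- k + 1L
    }
  }
  if (!is.null(cfg$poolTo)) {
    fr <- cache$imgDim[1L] %/% cfg$poolTo
    fc <- cache$imgDim[2L] %/% cfg$poolTo
    dfull <- matrix(0, cache$imgDim[1L], cache$imgDim[2L])
    for (r in seq_len(cfg$poolTo)) {
      for (cc in seq_len(cfg$poolTo)) {
        dfull[((r - 1L) * fr + 1L):(r * fr),
              ((cc - 1L) * fc + 1L):(cc * fc)] <- dimg[r, cc] / (fr * fc)
      }
    }
    dimg <- dfull
  }
  grads$Wproj <- grads$Wproj + t(dimg) %*% window
  grads
}

# batched LSTM over an input array B x P x Cin; returns final hidden state
.lstmForward <- function(X, p, h) {
  B <- dim(X)[1L]; P <- dim(X)[2L]
  H <- matrix(0, B, h); C <- matrix(0, B, h)
  cache <- vector("list", P)
  for (t in seq_len(P)) {
    xt <- matrix(X[, t, ], B)
    A <- cbind(H, xt) %*% t(p$Wlstm) +
      matrix(p$blstm, B, 4L * h, byrow = TRUE)
    f <- .sigmoid(A[, seq_len(h), drop = FALSE])
    i <- .sigmoid(A[, h + seq_len(h), drop = FALSE])
    g <- tanh(A[, 2L * h + seq_len(h), drop = FALSE])
    o <- .sigmoid(A[, 3L * h + seq_len(h), drop = FALSE])
    Cprev <- C
    C <- f * Cprev + i * g
    Hprev <- H
    H <- o * tanh(C)
    cache[[t]] <- list(f = f, i = i, g = g, o = o, C = C, Cprev = Cprev,
                       Hprev = Hprev, xt = xt)
  }
  list(H = H, cache = cache)
}

.lstmBackward <- function(dH, fw, p, h, grads, wantInputGrad = FALSE) {
  P <- length(fw$cache)
  B <- nrow(dH)
  Cin <- ncol(fw$cache[[1L]]$xt)
  dX <- if (wantInputGrad) array(0, c(B, P, Cin)) else NULL
  dC <- matrix(0, B, h)
  dWl <- matrix(0, nrow(p$Wlstm), ncol(p$Wlstm))
  dbl <- numeric(4L * h)
  for (t in P:1) {
    cc <- fw$cache[[t]]
    tC <- tanh(cc$C)
    do <- dH * tC
    dC <- dC + dH * cc$o * (1 - tC^2)
    df <- dC * cc$Cprev
    di <- dC * cc$g
    dg <- dC * cc$i
    dA <- cbind(df * cc$f * (1 - cc$f),
                di * cc$i * (1 - cc$i),
                dg * (1 - cc$g^2),
                do * cc$o * (1 - cc$o))
    hx <- cbind(cc$Hprev, cc$xt)
    dWl <- dWl + t(dA) %*% hx
    dbl <- dbl + colSums(dA)
    dhx <- dA %*% p$Wlstm
    dH <- dhx[, seq_len(h), drop = FALSE]
    if (wantInputGrad) dX[, t, ] <- dhx[, h + seq_len(Cin), drop = FALSE]
    dC <- dC * cc$f
  }
  grads$Wlstm <- grads$Wlstm + dWl
  grads$blstm <- grads$blstm + dbl
  attr(grads, "dX") <- dX
  grads
}

# ---- full batch forward/backward ----------------------------------------

# X: B x T x C array. Returns loss, logits, caches (training mode) or just
# logits/probabilities (eval). Diffusion corruption and dropout only when
# training = TRUE; RNG draws come from the current global RNG state.
.ditlstmForward <- function(X, y, p, cfg, schedule, training = TRUE,
                            ablation = c("none", "dit", "lstm")) {
  ablation <- match.arg(ablation)
  B <- dim(X)[1L]
  h <- cfg$lstmHidden
  d <- cfg$dEmb
  nTok <- NULL
  embeds <- vector("list", B)
  toks <- vector("list", B)
  noises <- vector("list", B)
  ts <- integer(B)
  lstmKeep <- seq(1L, dim(X)[2L], by = cfg$lstmSubsample)
  Xl <- array(0, c(B, length(lstmKeep), cfg$dImg))
  peT <- if (training) .sinusoidalPE(schedule$steps, d) else NULL
  for (bI in seq_len(B)) {
    emb <- .embedForward(matrix(X[bI, , ], dim(X)[2L]), p, cfg)
    embeds[[bI]] <- emb
    tok <- emb$tok
    nTok <- nrow(tok)
    if (training) {
      ts[bI] <- sample.int(schedule$steps, 1L)
      dj <- diffuseTo(tok, ts[bI], schedule)
      tok <- dj$xt
      noises[[bI]] <- dj$noise
      tok <- tok + matrix(peT[ts[bI], ], nTok, d, byrow = TRUE)
    }
    toks[[bI]] <- tok
    Xl[bI, , ] <- emb$imgFull[lstmKeep, , drop = FALSE]
  }
  blockCaches <- vector("list", B)
  finalToks <- vector("list", B)
  lnFcaches <- vector("list", B)
  noisePred <- vector("list", B)
  Hdit <- matrix(0, B, d)
  for (bI in seq_len(B)) {
    Xb <- toks[[bI]]
    caches <- vector("list", cfg$nBlocks)
    for (blk in seq_len(cfg$nBlocks)) {
      caches[[blk]] <- .blockForward(Xb, p, blk, cfg$nHeads)
      Xb <- caches[[blk]]$out
    }
    lnF <- .lnForward(Xb, p$lnFg, p$lnFb)
    blockCaches[[bI]] <- caches
    lnFcaches[[bI]] <- lnF
    finalToks[[bI]] <- lnF$y
    if (training)
      noisePred[[bI]] <- lnF$y %*% t(p$Wnoise) +
        matrix(p$bnoise, nTok, d, byrow = TRUE)
    Hdit[bI, ] <- colMeans(lnF$y)
  }
  hDit <- Hdit %*% t(p$Wd) + matrix(p$bd, B, h, byrow = TRUE)
  lstmFw <- .lstmForward(Xl, p, h)
  hLstm <- lstmFw$H
  gPre <- cbind(hDit, hLstm) %*% t(p$Wg) + matrix(p$bg, B, h, byrow = TRUE)
  G <- .sigmoid(gPre)
  if (ablation == "dit") G <- matrix(1, B, h)
  if (ablation == "lstm") G <- matrix(0, B, h)
  fused <- G * hDit + (1 - G) * hLstm
  mask <- NULL
  if (training && cfg$dropoutFusion > 0) {
    mask <- matrix(stats::rbinom(B * h, 1L, 1 - cfg$dropoutFusion), B, h)
    fusedDrop <- fused * mask / (1 - cfg$dropoutFusion)
  } else fusedDrop <- fused
  logits <- fusedDrop %*% t(p$Wcls) + matrix(p$bcls, B, nrow(p$Wcls),
                                             byrow = TRUE)
  lse <- apply(logits, 1L, function(r) { m <- max(r); m + log(sum(exp(r - m))) })
  logp <- logits - lse
  probs <- exp(logp)
  out <- list(logits = logits, probs = probs)
  if (!is.null(y)) {
    ce <- mean(-logp[cbind(seq_len(B), y)])
    mse <- 0
    if (training) {
      mse <- mean(vapply(seq_len(B), function(bI)
        mean((noisePred[[bI]] - noises[[bI]])^2), numeric(1L)))
    }
    out$loss <- cfg$lambda * mse + (1 - cfg$lambda) * ce
    out$ce <- ce; out$mse <- mse
  }
  if (training) {
    out$cache <- list(embeds = embeds, toks = toks, noises = noises, ts = ts,
                      blockCaches = blockCaches, lnFcaches = lnFcaches,
                      finalToks = finalToks, noisePred = noisePred,
                      Hdit = Hdit, hDit = hDit, lstmFw = lstmFw,
                      hLstm = hLstm, G = G, gPre = gPre, fused = fused,
                      mask = mask, fusedDrop = fusedDrop, Xl = Xl,
                      lstmKeep = lstmKeep, nTok = nTok,
                      ablation = ablation)
  }
  out
}

.zeroLike <- function(p) lapply(p, function(w) w * 0)

.ditlstmBackward <- function(X, y, p, cfg, schedule, fwd) {
  cc <- fwd$cache
  B <- dim(X)[1L]
  h <- cfg$lstmHidden
  d <- cfg$dEmb
  nTok <- cc$nTok
  grads <- .zeroLike(p)
  # classifier
  dlogits <- fwd$probs
  dlogits[cbind(seq_len(B), y)] <- dlogits[cbind(seq_len(B), y)] - 1
  dlogits <- dlogits * (1 - cfg$lambda) / B
  grads$Wcls <- t(dlogits) %*% cc$fusedDrop
  grads$bcls <- colSums(dlogits)
  dfusedDrop <- dlogits %*% p$Wcls
  dfused <- if (!is.null(cc$mask))
    dfusedDrop * cc$mask / (1 - cfg$dropoutFusion) else dfusedDrop
  # gate
  dhDit <- dfused * cc$G
  dhLstm <- dfused * (1 - cc$G)
  if (cc$ablation == "none") {
    dG <- dfused * (cc$hDit - cc$hLstm)
    dgPre <- dG * cc$G * (1 - cc$G)
    grads$Wg <- t(dgPre) %*% cbind(cc$hDit, cc$hLstm)
    grads$bg <- colSums(dgPre)
    dhd2 <- dgPre %*% p$Wg
    dhDit <- dhDit + dhd2[, seq_len(h), drop = FALSE]
    dhLstm <- dhLstm + dhd2[, h + seq_len(h), drop = FALSE]
  }
  # DiT pooled projection
  grads$Wd <- t(dhDit) %*% cc$Hdit
  grads$bd <- colSums(dhDit)
  dHdit <- dhDit %*% p$Wd
  # LSTM branch (back through time, then into the pseudo-image)
  grads <- .lstmBackward(dhLstm, cc$lstmFw, p, h, grads,
                         wantInputGrad = TRUE)
  dXl <- attr(grads, "dX")
  attr(grads, "dX") <- NULL
  # per-sample transformer backward
  mseScale <- cfg$lambda / (B * nTok * d)
  for (bI in seq_len(B)) {
    dFinal <- matrix(dHdit[bI, ] / nTok, nTok, d, byrow = TRUE)
    dnp <- 2 * (cc$noisePred[[bI]] - cc$noises[[bI]]) * mseScale
    grads$Wnoise <- grads$Wnoise + t(dnp) %*% cc$finalToks[[bI]]
    grads$bnoise <- grads$bnoise + colSums(dnp)
    dFinal <- dFinal + dnp %*% p$Wnoise
    lnb <- .lnBackward(dFinal, cc$lnFcaches[[bI]], p$lnFg)
    grads$lnFg <- grads$lnFg + lnb$dg
    grads$lnFb <- grads$lnFb + lnb$db
    dXb <- lnb$dX
    for (blk in cfg$nBlocks:1) {
      bb <- .blockBackward(dXb, cc$blockCaches[[bI]][[blk]], p, blk,
                           cfg$nHeads, grads)
      dXb <- bb$dX
      grads <- bb$grads
    }
    # through the diffusion corruption: x_t = sqrt(abar) x0 + ...
    dtok <- dXb * sqrt(schedule$alphaBar[cc$ts[bI]])
    grads <- .embedBackward(dtok, cc$embeds[[bI]],
                            matrix(X[bI, , ], dim(X)[2L]), p, cfg, grads)
  }
  # the LSTM consumes subsampled unpooled pseudo-image rows: those rows'
  # gradients flow straight into the step projection
  for (bI in seq_len(B)) {
    dimg <- matrix(dXl[bI, , ], dim(dXl)[2L])
    win <- matrix(X[bI, , ], dim(X)[2L])
    grads$Wproj <- grads$Wproj +
      t(dimg) %*% win[cc$lstmKeep, , drop = FALSE]
  }
  grads
}

# ---- Adam ----------------------------------------------------------------

.adamInit <- function(p) list(m = .zeroLike(p), v = .zeroLike(p), t = 0L)

.adamStep <- function(p, grads, opt, lr, wd, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  opt$t <- opt$t + 1L
  for (nm in names(p)) {
    g <- grads[[nm]] + wd * p[[nm]]    # L2 weight decay in the gradient
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g^2
    mhat <- opt$m[[nm]] / (1 - beta1^opt$t)
    vhat <- opt$v[[nm]] / (1 - beta2^opt$t)
    p[[nm]] <- p[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(p = p, opt = opt)
}

# ---- training / prediction ----------------------------------------------

#' Train the DiT-LSTM posture recognizer
#'
#' Trains on the `train` split of a [WindowedGaitData-class], monitoring the
#' `val` split for early stopping (accuracy plateau with configurable
#' patience), and returns the best-validation checkpoint. Training-time
#' behaviour per batch: tokens are corrupted at a uniformly sampled
#' diffusion step and the model jointly predicts that noise (MSE, weight
#' `lambda`) and the class (cross-entropy, weight `1 - lambda`). Inference
#' is the clean forward pass (no corruption, no dropout). Fully
#' deterministic given `seed`.
#'
#' @param data A [WindowedGaitData-class] with train and val splits.
#' @param config A [ditlstmConfig()] (use [scaledDownConfig()] on a
#'   laptop-scale budget).
#' @param seed Integer seed controlling initialization, batching, diffusion
#'   steps, noise, and dropout.
#' @param verbose Print per-epoch progress.
#' @return A list of class `DitLstmModel`: `params`, `config`, `classes`,
#'   `normStats`, `log` (per-epoch data frame), `bestEpoch`.
#' @export
trainDitLstm <- function(data, config = scaledDownConfig(), seed = 1L,
                         verbose = FALSE) {
  stopifnot(is(data, "WindowedGaitData"))
  tr <- subsetSplit(data, "train")
  va <- subsetSplit(data, "val")
  if (nWindows(tr) == 0L || nWindows(va) == 0L)
    stop("data must contain non-empty train and val splits")
  set.seed(as.integer(seed))
  cfg <- config
  if (dim(tr@windows)[2L] != cfg$T)
    cfg$T <- dim(tr@windows)[2L]
  classes <- levels(tr@labels)
  p <- .initParams(cfg, nChannels = dim(tr@windows)[3L],
                   nClasses = length(classes))
  schedule <- diffusionSchedule(cfg$diffusionSteps, cfg$betaStart,
                                cfg$betaEnd)
  opt <- .adamInit(p)
  n <- nWindows(tr)
  yTr <- as.integer(tr@labels)
  log <- data.frame()
  best <- list(acc = -Inf, ce = Inf, p = p, epoch = 0L)
  wait <- 0L
  yVaIdx <- cbind(seq_len(nWindows(va)), as.integer(va@labels))
  for (epoch in seq_len(cfg$maxEpochs)) {
    ord <- sample.int(n)
    epochLoss <- 0; nb <- 0L
    for (start in seq(1L, n, by = cfg$batch)) {
      idx <- ord[start:min(start + cfg$batch - 1L, n)]
      Xb <- tr@windows[idx, , , drop = FALSE]
      yb <- yTr[idx]
      fwd <- .ditlstmForward(Xb, yb, p, cfg, schedule, training = TRUE)
      grads <- .ditlstmBackward(Xb, yb, p, cfg, schedule, fwd)
      st <- .adamStep(p, grads, opt, cfg$learningRate, cfg$weightDecay)
      p <- st$p; opt <- st$opt
      epochLoss <- epochLoss + fwd$loss; nb <- nb + 1L
    }
    model <- list(params = p, config = cfg, classes = classes,
                  normStats = data@normStats)
    class(model) <- "DitLstmModel"
    valPred <- predictDitLstm(model, va)
    valAcc <- mean(valPred$labels == as.character(va@labels))
    valCe <- mean(-log(pmax(valPred$probabilities[yVaIdx], 1e-12)))
    trainLoss <- epochLoss / nb
    log <- rbind(log, data.frame(epoch = epoch, trainLoss = trainLoss,
                                 valAccuracy = valAcc, valCe = valCe))
    if (verbose)
      message(sprintf("epoch %3d  loss %.4f  val acc %.3f  val ce %.3f",
                      epoch, trainLoss, valAcc, valCe))
    # best checkpoint: highest val accuracy, cross-entropy as tie-break
    if (valAcc > best$acc + 1e-12 ||
        (valAcc > best$acc - 1e-12 && valCe < best$ce)) {
      improved <- valAcc > best$acc + 1e-12
      best <- list(acc = valAcc, ce = valCe, p = p, epoch = epoch)
      wait <- if (improved) 0L else wait + 1L
    } else {
      wait <- wait + 1L
    }
    if (wait >= cfg$patience) break
  }
  structure(list(params = best$p, config = cfg, classes = classes,
                 normStats = data@normStats, log = log,
                 bestEpoch = best$epoch),
            class = "DitLstmModel")
}

#' Predict posture classes with a trained DiT-LSTM
#'
#' Clean forward pass (no diffusion corruption, no dropout): per-window
#' probability rows over the classes (summing to 1) and argmax labels.
#'
#' @param model A `DitLstmModel` from [trainDitLstm()].
#' @param data A [WindowedGaitData-class] or a bare `N x T x C` array
#'   already normalized with the training statistics.
#' @param ablation `"none"` (default), `"dit"` (gate forced to the DiT
#'   branch), or `"lstm"` (gate forced to the LSTM branch).
#' @return A list with `probabilities` (N x nClasses) and `labels`.
#' @export
predictDitLstm <- function(model, data,
                           ablation = c("none", "dit", "lstm")) {
  ablation <- match.arg(ablation)
  stopifnot(inherits(model, "DitLstmModel"))
  X <- if (is(data, "WindowedGaitData")) data@windows else data
  if (length(dim(X)) != 3L || dim(X)[3L] != ncol(model$params$Wproj))
    stop("window array has the wrong channel count for this model")
  cfg <- model$config
  schedule <- diffusionSchedule(cfg$diffusionSteps, cfg$betaStart,
                                cfg$betaEnd)
  fwd <- .ditlstmForward(X, NULL, model$params, cfg, schedule,
                         training = FALSE, ablation = ablation)
  probs <- fwd$probs
  colnames(probs) <- model$classes
  list(probabilities = probs,
       labels = model$classes[max.col(probs, ties.method = "first")])
}

#' Train the plain-LSTM reference classifier
#'
#' The temporal baseline: a single LSTM over the raw normalized window
#' (optionally time-subsampled), final hidden state into a softmax
#' classifier, cross-entropy loss, Adam. Used to gate DiT-LSTM comparisons
#' and to certify that a synthetic dataset is learnable.
#'
#' @param data A [WindowedGaitData-class].
#' @param hidden LSTM hidden size.
#' @param epochs Training epochs.
#' @param lr Learning rate.
#' @param batch Batch size.
#' @param subsample Keep every k-th time step of the window.
#' @param seed RNG seed.
#' @return A list of class `LstmRefModel` with `params`, `classes`,
#'   `subsample`, `log`.
#' @export
trainLstmReference <- function(data, hidden = 32L, epochs = 15L, lr = 3e-3,
                               batch = 30L, subsample = 4L, seed = 1L) {
  stopifnot(is(data, "WindowedGaitData"))
  tr <- subsetSplit(data, "train")
  set.seed(as.integer(seed))
  keep <- seq(1L, dim(tr@windows)[2L], by = subsample)
  X <- tr@windows[, keep, , drop = FALSE]
  y <- as.integer(tr@labels)
  classes <- levels(tr@labels)
  h <- as.integer(hidden)
  Cin <- dim(X)[3L]
  p <- list(Wlstm = .glorot(4L * h, h + Cin), blstm = numeric(4L * h),
            Wcls = .glorot(length(classes), h), bcls = numeric(length(classes)))
  p$blstm[seq_len(h)] <- 1
  opt <- .adamInit(p)
  n <- dim(X)[1L]
  log <- data.frame()
  for (epoch in seq_len(epochs)) {
    ord <- sample.int(n)
    epochLoss <- 0; nb <- 0L
    for (start in seq(1L, n, by = batch)) {
      idx <- ord[start:min(start + batch - 1L, n)]
      Xb <- X[idx, , , drop = FALSE]
      yb <- y[idx]
      fw <- .lstmForward(Xb, p, h)
      logits <- fw$H %*% t(p$Wcls) +
        matrix(p$bcls, length(idx), length(classes), byrow = TRUE)
      lse <- apply(logits, 1L, function(r) {
        m <- max(r); m + log(sum(exp(r - m)))
      })
      logp <- logits - lse
      loss <- mean(-logp[cbind(seq_along(idx), yb)])
      dlogits <- exp(logp)
      dlogits[cbind(seq_along(idx), yb)] <-
        dlogits[cbind(seq_along(idx), yb)] - 1
      dlogits <- dlogits / length(idx)
      grads <- .zeroLike(p)
      grads$Wcls <- t(dlogits) %*% fw$H
      grads$bcls <- colSums(dlogits)
      dH <- dlogits %*% p$Wcls
      grads <- .lstmBackward(dH, fw, p, h, grads)
      st <- .adamStep(p, grads, opt, lr, 0)
      p <- st$p; opt <- st$opt
      epochLoss <- epochLoss + loss; nb <- nb + 1L
    }
    log <- rbind(log, data.frame(epoch = epoch, trainLoss = epochLoss / nb))
  }
  structure(list(params = p, classes = classes, subsample = subsample,
                 hidden = h, log = log), class = "LstmRefModel")
}

#' Predict with the plain-LSTM reference classifier
#'
#' @param model An `LstmRefModel`.
#' @param data A [WindowedGaitData-class] or `N x T x C` array.
#' @return A list with `probabilities` and `labels`.
#' @export
predictLstmReference <- function(model, data) {
  stopifnot(inherits(model, "LstmRefModel"))
  X <- if (is(data, "WindowedGaitData")) data@windows else data
  keep <- seq(1L, dim(X)[2L], by = model$subsample)
  X <- X[, keep, , drop = FALSE]
  fw <- .lstmForward(X, model$params, model$hidden)
  logits <- fw$H %*% t(model$params$Wcls) +
    matrix(model$params$bcls, dim(X)[1L], length(model$classes),
           byrow = TRUE)
  lse <- apply(logits, 1L, function(r) { m <- max(r); m + log(sum(exp(r - m))) })
  probs <- exp(logits - lse)
  colnames(probs) <- model$classes
  list(probabilities = probs,
       labels = model$classes[max.col(probs, ties.method = "first")])
}

#' Save/load a DiT-LSTM checkpoint as JSON
#'
#' Single-file plain-text archive holding the configuration, all weights,
#' the class map, and the normalization statistics.
#'
#' @param model A `DitLstmModel`.
#' @param path File path.
#' @return `loadCheckpoint` returns the model; `saveCheckpoint` returns
#'   `path` invisibly.
#' @export
saveCheckpoint <- function(model, path) {
  stopifnot(inherits(model, "DitLstmModel"))
  cfgSer <- unclass(model$config)
  cfgSer <- cfgSer[!vapply(cfgSer, is.null, logical(1L))]
  ser <- list(
    config = cfgSer,
    classes = model$classes,
    normStats = model$normStats,
    bestEpoch = model$bestEpoch,
    params = lapply(model$params, function(w)
      list(dim = dim(w), values = as.numeric(w)))
  )
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(path) {
  ser <- jsonlite::read_json(path, simplifyVector = TRUE)
  params <- lapply(ser$params, function(w) {
    v <- as.numeric(w$values)
    if (!is.null(w$dim) && length(w$dim) == 2L) dim(v) <- as.integer(w$dim)
    v
  })
  cfgIn <- ser$config
  cfgIn <- cfgIn[!vapply(cfgIn, function(v)
    is.null(v) || (is.list(v) && !length(v)), logical(1L))]
  intFields <- c("diffusionSteps", "lstmHidden", "dEmb", "dImg", "patch",
                 "T", "batch", "maxEpochs", "nBlocks", "nHeads", "mlpMult",
                 "poolTo", "lstmSubsample", "patience", "nModalities")
  for (f in intersect(names(cfgIn), intFields))
    cfgIn[[f]] <- as.integer(cfgIn[[f]])
  cfg <- do.call(ditlstmConfig, cfgIn)
  ns <- ser$normStats
  structure(list(params = params, config = cfg, classes = ser$classes,
                 normStats = list(mean = as.numeric(ns$mean),
                                  sd = as.numeric(ns$sd)),
                 log = NULL, bestEpoch = ser$bestEpoch),
            class = "DitLstmModel")
}
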