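# Neural building blocks of the DiT-LSTM recognizer, as pure functions:
# scaled dot-product attention, the linear-beta diffusion forward process,
# the LSTM cell equations, pseudo-image patch embedding, gated fusion, and
# the joint diffusion+classification loss.

#' Scaled dot-product attention
#'
#' `Attention(Q, K, V) = softmax(Q K^T / sqrt(d_k)) V`, rows of the weight
#' matrix summing to 1.
#'
#' @param queries `n x d_k` matrix.
#' @param keys `m x d_k` matrix.
#' @param values `m x d_v` matrix.
#' @param dk Key dimensionality used in the scaling (defaults to
#'   `ncol(keys)`).
#' @return The `n x d_v` context matrix, with the weight matrix attached as
#'   attribute `"weights"`.
#' @examples
#' attention(diag(2), diag(2), matrix(1:4, 2))
#' @export
attention <- function(queries, keys, values, dk = ncol(keys)) {
  queries <- as.matrix(queries); keys <- as.matrix(keys)
  values <- as.matrix(values)
  if (dk <= 0) stop("dk must be positive")
  if (ncol(queries) != ncol(keys) || nrow(keys) != nrow(values))
    stop("inconsistent attention dimensions")
  scores <- queries %*% t(keys) / sqrt(dk)
  w <- .softmaxRows(scores)
  out <- w %*% values
  attr(out, "weights") <- w
  out
}

.softmaxRows <- function(x) {
  x <- x - apply(x, 1L, max)   # shift for numerical stability
  ex <- exp(x)
  ex / rowSums(ex)
}

#' Linear beta schedule for the diffusion forward process
#'
#' `beta_t` rises linearly from `betaStart` to `betaEnd` over `steps`
#' diffusion steps; the cumulative signal coefficients
#' `alphaBar_t = prod_{s<=t} (1 - beta_s)` are strictly decreasing.
#'
#' @param steps Number of diffusion steps (default 100).
#' @param betaStart,betaEnd Schedule endpoints (defaults 0.003 and 0.06).
#' @return A list with `betas`, `alphas` (`1 - beta`), and `alphaBar`.
#' @export
diffusionSchedule <- function(steps = 100L, betaStart = 0.003,
                              betaEnd = 0.06) {
  if (!(betaStart > 0 && betaStart < betaEnd && betaEnd < 1))
    stop("require 0 < betaStart < betaEnd < 1")
  betas <- seq(betaStart, betaEnd, length.out = steps)
  alphas <- 1 - betas
  list(betas = betas, alphas = alphas, alphaBar = cumprod(alphas),
       steps = as.integer(steps))
}

#' One step of the diffusion forward (noising) process
#'
#' `x_t = sqrt(1 - beta_t) x_{t-1} + sqrt(beta_t) eps` with
#' `eps ~ N(0, 1)`: a variance-preserving corruption for unit-variance
#' input.
#'
#' @param xPrev Numeric vector/matrix/array `x_{t-1}`.
#' @param t Step index in `1..steps`.
#' @param schedule A [diffusionSchedule()].
#' @param noise Optional noise tensor shaped like `xPrev` (supply zeros for
#'   the deterministic decay); drawn with `seed` when absent.
#' @param seed RNG seed for the noise draw.
#' @return `x_t`, same shape as `xPrev`.
#' @export
diffuseStep <- function(xPrev, t, schedule, noise = NULL, seed = NULL) {
  t <- as.integer(t)
  if (t < 1L || t > schedule$steps)
    stop("diffusion step t out of range 1..", schedule$steps)
  if (is.null(noise)) {
    if (!is.null(seed)) set.seed(as.integer(seed))
    noise <- stats::rnorm(length(xPrev))
    if (!is.null(dim(xPrev))) dim(noise) <- dim(xPrev)
  }
  b <- schedule$betas[t]
  sqrt(1 - b) * xPrev + sqrt(b) * noise
}

#' Closed-form jump of the diffusion process to step t
#'
#' `x_t = sqrt(alphaBar_t) x_0 + sqrt(1 - alphaBar_t) eps`, the
#' distributional composition of the per-step corruption.
#'
#' @inheritParams diffuseStep
#' @param x0 Clean input.
#' @return A list with `xt` and the `noise` used (the regression target of
#'   the noise-prediction head).
#' @export
diffuseTo <- function(x0, t, schedule, noise = NULL, seed = NULL) {
  t <- as.integer(t)
  if (t < 1L || t > schedule$steps)
    stop("diffusion step t out of range 1..", schedule$steps)
  if (is.null(noise)) {
    if (!is.null(seed)) set.seed(as.integer(seed))
    noise <- stats::rnorm(length(x0))
    if (!is.null(dim(x0))) dim(noise) <- dim(x0)
  }
  ab <- schedule$alphaBar[t]
  list(xt = sqrt(ab) * x0 + sqrt(1 - ab) * noise, noise = noise)
}

#' One LSTM cell step
#'
#' The six gate equations, in order: forget `f_t`, input `i_t`, candidate
#' `C~_t`, cell `C_t = f_t * C_{t-1} + i_t * C~_t`, output `o_t`, hidden
#' `h_t = o_t * tanh(C_t)`. Weights act on the concatenation
#' `[h_{t-1}, x_t]`.
#'
#' @param x Input vector at this step.
#' @param hPrev,cPrev Previous hidden and cell state (length `d`).
#' @param cell List with weight matrices `Wf, Wi, Wc, Wo` (`d x (d + p)`)
#'   and bias vectors `bf, bi, bc, bo` (length `d`).
#' @return A list with `h`, `c`, and the gate activations
#'   (`f`, `i`, `g`, `o`) for gradient computation.
#' @export
lstmCellStep <- function(x, hPrev, cPrev, cell) {
  hx <- c(hPrev, x)
  d <- length(hPrev)
  if (ncol(cell$Wf) != length(hx))
    stop("LSTM weight shape does not match [h, x] length")
  f <- .sigmoid(as.numeric(cell$Wf %*% hx) + cell$bf)
  i <- .sigmoid(as.numeric(cell$Wi %*% hx) + cell$bi)
  g <- tanh(as.numeric(cell$Wc %*% hx) + cell$bc)
  cNew <- f * cPrev + i * g
  o <- .sigmoid(as.numeric(cell$Wo %*% hx) + cell$bo)
  h <- o * tanh(cNew)
  list(h = h, c = cNew, f = f, i = i, g = g, o = o)
}

.sigmoid <- function(x) 1 / (1 + exp(-x))

#' Pseudo-image construction and patch tokenization
#'
#' Builds the `T x dImg` pseudo-image by linearly projecting each
#' C-dimensional time step, optionally average-pools it to a smaller square
#' for desk-scale configurations, cuts it into non-overlapping
#' `patch x patch` tiles (row-major over the time-embedding grid), projects
#' each flattened tile to `dEmb`, and adds sinusoidal positional encodings
#' along time plus per-modality embeddings. At the reference scale
#' (T = 256, dImg = 256, patch 2) this yields 128 x 128 = 16384 tokens.
#'
#' @param window `T x C` matrix (one normalized sensor window).
#' @param proj `dImg x C` step-projection matrix.
#' @param tokenProj `dEmb x patch^2` patch-projection matrix.
#' @param patch Patch side length (must divide both grid dimensions).
#' @param poolTo Optional side length to average-pool the pseudo-image to
#'   before patching (`NULL` = no pooling).
#' @param modality Optional length-C integer vector of sensor-modality ids;
#'   with `modalityEmb` (`dEmb x nModalities`) adds one embedding per token
#'   according to the dominant modality of its embedding columns.
#' @param modalityEmb Optional modality embedding matrix.
#' @return `nTokens x dEmb` token matrix, with attribute `"grid"` giving
#'   the patched grid size.
#' @export
patchEmbed <- function(window, proj, tokenProj, patch = 2L, poolTo = NULL,
                       modality = NULL, modalityEmb = NULL) {
  window <- as.matrix(window)
  img <- window %*% t(proj)            # T x dImg
  if (!is.null(poolTo)) img <- .avgPool2d(img, poolTo)
  Tg <- nrow(img); Dg <- ncol(img)
  if (Tg %% patch != 0L || Dg %% patch != 0L)
    stop("pseudo-image dimensions must be divisible by the patch size")
  nR <- Tg %/% patch; nC <- Dg %/% patch
  tiles <- matrix(0, nR * nC, patch * patch)
  k <- 1L
  for (r in seq_len(nR)) {
    rows <- ((r - 1L) * patch + 1L):(r * patch)
    for (cc in seq_len(nC)) {
      cols <- ((cc - 1L) * patch + 1L):(cc * patch)
      tiles[k, ] <- as.numeric(img[rows, cols])
      k <- k + 1L
    }
  }
  tok <- tiles %*% t(tokenProj)        # nTokens x dEmb
  pe <- .sinusoidalPE(nR, ncol(tok))   # position along (patched) time
  tok <- tok + pe[rep(seq_len(nR), each = nC), , drop = FALSE]
  if (!is.null(modalityEmb)) {
    # tokens inherit the modality embedding of their column block
    blockMod <- rep(seq_len(ncol(modalityEmb)), length.out = nC)
    tok <- tok + t(modalityEmb)[rep(blockMod, times = nR), , drop = FALSE]
  }
  attr(tok, "grid") <- c(nR, nC)
  tok
}

.avgPool2d <- function(img, sideTo) {
  fr <- nrow(img) %/% sideTo; fc <- ncol(img) %/% sideTo
  if (fr < 1L || fc < 1L) stop("poolTo larger than the pseudo-image")
  out <- matrix(0, sideTo, sideTo)
  for (r in seq_len(sideTo)) {
    for (cc in seq_len(sideTo)) {
      out[r, cc] <- mean(img[((r - 1L) * fr + 1L):(r * fr),
                             ((cc - 1L) * fc + 1L):(cc * fc)])
    }
  }
  out
}

.sinusoidalPE <- function(n, d) {
  pos <- seq_len(n) - 1L
  i <- seq_len(d) - 1L
  angle <- outer(pos, 10000^(-(i %/% 2L) * 2 / d))
  pe <- matrix(0, n, d)
  even <- which(i %% 2L == 0L); odd <- which(i %% 2L == 1L)
  pe[, even] <- sin(angle[, even, drop = FALSE])
  pe[, odd] <- cos(angle[, odd, drop = FALSE])
  pe
}

#' Gated fusion of the DiT and LSTM representations
#'
#' `g = sigmoid(Wg [h_dit; h_lstm] + bg)`;
#' `fused = g * h_dit + (1 - g) * h_lstm`. During training, dropout is
#' applied to the fused vector (inverted dropout; inactive in evaluation
#' mode).
#'
#' @param hDit,hLstm Equal-length representation vectors.
#' @param Wg `d x 2d` gate weight matrix.
#' @param bg Length-`d` gate bias.
#' @param dropout Dropout probability applied to the fused vector when
#'   `training = TRUE`.
#' @param training Logical; dropout only acts in training mode.
#' @param dropMask Optional precomputed 0/1 mask (for reproducible
#'   gradients).
#' @return The fused vector with attributes `"gate"` and `"mask"`.
#' @export
gatedFuse <- function(hDit, hLstm, Wg, bg, dropout = 0, training = FALSE,
                      dropMask = NULL) {
  if (length(hDit) != length(hLstm))
    stop("hDit and hLstm must have equal length")
  g <- .sigmoid(as.numeric(Wg %*% c(hDit, hLstm)) + bg)
  fused <- g * hDit + (1 - g) * hLstm
  mask <- NULL
  if (training && dropout > 0) {
    if (is.null(dropMask))
      dropMask <- stats::rbinom(length(fused), 1L, 1 - dropout)
    fused <- fused * dropMask / (1 - dropout)
    mask <- dropMask
  }
  attr(fused, "gate") <- g
  attr(fused, "mask") <- mask
  fused
}

#' Joint diffusion + classification loss
#'
#' `L = lambda * MSE(noisePred, noiseTrue) +
#'      (1 - lambda) * CE(logits, label)`,
#' the training objective balancing the diffusion noise-prediction MSE and
#' the posture-class cross-entropy; `lambda = 0.7` weights the diffusion
#' term by default.
#'
#' @param noisePred,noiseTrue Noise prediction and target (same shape).
#' @param classLogits Numeric vector of unnormalized class scores.
#' @param classLabel Integer class index (1-based).
#' @param lambda Loss-balancing coefficient in `[0, 1]`.
#' @return Scalar loss, with attribute `"parts"` holding the two terms.
#' @export
jointLoss <- function(noisePred, noiseTrue, classLogits, classLabel,
                      lambda = 0.7) {
  if (!is.finite(lambda) || lambda < 0 || lambda > 1)
    stop("lambda must lie in [0, 1]")
  mse <- mean((noisePred - noiseTrue)^2)
  lp <- .logSoftmax(classLogits)
  ce <- -lp[classLabel]
  loss <- lambda * mse + (1 - lambda) * ce
  attr(loss, "parts") <- c(mse = mse, ce = ce)
  loss
}

.logSoftmax <- function(x) {
  m <- max(x)
  x - m - log(sum(exp(x - m)))
}
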