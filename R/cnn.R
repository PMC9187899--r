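## Seven-layer 1-D convolutional binary classifier over the 35-feature
## vector: six valid (no padding, stride 1) convolutions with ReLU followed
## by a final convolution whose kernel spans the remaining length, with a
## Sigmoid output. Forward/backward passes are written directly (im2col per
## position); training is seeded mini-batch Adam on binary cross-entropy.

#' CNN configuration
#'
#' The default schedule maps a length-35, 1-channel input through channels
#' 1-8-16-16-32-32-16-1 with kernel 3 in the first six layers and a final
#' kernel spanning the remaining length 23, reducing to a single scalar.
#'
#' @param channels integer vector of length 8: input channel count followed
#'   by the seven layers' output channels (the last must be 1).
#' @param kernels integer vector of length 7 (the last entry may be `NA` to
#'   auto-span the remaining length).
#' @param inputLength input vector length (35).
#' @param learningRate,epochs,batchSize,seed training schedule.
#' @return list of class `CNNConfig`.
#' @export
cnnConfig <- function(channels = c(1, 8, 16, 16, 32, 32, 16, 1),
                      kernels = c(3, 3, 3, 3, 3, 3, NA),
                      inputLength = 35L, learningRate = 1e-3,
                      epochs = 100L, batchSize = 64L, seed = 1L) {
  if (length(channels) != 8 || length(kernels) != 7)
    stop("exactly 7 convolution layers are required")
  if (channels[8] != 1) stop("final layer must emit a single channel")
  len <- inputLength
  for (i in 1:6) len <- len - kernels[i] + 1
  if (is.na(kernels[7])) kernels[7] <- len
  len <- len - kernels[7] + 1
  if (len != 1)
    stop("layer schedule does not reduce the input to length 1 (got ", len, ")")
  structure(list(channels = as.integer(channels), kernels = as.integer(kernels),
                 inputLength = as.integer(inputLength),
                 learningRate = learningRate, epochs = as.integer(epochs),
                 batchSize = as.integer(batchSize), seed = as.integer(seed)),
            class = "CNNConfig")
}

#' Build (initialize) the CNN
#'
#' He-normal weight initialization; shapes are validated against the
#' schedule's receptive-field arithmetic at build time.
#'
#' @param config a [cnnConfig()].
#' @param seed integer seed (defaults to the config seed).
#' @return A [CNNModel-class] with untrained weights.
#' @export
cnnBuild <- function(config = cnnConfig(), seed = config$seed) {
  set.seed(as.integer(seed))
  weights <- vector("list", 7)
  for (i in 1:7) {
    k <- config$kernels[i]; cin <- config$channels[i]; cout <- config$channels[i + 1]
    weights[[i]] <- list(
      W = array(stats::rnorm(k * cin * cout, 0, sqrt(2 / (k * cin))),
                dim = c(k, cin, cout)),
      b = rep(0, cout))
  }
  methods::new("CNNModel", config = unclass(config), weights = weights,
               lossTrace = numeric(0))
}

#' Parameter count of a CNN schedule
#'
#' @param config a [cnnConfig()].
#' @return total number of weights and biases.
#' @export
cnnParameterCount <- function(config = cnnConfig()) {
  sum(vapply(1:7, function(i)
    config$kernels[i] * config$channels[i] * config$channels[i + 1] +
      config$channels[i + 1], 0))
}

## valid 1-D convolution of A (n, cin, len) with W (k, cin, cout)
.conv1d <- function(A, W, b) {
  dA <- dim(A); n <- dA[1]; cin <- dA[2]; len <- dA[3]
  dW <- dim(W); k <- dW[1]; cout <- dW[3]
  lout <- len - k + 1
  Wmat <- matrix(aperm(W, c(2, 1, 3)), cin * k, cout)  # row = (kk-1)*cin + c
  out <- array(0, dim = c(n, cout, lout))
  for (t in seq_len(lout)) {
    Xt <- matrix(A[, , t:(t + k - 1), drop = FALSE], n, cin * k)
    out[, , t] <- Xt %*% Wmat + matrix(b, n, cout, byrow = TRUE)
  }
  out
}

## full forward pass retaining pre-activations for backprop
.cnnForwardFull <- function(model, X) {
  n <- nrow(X)
  A <- array(X, dim = c(n, 1, ncol(X)))
  acts <- list(A)
  pre <- vector("list", 7)
  for (i in 1:7) {
    Z <- .conv1d(A, model@weights[[i]]$W, model@weights[[i]]$b)
    pre[[i]] <- Z
    A <- if (i < 7) pmax(Z, 0) else 1 / (1 + exp(-Z))
    acts[[i + 1]] <- A
  }
  list(prob = as.vector(acts[[8]]), acts = acts, pre = pre)
}

#' CNN forward pass
#'
#' @param model a [CNNModel-class].
#' @param x length-35 vector or n x 35 matrix.
#' @return death probabilities in (0, 1).
#' @export
cnnForward <- function(model, x) {
  if (!is.matrix(x)) x <- matrix(x, 1)
  if (ncol(x) != model@config$inputLength)
    stop("expected input length ", model@config$inputLength)
  .cnnForwardFull(model, x)$prob
}

## backward pass: returns per-layer gradients given dLoss/dProb-preactivation
.cnnBackward <- function(model, fwd, dZlast) {
  grads <- vector("list", 7)
  dOut <- dZlast  # gradient wrt pre-activation of layer 7, array (n, 1, 1)
  for (i in 7:1) {
    W <- model@weights[[i]]$W
    dW <- dim(W); k <- dW[1]; cin <- dW[2]; cout <- dW[3]
    A <- fwd$acts[[i]]
    dA <- dim(A); n <- dA[1]; len <- dA[3]
    lout <- len - k + 1
    Wmat <- matrix(aperm(W, c(2, 1, 3)), cin * k, cout)
    gW <- matrix(0, cin * k, cout)
    gb <- rep(0, cout)
    dAprev <- array(0, dim = dim(A))
    for (t in seq_len(lout)) {
      dZt <- matrix(dOut[, , t], n, cout)
      Xt <- matrix(A[, , t:(t + k - 1), drop = FALSE], n, cin * k)
      gW <- gW + crossprod(Xt, dZt)
      gb <- gb + colSums(dZt)
      dAprev[, , t:(t + k - 1)] <- dAprev[, , t:(t + k - 1), drop = FALSE] +
        array(dZt %*% t(Wmat), dim = c(n, cin, k))
    }
    grads[[i]] <- list(W = aperm(array(gW, dim = c(cin, k, cout)), c(2, 1, 3)),
                       b = gb)
    if (i > 1) {
      ## through the previous layer's ReLU
      dOut <- dAprev * (fwd$pre[[i - 1]] > 0)
    }
  }
  grads
}

#' Train the CNN
#'
#' Seeded mini-batch Adam on binary cross-entropy; the positive class is
#' death.
#'
#' @param x n x 35 matrix of normalized features, or a normalized
#'   [SepsisCohort-class].
#' @param y binary labels (1 = death); ignored when `x` is a cohort.
#' @param config a [cnnConfig()].
#' @return A trained [CNNModel-class] with its epoch loss trace.
#' @export
cnnFit <- function(x, y = NULL, config = cnnConfig()) {
  if (methods::is(x, "SepsisCohort")) {
    y <- 1 - SummarizedExperiment::colData(x)$survived_28d
    x <- bloodTests(x)
  }
  y <- as.numeric(y)
  if (length(unique(y)) < 2) stop("both classes must be present")
  model <- cnnBuild(config, seed = config$seed)
  n <- nrow(x)
  mState <- vState <- lapply(model@weights, function(w)
    list(W = w$W * 0, b = w$b * 0))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; t <- 0
  set.seed(config$seed + 1L)
  losses <- numeric(config$epochs)
  for (ep in seq_len(config$epochs)) {
    idx <- sample.int(n)
    epLoss <- 0; nb <- 0
    for (start in seq(1, n, by = config$batchSize)) {
      bidx <- idx[start:min(start + config$batchSize - 1, n)]
      Xb <- x[bidx, , drop = FALSE]; yb <- y[bidx]
      fwd <- .cnnForwardFull(model, Xb)
      p <- pmin(pmax(fwd$prob, 1e-12), 1 - 1e-12)
      loss <- -mean(yb * log(p) + (1 - yb) * log(1 - p))
      if (!is.finite(loss)) stop("training diverged (non-finite loss)")
      ## BCE + sigmoid: dL/dz = (p - y) / batch
      dZ <- array((fwd$prob - yb) / length(yb), dim = c(length(yb), 1, 1))
      grads <- .cnnBackward(model, fwd, dZ)
      t <- t + 1
      for (i in 1:7) for (nm in c("W", "b")) {
        g <- grads[[i]][[nm]]
        mState[[i]][[nm]] <- b1 * mState[[i]][[nm]] + (1 - b1) * g
        vState[[i]][[nm]] <- b2 * vState[[i]][[nm]] + (1 - b2) * g^2
        mh <- mState[[i]][[nm]] / (1 - b1^t)
        vh <- vState[[i]][[nm]] / (1 - b2^t)
        model@weights[[i]][[nm]] <- model@weights[[i]][[nm]] -
          config$learningRate * mh / (sqrt(vh) + eps)
      }
      epLoss <- epLoss + loss; nb <- nb + 1
    }
    losses[ep] <- epLoss / nb
  }
  model@lossTrace <- losses
  model
}

#' Predict with a trained CNN
#'
#' @param model a [CNNModel-class].
#' @param x n x 35 matrix or a normalized [SepsisCohort-class].
#' @return data.frame with `p_death` and `label` (1 = death iff
#'   `p_death > 0.5`).
#' @export
cnnPredict <- function(model, x) {
  if (methods::is(x, "SepsisCohort")) x <- bloodTests(x)
  p <- cnnForward(model, x)
  data.frame(p_death = p, label = as.integer(p > 0.5))
}
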