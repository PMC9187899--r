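## Double-coefficient quadratic multivariate fitting function (DCQMFF).
##
## Each of the two heads is a sum over L channels (33 by default) of a
## channel weight times a per-channel quadratic form in the 11 normalized
## inputs: y1 = sum_l b_l (a0_l + sum_i a_li x_i + sum_{i<=j} a_lij x_i x_j),
## y2 analogously with (c, d); the output pair is the softmax of (y1, y2),
## read as (p_survive, p_death). The function class collapses to a single
## 78-coefficient quadratic logit per head; the doubled parameterization is
## what is trained.

.NQUAD <- 78L  # 1 intercept + 11 linear + 66 ordered pairs i <= j

#' Quadratic feature expansion of an 11-vector
#'
#' Ordered expansion `[1, x1..x11, x_i * x_j for 1 <= i <= j <= 11]`
#' (66 products including squares), length 78. Matrices are expanded
#' row-wise.
#'
#' @param x numeric vector of length 11, or an n x 11 matrix.
#' @return length-78 vector, or n x 78 matrix.
#' @export
#' @examples
#' quadFeatures(rep(0, 11))[1]  # intercept slot
quadFeatures <- function(x) {
  if (is.matrix(x)) {
    if (ncol(x) != 11) stop("expected 11 features, got ", ncol(x))
    if (any(!is.finite(x))) stop("features must be finite")
    n <- nrow(x)
    out <- matrix(NA_real_, n, .NQUAD)
    out[, 1] <- 1
    out[, 2:12] <- x
    col <- 13L
    for (i in 1:11) for (j in i:11) {
      out[, col] <- x[, i] * x[, j]
      col <- col + 1L
    }
    out
  } else {
    if (length(x) != 11) stop("expected 11 features, got ", length(x))
    drop(quadFeatures(matrix(x, 1)))
  }
}

#' Initialize DCQMFF parameters
#'
#' Channel weights are drawn N(0, 1/sqrt(L)) and channel coefficients
#' N(0, 1/sqrt(78)) so that initial logits are O(1).
#'
#' @param L channel count (default 33).
#' @param seed integer seed.
#' @param featureNames names of the 11 inputs.
#' @return A [DCQMFFModel-class] with untrained parameters.
#' @export
dcqmffInit <- function(L = 33L, seed = 1L, featureNames = dcqmffFeatureNames()) {
  set.seed(as.integer(seed))
  L <- as.integer(L)
  if (L < 1) stop("L must be >= 1")
  methods::new("DCQMFFModel", L = L,
               b = stats::rnorm(L, 0, 1 / sqrt(L)),
               a = matrix(stats::rnorm(L * .NQUAD, 0, 1 / sqrt(.NQUAD)), L, .NQUAD),
               cc = stats::rnorm(L, 0, 1 / sqrt(L)),
               d = matrix(stats::rnorm(L * .NQUAD, 0, 1 / sqrt(.NQUAD)), L, .NQUAD),
               featureNames = featureNames, config = list(),
               lossTrace = numeric(0))
}

## raw head logits for an n x 78 expansion matrix
.dcqmffLogits <- function(model, Phi) {
  w1 <- drop(crossprod(model@a, model@b))  # 78
  w2 <- drop(crossprod(model@d, model@cc))
  cbind(y1 = drop(Phi %*% w1), y2 = drop(Phi %*% w2))
}

.softmaxPair <- function(Y) {
  m <- pmax(Y[, 1], Y[, 2])
  e1 <- exp(Y[, 1] - m); e2 <- exp(Y[, 2] - m)
  s <- e1 + e2
  cbind(p_survive = e1 / s, p_death = e2 / s)
}

#' DCQMFF forward pass
#'
#' Evaluates the two channel-summed quadratic heads and returns the softmax
#' pair `(p_survive, p_death)`, numerically stabilized by max-subtraction.
#'
#' @param model a [DCQMFFModel-class].
#' @param x length-11 vector or n x 11 matrix of normalized features.
#' @return n x 2 matrix with columns `p_survive`, `p_death` (rows sum to 1).
#' @export
dcqmffForward <- function(model, x) {
  if (!all(is.finite(model@b)) || !all(is.finite(model@a)) ||
      !all(is.finite(model@cc)) || !all(is.finite(model@d)))
    stop("non-finite parameters")
  Phi <- quadFeatures(if (is.matrix(x)) x else matrix(x, 1))
  .softmaxPair(.dcqmffLogits(model, Phi))
}

#' Collapse the double-coefficient parameterization
#'
#' The function class is exactly a quadratic logit: collapsing gives the
#' 78-coefficient vector per head, `w_k = sum_l b_l a[l, k]`, whose forward
#' pass equals the doubled form pointwise.
#'
#' @param model a [DCQMFFModel-class].
#' @return list with `w1`, `w2` (length-78 coefficient vectors).
#' @export
dcqmffCollapse <- function(model) {
  list(w1 = drop(crossprod(model@a, model@b)),
       w2 = drop(crossprod(model@d, model@cc)))
}

#' Forward pass of a collapsed quadratic logit
#'
#' @param collapsed a [dcqmffCollapse()] result.
#' @param x length-11 vector or n x 11 matrix.
#' @return n x 2 softmax matrix, identical to the doubled forward pass.
#' @export
dcqmffForwardCollapsed <- function(collapsed, x) {
  Phi <- quadFeatures(if (is.matrix(x)) x else matrix(x, 1))
  .softmaxPair(cbind(drop(Phi %*% collapsed$w1), drop(Phi %*% collapsed$w2)))
}

#' DCQMFF training configuration
#'
#' @param L channel count; `learningRate`, `epochs`, `batchSize` the
#'   mini-batch schedule; `optimizer` `"sgd"` (plain mini-batch gradient
#'   descent) or `"adam"`; `seed`; `patience` early-stop patience in epochs
#'   without training-loss improvement (Inf disables).
#' @param learningRate,epochs,batchSize,optimizer,seed,patience see above.
#' @return list of class `DCQMFFConfig`.
#' @export
dcqmffConfig <- function(L = 33L, learningRate = 1e-2, epochs = 500L,
                         batchSize = 64L, optimizer = c("adam", "sgd"),
                         seed = 1L, patience = Inf) {
  optimizer <- match.arg(optimizer)
  if (learningRate <= 0 || epochs < 1) stop("positive learning rate and epochs required")
  structure(list(L = as.integer(L), learningRate = learningRate,
                 epochs = as.integer(epochs), batchSize = as.integer(batchSize),
                 optimizer = optimizer, seed = as.integer(seed),
                 patience = patience),
            class = "DCQMFFConfig")
}

## one Adam/SGD step on a flat parameter list
.optimStep <- function(state, grads, lr, optimizer, t) {
  if (optimizer == "sgd") {
    for (nm in names(grads)) state$par[[nm]] <- state$par[[nm]] - lr * grads[[nm]]
    return(state)
  }
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  for (nm in names(grads)) {
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * grads[[nm]]
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * grads[[nm]]^2
    mhat <- state$m[[nm]] / (1 - b1^t)
    vhat <- state$v[[nm]] / (1 - b2^t)
    state$par[[nm]] <- state$par[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  state
}

## analytic gradients of mean softmax cross-entropy wrt (b, a, cc, d) on a
## batch: with g = p_death - y_death (per row), dL/dy2 = g, dL/dy1 = -g;
## chain rule through y1 = b' A phi gives dL/db = A (Phi' (-g))/n and
## dL/dA = b ((Phi' (-g))/n)'.
.dcqmffGrads <- function(par, Phi, yDeath) {
  n <- nrow(Phi)
  y1 <- drop(Phi %*% crossprod(par$a, par$b))
  y2 <- drop(Phi %*% crossprod(par$d, par$cc))
  m <- pmax(y1, y2)
  e1 <- exp(y1 - m); e2 <- exp(y2 - m)
  pDeath <- e2 / (e1 + e2)
  g <- (pDeath - yDeath) / n
  gphi1 <- drop(crossprod(Phi, -g))   # 78
  gphi2 <- drop(crossprod(Phi, g))
  loss <- -mean(ifelse(yDeath == 1, log(pmax(pDeath, 1e-300)),
                       log(pmax(1 - pDeath, 1e-300))))
  list(grads = list(b = drop(par$a %*% gphi1),
                    a = tcrossprod(par$b, gphi1),
                    cc = drop(par$d %*% gphi2),
                    d = tcrossprod(par$cc, gphi2)),
       loss = loss)
}

#' Fit the DCQMFF classifier
#'
#' Minimizes the mean softmax cross-entropy of the two-headed model over the
#' doubled parameterization by seeded mini-batch gradient training.
#'
#' @param x n x 11 matrix of normalized features (column order of
#'   [dcqmffFeatureNames()]), or a normalized [SepsisCohort-class] from which
#'   the 11 features and labels are taken.
#' @param y binary labels, 1 = death (ignored when `x` is a cohort).
#' @param config a [dcqmffConfig()].
#' @return A fitted [DCQMFFModel-class] with its epoch loss trace.
#' @export
dcqmffFit <- function(x, y = NULL, config = dcqmffConfig()) {
  if (methods::is(x, "SepsisCohort")) {
    y <- 1 - SummarizedExperiment::colData(x)$survived_28d
    x <- bloodTests(x)[, dcqmffFeatureNames(), drop = FALSE]
  }
  y <- as.numeric(y)
  if (length(unique(y)) < 2) stop("both classes must be present")
  Phi <- quadFeatures(x)
  n <- nrow(Phi)
  model <- dcqmffInit(config$L, seed = config$seed)
  par <- list(b = model@b, a = model@a, cc = model@cc, d = model@d)
  state <- list(par = par,
                m = lapply(par, function(p) p * 0),
                v = lapply(par, function(p) p * 0))
  set.seed(config$seed + 1L)
  losses <- numeric(config$epochs)
  best <- Inf; stall <- 0; t <- 0
  for (ep in seq_len(config$epochs)) {
    idx <- sample.int(n)
    epLoss <- 0; nb <- 0
    for (start in seq(1, n, by = config$batchSize)) {
      bidx <- idx[start:min(start + config$batchSize - 1, n)]
      t <- t + 1
      gr <- .dcqmffGrads(state$par, Phi[bidx, , drop = FALSE], y[bidx])
      if (!is.finite(gr$loss))
        stop("training diverged (non-finite loss); reduce the learning rate")
      state <- .optimStep(state, gr$grads, config$learningRate,
                          config$optimizer, t)
      epLoss <- epLoss + gr$loss; nb <- nb + 1
    }
    losses[ep] <- epLoss / nb
    if (losses[ep] < best - 1e-9) { best <- losses[ep]; stall <- 0 }
    else stall <- stall + 1
    if (stall >= config$patience) { losses <- losses[seq_len(ep)]; break }
  }
  methods::new("DCQMFFModel", L = config$L, b = state$par$b, a = state$par$a,
               cc = state$par$cc, d = state$par$d,
               featureNames = dcqmffFeatureNames(),
               config = unclass(config), lossTrace = losses)
}

#' Predict with a fitted DCQMFF model
#'
#' @param model a [DCQMFFModel-class].
#' @param x n x 11 matrix (training-normalizer scale) or a normalized
#'   [SepsisCohort-class].
#' @return data.frame with `p_survive`, `p_death` and `label` (1 = death iff
#'   `p_death > 0.5`; an exact tie predicts survival, the majority class).
#' @export
dcqmffPredict <- function(model, x) {
  if (methods::is(x, "SepsisCohort"))
    x <- bloodTests(x)[, model@featureNames, drop = FALSE]
  p <- dcqmffForward(model, x)
  data.frame(p_survive = p[, 1], p_death = p[, 2],
             label = as.integer(p[, 2] > 0.5))
}

#' Serialize / load DCQMFF parameters as JSON
#'
#' @param model a [DCQMFFModel-class].
#' @param path JSON file path.
#' @return `readDCQMFF` returns a shape-checked [DCQMFFModel-class].
#' @export
writeDCQMFF <- function(model, path) {
  jsonlite::write_json(list(L = model@L, b = model@b, a = model@a,
                            cc = model@cc, d = model@d,
                            featureNames = model@featureNames),
                       path, digits = NA)
  invisible(path)
}

#' @rdname writeDCQMFF
#' @export
readDCQMFF <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  methods::new("DCQMFFModel", L = as.integer(obj$L), b = as.numeric(obj$b),
               a = matrix(obj$a, as.integer(obj$L), .NQUAD),
               cc = as.numeric(obj$cc),
               d = matrix(obj$d, as.integer(obj$L), .NQUAD),
               featureNames = as.character(obj$featureNames),
               config = list(), lossTrace = numeric(0))
}
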