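test_that("the quadratic expansion has the documented layout", {
  z <- quadFeatures(rep(0, 11))
  expect_length(z, 78)
  expect_equal(z, c(1, rep(0, 77)))
  o <- quadFeatures(rep(1, 11))
  expect_equal(o, rep(1, 78))
  ## term order: intercept, linear, then products for i <= j row-wise
  x <- seq_len(11) / 10
  phi <- quadFeatures(x)
  expect_equal(phi[1], 1)
  expect_equal(phi[2:12], x)
  expect_equal(phi[13], x[1]^2)
  expect_equal(phi[14], x[1] * x[2])
  expect_equal(phi[78], x[11]^2)
  ## matrix input expands row-wise
  M <- rbind(x, rep(0, 11))
  expect_equal(quadFeatures(M)[1, ], phi)
  expect_error(quadFeatures(rep(0, 10)), "11")
  expect_error(quadFeatures(c(rep(0, 10), NA)), "finite")
})

test_that("the forward pass equals an explicit triple-loop evaluation", {
  model <- dcqmffInit(L = 5, seed = 71)
  set.seed(72)
  X <- matrix(stats::runif(4 * 11), 4, 11)
  p <- dcqmffForward(model, X)
  for (r in 1:4) {
    x <- X[r, ]
    yHead <- function(wts, coefs) {
      y <- 0
      for (l in 1:5) {
        q <- coefs[l, 1]
        for (i in 1:11) q <- q + coefs[l, 1 + i] * x[i]
        col <- 13
        for (i in 1:11) for (j in i:11) {
          q <- q + coefs[l, col] * x[i] * x[j]
          col <- col + 1
        }
        y <- y + wts[l] * q
      }
      y
    }
    y1 <- yHead(model@b, model@a)
    y2 <- yHead(model@cc, model@d)
    expect_equal(unname(p[r, "p_death"]), exp(y2) / (exp(y1) + exp(y2)),
                 tolerance = 1e-10)
  }
  expect_equal(unname(rowSums(p)), rep(1, 4), tolerance = 1e-12)
})

test_that("collapsing the doubled parameterization preserves the function", {
  model <- dcqmffInit(L = 33, seed = 73)
  set.seed(74)
  X <- matrix(stats::runif(50 * 11), 50, 11)
  col <- dcqmffCollapse(model)
  expect_length(col$w1, 78)
  expect_equal(dcqmffForwardCollapsed(col, X), dcqmffForward(model, X),
               tolerance = 1e-12)
  ## single channel: the collapsed quadratic is just b * a
  m1 <- dcqmffInit(L = 1, seed = 1)
  m1@b <- 2; m1@a[1, ] <- 0; m1@a[1, 1] <- 3
  expect_equal(dcqmffCollapse(m1)$w1[1], 6)
  expect_equal(dcqmffCollapse(m1)$w1[-1], rep(0, 77))
})

test_that("symmetric heads are maximally uncertain", {
  model <- dcqmffInit(L = 3, seed = 75)
  model@cc <- model@b
  model@d <- model@a
  set.seed(76)
  X <- matrix(stats::runif(20 * 11), 20, 11)
  p <- dcqmffForward(model, X)
  expect_equal(unname(p[, "p_death"]), rep(0.5, 20), tolerance = 1e-12)
  ## extreme logits stay finite thanks to max-subtraction
  model@b <- model@b * 1e4
  expect_true(all(is.finite(dcqmffForward(model, X))))
})

test_that("analytic gradients agree with central finite differences", {
  set.seed(77)
  L <- 3
  par <- list(b = stats::rnorm(L, 0, 0.3),
              a = matrix(stats::rnorm(L * 78, 0, 0.1), L, 78),
              cc = stats::rnorm(L, 0, 0.3),
              d = matrix(stats::rnorm(L * 78, 0, 0.1), L, 78))
  X <- matrix(stats::runif(12 * 11), 12, 11)
  Phi <- quadFeatures(X)
  y <- rep(c(0, 1), 6)
  lossAt <- function(p) sepsisPhenoscope:::.dcqmffGrads(p, Phi, y)$loss
  gr <- sepsisPhenoscope:::.dcqmffGrads(par, Phi, y)$grads
  h <- 1e-6
  for (nm in names(par)) {
    probe <- if (nm %in% c("b", "cc")) seq_along(par[[nm]])
             else sample.int(length(par[[nm]]), 20)
    for (i in probe) {
      up <- par; up[[nm]][i] <- up[[nm]][i] + h
      dn <- par; dn[[nm]][i] <- dn[[nm]][i] - h
      fd <- (lossAt(up) - lossAt(dn)) / (2 * h)
      expect_equal(gr[[nm]][i], fd, tolerance = 1e-5,
                   label = paste("gradient", nm, i))
    }
  }
})

test_that("training learns a planted quadratic decision rule", {
  dat <- quadLogitData(600, seed = 78)
  fit <- dcqmffFit(dat$X, dat$y,
                   dcqmffConfig(L = 33, epochs = 150, seed = 3))
  pred <- dcqmffPredict(fit, dat$X)
  expect_gt(mean(pred$label == dat$y), 0.85)
  ## the loss trace is recorded and improves substantially
  expect_gt(length(fit@lossTrace), 10)
  expect_lt(fit@lossTrace[length(fit@lossTrace)], 0.6 * fit@lossTrace[1])
  ## AUC beats chance comfortably
  expect_gt(aucScore(pred$p_death, dat$y), 0.9)
})

test_that("fits are reproducible under the seed and sensitive to it", {
  dat <- quadLogitData(200, seed = 79)
  cfg <- dcqmffConfig(L = 8, epochs = 20, seed = 5)
  f1 <- dcqmffFit(dat$X, dat$y, cfg)
  f2 <- dcqmffFit(dat$X, dat$y, cfg)
  expect_identical(f1@b, f2@b)
  expect_identical(f1@a, f2@a)
  expect_identical(f1@lossTrace, f2@lossTrace)
  f3 <- dcqmffFit(dat$X, dat$y, dcqmffConfig(L = 8, epochs = 20, seed = 6))
  expect_false(identical(f1@b, f3@b))
})

test_that("plain SGD also trains, and early stopping truncates the trace", {
  dat <- quadLogitData(300, seed = 80)
  sgd <- dcqmffFit(dat$X, dat$y,
                   dcqmffConfig(L = 8, epochs = 60, learningRate = 0.05,
                                optimizer = "sgd", seed = 2))
  expect_lt(sgd@lossTrace[length(sgd@lossTrace)], sgd@lossTrace[1])
  stopped <- dcqmffFit(dat$X, dat$y,
                       dcqmffConfig(L = 8, epochs = 500, seed = 2,
                                    patience = 5))
  expect_lt(length(stopped@lossTrace), 500)
})

test_that("degenerate inputs are rejected; a divergent schedule fails loudly", {
  dat <- quadLogitData(100, seed = 81)
  expect_error(dcqmffFit(dat$X, rep(1, 100)), "classes")
  expect_error(dcqmffFit(dat$X, dat$y,
                         dcqmffConfig(L = 4, epochs = 5, learningRate = -1)),
               "learning rate")
  ## an exact tie predicts survival (the majority class)
  model <- dcqmffInit(L = 2, seed = 1)
  model@cc <- model@b
  model@d <- model@a
  pred <- dcqmffPredict(model, matrix(0.5, 3, 11))
  expect_equal(pred$label, c(0L, 0L, 0L))
})

test_that("a single channel can match the collapsed 33-channel fit in accuracy", {
  ## the function class is identical, so test-set AUC should be close
  dat <- quadLogitData(800, seed = 82)
  trainIdx <- 1:560
  f33 <- dcqmffFit(dat$X[trainIdx, ], dat$y[trainIdx],
                   dcqmffConfig(L = 33, epochs = 120, seed = 4))
  f1 <- dcqmffFit(dat$X[trainIdx, ], dat$y[trainIdx],
                  dcqmffConfig(L = 1, epochs = 120, seed = 4))
  a33 <- aucScore(dcqmffPredict(f33, dat$X[-trainIdx, ])$p_death,
                  dat$y[-trainIdx])
  a1 <- aucScore(dcqmffPredict(f1, dat$X[-trainIdx, ])$p_death,
                 dat$y[-trainIdx])
  expect_lt(abs(a33 - a1), 0.05)
  expect_gt(min(a33, a1), 0.85)
})

test_that("model parameters survive a JSON round trip", {
  dat <- quadLogitData(150, seed = 83)
  fit <- dcqmffFit(dat$X, dat$y, dcqmffConfig(L = 4, epochs = 10, seed = 9))
  path <- tempfile(fileext = ".json")
  writeDCQMFF(fit, path)
  back <- readDCQMFF(path)
  expect_equal(back@b, fit@b)
  expect_equal(back@a, fit@a)
  expect_equal(dcqmffForward(back, dat$X), dcqmffForward(fit, dat$X))
  unlink(path)
})

test_that("cohort input wires the 11 features and labels automatically", {
  cohort <- sampleCohort(separableConfig(400, seed = 84))
  norm <- applyNormalizer(fitNormalizer(cohort), cohort)
  fit <- dcqmffFit(norm, config = dcqmffConfig(L = 8, epochs = 30, seed = 1))
  pred <- dcqmffPredict(fit, norm)
  y <- 1 - SummarizedExperiment::colData(norm)$survived_28d
  expect_gt(aucScore(pred$p_death, y), 0.5)
  expect_equal(nrow(pred), 400)
})
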