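## Shared fixtures, all generated in code.

## default phenotypes with equal mixing weights (for per-cluster asymptotics)
equalWeightConfig <- function(n, seed = 1L, missingRate = 0) {
  specs <- defaultPhenotypeSpecs()
  for (i in seq_along(specs)) specs[[i]]@mixingWeight <- 0.25
  cohortConfig(nPatients = n, specs = specs, missingRate = missingRate,
               seed = seed)
}

## cluster-linked mortality: benign C1/C2 vs near-lethal C3/C4, balanced mix
separableConfig <- function(n, seed = 1L) {
  specs <- defaultPhenotypeSpecs()
  hz <- list(c(5e-4, 5e-4), c(5e-4, 5e-4), c(0.25, 0.25), c(0.25, 0.25))
  w <- c(0.35, 0.35, 0.15, 0.15)
  for (i in seq_along(specs)) {
    specs[[i]]@hazard <- hz[[i]]
    specs[[i]]@mixingWeight <- w[i]
  }
  cohortConfig(nPatients = n, specs = specs, missingRate = 0, seed = seed)
}

## minimal hand-built cohort around a given feature matrix (patients x 35)
toyCohort <- function(X, survived = NULL, time = NULL, normalized = FALSE) {
  n <- nrow(X)
  colnames(X) <- bloodTestFeatures()
  if (is.null(survived)) survived <- rep(1L, n)
  if (is.null(time)) time <- ifelse(survived == 1, 28, 14)
  cd <- data.frame(patient_id = sprintf("T%03d", seq_len(n)),
                   survived_28d = as.integer(survived),
                   time_days = time,
                   event = 1L - as.integer(survived))
  SepsisCohort(t(X), cd, metadata = list(normalized = normalized))
}

## four well-separated Gaussian blobs in 35 dimensions (planted partition)
blobCohort <- function(nPerCluster = 200, sep = 10, sd = 1, seed = 1L,
                       k = 4) {
  set.seed(seed)
  centers <- matrix(stats::rnorm(k * 35), k, 35)
  centers <- centers / sqrt(rowSums(centers^2)) * sep * sd
  X <- do.call(rbind, lapply(seq_len(k), function(i)
    matrix(stats::rnorm(nPerCluster * 35, 0, sd), nPerCluster, 35) +
      matrix(centers[i, ], nPerCluster, 35, byrow = TRUE)))
  list(cohort = toyCohort(X, normalized = TRUE),
       truth = rep(seq_len(k), each = nPerCluster))
}

## labels from a known quadratic logit over 11 uniform features
quadLogitData <- function(n, seed = 7L) {
  set.seed(seed)
  X <- matrix(stats::runif(n * 11), n, 11)
  Phi <- quadFeatures(X)
  set.seed(100)
  w <- c(0, stats::rnorm(11, 0, 4), stats::rnorm(66, 0, 4))
  logit <- drop(Phi %*% w)
  logit <- logit - stats::median(logit)
  y <- stats::rbinom(n, 1, stats::plogis(logit))
  list(X = X, y = y, w = w)
}

## brute-force permutation p over all n! orderings (test oracle, independent
## of the package's multiset-combination enumeration)
.permutations <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in .permutations(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
  }
  out
}

bruteForcePermP <- function(groups, statFun, observed, side = "ge") {
  pooled <- unlist(groups)
  sizes <- lengths(groups)
  ends <- cumsum(sizes); starts <- ends - sizes + 1
  stats <- vapply(.permutations(pooled), function(perm) {
    statFun(lapply(seq_along(sizes), function(i) perm[starts[i]:ends[i]]))
  }, 0)
  switch(side,
         ge = mean(stats >= observed - 1e-12),
         le = mean(stats <= observed + 1e-12),
         abs = mean(abs(stats - mean(stats)) >= abs(observed - mean(stats)) - 1e-12))
}
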