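test_that("complete-case exclusion drops exactly the admissions with gaps", {
  cohort <- sampleCohort(defaultCohortConfig(nPatients = 400, seed = 21))
  a <- SummarizedExperiment::assay(cohort, "bloodTests")
  nIncomplete <- sum(colSums(is.na(a)) > 0)
  res <- excludeIncomplete(cohort)
  expect_equal(res$excluded, nIncomplete)
  expect_equal(ncol(res$cohort), 400 - nIncomplete)
  expect_false(anyNA(SummarizedExperiment::assay(res$cohort, "bloodTests")))
  ## original order preserved
  ids <- SummarizedExperiment::colData(res$cohort)$patient_id
  expect_identical(ids, sort(ids))
  ## a complete cohort passes through untouched
  full <- sampleCohort(defaultCohortConfig(nPatients = 50, seed = 3,
                                           missingRate = 0))
  res2 <- excludeIncomplete(full)
  expect_equal(res2$excluded, 0)
  expect_identical(SummarizedExperiment::assay(res2$cohort),
                   SummarizedExperiment::assay(full))
})

test_that("shifted min-max normalization matches hand values and round-trips", {
  X <- matrix(rep(c(2, 4, 6), 35), nrow = 3)
  cohort <- toyCohort(X)
  params <- fitNormalizer(cohort)
  norm <- applyNormalizer(params, cohort)
  Xn <- bloodTests(norm)
  ## x* = (x - 0.99 * 2) / (6 - 2)
  expect_equal(unname(Xn[, 1]), c(0.005, 0.505, 1.005))
  expect_true(isTRUE(S4Vectors::metadata(norm)$normalized))
  ## strictly positive minimum by construction
  expect_true(all(Xn > 0))
  back <- invertNormalizer(params, norm)
  expect_equal(bloodTests(back), bloodTests(cohort), tolerance = 1e-12)
  expect_false(isTRUE(S4Vectors::metadata(back)$normalized))
  ## out-of-range values of a later table are not clipped
  X2 <- matrix(rep(c(0, 10), 35), nrow = 2)
  Xn2 <- bloodTests(applyNormalizer(params, toyCohort(X2)))
  expect_lt(min(Xn2), 0)
  expect_gt(max(Xn2), 1)
})

test_that("a constant feature makes the normalizer fail loudly, by name", {
  X <- matrix(rep(c(2, 4, 6), 35), nrow = 3)
  X[, 22] <- 5  # Glucose constant
  expect_error(fitNormalizer(toyCohort(X)), "Glucose")
})

test_that("normalizer parameters survive a JSON round trip at full precision", {
  cohort <- sampleCohort(defaultCohortConfig(nPatients = 80, seed = 4,
                                             missingRate = 0))
  params <- fitNormalizer(cohort)
  path <- tempfile(fileext = ".json")
  writeNormalizer(params, path)
  back <- readNormalizer(path)
  expect_equal(back$min, params$min)
  expect_equal(back$max, params$max)
  expect_equal(bloodTests(applyNormalizer(back, cohort)),
               bloodTests(applyNormalizer(params, cohort)))
  unlink(path)
})

test_that("the 7:3 split has the documented sizes and is seed-stable", {
  cohort <- sampleCohort(defaultCohortConfig(nPatients = 2371, seed = 6,
                                             missingRate = 0))
  sp <- splitCohort(cohort, ratio = 0.7, seed = 11)
  expect_equal(ncol(sp$train), 1660)  # round(0.7 * 2371)
  expect_equal(ncol(sp$test), 711)
  ## partition: disjoint and exhaustive
  idTr <- SummarizedExperiment::colData(sp$train)$patient_id
  idTe <- SummarizedExperiment::colData(sp$test)$patient_id
  expect_length(intersect(idTr, idTe), 0)
  expect_setequal(c(idTr, idTe),
                  SummarizedExperiment::colData(cohort)$patient_id)
  ## same seed, same split; different seed, different split
  sp2 <- splitCohort(cohort, ratio = 0.7, seed = 11)
  expect_identical(SummarizedExperiment::colData(sp2$train)$patient_id, idTr)
  sp3 <- splitCohort(cohort, ratio = 0.7, seed = 12)
  expect_false(identical(SummarizedExperiment::colData(sp3$train)$patient_id,
                         idTr))
  ## tiny example
  small <- sampleCohort(defaultCohortConfig(nPatients = 10, seed = 1,
                                            missingRate = 0))
  sps <- splitCohort(small, 0.7, seed = 1)
  expect_equal(ncol(sps$train), 7)
  expect_equal(ncol(sps$test), 3)
  expect_error(splitCohort(small, 1.2), "ratio")
})

test_that("every admission is equally likely to land in the training split", {
  cohort <- sampleCohort(defaultCohortConfig(nPatients = 40, seed = 2,
                                             missingRate = 0))
  reps <- 500
  counts <- integer(40)
  for (s in seq_len(reps)) {
    sp <- splitCohort(cohort, 0.7, seed = s)
    idx <- match(SummarizedExperiment::colData(sp$train)$patient_id,
                 SummarizedExperiment::colData(cohort)$patient_id)
    counts[idx] <- counts[idx] + 1
  }
  ## each patient ~ Binomial(500, 0.7); Bonferroni band over the 40 patients
  band <- stats::qbinom(c(0.005 / 40, 1 - 0.005 / 40), reps, 0.7)
  expect_gte(min(counts), band[1])
  expect_lte(max(counts), band[2])
})

test_that("stratified splitting preserves the outcome mix in both halves", {
  cohort <- sampleCohort(separableConfig(1000, seed = 9))
  sp <- splitCohort(cohort, 0.7, seed = 5, stratify = TRUE)
  yTr <- SummarizedExperiment::colData(sp$train)$survived_28d
  yTe <- SummarizedExperiment::colData(sp$test)$survived_28d
  y <- SummarizedExperiment::colData(cohort)$survived_28d
  expect_equal(sum(yTr == 0), round(0.7 * sum(y == 0)))
  expect_equal(length(yTr) + length(yTe), 1000)
})

test_that("up-sampling balances deaths without touching survivors", {
  set.seed(31)
  X <- matrix(stats::rnorm(100 * 35), 100, 35)
  survived <- rep(c(1L, 0L), c(80, 20))
  cohort <- toyCohort(X, survived = survived, normalized = TRUE)
  aug <- upsampleMinority(cohort, upsampleConfig(seed = 17))
  cd <- SummarizedExperiment::colData(aug)
  nDeath <- sum(cd$survived_28d == 0)
  expect_gte(nDeath, 76)  # within 5% of the 80 majority records
  expect_lte(nDeath, 84)
  ## survivors byte-identical and never flagged synthetic
  keep <- which(!cd$synthetic & cd$survived_28d == 1)
  expect_equal(length(keep), 80)
  expect_equal(t(bloodTests(aug))[, keep],
               t(bloodTests(cohort))[, survived == 1])
  expect_true(all(cd$synthetic[101:nrow(cd)]))
  ## synthetic records inherit the minority label
  expect_true(all(cd$survived_28d[cd$synthetic] == 0))
})

test_that("pure replication reproduces existing minority records verbatim", {
  set.seed(32)
  X <- matrix(stats::rnorm(60 * 35), 60, 35)
  survived <- rep(c(1L, 0L), c(50, 10))
  cohort <- toyCohort(X, survived = survived, normalized = TRUE)
  aug <- upsampleMinority(cohort,
                          upsampleConfig(weights = c(replicate = 1, median = 0,
                                                     jitter = 0),
                                         seed = 2))
  A <- bloodTests(aug)
  newRows <- A[61:nrow(A), , drop = FALSE]
  minority <- A[51:60, , drop = FALSE]
  for (i in seq_len(nrow(newRows))) {
    match1 <- apply(minority, 1, function(r) all(r == newRows[i, ]))
    expect_true(any(match1))
  }
})

test_that("an already balanced cohort is returned unchanged", {
  set.seed(33)
  X <- matrix(stats::rnorm(40 * 35), 40, 35)
  cohort <- toyCohort(X, survived = rep(c(1L, 0L), each = 20),
                      normalized = TRUE)
  aug <- upsampleMinority(cohort, upsampleConfig(seed = 1))
  expect_equal(ncol(aug), 40)
  expect_equal(bloodTests(aug), bloodTests(cohort))
  ## single-class input is rejected
  one <- toyCohort(X, survived = rep(1L, 40), normalized = TRUE)
  expect_error(upsampleMinority(one), "classes")
})

test_that("median-synthesized records hug the minority medians", {
  set.seed(34)
  X <- matrix(stats::rnorm(200 * 35), 200, 35)
  survived <- rep(c(1L, 0L), c(160, 40))
  time <- ifelse(survived == 1, 28, seq_len(200) %% 20 + 1)
  cohort <- toyCohort(X, survived = survived, time = time, normalized = TRUE)
  aug <- upsampleMinority(cohort,
                          upsampleConfig(weights = c(0, 1, 0),
                                         noiseScale = 0.01, seed = 5))
  cd <- SummarizedExperiment::colData(aug)
  A <- bloodTests(aug)
  synth <- which(cd$synthetic)
  med <- apply(X[survived == 0, ], 2, stats::median)
  dev <- sweep(A[synth, , drop = FALSE], 2, med)
  iqr <- apply(X[survived == 0, ], 2, stats::IQR)
  expect_lt(max(abs(t(dev)) / iqr), 0.1)  # noise is 1% of the IQR
  ## and take the minority median survival time
  expect_true(all(cd$time_days[synth] ==
                  stats::median(time[survived == 0])))
})
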