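## Data conditioning: complete-case exclusion, the shifted min-max
## normalization x* = (x - 0.99*min) / (max - min), the 7:3 random split,
## and three-mechanism minority up-sampling.

#' Drop admissions with any missing blood test
#'
#' @param cohort a [SepsisCohort-class].
#' @return list with `cohort` (complete cases, original order preserved) and
#'   `excluded` (number of dropped admissions).
#' @export
excludeIncomplete <- function(cohort) {
  a <- SummarizedExperiment::assay(cohort, "bloodTests")
  keep <- colSums(is.na(a)) == 0
  list(cohort = cohort[, keep], excluded = sum(!keep))
}

#' Fit the per-feature normalizer on training data
#'
#' Learns the per-feature minimum and maximum of the training cohort. The
#' transform itself is the shifted min-max map
#' `x* = (x - 0.99 * min) / (max - min)`, whose offset keeps the normalized
#' minimum strictly positive (at `0.01 * min / (max - min)`); values of a
#' later table may fall outside `[0, 1]` and are deliberately not clipped.
#'
#' @param train a complete-case [SepsisCohort-class].
#' @return object of class `NormalizationParams`: list with `min` and `max`
#'   named numeric vectors.
#' @export
fitNormalizer <- function(train) {
  a <- SummarizedExperiment::assay(train, "bloodTests")
  if (!ncol(a)) stop("cannot fit a normalizer on an empty cohort")
  if (anyNA(a)) stop("normalizer requires complete cases")
  mins <- apply(a, 1, min)
  maxs <- apply(a, 1, max)
  degen <- maxs == mins
  if (any(degen))
    stop("degenerate (constant) feature(s): ",
         paste(rownames(a)[degen], collapse = ", "))
  structure(list(min = mins, max = maxs), class = "NormalizationParams")
}

#' Apply (or invert) a fitted normalizer
#'
#' @param params a `NormalizationParams` from [fitNormalizer()].
#' @param cohort a [SepsisCohort-class] on the raw (or, for the inverse,
#'   normalized) scale.
#' @return The cohort with the transformed assay;
#'   `metadata(x)$normalized` records the state.
#' @export
applyNormalizer <- function(params, cohort) {
  a <- SummarizedExperiment::assay(cohort, "bloodTests")
  if (!identical(rownames(a), names(params$min)))
    stop("normalizer features do not match the cohort schema")
  a <- (a - 0.99 * params$min) / (params$max - params$min)
  SummarizedExperiment::assay(cohort, "bloodTests") <- a
  S4Vectors::metadata(cohort)$normalized <- TRUE
  cohort
}

#' @rdname applyNormalizer
#' @export
invertNormalizer <- function(params, cohort) {
  a <- SummarizedExperiment::assay(cohort, "bloodTests")
  if (!identical(rownames(a), names(params$min)))
    stop("normalizer features do not match the cohort schema")
  a <- a * (params$max - params$min) + 0.99 * params$min
  SummarizedExperiment::assay(cohort, "bloodTests") <- a
  S4Vectors::metadata(cohort)$normalized <- FALSE
  cohort
}

#' Serialize / load normalization parameters as JSON
#'
#' @param params a `NormalizationParams`.
#' @param path JSON file path.
#' @return `readNormalizer` returns a `NormalizationParams`.
#' @export
writeNormalizer <- function(params, path) {
  obj <- lapply(seq_along(params$min), function(i)
    list(min = params$min[[i]], max = params$max[[i]]))
  names(obj) <- names(params$min)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeNormalizer
#' @export
readNormalizer <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(min = vapply(obj, `[[`, 0, "min"),
                 max = vapply(obj, `[[`, 0, "max")),
            class = "NormalizationParams")
}

#' Random train/test split
#'
#' Uniform random partition with `round(ratio * n)` training admissions
#' (round-half-even), reproducible under the seed. Optionally stratified by
#' 28-day outcome.
#'
#' @param cohort a [SepsisCohort-class] with at least 2 admissions.
#' @param ratio training fraction in (0, 1); default 0.7.
#' @param seed integer seed.
#' @param stratify stratify the partition by `survived_28d` (off by default).
#' @return list with `train`, `test` ([SepsisCohort-class]), `seed`, `ratio`.
#' @export
splitCohort <- function(cohort, ratio = 0.7, seed = 1L, stratify = FALSE) {
  n <- ncol(cohort)
  if (n < 2) stop("need at least 2 admissions to split")
  if (!is.numeric(ratio) || ratio <= 0 || ratio >= 1)
    stop("ratio must lie strictly inside (0, 1)")
  set.seed(as.integer(seed))
  if (stratify) {
    y <- SummarizedExperiment::colData(cohort)$survived_28d
    trainIdx <- integer(0)
    for (cls in unique(y)) {
      idx <- which(y == cls)
      trainIdx <- c(trainIdx, sample(idx, round(ratio * length(idx))))
    }
    trainIdx <- sort(trainIdx)
  } else {
    trainIdx <- sort(sample.int(n, round(ratio * n)))
  }
  list(train = cohort[, trainIdx],
       test = cohort[, setdiff(seq_len(n), trainIdx)],
       seed = as.integer(seed), ratio = ratio)
}

#' Up-sampling configuration
#'
#' @param weights non-negative mechanism weights `replicate`, `median`,
#'   `jitter`; normalized to sum to 1.
#' @param noiseScale synthetic-record noise as a fraction of the per-feature
#'   minority IQR (> 0).
#' @param targetRatio desired minority:majority ratio (1 = balanced).
#' @param tolerance acceptable relative deviation from the target ratio.
#' @param seed integer seed.
#' @return list of class `UpsampleConfig`.
#' @export
upsampleConfig <- function(weights = c(replicate = 1, median = 1, jitter = 1) / 3,
                           noiseScale = 0.1, targetRatio = 1,
                           tolerance = 0.05, seed = 1L) {
  if (length(weights) != 3 || any(weights < 0) || sum(weights) <= 0)
    stop("weights must be 3 non-negative values")
  if (noiseScale <= 0) stop("noiseScale must be positive")
  structure(list(weights = weights / sum(weights), noiseScale = noiseScale,
                 targetRatio = targetRatio, tolerance = tolerance,
                 seed = as.integer(seed)),
            class = "UpsampleConfig")
}

#' Up-sample the minority (death) class
#'
#' Augments the minority class until the class ratio is within the configured
#' tolerance of the target by a mix of three mechanisms: verbatim
#' replication, random generation around the per-feature minority medians,
#' and jittering sampled minority records with noise scaled by the
#' per-feature minority IQR. Majority records are never altered; synthetic
#' records carry `synthetic = TRUE` in `colData`.
#'
#' @param train a [SepsisCohort-class] containing both outcome classes.
#' @param config an [upsampleConfig()].
#' @return The augmented cohort.
#' @export
upsampleMinority <- function(train, config = upsampleConfig()) {
  cd <- SummarizedExperiment::colData(train)
  y <- cd$survived_28d
  if (length(unique(y)) < 2) stop("both outcome classes must be present")
  tabs <- table(y)
  minorityClass <- as.integer(names(tabs)[which.min(tabs)])
  nMin <- min(tabs); nMaj <- max(tabs)
  target <- round(nMaj * config$targetRatio)
  nNew <- target - nMin
  if (!("synthetic" %in% colnames(cd)))
    SummarizedExperiment::colData(train)$synthetic <- FALSE
  if (nNew <= max(0, config$tolerance * target)) return(train)

  set.seed(config$seed)
  a <- SummarizedExperiment::assay(train, "bloodTests")
  minIdx <- which(y == minorityClass)
  Xmin <- a[, minIdx, drop = FALSE]
  med <- apply(Xmin, 1, stats::median)
  iqr <- apply(Xmin, 1, stats::IQR)
  mech <- sample(c("replicate", "median", "jitter"), nNew, replace = TRUE,
                 prob = config$weights)
  src <- sample(minIdx, nNew, replace = TRUE)
  p <- nrow(a)
  newX <- matrix(NA_real_, p, nNew, dimnames = list(rownames(a), NULL))
  for (i in seq_len(nNew)) {
    newX[, i] <- switch(mech[i],
      replicate = a[, src[i]],
      median = med + stats::rnorm(p, 0, config$noiseScale * iqr),
      jitter = a[, src[i]] + stats::rnorm(p, 0, config$noiseScale * iqr))
  }
  cdf <- as.data.frame(SummarizedExperiment::colData(train))
  newCd <- cdf[src, , drop = FALSE]
  if ("patient_id" %in% colnames(newCd))
    newCd$patient_id <- sprintf("S%05d", seq_len(nNew))
  newCd$synthetic <- TRUE
  ## median-synthesized records take the minority median survival time
  medTime <- stats::median(cdf$time_days[minIdx])
  newCd$time_days[mech == "median"] <- medTime
  rownames(newCd) <- NULL
  aug <- SepsisCohort(cbind(a, newX), rbind(cdf, newCd),
                      metadata = S4Vectors::metadata(train))
  aug
}
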