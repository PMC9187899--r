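## Synthetic MIMIC-like sepsis cohort generator.
##
## Each phenotype cluster is described by printed-scale quartile triples
## (median, q1, q3) per feature. Marginals are drawn from a two-piece
## (split) log-normal -- or a two-piece normal for bounded/percentage/pH and
## log-scale analytes -- whose three quartiles match the printed triple
## exactly; values are then clamped at physical bounds (clamping outside the
## quartile range leaves the printed quartiles untouched). Survival times
## follow a two-piece constant hazard with administrative censoring at day 28.

.Z75 <- stats::qnorm(0.75)

## features sampled additively (two-piece normal) rather than multiplicatively
.additiveFeatures <- function() {
  f <- bloodTestFeatures()
  f[grepl("\\(%\\)", f) | grepl("log", f, fixed = TRUE) | f == "pH (units)"]
}

## physical clamping bounds per feature on the stored scale
.featureBounds <- function() {
  f <- bloodTestFeatures()
  lo <- rep(0, length(f))
  hi <- rep(Inf, length(f))
  pct <- grepl("\\(%\\)", f)
  hi[pct] <- 100
  lo[f == "pH (units)"] <- 6.5
  hi[f == "pH (units)"] <- 7.9
  lo[grepl("log", f, fixed = TRUE)] <- -Inf
  cbind(lo = lo, hi = hi)[, , drop = FALSE] -> b
  rownames(b) <- f
  b
}

## Draw n values from the two-piece family matching (median, q1, q3) exactly.
## additive = FALSE: split log-normal (strictly positive scale required).
.sampleQuartileMatched <- function(n, med, q1, q3, additive, feature) {
  if (!(q1 <= med && med <= q3))
    stop("unsolvable (median, q1, q3) triple for feature '", feature, "'")
  z <- stats::rnorm(n)
  if (additive) {
    sLo <- (med - q1) / .Z75
    sUp <- (q3 - med) / .Z75
    med + ifelse(z >= 0, sUp, sLo) * z
  } else {
    if (q1 <= 0 || med <= 0)
      stop("unsolvable (median, q1, q3) triple for feature '", feature,
           "': non-positive quartile on a multiplicative scale")
    sLo <- log(med / q1) / .Z75
    sUp <- log(q3 / med) / .Z75
    med * exp(ifelse(z >= 0, sUp, sLo) * z)
  }
}

## Invert the cumulative hazard of a two-piece constant hazard.
.sampleSurvivalTimes <- function(n, hazard, breakDay, horizon = 28) {
  u <- stats::runif(n)
  target <- -log(u)
  h1 <- hazard[1]; h2 <- hazard[2]
  cumAtBreak <- h1 * breakDay
  tEarly <- if (h1 > 0) target / h1 else rep(Inf, n)
  tLate <- if (h2 > 0) breakDay + (target - cumAtBreak) / h2 else rep(Inf, n)
  t <- ifelse(target <= cumAtBreak, tEarly, tLate)
  event <- as.integer(t <= horizon)
  time <- pmin(t, horizon)
  list(time = time, event = event)
}

.defaultFeatureTable <- function() {
  f <- bloodTestFeatures()
  ## per-cluster (median, q1, q3); top-10 heterogeneous features carry the
  ## printed per-cluster quartiles, severity markers get severity-linked
  ## values, the remainder share one clinically plausible baseline.
  tab <- array(NA_real_, dim = c(length(f), 3, 4),
               dimnames = list(f, c("median", "q1", "q3"),
                               c("C1", "C2", "C3", "C4")))
  set3 <- function(feature, c1, c2, c3, c4) {
    tab[feature, , "C1"] <<- c1; tab[feature, , "C2"] <<- c2
    tab[feature, , "C3"] <<- c3; tab[feature, , "C4"] <<- c4
  }
  same <- function(feature, v) set3(feature, v, v, v, v)

  set3("PTT (sec)", c(30.6, 26.5, 36.3), c(29.6, 26.2, 34.3),
       c(150, 122.9, 150), c(51.6, 43.5, 60.6))
  set3("Neutrophils (%)", c(51, 33, 61.7), c(84, 77, 89.9),
       c(81.8, 77.2, 86), c(83, 76.4, 89))
  set3("PT (sec)", c(14.3, 13.1, 16.4), c(14.2, 13.1, 16.0),
       c(17.7, 15.3, 23.8), c(30.2, 21.9, 43.1))
  set3("INR(PT)", c(1.3, 1.1, 1.5), c(1.3, 1.1, 1.5),
       c(1.9, 1.5, 3.2), c(3.4, 2.2, 5.2))
  set3("Lymphocytes (%)", c(26, 15.5, 34.3), c(7, 4, 11.3),
       c(7, 4.6, 14.0), c(8, 4, 13))
  ## upper quartiles for C2/C3 white cells repaired from inconsistent
  ## transcription (q3 must exceed the median)
  set3("White Blood Cells (K/uL)", c(6.1, 3.4, 10.8), c(13.2, 8.9, 18.1),
       c(10.7, 7.0, 18.4), c(12.1, 8.5, 17.4))
  set3("Platelet Count (log K/uL)", c(2.3, 2.0, 2.5), c(2.4, 2.2, 2.5),
       c(2.3, 2.2, 2.4), c(2.3, 2.1, 2.5))
  set3("MCHC (%)", c(33.3, 32.3, 34.3), c(33, 32, 34.1),
       c(32.5, 32.2, 34), c(32, 31, 33.3))
  set3("Albumin (g/dL)", c(2.9, 2.5, 3.3), c(2.9, 2.5, 3.4),
       c(2.9, 2.5, 3.4), c(2.9, 2.4, 3.2))
  set3("Red Blood Cells (m/uL)", c(3.5, 3.1, 4.0), c(3.7, 3.3, 4.2),
       c(3.7, 3.2, 4.0), c(3.7, 3.1, 4.0))

  ## severity-linked markers (coagulopathy clusters sicker)
  set3("Creatinine (mg/dL)", c(1.0, 0.7, 1.6), c(1.0, 0.7, 1.5),
       c(1.3, 0.8, 2.2), c(1.5, 0.9, 2.6))
  set3("Bilirubin (IU/L)", c(0.7, 0.4, 1.3), c(0.6, 0.4, 1.1),
       c(1.4, 0.7, 3.2), c(1.9, 0.8, 4.6))
  set3("Lactate (mmol/L)", c(1.8, 1.2, 2.8), c(1.7, 1.2, 2.6),
       c(2.4, 1.5, 3.9), c(2.8, 1.7, 4.8))
  set3("pH (units)", c(7.38, 7.32, 7.43), c(7.39, 7.34, 7.44),
       c(7.35, 7.28, 7.41), c(7.33, 7.25, 7.40))
  set3("Hemoglobin (g/dL)", c(10.8, 9.5, 12.2), c(11.2, 9.9, 12.6),
       c(10.9, 9.6, 12.3), c(10.5, 9.2, 12.0))

  ## shared baselines for the remaining analytes
  same("ALT (IU/L)", c(35, 20, 78))
  same("Alkaline Phosphatase (log IU/L)", c(1.95, 1.80, 2.15))
  same("Anion Gap (mEq/L)", c(14, 12, 17))
  same("AST (log IU/L)", c(1.70, 1.48, 2.00))
  same("Basophils (%)", c(0.3, 0.1, 0.5))
  same("Bicarbonate (mEq/L)", c(23, 20, 26))
  same("Calcium (mg/dL)", c(8.3, 7.8, 8.8))
  same("Chloride (mEq/L)", c(103, 99, 107))
  same("Eosinophils (%)", c(1.0, 0.3, 2.2))
  same("Glucose (mg/dL)", c(130, 105, 172))
  same("Hematocrit (%)", c(33, 29.5, 37))
  same("Magnesium (mg/dL)", c(2.0, 1.8, 2.3))
  same("MCH (pg)", c(30, 28.5, 31.6))
  same("MCV (fL)", c(90, 86, 95))
  same("Monocytes (%)", c(4.0, 2.5, 6.0))
  same("Phosphate (mg/dL)", c(3.4, 2.7, 4.3))
  same("Potassium (mEq/L)", c(4.1, 3.7, 4.6))
  same("RDW (%)", c(14.8, 13.8, 16.3))
  same("Sodium (mEq/L)", c(139, 135, 143))
  same("Urea Nitrogen (log mg/dL)", c(1.40, 1.18, 1.65))
  tab
}

#' Default four-phenotype simulator specification
#'
#' Builds the four phenotype specifications the downstream analysis assumes:
#' mixing weights proportional to the training-set cluster sizes
#' (211, 1215, 46, 189), per-cluster blood-test quartiles (with the PTT of C3
#' pinned at the 150 s assay ceiling and C4 carrying the largest PT/INR),
#' heparin usage maximal in C3, and two-piece 28-day hazards calibrated so
#' that C2 has the best survival throughout while the C3 and C4 curves cross
#' (C3 dies early but outlives C4 in the long run).
#'
#' @return list of four [PhenotypeSpec-class] objects named C1..C4.
#' @export
#' @examples
#' specs <- defaultPhenotypeSpecs()
#' specs$C3@featureParams["PTT (sec)", ]
defaultPhenotypeSpecs <- function() {
  tab <- .defaultFeatureTable()
  w <- c(C1 = 211, C2 = 1215, C3 = 46, C4 = 189) / 1661
  ## daily hazards solved from per-cluster 28-day survival
  ## (0.782, 0.827, 0.761, 0.698) with the C3/C4 crossing built in
  hz <- list(C1 = c(0.008782, 0.008782),
             C2 = c(0.006785, 0.006785),
             C3 = c(0.030, 0.003005),
             C4 = c(0.008, 0.014462))
  hep <- c(C1 = 0.25, C2 = 0.20, C3 = 0.70, C4 = 0.40)
  male <- c(C1 = 0.483, C2 = 0.546, C3 = 0.370, C4 = 0.582)
  panels <- list(
    C1 = list(pf = c(330, 70), map = c(75, 9),  gcs = c(13.5, 1.5)),
    C2 = list(pf = c(380, 60), map = c(79, 8),  gcs = c(14.3, 1.0)),
    C3 = list(pf = c(250, 70), map = c(68, 10), gcs = c(12.0, 2.5)),
    C4 = list(pf = c(230, 70), map = c(66, 10), gcs = c(11.5, 2.5)))
  out <- lapply(c("C1", "C2", "C3", "C4"), function(cl) {
    phenotypeSpec(clusterId = cl,
                  featureParams = tab[, , cl],
                  heparinProb = hep[[cl]],
                  hazard = hz[[cl]],
                  hazardBreak = 7,
                  mixingWeight = w[[cl]],
                  maleProb = male[[cl]],
                  panelParams = panels[[cl]])
  })
  names(out) <- c("C1", "C2", "C3", "C4")
  out
}

#' Default simulator configuration
#'
#' A cohort of 2902 admissions (the size of the source sepsis extraction),
#' four default phenotypes, a 150 s PTT assay ceiling, and a per-cell
#' missingness rate of 0.0058 chosen so that complete-case exclusion over 35
#' features removes roughly 18% of admissions.
#'
#' @param nPatients cohort size.
#' @param seed integer seed.
#' @param missingRate per-cell blanking probability.
#' @param specs list of [PhenotypeSpec-class].
#' @return A [CohortConfig-class].
#' @export
defaultCohortConfig <- function(nPatients = 2902, seed = 1L,
                                missingRate = 0.0058,
                                specs = defaultPhenotypeSpecs()) {
  cohortConfig(nPatients = nPatients, specs = specs, pttCeiling = 150,
               missingRate = missingRate, seed = seed)
}

#' Sample a synthetic sepsis cohort
#'
#' Draws cluster labels from the mixing weights, every blood test from its
#' quartile-matched two-piece marginal (PT and INR share a latent normal with
#' rank correlation about 0.9), caps PTT at the assay ceiling, simulates
#' 28-day survival from the cluster's two-piece hazard with administrative
#' censoring at day 28, and attaches heparin usage, demographics and the
#' organ panel used by the severity scores. Reproducible for a fixed seed.
#'
#' @param config a [CohortConfig-class].
#' @return A [SepsisCohort-class] with `true_cluster` in its `colData`.
#' @export
#' @examples
#' cohort <- sampleCohort(defaultCohortConfig(nPatients = 200, seed = 7))
#' cohort
sampleCohort <- function(config) {
  methods::validObject(config)
  set.seed(config@seed)
  n <- config@nPatients
  specs <- config@specs
  w <- vapply(specs, function(s) s@mixingWeight, 0)
  labels <- sample.int(length(specs), n, replace = TRUE, prob = w)
  feats <- bloodTestFeatures()
  additive <- feats %in% .additiveFeatures()
  bounds <- .featureBounds()
  X <- matrix(NA_real_, nrow = n, ncol = length(feats),
              dimnames = list(NULL, feats))
  cd <- data.frame(
    patient_id = sprintf("P%05d", seq_len(n)),
    survived_28d = NA_integer_, time_days = NA_real_, event = NA_integer_,
    heparin = NA_integer_, age = NA_real_,
    sex = NA_character_, true_cluster = NA_character_,
    pf_ratio = NA_real_, map_mmHg = NA_real_, gcs = NA_integer_,
    stringsAsFactors = FALSE)

  iPT <- match("PT (sec)", feats); iINR <- match("INR(PT)", feats)
  for (k in seq_along(specs)) {
    idx <- which(labels == k)
    if (!length(idx)) next
    sp <- specs[[k]]
    fp <- sp@featureParams
    for (j in seq_along(feats)) {
      X[idx, j] <- .sampleQuartileMatched(length(idx), fp[j, "median"],
                                          fp[j, "q1"], fp[j, "q3"],
                                          additive[j], feats[j])
    }
    ## PT and INR re-drawn from a shared latent normal (rank cor ~ 0.9)
    zShared <- stats::rnorm(length(idx))
    rho <- 0.9
    for (jj in c(iPT, iINR)) {
      zi <- rho * zShared + sqrt(1 - rho^2) * stats::rnorm(length(idx))
      sLo <- log(fp[jj, "median"] / fp[jj, "q1"]) / .Z75
      sUp <- log(fp[jj, "q3"] / fp[jj, "median"]) / .Z75
      X[idx, jj] <- fp[jj, "median"] * exp(ifelse(zi >= 0, sUp, sLo) * zi)
    }
    surv <- .sampleSurvivalTimes(length(idx), sp@hazard, sp@hazardBreak)
    cd$time_days[idx] <- surv$time
    cd$event[idx] <- surv$event
    cd$survived_28d[idx] <- 1L - surv$event
    cd$heparin[idx] <- stats::rbinom(length(idx), 1, sp@heparinProb)
    cd$sex[idx] <- ifelse(stats::rbinom(length(idx), 1, sp@maleProb) == 1,
                          "M", "F")
    age <- .sampleQuartileMatched(length(idx), 66, 54, 76, FALSE, "age")
    cd$age[idx] <- pmin(pmax(age, 18), 100)
    pp <- sp@panelParams
    cd$pf_ratio[idx] <- pmin(pmax(stats::rnorm(length(idx), pp$pf[1], pp$pf[2]), 60), 600)
    cd$map_mmHg[idx] <- pmin(pmax(stats::rnorm(length(idx), pp$map[1], pp$map[2]), 35), 130)
    cd$gcs[idx] <- as.integer(pmin(pmax(round(stats::rnorm(length(idx), pp$gcs[1], pp$gcs[2])), 3), 15))
    cd$true_cluster[idx] <- sp@clusterId
  }
  ## clamp at physical bounds; assay ceiling on PTT
  X <- pmin(pmax(X, matrix(bounds[, "lo"], n, length(feats), byrow = TRUE)),
            matrix(bounds[, "hi"], n, length(feats), byrow = TRUE))
  X[, "PTT (sec)"] <- pmin(X[, "PTT (sec)"], config@pttCeiling)

  cohort <- SepsisCohort(t(X), cd,
                         metadata = list(seed = config@seed,
                                         pttCeiling = config@pttCeiling))
  if (config@missingRate > 0)
    cohort <- injectMissingness(cohort, config@missingRate,
                                seed = config@seed + 10000L)
  cohort
}

#' Blank feature cells at random
#'
#' Each blood-test cell is independently set to `NA` with probability `rate`,
#' emulating incomplete laboratory panels; outcome and covariate columns are
#' never blanked.
#'
#' @param cohort a [SepsisCohort-class].
#' @param rate probability in `[0, 1)`.
#' @param seed integer seed for the blanking mask.
#' @return The cohort with missing feature cells.
#' @export
injectMissingness <- function(cohort, rate, seed = 1L) {
  if (!is.numeric(rate) || rate < 0 || rate >= 1)
    stop("rate must lie in [0, 1)")
  if (rate == 0) return(cohort)
  a <- SummarizedExperiment::assay(cohort, "bloodTests")
  set.seed(as.integer(seed))
  mask <- matrix(stats::runif(length(a)) < rate, nrow(a), ncol(a))
  a[mask] <- NA_real_
  SummarizedExperiment::assay(cohort, "bloodTests") <- a
  cohort
}

#' Write / read a cohort as CSV
#'
#' Patients as rows: `patient_id`, the 35 blood-test columns (exact canonical
#' headers), then outcome and covariate columns. Missing cells are encoded as
#' empty strings. `writeCohortCsv` also writes a `<path>.json` sidecar with
#' any metadata (seed, ceilings).
#'
#' @param cohort a [SepsisCohort-class].
#' @param path CSV file path.
#' @return `readCohortCsv` returns a [SepsisCohort-class]; `writeCohortCsv`
#'   returns `path` invisibly.
#' @export
writeCohortCsv <- function(cohort, path) {
  X <- bloodTests(cohort)
  cd <- as.data.frame(SummarizedExperiment::colData(cohort))
  df <- cbind(cd["patient_id"], as.data.frame(X, check.names = FALSE),
              cd[setdiff(colnames(cd), "patient_id")])
  utils::write.csv(df, path, row.names = FALSE, na = "")
  meta <- S4Vectors::metadata(cohort)
  if (length(meta))
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeCohortCsv
#' @export
readCohortCsv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  feats <- bloodTestFeatures()
  miss <- setdiff(feats, colnames(df))
  if (length(miss))
    stop("CSV lacks feature column(s): ", paste(miss, collapse = ", "))
  X <- as.matrix(df[, feats])
  cd <- df[, setdiff(colnames(df), feats), drop = FALSE]
  meta <- list()
  side <- paste0(path, ".json")
  if (file.exists(side)) meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  SepsisCohort(t(X), cd, metadata = meta)
}
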