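#' Canonical blood-test feature names
#'
#' The 35 routine blood-test variables the pipeline operates on, in canonical
#' order, each suffixed with its reporting unit. Features whose name contains
#' `log` are stored (and simulated) on the log10 scale, matching how they are
#' customarily reported for right-skewed analytes.
#'
#' @return Character vector of length 35.
#' @export
#' @examples
#' bloodTestFeatures()
bloodTestFeatures <- function() {
  c("PTT (sec)",
    "Neutrophils (%)",
    "PT (sec)",
    "INR(PT)",
    "Lymphocytes (%)",
    "White Blood Cells (K/uL)",
    "Platelet Count (log K/uL)",
    "MCHC (%)",
    "Albumin (g/dL)",
    "Red Blood Cells (m/uL)",
    "ALT (IU/L)",
    "Alkaline Phosphatase (log IU/L)",
    "Anion Gap (mEq/L)",
    "AST (log IU/L)",
    "Basophils (%)",
    "Bicarbonate (mEq/L)",
    "Bilirubin (IU/L)",
    "Calcium (mg/dL)",
    "Chloride (mEq/L)",
    "Creatinine (mg/dL)",
    "Eosinophils (%)",
    "Glucose (mg/dL)",
    "Hematocrit (%)",
    "Hemoglobin (g/dL)",
    "Lactate (mmol/L)",
    "Magnesium (mg/dL)",
    "MCH (pg)",
    "MCV (fL)",
    "Monocytes (%)",
    "pH (units)",
    "Phosphate (mg/dL)",
    "Potassium (mEq/L)",
    "RDW (%)",
    "Sodium (mEq/L)",
    "Urea Nitrogen (log mg/dL)")
}

#' Features entering the DCQMFF classifier
#'
#' The 11-feature subset used by the double-coefficient quadratic model:
#' organ-function markers plus two blood-gas variables (pH, lactate), in the
#' fixed order the model expects.
#'
#' @return Character vector of length 11 (a subset of [bloodTestFeatures()]).
#' @export
dcqmffFeatureNames <- function() {
  c("Creatinine (mg/dL)",
    "Hemoglobin (g/dL)",
    "INR(PT)",
    "Lymphocytes (%)",
    "Neutrophils (%)",
    "Platelet Count (log K/uL)",
    "PTT (sec)",
    "White Blood Cells (K/uL)",
    "Lactate (mmol/L)",
    "Bilirubin (IU/L)",
    "pH (units)")
}

## feature names constrained to [0, 100] on the stored scale
.percentFeatures <- function() {
  f <- bloodTestFeatures()
  f[grepl("\\(%\\)", f)]
}

.isLogScale <- function(features) grepl("log", features, fixed = TRUE)

#' @title SepsisCohort: container for a sepsis admission cohort
#'
#' @description
#' A [SummarizedExperiment::SummarizedExperiment] subclass holding the 35
#' blood-test features as the `"bloodTests"` assay (features x patients) and
#' per-patient outcome/covariate columns in `colData`: `survived_28d`,
#' `time_days`, `event`, `heparin`, `age`, `sex`, and (for simulated cohorts)
#' `true_cluster` plus an organ panel (`pf_ratio`, `map_mmHg`, `gcs`) used for
#' severity scoring.
#'
#' @slot normalized scan `metadata(x)$normalized` for whether the assay holds
#'   normalized values (set by [applyNormalizer()]).
#' @export
setClass("SepsisCohort", contains = "SummarizedExperiment")

.validSepsisCohort <- function(object) {
  msg <- character()
  feats <- bloodTestFeatures()
  if (!identical(rownames(object), feats))
    msg <- c(msg, "assay rows must be exactly the 35 canonical blood-test features, in order")
  if (!("bloodTests" %in% SummarizedExperiment::assayNames(object)))
    msg <- c(msg, "assay 'bloodTests' is required")
  cd <- SummarizedExperiment::colData(object)
  needed <- c("survived_28d", "time_days", "event")
  miss <- setdiff(needed, colnames(cd))
  if (length(miss))
    msg <- c(msg, paste0("colData lacks column(s): ", paste(miss, collapse = ", ")))
  if (!length(msg) && ncol(object)) {
    tm <- cd$time_days
    if (any(!is.finite(tm)) || any(tm < 0) || any(tm > 28))
      msg <- c(msg, "time_days must lie in [0, 28]")
    if (any(cd$survived_28d != (1 - cd$event)))
      msg <- c(msg, "survived_28d must equal 1 - event under the 28-day horizon")
    ## on the raw scale, percentage analytes must be valid percentages
    if (!isTRUE(S4Vectors::metadata(object)$normalized)) {
      a <- SummarizedExperiment::assay(object, "bloodTests")
      pc <- a[.percentFeatures(), , drop = FALSE]
      if (any(pc < 0 | pc > 100, na.rm = TRUE))
        msg <- c(msg, "percentage features must lie in [0, 100]")
    }
  }
  if (length(msg)) msg else TRUE
}
setValidity("SepsisCohort", .validSepsisCohort)

#' Construct a SepsisCohort
#'
#' @param features numeric matrix, 35 features x n patients (rownames must be
#'   [bloodTestFeatures()]) or its transpose (auto-detected by dimnames).
#' @param colData data.frame / DataFrame of per-patient columns; must contain
#'   `survived_28d`, `time_days`, `event`.
#' @param metadata list stored as experiment metadata.
#' @return A [SepsisCohort-class] object.
#' @export
SepsisCohort <- function(features, colData, metadata = list()) {
  if (!is.null(colnames(features)) &&
      identical(colnames(features), bloodTestFeatures())) {
    features <- t(features)
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(bloodTests = features),
    colData = S4Vectors::DataFrame(colData, check.names = FALSE),
    metadata = metadata)
  methods::new("SepsisCohort", se)
}

#' @title PhenotypeSpec: generative parameters for one phenotype cluster
#'
#' @description Per-cluster simulator parameters: printed-scale quartile
#' triples for every feature, a heparin-usage probability, a two-piece daily
#' hazard over the 28-day horizon, covariate/panel parameters, and the
#' cluster's mixing weight.
#'
#' @slot clusterId one of `"C1".."C4"` (or any label).
#' @slot featureParams 35 x 3 matrix, columns `median`, `q1`, `q3`, rows
#'   [bloodTestFeatures()], on the stored (printed) scale.
#' @slot heparinProb probability of low-molecular-weight heparin usage.
#' @slot hazard numeric length-2, daily hazard on `[0, break)` and
#'   `[break, 28]`.
#' @slot hazardBreak day at which the hazard changes.
#' @slot mixingWeight mixture weight.
#' @slot maleProb probability of male sex.
#' @slot panelParams list with `pf`, `map`, `gcs` mean/sd pairs for the organ
#'   panel columns used in SOFA scoring.
#' @export
setClass("PhenotypeSpec",
  representation(clusterId = "character",
                 featureParams = "matrix",
                 heparinProb = "numeric",
                 hazard = "numeric",
                 hazardBreak = "numeric",
                 mixingWeight = "numeric",
                 maleProb = "numeric",
                 panelParams = "list"))

setValidity("PhenotypeSpec", function(object) {
  msg <- character()
  fp <- object@featureParams
  if (!identical(rownames(fp), bloodTestFeatures()) ||
      !identical(colnames(fp), c("median", "q1", "q3")))
    msg <- c(msg, "featureParams must be 35 x {median, q1, q3} with canonical rownames")
  else {
    bad <- fp[, "q1"] > fp[, "median"] | fp[, "median"] > fp[, "q3"]
    if (any(bad))
      msg <- c(msg, paste0("q1 <= median <= q3 violated for: ",
                           paste(rownames(fp)[bad], collapse = ", ")))
  }
  if (object@heparinProb < 0 || object@heparinProb > 1)
    msg <- c(msg, "heparinProb must be in [0, 1]")
  if (length(object@hazard) != 2L || any(object@hazard < 0))
    msg <- c(msg, "hazard must be two non-negative daily rates")
  if (object@hazardBreak <= 0 || object@hazardBreak >= 28)
    msg <- c(msg, "hazardBreak must lie strictly inside (0, 28)")
  if (object@mixingWeight < 0) msg <- c(msg, "mixingWeight must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct a PhenotypeSpec
#'
#' @param clusterId cluster label.
#' @param featureParams 35 x 3 matrix (`median`, `q1`, `q3`).
#' @param heparinProb,hazard,hazardBreak,mixingWeight,maleProb,panelParams see
#'   [PhenotypeSpec-class].
#' @return A [PhenotypeSpec-class] object.
#' @export
phenotypeSpec <- function(clusterId, featureParams, heparinProb, hazard,
                          hazardBreak = 7, mixingWeight = 0.25,
                          maleProb = 0.5,
                          panelParams = list(pf = c(330, 70),
                                             map = c(75, 9),
                                             gcs = c(13.5, 1.5))) {
  methods::new("PhenotypeSpec", clusterId = clusterId,
               featureParams = featureParams, heparinProb = heparinProb,
               hazard = hazard, hazardBreak = hazardBreak,
               mixingWeight = mixingWeight, maleProb = maleProb,
               panelParams = panelParams)
}

#' @title CohortConfig: simulator configuration
#'
#' @slot nPatients number of admissions to draw.
#' @slot specs list of [PhenotypeSpec-class], mixing weights summing to 1.
#' @slot pttCeiling assay cap (seconds) applied to PTT.
#' @slot missingRate per-cell blanking probability in `[0, 1)`.
#' @slot seed integer RNG seed.
#' @export
setClass("CohortConfig",
  representation(nPatients = "integer", specs = "list",
                 pttCeiling = "numeric", missingRate = "numeric",
                 seed = "integer"))

setValidity("CohortConfig", function(object) {
  msg <- character()
  if (object@nPatients < length(object@specs))
    msg <- c(msg, "nPatients must be at least the number of clusters")
  if (object@missingRate < 0 || object@missingRate >= 1)
    msg <- c(msg, "missingRate must lie in [0, 1)")
  if (!length(object@specs) ||
      !all(vapply(object@specs, methods::is, TRUE, "PhenotypeSpec")))
    msg <- c(msg, "specs must be a non-empty list of PhenotypeSpec")
  else {
    w <- vapply(object@specs, function(s) s@mixingWeight, 0)
    if (abs(sum(w) - 1) > 1e-8)
      msg <- c(msg, "mixing weights must sum to 1")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a CohortConfig
#'
#' @param nPatients cohort size.
#' @param specs list of [PhenotypeSpec-class] with weights summing to 1.
#' @param pttCeiling PTT assay cap in seconds.
#' @param missingRate per-cell missingness probability in `[0, 1)`.
#' @param seed integer seed.
#' @return A [CohortConfig-class] object.
#' @export
cohortConfig <- function(nPatients, specs, pttCeiling = 150,
                         missingRate = 0, seed = 1L) {
  methods::new("CohortConfig", nPatients = as.integer(nPatients),
               specs = specs, pttCeiling = pttCeiling,
               missingRate = missingRate, seed = as.integer(seed))
}

#' @title KSelectionReport: elbow/silhouette compromise over a K grid
#'
#' @slot kGrid integer grid of candidate cluster counts.
#' @slot inertia best-of-restarts within-cluster sum of squares per K.
#' @slot silhouette mean silhouette coefficient per K.
#' @slot kElbow,kSilhouette,kChosen selected counts.
#' @export
setClass("KSelectionReport",
  representation(kGrid = "integer", inertia = "numeric",
                 silhouette = "numeric", kElbow = "integer",
                 kSilhouette = "integer", kChosen = "integer"))

setValidity("KSelectionReport", function(object) {
  msg <- character()
  if (any(diff(object@inertia) > 1e-8 * object@inertia[1]))
    msg <- c(msg, "inertia must be non-increasing in K")
  if (any(object@silhouette < -1 | object@silhouette > 1))
    msg <- c(msg, "silhouette must lie in [-1, 1]")
  if (!(object@kChosen %in% object@kGrid))
    msg <- c(msg, "kChosen must lie in kGrid")
  if (length(msg)) msg else TRUE
})

#' @title ClusterModel: fitted K-means phenotype model
#'
#' @slot K cluster count.
#' @slot centroids K x 35 matrix in normalized feature space.
#' @slot assignments integer cluster label per patient.
#' @slot inertia total within-cluster sum of squares.
#' @slot seed integer seed used for the fit.
#' @export
setClass("ClusterModel",
  representation(K = "integer", centroids = "matrix",
                 assignments = "integer", inertia = "numeric",
                 seed = "integer"))

setValidity("ClusterModel", function(object) {
  msg <- character()
  if (nrow(object@centroids) != object@K)
    msg <- c(msg, "centroids must have K rows")
  if (length(object@assignments) &&
      !all(seq_len(object@K) %in% object@assignments))
    msg <- c(msg, "every cluster must be non-empty")
  if (length(msg)) msg else TRUE
})

#' @title DCQMFFModel: fitted double-coefficient quadratic classifier
#'
#' @description Parameters of the two-headed quadratic softmax model: each
#' head is a sum over `L` channels of a channel weight (`b` or `cc`) times a
#' per-channel quadratic form in the 11 inputs (`a` or `d`, rows = channels,
#' columns = the 78 quadratic-expansion terms).
#'
#' @slot L channel count (33 by default).
#' @slot b,a head-1 channel weights (length L) and coefficients (L x 78).
#' @slot cc,d head-2 channel weights and coefficients.
#' @slot featureNames the 11 input feature names.
#' @slot config fitting configuration used.
#' @slot lossTrace mean training cross-entropy per epoch.
#' @export
setClass("DCQMFFModel",
  representation(L = "integer", b = "numeric", a = "matrix",
                 cc = "numeric", d = "matrix",
                 featureNames = "character", config = "list",
                 lossTrace = "numeric"))

setValidity("DCQMFFModel", function(object) {
  msg <- character()
  if (length(object@b) != object@L || length(object@cc) != object@L)
    msg <- c(msg, "channel weights must have length L")
  if (!all(dim(object@a) == c(object@L, 78L)) ||
      !all(dim(object@d) == c(object@L, 78L)))
    msg <- c(msg, "coefficient matrices must be L x 78")
  if (!all(is.finite(object@b)) || !all(is.finite(object@a)) ||
      !all(is.finite(object@cc)) || !all(is.finite(object@d)))
    msg <- c(msg, "all parameters must be finite")
  if (length(msg)) msg else TRUE
})

#' @title CNNModel: seven-layer 1-D convolutional classifier
#'
#' @slot config layer schedule and training configuration.
#' @slot weights list of per-layer `W` (kernel x inChannels x outChannels)
#'   arrays and bias vectors.
#' @slot lossTrace mean training binary cross-entropy per epoch.
#' @export
setClass("CNNModel",
  representation(config = "list", weights = "list", lossTrace = "numeric"))
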