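## SOFA and SIC severity scoring. The paper-facing analysis uses the scores
## for cluster characterization and as a baseline predictor; the threshold
## tables themselves are data, shipped as a versioned JSON config so variant
## criteria can be swapped without touching code.

#' Load the severity threshold tables
#'
#' @param path optional path to an alternative JSON config; defaults to the
#'   table shipped with the package (standard SOFA component tiers and the
#'   ISTH sepsis-induced-coagulopathy tiers).
#' @return nested list with `version`, `sofa`, `sic`.
#' @export
severityThresholds <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "severity_thresholds.json",
                        package = "sepsisPhenoscope", mustWork = TRUE)
  jsonlite::read_json(path, simplifyVector = TRUE)
}

## tier lookup: lower_worse counts cutoffs the value falls strictly below
## (cutoffs descending); higher_worse counts cutoffs met or exceeded
## (cutoffs ascending). Missing values score 0 points.
.tierScore <- function(values, spec) {
  cutoffs <- as.numeric(spec$cutoffs)
  score <- rep(0L, length(values))
  known <- !is.na(values)
  if (identical(spec$direction, "lower_worse")) {
    for (c0 in cutoffs) score[known] <- score[known] + (values[known] < c0)
  } else {
    for (c0 in cutoffs) score[known] <- score[known] + (values[known] >= c0)
  }
  as.integer(score)
}

#' SOFA score from an organ panel
#'
#' Sum of six 0-4 component scores: respiration (PaO2/FiO2 ratio),
#' coagulation (platelets, linear K/uL), liver (bilirubin mg/dL),
#' cardiovascular (MAP, optionally overridden by a vasopressor tier 0-4),
#' central nervous system (GCS) and renal (creatinine mg/dL). Missing
#' components contribute 0 points and are flagged in the `"flagged"`
#' attribute.
#'
#' @param panel data.frame (or list of equal-length vectors) with columns
#'   `pf_ratio`, `platelets`, `bilirubin`, `map_mmHg` (and/or
#'   `vasopressor_tier`), `gcs`, `creatinine`.
#' @param thresholds a [severityThresholds()] table.
#' @return integer vector in `[0, 24]`, with attribute `flagged` marking rows
#'   with missing components.
#' @export
#' @examples
#' sofaScore(data.frame(pf_ratio = 500, platelets = 300, bilirubin = 0.5,
#'                      map_mmHg = 80, gcs = 15, creatinine = 0.8))
sofaScore <- function(panel, thresholds = severityThresholds()) {
  panel <- as.data.frame(panel)
  for (col in c("pf_ratio", "platelets", "bilirubin", "gcs", "creatinine",
                "map_mmHg", "vasopressor_tier")) {
    if (!col %in% colnames(panel)) panel[[col]] <- NA_real_
    v <- panel[[col]]
    if (any(v < 0, na.rm = TRUE))
      stop("negative values in panel column '", col, "'")
  }
  if (any(!is.na(panel$gcs) & (panel$gcs < 3 | panel$gcs > 15)))
    stop("gcs must lie in [3, 15]")
  th <- thresholds$sofa
  resp <- .tierScore(panel$pf_ratio, th$respiration_pf)
  coag <- .tierScore(panel$platelets, th$coagulation_platelets)
  liver <- .tierScore(panel$bilirubin, th$liver_bilirubin)
  cardioMap <- .tierScore(panel$map_mmHg, th$cardiovascular_map)
  tier <- ifelse(is.na(panel$vasopressor_tier), 0L,
                 as.integer(panel$vasopressor_tier))
  cardio <- pmax(cardioMap, pmin(tier, 4L))
  cns <- .tierScore(panel$gcs, th$cns_gcs)
  renal <- .tierScore(panel$creatinine, th$renal_creatinine)
  total <- as.integer(resp + coag + liver + cardio + cns + renal)
  flagged <- is.na(panel$pf_ratio) | is.na(panel$platelets) |
    is.na(panel$bilirubin) | is.na(panel$gcs) | is.na(panel$creatinine) |
    (is.na(panel$map_mmHg) & is.na(panel$vasopressor_tier))
  attr(total, "flagged") <- flagged
  attr(total, "components") <- cbind(respiration = resp, coagulation = coag,
                                     liver = liver, cardiovascular = cardio,
                                     cns = cns, renal = renal)
  total
}

#' Flag a high-mortality SOFA score
#'
#' A SOFA score above 12 marks the regime in which mortality exceeds one
#' half.
#'
#' @param score SOFA score(s) in `[0, 24]`.
#' @return logical: `score > 12`.
#' @export
sofaFlagHigh <- function(score) {
  if (any(score < 0 | score > 24)) stop("SOFA scores lie in [0, 24]")
  score > 12
}

#' SIC (sepsis-induced coagulopathy) score
#'
#' Sum of three 0-2 component tiers: platelet count (linear K/uL), INR, and a
#' four-item SOFA subtotal (respiratory + cardiovascular + hepatic + renal).
#'
#' @param panel data.frame with columns `platelets`, `inr`, `sofa_subtotal`.
#' @param thresholds a [severityThresholds()] table.
#' @return integer vector in `[0, 6]`.
#' @export
sicScore <- function(panel, thresholds = severityThresholds()) {
  panel <- as.data.frame(panel)
  stopifnot(all(c("platelets", "inr", "sofa_subtotal") %in% colnames(panel)))
  if (any(unlist(panel[, c("platelets", "inr", "sofa_subtotal")]) < 0,
          na.rm = TRUE))
    stop("negative values in SIC panel")
  if (any(panel$inr <= 0, na.rm = TRUE)) stop("inr must be positive")
  th <- thresholds$sic
  as.integer(.tierScore(panel$platelets, th$platelets) +
             .tierScore(panel$inr, th$inr) +
             .tierScore(panel$sofa_subtotal, th$sofa_subtotal))
}

#' Severity scores for a whole cohort
#'
#' Assembles the SOFA and SIC panels from a cohort's blood tests (platelets
#' back-transformed from the log scale; bilirubin, creatinine and INR taken
#' from their features) and from the organ panel carried in `colData`
#' (`pf_ratio`, `map_mmHg`, `gcs`), then appends `sofa` and `sic` columns.
#'
#' @param cohort a raw-scale [SepsisCohort-class].
#' @param thresholds a [severityThresholds()] table.
#' @return The cohort with `sofa` and `sic` columns in `colData`.
#' @export
cohortSeverityScores <- function(cohort, thresholds = severityThresholds()) {
  if (isTRUE(S4Vectors::metadata(cohort)$normalized))
    stop("severity scoring needs raw-scale blood tests")
  X <- bloodTests(cohort)
  cd <- SummarizedExperiment::colData(cohort)
  panel <- data.frame(
    pf_ratio = cd$pf_ratio,
    platelets = 10^X[, "Platelet Count (log K/uL)"],
    bilirubin = X[, "Bilirubin (IU/L)"],
    map_mmHg = cd$map_mmHg,
    gcs = cd$gcs,
    creatinine = X[, "Creatinine (mg/dL)"])
  sofa <- sofaScore(panel, thresholds)
  comp <- attr(sofa, "components")
  subtotal <- comp[, "respiration"] + comp[, "cardiovascular"] +
    comp[, "liver"] + comp[, "renal"]
  sic <- sicScore(data.frame(platelets = panel$platelets,
                             inr = X[, "INR(PT)"],
                             sofa_subtotal = subtotal), thresholds)
  SummarizedExperiment::colData(cohort)$sofa <- as.integer(sofa)
  SummarizedExperiment::colData(cohort)$sic <- sic
  cohort
}
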