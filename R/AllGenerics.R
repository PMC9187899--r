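#' Extract the blood-test matrix
#'
#' @param x a [SepsisCohort-class].
#' @return numeric matrix, patients x 35 features.
#' @export
setGeneric("bloodTests", function(x) standardGeneric("bloodTests"))

#' @rdname bloodTests
#' @export
setMethod("bloodTests", "SepsisCohort", function(x) {
  t(SummarizedExperiment::assay(x, "bloodTests"))
})

#' Per-patient survival data
#'
#' @param x a [SepsisCohort-class].
#' @param group optional per-patient grouping vector (defaults to
#'   `true_cluster` when present, otherwise a single group).
#' @return data.frame with `time`, `event`, `group`.
#' @export
setGeneric("survivalData", function(x, group = NULL) standardGeneric("survivalData"))

#' @rdname survivalData
#' @export
setMethod("survivalData", "SepsisCohort", function(x, group = NULL) {
  cd <- SummarizedExperiment::colData(x)
  if (is.null(group)) {
    group <- if ("true_cluster" %in% colnames(cd)) cd$true_cluster
             else rep("all", ncol(x))
  }
  data.frame(time = cd$time_days, event = cd$event, group = as.character(group),
             stringsAsFactors = FALSE)
})

#' Cluster assignments of a fitted model
#'
#' @param object a [ClusterModel-class].
#' @return integer vector of labels.
#' @export
setGeneric("clusterAssignments", function(object) standardGeneric("clusterAssignments"))

#' @rdname clusterAssignments
#' @export
setMethod("clusterAssignments", "ClusterModel", function(object) object@assignments)

#' Centroids of a fitted model
#'
#' @param object a [ClusterModel-class].
#' @return K x 35 numeric matrix.
#' @export
setGeneric("centroids", function(object) standardGeneric("centroids"))

#' @rdname centroids
#' @export
setMethod("centroids", "ClusterModel", function(object) object@centroids)

#' Chosen cluster count of a selection report
#'
#' @param object a [KSelectionReport-class].
#' @return integer.
#' @export
setGeneric("kChosen", function(object) standardGeneric("kChosen"))

#' @rdname kChosen
#' @export
setMethod("kChosen", "KSelectionReport", function(object) object@kChosen)

#' Mixing weights of a simulator configuration
#'
#' @param object a [CohortConfig-class].
#' @return named numeric vector.
#' @export
setGeneric("mixingWeights", function(object) standardGeneric("mixingWeights"))

#' @rdname mixingWeights
#' @export
setMethod("mixingWeights", "CohortConfig", function(object) {
  w <- vapply(object@specs, function(s) s@mixingWeight, 0)
  names(w) <- vapply(object@specs, function(s) s@clusterId, "")
  w
})

setMethod("show", "SepsisCohort", function(object) {
  cd <- SummarizedExperiment::colData(object)
  cat("SepsisCohort:", ncol(object), "patients x", nrow(object), "blood tests\n")
  if (ncol(object)) {
    cat(sprintf("  28-day survival: %.1f%%; events: %d\n",
                100 * mean(cd$survived_28d), sum(cd$event)))
    if ("true_cluster" %in% colnames(cd))
      cat("  planted clusters:",
          paste(names(table(cd$true_cluster)), table(cd$true_cluster),
                sep = "=", collapse = ", "), "\n")
  }
  if (isTRUE(S4Vectors::metadata(object)$normalized))
    cat("  assay: normalized scale\n")
  invisible(NULL)
})

setMethod("show", "PhenotypeSpec", function(object) {
  cat(sprintf("PhenotypeSpec %s: weight %.3f, heparin %.2f, hazard (%.4f, %.4f)/day, break day %g\n",
              object@clusterId, object@mixingWeight, object@heparinProb,
              object@hazard[1], object@hazard[2], object@hazardBreak))
  invisible(NULL)
})

setMethod("show", "CohortConfig", function(object) {
  cat(sprintf("CohortConfig: n = %d, %d phenotypes, PTT ceiling %g s, missing rate %.4f, seed %d\n",
              object@nPatients, length(object@specs), object@pttCeiling,
              object@missingRate, object@seed))
  invisible(NULL)
})

setMethod("show", "KSelectionReport", function(object) {
  cat("KSelectionReport over K =", paste(range(object@kGrid), collapse = ".."), "\n")
  cat("  elbow K:", object@kElbow, " silhouette K:", object@kSilhouette,
      " chosen K:", object@kChosen, "\n")
  invisible(NULL)
})

setMethod("show", "ClusterModel", function(object) {
  cat(sprintf("ClusterModel: K = %d, n = %d, inertia %.4f\n",
              object@K, length(object@assignments), object@inertia))
  invisible(NULL)
})

setMethod("show", "DCQMFFModel", function(object) {
  cat(sprintf("DCQMFFModel: %d channels, %d quadratic terms over %d features\n",
              object@L, ncol(object@a), length(object@featureNames)))
  if (length(object@lossTrace))
    cat(sprintf("  training cross-entropy: %.4f -> %.4f over %d epochs\n",
                object@lossTrace[1], object@lossTrace[length(object@lossTrace)],
                length(object@lossTrace)))
  invisible(NULL)
})

setMethod("show", "CNNModel", function(object) {
  ch <- object@config$channels
  cat("CNNModel: channels", paste(ch, collapse = "-"), "\n")
  if (length(object@lossTrace))
    cat(sprintf("  training BCE: %.4f -> %.4f over %d epochs\n",
                object@lossTrace[1], object@lossTrace[length(object@lossTrace)],
                length(object@lossTrace)))
  invisible(NULL)
})
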