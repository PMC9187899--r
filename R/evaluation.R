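## Metrics, ROC/AUC, baseline comparators, and the end-to-end pipeline
## runner. Death is the positive class throughout.

#' ROC points
#'
#' Sweeps thresholds over the unique scores (ties grouped) and returns the
#' (FPR, TPR) trace from (0, 0) to (1, 1), monotone in FPR.
#'
#' @param scores numeric risk scores (higher = more death-like).
#' @param labels binary labels, 1 = death.
#' @return data.frame with `threshold`, `fpr`, `tpr`.
#' @export
rocPoints <- function(scores, labels) {
  if (length(scores) != length(labels)) stop("length mismatch")
  if (any(!is.finite(scores))) stop("scores must be finite")
  labels <- as.numeric(labels)
  if (length(unique(labels)) < 2)
    stop("undefined AUC: both classes must be present")
  nPos <- sum(labels == 1); nNeg <- sum(labels == 0)
  thr <- sort(unique(scores), decreasing = TRUE)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  cumPos <- cumsum(l == 1); cumNeg <- cumsum(l == 0)
  ## index of the last observation at each threshold (ties grouped)
  lastAt <- cumsum(rle(s)$lengths)
  data.frame(threshold = c(Inf, thr),
             fpr = c(0, cumNeg[lastAt] / nNeg),
             tpr = c(0, cumPos[lastAt] / nPos))
}

#' Trapezoid AUC of an ROC trace
#'
#' @param points a [rocPoints()] result (or any data.frame with `fpr`, `tpr`
#'   ordered by `fpr`).
#' @return area under the curve.
#' @export
aucTrapezoid <- function(points) {
  fpr <- points$fpr; tpr <- points$tpr
  k <- length(tpr)
  sum(diff(fpr) * (tpr[-k] + tpr[-1]) / 2)
}

#' AUC of scores against labels
#'
#' @param scores,labels as in [rocPoints()].
#' @return trapezoid AUC.
#' @export
aucScore <- function(scores, labels) aucTrapezoid(rocPoints(scores, labels))

#' Classification metrics with death as the positive class
#'
#' @param pred binary predicted labels (1 = death).
#' @param truth binary true labels.
#' @return list with `accuracy`, `precision`, `recall`, `f1`, the 2 x 2
#'   `confusion` matrix, and `flagged` naming any zero-denominator metric
#'   reported as 0.
#' @export
classificationMetrics <- function(pred, truth) {
  if (length(pred) != length(truth)) stop("length mismatch")
  tp <- sum(pred == 1 & truth == 1); fp <- sum(pred == 1 & truth == 0)
  fn <- sum(pred == 0 & truth == 1); tn <- sum(pred == 0 & truth == 0)
  flagged <- character(0)
  prec <- if (tp + fp == 0) { flagged <- c(flagged, "precision"); 0 } else tp / (tp + fp)
  rec <- if (tp + fn == 0) { flagged <- c(flagged, "recall"); 0 } else tp / (tp + fn)
  f1 <- if (prec + rec == 0) { flagged <- c(flagged, "f1"); 0 } else 2 * prec * rec / (prec + rec)
  list(accuracy = (tp + tn) / length(pred), precision = prec, recall = rec,
       f1 = f1,
       confusion = matrix(c(tp, fn, fp, tn), 2, 2,
                          dimnames = list(pred = c("death", "survive"),
                                          truth = c("death", "survive"))),
       flagged = flagged)
}

#' SOFA score as a mortality predictor
#'
#' Applies the ROC/AUC machinery to the integer SOFA score.
#'
#' @param scores integer SOFA scores.
#' @param labels binary labels (1 = death).
#' @return list with `roc` points and `auc`.
#' @export
sofaAsPredictor <- function(scores, labels) {
  if (length(unique(scores)) < 2)
    stop("undefined AUC: SOFA score is constant")
  roc <- rocPoints(scores, labels)
  list(roc = roc, auc = aucTrapezoid(roc))
}

#' Standard baseline classifiers
#'
#' Default-hyperparameter logistic regression, random forest, and
#' cross-validated lasso on the 35 normalized features, evaluated with the
#' same ROC/metric machinery as the bespoke models.
#'
#' @param train,test normalized [SepsisCohort-class] objects.
#' @param seed integer seed.
#' @return named list (`logistic`, `random_forest`, `lasso`) of lists with
#'   `auc` and [classificationMetrics()] on the test set.
#' @export
fitBaselines <- function(train, test, seed = 1L) {
  Xtr <- bloodTests(train); Xte <- bloodTests(test)
  ytr <- 1 - SummarizedExperiment::colData(train)$survived_28d
  yte <- 1 - SummarizedExperiment::colData(test)$survived_28d
  dtr <- data.frame(Xtr, check.names = TRUE); dtr$y <- ytr
  dte <- data.frame(Xte, check.names = TRUE)

  set.seed(seed)
  lg <- suppressWarnings(stats::glm(y ~ ., data = dtr, family = stats::binomial()))
  pLg <- stats::predict(lg, dte, type = "response")

  set.seed(seed)
  rf <- randomForest::randomForest(x = Xtr, y = factor(ytr))
  pRf <- stats::predict(rf, Xte, type = "prob")[, "1"]

  set.seed(seed)
  cv <- glmnet::cv.glmnet(Xtr, ytr, family = "binomial", alpha = 1)
  pLa <- as.numeric(stats::predict(cv, Xte, s = "lambda.min", type = "response"))

  wrap <- function(p) list(auc = aucScore(p, yte),
                           metrics = classificationMetrics(as.integer(p > 0.5), yte))
  list(logistic = wrap(pLg), random_forest = wrap(pRf), lasso = wrap(pLa))
}

#' Pipeline configuration
#'
#' @param cohort optional pre-built [SepsisCohort-class]; when `NULL` a
#'   cohort is simulated from `cohortConfig`.
#' @param cohortConfig a [CohortConfig-class] for simulation.
#' @param seed master seed for split/up-sampling/model fits.
#' @param kGrid candidate cluster counts.
#' @param K optional override of the chosen cluster count.
#' @param dcqmff a [dcqmffConfig()].
#' @param cnn a [cnnConfig()].
#' @param outDir optional artifact directory (created if needed); `NULL`
#'   writes nothing.
#' @return list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(cohort = NULL,
                           cohortConfig = defaultCohortConfig(seed = seed),
                           seed = 1L, kGrid = 2:8, K = NULL,
                           dcqmff = dcqmffConfig(epochs = 300L, seed = seed),
                           cnn = cnnConfig(epochs = 60L, seed = seed),
                           outDir = NULL) {
  structure(list(cohort = cohort, cohortConfig = cohortConfig,
                 seed = as.integer(seed), kGrid = kGrid, K = K,
                 dcqmff = dcqmff, cnn = cnn, outDir = outDir),
            class = "PipelineConfig")
}

.writeJson <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Run the end-to-end analysis pipeline
#'
#' Generate (or accept) a cohort, exclude incomplete admissions, split 7:3,
#' normalize on the training minima/maxima, up-sample the training deaths,
#' select and fit the phenotype clusters, profile their heterogeneity, embed
#' in 3-D, score severity, compare per-cluster survival, train the DCQMFF and
#' CNN classifiers and the standard baselines, and assemble the evaluation
#' report. Every stage is seeded from `config$seed`, so a rerun with the same
#' configuration reproduces the report byte for byte.
#'
#' @param config a [pipelineConfig()].
#' @param verbose print stage-level progress.
#' @return list of class `EvalReport` (also written as `report.json` plus CSV
#'   artifacts when `outDir` is set).
#' @export
runPipeline <- function(config = pipelineConfig(), verbose = FALSE) {
  say <- function(...) if (verbose) message("[pipeline] ", ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  out <- config$outDir
  if (!is.null(out) && !dir.exists(out)) dir.create(out, recursive = TRUE)
  emit <- function(fn, obj, writer) {
    if (!is.null(out)) writer(obj, file.path(out, fn))
  }

  say("cohort")
  cohort <- stage("cohort", {
    if (is.null(config$cohort)) sampleCohort(config$cohortConfig)
    else config$cohort
  })
  emit("cohort.csv", cohort, writeCohortCsv)

  say("exclude incomplete")
  ex <- stage("exclude_incomplete", excludeIncomplete(cohort))
  complete <- ex$cohort

  say("split 7:3")
  sp <- stage("split", splitCohort(complete, ratio = 0.7, seed = config$seed))

  say("normalize")
  norm <- stage("normalize", fitNormalizer(sp$train))
  trainN <- applyNormalizer(norm, sp$train)
  testN <- applyNormalizer(norm, sp$test)
  emit("normalization.json", norm, writeNormalizer)

  say("up-sample deaths")
  trainBal <- stage("upsample",
    upsampleMinority(trainN, upsampleConfig(seed = config$seed)))

  say("select K")
  ksel <- stage("select_k", selectK(trainN, kGrid = config$kGrid,
                                    seed = config$seed))
  K <- if (is.null(config$K)) kChosen(ksel) else as.integer(config$K)

  say("fit clusters (K = ", K, ")")
  model <- stage("fit_clusters", fitClusters(trainN, K, seed = config$seed))
  profile <- stage("profile_clusters", profileClusters(trainN, model))
  emb <- stage("pca3", projectPCA3(trainN))
  if (!is.null(out)) {
    utils::write.csv(data.frame(patient_id = SummarizedExperiment::colData(sp$train)$patient_id,
                                cluster = clusterAssignments(model)),
                     file.path(out, "clusters.csv"), row.names = FALSE)
    utils::write.csv(data.frame(pc1 = emb$scores[, 1], pc2 = emb$scores[, 2],
                                pc3 = emb$scores[, 3]),
                     file.path(out, "embedding.csv"), row.names = FALSE)
    utils::write.csv(profile$table, file.path(out, "heterogeneity.csv"),
                     row.names = FALSE)
  }

  say("severity scores")
  trainScored <- stage("severity", cohortSeverityScores(sp$train))
  cdTr <- SummarizedExperiment::colData(trainScored)

  say("survival comparison")
  sdata <- data.frame(time = cdTr$time_days, event = cdTr$event,
                      group = clusterAssignments(model))
  survTest <- stage("survival_tests", survivalHigherP(sdata))
  kmCurves <- lapply(sort(unique(sdata$group)), function(g)
    cbind(group = g, kmEstimate(sdata, g)))
  if (!is.null(out))
    utils::write.csv(do.call(rbind, kmCurves), file.path(out, "km_curves.csv"),
                     row.names = FALSE)

  yTest <- 1 - SummarizedExperiment::colData(sp$test)$survived_28d

  say("DCQMFF")
  dcq <- stage("dcqmff", dcqmffFit(trainBal, config = config$dcqmff))
  dcqPred <- dcqmffPredict(dcq, testN)
  dcqTrainPred <- dcqmffPredict(dcq, trainN)
  yTrain <- 1 - SummarizedExperiment::colData(sp$train)$survived_28d

  say("CNN")
  cnn <- stage("cnn", cnnFit(trainBal, config = config$cnn))
  cnnPred <- cnnPredict(cnn, testN)
  cnnTrainPred <- cnnPredict(cnn, trainN)

  say("baselines")
  baselines <- stage("baselines", fitBaselines(trainN, testN,
                                               seed = config$seed))

  say("SOFA as predictor")
  testScored <- cohortSeverityScores(sp$test)
  sofaTest <- SummarizedExperiment::colData(testScored)$sofa
  sofaEval <- stage("sofa_predictor", sofaAsPredictor(sofaTest, yTest))

  modelEval <- function(pDeath, labels, y) list(
    auc = aucScore(pDeath, y),
    metrics = classificationMetrics(labels, y))
  report <- list(
    positive_class = "death",
    n = list(total = ncol(cohort), excluded = ex$excluded,
             train = ncol(sp$train), test = ncol(sp$test),
             train_upsampled = ncol(trainBal)),
    k_selection = list(k_grid = ksel@kGrid, inertia = ksel@inertia,
                       silhouette = ksel@silhouette, k_elbow = ksel@kElbow,
                       k_silhouette = ksel@kSilhouette, k_chosen = K),
    cluster_sizes = as.list(table(clusterAssignments(model))),
    top_features = profile$topFeatures,
    cluster_survival = list(fraction = as.list(profile$survival$fraction),
                            p_dual = profile$survival$p),
    survival_logrank = list(method = survTest$method,
                            statistic = survTest$statistic,
                            p = survTest$p.value),
    severity = list(mean_sofa_by_cluster =
                      as.list(tapply(cdTr$sofa, clusterAssignments(model), mean)),
                    mean_sic_by_cluster =
                      as.list(tapply(cdTr$sic, clusterAssignments(model), mean))),
    models = list(
      dcqmff = list(train = modelEval(dcqTrainPred$p_death, dcqTrainPred$label, yTrain),
                    test = modelEval(dcqPred$p_death, dcqPred$label, yTest)),
      cnn = list(train = modelEval(cnnTrainPred$p_death, cnnTrainPred$label, yTrain),
                 test = modelEval(cnnPred$p_death, cnnPred$label, yTest)),
      sofa_score = list(test = list(auc = sofaEval$auc)),
      baselines = lapply(baselines, function(b)
        list(test = list(auc = b$auc, metrics = b$metrics)))),
    seeds = list(master = config$seed,
                 cohort = if (is.null(config$cohort)) config$cohortConfig@seed else NA))
  ## confusion matrices serialize as plain counts
  report <- rapply(report, function(x) {
    if (is.matrix(x)) as.list(as.data.frame(x)) else x
  }, how = "replace")
  class(report) <- c("EvalReport", "list")
  if (!is.null(out)) .writeJson(unclass(report), file.path(out, "report.json"))
  report
}

#' @export
print.EvalReport <- function(x, ...) {
  cat("EvalReport:", x$n$train, "train /", x$n$test, "test admissions;",
      "K =", x$k_selection$k_chosen, "\n")
  cat(sprintf("  DCQMFF test AUC %.3f, CNN test AUC %.3f, SOFA AUC %.3f\n",
              x$models$dcqmff$test$auc, x$models$cnn$test$auc,
              x$models$sofa_score$test$auc))
  cat(sprintf("  baselines (test AUC): logistic %.3f, RF %.3f, lasso %.3f\n",
              x$models$baselines$logistic$test$auc,
              x$models$baselines$random_forest$test$auc,
              x$models$baselines$lasso$test$auc))
  invisible(x)
}
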