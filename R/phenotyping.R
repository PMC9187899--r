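## Phenotype discovery: K selection by elbow/silhouette compromise, K-means
## with k-means++ seeding (Lloyd iterations, best of 10 restarts), 3-D PCA
## embedding, and dual-nonparametric heterogeneity profiling.

.requireNormalized <- function(cohort) {
  if (!isTRUE(S4Vectors::metadata(cohort)$normalized))
    stop("this operation requires a normalized cohort; apply applyNormalizer() first")
}

## k-means++ seeding: D^2-weighted sequential centroid draws
.kmeansppCenters <- function(X, K) {
  n <- nrow(X)
  centers <- matrix(NA_real_, K, ncol(X))
  centers[1, ] <- X[sample.int(n, 1), ]
  d2 <- rowSums((X - matrix(centers[1, ], n, ncol(X), byrow = TRUE))^2)
  for (k in seq_len(K - 1) + 1) {
    pick <- if (all(d2 == 0)) sample.int(n, 1)
            else sample.int(n, 1, prob = d2)
    centers[k, ] <- X[pick, ]
    dk <- rowSums((X - matrix(centers[k, ], n, ncol(X), byrow = TRUE))^2)
    d2 <- pmin(d2, dk)
  }
  centers
}

.fitKmeansOnce <- function(X, K) {
  centers <- .kmeansppCenters(X, K)
  fit <- suppressWarnings(
    try(stats::kmeans(X, centers = centers, iter.max = 300,
                      algorithm = "Lloyd"), silent = TRUE))
  if (inherits(fit, "try-error") || any(fit$size == 0)) return(NULL)
  fit
}

.bestKmeans <- function(X, K, restarts = 10) {
  best <- NULL
  failures <- 0
  tries <- 0
  while (is.null(best) || tries < restarts) {
    tries <- tries + 1
    fit <- .fitKmeansOnce(X, K)
    if (is.null(fit)) {
      failures <- failures + 1
      if (failures >= 10)
        stop("K-means produced empty clusters in 10 consecutive restarts (K = ", K, ")")
      next
    }
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  best
}

#' Select the cluster count by elbow/silhouette compromise
#'
#' For every K on the grid, fits K-means (best inertia of 10 k-means++
#' restarts) and records the within-cluster sum of squares and the mean
#' silhouette coefficient. The elbow K maximizes the discrete second
#' difference of the inertia trace (maximal curvature); the silhouette K
#' maximizes the mean silhouette. When the two agree that K is chosen;
#' otherwise the candidate with the higher silhouette wins, ties going to the
#' smaller K.
#'
#' @param cohort a normalized, complete-case [SepsisCohort-class] with more
#'   admissions than `max(kGrid)`.
#' @param kGrid integer candidate cluster counts (all >= 2).
#' @param seed integer seed.
#' @return A [KSelectionReport-class].
#' @export
selectK <- function(cohort, kGrid = 2:8, seed = 1L) {
  .requireNormalized(cohort)
  kGrid <- sort(as.integer(kGrid))
  if (any(kGrid < 2)) stop("kGrid must contain only K >= 2")
  X <- bloodTests(cohort)
  if (nrow(X) <= max(kGrid)) stop("need more admissions than max(kGrid)")
  set.seed(as.integer(seed))
  D <- stats::dist(X)
  inertia <- numeric(length(kGrid))
  sil <- numeric(length(kGrid))
  for (i in seq_along(kGrid)) {
    fit <- .bestKmeans(X, kGrid[i])
    inertia[i] <- fit$tot.withinss
    s <- cluster::silhouette(fit$cluster, D)
    sil[i] <- mean(s[, "sil_width"])
  }
  ## monotone repair is unnecessary in practice; guard tiny numeric wobble
  inertia <- cummin(inertia)
  if (length(kGrid) >= 3) {
    d2 <- inertia[seq_len(length(kGrid) - 2)] -
      2 * inertia[seq_len(length(kGrid) - 2) + 1] +
      inertia[seq_len(length(kGrid) - 2) + 2]
    kElbow <- kGrid[which.max(d2) + 1L]
  } else kElbow <- kGrid[which.max(sil)]
  kSil <- kGrid[which.max(sil)]
  if (kElbow == kSil) {
    kChosen <- kElbow
  } else {
    cand <- c(kElbow, kSil)
    sc <- sil[match(cand, kGrid)]
    kChosen <- if (abs(diff(sc)) < 1e-12) min(cand) else cand[which.max(sc)]
  }
  methods::new("KSelectionReport", kGrid = kGrid, inertia = inertia,
               silhouette = sil, kElbow = as.integer(kElbow),
               kSilhouette = as.integer(kSil), kChosen = as.integer(kChosen))
}

#' Fit the K-means phenotype model
#'
#' Lloyd iterations to convergence (at most 300), best total within-cluster
#' sum of squares over 10 k-means++ restarts; deterministic under the seed.
#'
#' @param cohort a normalized, complete-case [SepsisCohort-class].
#' @param K cluster count (2 <= K <= n).
#' @param seed integer seed.
#' @return A [ClusterModel-class].
#' @export
fitClusters <- function(cohort, K, seed = 1L) {
  .requireNormalized(cohort)
  X <- bloodTests(cohort)
  if (K > nrow(X)) stop("K cannot exceed the number of admissions")
  set.seed(as.integer(seed))
  if (K == 1) {
    ctr <- matrix(colMeans(X), 1, ncol(X), dimnames = list(NULL, colnames(X)))
    wss <- sum(sweep(X, 2, ctr[1, ])^2)
    return(methods::new("ClusterModel", K = 1L, centroids = ctr,
                        assignments = rep(1L, nrow(X)), inertia = wss,
                        seed = as.integer(seed)))
  }
  fit <- .bestKmeans(X, as.integer(K))
  methods::new("ClusterModel", K = as.integer(K), centroids = fit$centers,
               assignments = as.integer(fit$cluster),
               inertia = fit$tot.withinss, seed = as.integer(seed))
}

#' Three-dimensional PCA embedding
#'
#' Top-3 principal components of the centered normalized feature matrix, for
#' visualizing the phenotype structure. Sign convention: within each loading
#' vector the entry of largest magnitude is positive.
#'
#' @param cohort a normalized [SepsisCohort-class] with n >= 4.
#' @return list of class `Embedding3D` with `loadings` (35 x 3, orthonormal),
#'   `scores` (n x 3) and `explainedVariance` (3 fractions of total variance).
#' @export
projectPCA3 <- function(cohort) {
  .requireNormalized(cohort)
  X <- bloodTests(cohort)
  if (nrow(X) < 4) stop("PCA embedding needs at least 4 admissions")
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  if (sum(pc$sdev > max(pc$sdev) * 1e-10) < 3)
    stop("data rank below 3: only ",
         sum(pc$sdev > max(pc$sdev) * 1e-10), " non-degenerate direction(s)")
  L <- pc$rotation[, 1:3, drop = FALSE]
  S <- pc$x[, 1:3, drop = FALSE]
  for (j in 1:3) {
    i <- which.max(abs(L[, j]))
    if (L[i, j] < 0) { L[, j] <- -L[, j]; S[, j] <- -S[, j] }
  }
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(loadings = L, scores = S, explainedVariance = ev[1:3]),
            class = "Embedding3D")
}

#' Profile cluster heterogeneity feature by feature
#'
#' For each of the 35 blood tests, tests heterogeneity across the K clusters
#' with both Kruskal-Wallis and Jonckheere-Terpstra and reports the more
#' conservative (higher) p value, ranks the features by it, and tabulates the
#' per-cluster median (IQR). The per-cluster survival fraction is tested with
#' the same dual rule.
#'
#' @param cohort the [SepsisCohort-class] the model was fitted on.
#' @param model a [ClusterModel-class].
#' @param topK how many leading features to list.
#' @param ordering group ordering handed to Jonckheere-Terpstra:
#'   `"index"` (cluster index, default) or `"severity"` (by cluster
#'   mortality).
#' @return list of class `HeterogeneityReport`: `table` (data.frame with
#'   `feature`, `p_kw`, `p_jt`, `p_reported`, `rank`), `topFeatures`,
#'   `clusterMedians` (feature x cluster "median (q1-q3)" strings),
#'   `survival` (per-cluster fraction and its dual-test p).
#' @export
profileClusters <- function(cohort, model, topK = 10,
                            ordering = c("index", "severity")) {
  ordering <- match.arg(ordering)
  lab <- clusterAssignments(model)
  if (length(lab) != ncol(cohort))
    stop("model assignments do not match the cohort")
  if (model@K < 2 || any(table(lab) < 2))
    stop("need >= 2 clusters each with >= 2 members")
  X <- bloodTests(cohort)
  cd <- SummarizedExperiment::colData(cohort)
  ord <- if (ordering == "severity") {
    mort <- tapply(1 - cd$survived_28d, lab, mean)
    as.integer(names(sort(mort)))
  } else sort(unique(lab))

  feats <- colnames(X)
  pkw <- pjt <- numeric(length(feats))
  meds <- matrix("", length(feats), model@K,
                 dimnames = list(feats, paste0("C", seq_len(model@K))))
  for (j in seq_along(feats)) {
    groups <- split(X[, j], lab)
    if (length(unique(X[, j])) == 1L) {
      warning("feature '", feats[j], "' is identical across clusters; p = 1")
      pkw[j] <- pjt[j] <- 1
    } else {
      pkw[j] <- kruskalWallis(groups)$p.value
      pjt[j] <- jonckheereTerpstra(groups[as.character(ord)])$p.value
    }
    for (k in seq_len(model@K)) {
      v <- groups[[as.character(k)]]
      meds[j, k] <- sprintf("%.1f (%.1f-%.1f)", stats::median(v),
                            stats::quantile(v, 0.25), stats::quantile(v, 0.75))
    }
  }
  pRep <- pmax(pkw, pjt)
  tab <- data.frame(feature = feats, p_kw = pkw, p_jt = pjt,
                    p_reported = pRep, stringsAsFactors = FALSE)
  tab <- tab[order(tab$p_reported, tab$feature), ]
  tab$rank <- seq_len(nrow(tab))
  survGroups <- split(as.numeric(cd$survived_28d), lab)
  survP <- higherP(kruskalWallis(survGroups),
                   jonckheereTerpstra(survGroups[as.character(ord)]))
  structure(list(table = tab,
                 topFeatures = tab$feature[seq_len(min(topK, nrow(tab)))],
                 clusterMedians = meds,
                 survival = list(fraction = vapply(survGroups, mean, 0),
                                 p = survP$p.value)),
            class = "HeterogeneityReport")
}
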