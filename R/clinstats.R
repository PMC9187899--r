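## Self-contained nonparametric and survival machinery: Kruskal-Wallis and
## Jonckheere-Terpstra (exact permutation for small samples, tie-corrected
## asymptotics otherwise), the Kaplan-Meier product-limit estimator, the
## Mantel log-rank and Gehan-Breslow-Wilcoxon k-sample tests, and the
## conservative higher-p reporting combinator.

.testResult <- function(method, statistic, p, df = NULL, approximation) {
  structure(list(method = method, statistic = unname(statistic),
                 p.value = min(max(unname(p), 0), 1), df = df,
                 approximation = approximation),
            class = "TestResult")
}

#' @export
print.TestResult <- function(x, ...) {
  cat(sprintf("%s: statistic = %.6g, p = %.6g (%s%s)\n", x$method,
              x$statistic, x$p.value, x$approximation,
              if (!is.null(x$df)) paste0(", df = ", x$df) else ""))
  invisible(x)
}

## enumerate all distinct assignments of N pooled observations to groups of
## the given sizes and apply FUN(list-of-groups); used by the exact paths
.enumeratePartitions <- function(pooled, sizes, FUN) {
  out <- numeric(0)
  recurse <- function(idx, remaining, acc) {
    if (!length(remaining)) {
      out[[length(out) + 1]] <<- FUN(acc)
      return(invisible(NULL))
    }
    take <- remaining[1]
    if (take == length(idx)) {
      recurse(integer(0), remaining[-1], c(acc, list(pooled[idx])))
    } else {
      cmb <- utils::combn(length(idx), take)
      for (c0 in seq_len(ncol(cmb))) {
        sel <- cmb[, c0]
        recurse(idx[-sel], remaining[-1], c(acc, list(pooled[idx[sel]])))
      }
    }
    invisible(NULL)
  }
  recurse(seq_along(pooled), sizes, list())
  out
}

.kwStatistic <- function(groups) {
  x <- unlist(groups, use.names = FALSE)
  N <- length(x)
  r <- rank(x)
  sizes <- lengths(groups)
  ends <- cumsum(sizes)
  starts <- ends - sizes + 1
  H <- 0
  for (i in seq_along(groups)) {
    Ri <- mean(r[starts[i]:ends[i]])
    H <- H + sizes[i] * (Ri - (N + 1) / 2)^2
  }
  H <- 12 * H / (N * (N + 1))
  ties <- table(x)
  corr <- 1 - sum(ties^3 - ties) / (N^3 - N)
  if (corr > 0) H <- H / corr else H <- 0
  H
}

#' Kruskal-Wallis heterogeneity test
#'
#' Rank-based k-sample location test with tie correction. For total sample
#' size at most `exactLimit` the p value is computed by exact permutation
#' (full enumeration over all distinct group assignments); otherwise from the
#' chi-square approximation with k-1 degrees of freedom.
#'
#' @param groups list of >= 2 non-empty numeric vectors.
#' @param exactLimit largest total n for the exact path (default 12).
#' @return A `TestResult`.
#' @export
#' @examples
#' kruskalWallis(list(c(1, 2, 3), c(4, 5, 6)))
kruskalWallis <- function(groups, exactLimit = 12) {
  if (length(groups) < 2) stop("need at least 2 groups")
  if (any(lengths(groups) == 0)) stop("every group must be non-empty")
  H <- .kwStatistic(groups)
  k <- length(groups)
  N <- sum(lengths(groups))
  if (N <= exactLimit) {
    pooled <- unlist(groups, use.names = FALSE)
    stats <- .enumeratePartitions(pooled, lengths(groups), .kwStatistic)
    p <- mean(stats >= H - 1e-12)
    .testResult("Kruskal-Wallis", H, p, df = NULL, "exact-permutation")
  } else {
    p <- stats::pchisq(H, df = k - 1, lower.tail = FALSE)
    .testResult("Kruskal-Wallis", H, p, df = k - 1, "chi-square")
  }
}

.jtStatistic <- function(groups) {
  k <- length(groups)
  jt <- 0
  for (a in seq_len(k - 1)) {
    xa <- sort(groups[[a]])
    for (b in (a + 1):k) {
      xb <- groups[[b]]
      nLess <- findInterval(xb, xa)                     # xa values <= xb
      nLeq <- findInterval(xb, xa, left.open = TRUE)    # xa values <  xb
      jt <- jt + sum(nLeq) + 0.5 * sum(nLess - nLeq)
    }
  }
  jt
}

.jtMoments <- function(groups) {
  x <- unlist(groups, use.names = FALSE)
  N <- length(x)
  ni <- lengths(groups)
  tj <- as.numeric(table(x))
  mu <- (N^2 - sum(ni^2)) / 4
  A <- N * (N - 1) * (2 * N + 5) - sum(ni * (ni - 1) * (2 * ni + 5)) -
    sum(tj * (tj - 1) * (2 * tj + 5))
  B <- sum(ni * (ni - 1) * (ni - 2)) * sum(tj * (tj - 1) * (tj - 2))
  C <- sum(ni * (ni - 1)) * sum(tj * (tj - 1))
  v <- A / 72 +
    B / (36 * N * (N - 1) * (N - 2)) +
    C / (8 * N * (N - 1))
  list(mean = mu, var = max(v, 0))
}

#' Jonckheere-Terpstra ordered-alternative test
#'
#' Trend test across ordered groups: the statistic is the sum over ordered
#' group pairs of Mann-Whitney counts, ties counted one half. The group
#' ordering is semantic and must be supplied by the caller through the list
#' order. For total n at most `exactLimit` the p value is exact (full
#' enumeration); otherwise a normal approximation with tie-corrected variance
#' is used (no continuity correction, so reversing the group order
#' complements a one-sided p exactly).
#'
#' @param groups list of >= 2 numeric vectors, in hypothesis order.
#' @param alternative `"two.sided"` (default), `"increasing"` or
#'   `"decreasing"`.
#' @param exactLimit largest total n for the exact path (default 10).
#' @return A `TestResult`.
#' @export
jonckheereTerpstra <- function(groups,
                               alternative = c("two.sided", "increasing",
                                               "decreasing"),
                               exactLimit = 10) {
  alternative <- match.arg(alternative)
  if (!is.list(groups) || length(groups) < 2)
    stop("groups must be a list of >= 2 ordered samples (ordering is semantic)")
  if (any(lengths(groups) == 0)) stop("every group must be non-empty")
  jt <- .jtStatistic(groups)
  mom <- .jtMoments(groups)
  N <- sum(lengths(groups))
  if (N <= exactLimit) {
    pooled <- unlist(groups, use.names = FALSE)
    stats <- .enumeratePartitions(pooled, lengths(groups), .jtStatistic)
    p <- switch(alternative,
      increasing = mean(stats >= jt - 1e-12),
      decreasing = mean(stats <= jt + 1e-12),
      two.sided = mean(abs(stats - mom$mean) >= abs(jt - mom$mean) - 1e-12))
    return(.testResult("Jonckheere-Terpstra", jt, p, NULL, "exact-permutation"))
  }
  if (mom$var <= 0)
    return(.testResult("Jonckheere-Terpstra", jt, 1, NULL, "normal"))
  z <- (jt - mom$mean) / sqrt(mom$var)
  p <- switch(alternative,
    increasing = stats::pnorm(z, lower.tail = FALSE),
    decreasing = stats::pnorm(z),
    two.sided = 2 * stats::pnorm(-abs(z)))
  .testResult("Jonckheere-Terpstra", jt, p, NULL, "normal")
}

#' Conservative higher-p reporting rule
#'
#' Given two test results on the same comparison, reports the one with the
#' larger p value (a deliberately conservative combination); both component
#' results are attached, and exact ties are flagged and resolved to the first
#' argument.
#'
#' @param a,b `TestResult` objects.
#' @return The more conservative `TestResult`, with `components` and `tie`
#'   fields added.
#' @export
higherP <- function(a, b) {
  tie <- a$p.value == b$p.value
  out <- if (b$p.value > a$p.value) b else a
  out$components <- list(a = a, b = b)
  out$tie <- tie
  out$method <- paste0("higher-p(", a$method, ", ", b$method, ")")
  out
}

.checkSurvivalData <- function(data) {
  stopifnot(all(c("time", "event", "group") %in% colnames(data)))
  if (any(!is.finite(data$time)) || any(data$time < 0))
    stop("times must be finite and non-negative")
  if (any(table(data$group) == 0)) stop("every group must be non-empty")
  data
}

#' Kaplan-Meier product-limit estimator
#'
#' @param data data.frame with `time`, `event` (1 = death), `group`.
#' @param group which group to estimate (default: pool all subjects).
#' @return data.frame of class `kmEstimate` with one row per distinct event
#'   time: `time`, `n.risk`, `n.event`, `survival` (the step value from that
#'   time on); survival is 1 before the first event.
#' @export
#' @examples
#' d <- data.frame(time = c(5, 10, 12, 28), event = c(1, 1, 0, 0), group = "a")
#' kmEstimate(d)
kmEstimate <- function(data, group = NULL) {
  .checkSurvivalData(data)
  if (!is.null(group)) {
    if (!group %in% data$group) stop("group '", group, "' not present")
    data <- data[data$group == group, ]
  }
  tt <- sort(unique(data$time[data$event == 1]))
  s <- 1
  rows <- lapply(tt, function(t0) {
    nRisk <- sum(data$time >= t0)
    nEvent <- sum(data$time == t0 & data$event == 1)
    s <<- s * (1 - nEvent / nRisk)
    data.frame(time = t0, n.risk = nRisk, n.event = nEvent, survival = s)
  })
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(time = numeric(0), n.risk = integer(0),
                         n.event = integer(0), survival = numeric(0))
  class(out) <- c("kmEstimate", "data.frame")
  out
}

#' Evaluate a Kaplan-Meier curve at given times
#'
#' @param km a [kmEstimate()] result.
#' @param times numeric vector.
#' @return survival probabilities (1 before the first event).
#' @export
kmSurvivalAt <- function(km, times) {
  vapply(times, function(t0) {
    i <- findInterval(t0, km$time)
    if (i == 0) 1 else km$survival[i]
  }, 0)
}

## weighted k-sample observed-minus-expected test over pooled event times;
## weightFun maps the total at-risk count to the event-time weight
.weightedLogrank <- function(data, weightFun, method) {
  .checkSurvivalData(data)
  groups <- sort(unique(data$group))
  k <- length(groups)
  if (k < 2) stop("need at least 2 groups")
  if (sum(data$event) == 0)
    stop("undefined test: no events observed")
  tt <- sort(unique(data$time[data$event == 1]))
  U <- rep(0, k - 1)
  V <- matrix(0, k - 1, k - 1)
  for (t0 in tt) {
    atRisk <- data$time >= t0
    nj <- sum(atRisk)
    dj <- sum(data$time == t0 & data$event == 1)
    if (nj == 0) next
    w <- weightFun(nj)
    nij <- vapply(groups, function(g) sum(atRisk & data$group == g), 0)
    dij <- vapply(groups, function(g)
      sum(data$time == t0 & data$event == 1 & data$group == g), 0)
    oe <- dij - dj * nij / nj
    U <- U + w * oe[-k]
    if (nj > 1) {
      p <- nij / nj
      Vj <- (diag(p[-k], k - 1) - tcrossprod(p[-k])) *
        dj * (nj - dj) / (nj - 1)
      V <- V + w^2 * Vj
    }
  }
  ## chi-square quadratic form with a pseudo-inverse guard for rank loss
  sv <- svd(V)
  pos <- sv$d > max(sv$d) * 1e-10
  if (!any(pos)) {
    stat <- 0
  } else {
    Vinv <- sv$v[, pos, drop = FALSE] %*%
      (t(sv$u[, pos, drop = FALSE]) / sv$d[pos])
    stat <- drop(t(U) %*% Vinv %*% U)
  }
  p <- stats::pchisq(stat, df = k - 1, lower.tail = FALSE)
  .testResult(method, stat, p, df = k - 1, "chi-square")
}

#' Mantel log-rank test
#'
#' Observed-minus-expected chi-square over pooled event times with unit
#' weights; degrees of freedom = groups - 1.
#'
#' @param data data.frame with `time`, `event`, `group` and >= 1 event.
#' @return A `TestResult`.
#' @export
logrankMantel <- function(data) {
  .weightedLogrank(data, function(nj) 1, "log-rank (Mantel)")
}

#' Gehan-Breslow-Wilcoxon test
#'
#' Same observed-minus-expected construction as the log-rank test but with
#' each event time weighted by the total at-risk count, emphasizing early
#' deaths. Reported alongside the log-rank test through [higherP()].
#'
#' @param data data.frame with `time`, `event`, `group` and >= 1 event.
#' @return A `TestResult`.
#' @export
gehanBreslowWilcoxon <- function(data) {
  .weightedLogrank(data, function(nj) nj, "Gehan-Breslow-Wilcoxon")
}

#' Dual survival comparison with the higher-p rule
#'
#' Runs [logrankMantel()] and [gehanBreslowWilcoxon()] and reports the more
#' conservative of the two.
#'
#' @param data data.frame with `time`, `event`, `group`.
#' @return A `TestResult` (see [higherP()]).
#' @export
survivalHigherP <- function(data) {
  higherP(logrankMantel(data), gehanBreslowWilcoxon(data))
}
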