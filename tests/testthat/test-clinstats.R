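test_that("Kruskal-Wallis exact p matches the hand-enumerated value", {
  ## ranks 1-3 vs 4-6: H = 3.857...; 2 of the 20 assignments are as extreme
  res <- kruskalWallis(list(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(res$statistic, 12 / 42 * (3 * 1.5^2 + 3 * 1.5^2))
  expect_equal(res$p.value, 2 / 20)
  expect_equal(res$approximation, "exact-permutation")
  ## identical samples are maximally unsurprising
  flat <- kruskalWallis(list(c(5, 5), c(5, 5), c(5, 5)))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p.value, 1)
})

test_that("Kruskal-Wallis asymptotic path reproduces stats::kruskal.test", {
  set.seed(51)
  for (r in 1:5) {
    groups <- lapply(c(8, 12, 10), function(n)
      round(stats::rnorm(n, mean = r / 2), 1))  # induces ties
    res <- kruskalWallis(groups)
    ref <- stats::kruskal.test(unlist(groups),
                               rep(seq_along(groups), lengths(groups)))
    expect_equal(res$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(res$p.value, ref$p.value, tolerance = 1e-12)
    expect_equal(res$df, 2)
  }
})

test_that("exact Kruskal-Wallis agrees with the brute-force permutation oracle", {
  groups <- list(c(1.2, 3.4, 3.4), c(2.2, 5.1), c(0.4, 3.4))
  res <- kruskalWallis(groups)
  ## independent re-derivation of the tie-corrected statistic for the oracle
  statFun <- function(g) {
    x <- unlist(g); r <- rank(x); N <- length(x)
    H <- 12 / (N * (N + 1)) *
      sum(vapply(split(r, rep(seq_along(g), lengths(g))),
                 function(ri) length(ri) * (mean(ri) - (N + 1) / 2)^2, 0))
    ties <- table(x)
    H / (1 - sum(ties^3 - ties) / (N^3 - N))
  }
  pBrute <- bruteForcePermP(groups, statFun, statFun(groups), "ge")
  expect_equal(res$p.value, pBrute, tolerance = 1e-12)
})

test_that("Jonckheere-Terpstra nails the textbook perfect-trend example", {
  groups <- list(c(1, 2), c(3, 4), c(5, 6))
  res <- jonckheereTerpstra(groups, alternative = "increasing")
  expect_equal(res$statistic, 12)  # every ordered pair concordant
  expect_equal(res$p.value, 1 / 90)  # 6!/(2!2!2!) = 90 distinct assignments
  expect_equal(res$approximation, "exact-permutation")
  ## ties count one half
  expect_equal(jonckheereTerpstra(list(c(1, 1), c(1, 1)))$statistic, 2)
  ## all-tied data: the trend test has no evidence at all
  expect_equal(jonckheereTerpstra(list(c(2, 2), c(2, 2), c(2, 2)))$p.value, 1)
})

test_that("exact Jonckheere-Terpstra agrees with the brute-force oracle", {
  statFun <- function(g) {
    jt <- 0
    for (a in seq_len(length(g) - 1)) for (b in (a + 1):length(g)) {
      for (xa in g[[a]]) jt <- jt + sum(g[[b]] > xa) + 0.5 * sum(g[[b]] == xa)
    }
    jt
  }
  groups <- list(c(0.5, 2.5, 2.5), c(1.5, 4.0), c(2.5, 6.0, 0.1))
  obs <- statFun(groups)
  res <- jonckheereTerpstra(groups, alternative = "increasing")
  expect_equal(res$statistic, obs)
  expect_equal(res$p.value, bruteForcePermP(groups, statFun, obs, "ge"),
               tolerance = 1e-12)
  resDec <- jonckheereTerpstra(groups, alternative = "decreasing")
  expect_equal(resDec$p.value, bruteForcePermP(groups, statFun, obs, "le"),
               tolerance = 1e-12)
})

test_that("one-sided asymptotic JT p values complement exactly under reversal", {
  set.seed(52)
  groups <- lapply(1:4, function(k) stats::rnorm(12, mean = 0.8 * k))
  up <- jonckheereTerpstra(groups, alternative = "increasing")
  expect_equal(up$approximation, "normal")
  down <- jonckheereTerpstra(rev(groups), alternative = "increasing")
  expect_equal(up$p.value + down$p.value, 1, tolerance = 1e-12)
  ## a strong planted trend is detected
  expect_lt(up$p.value, 0.01)
  ## group order is semantic: shuffling it changes the statistic
  shuffled <- jonckheereTerpstra(groups[c(2, 4, 1, 3)],
                                 alternative = "increasing")
  expect_false(isTRUE(all.equal(shuffled$statistic, up$statistic)))
})

test_that("asymptotic JT rejection rate is calibrated under the null", {
  set.seed(53)
  reps <- 2000
  rej <- logical(reps)
  for (r in seq_len(reps)) {
    g <- lapply(1:3, function(i) stats::rnorm(12))
    rej[r] <- jonckheereTerpstra(g)$p.value < 0.05
  }
  ## +/- 3 sigma band around 0.05 at 2000 replicates
  expect_gte(mean(rej), 0.035)
  expect_lte(mean(rej), 0.065)
})

test_that("the higher-p rule is conservative, symmetric-aware, and transparent", {
  a <- sepsisPhenoscope:::.testResult("A", 1, 0.03, NULL, "exact")
  b <- sepsisPhenoscope:::.testResult("B", 2, 0.20, NULL, "normal")
  out <- higherP(a, b)
  expect_equal(out$p.value, 0.20)
  expect_equal(out$statistic, 2)
  expect_false(out$tie)
  expect_equal(out$components$a$p.value, 0.03)
  tied <- higherP(a, sepsisPhenoscope:::.testResult("B", 9, 0.03, NULL, "x"))
  expect_true(tied$tie)
  expect_equal(tied$statistic, 1)  # ties resolve to the first argument
})

test_that("Kaplan-Meier estimator matches the hand calculation and survival::survfit", {
  d <- data.frame(time = c(5, 10, 12, 28), event = c(1, 1, 0, 0), group = "a")
  km <- kmEstimate(d)
  expect_equal(km$time, c(5, 10))
  expect_equal(km$survival, c(3 / 4, 3 / 4 * 2 / 3))
  expect_equal(kmSurvivalAt(km, c(0, 5, 11, 28)), c(1, 0.75, 0.5, 0.5))

  set.seed(54)
  n <- 300
  d2 <- data.frame(time = round(stats::rexp(n, 0.05), 1),
                   event = stats::rbinom(n, 1, 0.7), group = "all")
  d2$time <- pmin(d2$time, 28)
  km2 <- kmEstimate(d2)
  sf <- survival::survfit(survival::Surv(time, event) ~ 1, data = d2)
  evTimes <- sf$time[sf$n.event > 0]
  expect_equal(km2$time, evTimes)
  expect_equal(km2$survival, sf$surv[sf$n.event > 0], tolerance = 1e-12)
  ## no events: flat curve
  flat <- kmEstimate(data.frame(time = c(3, 9), event = c(0, 0), group = "a"))
  expect_equal(nrow(flat), 0)
  expect_equal(kmSurvivalAt(flat, 20), 1)
})

test_that("log-rank statistic matches a hand-worked two-group example", {
  ## group a: deaths at 1 and 3; group b: death at 2, censored at 4
  d <- data.frame(time = c(1, 3, 2, 4), event = c(1, 1, 1, 0),
                  group = rep(c("a", "b"), each = 2))
  ## t=1: O_a=1, E_a=2/4, V=(2*2*1*3)/(16*3)=1/4
  ## t=2: O_a=0, E_a=1/3, V=(1*2*1*2)/(9*2)=2/9
  ## t=3: O_a=1, E_a=1/2, V=(1*1*1*1)/(4*1)=1/4
  U <- (1 - 2 / 4) + (0 - 1 / 3) + (1 - 1 / 2)
  V <- 1 / 4 + 2 / 9 + 1 / 4
  res <- logrankMantel(d)
  expect_equal(res$statistic, U^2 / V, tolerance = 1e-12)
  expect_equal(res$df, 1)
  expect_equal(res$p.value, stats::pchisq(U^2 / V, 1, lower.tail = FALSE))
})

test_that("log-rank agrees with survival::survdiff across k groups", {
  set.seed(55)
  for (k in 2:4) {
    n <- 60 * k
    g <- rep(letters[1:k], each = 60)
    rate <- 0.03 * (1 + 0.5 * (seq_len(k) - 1))
    d <- data.frame(time = pmin(round(stats::rexp(n, rate[match(g, letters)]), 2), 28),
                    event = 1L, group = g)
    d$event[d$time >= 28] <- 0L
    res <- logrankMantel(d)
    ref <- survival::survdiff(survival::Surv(time, event) ~ group, data = d,
                              rho = 0)
    expect_equal(res$statistic, unname(ref$chisq), tolerance = 1e-8)
    expect_equal(res$df, k - 1)
  }
})

test_that("identical survival in both groups yields a null log-rank test", {
  base <- data.frame(time = c(2, 5, 9, 14, 28), event = c(1, 1, 0, 1, 0))
  d <- rbind(cbind(base, group = "a"), cbind(base, group = "b"))
  res <- logrankMantel(d)
  expect_equal(res$statistic, 0, tolerance = 1e-12)
  expect_equal(res$p.value, 1)
  gbw <- gehanBreslowWilcoxon(d)
  expect_equal(gbw$statistic, 0, tolerance = 1e-12)
  ## no events at all is undefined, not silently zero
  none <- data.frame(time = c(5, 6, 7, 8), event = 0,
                     group = c("a", "a", "b", "b"))
  expect_error(logrankMantel(none), "no events")
})

test_that("with a single event time Gehan weighting cannot change the statistic", {
  d <- data.frame(time = c(3, 3, 7, 9, 3, 12), event = c(1, 1, 0, 0, 1, 0),
                  group = c("a", "a", "a", "b", "b", "b"))
  expect_equal(gehanBreslowWilcoxon(d)$statistic,
               logrankMantel(d)$statistic, tolerance = 1e-12)
})

test_that("Gehan-Breslow-Wilcoxon emphasizes early deaths; higher-p arbitrates", {
  ## crossing hazards: many early deaths in a, late deaths in b
  set.seed(56)
  ta <- c(stats::rexp(80, 0.30), stats::rexp(40, 0.005))
  tb <- stats::rexp(120, 0.045)
  d <- data.frame(time = pmin(c(ta, tb), 28),
                  event = as.integer(c(ta, tb) < 28),
                  group = rep(c("a", "b"), each = 120))
  gbw <- gehanBreslowWilcoxon(d)
  lr <- logrankMantel(d)
  ## early-difference design: the early-weighted test is more sensitive
  expect_lt(gbw$p.value, lr$p.value)
  dual <- survivalHigherP(d)
  expect_equal(dual$p.value, max(gbw$p.value, lr$p.value))
  expect_match(dual$method, "higher-p")
})
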