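test_that("fisher_exact enumerates 2 x m tables exactly", {
  # the study's gender-by-group table
  p <- fisher_exact(rbind(c(3, 3, 2), c(3, 2, 3)))$p
  expect_equal(p, 1, tolerance = 1e-9)

  # diagonal 2 x 2: p = 2 / C(10, 5)
  expect_equal(fisher_exact(rbind(c(5, 0), c(0, 5)))$p, 2 / 252,
               tolerance = 1e-12)

  expect_equal(fisher_exact(rbind(c(0, 0), c(3, 4)))$p, 1)

  expect_error(fisher_exact(rbind(c(-1, 2), c(3, 4))), "non-negative")
  expect_error(fisher_exact(rbind(c(1.5, 2), c(3, 4))), "integer")
})

test_that("fisher_exact matches stats::fisher.test on random tables", {
  set.seed(51)
  for (r in 1:25) {
    m <- sample(2:3, 1)
    tab <- matrix(rpois(2 * m, 2), 2, m)
    if (sum(tab) == 0 || sum(tab) > 20) next
    ours <- fisher_exact(tab)$p
    ref <- stats::fisher.test(tab)$p.value
    # fisher.test uses a relative (1 + 1e-7) tie slack; allow tiny drift
    expect_equal(ours, ref, tolerance = 1e-6)
  }
})

test_that("kruskal_wallis computes the tie-corrected H", {
  r0 <- kruskal_wallis(list(c(1, 2), c(1, 2), c(1, 2)))
  expect_equal(r0$statistic, 0, tolerance = 1e-12)
  expect_equal(r0$p, 1)

  # hand formula on ranks 1..6
  g <- list(c(1, 2), c(3, 4), c(5, 6))
  H_hand <- 12 / (6 * 7) * (3^2 / 2 + 7^2 / 2 + 11^2 / 2) - 3 * 7
  r1 <- kruskal_wallis(g)
  expect_equal(r1$statistic, H_hand, tolerance = 1e-12)
  expect_equal(r1$df, 2)

  # rank invariance under strictly monotone transforms
  r2 <- kruskal_wallis(lapply(g, function(x) exp(3 * x)))
  expect_equal(r2$statistic, r1$statistic, tolerance = 1e-12)

  # against the base oracle, with ties
  set.seed(52)
  for (i in 1:10) {
    gs <- lapply(1:3, function(j) sample(1:5, sample(3:6, 1), replace = TRUE))
    ref <- stats::kruskal.test(gs)
    ours <- kruskal_wallis(gs)
    expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(ours$p, ref$p.value, tolerance = 1e-10)
  }
  expect_error(kruskal_wallis(list(1:3, numeric())), "empty")
})

test_that("wilcoxon_ranksum is exact for small untied samples", {
  r <- wilcoxon_ranksum(c(1, 2), c(3, 4))
  expect_equal(r$p, 2 / 6, tolerance = 1e-12)

  expect_equal(wilcoxon_ranksum(c(1, 2, 3), c(1, 2, 3))$p, 1)

  # enumeration equivalence against the base exact test, n <= 12, no ties
  set.seed(53)
  for (i in 1:20) {
    nx <- sample(2:6, 1); ny <- sample(2:6, 1)
    v <- sample(1000, nx + ny)          # distinct values
    x <- v[1:nx]; y <- v[-(1:nx)]
    ref <- stats::wilcox.test(x, y, exact = TRUE)$p.value
    expect_equal(wilcoxon_ranksum(x, y)$p, ref, tolerance = 1e-12)
  }

  # exact and approximate branches agree reasonably at n = 12
  set.seed(54)
  diffs <- replicate(30, {
    x <- rnorm(6); y <- rnorm(6, 0.5)
    exact <- wilcoxon_ranksum(x, y)$p
    approx <- {
      n <- 12; W <- sum(rank(c(x, y))[1:6]); mu <- 6 * 13 / 2
      sig2 <- 36 * 13 / 12
      2 * pnorm(-abs((W - mu - sign(W - mu) * 0.5) / sqrt(sig2)))
    }
    abs(exact - min(1, approx))
  })
  expect_lt(max(diffs), 0.02)
  expect_error(wilcoxon_ranksum(numeric(), 1:3), "empty")
})

test_that("ancova_group_test matches the linear-model oracle", {
  set.seed(55)
  n <- 16
  group <- rep(c("a", "b", "c"), c(6, 5, 5))
  age <- rnorm(n, 50, 10)
  gender <- sample(c("f", "m"), n, replace = TRUE)
  y <- rnorm(n) + 0.5 * (group == "b") + 0.02 * age

  ours <- ancova_group_test(y, group, age, gender)
  gnum <- as.numeric(factor(gender)) - 1
  full <- stats::lm(y ~ age + gnum + factor(group))
  red <- stats::lm(y ~ age + gnum)
  ref <- stats::anova(red, full)
  expect_equal(ours$statistic, ref$F[2], tolerance = 1e-10)
  expect_equal(ours$p, ref$`Pr(>F)`[2], tolerance = 1e-10)
  expect_equal(ours$df, c(2, 11))

  # identical response: F = 0, p = 1
  r0 <- ancova_group_test(rep(3, n), group, age, gender)
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p, 1)

  # orthogonal covariates with no effect: F equals the same full-vs-
  # reduced comparison computed from one-way fits
  age0 <- rep(c(-1, 0, 1), length.out = n)
  y2 <- rnorm(n) + (group == "c")
  ref2 <- stats::anova(stats::lm(y2 ~ age0 + gnum),
                       stats::lm(y2 ~ age0 + gnum + factor(group)))
  expect_equal(ancova_group_test(y2, group, age0, gnum)$statistic,
               ref2$F[2], tolerance = 1e-6)

  # group confounded with gender: named collinearity error
  expect_error(ancova_group_test(y[1:11], rep(c("a", "b"), c(6, 5)),
                                 age[1:11], rep(c(0, 1), c(6, 5))),
               "rank-deficient")
})

test_that("log_transform and cohens_d follow their definitions", {
  expect_equal(log_transform(1), 0)
  expect_equal(log_transform(exp(1)), 1)
  set.seed(56)
  v <- runif(20, 0.1, 5)
  expect_equal(log_transform(v), vapply(v, log, 0))
  expect_error(log_transform(c(1, 0)), "positive")

  x <- c(1, 2, 3); y <- c(2, 3, 4)
  expect_equal(cohens_d(x, x + 0), 0)
  expect_equal(cohens_d(x, y), -cohens_d(y, x))
  # one pooled SD apart -> d = 1
  expect_equal(cohens_d(c(1, 2, 3) + 1, c(1, 2, 3)), 1)

  # moments reconstructed from the printed group statistics: the pooled
  # formula gives ~0.958 (not the printed 0.940, which used unrounded data)
  mk <- function(n, m, s) m + s * scale(seq_len(n))[, 1]
  d <- cohens_d(mk(6, 3.36, 0.16), mk(5, 2.88, 0.73))
  expect_equal(d, 0.48 / sqrt((5 * 0.16^2 + 4 * 0.73^2) / 9),
               tolerance = 1e-9)
  expect_equal(d, 0.958, tolerance = 1e-3)

  expect_error(cohens_d(c(1, 1), c(1, 1)), "zero pooled SD")
  expect_error(cohens_d(1, c(1, 2)), ">= 2")
})

test_that("stratified_summary is descriptive only", {
  tab <- simulate_cohort(cohort_spec(seed = 57))
  strata <- ifelse(tab$group != "patient", tab$group,
                   ifelse(tab$disease_duration_years < 1, "patient_early",
                          "patient_late"))
  sm <- stratified_summary(tab, strata, features = c("duration_D",
                                                     "occurrence_D"))
  expect_equal(nrow(sm), 4)
  expect_equal(sort(sm$n), c(2, 3, 5, 6))
  # no test-statistic columns
  expect_false(any(grepl("p$|statistic|F", names(sm))))

  # weighted pooled mean identity
  pooled <- sum(sm$duration_D_mean * sm$n) / sum(sm$n)
  expect_equal(pooled, mean(tab$duration_D), tolerance = 1e-12)

  one <- stratified_summary(tab[1, ], "control", features = "duration_D")
  expect_true(is.na(one$duration_D_sd))
  expect_equal(one$duration_D_mean, tab$duration_D[1])

  expect_error(stratified_summary(tab, strata[-1]), "every row")
})
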