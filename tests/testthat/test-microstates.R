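test_that("gfp is the spatial standard deviation of the topography", {
  m <- toy_montage(2)
  e <- epoched_recording(list(matrix(c(1, -1), 2, 1)), 1, m, 1)
  expect_equal(gfp(e)$values, 1)

  e0 <- epoched_recording(list(matrix(0, 2, 3)), 1, m, 3)
  expect_equal(gfp(e0)$values, c(0, 0, 0))

  set.seed(21)
  v <- rnorm(18)
  e1 <- epoched_recording(list(matrix(v - mean(v), 18, 1)), 1,
                          study_montage(), 1)
  # independent population-SD oracle
  sd_pop <- sqrt(sum((v - mean(v))^2) / 18)
  expect_equal(gfp(e1)$values, sd_pop, tolerance = 1e-12)

  # non-referenced input warns and re-references
  e2 <- epoched_recording(list(matrix(v + 5, 18, 1)), 1, study_montage(), 1)
  expect_warning(g2 <- gfp(e2), "not average-referenced")
  expect_equal(g2$values, sd_pop, tolerance = 1e-12)
})

test_that("find_gfp_peaks keeps separated strict local maxima", {
  mk_gfp <- function(v, fs = 200) {
    structure(list(values = v, epoch_index = rep(1L, length(v)),
                   sample_index = seq_along(v), fs = fs), class = "ms_gfp")
  }
  bump <- exp(-(seq(-3, 3, length.out = 50))^2)
  expect_equal(find_gfp_peaks(mk_gfp(bump)), which.max(bump))

  ramp <- seq_len(50) / 50
  expect_length(find_gfp_peaks(mk_gfp(ramp)), 0)

  # two peaks 1 sample apart at fs = 200 (min distance 2 samples)
  # two peaks 2 samples apart, separation below 15 ms: larger retained
  v <- c(0, 1, 0.5, 0.9, 0)
  expect_equal(find_gfp_peaks(mk_gfp(v), 15), 2)
  expect_setequal(find_gfp_peaks(mk_gfp(v), 10), c(2, 4))
  # exhaustive-oracle check on random small series
  set.seed(22)
  for (r in 1:20) {
    x <- runif(15)
    got <- find_gfp_peaks(mk_gfp(x), 10)
    # oracle: strict local maxima, then greedy elimination from largest
    cand <- which(diff(sign(diff(x))) == -2) + 1
    cand <- cand[x[cand] > x[cand - 1] & x[cand] > x[cand + 1]]
    keep <- integer()
    for (j in cand[order(x[cand], decreasing = TRUE)]) {
      if (all(abs(keep - j) >= 2)) keep <- c(keep, j)
    }
    expect_setequal(got, keep)
  }
})

test_that("select_peak_maps caps chronologically and drops GFP outliers", {
  set.seed(23)
  mont <- study_montage()
  n <- 3000
  U <- matrix(rnorm(18 * n), 18)
  e <- epoched_recording(list(U), 1000, mont, n / 1000)
  e <- average_reference(e)
  all_peaks <- seq_len(n)
  got <- select_peak_maps(e, all_peaks, n_max = 2500, sd_mult = 2)
  # only the 2500 earliest considered, minus mean+2SD outliers
  expect_lte(nrow(got), 2500)
  flat <- t(e$epochs[[1]][, 1:2500])
  flat <- flat - rowMeans(flat)
  gf <- sqrt(rowMeans(flat^2))
  expect_equal(nrow(got), sum(gf <= mean(gf) + 2 * sd(gf)))

  # a 10x-GFP outlier among equals is excluded
  base <- random_topographies(1, 18)
  U2 <- rbind(base[rep(1, 100), ] * rep(runif(100, 0.9, 1.1), each = 1),
              10 * base)
  e2 <- epoched_recording(list(t(U2)), 101, mont, 1)
  got2 <- select_peak_maps(average_reference(e2), seq_len(101))
  expect_equal(nrow(got2), 100)
  expect_error(select_peak_maps(e2, integer()), "no peaks")
})

test_that("modified_kmeans recovers planted polarity-invariant structure", {
  set.seed(24)
  C <- 8
  m1 <- rnorm(C); m1 <- m1 - mean(m1); m1 <- m1 / sqrt(sum(m1^2))
  m2 <- rnorm(C); m2 <- m2 - mean(m2)
  m2 <- m2 - sum(m2 * m1) * m1           # orthogonalize
  m2 <- m2 / sqrt(sum(m2^2))
  U <- rbind(m1, -m1, m2, -m2)
  res <- modified_kmeans(U, K = 2, restarts = 10, seed = 1)
  expect_equal(res$gev, 100, tolerance = 1e-9)
  cors <- abs(res$maps$maps %*% cbind(m1, m2))
  expect_equal(unname(sort(apply(cors, 1, max))), c(1, 1), tolerance = 1e-9)

  # single cluster identity
  U1 <- rbind(m1, -m1, m1 * 2)
  r1 <- modified_kmeans(U1, K = 1, restarts = 3, seed = 2)
  expect_equal(r1$gev, 100, tolerance = 1e-9)
  expect_equal(abs(sum(r1$maps$maps[1, ] * m1)), 1, tolerance = 1e-9)

  # determinism
  set.seed(25)
  U3 <- random_topographies(40, 6)
  a <- modified_kmeans(U3, K = 3, restarts = 5, seed = 7)
  b <- modified_kmeans(U3, K = 3, restarts = 5, seed = 7)
  expect_identical(a$maps$maps, b$maps$maps)
  expect_identical(a$gev, b$gev)

  expect_error(modified_kmeans(U1, K = 5), "exceeds")
})

test_that("group_maps pools subjects correctly", {
  set.seed(26)
  U <- random_topographies(30, 6)
  one <- group_maps(list(U), K = 2, restarts = 5, seed = 3)
  solo <- modified_kmeans(U, K = 2, restarts = 5, seed = 3)
  expect_equal(one$maps$maps, solo$maps$maps)
  expect_equal(one$n_pooled, 30)

  # duplicating a subject leaves the optimal GEV unchanged
  two <- group_maps(list(U, U), K = 2, restarts = 5, seed = 3)
  expect_equal(two$gev, solo$gev, tolerance = 1e-9)
  expect_equal(two$n_pooled, 60)

  expect_error(group_maps(list(U, U[, 1:5])), "mismatch")
})

test_that("order_maps finds the archetype permutation and signs", {
  tm <- template_maps()
  expect_equal(order_maps(tm, tm)$maps, tm$maps)

  flipped <- microstate_maps(tm$maps * c(1, -1, -1, 1))
  of <- order_maps(flipped, tm)
  expect_equal(of$maps, tm$maps, tolerance = 1e-12)

  perm <- microstate_maps(tm$maps[4:1, ], c("w", "x", "y", "z"))
  op <- order_maps(perm, tm)
  expect_equal(op$labels_order, c("A", "B", "C", "D"))
  expect_equal(op$maps, tm$maps, ignore_attr = TRUE, tolerance = 1e-12)

  # exhaustive 4! oracle on random maps
  set.seed(27)
  est <- microstate_maps(random_topographies(4, 18))
  got <- order_maps(est, tm)
  Cmat <- tm$maps %*% t(est$maps)
  perms <- eegmicrostates:::permutations(4)
  scores <- apply(perms, 1, function(p) sum(abs(Cmat[cbind(1:4, p)])))
  expect_equal(sum(attr(got, "template_corr")), max(scores),
               tolerance = 1e-12)

  expect_error(order_maps(microstate_maps(random_topographies(3, 18)), tm),
               "K mismatch")
})

test_that("modified_kmeans matches the exhaustive oracle on tiny instances", {
  set.seed(28)
  for (i in 1:8) {
    n <- sample(6:9, 1)
    K <- sample(2:3, 1)
    U <- random_topographies(n, 3)
    expect_equal(modified_kmeans(U, K = K, restarts = 200, seed = i)$gev,
                 exhaustive_best_gev(U, K), tolerance = 1e-9)
  }
})
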