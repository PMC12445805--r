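test_that("Benjamini-Hochberg matches the hand-worked step-up and p.adjust", {
  expect_equal(benjamini_hochberg(0.03), 0.03)
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04)),
               rep(0.04, 4))
  expect_equal(benjamini_hochberg(rep(0.2, 5)), rep(0.2, 5))
  set.seed(2)
  p <- runif(25)
  adj <- benjamini_hochberg(p)
  expect_true(all(adj >= p))
  expect_equal(adj, p.adjust(p, "BH"))
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("PERMANOVA pseudo-F equals brute-force SS partition and vegan", {
  # 6-point fixture, 2 groups of 3
  set.seed(14)
  m <- simplex_matrix(6, 4, seed = 14)
  g <- rep(c("x", "y"), each = 3)
  d <- bray_curtis_matrix(profiles_long(m))
  fit <- permanova(d, g, nperm = 99, seed = 1)
  # brute force straight from the definitions
  d2 <- d^2
  n <- 6
  ss_tot <- sum(d2[upper.tri(d2)]) / n
  ss_w <- sum(d2[1:3, 1:3][upper.tri(d2[1:3, 1:3])]) / 3 +
    sum(d2[4:6, 4:6][upper.tri(d2[4:6, 4:6])]) / 3
  f_manual <- ((ss_tot - ss_w) / 1) / (ss_w / 4)
  expect_equal(fit$statistic, f_manual)
  expect_equal(fit$r_squared, (ss_tot - ss_w) / ss_tot)
  skip_if_not_installed("vegan")
  va <- suppressMessages(vegan::adonis2(as.dist(d) ~ g, permutations = 99))
  expect_equal(fit$statistic, va$F[1], tolerance = 1e-10)
  expect_equal(fit$r_squared, va$R2[1], tolerance = 1e-10)
})

test_that("fully separated clusters reach the minimal permutation p", {
  # 8 + 8 points with disjoint sterol support: only the 2 / C(16,8)
  # relabelings reproducing the partition can tie the observed F
  m <- rbind(matrix(c(1, 0), 8, 2, byrow = TRUE),
             matrix(c(0, 1), 8, 2, byrow = TRUE))
  dimnames(m) <- list(paste0("s", 1:16), c("a", "b"))
  d <- bray_curtis_matrix(profiles_long(m))
  fit <- permanova(d, rep(c("x", "y"), each = 8), nperm = 199, seed = 3)
  expect_equal(fit$p_value, 1 / 200)
})

test_that("PERMANOVA type-I error is nominal on null data", {
  set.seed(7)
  reject <- vapply(1:200, function(i) {
    m <- matrix(abs(rnorm(12 * 3)), 12, 3)
    dimnames(m) <- list(paste0("s", 1:12), c("a", "b", "c"))
    d <- bray_curtis_matrix(profiles_long(m))
    permanova(d, rep(c("x", "y"), each = 6), nperm = 99,
              seed = 1000 + i)$p_value <= 0.05
  }, logical(1))
  # binomial 99.9% band around 0.05 with n = 200
  expect_gt(mean(reject), 0.05 - 0.055)
  expect_lt(mean(reject), 0.05 + 0.06)
})

test_that("pairwise PERMANOVA covers all pairs with BH adjustment", {
  m <- simplex_matrix(9, 4, seed = 20)
  g <- rep(c("x", "y", "z"), each = 3)
  d <- bray_curtis_matrix(profiles_long(m))
  pw <- pairwise_permanova(d, g, nperm = 99, seed = 2)
  expect_equal(nrow(pw), choose(3, 2))
  expect_true(all(pw$p_adjusted >= pw$p_value))
})

test_that("dispersion test separates unequal spreads and matches betadisper distances", {
  set.seed(30)
  tight <- matrix(rnorm(12 * 2, sd = 0.02), 12, 2) +
    matrix(c(0.5, 0.5), 12, 2, byrow = TRUE)
  wide <- matrix(rnorm(12 * 2, sd = 0.25), 12, 2) +
    matrix(c(0.5, 0.5), 12, 2, byrow = TRUE)
  x <- abs(rbind(tight, wide))
  rownames(x) <- paste0("s", 1:24)
  colnames(x) <- c("a", "b")
  d <- bray_curtis_matrix(profiles_long(x))
  g <- rep(c("t", "w"), each = 12)
  fit <- dispersion_test(d, g, nperm = 199, seed = 4)
  expect_lt(fit$p_value, 0.05)
  expect_true(all(fit$distances >= 0))
  skip_if_not_installed("vegan")
  bd <- suppressWarnings(vegan::betadisper(as.dist(d), g, type = "centroid"))
  expect_equal(unname(fit$distances), unname(bd$distances),
               tolerance = 1e-8)
  # equal-spread groups: mirror-image configurations keep p comfortably high
  y <- rbind(tight, tight * -1 + 1)
  rownames(y) <- paste0("s", 1:24)
  colnames(y) <- c("a", "b")
  d2 <- bray_curtis_matrix(profiles_long(abs(y)))
  fit2 <- dispersion_test(d2, g, nperm = 199, seed = 5)
  expect_gt(fit2$p_value, 0.05)
})

test_that("NMDS embeds exactly embeddable configurations", {
  # equilateral triangle
  d3 <- matrix(1, 3, 3) - diag(3)
  expect_lt(nmds(d3, k = 2, max_tries = 5, seed = 1)$stress, 1e-6)
  # Euclidean distances of 2-D points re-embed with ~zero stress
  set.seed(8)
  x <- matrix(rnorm(16), 8, 2)
  d <- as.matrix(dist(x))
  fit <- nmds(d, k = 2, max_tries = 10, seed = 2)
  expect_lt(fit$stress, 1e-4)
  expect_equal(colMeans(fit$coordinates), c(NMDS1 = 0, NMDS2 = 0),
               tolerance = 1e-8)
  # identical points are degenerate
  expect_error(nmds(matrix(0, 4, 4), k = 2), "identical")
})

test_that("NMDS stress decreases with dimensions and ignores rescaling", {
  set.seed(9)
  m <- simplex_matrix(7, 5, seed = 9)
  d <- bray_curtis_matrix(profiles_long(m))
  s2 <- nmds(d, k = 2, max_tries = 10, seed = 3)$stress
  s6 <- nmds(d, k = 6, max_tries = 10, seed = 3)$stress
  expect_lte(s6, s2 + 1e-8)
  # stress is scale-free in the dissimilarities
  s2b <- nmds(d * 3, k = 2, max_tries = 10, seed = 3)$stress
  expect_equal(s2, s2b, tolerance = 1e-6)
  # seed reproducibility
  expect_equal(nmds(d, k = 2, max_tries = 5, seed = 11)$coordinates,
               nmds(d, k = 2, max_tries = 5, seed = 11)$coordinates)
})

test_that("indicator values match the A x B definitions", {
  x <- rbind(
    s1 = c(only_g1 = 1.0, shared = 0.5),
    s2 = c(only_g1 = 0.8, shared = 0.5),
    s3 = c(only_g1 = 0.0, shared = 0.5),
    s4 = c(only_g1 = 0.0, shared = 0.5),
    s5 = c(only_g1 = 0.0, shared = 0.5),
    s6 = c(only_g1 = 0.0, shared = 0.5)
  )
  g <- rep(c("g1", "g2", "g3"), each = 2)
  res <- indval(x, g, nperm = 99, seed = 5)
  r1 <- res[res$sterol == "only_g1" & res$group == "g1", ]
  expect_equal(r1$A, 1)
  expect_equal(r1$B, 1)
  expect_equal(r1$stat, 1)
  # equal means in equal groups: A = 1/g
  rs <- res[res$sterol == "shared", ]
  expect_equal(rs$A, rep(1 / 3, 3))
  expect_equal(rs$stat, rep(sqrt(1 / 3), 3))
  # sum over groups of A is 1 for every sterol; stat in [0, 1]
  sums <- tapply(res$A, res$sterol, sum)
  expect_equal(as.numeric(sums), rep(1, 2))
  expect_true(all(res$stat >= 0 & res$stat <= 1))

  # 3-group toy matrix equals brute-force evaluation
  set.seed(16)
  xr <- matrix(abs(rnorm(9 * 2)), 9, 2,
               dimnames = list(paste0("s", 1:9), c("u", "v")))
  gr <- rep(c("a", "b", "c"), each = 3)
  rr <- indval(xr, gr, nperm = 99, seed = 6)
  for (s in c("u", "v")) {
    means <- tapply(xr[, s], gr, mean)
    for (gg in c("a", "b", "c")) {
      a <- means[gg] / sum(means)
      b <- mean(xr[gr == gg, s] > 0)
      expect_equal(rr$stat[rr$sterol == s & rr$group == gg],
                   sqrt(unname(a * b)))
    }
  }
  expect_warning(indval(cbind(xr, zero = 0), gr, nperm = 9, seed = 1),
                 "absent")
})

test_that("Kruskal-Wallis + Dunn agree with the rank formulas and kruskal.test", {
  vals <- c(1, 2, 3, 10, 11, 12, 20, 21, 22)
  g <- rep(c("a", "b", "c"), each = 3)
  fit <- kruskal_dunn(vals, g)
  ref <- kruskal.test(vals, factor(g))
  expect_equal(fit$H, unname(ref$statistic))
  expect_equal(fit$df, unname(ref$parameter))
  expect_equal(fit$p_value, ref$p.value)
  # Dunn z for a vs c from mean ranks: (2 - 8) / sqrt((9*10/12)(2/3))
  expect_equal(fit$pairwise$z[fit$pairwise$group1 == "a" &
                                fit$pairwise$group2 == "c"],
               (2 - 8) / sqrt(9 * 10 / 12 * (2 / 3)))
  expect_equal(fit$pairwise$p_adjusted,
               benjamini_hochberg(fit$pairwise$p_value))

  # ties: H still matches the tie-corrected kruskal.test
  vt <- c(1, 1, 2, 2, 3, 3, 4, 4)
  gt <- rep(c("a", "b"), 4)
  expect_equal(kruskal_dunn(vt, gt)$H,
               unname(kruskal.test(vt, factor(gt))$statistic))

  # identical groups
  same <- kruskal_dunn(rep(c(5, 5, 5, 5), 2), rep(c("a", "b"), each = 4))
  expect_equal(same$H, 0)
  expect_equal(same$p_value, 1)
})

test_that("permutation tests are seed-reproducible", {
  m <- simplex_matrix(8, 3, seed = 22)
  d <- bray_curtis_matrix(profiles_long(m))
  g <- rep(c("x", "y"), each = 4)
  expect_equal(permanova(d, g, nperm = 49, seed = 9)$p_value,
               permanova(d, g, nperm = 49, seed = 9)$p_value)
  expect_equal(indval(m, g, nperm = 49, seed = 9)$p_value,
               indval(m, g, nperm = 49, seed = 9)$p_value)
  expect_equal(dispersion_test(d, g, nperm = 49, seed = 9)$p_value,
               dispersion_test(d, g, nperm = 49, seed = 9)$p_value)
})
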