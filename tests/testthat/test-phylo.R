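test_that("pruning applies rename rules and refuses redundant congeners", {
  tr <- toy_tree("((Genus_one:1,Genus_two:1):1,(Other_sp:1,Third_sp:1):1);")
  # no rules, all taxa present
  got <- prune_and_match(tr, c("Genus_one", "Other_sp", "Third_sp"))
  expect_equal(sort(got$tree$tip.label),
               c("Genus_one", "Other_sp", "Third_sp"))
  expect_equal(got$unplaced, character(0))

  # synonym rename keeps the tip under the requested name
  got2 <- prune_and_match(tr, c("Genus_renamed", "Other_sp", "Third_sp"),
                          rename_rules("Genus_one", "Genus_renamed",
                                       "synonym"))
  expect_true("Genus_renamed" %in% got2$tree$tip.label)

  # congener substitution refused when the genus already has a match
  got3 <- prune_and_match(tr, c("Genus_one", "Genus_three", "Other_sp",
                                "Third_sp"),
                          rename_rules("Genus_two", "Genus_three",
                                       "congener"))
  expect_true("Genus_three" %in% got3$unplaced)
  expect_false("Genus_three" %in% got3$tree$tip.label)

  # but applied when the genus is otherwise unrepresented
  tr2 <- toy_tree("((Alpha_a:1,Beta_b:1):1,(Other_sp:1,Third_sp:1):1);")
  got4 <- prune_and_match(tr2, c("Beta_c", "Other_sp", "Third_sp"),
                          rename_rules("Beta_b", "Beta_c", "congener"))
  expect_true("Beta_c" %in% got4$tree$tip.label)

  expect_error(prune_and_match(tr, "Other_sp",
                               rename_rules("NoSuchTip", "X", "synonym")),
               "non-existent")
})

test_that("monophyly check classifies families correctly", {
  tr <- toy_tree("((A:1,B:1):1,(C:1,D:1):1);")
  got <- check_monophyly(tr, c(A = "f1", B = "f1", C = "f2", D = "f2"))
  expect_equal(got$status[got$group == "f1"], "monophyletic")
  got2 <- check_monophyly(toy_tree("((A:1,C:1):1,B:2);"),
                          c(A = "f1", B = "f1", C = "f2"))
  expect_equal(got2$status[got2$group == "f1"], "non-monophyletic")
  expect_equal(got2$status[got2$group == "f2"], "singleton")
  expect_error(check_monophyly(tr, c(A = "f1")), "without a group")
})

test_that("phylogenetic covariance equals brute-force shared path lengths", {
  C <- phylo_vcv(toy_tree())
  expect_equal(C["A", "B"], 1)
  expect_equal(C["A", "A"], 2)
  expect_equal(C["C", "C"], 2)
  expect_equal(C["A", "C"], 0)

  # oracle: shared root-to-MRCA depth from node paths, random trees to 6 tips
  for (n in 4:6) {
    tr <- sim_tree(n, seed = 100 + n)
    C <- phylo_vcv(tr)
    depths <- ape::node.depth.edgelength(tr)
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        expected <- if (i == j) depths[i] else
          depths[ape::getMRCA(tr, c(tr$tip.label[i], tr$tip.label[j]))]
        expect_equal(unname(C[tr$tip.label[i], tr$tip.label[j]]), expected,
                     tolerance = 1e-10)
      }
    }
    expect_equal(C, t(C))
    expect_gte(min(eigen(C, symmetric = TRUE, only.values = TRUE)$values),
               -1e-10)
  }
})

test_that("Blomberg's K is exactly 1 on a star tree and calibrated under BM", {
  st <- star_tree(8)
  set.seed(40)
  for (i in 1:5) {
    z <- setNames(rnorm(8), st$tip.label)
    expect_equal(blomberg_k(st, z, nperm = 0)$K, 1, tolerance = 1e-10)
  }

  tr <- sim_tree(100, seed = 41)
  z <- sim_traits(tr, lambda_true = 1, n_traits = 50, seed = 42)
  ks <- apply(z, 2, function(zz) blomberg_k(tr, zz, nperm = 0)$K)
  expect_equal(mean(ks), 1, tolerance = 0.15)

  # shuffled traits: K collapses and the permutation test is insensitive
  set.seed(43)
  zs <- sample(z[, 1])
  names(zs) <- tr$tip.label
  ksh <- blomberg_k(tr, zs, nperm = 199, seed = 44)
  expect_lt(ksh$K, 0.5)
  expect_gt(ksh$p_value, 0.05)

  expect_error(blomberg_k(tr, setNames(rep(1, 100), tr$tip.label)),
               "constant")
})

test_that("K and the permutation p agree with phytools on one trait", {
  skip_if_not_installed("phytools")
  tr <- sim_tree(40, seed = 50)
  z <- sim_traits(tr, lambda_true = 1, n_traits = 1, seed = 51)[, 1]
  mine <- blomberg_k(tr, z, nperm = 0)
  ref <- unname(phytools::phylosig(tr, z, method = "K"))
  expect_equal(mine$K, as.numeric(ref), tolerance = 1e-8)
})

test_that("Pagel's lambda ML recovers the generating signal", {
  tr <- sim_tree(100, seed = 60)
  z1 <- sim_traits(tr, lambda_true = 1, n_traits = 30, seed = 61)
  l1 <- apply(z1, 2, function(zz) pagel_lambda(tr, zz)$lambda_capped)
  expect_equal(mean(l1), 1, tolerance = 0.1)

  z0 <- sim_traits(tr, lambda_true = 0, n_traits = 30, seed = 62)
  l0 <- apply(z0, 2, function(zz) pagel_lambda(tr, zz)$lambda)
  expect_equal(mean(l0), 0, tolerance = 0.1)

  # at intermediate lambda the single-tree ML mean reflects the tree's own
  # information content, so the bias check averages over trees
  lh <- unlist(lapply(1:3, function(i) {
    tri <- sim_tree(100, seed = 300 + i)
    zi <- sim_traits(tri, lambda_true = 0.5, n_traits = 20, seed = 400 + i)
    apply(zi, 2, function(zz) pagel_lambda(tri, zz)$lambda)
  }))
  expect_lt(abs(mean(lh) - 0.5), 0.1)

  fit <- pagel_lambda(tr, z1[, 1])
  expect_gte(fit$logL, fit$logL0 - 1e-8)
  expect_gte(fit$logL, pagel_lambda(tr, z1[, 1])$logL - 1e-8)
  expect_gte(fit$lambda_max, 1)

  skip_if_not_installed("phytools")
  ref <- phytools::phylosig(tr, z1[, 1], method = "lambda")
  expect_equal(fit$logL, ref$logL, tolerance = 1e-4)
  expect_equal(min(fit$lambda, 1), min(ref$lambda, 1), tolerance = 0.01)
})

test_that("K and lambda are invariant to affine trait transforms", {
  tr <- sim_tree(30, seed = 70)
  z <- sim_traits(tr, lambda_true = 0.7, n_traits = 1, seed = 71)[, 1]
  z2 <- 3.5 * z - 11
  expect_equal(blomberg_k(tr, z, nperm = 0)$K,
               blomberg_k(tr, z2, nperm = 0)$K, tolerance = 1e-10)
  expect_equal(pagel_lambda(tr, z)$lambda, pagel_lambda(tr, z2)$lambda,
               tolerance = 1e-5)
})

test_that("the signal screen filters, always keeps totals, and separates signal", {
  tr <- sim_tree(40, seed = 80)
  n_hi <- 8
  n_lo <- 8
  zh <- sim_traits(tr, lambda_true = 1, n_traits = n_hi, seed = 81)
  zl <- sim_traits(tr, lambda_true = 0, n_traits = n_lo, seed = 82)
  # map traits to (0, 0.5) so they read as proportions; affine, signal kept
  squish <- function(m) (m - min(m)) / (max(m) - min(m)) * 0.5
  prof <- NULL
  mats <- cbind(squish(zh), squish(zl))
  colnames(mats) <- c(paste0("hi", seq_len(n_hi)), paste0("lo", seq_len(n_lo)))
  # plus one sterol that never exceeds 1%
  mats <- cbind(mats, rare = runif(40, 0, 0.005))
  prof <- profiles_long(mats, id = "taxon")
  prof$total_mg_kg <- rep(exp(rnorm(40, 8)), times = ncol(mats))[
    seq_len(nrow(prof))]
  tot <- tibble::tibble(taxon = rownames(mats),
                        total_mg_kg = exp(rnorm(40, 8)))
  prof <- dplyr::select(prof, -total_mg_kg) |>
    dplyr::left_join(tot, by = "taxon")
  res <- signal_screen(prof, tr, nperm = 49, seed = 83)
  expect_false("rare" %in% res$trait)
  expect_true("total_mg_kg" %in% res$trait)
  # AUC of lambda-hat separating high-signal from no-signal traits
  hi <- res$lambda[grepl("^hi", res$trait)]
  lo <- res$lambda[grepl("^lo", res$trait)]
  auc <- mean(outer(hi, lo, ">") + 0.5 * outer(hi, lo, "=="))
  expect_gt(auc, 0.9)
})
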