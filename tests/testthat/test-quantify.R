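cfg <- run_config(n_permutations = 99)

test_that("signal filtering equals the brute-force window predicate", {
  keep1 <- filter_signals(tibble::tibble(sample = "s", mz = 400, rt = 5,
                                         area = 1e6), cfg)
  expect_equal(nrow(keep1), 1L)
  drop1 <- filter_signals(tibble::tibble(sample = "s", mz = 350, rt = 5,
                                         area = 1e6), cfg)
  expect_equal(nrow(drop1), 0L)

  set.seed(21)
  sig <- tibble::tibble(
    sample = "s",
    mz = runif(100, 355, 447),           # straddles both m/z bounds
    rt = runif(100, 2.5, 11.5),
    area = runif(100, 4e5, 6e5)
  )
  got <- filter_signals(sig, cfg)
  manual <- sig[sig$rt >= 3 & sig$rt <= 11 & sig$mz >= 360 & sig$mz <= 442 &
                  sig$area >= 5e5, ]
  expect_equal(got, manual)
})

test_that("annotation assigns level 1 by mass + RT and level 2 by ST code", {
  ref <- read_reference_sterols()
  feats <- tibble::tibble(
    feature_id = c("F1", "F2", "F3", "F4"),
    feature_mz = c(369.3516, sterol_ion_mz(30, 2), sterol_ion_mz(30, 2),
                   sterol_ion_mz(30, 2)),
    feature_rt = c(5.55, 4.1, 5.0, 6.2)
  )
  ann <- annotate_features(feats, ref, cfg)
  expect_equal(ann$level[ann$feature_id == "F1"], 1L)
  expect_equal(ann$sterol[ann$feature_id == "F1"], "cholesterol")
  # three co-eluting-mass isomers lettered in ascending RT order
  lvl2 <- ann[ann$level == 2L, ]
  expect_equal(lvl2$sterol[order(lvl2$rt)],
               c("ST(30:2)A", "ST(30:2)B", "ST(30:2)C"))
  expect_true(all(lvl2$bring_class == "NA"))
})

test_that("a lone level-2 feature carries no disambiguating letter and level 3 is kept", {
  ref <- read_reference_sterols()
  feats <- tibble::tibble(feature_id = c("F1", "F2"),
                          feature_mz = c(sterol_ion_mz(26, 0), 365.0),
                          feature_rt = c(4.0, 4.0))
  ann <- annotate_features(feats, ref, cfg)
  expect_equal(ann$sterol[ann$feature_id == "F1"], "ST(26:0)")
  expect_equal(ann$level[ann$feature_id == "F2"], 3L)
  expect_true(is.na(ann$molar_mass[ann$feature_id == "F2"]))
})

test_that("internal-standard normalization divides by IS and drops it", {
  aligned <- tibble::tibble(
    sample = c("s1", "s1", "s2", "s2"),
    feature_id = c("F1", "FIS", "F1", "FIS"),
    feature_mz = c(369.3516, 376.3955, 369.3516, 376.3955),
    feature_rt = c(5.55, 5.6, 5.55, 5.6),
    area = c(2e6, 1e6, 4e6, 1e6)
  )
  norm <- normalize_to_is(aligned, cfg)
  expect_equal(norm$rel_abundance[norm$sample == "s1"], 2)
  expect_equal(norm$rel_abundance[norm$sample == "s2"], 4)
  expect_false("FIS" %in% norm$feature_id)

  # ratios are invariant to rescaling all areas in a sample
  aligned2 <- dplyr::mutate(aligned, area = area * 7)
  expect_equal(normalize_to_is(aligned2, cfg)$rel_abundance,
               norm$rel_abundance)

  # zero IS invalidates the sample
  aligned$area[2] <- 0
  norm2 <- normalize_to_is(aligned, cfg)
  expect_false("s1" %in% norm2$sample)
  expect_equal(attr(norm2, "invalid_samples"), "s1")
})

test_that("the quantification formula behaves as printed", {
  expect_equal(mg_per_kg(386.65, 0, weight_mg = 10), 0)
  expect_equal(mg_per_kg(386.65, 1, weight_mg = 10), 196.4, tolerance = 0.001)
  # doubling the weight halves mg/kg at fixed signal
  expect_equal(mg_per_kg(400, 2, weight_mg = 20),
               mg_per_kg(400, 2, weight_mg = 10) / 2)
  expect_error(mg_per_kg(400, 1, weight_mg = 0), "weight")
})

test_that("QC filter keeps load-proportional features and drops the rest", {
  loads <- c(QC1 = 1, QC2 = 0.5, QC3 = 0.25)
  qc <- tibble::tibble(
    sample = rep(names(loads), times = 3),
    feature_id = rep(c("prop", "const", "anti"), each = 3),
    rel_abundance = c(1, 0.5, 0.25,     # proportional
                      2, 2, 2,          # constant
                      0.25, 0.5, 1)     # anti-correlated
  )
  res <- qc_filter(c("prop", "const", "anti", "absent"), qc, loads, cfg)
  expect_true(res$kept[res$feature_id == "prop"])
  expect_equal(res$r[res$feature_id == "prop"], 1)
  expect_false(res$kept[res$feature_id == "const"])  # undefined r
  expect_false(res$kept[res$feature_id == "anti"])
  expect_true(res$r[res$feature_id == "anti"] < 0)
  expect_false(res$kept[res$feature_id == "absent"])
})

test_that("blank filter matches a brute-force scan on a 10-feature fixture", {
  set.seed(31)
  ids <- sprintf("F%02d", 1:10)
  samp <- tibble::tibble(sample = rep(c("s1", "s2"), each = 10),
                         feature_id = rep(ids, 2),
                         area = runif(20, 0, 1e6))
  blank <- tibble::tibble(sample = "b1", feature_id = ids[1:6],
                          area = runif(6, 0, 4e5))
  res <- blank_filter(samp, blank, cfg)
  manual <- vapply(ids, function(f) {
    ms <- median(samp$area[samp$feature_id == f])
    mb <- if (f %in% blank$feature_id) blank$area[blank$feature_id == f] else 0
    ms >= 3 * mb
  }, logical(1))
  expect_equal(res$kept, unname(manual))
  # absent from blanks -> always kept
  expect_true(all(res$kept[res$feature_id %in% ids[7:10]]))
  # equal blank and sample signal at factor 3 -> dropped
  eq <- blank_filter(
    tibble::tibble(sample = "s", feature_id = "F", area = 5e5),
    tibble::tibble(sample = "b", feature_id = "F", area = 5e5), cfg)
  expect_false(eq$kept)
})
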