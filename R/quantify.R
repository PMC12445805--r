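# d7-cholesterol internal standard: dehydrated protonated cation C27H38D7+
IS_ION_MZ <- 27 * MASS_C + 38 * MASS_H + 7 * MASS_D - MASS_E
IS_RT <- 5.6

#' Filter raw signals to the sterol acquisition window
#'
#' Keeps signals with retention time, m/z and area inside the configured
#' extraction windows (all bounds inclusive). Defaults: 3-11 min,
#' 360-442 m/z, area >= 5e5 counts.
#'
#' @param signals tibble with `sample`, `mz`, `rt`, `area`.
#' @param config a [run_config()].
#' @return The kept rows.
#' @export
filter_signals <- function(signals, config = run_config()) {
  check_columns(signals, c("sample", "mz", "rt", "area"), "signals")
  filter(signals,
         .data$rt >= config$rt_window[1], .data$rt <= config$rt_window[2],
         .data$mz >= config$mz_window[1], .data$mz <= config$mz_window[2],
         .data$area >= config$area_threshold)
}

#' Align signals across samples into consensus features
#'
#' Greedy one-dimensional clustering: signals are grouped when their m/z
#' agree within the ppm tolerance and their retention times within the RT
#' window (the 0.1 min extraction window is reused for cross-sample
#' alignment). Each cluster becomes one feature identified by the median
#' m/z and retention time of its members.
#'
#' @inheritParams filter_signals
#' @return `signals` with `feature_id`, `feature_mz`, `feature_rt` columns
#'   added; feature ids are ordered by (m/z, rt).
#' @export
align_features <- function(signals, config = run_config()) {
  check_columns(signals, c("sample", "mz", "rt", "area"), "signals")
  if (nrow(signals) == 0L) {
    return(mutate(signals, feature_id = character(),
                  feature_mz = numeric(), feature_rt = numeric()))
  }
  df <- arrange(signals, .data$mz, .data$rt)
  gap <- diff(df$mz) / df$mz[-nrow(df)] * 1e6
  mz_grp <- cumsum(c(1, as.integer(gap > config$ppm_tolerance)))
  df$..grp <- mz_grp
  df <- df |>
    group_by(.data$..grp) |>
    arrange(.data$rt, .by_group = TRUE) |>
    mutate(..sub = cumsum(c(1, as.integer(diff(.data$rt) > config$rt_tolerance)))) |>
    ungroup()
  df <- df |>
    group_by(.data$..grp, .data$..sub) |>
    mutate(feature_mz = median(.data$mz), feature_rt = median(.data$rt)) |>
    ungroup() |>
    arrange(.data$feature_mz, .data$feature_rt)
  key <- paste(df$..grp, df$..sub, sep = "_")
  df$feature_id <- sprintf("F%04d", match(key, unique(key)))
  select(df, -"..grp", -"..sub") |> arrange(.data$feature_id, .data$sample)
}

#' Annotate consensus features at level 1 or level 2
#'
#' Level 1: a feature is assigned a reference compound's name when its m/z
#' matches the reference dehydrated-cation m/z within the ppm tolerance and
#' its retention time matches within the RT tolerance; when several
#' references qualify the nearest retention time wins (a warning is
#' logged). Level 2: the accurate mass is decomposed into a sterol carbon
#' and double-bond count and the feature coded `ST(C:D)`; co-occurring
#' level-2 features sharing (C,D) get suffix letters A, B, C ... in
#' ascending retention-time order. Features whose mass fits no sterol
#' composition are level 3 (mass and retention time only).
#'
#' @param features tibble with `feature_id`, `feature_mz`, `feature_rt`
#'   (one row per feature; e.g. `dplyr::distinct()` of [align_features()]).
#' @param reference a [read_reference_sterols()] table.
#' @param config a [run_config()].
#' @return A tibble: `feature_id`, `mz`, `rt`, `level`, `sterol`,
#'   `carbons`, `double_bonds`, `bring_class`, `molar_mass`.
#' @export
annotate_features <- function(features, reference = read_reference_sterols(),
                              config = run_config()) {
  check_columns(features, c("feature_id", "feature_mz", "feature_rt"),
                "features")
  feats <- dplyr::distinct(features, .data$feature_id,
                           .data$feature_mz, .data$feature_rt)
  ann <- purrr::pmap_dfr(feats, function(feature_id, feature_mz, feature_rt) {
    ppm <- (feature_mz - reference$ion_mz) / reference$ion_mz * 1e6
    drt <- feature_rt - reference$expected_rt
    cand <- which(abs(ppm) <= config$ppm_tolerance &
                    abs(drt) <= config$rt_tolerance)
    if (length(cand) > 0L) {
      if (length(cand) > 1L) {
        warn(sprintf("feature %s matches %d references; using nearest RT (%s)",
                     feature_id, length(cand),
                     reference$name[cand[which.min(abs(drt[cand]))]]))
      }
      i <- cand[which.min(abs(drt[cand]))]
      return(tibble(feature_id = feature_id, mz = feature_mz,
                    rt = feature_rt, level = 1L,
                    sterol = reference$name[i],
                    carbons = reference$carbons[i],
                    double_bonds = reference$double_bonds[i],
                    bring_class = reference$bring_class[i],
                    molar_mass = reference$molar_mass[i]))
    }
    dec <- decompose_mass(feature_mz, config$ppm_tolerance)
    if (is.na(dec$carbons)) {
      return(tibble(feature_id = feature_id, mz = feature_mz,
                    rt = feature_rt, level = 3L, sterol = NA_character_,
                    carbons = NA_integer_, double_bonds = NA_integer_,
                    bring_class = NA_character_, molar_mass = NA_real_))
    }
    tibble(feature_id = feature_id, mz = feature_mz, rt = feature_rt,
           level = 2L, sterol = NA_character_,
           carbons = dec$carbons, double_bonds = dec$double_bonds,
           bring_class = "NA",
           molar_mass = implied_molar_mass(dec$carbons, dec$double_bonds))
  })
  # ST codes with disambiguating letters in ascending RT order
  lvl2 <- ann$level == 2L
  if (any(lvl2)) {
    ann2 <- ann[lvl2, ]
    ann2 <- ann2 |>
      group_by(.data$carbons, .data$double_bonds) |>
      arrange(.data$rt, .by_group = TRUE) |>
      mutate(sterol = if (n() == 1L) {
        sprintf("ST(%d:%d)", .data$carbons, .data$double_bonds)
      } else {
        sprintf("ST(%d:%d)%s", .data$carbons, .data$double_bonds,
                LETTERS[row_number()])
      }) |>
      ungroup()
    ann[lvl2, ] <- ann2[match(ann$feature_id[lvl2], ann2$feature_id), ]
  }
  lvl3 <- ann$level == 3L
  ann$sterol[lvl3] <- sprintf("mz%.4f@%.2f", ann$mz[lvl3], ann$rt[lvl3])
  arrange(ann, .data$feature_id)
}

#' Internal-standard normalization
#'
#' Divides each analyte's signal area by the area of the d7-cholesterol
#' internal standard in the same sample, and drops the IS feature from the
#' analyte set. Samples where the IS is missing or has zero area are
#' excluded with a logged reason.
#'
#' @param aligned output of [align_features()].
#' @param config a [run_config()].
#' @param is_mz,is_rt expected IS ion m/z and retention time.
#' @return A tibble `sample`, `feature_id`, `feature_mz`, `feature_rt`,
#'   `rel_abundance`, `is_area`; attribute `invalid_samples` lists excluded
#'   samples.
#' @export
normalize_to_is <- function(aligned, config = run_config(),
                            is_mz = IS_ION_MZ, is_rt = IS_RT) {
  check_columns(aligned, c("sample", "feature_id", "feature_mz",
                           "feature_rt", "area"), "aligned signals")
  is_ids <- aligned |>
    dplyr::distinct(.data$feature_id, .data$feature_mz, .data$feature_rt) |>
    filter(abs(.data$feature_mz - is_mz) / is_mz * 1e6 <= config$ppm_tolerance,
           abs(.data$feature_rt - is_rt) <= config$rt_tolerance)
  if (nrow(is_ids) == 0L) abort("internal-standard feature not found in any sample")
  is_per_sample <- aligned |>
    filter(.data$feature_id %in% is_ids$feature_id) |>
    group_by(.data$sample) |>
    summarise(is_area = sum(.data$area), .groups = "drop")
  all_samples <- unique(aligned$sample)
  valid <- is_per_sample$sample[is_per_sample$is_area > 0]
  invalid <- setdiff(all_samples, valid)
  if (length(invalid) > 0L) {
    ster_log("excluding sample(s) with missing/zero internal standard: ",
             paste(invalid, collapse = ", "), level = "WARN")
  }
  out <- aligned |>
    filter(!(.data$feature_id %in% is_ids$feature_id),
           .data$sample %in% valid) |>
    inner_join(is_per_sample, by = "sample") |>
    mutate(rel_abundance = .data$area / .data$is_area) |>
    select("sample", "feature_id", "feature_mz", "feature_rt",
           "rel_abundance", "is_area")
  attr(out, "invalid_samples") <- invalid
  out
}

#' Sterol mass per kilogram of fresh pollen
#'
#' The assay's quantification: mg sterol per kg fresh pollen =
#' MW (g/mol) x IS-normalized signal x IS moles x 1e6 / (weight_mg / 1000).
#'
#' @param mw molar mass, g/mol.
#' @param signal IS-normalized signal (analyte area / IS area).
#' @param is_moles internal-standard amount, mol (default 5.08e-9).
#' @param weight_mg fresh pollen weight, mg.
#' @return mg/kg.
#' @export
#' @examples
#' mg_per_kg(386.65, 1, weight_mg = 10)  # 196.4 mg/kg
mg_per_kg <- function(mw, signal, is_moles = 5.08e-9, weight_mg) {
  if (any(weight_mg <= 0)) abort("weight_mg must be > 0")
  mw * signal * is_moles * 1e6 / (weight_mg / 1000)
}

#' Absolute quantification of sample profiles
#'
#' Applies [mg_per_kg()] per analyte and sums to a per-sample total.
#' Level-2 analytes use the molar mass implied by their (carbons,
#' double-bonds) code; analytes without a molar mass (level 3) are kept for
#' proportions but skipped from the mg/kg total with a warning.
#'
#' @param normalized output of [normalize_to_is()].
#' @param annotations output of [annotate_features()].
#' @param metadata tibble with `sample`, `taxon`, `weight_mg`.
#' @param config a [run_config()].
#' @return A long tibble (one row per sample x analyte): `sample`, `taxon`,
#'   `weight_mg`, `sterol`, `level`, `bring_class`, `carbons`,
#'   `rel_abundance`, `proportion`, `mg_kg`, `total_mg_kg`.
#' @export
quantify_profiles <- function(normalized, annotations, metadata,
                              config = run_config()) {
  check_columns(metadata, c("sample", "taxon", "weight_mg"), "metadata")
  if (any(metadata$weight_mg <= 0)) abort("weight_mg must be > 0")
  df <- normalized |>
    inner_join(select(annotations, "feature_id", "sterol", "level",
                      "bring_class", "carbons", "molar_mass"),
               by = "feature_id") |>
    inner_join(select(metadata, "sample", "taxon", "weight_mg"),
               by = "sample")
  if (anyNA(df$molar_mass)) {
    warn(sprintf("%d analyte(s) lack a molar mass; excluded from mg/kg totals",
                 length(unique(df$sterol[is.na(df$molar_mass)]))))
  }
  df |>
    mutate(mg_kg = ifelse(is.na(.data$molar_mass), NA_real_,
                          mg_per_kg(.data$molar_mass, .data$rel_abundance,
                                    config$is_moles, .data$weight_mg))) |>
    group_by(.data$sample) |>
    mutate(proportion = .data$rel_abundance / sum(.data$rel_abundance),
           total_mg_kg = sum(.data$mg_kg, na.rm = TRUE)) |>
    ungroup() |>
    select("sample", "taxon", "weight_mg", "sterol", "level", "bring_class",
           "carbons", "rel_abundance", "proportion", "mg_kg", "total_mg_kg")
}

#' QC dilution-series filter
#'
#' Each feature's IS-normalized signal is correlated (Pearson) with the
#' nominal QC load (1.0 / 0.5 / 0.25); features with r below the threshold
#' are discarded. A feature absent from a QC sample contributes zero
#' signal there; features absent from all QC samples, or constant across
#' them (undefined r), are discarded and logged.
#'
#' @param feature_ids character vector of candidate features.
#' @param qc_normalized [normalize_to_is()] output for the QC samples.
#' @param qc_loads named numeric: nominal relative load per QC sample.
#' @param config a [run_config()] (threshold `qc_threshold`, default 0.75).
#' @return A tibble `feature_id`, `r`, `kept`.
#' @export
qc_filter <- function(feature_ids, qc_normalized, qc_loads,
                      config = run_config()) {
  if (length(unique(qc_loads)) < 2L) abort("need >= 2 distinct QC loads")
  grid <- tidyr::expand_grid(feature_id = unique(feature_ids),
                             sample = names(qc_loads))
  obs <- grid |>
    left_join(select(qc_normalized, "sample", "feature_id", "rel_abundance"),
              by = c("feature_id", "sample")) |>
    mutate(rel_abundance = dplyr::coalesce(.data$rel_abundance, 0),
           load = qc_loads[.data$sample])
  res <- obs |>
    group_by(.data$feature_id) |>
    summarise(r = if (sd(.data$rel_abundance) == 0) NA_real_ else
      cor(.data$load, .data$rel_abundance), .groups = "drop") |>
    mutate(kept = !is.na(.data$r) & .data$r >= config$qc_threshold)
  dropped <- res$feature_id[!res$kept]
  if (length(dropped) > 0L) {
    ster_log("QC filter discarded ", length(dropped), " feature(s)")
  }
  res
}

#' Blank (background) filter
#'
#' A feature is discarded when its median signal area across study samples
#' is below `blank_factor` times its median area across blank runs;
#' features absent from every blank are always kept.
#'
#' @param sample_signals,blank_signals [align_features()]-style tibbles
#'   (need `feature_id`, `sample`, `area`).
#' @param config a [run_config()] (`blank_factor`, default 3).
#' @return A tibble `feature_id`, `median_sample`, `median_blank`, `kept`.
#' @export
blank_filter <- function(sample_signals, blank_signals,
                         config = run_config()) {
  med_by <- function(sig, ids) {
    grid <- tidyr::expand_grid(feature_id = ids,
                               sample = unique(sig$sample))
    grid |>
      left_join(select(sig, "feature_id", "sample", "area"),
                by = c("feature_id", "sample")) |>
      mutate(area = dplyr::coalesce(.data$area, 0)) |>
      group_by(.data$feature_id) |>
      summarise(med = median(.data$area), .groups = "drop")
  }
  if (nrow(blank_signals) == 0L) abort("need at least one blank sample")
  ids <- unique(sample_signals$feature_id)
  ms <- med_by(sample_signals, ids)
  mb <- med_by(blank_signals, ids)
  res <- tibble(feature_id = ids,
                median_sample = dplyr::coalesce(ms$med[match(ids, ms$feature_id)], 0),
                median_blank = dplyr::coalesce(mb$med[match(ids, mb$feature_id)], 0)) |>
    mutate(kept = .data$median_sample >= config$blank_factor * .data$median_blank)
  res
}
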