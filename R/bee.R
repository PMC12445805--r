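BEE_STEROLS <- c("24-methylenecholesterol", "beta-sitosterol",
                 "isofucosterol", "campesterol", "cholesterol",
                 "desmosterol")

#' Honeybee sterol requirements
#'
#' The six sterols reported from prepupal honeybee tissues with the
#' minimum whole-profile proportion a pollen must exceed (strictly) to
#' count as sufficient: 24-methylenecholesterol > 30%, beta-sitosterol
#' > 19%, isofucosterol > 10%, campesterol > 5%, cholesterol > 0.5%,
#' desmosterol > 0.5%. The bundled reference bee mean profile is a
#' synthetic composition consistent with these thresholds (each component
#' above its own threshold); replace it with measured data via
#' `bee_mean`.
#'
#' @param thresholds named fractions; defaults as above.
#' @param bee_mean named simplex vector over the same six sterols.
#' @return A list of class `sterolome_bee_req`: `thresholds`, `bee_mean`.
#' @export
bee_requirements <- function(thresholds = c(
                               "24-methylenecholesterol" = 0.30,
                               "beta-sitosterol" = 0.19,
                               "isofucosterol" = 0.10,
                               "campesterol" = 0.05,
                               "cholesterol" = 0.005,
                               "desmosterol" = 0.005),
                             bee_mean = c(
                               "24-methylenecholesterol" = 0.50,
                               "beta-sitosterol" = 0.25,
                               "isofucosterol" = 0.13,
                               "campesterol" = 0.08,
                               "cholesterol" = 0.02,
                               "desmosterol" = 0.02)) {
  if (!setequal(names(thresholds), BEE_STEROLS)) {
    abort("thresholds must cover exactly the six bee-relevant sterols")
  }
  if (any(thresholds <= 0)) abort("thresholds must be > 0")
  if (!setequal(names(bee_mean), BEE_STEROLS) ||
      abs(sum(bee_mean) - 1) > 1e-9) {
    abort("bee_mean must be a simplex vector over the six sterols")
  }
  structure(list(thresholds = thresholds[BEE_STEROLS],
                 bee_mean = bee_mean[BEE_STEROLS]),
            class = "sterolome_bee_req")
}

#' Subset a pollen profile to the six bee-relevant sterols
#'
#' Extracts the whole-profile proportions of the six sterols without
#' renormalizing (so the subset sums to at most 1); a sterol missing from
#' the profile contributes 0.
#'
#' @param profile named proportions, or a tibble `sterol`, `proportion`.
#' @return Named numeric vector over the six sterols.
#' @export
subset_bee_sterols <- function(profile) {
  if (is.data.frame(profile)) {
    check_columns(profile, c("sterol", "proportion"), "profile")
    profile <- setNames(profile$proportion, profile$sterol)
  }
  out <- setNames(rep(0, length(BEE_STEROLS)), BEE_STEROLS)
  hit <- intersect(names(profile), BEE_STEROLS)
  out[hit] <- profile[hit]
  out
}

#' Score pollen profiles against the honeybee sterol requirements
#'
#' A requirement is met when the sterol's whole-profile proportion is
#' strictly greater than its threshold (profiles are never renormalized
#' to the six-sterol subset). `contains_all_six` records whether all six
#' sterols are present at any level.
#'
#' @param taxon_profiles long tibble (`taxon`, `sterol`, `proportion`),
#'   e.g. [taxon_means()] output.
#' @param req a [bee_requirements()].
#' @return A tibble, one row per taxon: one logical column per sterol
#'   (`met_<sterol>`), `count_met` (0-6), `contains_all_six`.
#' @export
score_requirements <- function(taxon_profiles, req = bee_requirements()) {
  check_columns(taxon_profiles, c("taxon", "sterol", "proportion"),
                "taxon profiles")
  stopifnot(inherits(req, "sterolome_bee_req"))
  taxa <- unique(taxon_profiles$taxon)
  rows <- purrr::map_dfr(taxa, function(tx) {
    p <- subset_bee_sterols(filter(taxon_profiles, .data$taxon == tx))
    met <- p > req$thresholds
    out <- tibble(taxon = tx)
    for (s in BEE_STEROLS) out[[paste0("met_", s)]] <- unname(met[s])
    out$count_met <- sum(met)
    out$contains_all_six <- all(p > 0)
    out
  })
  rows
}

#' Cohort summary of bee-sufficiency scores
#'
#' @param reports [score_requirements()] output.
#' @return A list: `histogram` (tibble `count_met` 0..6, `n_taxa`),
#'   `per_sterol` (tibble `sterol`, `n_passing`), `n_taxa`.
#' @export
cohort_summary <- function(reports) {
  if (nrow(reports) == 0L) abort("need at least one report")
  hist <- tibble(count_met = 0:6) |>
    left_join(dplyr::count(reports, .data$count_met, name = "n_taxa"),
              by = "count_met") |>
    mutate(n_taxa = dplyr::coalesce(.data$n_taxa, 0L))
  per <- purrr::map_dfr(BEE_STEROLS, function(s) {
    tibble(sterol = s, n_passing = sum(reports[[paste0("met_", s)]]))
  })
  list(histogram = hist, per_sterol = per, n_taxa = nrow(reports))
}

#' Combined bee-and-pollen six-sterol dataset
#'
#' Stacks pollen taxon profiles (subset to the six bee-relevant sterols,
#' unrenormalized) with bee sample compositions and labels the rows, ready
#' for ordination and PERMANOVA.
#'
#' @param taxon_profiles long pollen profiles (`taxon`, `sterol`,
#'   `proportion`).
#' @param bee_samples matrix from [sim_bee_samples()] (rows = samples,
#'   columns = the six sterols) or equivalent.
#' @return A list: `x` (rows x six sterols matrix), `labels`
#'   (`"pollen"` / `"bee"` per row).
#' @export
bee_pollen_dataset <- function(taxon_profiles, bee_samples) {
  taxa <- unique(taxon_profiles$taxon)
  pollen <- t(vapply(taxa, function(tx) {
    subset_bee_sterols(filter(taxon_profiles, .data$taxon == tx))
  }, numeric(length(BEE_STEROLS))))
  bee <- as.matrix(bee_samples)[, BEE_STEROLS, drop = FALSE]
  x <- rbind(pollen, bee)
  list(x = x, labels = c(rep("pollen", nrow(pollen)),
                         rep("bee", nrow(bee))))
}
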