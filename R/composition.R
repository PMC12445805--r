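#' Taxon-mean sterol profiles
#'
#' Averages per-sample proportions within each taxon (arithmetic mean,
#' renormalized to sum to one to guard against per-sample rounding drift)
#' and averages the per-sample total sterol content.
#'
#' @param profiles long tibble from [quantify_profiles()] (needs `sample`,
#'   `taxon`, `sterol`, `proportion`; `total_mg_kg` optional).
#' @return A long tibble `taxon`, `sterol`, `proportion`, plus `n_samples`
#'   and `total_mg_kg` (mean over the taxon's samples) per taxon.
#' @export
taxon_means <- function(profiles) {
  check_columns(profiles, c("sample", "taxon", "sterol", "proportion"),
                "profiles")
  has_total <- "total_mg_kg" %in% names(profiles)
  per_taxon <- profiles |>
    dplyr::distinct(.data$taxon, .data$sample,
                    total_mg_kg = if (has_total) .data$total_mg_kg else NA_real_) |>
    group_by(.data$taxon) |>
    summarise(n_samples = dplyr::n_distinct(.data$sample),
              total_mg_kg = mean(.data$total_mg_kg), .groups = "drop")
  # zero-fill so a sterol absent from one sample still dilutes the mean
  wide <- pivot_matrix(profiles, "sample", "sterol", "proportion")
  smap <- dplyr::distinct(profiles, .data$sample, .data$taxon)
  means <- rowsum(wide[smap$sample, , drop = FALSE], group = smap$taxon) /
    as.vector(table(smap$taxon)[sort(unique(smap$taxon))])
  means <- means / rowSums(means)
  tibble(taxon = rep(rownames(means), each = ncol(means)),
         sterol = rep(colnames(means), times = nrow(means)),
         proportion = as.vector(t(means))) |>
    left_join(per_taxon, by = "taxon")
}

#' Arcsine square-root transform
#'
#' Variance-stabilizing transform for proportions: asin(sqrt(p)),
#' monotone from 0 to pi/2 on \[0, 1\].
#'
#' @param p proportions in \[0, 1\].
#' @return transformed values.
#' @export
arcsine_sqrt <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    abort("proportions must lie in [0, 1]")
  }
  asin(sqrt(p))
}

#' Bray-Curtis dissimilarity
#'
#' `bray_curtis()` compares two non-negative abundance vectors:
#' sum|x - y| / sum(x + y). `bray_curtis_matrix()` builds the full
#' symmetric dissimilarity matrix from a long profile table.
#'
#' @param x,y equal-length non-negative vectors, not both all-zero.
#' @return dissimilarity in \[0, 1\].
#' @export
#' @examples
#' bray_curtis(c(0.7, 0.3), c(0.3, 0.7))  # 0.4
bray_curtis <- function(x, y) {
  if (length(x) != length(y)) abort("vectors must have equal length")
  if (any(x < 0) || any(y < 0)) abort("abundances must be non-negative")
  tot <- sum(x + y)
  if (tot == 0) abort("both vectors are all-zero; dissimilarity undefined")
  sum(abs(x - y)) / tot
}

#' @rdname bray_curtis
#' @param profiles long tibble with id, sterol and value columns.
#' @param id,value column names (strings) for the unit and abundance;
#'   defaults suit [quantify_profiles()] output.
#' @param transform optional function applied to the abundance matrix
#'   before distances (e.g. [arcsine_sqrt()]); default identity.
#' @export
bray_curtis_matrix <- function(profiles, id = "sample", value = "proportion",
                               transform = identity) {
  check_columns(profiles, c(id, "sterol", value), "profiles")
  m <- transform(pivot_matrix(profiles, id, "sterol", value))
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      d[i, j] <- d[j, i] <- bray_curtis(m[i, ], m[j, ])
    }
  }
  d
}

#' Compositional outlier screen
#'
#' Flags a sample as an outlier when its minimum Bray-Curtis dissimilarity
#' (on untransformed proportions) to every other sample exceeds the
#' threshold, i.e. it has no compositional neighbour.
#'
#' @param profiles long tibble (`sample`, `sterol`, `proportion`).
#' @param threshold minimum-dissimilarity cutoff, default 0.5.
#' @return A tibble `sample`, `min_dissimilarity`, `outlier`.
#' @export
detect_outliers <- function(profiles, threshold = 0.5) {
  d <- bray_curtis_matrix(profiles)
  if (nrow(d) < 2L) abort("need at least 2 samples")
  diag(d) <- NA
  mins <- apply(d, 1, min, na.rm = TRUE)
  tibble(sample = rownames(d), min_dissimilarity = unname(mins),
         outlier = unname(mins) > threshold)
}

#' Simpson's diversity index
#'
#' 1 - sum(p_i^2) over a compositional profile; 0 for a single-sterol
#' profile, approaching 1 - 1/k for an even profile of k sterols.
#'
#' @param p proportions (renormalized internally if they do not sum to 1).
#' @return diversity in \[0, 1).
#' @export
simpson_index <- function(p) {
  if (any(p < 0)) abort("proportions must be non-negative")
  s <- sum(p)
  if (s == 0) abort("empty profile")
  p <- p / s
  1 - sum(p^2)
}

#' Group sterol proportions by structural class
#'
#' Sums proportions within B-ring double-bond classes (CPR, D0, D5, D7,
#' D8, NA) and within carbon counts. Ergosterol belongs to the NA class
#' (it carries both a 5- and a 7-position double bond) and all level-2
#' sterols are NA; these assignments come in via the `mapping`.
#'
#' @param profiles long tibble (`taxon` or `sample` id, `sterol`, value).
#' @param mapping tibble `sterol`, `bring_class`, `carbons` (e.g. from
#'   [annotate_features()]).
#' @param id,value column names for the unit and abundance.
#' @return A tibble `id`, `class_type` ("bring" or "carbons"), `class`,
#'   `proportion`; within each id and class_type proportions sum to the
#'   profile total.
#' @export
class_proportions <- function(profiles, mapping, id = "taxon",
                              value = "proportion") {
  check_columns(profiles, c(id, "sterol", value), "profiles")
  check_columns(mapping, c("sterol", "bring_class", "carbons"), "mapping")
  unmapped <- setdiff(unique(profiles$sterol), mapping$sterol)
  if (length(unmapped) > 0L) {
    abort(sprintf("sterol(s) missing from class mapping: %s",
                  paste(unmapped, collapse = ", ")))
  }
  df <- left_join(profiles, dplyr::distinct(mapping, .data$sterol,
                                            .data$bring_class, .data$carbons),
                  by = "sterol")
  br <- df |>
    mutate(class = dplyr::coalesce(as.character(.data$bring_class), "NA")) |>
    group_by(.data[[id]], .data$class) |>
    summarise(proportion = sum(.data[[value]]), .groups = "drop") |>
    mutate(class_type = "bring")
  cc <- df |>
    mutate(class = ifelse(is.na(.data$carbons), "NA",
                          as.character(.data$carbons))) |>
    group_by(.data[[id]], .data$class) |>
    summarise(proportion = sum(.data[[value]]), .groups = "drop") |>
    mutate(class_type = "carbons")
  bind_rows(br, cc) |>
    select(all_of(id), "class_type", "class", "proportion") |>
    arrange(.data$class_type, .data[[id]], .data$class)
}

#' Dominant sterols of a profile
#'
#' Ranks sterols by proportion (ties broken alphabetically), reports the
#' top k, the sterol richness (count with proportion > 0), and whether a
#' single sterol reaches the dominance cutoff (default 65%).
#'
#' @param profile named numeric vector of proportions, or a two-column
#'   tibble `sterol`, `proportion`.
#' @param k how many top sterols to report (default 3).
#' @param dominant_cutoff fraction above which a sterol counts as
#'   dominating the profile (default 0.65).
#' @return A list: `top` (tibble `rank`, `sterol`, `proportion`),
#'   `richness`, `dominant` (sterol name or NA).
#' @export
dominance <- function(profile, k = 3, dominant_cutoff = 0.65) {
  if (is.data.frame(profile)) {
    check_columns(profile, c("sterol", "proportion"), "profile")
    p <- setNames(profile$proportion, profile$sterol)
  } else {
    p <- profile
  }
  if (length(p) == 0L) abort("empty profile")
  ord <- order(-p, names(p))
  top <- tibble(rank = seq_len(min(k, length(p))),
                sterol = names(p)[ord][seq_len(min(k, length(p)))],
                proportion = unname(p[ord])[seq_len(min(k, length(p)))])
  dom <- if (max(p) >= dominant_cutoff) names(p)[ord][1] else NA_character_
  list(top = top, richness = sum(p > 0), dominant = dom)
}
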