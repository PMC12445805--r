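#' Read an MS feature table
#'
#' Reads a CSV/TSV export with one row per detected chromatographic signal.
#' Required columns: `sample` (sample id), `mz` (Da), `rt` (minutes),
#' `area` (counts). Extra columns are carried through untouched.
#'
#' @param path path to a delimited file (delimiter sniffed from extension:
#'   `.tsv`/`.txt` read as tab, anything else as comma).
#' @return A tibble with columns `sample`, `mz`, `rt`, `area`.
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("feature table not found: %s", path))
  delim <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  df <- suppressWarnings(
    readr::read_delim(path, delim = delim, show_col_types = FALSE,
                      progress = FALSE,
                      col_types = readr::cols(sample = "c", mz = "d",
                                              rt = "d", area = "d"))
  )
  check_columns(df, c("sample", "mz", "rt", "area"), "feature table")
  df <- mutate(df, sample = as.character(.data$sample))
  check_numeric_finite(df, c("mz", "rt", "area"), "feature table")
  if (any(df$mz <= 0) || any(df$rt < 0) || any(df$area < 0)) {
    abort("feature table has negative mz/rt/area values")
  }
  as_tibble(df)
}

#' @rdname read_feature_table
#' @param signals a feature-table tibble.
#' @export
write_feature_table <- function(signals, path) {
  check_columns(signals, c("sample", "mz", "rt", "area"), "feature table")
  readr::write_csv(signals, path, progress = FALSE)
  invisible(path)
}

#' Parse an elemental formula
#'
#' Supports C, H, D (deuterium) and O, the elements occurring in sterol
#' dehydration ions and the lock-mass calibrant.
#'
#' @param formula character vector like `"C27H46O"` or `"C27H39D7O"`.
#' @return A tibble with columns `c`, `h`, `d`, `o`.
#' @export
#' @examples
#' parse_formula("C27H46O")
parse_formula <- function(formula) {
  parse_one <- function(f) {
    if (!grepl("^([CHDO][0-9]*)+$", f)) {
      abort(sprintf("cannot parse formula '%s' (elements C,H,D,O only)", f))
    }
    m <- gregexpr("[CHDO][0-9]*", f)[[1]]
    toks <- regmatches(f, list(m))[[1]]
    counts <- c(C = 0, H = 0, D = 0, O = 0)
    for (tk in toks) {
      el <- substr(tk, 1, 1)
      nn <- substr(tk, 2, nchar(tk))
      counts[el] <- counts[el] + if (nzchar(nn)) as.integer(nn) else 1L
    }
    counts
  }
  out <- t(vapply(formula, parse_one, numeric(4)))
  tibble(c = unname(out[, "C"]), h = unname(out[, "H"]),
         d = unname(out[, "D"]), o = unname(out[, "O"]))
}

BRING_CLASSES <- c("CPR", "D0", "D5", "D7", "D8", "NA")

#' Read a reference sterol table
#'
#' The reference table lists authenticated standards used for level-1
#' annotation: compound name, elemental formula, expected retention time,
#' and the B-ring double-bond class (one of CPR, D0, D5, D7, D8, NA).
#' Monoisotopic neutral mass, the theoretical dehydrated-cation m/z
#' (\[M-H2O+H\]+), average molar mass, carbon count and the double-bond
#' count beyond the tetracyclic core are derived from the formula.
#'
#' @param path CSV with columns `name`, `formula`, `expected_rt`,
#'   `bring_class` (use the string "NA" for the undetermined class).
#' @return A tibble with the derived columns added.
#' @export
read_reference_sterols <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "reference_sterols_synthetic.csv",
                        package = "sterolome", mustWork = TRUE)
  }
  if (!file.exists(path)) abort(sprintf("reference table not found: %s", path))
  # the undetermined B-ring class is the literal string "NA"
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(bring_class = "c"),
                        na = character())
  check_columns(df, c("name", "formula", "expected_rt", "bring_class"),
                "reference sterol table")
  bad <- setdiff(unique(df$bring_class), BRING_CLASSES)
  if (length(bad) > 0L) {
    abort(sprintf("unknown bring_class value(s): %s",
                  paste(bad, collapse = ", ")))
  }
  el <- parse_formula(df$formula)
  # dehydrated protonated cation: lose H2O, gain H (net -O -H), lose e-
  ion_mz <- purrr::pmap_dbl(el, function(c, h, d, o) {
    theoretical_mz(c, h - 1L, d, o_count = o - 1L)
  })
  mutate(df,
    carbons = el$c,
    monoisotopic_mass = monoisotopic_mass(df$formula),
    molar_mass = molar_mass(df$formula),
    ion_mz = ion_mz,
    # DBE of CcHhOx = (2c+2-h)/2; sterol core contributes 4 (5 with CPR ring,
    # but the printed ST codes count ring-closure DBE, so subtract 4 always)
    double_bonds = as.integer((2 * el$c + 2 - (el$h + el$d)) / 2 - 4)
  )
}

#' Read and validate a rooted phylogeny
#'
#' Thin wrapper over the Newick reader that enforces the invariants the
#' signal estimators rely on: unique tip labels, branch lengths present and
#' non-negative, rooted topology.
#'
#' @param path Newick file.
#' @return An `ape::phylo` tree.
#' @export
read_phylogeny <- function(path) {
  if (!file.exists(path)) abort(sprintf("tree file not found: %s", path))
  tree <- ape::read.tree(path)
  if (is.null(tree)) abort(sprintf("could not parse Newick in %s", path))
  validate_phylogeny(tree)
}

#' @rdname read_phylogeny
#' @param tree an `ape::phylo`.
#' @export
write_phylogeny <- function(tree, path) {
  validate_phylogeny(tree)
  ape::write.tree(tree, file = path)
  invisible(path)
}

validate_phylogeny <- function(tree) {
  if (!inherits(tree, "phylo")) abort("not a phylo object")
  dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
  if (length(dup) > 0L) {
    abort(sprintf("duplicate tip label(s): %s", paste(dup, collapse = ", ")))
  }
  if (is.null(tree$edge.length)) abort("tree has no branch lengths")
  if (any(tree$edge.length < 0)) abort("negative branch length(s) in tree")
  # a basal polytomy (e.g. a star tree) still defines a valid rooted VCV
  if (!ape::is.rooted(tree) && tree$Nnode > 1L) abort("tree must be rooted")
  tree
}

#' Read sample metadata
#'
#' @param path CSV with at least `sample` and `taxon` columns; typical extra
#'   columns are `family`, `subfamily`, `genus`, `county`, `weight_mg`.
#' @return A tibble.
#' @export
read_sample_metadata <- function(path) {
  if (!file.exists(path)) abort(sprintf("metadata file not found: %s", path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  check_columns(df, c("sample", "taxon"), "sample metadata")
  mutate(df, sample = as.character(.data$sample),
         taxon = as.character(.data$taxon))
}
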