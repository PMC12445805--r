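# monoisotopic atomic masses (Da) and the electron mass
MASS_C <- 12.000000
MASS_H <- 1.0078250319
MASS_D <- 2.0141018
MASS_O <- 15.9949146
MASS_E <- 0.00054858

# average (chemical) atomic masses, used only for molar-mass quantification
AVG_C <- 12.011
AVG_H <- 1.008
AVG_D <- 2.014
AVG_O <- 15.999

#' Theoretical m/z of a small cation
#'
#' Sums monoisotopic atomic masses for the given elemental composition and
#' subtracts one electron mass per positive charge. For an even-electron
#' protonated species pass the ion's H count directly (e.g. cholesterol
#' \[M-H2O+H\]+ is C27H45+); for an odd-electron radical cation such as the
#' fluoranthene lock mass set `radical = TRUE` (the flag is documentation
#' of intent -- the H count is always taken as given).
#'
#' @param c_carbons,h_count,d_count,o_count atom counts (non-negative).
#' @param charge positive integer charge, default +1.
#' @param radical logical, odd-electron cation.
#' @return m/z in Da.
#' @export
#' @examples
#' theoretical_mz(27, 45)              # cholesterol [M-H2O+H]+  369.3516
#' theoretical_mz(16, 10, radical = TRUE)  # fluoranthene C16H10+.  202.0777
theoretical_mz <- function(c_carbons, h_count, d_count = 0L, o_count = 0L,
                           charge = 1L, radical = FALSE) {
  counts <- c(c_carbons, h_count, d_count, o_count)
  if (any(counts < 0)) abort("atom counts must be non-negative")
  if (charge < 1) abort("charge must be a positive integer")
  m <- c_carbons * MASS_C + h_count * MASS_H + d_count * MASS_D +
    o_count * MASS_O - charge * MASS_E
  m / charge
}

#' Monoisotopic and average mass of a neutral formula
#'
#' @param formula character, e.g. `"C27H46O"`.
#' @return mass in Da (monoisotopic) or g/mol (average).
#' @export
monoisotopic_mass <- function(formula) {
  el <- parse_formula(formula)
  el$c * MASS_C + el$h * MASS_H + el$d * MASS_D + el$o * MASS_O
}

#' @rdname monoisotopic_mass
#' @export
molar_mass <- function(formula) {
  el <- parse_formula(formula)
  el$c * AVG_C + el$h * AVG_H + el$d * AVG_D + el$o * AVG_O
}

#' Dehydrated sterol cation m/z for an (carbons, double-bonds) pair
#'
#' The sterol \[M-H2O+H\]+ ion of a CcH(2c+2-2(4+d))O sterol is
#' CcH(2c+1-2(4+d))+ where `d` counts double-bond equivalents beyond the
#' tetracyclic core (so cholesterol is (27,1), cycloartenol-type (30,2)).
#'
#' @param carbons,double_bonds integer vectors.
#' @return m/z in Da.
#' @export
sterol_ion_mz <- function(carbons, double_bonds) {
  h <- 2 * carbons + 1 - 2 * (4 + double_bonds)
  if (any(h < 0)) abort("hydrogen count negative: (c,d) outside sterol space")
  mapply(function(c, hh) theoretical_mz(c, hh), carbons, h)
}

#' Decompose an accurate mass into sterol carbon / double-bond counts
#'
#' Searches carbons 26-32 and 0-7 double-bond equivalents beyond the core
#' for the dehydrated sterol cation best matching `mz`, and reports it if
#' within `ppm_tolerance`. Ties within tolerance are resolved to the
#' smallest ppm error and flagged ambiguous.
#'
#' @param mz observed m/z (Da).
#' @param ppm_tolerance match tolerance in ppm (default 3).
#' @param carbons_range,db_range integer search bounds.
#' @return A one-row tibble with `carbons`, `double_bonds`, `ppm_error`,
#'   `ambiguous`; all-NA row when nothing matches.
#' @export
#' @examples
#' decompose_mass(369.3516)   # cholesterol-type -> (27, 1)
decompose_mass <- function(mz, ppm_tolerance = 3,
                           carbons_range = c(26L, 32L),
                           db_range = c(0L, 7L)) {
  stopifnot(length(mz) == 1L, is.finite(mz), mz > 0)
  grid <- expand.grid(carbons = seq(carbons_range[1], carbons_range[2]),
                      double_bonds = seq(db_range[1], db_range[2]))
  grid$mz_theo <- sterol_ion_mz(grid$carbons, grid$double_bonds)
  grid$ppm <- (mz - grid$mz_theo) / grid$mz_theo * 1e6
  hits <- grid[abs(grid$ppm) <= ppm_tolerance, , drop = FALSE]
  if (nrow(hits) == 0L) {
    return(tibble(carbons = NA_integer_, double_bonds = NA_integer_,
                  ppm_error = NA_real_, ambiguous = FALSE))
  }
  hits <- hits[order(abs(hits$ppm)), , drop = FALSE]
  if (nrow(hits) > 1L) {
    warn(sprintf("mass %.4f matches %d sterol compositions within %g ppm; using (%d,%d)",
                 mz, nrow(hits), ppm_tolerance,
                 hits$carbons[1], hits$double_bonds[1]))
  }
  tibble(carbons = as.integer(hits$carbons[1]),
         double_bonds = as.integer(hits$double_bonds[1]),
         ppm_error = hits$ppm[1],
         ambiguous = nrow(hits) > 1L)
}

#' Average molar mass implied by a sterol (carbons, double-bonds) code
#'
#' Used to quantify level-2 annotated sterols, whose neutral formula
#' CcH(2c+2-2(4+d))O is implied by the ST code.
#'
#' @inheritParams sterol_ion_mz
#' @return g/mol.
#' @export
implied_molar_mass <- function(carbons, double_bonds) {
  h <- 2 * carbons + 2 - 2 * (4 + double_bonds)
  carbons * AVG_C + h * AVG_H + AVG_O
}

#' Internal-standard spike amount
#'
#' Moles delivered by a spike of `volume_ul` microlitres at
#' `conc_mg_ml` mg/ml of a compound of molar mass `mw` g/mol. With the
#' assay defaults (20 ul of 0.1 mg/ml d7-cholesterol, 393.71 g/mol) this
#' is 5.08 nmol.
#'
#' @param volume_ul spike volume (microlitres).
#' @param conc_mg_ml spike concentration (mg/ml).
#' @param mw molar mass (g/mol); default d7-cholesterol C27H39D7O.
#' @return moles.
#' @export
is_spike_moles <- function(volume_ul = 20, conc_mg_ml = 0.1,
                           mw = molar_mass("C27H39D7O")) {
  mg <- volume_ul / 1000 * conc_mg_ml
  mg / 1000 / mw
}

#' Smallest detectable sterol mass for a given pollen sample
#'
#' @param weight_mg fresh pollen weight (mg).
#' @param fraction sterol content as a fraction of fresh weight.
#' @return micrograms of sterol.
#' @export
detectable_sterol_ug <- function(weight_mg = 10, fraction = 0.001) {
  weight_mg * fraction * 1000
}
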