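#' Pipeline configuration
#'
#' Builds the run configuration shared by all pipeline stages. Defaults
#' mirror the acquisition and filtering settings of the sterolome assay:
#' signals retained between 3 and 11 min and 360-442 m/z with a minimum
#' area of 5e5 counts; a d7-cholesterol internal-standard spike of
#' 5.08 nmol per sample; 3 ppm mass tolerance and a 0.1 min retention-time
#' window for annotation and alignment; QC correlation threshold 0.75;
#' 999 permutations for all permutation tests; NMDS accepted at Kruskal
#' stress <= 0.2.
#'
#' @param rt_window numeric length-2, retention-time window in minutes.
#' @param mz_window numeric length-2, m/z window in Da.
#' @param area_threshold minimum signal area (counts).
#' @param is_moles internal-standard amount per sample (mol).
#' @param ppm_tolerance mass-match tolerance (ppm).
#' @param rt_tolerance retention-time match tolerance (minutes).
#' @param qc_threshold minimum Pearson r between QC load and signal.
#' @param blank_factor a feature is kept only if its median sample signal
#'   is at least `blank_factor` times its median blank signal.
#' @param n_permutations permutations for PERMANOVA/IndVal/K tests.
#' @param nmds_max_tries random restarts for NMDS.
#' @param stress_cutoff maximum acceptable Kruskal stress-1.
#' @param min_max_proportion a sterol enters the phylogenetic-signal screen
#'   only if its maximum taxon proportion exceeds this (fraction).
#' @param random_seed integer seed used by stochastic stages.
#' @return A named list of class `sterolome_config`.
#' @export
#' @examples
#' cfg <- run_config(n_permutations = 199)
#' cfg$rt_window
run_config <- function(rt_window = c(3, 11),
                       mz_window = c(360, 442),
                       area_threshold = 5e5,
                       is_moles = 5.08e-9,
                       ppm_tolerance = 3,
                       rt_tolerance = 0.1,
                       qc_threshold = 0.75,
                       blank_factor = 3,
                       n_permutations = 999,
                       nmds_max_tries = 200,
                       stress_cutoff = 0.2,
                       min_max_proportion = 0.01,
                       random_seed = 1L) {
  cfg <- list(
    rt_window = as.numeric(rt_window), mz_window = as.numeric(mz_window),
    area_threshold = area_threshold, is_moles = is_moles,
    ppm_tolerance = ppm_tolerance, rt_tolerance = rt_tolerance,
    qc_threshold = qc_threshold, blank_factor = blank_factor,
    n_permutations = as.integer(n_permutations),
    nmds_max_tries = as.integer(nmds_max_tries),
    stress_cutoff = stress_cutoff,
    min_max_proportion = min_max_proportion,
    random_seed = as.integer(random_seed)
  )
  class(cfg) <- "sterolome_config"
  validate_config(cfg)
}

validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "sterolome_config"))
  if (length(cfg$rt_window) != 2L || diff(cfg$rt_window) <= 0) {
    abort("rt_window must be an increasing [min, max] pair")
  }
  if (length(cfg$mz_window) != 2L || diff(cfg$mz_window) <= 0) {
    abort("mz_window must be an increasing [min, max] pair")
  }
  for (nm in c("ppm_tolerance", "rt_tolerance", "is_moles", "blank_factor")) {
    if (!is.numeric(cfg[[nm]]) || cfg[[nm]] <= 0) {
      abort(sprintf("%s must be > 0", nm))
    }
  }
  if (cfg$n_permutations < 1L) abort("n_permutations must be >= 1")
  if (cfg$nmds_max_tries < 1L) abort("nmds_max_tries must be >= 1")
  if (cfg$area_threshold < 0) abort("area_threshold must be >= 0")
  cfg
}

#' Read / write a pipeline configuration file
#'
#' The configuration is stored as YAML; unknown keys are rejected so typos
#' fail loudly rather than silently using a default.
#'
#' @param path file path.
#' @return `read_run_config()` returns a `sterolome_config`;
#'   `write_run_config()` returns `path` invisibly.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  raw <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0L) {
    abort(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  }
  do.call(run_config, raw)
}

#' @rdname read_run_config
#' @param config a `sterolome_config`.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "sterolome_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @export
print.sterolome_config <- function(x, ...) {
  cat("<sterolome run configuration>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-18s %s\n", nm, paste(format(x[[nm]]), collapse = " .. ")))
  }
  invisible(x)
}
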