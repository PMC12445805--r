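#' Simulate a birth-death phylogeny
#'
#' Ultrametric rooted tree with exactly `n_tips` tips, generated under a
#' constant-rate birth-death process conditioned on the number of tips,
#' with tips relabelled t1..tn.
#'
#' @param n_tips number of tips (>= 3).
#' @param birth_rate,death_rate per-lineage rates (birth > death >= 0).
#' @param seed integer seed.
#' @return An `ape::phylo`.
#' @export
sim_tree <- function(n_tips, birth_rate = 1, death_rate = 0, seed = 1L) {
  if (n_tips < 3) abort("n_tips must be >= 3")
  if (!(birth_rate > death_rate) || death_rate < 0) {
    abort("need birth_rate > death_rate >= 0")
  }
  tree <- with_seed(seed, ape::rphylo(n_tips, birth = birth_rate,
                                      death = death_rate))
  tree$tip.label <- paste0("t", seq_len(n_tips))
  validate_phylogeny(tree)
}

#' Simulate tip traits with controlled phylogenetic signal
#'
#' Draws `n_traits` independent trait vectors from a zero-mean
#' multivariate normal whose covariance is the lambda-transformed
#' Brownian phylogenetic covariance: off-diagonal entries of sigma2 * C
#' scaled by `lambda_true`, diagonal unchanged. lambda_true = 1 is pure
#' Brownian motion; lambda_true = 0 makes tips independent with the same
#' marginal variances.
#'
#' @param tree an `ape::phylo` with branch lengths.
#' @param lambda_true signal strength in \[0, 1\].
#' @param sigma2 Brownian rate (trait variance per unit branch length).
#' @param n_traits number of independent traits.
#' @param seed integer seed.
#' @return A tips x traits matrix (rownames = tip labels).
#' @export
sim_traits <- function(tree, lambda_true = 1, sigma2 = 1, n_traits = 1,
                       seed = 1L) {
  validate_phylogeny(tree)
  if (lambda_true < 0 || lambda_true > 1) abort("lambda_true must be in [0, 1]")
  if (sigma2 < 0) abort("sigma2 must be >= 0")
  n <- length(tree$tip.label)
  if (sigma2 == 0) {
    m <- matrix(0, n, n_traits,
                dimnames = list(tree$tip.label,
                                paste0("trait", seq_len(n_traits))))
    return(m)
  }
  V <- sigma2 * lambda_vcv(phylo_vcv(tree), lambda_true)
  # chol needs strict PD; nudge by a relative jitter for degenerate trees
  ch <- tryCatch(chol(V), error = function(e) {
    chol(V + diag(1e-10 * max(diag(V)), n))
  })
  z <- with_seed(seed, matrix(rnorm(n * n_traits), n, n_traits))
  m <- crossprod(ch, z)
  dimnames(m) <- list(tree$tip.label, paste0("trait", seq_len(n_traits)))
  m
}

#' Map latent traits to compositional sterol profiles
#'
#' Softmax over sterols within each taxon: proportions are positive and
#' sum to one, and large latent differences translate into near-pure
#' profiles.
#'
#' @param latent taxa x sterols matrix of finite latent values.
#' @return A matrix of the same shape whose rows sum to 1.
#' @export
traits_to_profiles <- function(latent) {
  latent <- as.matrix(latent)
  if (any(!is.finite(latent))) abort("latent values must be finite")
  e <- exp(latent - apply(latent, 1, max))
  e / rowSums(e)
}

#' Simulation truth for a synthetic sterolome study
#'
#' Bundles the tree, the latent-trait parameters, the taxon-level baseline
#' profiles (softmax of lambda-transformed Brownian traits) and the true
#' total sterol contents that [sim_sample_tables()] turns into MS-level
#' feature tables.
#'
#' @param tree an `ape::phylo` (e.g. [sim_tree()]).
#' @param sterols character vector of sterol names; must appear in
#'   `reference` when sample tables are generated. Default: six common
#'   pollen sterols.
#' @param lambda_true phylogenetic signal of the latent traits in \[0, 1\].
#' @param sigma2 Brownian rate on the latent scale.
#' @param total_mean,total_cv lognormal mean (mg/kg) and coefficient of
#'   variation of the true per-taxon total sterol content. Defaults span
#'   the observed range of pollen totals (roughly 700 to 75000 mg/kg).
#' @param noise_cv coefficient of variation of the multiplicative
#'   lognormal noise applied to signal areas (default 0.1).
#' @param seed integer seed.
#' @return A list of class `sterolome_truth`: `tree`, `lambda_true`,
#'   `sigma2`, `baseline_profiles` (taxa x sterols), `totals_true`
#'   (named, mg/kg), `noise_cv`, `seed`.
#' @export
sim_truth <- function(tree,
                      sterols = c("24-methylenecholesterol", "beta-sitosterol",
                                  "isofucosterol", "campesterol",
                                  "cholesterol", "desmosterol"),
                      lambda_true = 1, sigma2 = 1,
                      total_mean = 5000, total_cv = 1,
                      noise_cv = 0.1, seed = 1L) {
  validate_phylogeny(tree)
  latent <- sim_traits(tree, lambda_true, sigma2, n_traits = length(sterols),
                       seed = seed)
  colnames(latent) <- sterols
  profiles <- traits_to_profiles(latent)
  sdlog <- sqrt(log(1 + total_cv^2))
  totals <- with_seed(seed + 1L, {
    setNames(stats::rlnorm(nrow(profiles),
                           meanlog = log(total_mean) - sdlog^2 / 2,
                           sdlog = sdlog), rownames(profiles))
  })
  structure(list(tree = tree, lambda_true = lambda_true, sigma2 = sigma2,
                 baseline_profiles = profiles, totals_true = totals,
                 noise_cv = noise_cv, seed = seed),
            class = "sterolome_truth")
}

#' Generate MS-level sample tables from a simulation truth
#'
#' Produces the raw feature tables the quantification stage consumes. For
#' each taxon and replicate, every sterol's signal area is chosen so that
#' the internal-standard quantification inverts to the truth in
#' expectation: area = IS_area x total x proportion x (weight/1000) /
#' (MW x is_moles x 1e6), times multiplicative lognormal noise with the
#' truth's coefficient of variation. Every non-blank sample carries the
#' d7-cholesterol IS feature; QC samples repeat a fixed pooled profile at
#' relative loads 1.0 / 0.5 / 0.25; blanks contain only low-level
#' background features and no IS.
#'
#' @param truth a [sim_truth()].
#' @param reference a [read_reference_sterols()] table covering every
#'   sterol in the truth.
#' @param replicates samples per taxon (default 3).
#' @param qc_per_level QC samples per dilution level (default 1).
#' @param n_blanks blank runs (default 2).
#' @param weight_mg fresh pollen weight per sample (default 10).
#' @param is_area internal-standard signal area (default 1e7 counts).
#' @param config a [run_config()] (supplies `is_moles`).
#' @param seed integer seed.
#' @return A list: `signals` (study-sample feature table), `qc_signals`,
#'   `qc_loads` (named vector), `blank_signals`, `metadata` (sample,
#'   taxon, weight_mg).
#' @export
sim_sample_tables <- function(truth, reference = read_reference_sterols(),
                              replicates = 3, qc_per_level = 1,
                              n_blanks = 2, weight_mg = 10, is_area = 1e7,
                              config = run_config(), seed = 1L) {
  stopifnot(inherits(truth, "sterolome_truth"))
  sterols <- colnames(truth$baseline_profiles)
  missing <- setdiff(sterols, reference$name)
  if (length(missing) > 0L) {
    abort(sprintf("sterol(s) missing from the reference table: %s",
                  paste(missing, collapse = ", ")))
  }
  ref <- reference[match(sterols, reference$name), ]
  sdlog <- if (truth$noise_cv > 0) sqrt(log(1 + truth$noise_cv^2)) else 0
  # lognormal with mean 1 so quantification is unbiased
  noise <- function(k) {
    if (sdlog == 0) rep(1, k) else stats::rlnorm(k, -sdlog^2 / 2, sdlog)
  }
  area_for <- function(total, props) {
    signal <- total * props * (weight_mg / 1000) /
      (ref$molar_mass * config$is_moles * 1e6)
    signal * is_area
  }
  with_seed(seed, {
    taxa <- rownames(truth$baseline_profiles)
    rows <- purrr::map_dfr(taxa, function(tx) {
      purrr::map_dfr(seq_len(replicates), function(r) {
        sid <- sprintf("%s_r%d", tx, r)
        areas <- area_for(truth$totals_true[tx],
                          truth$baseline_profiles[tx, ]) * noise(length(sterols))
        bind_rows(
          tibble(sample = sid, mz = ref$ion_mz, rt = ref$expected_rt,
                 area = areas),
          tibble(sample = sid, mz = IS_ION_MZ, rt = IS_RT, area = is_area)
        )
      })
    })
    metadata <- tibble(sample = unique(rows$sample)) |>
      mutate(taxon = sub("_r[0-9]+$", "", .data$sample),
             weight_mg = weight_mg)
    # QC pool: average of all baseline profiles at the mean total
    qc_props <- colMeans(truth$baseline_profiles)
    qc_total <- mean(truth$totals_true)
    loads <- rep(c(1, 0.5, 0.25), each = qc_per_level)
    qc_ids <- sprintf("QC%d_load%g", seq_along(loads), loads)
    qc_rows <- purrr::map_dfr(seq_along(loads), function(i) {
      areas <- area_for(qc_total, qc_props) * loads[i] * noise(length(sterols))
      bind_rows(
        tibble(sample = qc_ids[i], mz = ref$ion_mz, rt = ref$expected_rt,
               area = areas),
        tibble(sample = qc_ids[i], mz = IS_ION_MZ, rt = IS_RT,
               area = is_area)
      )
    })
    blank_rows <- purrr::map_dfr(seq_len(n_blanks), function(b) {
      # sparse background: a few random low-mass features, never the IS
      k <- 3L
      tibble(sample = sprintf("BLANK%d", b),
             mz = runif(k, config$mz_window[1], config$mz_window[2]),
             rt = runif(k, config$rt_window[1], config$rt_window[2]),
             area = runif(k, 0, config$area_threshold / 10))
    })
    list(signals = rows, qc_signals = qc_rows,
         qc_loads = setNames(loads, qc_ids),
         blank_signals = blank_rows, metadata = metadata)
  })
}

#' Simulate honeybee six-sterol profiles
#'
#' Dirichlet draws with the given mean and precision, emulating replicate
#' prepupal honeybee sterol compositions over the six bee-relevant
#' sterols.
#'
#' @param mean_profile named simplex vector (sums to 1).
#' @param concentration Dirichlet precision; draws concentrate on the mean
#'   as it grows.
#' @param n number of samples (the reference study used 18).
#' @param seed integer seed.
#' @return An n x length(mean_profile) matrix; rows sum to 1.
#' @export
sim_bee_samples <- function(mean_profile, concentration = 200, n = 18,
                            seed = 1L) {
  if (n < 1) abort("n must be >= 1")
  if (any(mean_profile < 0) || abs(sum(mean_profile) - 1) > 1e-9) {
    abort("mean_profile must be a simplex vector (non-negative, sums to 1)")
  }
  alpha <- mean_profile * concentration
  m <- with_seed(seed, {
    g <- matrix(rgamma(n * length(alpha), shape = rep(alpha, each = n),
                       rate = 1), nrow = n)
    g / rowSums(g)
  })
  colnames(m) <- names(mean_profile)
  rownames(m) <- sprintf("bee%02d", seq_len(n))
  m
}
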