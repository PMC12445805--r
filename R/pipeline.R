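# groups tips by the clades hanging off the root: a coarse stand-in for
# family membership when only a tree is available
root_clades <- function(tree) {
  n <- length(tree$tip.label)
  root <- n + 1L
  kids <- tree$edge[tree$edge[, 1] == root, 2]
  grp <- setNames(rep(NA_character_, n), tree$tip.label)
  for (i in seq_along(kids)) {
    tips <- if (kids[i] <= n) tree$tip.label[kids[i]] else
      ape::extract.clade(tree, kids[i])$tip.label
    grp[tips] <- paste0("clade", i)
  }
  grp
}

#' Run the full sterolome pipeline
#'
#' Executes every stage in order -- signal filtering, blank and QC
#' filtering, feature alignment and annotation, internal-standard
#' quantification, taxon summaries (means, Simpson diversity, outlier
#' screen, class proportions), ordination and PERMANOVA on the
#' arcsine-root Bray-Curtis matrix, the phylogenetic-signal screen, and
#' honeybee sufficiency scoring -- and writes JSON results plus CSV tables
#' to `out_dir`. With `inputs = NULL` a synthetic study is simulated from
#' the config seed, so the pipeline is fully reproducible without
#' instrument data.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if needed).
#' @param inputs NULL, or a list with `signals`, `qc_signals`, `qc_loads`,
#'   `blank_signals`, `metadata`, `tree` (tibbles/objects, or file paths
#'   for `signals`, `metadata` and `tree`).
#' @param n_taxa,replicates synthetic-study size when simulating.
#' @return Invisibly, a list with every stage's result; also written to
#'   `out_dir/results.json` and CSV files.
#' @export
run_pipeline <- function(config = run_config(), out_dir, inputs = NULL,
                         n_taxa = 20, replicates = 3) {
  validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    ster_log("stage: ", name)
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline failed at stage '%s': %s", name,
                    conditionMessage(e)))
    })
  }
  reference <- read_reference_sterols()
  if (is.null(inputs)) {
    inputs <- stage("simulate", {
      tree <- sim_tree(n_taxa, seed = config$random_seed)
      truth <- sim_truth(tree, lambda_true = 1,
                         seed = config$random_seed + 1L)
      tabs <- sim_sample_tables(truth, reference, replicates = replicates,
                                config = config,
                                seed = config$random_seed + 2L)
      tabs$tree <- tree
      tabs$truth <- truth
      tabs
    })
  } else {
    if (is.character(inputs$signals)) {
      inputs$signals <- read_feature_table(inputs$signals)
    }
    if (is.character(inputs$metadata)) {
      inputs$metadata <- read_sample_metadata(inputs$metadata)
    }
    if (is.character(inputs$tree)) inputs$tree <- read_phylogeny(inputs$tree)
  }

  filtered <- stage("filter", filter_signals(inputs$signals, config))
  aligned <- stage("align", align_features(filtered, config))
  kept <- aligned
  if (!is.null(inputs$blank_signals) && nrow(inputs$blank_signals) > 0L) {
    kept <- stage("blank_filter", {
      ab <- align_blanks(inputs$blank_signals, aligned, config)
      if (nrow(ab) == 0L) aligned else {
        bf <- blank_filter(aligned, ab, config)
        filter(aligned, .data$feature_id %in% bf$feature_id[bf$kept])
      }
    })
  }
  normalized <- stage("normalize", normalize_to_is(kept, config))
  if (!is.null(inputs$qc_signals) && nrow(inputs$qc_signals) > 0L) {
    qc_norm <- stage("qc_normalize", {
      qf <- filter_signals(inputs$qc_signals, config)
      qa <- align_features(bind_rows(filtered, qf), config)
      normalize_to_is(filter(qa, .data$sample %in% qf$sample), config)
    })
    qc_res <- stage("qc_filter", {
      qc_filter(unique(normalized$feature_id), qc_norm, inputs$qc_loads,
                config)
    })
    normalized <- filter(normalized, .data$feature_id %in%
                           qc_res$feature_id[qc_res$kept])
  }
  annotations <- stage("annotate", {
    annotate_features(dplyr::distinct(normalized, .data$feature_id,
                                      .data$feature_mz, .data$feature_rt),
                      reference, config)
  })
  profiles <- stage("quantify", {
    quantify_profiles(normalized, annotations, inputs$metadata, config)
  })
  outliers <- stage("outliers", detect_outliers(profiles))
  clean <- filter(profiles, !(.data$sample %in%
                                outliers$sample[outliers$outlier]))
  taxon_prof <- stage("profile", taxon_means(clean))
  diversity <- stage("diversity", {
    taxon_prof |>
      group_by(.data$taxon) |>
      summarise(simpson = simpson_index(.data$proportion), .groups = "drop")
  })
  classes <- stage("classes", class_proportions(taxon_prof, annotations))
  d_taxa <- stage("dissimilarity", {
    bray_curtis_matrix(taxon_prof, id = "taxon", transform = arcsine_sqrt)
  })
  ord <- stage("ordinate", {
    nmds_screen(d_taxa, stress_cutoff = config$stress_cutoff,
                max_tries = min(config$nmds_max_tries, 25),
                seed = config$random_seed + 3L)
  })
  groups <- root_clades(inputs$tree)[rownames(d_taxa)]
  perm <- disp <- ind <- NULL
  if (length(unique(groups)) >= 2L && all(table(groups) >= 2L)) {
    perm <- stage("permanova", {
      permanova(d_taxa, groups, nperm = config$n_permutations,
                seed = config$random_seed + 4L)
    })
    disp <- stage("dispersion", {
      dispersion_test(d_taxa, groups, nperm = config$n_permutations,
                      seed = config$random_seed + 5L)
    })
    ind <- stage("indval", {
      x <- arcsine_sqrt(pivot_matrix(taxon_prof, "taxon", "sterol",
                                     "proportion"))
      indval(x[names(groups), , drop = FALSE], groups,
             nperm = config$n_permutations,
             seed = config$random_seed + 6L)
    })
  }
  signal <- stage("physignal", {
    signal_screen(taxon_prof, inputs$tree, mapping = annotations,
                  min_max_proportion = config$min_max_proportion,
                  nperm = config$n_permutations,
                  seed = config$random_seed + 7L)
  })
  bees <- stage("beescore", {
    reports <- score_requirements(taxon_prof)
    cohort_summary(reports)
  })

  readr::write_csv(profiles, file.path(out_dir, "sample_profiles.csv"))
  readr::write_csv(taxon_prof, file.path(out_dir, "taxon_profiles.csv"))
  readr::write_csv(as_tibble(signal), file.path(out_dir, "signal_screen.csv"))
  readr::write_csv(classes, file.path(out_dir, "class_proportions.csv"))
  results <- list(
    n_samples = length(unique(profiles$sample)),
    n_taxa = length(unique(taxon_prof$taxon)),
    n_features = length(unique(profiles$sterol)),
    outliers = outliers$sample[outliers$outlier],
    nmds = list(stress = ord$stress, k = ord$k, converged = ord$converged),
    permanova = if (!is.null(perm)) {
      list(F = perm$statistic, R2 = perm$r_squared, p = perm$p_value)
    },
    dispersion = if (!is.null(disp)) {
      list(F = disp$statistic, p = disp$p_value)
    },
    signal = purrr::transpose(as.list(as_tibble(signal))),
    bee_histogram = setNames(as.list(bees$histogram$n_taxa),
                             paste0("met_", bees$histogram$count_met)),
    seed = config$random_seed
  )
  jsonlite::write_json(results, file.path(out_dir, "results.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE,
                       null = "null")
  ster_log("pipeline complete: ", out_dir)
  invisible(list(inputs = inputs, profiles = profiles,
                 taxon_profiles = taxon_prof, outliers = outliers,
                 diversity = diversity, classes = classes, nmds = ord,
                 permanova = perm, dispersion = disp, indval = ind,
                 signal = signal, bees = bees, annotations = annotations))
}

# maps blank signals onto the consensus features of the study samples so
# blank and sample areas are compared feature-by-feature
align_blanks <- function(blank_signals, aligned, config) {
  feats <- dplyr::distinct(aligned, .data$feature_id, .data$feature_mz,
                           .data$feature_rt)
  purrr::pmap_dfr(blank_signals, function(sample, mz, rt, area, ...) {
    hit <- feats |>
      filter(abs(.data$feature_mz - mz) / mz * 1e6 <= config$ppm_tolerance,
             abs(.data$feature_rt - rt) <= config$rt_tolerance)
    if (nrow(hit) == 0L) return(tibble())
    tibble(sample = sample, feature_id = hit$feature_id[1], area = area)
  })
}
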