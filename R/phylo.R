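#' Rename rules for placing study taxa on a reference tree
#'
#' Builds the rename-rule table used by [prune_and_match()]. Rule kinds:
#' `synonym` (taxonomic synonym on the tree), `subspecies` (a species-level
#' branch stands in for a subspecies), `hybrid` (a parent species stands in
#' for a hybrid) and `congener` (another species of the same genus stands
#' in, applied only when the genus has no correctly matched species
#' already).
#'
#' @param source tip labels present on the tree.
#' @param target study taxon names the tips should carry.
#' @param kind one of `"synonym"`, `"subspecies"`, `"hybrid"`, `"congener"`.
#' @return A tibble `source`, `target`, `kind`.
#' @export
rename_rules <- function(source = character(), target = character(),
                         kind = character()) {
  kinds <- c("synonym", "subspecies", "hybrid", "congener")
  if (!all(kind %in% kinds)) {
    abort(sprintf("rule kind must be one of: %s", paste(kinds, collapse = ", ")))
  }
  tibble(source = as.character(source), target = as.character(target),
         kind = as.character(kind))
}

genus_of <- function(x) sub("[ _].*$", "", x)

#' Prune a reference phylogeny to the study taxa
#'
#' Applies rename rules in order (synonyms, subspecies-to-species and
#' hybrid-to-parent substitutions, then congener substitutions -- the last
#' refused whenever the target's genus already has a correctly matched
#' species on the tree), then prunes the tree to the matched taxa and
#' reports the taxa that could not be placed.
#'
#' @param tree an `ape::phylo`.
#' @param taxa character vector of study taxon names.
#' @param rules a [rename_rules()] tibble.
#' @return A list: `tree` (pruned, tips renamed to study taxa),
#'   `unplaced` (taxa without a tip), `applied` (rules actually applied).
#' @export
prune_and_match <- function(tree, taxa, rules = rename_rules()) {
  validate_phylogeny(tree)
  missing_src <- setdiff(rules$source, tree$tip.label)
  if (length(missing_src) > 0L) {
    abort(sprintf("rename rule(s) target non-existent tip(s): %s",
                  paste(missing_src, collapse = ", ")))
  }
  applied <- rules[0, ]
  for (i in seq_len(nrow(rules))) {
    rl <- rules[i, ]
    if (!(rl$source %in% tree$tip.label)) next  # consumed by earlier rule
    if (rl$target %in% tree$tip.label) next     # target already present
    if (rl$kind == "congener") {
      genus_hit <- any(genus_of(tree$tip.label) == genus_of(rl$target) &
                         tree$tip.label %in% taxa)
      if (genus_hit) {
        ster_log("congener substitution refused for ", rl$target,
                 ": genus already matched", level = "WARN")
        next
      }
    }
    tree$tip.label[tree$tip.label == rl$source] <- rl$target
    applied <- bind_rows(applied, rl)
  }
  matched <- intersect(taxa, tree$tip.label)
  unplaced <- setdiff(taxa, matched)
  if (length(matched) < 3L) abort("fewer than 3 taxa could be placed on the tree")
  pruned <- ape::keep.tip(tree, matched)
  if (length(unplaced) > 0L) {
    ster_log(length(unplaced), " of ", length(taxa),
             " taxa could not be placed on the tree")
  }
  list(tree = pruned, unplaced = unplaced, applied = applied)
}

#' Check families (or any grouping) for monophyly
#'
#' A group is monophyletic when the smallest clade containing all its tips
#' contains no tips from other groups; single-tip groups are reported as
#' singletons.
#'
#' @param tree an `ape::phylo`.
#' @param grouping named character vector mapping tip label to group.
#' @return A tibble `group`, `n_tips`, `status` in
#'   {"monophyletic", "non-monophyletic", "singleton"}.
#' @export
check_monophyly <- function(tree, grouping) {
  validate_phylogeny(tree)
  unmapped <- setdiff(tree$tip.label, names(grouping))
  if (length(unmapped) > 0L) {
    abort(sprintf("tip(s) without a group: %s", paste(unmapped, collapse = ", ")))
  }
  purrr::map_dfr(sort(unique(grouping[tree$tip.label])), function(g) {
    tips <- tree$tip.label[grouping[tree$tip.label] == g]
    if (length(tips) == 1L) {
      return(tibble(group = g, n_tips = 1L, status = "singleton"))
    }
    mrca <- ape::getMRCA(tree, tips)
    clade_tips <- ape::extract.clade(tree, mrca)$tip.label
    tibble(group = g, n_tips = length(tips),
           status = if (setequal(clade_tips, tips)) "monophyletic"
                    else "non-monophyletic")
  })
}

#' Phylogenetic variance-covariance matrix
#'
#' C\[i, j\] is the shared root-to-MRCA path length of tips i and j;
#' C\[i, i\] the root-to-tip distance. Positive semidefinite for any valid
#' tree; under Brownian motion with rate sigma^2 the tip values are
#' multivariate normal with covariance sigma^2 C.
#'
#' @param tree an `ape::phylo` with branch lengths.
#' @return A tips x tips matrix in `tree$tip.label` order.
#' @export
phylo_vcv <- function(tree) {
  validate_phylogeny(tree)
  ape::vcv.phylo(tree)
}

# lambda transform: off-diagonals scaled, diagonal fixed
lambda_vcv <- function(C, lambda) {
  cl <- C * lambda
  diag(cl) <- diag(C)
  cl
}

# largest lambda keeping C(lambda) positive semidefinite (>= 1 for
# ultrametric trees); bisection on the smallest eigenvalue
lambda_max <- function(C, tol = 1e-6) {
  upper <- max(diag(C)) / max(C[row(C) != col(C)])
  psd <- function(l) min(eigen(lambda_vcv(C, l), symmetric = TRUE,
                               only.values = TRUE)$values) > -1e-10
  if (psd(upper)) return(upper)
  lo <- 1
  hi <- upper
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (psd(mid)) lo <- mid else hi <- mid
  }
  lo
}

# GLS pieces shared by K and lambda: phylogenetic mean and quadratic forms
gls_pieces <- function(C, z) {
  ch <- tryCatch(chol(C), error = function(e) {
    # near the PSD boundary (lambda ~ lambda_max) nudge onto the cone
    chol(C + diag(1e-8 * max(diag(C)), nrow(C)))
  })
  one <- rep(1, length(z))
  ci_one <- backsolve(ch, forwardsolve(t(ch), one))
  ci_z <- backsolve(ch, forwardsolve(t(ch), z))
  ahat <- sum(one * ci_z) / sum(one * ci_one)
  resid <- z - ahat
  ci_resid <- backsolve(ch, forwardsolve(t(ch), resid))
  list(ahat = ahat, resid = resid,
       qform = sum(resid * ci_resid),      # (z-a)' C^-1 (z-a)
       ss0 = sum(resid^2),                 # (z-a)' (z-a)
       logdet = 2 * sum(log(diag(ch))),
       sum_ci_one = sum(one * ci_one))
}

#' Blomberg's K with permutation inference
#'
#' K is the ratio of the observed MSE0/MSE (numerator: variance of tip
#' values about the phylogenetic mean; denominator: the GLS mean squared
#' error under the tree) to its Brownian expectation
#' (tr(C) - n / (1' C^-1 1)) / (n - 1). K = 1 under Brownian motion,
#' K near 0 when trait values are independent of the tree. The p-value
#' shuffles trait values across tips and counts permuted K >= observed,
#' with the (1 + b) / (1 + m) estimator.
#'
#' @param tree an `ape::phylo`.
#' @param trait named numeric vector (names = tip labels) or unnamed in
#'   tip order.
#' @param nperm permutations for the p-value (default 999); `nperm = 0`
#'   skips inference.
#' @param seed integer seed.
#' @return A list: `K`, `p_value`, `n_tips`, `n_permutations`, `seed`.
#' @export
blomberg_k <- function(tree, trait, nperm = 999, seed = 1L) {
  validate_phylogeny(tree)
  trait <- align_trait(tree, trait)
  if (var(trait) == 0) abort("trait is constant; K undefined")
  C <- phylo_vcv(tree)
  n <- length(trait)
  k_of <- function(z) {
    p <- gls_pieces(C, z)
    obs_ratio <- p$ss0 / p$qform
    exp_ratio <- (sum(diag(C)) - n / p$sum_ci_one) / (n - 1)
    obs_ratio / exp_ratio
  }
  k_obs <- k_of(trait)
  p_val <- NA_real_
  if (nperm > 0) {
    exceed <- with_seed(seed, {
      sum(vapply(seq_len(nperm), function(i) k_of(sample(trait)) >= k_obs,
                 logical(1)))
    })
    p_val <- (1 + exceed) / (1 + nperm)
  }
  list(K = k_obs, p_value = p_val, n_tips = n, n_permutations = nperm,
       seed = seed)
}

align_trait <- function(tree, trait) {
  if (!is.null(names(trait))) {
    missing <- setdiff(tree$tip.label, names(trait))
    if (length(missing) > 0L) {
      abort(sprintf("trait missing for tip(s): %s",
                    paste(utils::head(missing, 5), collapse = ", ")))
    }
    trait <- trait[tree$tip.label]
  } else if (length(trait) != length(tree$tip.label)) {
    abort("unnamed trait must have one value per tip")
  }
  if (any(!is.finite(trait))) abort("trait has non-finite values")
  unname(trait)
}

# profile log-likelihood of lambda (sigma^2 and the mean profiled out);
# -Inf when C(lambda) has left the PSD cone numerically
lambda_loglik <- function(C, z, lambda) {
  n <- length(z)
  p <- tryCatch(gls_pieces(lambda_vcv(C, lambda), z),
                error = function(e) NULL)
  if (is.null(p) || p$qform <= 0) return(-Inf)
  sigma2 <- p$qform / n
  -n / 2 * log(2 * pi * sigma2) - p$logdet / 2 - n / 2
}

#' Pagel's lambda by maximum likelihood
#'
#' Scales the off-diagonal phylogenetic covariances by lambda (diagonal
#' fixed) and maximizes the multivariate-normal likelihood over lambda in
#' \[0, lambda_max\], with the Brownian rate and the root state profiled
#' out. lambda_max is the largest value keeping the transformed covariance
#' positive semidefinite (computed from the tree, >= 1 when ultrametric).
#' Inference is a likelihood-ratio test against lambda = 0 with a
#' chi-squared(1) reference (optionally the 50:50 boundary mixture).
#'
#' @inheritParams blomberg_k
#' @param mixture_null logical; if TRUE halve the chi-squared tail
#'   probability (boundary-corrected LRT). Default FALSE.
#' @param tol optimizer tolerance on lambda (default 1e-6).
#' @return A list: `lambda`, `lambda_capped` (display value, min(lambda,
#'   1)), `logL`, `logL0`, `p_value`, `lambda_max`, `n_tips`.
#' @export
pagel_lambda <- function(tree, trait, mixture_null = FALSE, tol = 1e-6) {
  validate_phylogeny(tree)
  trait <- align_trait(tree, trait)
  if (var(trait) == 0) abort("trait is constant; lambda undefined")
  C <- phylo_vcv(tree)
  lmax <- lambda_max(C)
  obj <- function(l) lambda_loglik(C, trait, l)
  opt <- optimize(obj, c(0, lmax), maximum = TRUE, tol = tol)
  # the interior optimum can miss a boundary maximum; check both ends
  cand <- c(opt$maximum, 0, lmax)
  ll <- vapply(cand, obj, numeric(1))
  best <- which.max(ll)
  lam <- cand[best]
  logl <- ll[best]
  logl0 <- obj(0)
  lrt <- 2 * (logl - logl0)
  p <- pchisq(max(lrt, 0), df = 1, lower.tail = FALSE)
  if (mixture_null) p <- p / 2
  p <- min(max(p, .Machine$double.xmin), 1)
  list(lambda = lam, lambda_capped = min(lam, 1), logL = logl,
       logL0 = logl0, p_value = p, lambda_max = lmax,
       n_tips = length(trait))
}

#' Phylogenetic-signal screen over sterol traits
#'
#' Assembles the trait set the signal analysis uses -- per-sterol
#' proportions passing the maximum-proportion filter (> 1% by default),
#' total sterol content (mg/kg, always included), carbon-class sums and
#' B-ring-class sums -- and estimates Blomberg's K (permutation p) and
#' Pagel's lambda (likelihood-ratio p) for each.
#'
#' @param taxon_profiles [taxon_means()] output (`taxon`, `sterol`,
#'   `proportion`, `total_mg_kg`).
#' @param tree an `ape::phylo` whose tips match the taxa (extra tips are
#'   pruned; taxa missing from the tree are dropped with a log message).
#' @param mapping annotation tibble (`sterol`, `bring_class`, `carbons`)
#'   for the class sums; NULL skips class traits.
#' @param min_max_proportion inclusion filter on each sterol's maximum
#'   taxon proportion (default 0.01).
#' @param nperm permutations for the K test.
#' @param seed integer seed.
#' @return A `sterolome_signal` tibble: `trait`, `trait_type`, `K`, `p_K`,
#'   `lambda`, `p_lambda`, `n_tips`.
#' @export
signal_screen <- function(taxon_profiles, tree, mapping = NULL,
                          min_max_proportion = 0.01, nperm = 999,
                          seed = 1L) {
  check_columns(taxon_profiles, c("taxon", "sterol", "proportion"),
                "taxon profiles")
  taxa <- intersect(unique(taxon_profiles$taxon), tree$tip.label)
  if (length(taxa) < 3L) abort("fewer than 3 taxa shared with the tree")
  dropped <- setdiff(unique(taxon_profiles$taxon), taxa)
  if (length(dropped) > 0L) {
    ster_log(length(dropped), " taxa not on the tree; excluded from screen")
  }
  tr <- ape::keep.tip(tree, taxa)
  prof <- filter(taxon_profiles, .data$taxon %in% taxa)
  m <- pivot_matrix(prof, "taxon", "sterol", "proportion")
  keep <- colnames(m)[apply(m, 2, max) > min_max_proportion]
  traits <- purrr::map(keep, function(s) setNames(m[, s], rownames(m)))
  names(traits) <- keep
  types <- rep("sterol", length(keep))
  if ("total_mg_kg" %in% names(prof)) {
    tot <- dplyr::distinct(prof, .data$taxon, .data$total_mg_kg)
    if (!anyNA(tot$total_mg_kg)) {
      traits <- c(traits, list(total_mg_kg = setNames(tot$total_mg_kg,
                                                      tot$taxon)))
      types <- c(types, "total")
    }
  }
  if (!is.null(mapping)) {
    cls <- class_proportions(prof, mapping, id = "taxon")
    for (ct in unique(cls$class_type)) {
      sub <- filter(cls, .data$class_type == ct)
      cm <- pivot_matrix(sub, "taxon", "class", "proportion")
      for (cl in colnames(cm)) {
        nm <- paste0(ct, "_", cl)
        traits <- c(traits, setNames(list(setNames(cm[, cl],
                                                   rownames(cm))), nm))
        types <- c(types, "class")
      }
    }
  }
  res <- purrr::imap_dfr(traits, function(z, nm) {
    if (var(z) == 0) {
      return(tibble(trait = nm, K = NA_real_, p_K = NA_real_,
                    lambda = NA_real_, p_lambda = NA_real_))
    }
    kk <- blomberg_k(tr, z, nperm = nperm, seed = seed)
    ll <- pagel_lambda(tr, z)
    tibble(trait = nm, K = kk$K, p_K = kk$p_value,
           lambda = ll$lambda_capped, p_lambda = ll$p_value)
  })
  res$trait_type <- types
  res$n_tips <- length(taxa)
  out <- select(res, "trait", "trait_type", "K", "p_K", "lambda",
                "p_lambda", "n_tips")
  class(out) <- c("sterolome_signal", class(out))
  out
}
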