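as_dissimilarity <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!is.matrix(d) || nrow(d) != ncol(d)) {
    abort("d must be a square dissimilarity matrix or a dist object")
  }
  if (max(abs(d - t(d))) > 1e-10) abort("dissimilarity matrix must be symmetric")
  if (any(diag(d) != 0)) abort("dissimilarity matrix must have a zero diagonal")
  if (any(d < 0)) abort("dissimilarities must be non-negative")
  d
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjustment: p_(i) * m / i with enforced monotonicity from the
#' largest p downwards, capped at 1.
#'
#' @param p p-values in \[0, 1\].
#' @return adjusted p-values, same order as input.
#' @export
#' @examples
#' benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
benjamini_hochberg <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    abort("p-values must lie in [0, 1]")
  }
  m <- length(p)
  if (m == 0L) return(numeric(0))
  ord <- order(p, decreasing = TRUE)
  adj <- pmin(1, cummin(p[ord] * m / seq(m, 1)))
  adj[order(ord)]
}

# sum of squared dissimilarities within index set, divided by set size
ss_within_set <- function(d2, idx) {
  sum(d2[idx, idx][upper.tri(d2[idx, idx])]) / length(idx)
}

permanova_f <- function(d2, groups) {
  n <- nrow(d2)
  g <- length(unique(groups))
  ss_total <- sum(d2[upper.tri(d2)]) / n
  ss_within <- sum(vapply(split(seq_len(n), groups), function(idx) {
    sum(d2[idx, idx][upper.tri(d2[idx, idx])]) / length(idx)
  }, numeric(1)))
  ss_between <- ss_total - ss_within
  f <- (ss_between / (g - 1)) / (ss_within / (n - g))
  c(f = f, r2 = ss_between / ss_total)
}

new_permtest <- function(statistic, r_squared, p_value, nperm, seed,
                         df, method, extra = list()) {
  structure(c(list(statistic = statistic, r_squared = r_squared,
                   p_value = p_value, n_permutations = nperm, seed = seed,
                   df = df, method = method), extra),
            class = "sterolome_permtest")
}

#' @export
print.sterolome_permtest <- function(x, ...) {
  cat(sprintf("%s: F = %.4f, R2 = %s, p = %.4g (%d permutations, df = %d,%d)\n",
              x$method, x$statistic,
              if (is.na(x$r_squared)) "-" else sprintf("%.4f", x$r_squared),
              x$p_value, x$n_permutations, x$df[1], x$df[2]))
  invisible(x)
}

#' PERMANOVA on a dissimilarity matrix
#'
#' One-way permutational multivariate analysis of variance. The total sum
#' of squares is the sum of squared dissimilarities divided by n (Gower
#' partition); within-group SS is the analogous quantity within each
#' group. The pseudo-F statistic is compared against `nperm` random
#' permutations of the group labels; the p-value uses the
#' (1 + exceedances) / (1 + nperm) estimator so it is never zero.
#'
#' @param d symmetric dissimilarity matrix or `dist`.
#' @param groups group labels, one per row of `d` (>= 2 groups, each of
#'   size >= 2).
#' @param nperm number of permutations (default 999).
#' @param seed integer seed for the permutations.
#' @return A `sterolome_permtest` with `statistic` (pseudo-F),
#'   `r_squared`, `p_value`, `df`, `n_permutations`, `seed`.
#' @export
permanova <- function(d, groups, nperm = 999, seed = 1L) {
  d <- as_dissimilarity(d)
  groups <- as.character(groups)
  if (length(groups) != nrow(d)) abort("groups must match rows of d")
  sizes <- table(groups)
  if (length(sizes) < 2L) abort("need at least 2 groups")
  if (any(sizes < 2L)) {
    abort(sprintf("every group needs >= 2 members (singleton: %s)",
                  names(sizes)[sizes < 2][1]))
  }
  d2 <- d^2
  obs <- permanova_f(d2, groups)
  n <- nrow(d)
  g <- length(sizes)
  exceed <- with_seed(seed, {
    sum(vapply(seq_len(nperm), function(i) {
      permanova_f(d2, sample(groups))[["f"]] >= obs[["f"]]
    }, logical(1)))
  })
  new_permtest(obs[["f"]], obs[["r2"]], (1 + exceed) / (1 + nperm),
               nperm, seed, c(g - 1L, n - g), "PERMANOVA")
}

#' Pairwise PERMANOVA with Benjamini-Hochberg correction
#'
#' Runs [permanova()] on every pair of groups' submatrix and adjusts the
#' p-values across pairs with [benjamini_hochberg()].
#'
#' @inheritParams permanova
#' @return A tibble: `group1`, `group2`, `statistic`, `r_squared`,
#'   `p_value`, `p_adjusted`, `n`.
#' @export
pairwise_permanova <- function(d, groups, nperm = 999, seed = 1L) {
  d <- as_dissimilarity(d)
  groups <- as.character(groups)
  levs <- sort(unique(groups))
  pairs <- utils::combn(levs, 2, simplify = FALSE)
  res <- purrr::imap_dfr(pairs, function(pr, i) {
    idx <- which(groups %in% pr)
    fit <- permanova(d[idx, idx], groups[idx], nperm = nperm,
                     seed = seed + i)
    tibble(group1 = pr[1], group2 = pr[2], statistic = fit$statistic,
           r_squared = fit$r_squared, p_value = fit$p_value,
           n = length(idx))
  })
  mutate(res, p_adjusted = benjamini_hochberg(.data$p_value))
}

# Gower-centered double-centering of squared dissimilarities
gower_center <- function(d) {
  a <- -0.5 * d^2
  n <- nrow(a)
  j <- diag(n) - matrix(1 / n, n, n)
  j %*% a %*% j
}

# principal-coordinate embedding retaining negative-eigenvalue axes
pcoa_axes <- function(d, tol = 1e-8) {
  e <- eigen(gower_center(d), symmetric = TRUE)
  scale_axes <- function(keep, sign) {
    if (!any(keep)) return(matrix(0, nrow(d), 0))
    sweep(e$vectors[, keep, drop = FALSE], 2,
          sqrt(sign * e$values[keep]), `*`)
  }
  list(pos = scale_axes(e$values > tol, 1),
       neg = scale_axes(e$values < -tol, -1),
       values = e$values)
}

#' Multivariate dispersion (homogeneity of variances) test
#'
#' Embeds the dissimilarity matrix by principal coordinates (retaining
#' negative-eigenvalue axes as imaginary components), computes each
#' sample's distance to its group centroid in that space, and tests
#' equality of mean distances with a one-way F whose null distribution is
#' obtained by permuting the distances across groups. The classical
#' F-table p-value is also reported.
#'
#' @inheritParams permanova
#' @return A `sterolome_permtest`; `$distances` holds the per-sample
#'   centroid distances, `$p_classical` the parametric p-value.
#' @export
dispersion_test <- function(d, groups, nperm = 999, seed = 1L) {
  d <- as_dissimilarity(d)
  groups <- as.character(groups)
  if (length(groups) != nrow(d)) abort("groups must match rows of d")
  sizes <- table(groups)
  if (length(sizes) < 2L || any(sizes < 2L)) {
    abort("need >= 2 groups with >= 2 members each")
  }
  ax <- pcoa_axes(d)
  centroid_dist <- function(g) {
    z2 <- rep(0, nrow(d))
    for (part in c("pos", "neg")) {
      m <- ax[[part]]
      if (ncol(m) == 0L) next
      cent <- rowsum(m, g) / as.vector(table(g)[sort(unique(g))])
      dev2 <- rowSums((m - cent[g, , drop = FALSE])^2)
      z2 <- z2 + if (part == "pos") dev2 else -dev2
    }
    sqrt(pmax(z2, 0))
  }
  z <- centroid_dist(groups)
  f_of <- function(zz) {
    gm <- tapply(zz, groups, mean)
    n_g <- table(groups)[names(gm)]
    ssb <- sum(n_g * (gm - mean(zz))^2)
    ssw <- sum((zz - gm[groups])^2)
    (ssb / (length(gm) - 1)) / (ssw / (length(zz) - length(gm)))
  }
  obs <- f_of(z)
  exceed <- with_seed(seed, {
    sum(vapply(seq_len(nperm), function(i) f_of(sample(z)) >= obs,
               logical(1)))
  })
  g <- length(sizes)
  n <- nrow(d)
  new_permtest(obs, NA_real_, (1 + exceed) / (1 + nperm), nperm, seed,
               c(g - 1L, n - g), "Multivariate dispersion",
               extra = list(distances = setNames(z, rownames(d)),
                            p_classical = pf(obs, g - 1, n - g,
                                             lower.tail = FALSE)))
}

# weighted pool-adjacent-violators: nondecreasing fit minimizing
# sum w (y - yhat)^2
pava <- function(y, w = rep(1, length(y))) {
  n <- length(y)
  if (n == 0L) return(numeric(0))
  vals <- y
  wts <- w
  sizes <- rep(1L, n)
  k <- 0L
  for (i in seq_len(n)) {
    k <- k + 1L
    vals[k] <- y[i]
    wts[k] <- w[i]
    sizes[k] <- 1L
    while (k > 1L && vals[k - 1L] > vals[k]) {
      tw <- wts[k - 1L] + wts[k]
      vals[k - 1L] <- (wts[k - 1L] * vals[k - 1L] + wts[k] * vals[k]) / tw
      wts[k - 1L] <- tw
      sizes[k - 1L] <- sizes[k - 1L] + sizes[k]
      k <- k - 1L
    }
  }
  rep(vals[seq_len(k)], times = sizes[seq_len(k)])
}

kruskal_stress1 <- function(d, dhat) {
  sqrt(sum((d - dhat)^2) / sum(d^2))
}

# one nonmetric-SMACOF descent from a starting configuration
nmds_engine <- function(delta, x0, ord, max_iter = 500, tol = 1e-8) {
  n <- nrow(x0)
  x <- scale(x0, scale = FALSE)
  pair_idx <- which(lower.tri(matrix(0, n, n)), arr.ind = TRUE)
  stress_prev <- Inf
  for (it in seq_len(max_iter)) {
    dm <- as.matrix(dist(x))
    dv <- dm[lower.tri(dm)]
    dhat <- numeric(length(dv))
    dhat[ord] <- pava(dv[ord])
    stress <- kruskal_stress1(dv, dhat)
    if (is.nan(stress) || abs(stress_prev - stress) < tol) break
    stress_prev <- stress
    # Guttman transform towards the fitted disparities
    b <- matrix(0, n, n)
    ratio <- ifelse(dv > 0, dhat / dv, 0)
    b[pair_idx] <- -ratio
    b <- b + t(b)
    diag(b) <- -rowSums(b)
    x <- scale((b %*% x) / n, scale = FALSE)
  }
  list(x = x, stress = stress, iterations = it)
}

#' Non-metric multidimensional scaling
#'
#' Minimizes Kruskal stress-1 by alternating monotone (isotonic)
#' regression of the configuration distances on the dissimilarities with
#' Guttman-transform majorization steps. Tied dissimilarities receive the
#' primary treatment (no order constraint within a tie block). The best of
#' `max_tries` starts is returned: the first start is the principal-
#' coordinate configuration, the rest are random; restarts stop early once
#' two independent starts agree on the minimum stress to 1e-6.
#'
#' @param d dissimilarity matrix or `dist`.
#' @param k embedding dimensions (default 2).
#' @param max_tries random restarts (default 50).
#' @param seed integer seed.
#' @return A `sterolome_nmds`: `coordinates` (n x k, centered), `stress`
#'   (Kruskal stress-1), `k`, `converged`, `n_tries`, `seed`.
#' @export
nmds <- function(d, k = 2, max_tries = 50, seed = 1L) {
  d <- as_dissimilarity(d)
  n <- nrow(d)
  if (n <= k) abort("need more samples than embedding dimensions")
  delta <- d[lower.tri(d)]
  if (all(delta == 0)) abort("all points are identical; ordination degenerate")
  # primary tie treatment: within tied delta, order follows current d,
  # approximated by breaking ties on the PCoA distances (fixed across runs)
  ax <- pcoa_axes(d)
  x_pcoa <- cbind(ax$pos, matrix(0, n, k))[, seq_len(k), drop = FALSE]
  d_ref <- as.matrix(dist(x_pcoa))[lower.tri(d)]
  ord <- order(delta, d_ref)
  best <- NULL
  n_hits <- 0L
  tries <- 0L
  with_seed(seed, {
    for (i in seq_len(max_tries)) {
      tries <- i
      x0 <- if (i == 1L) x_pcoa else matrix(rnorm(n * k), n, k)
      fit <- nmds_engine(delta, x0, ord)
      if (is.null(best) || fit$stress < best$stress - 1e-6) {
        best <- fit
        n_hits <- 1L
      } else if (fit$stress < best$stress + 1e-6) {
        n_hits <- n_hits + 1L
      }
      if (best$stress < 1e-6 || n_hits >= 2L) break
    }
  })
  coords <- best$x
  rownames(coords) <- rownames(d)
  colnames(coords) <- paste0("NMDS", seq_len(k))
  structure(list(coordinates = coords, stress = best$stress, k = k,
                 converged = n_hits >= 2L || best$stress < 1e-6,
                 n_tries = tries, seed = seed),
            class = "sterolome_nmds")
}

#' @export
print.sterolome_nmds <- function(x, ...) {
  cat(sprintf("NMDS: %d points in %d dimensions, stress = %.4f (%d starts%s)\n",
              nrow(x$coordinates), x$k, x$stress, x$n_tries,
              if (x$converged) ", converged" else ""))
  invisible(x)
}

#' NMDS with automatic dimension escalation
#'
#' Fits [nmds()] at k = `k_start` and raises k until the stress is at or
#' below the configured cutoff (default 0.2) or `k_max` is reached,
#' returning the lowest-dimensional acceptable solution.
#'
#' @inheritParams nmds
#' @param k_start,k_max dimension range to consider.
#' @param stress_cutoff acceptable Kruskal stress-1.
#' @return A `sterolome_nmds`.
#' @export
nmds_screen <- function(d, k_start = 2, k_max = 4, stress_cutoff = 0.2,
                        max_tries = 50, seed = 1L) {
  fit <- NULL
  for (k in seq(k_start, k_max)) {
    fit <- nmds(d, k = k, max_tries = max_tries, seed = seed)
    if (fit$stress <= stress_cutoff) return(fit)
  }
  warn(sprintf("stress %.3f still above cutoff %.2f at k = %d",
               fit$stress, stress_cutoff, k_max))
  fit
}

#' Indicator-value analysis
#'
#' For every sterol and group, the specificity A (the group's mean
#' abundance as a fraction of the summed group means), the fidelity B
#' (fraction of the group's samples where the sterol occurs) and the
#' indicator statistic sqrt(A x B). Each sterol's significance is assessed
#' by permuting group labels and comparing the sterol's maximum-group
#' statistic with its permutation distribution; groups are tested
#' individually, never in combination.
#'
#' @param x samples x sterols abundance matrix (typically arcsine-root
#'   transformed proportions).
#' @param groups group labels, one per row.
#' @param nperm permutations (default 999).
#' @param seed integer seed.
#' @return A tibble `sterol`, `group`, `A`, `B`, `stat`, `best`,
#'   `p_value` (on the best-group row; NA elsewhere).
#' @export
indval <- function(x, groups, nperm = 999, seed = 1L) {
  x <- as.matrix(x)
  groups <- as.character(groups)
  if (length(groups) != nrow(x)) abort("groups must match rows of x")
  if (length(unique(groups)) < 2L) abort("need >= 2 groups")
  absent <- colSums(x != 0) == 0
  if (any(absent)) {
    warn(sprintf("skipping sterol(s) absent everywhere: %s",
                 paste(colnames(x)[absent], collapse = ", ")))
    x <- x[, !absent, drop = FALSE]
  }
  stat_mat <- function(g) {
    means <- rowsum(x, g) / as.vector(table(g)[sort(unique(g))])
    a <- sweep(means, 2, colSums(means), `/`)
    b <- rowsum((x != 0) * 1, g) / as.vector(table(g)[sort(unique(g))])
    sqrt(a * b)
  }
  obs <- stat_mat(groups)
  obs_max <- apply(obs, 2, max)
  exceed <- rep(0, ncol(x))
  with_seed(seed, {
    for (i in seq_len(nperm)) {
      pm <- apply(stat_mat(sample(groups)), 2, max)
      exceed <- exceed + (pm >= obs_max)
    }
  })
  p <- setNames((1 + exceed) / (1 + nperm), colnames(x))
  out <- tibble(
    sterol = rep(colnames(x), each = nrow(obs)),
    group = rep(rownames(obs), times = ncol(x)),
    stat = as.vector(obs)
  )
  # recover A and B individually for the report
  means <- rowsum(x, groups) / as.vector(table(groups)[sort(unique(groups))])
  a <- sweep(means, 2, colSums(means), `/`)
  b <- rowsum((x != 0) * 1, groups) /
    as.vector(table(groups)[sort(unique(groups))])
  out$A <- as.vector(a)
  out$B <- as.vector(b)
  out <- out |>
    group_by(.data$sterol) |>
    mutate(best = .data$stat == max(.data$stat)) |>
    ungroup()
  out$p_value <- ifelse(out$best, p[out$sterol], NA_real_)
  select(out, "sterol", "group", "A", "B", "stat", "best", "p_value") |>
    arrange(.data$sterol, .data$group)
}

#' Kruskal-Wallis test with Dunn post hoc comparisons
#'
#' Rank-based H statistic with tie correction and a chi-squared reference,
#' followed by pairwise Dunn z tests on mean ranks (tie-corrected
#' variance) with Benjamini-Hochberg adjustment across pairs.
#'
#' @param values numeric observations.
#' @param groups group labels (>= 2 groups, >= 2 observations each).
#' @return A list of class `sterolome_kruskal`: `H`, `df`, `p_value`,
#'   `pairwise` (tibble `group1`, `group2`, `z`, `p_value`, `p_adjusted`).
#' @export
kruskal_dunn <- function(values, groups) {
  groups <- as.character(groups)
  if (length(values) != length(groups)) abort("values/groups length mismatch")
  sizes <- table(groups)
  if (length(sizes) < 2L) abort("need >= 2 groups")
  if (any(sizes < 2L)) abort("every group needs >= 2 observations")
  n <- length(values)
  r <- rank(values)
  ties <- table(values)
  tie_sum <- sum(ties^3 - ties)
  mean_rank <- tapply(r, groups, mean)
  n_g <- as.vector(sizes[names(mean_rank)])
  h <- 12 / (n * (n + 1)) * sum(n_g * mean_rank^2) - 3 * (n + 1)
  cfac <- 1 - tie_sum / (n^3 - n)
  if (cfac == 0) {
    h <- 0  # all values identical
  } else {
    h <- h / cfac
  }
  df <- length(sizes) - 1L
  p <- if (h == 0) 1 else pchisq(h, df, lower.tail = FALSE)
  levs <- names(mean_rank)
  pairs <- utils::combn(levs, 2, simplify = FALSE)
  var_base <- n * (n + 1) / 12 - tie_sum / (12 * (n - 1))
  pw <- purrr::map_dfr(pairs, function(pr) {
    i <- match(pr[1], levs)
    j <- match(pr[2], levs)
    se <- sqrt(var_base * (1 / n_g[i] + 1 / n_g[j]))
    z <- if (se == 0) 0 else (mean_rank[i] - mean_rank[j]) / se
    tibble(group1 = pr[1], group2 = pr[2], z = unname(z),
           p_value = 2 * stats::pnorm(-abs(z)))
  })
  pw$p_adjusted <- benjamini_hochberg(pw$p_value)
  structure(list(H = h, df = df, p_value = p, pairwise = pw),
            class = "sterolome_kruskal")
}

#' @export
print.sterolome_kruskal <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis: H(%d) = %.3f, p = %.4g\n", x$df, x$H,
              x$p_value))
  print(x$pairwise)
  invisible(x)
}
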