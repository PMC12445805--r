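#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a permutation-test result
#'
#' @param x a `sterolome_permtest` (from [permanova()] or
#'   [dispersion_test()]).
#' @param ... unused.
#' @return A one-row tibble: `method`, `statistic`, `r_squared`,
#'   `p_value`, `df1`, `df2`, `n_permutations`.
#' @export
tidy.sterolome_permtest <- function(x, ...) {
  tibble(method = x$method, statistic = x$statistic,
         r_squared = x$r_squared, p_value = x$p_value,
         df1 = x$df[1], df2 = x$df[2], n_permutations = x$n_permutations)
}

#' @rdname tidy.sterolome_permtest
#' @export
glance.sterolome_permtest <- function(x, ...) tidy(x, ...)

#' Tidy an NMDS ordination
#'
#' @param x a `sterolome_nmds`.
#' @param ... unused.
#' @return `tidy()`: one row per point with its coordinates; `glance()`:
#'   one row with `stress`, `k`, `converged`, `n_tries`.
#' @export
tidy.sterolome_nmds <- function(x, ...) {
  out <- as_tibble(x$coordinates)
  out$label <- rownames(x$coordinates) %||% as.character(seq_len(nrow(out)))
  select(out, "label", dplyr::everything())
}

#' @rdname tidy.sterolome_nmds
#' @export
glance.sterolome_nmds <- function(x, ...) {
  tibble(stress = x$stress, k = x$k, converged = x$converged,
         n_tries = x$n_tries)
}

#' Tidy a Kruskal-Wallis + Dunn result
#'
#' @param x a `sterolome_kruskal`.
#' @param ... unused.
#' @return `tidy()`: the pairwise Dunn table; `glance()`: one row with
#'   `H`, `df`, `p_value`.
#' @export
tidy.sterolome_kruskal <- function(x, ...) x$pairwise

#' @rdname tidy.sterolome_kruskal
#' @export
glance.sterolome_kruskal <- function(x, ...) {
  tibble(H = x$H, df = x$df, p_value = x$p_value)
}
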