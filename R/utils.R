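#' @keywords internal
"_PACKAGE"

#' @importFrom rlang .data abort warn %||%
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   left_join inner_join bind_rows n across all_of desc row_number rename
#' @importFrom tibble tibble as_tibble
#' @importFrom stats rnorm rgamma runif optimize median cor cmdscale dist
#'   pchisq pf setNames sd var
NULL

# stderr logging; silenced with options(sterolome.verbose = FALSE)
ster_log <- function(..., level = "INFO") {
  if (isFALSE(getOption("sterolome.verbose", TRUE))) return(invisible(NULL))
  message(sprintf("[%s] %s", level, paste0(...)))
  invisible(NULL)
}

# every stochastic stage funnels through here so the seed is always logged
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  set.seed(as.integer(seed))
  ster_log("seed = ", as.integer(seed), level = "SEED")
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  force(expr)
}

check_columns <- function(df, cols, what = "table") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}

check_numeric_finite <- function(df, cols, what = "table") {
  for (cl in cols) {
    x <- df[[cl]]
    if (!is.numeric(x)) {
      bad <- which(is.na(suppressWarnings(as.numeric(as.character(x)))))
      abort(sprintf("column '%s' of %s is not numeric (first bad row: %s)",
                    cl, what, if (length(bad)) bad[1] else "?"))
    }
    if (any(!is.finite(x))) {
      abort(sprintf("column '%s' of %s has non-finite values (row %d)",
                    cl, what, which(!is.finite(x))[1]))
    }
  }
  invisible(df)
}

# long (id x key x value) -> matrix with zero fill, deterministic ordering
pivot_matrix <- function(df, row, col, value) {
  wide <- tidyr::pivot_wider(
    df[, c(row, col, value)],
    names_from = all_of(col), values_from = all_of(value),
    values_fill = 0, values_fn = sum
  )
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- as.character(wide[[row]])
  m[, order(colnames(m)), drop = FALSE]
}
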