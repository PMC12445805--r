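options(sterolome.verbose = FALSE)

toy_tree <- function(text = "((A:1,B:1):1,C:2);") ape::read.tree(text = text)

star_tree <- function(n = 5, b = 1) {
  tr <- ape::stree(n, type = "star")
  tr$edge.length <- rep(b, nrow(tr$edge))
  tr
}

random_simplex <- function(k, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  x <- rgamma(k, 1)
  x / sum(x)
}

# long profile tibble from a samples x sterols matrix
profiles_long <- function(m, id = "sample") {
  tibble::tibble(
    !!id := rep(rownames(m), times = ncol(m)),
    sterol = rep(colnames(m), each = nrow(m)),
    proportion = as.vector(m)
  )
}

simplex_matrix <- function(n, k, seed = 1) {
  set.seed(seed)
  m <- matrix(rgamma(n * k, 1), n, k)
  m <- m / rowSums(m)
  dimnames(m) <- list(paste0("s", seq_len(n)), paste0("st", seq_len(k)))
  m
}

# quiet a single expected warning class while keeping others loud
quietly_warn <- function(expr) suppressWarnings(expr)
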