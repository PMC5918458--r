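#' @keywords internal
"_PACKAGE"

# Moore-Penrose pseudo-inverse of a symmetric PSD matrix.
# Eigenvalues below rtol * max(eigenvalue) are treated as exact zeros; the
# returned rank counts the retained ones.
pinv_sym <- function(M, rtol = 1e-10) {
  if (!is.matrix(M) || nrow(M) != ncol(M)) {
    stop("pinv_sym() expects a square matrix")
  }
  e <- eigen(M, symmetric = TRUE)
  lmax <- max(e$values, 0)
  keep <- e$values > rtol * lmax
  if (!any(keep)) {
    return(list(inv = matrix(0, nrow(M), ncol(M)), rank = 0L))
  }
  U <- e$vectors[, keep, drop = FALSE]
  list(inv = U %*% (t(U) / e$values[keep]), rank = sum(keep))
}

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards.  seed = NULL leaves the current stream
# untouched (and advancing).
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  if (!exists(".Random.seed", globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

# Deterministic per-gene seed stream: a rolling string hash of the gene id
# folded into the master seed, kept below 2^31 so set.seed() accepts it.
# Stable across R sessions and platforms (no dependence on R's own hashing),
# so per-gene results do not depend on analysis order.
gene_seed <- function(master_seed, gene_id) {
  h <- 0
  for (b in utf8ToInt(as.character(gene_id))) {
    h <- (h * 31 + b) %% 2147483647
  }
  as.integer((as.numeric(master_seed %% 2147483647) * 1000003 + h) %% 2147483646) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

join_flags <- function(...) {
  f <- c(...)
  f <- f[nzchar(f)]
  if (length(f) == 0L) "" else paste(f, collapse = ";")
}
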