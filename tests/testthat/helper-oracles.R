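# Brute-force reference implementations used only by the tests.
# Deliberately slow and simple, and deliberately sharing no code with the
# package: moments come from literal enumeration of every margin-preserving
# table weighted by the hypergeometric probability formula, and p-values
# from literal enumeration of label partitions.

# all distinct orderings of a multiset of genotype values
oracle_arrangements <- function(values) {
  values <- sort(values)
  if (length(values) == 1L) {
    return(matrix(values, 1, 1))
  }
  out <- NULL
  for (v in unique(values)) {
    rest <- values[-match(v, values)]
    sub <- oracle_arrangements(rest)
    out <- rbind(out, cbind(v, sub))
  }
  unname(out)
}

oracle_vec_table <- function(g) {
  # row-major vectorized t x 3 indicator table of a genotype vector
  t <- length(g)
  tab <- matrix(0, t, 3)
  tab[cbind(seq_len(t), g + 1)] <- 1
  as.vector(t(tab))
}

# exact null of one subject's table given its genotype column margins
# (length-3 counts). Probability of each arrangement evaluated from the
# hypergeometric formula: n.0! n.1! n.2! / (t! * prod of cell factorials),
# cell factorials all 1 because every row margin is 1.
oracle_enumerate_null <- function(col_margins) {
  t <- sum(col_margins)
  stopifnot(t >= 1, t <= 10)
  g <- rep(0:2, times = col_margins)
  arr <- oracle_arrangements(g)
  prob <- prod(factorial(col_margins)) / factorial(t)
  vecs <- t(apply(arr, 1, oracle_vec_table))
  stopifnot(abs(nrow(vecs) * prob - 1) < 1e-12)
  m <- colSums(vecs) * prob
  V <- matrix(0, 3 * t, 3 * t)
  for (i in seq_len(nrow(vecs))) {
    V <- V + prob * tcrossprod(vecs[i, ] - m)
  }
  list(tables = vecs, prob = rep(prob, nrow(vecs)), m = m, V = V)
}

# pseudo-inverse via plain SVD, independent of the package's eigen route
oracle_pinv <- function(M, rtol = 1e-10) {
  s <- svd(M)
  keep <- s$d > rtol * max(s$d, 0)
  if (!any(keep)) {
    return(matrix(0, nrow(M), ncol(M)))
  }
  s$v[, keep, drop = FALSE] %*% (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

# brute-force GCMH from a list of genotype vectors: enumeration moments,
# literal elimination matrix, generic quadratic form
oracle_gcmh <- function(geno_list, rtol = 1e-10) {
  t <- length(geno_list[[1]])
  A <- matrix(0, 2 * (t - 1), 3 * t)
  for (j in seq_len(t - 1)) {
    for (k in 0:1) {
      A[2 * (j - 1) + k + 1, 3 * (j - 1) + k + 1] <- 1
    }
  }
  G <- numeric(2 * (t - 1))
  VarG <- matrix(0, 2 * (t - 1), 2 * (t - 1))
  for (g in geno_list) {
    en <- oracle_enumerate_null(tabulate(g + 1, 3))
    G <- G + drop(A %*% (oracle_vec_table(g) - en$m))
    VarG <- VarG + A %*% en$V %*% t(A)
  }
  drop(t(G) %*% oracle_pinv(VarG, rtol) %*% G)
}

oracle_T <- function(counts, case_idx, tau = 1e-12) {
  gl <- lapply(seq_len(nrow(counts)), function(i) counts[i, ])
  s1 <- oracle_gcmh(gl[case_idx])
  s0 <- oracle_gcmh(gl[-case_idx])
  if (s1 <= tau || s0 <= tau) {
    return(NA_real_)
  }
  log(s1) - log(s0)
}

# exact two-sided p over every label partition with the observed group sizes
# (undefined partitions excluded from the denominator)
oracle_exhaustive_pvalue <- function(counts, is_case, tau = 1e-12) {
  n <- nrow(counts)
  stopifnot(n <= 12)
  n_case <- sum(is_case)
  T_obs <- oracle_T(counts, which(is_case), tau)
  stopifnot(!is.na(T_obs))
  parts <- utils::combn(n, n_case)
  Tb <- apply(parts, 2, function(idx) oracle_T(counts, idx, tau))
  # tie-tolerant comparison: many partitions share |T| exactly in law but
  # differ by rounding in the last bits
  mean(abs(Tb[!is.na(Tb)]) >= abs(T_obs) - 1e-9)
}
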