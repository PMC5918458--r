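# Batched permutation engine.
#
# The GCMH covariance factorizes as c * R~ %x% S with a row factor R~ shared
# by all subjects, and the per-subject column factors depend only on each
# subject's genotype histogram -- which a label permutation never changes.
# So for one gene we precompute per-subject indicator and margin summaries
# once, and evaluate the statistic for thousands of group assignments with a
# few matrix products. All quantities are algebraically identical to
# gcmh_statistic(); the test suite checks the two paths against each other.

engine_precompute <- function(counts) {
  # counts: n x t integer matrix (subjects x variants), no NAs
  Gt <- t(counts)
  t <- nrow(Gt)
  I0 <- (Gt == 0) * 1
  I1 <- (Gt == 1) * 1
  p0 <- colSums(I0) / t
  p1 <- colSums(I1) / t
  list(
    t = t, n = ncol(Gt),
    I0 = I0[seq_len(t - 1), , drop = FALSE],
    I1 = I1[seq_len(t - 1), , drop = FALSE],
    p0 = p0, p1 = p1,
    q00 = p0 * (1 - p0), q11 = p1 * (1 - p1), q01 = p0 * p1
  )
}

# GCMH statistic of the subject set marked 1 in each column of Z (n x B).
# Vectorized over columns; the 2x2 pooled column factor S_b is pseudo-inverted
# in closed form (full-rank inverse, or S / tr(S)^2 for rank one).
engine_stat <- function(pre, Z, rtol = 1e-10) {
  t <- pre$t
  U0 <- pre$I0 %*% Z
  U1 <- pre$I1 %*% Z
  sp0 <- drop(crossprod(pre$p0, Z))
  sp1 <- drop(crossprod(pre$p1, Z))
  X <- sweep(U0, 2, sp0)
  Y <- sweep(U1, 2, sp1)
  SXX <- colSums(X^2) + colSums(X)^2
  SXY <- colSums(X * Y) + colSums(X) * colSums(Y)
  SYY <- colSums(Y^2) + colSums(Y)^2

  a <- drop(crossprod(pre$q00, Z))
  d <- drop(crossprod(pre$q11, Z))
  b <- -drop(crossprod(pre$q01, Z))
  tr <- a + d
  det <- pmax(a * d - b^2, 0)
  lmax <- (tr + sqrt(pmax(tr^2 - 4 * det, 0))) / 2
  lmin <- ifelse(lmax > 0, det / lmax, 0)
  full <- lmax > 0 & lmin > rtol * lmax
  rank1 <- !full & lmax > 0

  ia <- ib <- id <- numeric(length(a))
  ia[full] <- d[full] / det[full]
  id[full] <- a[full] / det[full]
  ib[full] <- -b[full] / det[full]
  ia[rank1] <- a[rank1] / tr[rank1]^2
  id[rank1] <- d[rank1] / tr[rank1]^2
  ib[rank1] <- b[rank1] / tr[rank1]^2

  (t - 1) / t * (ia * SXX + 2 * ib * SXY + id * SYY)
}

# n x B matrix of uniformly random case-membership indicators with fixed
# group size
perm_memberships <- function(n, n_case, B) {
  Z <- matrix(0, n, B)
  for (b in seq_len(B)) {
    Z[sample.int(n, n_case), b] <- 1
  }
  Z
}

# Observed statistics plus B permuted log-ratio statistics for one gene.
# Returns observed cmh_case / cmh_control / T and the permuted T vector with
# NAs for permutations where either group statistic fell at or below tau.
engine_gene <- function(counts, ic, B, tau = 1e-12) {
  pre <- engine_precompute(counts)
  n <- nrow(counts)
  Zo <- matrix(as.numeric(ic), n, 1)
  cmh_case <- engine_stat(pre, Zo)
  cmh_control <- engine_stat(pre, 1 - Zo)
  T_obs <- if (cmh_case > tau && cmh_control > tau) {
    log(cmh_case) - log(cmh_control)
  } else {
    NA_real_
  }
  T_perm <- NULL
  if (B > 0L) {
    Z <- perm_memberships(n, sum(ic), B)
    cs <- engine_stat(pre, Z)
    ks <- engine_stat(pre, 1 - Z)
    T_perm <- ifelse(cs > tau & ks > tau, log(cs) - log(ks), NA_real_)
  }
  list(cmh_case = cmh_case, cmh_control = cmh_control,
       T_obs = T_obs, T_perm = T_perm)
}

# extract and clean one gene's submatrix; mirrors build_gene_tables() but
# stays on the matrix representation the engine needs
gene_counts <- function(x, variants,
                        missing_policy = c("fail", "drop_variant", "drop_subject"),
                        gene_id = NULL) {
  missing_policy <- match.arg(missing_policy)
  ic <- is_case(x)
  unknown <- setdiff(variants, colnames(x$counts))
  if (length(unknown) > 0L) {
    stop(sprintf("gene '%s' references unknown variants: %s",
                 gene_id %||% "?", paste(unknown, collapse = ", ")))
  }
  counts <- x$counts[, variants, drop = FALSE]
  dropped_variants <- character(0)
  dropped_subjects <- character(0)
  if (anyNA(counts)) {
    if (missing_policy == "fail") {
      idx <- which(is.na(counts), arr.ind = TRUE)[1, ]
      stop(sprintf(
        "missing genotype for subject '%s' at variant '%s' (missing_policy = \"fail\")",
        rownames(counts)[idx[1]], colnames(counts)[idx[2]]
      ))
    }
    if (missing_policy == "drop_variant") {
      dropped_variants <- colnames(counts)[colSums(is.na(counts)) > 0L]
      counts <- counts[, !colnames(counts) %in% dropped_variants, drop = FALSE]
    } else {
      dropped_subjects <- rownames(counts)[rowSums(is.na(counts)) > 0L]
      keep <- !rownames(counts) %in% dropped_subjects
      counts <- counts[keep, , drop = FALSE]
      ic <- ic[keep]
    }
  }
  list(counts = counts, ic = ic,
       dropped_variants = dropped_variants,
       dropped_subjects = dropped_subjects)
}
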