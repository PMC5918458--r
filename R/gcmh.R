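#' Exact null moments of a subject table
#'
#' With all margins fixed, a subject's `t x 3` table follows the multiple
#' hypergeometric distribution; because every row margin is 1 this is the
#' uniform law over the distinct assignments of the column labels to the `t`
#' rows. The mean and covariance of the vectorized table have closed forms.
#' Writing `P_row = (1, ..., 1)'/t` and `P_col = column margins / t`, and
#' vectorizing row-major (cell `(j, k)` at index `3(j-1) + k + 1`),
#'
#' \deqn{m = t (P_{row} \otimes P_{col})}
#' \deqn{V = \frac{t^2}{t-1}\,(D_{P_{row}} - P_{row}P_{row}')\otimes
#'           (D_{P_{col}} - P_{col}P_{col}')}
#'
#' where `D_v` is the diagonal matrix of `v`. Both are validated in the test
#' suite against brute-force enumeration of all margin-preserving tables.
#'
#' @param tab A [build_subject_table()] result (or any `t x 3` 0/1 matrix
#'   with unit row margins), `t >= 2`.
#' @return A list of class `table_moments`: `P_row`, `P_col`, `m` (length
#'   `3t`), `V` (`3t x 3t`).
#' @examples
#' tm <- table_moments(build_subject_table(c(0, 1, 2)))
#' matrix(tm$m, ncol = 3, byrow = TRUE)  # each row is the genotype histogram / t
#' @export
table_moments <- function(tab) {
  t <- nrow(tab)
  if (t < 2L) {
    stop("table_moments() requires t >= 2 variants; the null covariance is undefined at t = 1")
  }
  check_subject_table(tab)
  P_row <- rep(1 / t, t)
  P_col <- unname(colSums(tab)) / t
  m <- rep(P_col, times = t)  # = t * (P_row %x% P_col)
  V <- (t^2 / (t - 1)) *
    kronecker(diag(P_row) - tcrossprod(P_row),
              diag(P_col) - tcrossprod(P_col))
  structure(list(P_row = P_row, P_col = P_col, m = m, V = V),
            class = "table_moments")
}

check_subject_table <- function(tab) {
  if (!is.matrix(tab) || ncol(tab) != 3L) {
    stop("a subject table must be a t x 3 matrix")
  }
  if (!all(tab %in% c(0L, 1L)) || !all(rowSums(tab) == 1L)) {
    stop("subject table cells must be 0/1 with every row margin equal to 1")
  }
  invisible(tab)
}

#' Reduction matrix dropping the redundant row and column
#'
#' The table's degrees of freedom are `2(t - 1)`: margins fix the last
#' variant row and the `k = 2` column. `reduction_matrix(t)` is the
#' `2(t-1) x 3t` binary matrix `(I_{t-1} | 0) %x% (I_2 | 0)` that deletes
#' them from a row-major vectorized table.
#'
#' @param t Number of variants, at least 2.
#' @return A `2(t-1) x 3t` 0/1 matrix.
#' @examples
#' reduction_matrix(2)
#' @export
reduction_matrix <- function(t) {
  if (t < 2L) {
    stop("reduction_matrix() requires t >= 2")
  }
  kronecker(cbind(diag(t - 1), rep(0, t - 1)),
            cbind(diag(2), rep(0, 2)))
}

#' Generalized Cochran-Mantel-Haenszel statistic
#'
#' Pools a set of subject strata (all with the same `t`) into the GCMH
#' quadratic form for general association between variant and minor-allele
#' count. With `A` the [reduction_matrix()], `G = sum_i A (n_i - m_i)` and
#' `VarG = sum_i A V_i A'` (subjects independent; `m_i`, `V_i` from
#' [table_moments()]), the statistic is
#'
#' \deqn{GCMH = G' \, VarG^{+} \, G}
#'
#' with `VarG^+` the Moore-Penrose pseudo-inverse (eigenvalues below
#' `rtol` times the largest treated as zero). Rank-deficient `VarG` is
#' generic when variants are monomorphic or allele diversity is low; the
#' `degenerate` flag records it. Asymptotically (information accumulating
#' over many strata) the statistic is chi-squared with `2(t - 1)` degrees of
#' freedom.
#'
#' The per-subject covariance has the Kronecker form `c * R %x% C_i` with a
#' common row factor, so `VarG` is assembled as `c * R~ %x% sum_i C~_i`
#' without materializing any `3t x 3t` matrix; the test suite checks this
#' against the literal sum of `A V_i A'`.
#'
#' @param tables List of [build_subject_table()] strata sharing the same
#'   `t >= 2` (e.g. the `case` component of [build_gene_tables()]).
#' @param rtol Relative eigenvalue tolerance of the pseudo-inverse.
#' @return A list of class `gcmh_result`: `statistic`, `df = 2(t-1)`, `G`,
#'   `VarG`, `rank`, `degenerate`, `t`, `n_tables`.
#' @examples
#' tabs <- lapply(list(c(0, 1, 2), c(1, 0, 2), c(0, 0, 1)), build_subject_table)
#' gcmh_statistic(tabs)
#' @export
gcmh_statistic <- function(tables, rtol = 1e-10) {
  if (length(tables) == 0L) {
    stop("gcmh_statistic() needs at least one subject table")
  }
  ts <- vapply(tables, nrow, integer(1))
  t <- ts[1]
  if (any(ts != t)) {
    stop("all subject tables must have the same number of variants")
  }
  if (t < 2L) {
    stop("gcmh_statistic() requires t >= 2; single-variant genes go to Fisher's exact test")
  }

  Gmat <- matrix(0, t - 1, 2)   # rows: variants 1..t-1, cols: k = 0, 1
  S <- matrix(0, 2, 2)          # sum of per-subject 2x2 column factors
  for (tab in tables) {
    check_subject_table(tab)
    p <- colSums(tab) / t
    Gmat <- Gmat + tab[seq_len(t - 1), 1:2, drop = FALSE] -
      matrix(p[1:2], t - 1, 2, byrow = TRUE)
    S <- S + diag(p[1:2]) - tcrossprod(p[1:2])
  }
  Rt <- diag(t - 1) / t - matrix(1 / t^2, t - 1, t - 1)  # reduced row factor
  VarG <- (t^2 / (t - 1)) * kronecker(Rt, S)
  G <- as.vector(t(Gmat))  # (j, k) row-major, matching reduction_matrix()

  pv <- pinv_sym(VarG, rtol = rtol)
  statistic <- drop(crossprod(G, pv$inv %*% G))
  if (max(abs(G)) < 1e-12) statistic <- 0
  structure(
    list(
      statistic = statistic,
      df = 2L * (t - 1L),
      G = G,
      VarG = VarG,
      rank = pv$rank,
      degenerate = pv$rank < 2L * (t - 1L) || max(abs(G)) < 1e-12,
      t = t,
      n_tables = length(tables)
    ),
    class = "gcmh_result"
  )
}

#' @export
print.gcmh_result <- function(x, ...) {
  cat(sprintf(
    "GCMH = %.4f on df = %d (%d strata, t = %d, rank %d%s)\n",
    x$statistic, x$df, x$n_tables, x$t, x$rank,
    if (x$degenerate) ", degenerate" else ""
  ))
  invisible(x)
}
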