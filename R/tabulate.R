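#' Build one subject's SNV-by-genotype contingency table
#'
#' For a gene with `t` variants, a subject's genotypes are laid out as a
#' `t x 3` 0/1 table: cell `(j, k)` is 1 exactly when the subject carries
#' `k` minor alleles at variant `j` (k = 0, 1, 2). Every row margin is 1,
#' the column margins are the subject's genotype histogram over the gene,
#' and the grand total is `t`. These tables, one stratum per subject, are
#' the raw material of the GCMH statistic.
#'
#' @param genotype_row Vector of minor-allele counts in `{0, 1, 2}`, one per
#'   variant; no missing values. Names, if present, become row names.
#' @param subject_id Optional identifier used in error messages and stored
#'   as an attribute.
#' @return Integer matrix of class `subject_table` with columns `"0"`,
#'   `"1"`, `"2"`.
#' @examples
#' build_subject_table(c(rs1 = 0, rs2 = 1, rs3 = 2))
#' @export
build_subject_table <- function(genotype_row, subject_id = NULL) {
  g <- as.integer(genotype_row)
  t <- length(g)
  if (t < 1L) {
    stop("a subject table needs at least one variant")
  }
  bad <- which(is.na(g) | !(g %in% 0:2))
  if (length(bad) > 0L) {
    vname <- names(genotype_row)[bad[1]] %||% as.character(bad[1])
    stop(sprintf(
      "invalid genotype for subject '%s' at variant '%s': entries must be 0, 1 or 2 with no missing values",
      subject_id %||% "?", vname
    ))
  }
  tab <- matrix(0L, nrow = t, ncol = 3,
                dimnames = list(names(genotype_row), c("0", "1", "2")))
  tab[cbind(seq_len(t), g + 1L)] <- 1L
  structure(tab, class = c("subject_table", "matrix", "array"),
            subject_id = subject_id)
}

# genotype vector back out of a table (argmax over columns; rows are 0/1
# with a single 1, so this is exact)
table_genotypes <- function(tab) {
  as.integer(max.col(tab) - 1L)
}

#' Build the per-subject tables of one gene, split by phenotype
#'
#' Extracts the gene's variants from the genotype matrix, applies the
#' missing-data policy, and returns one [build_subject_table()] stratum per
#' retained subject, partitioned into cases and controls.
#'
#' Missing policies: `"fail"` (default) stops at the first missing call,
#' naming subject and variant; `"drop_variant"` removes any variant with a
#' missing call in any subject; `"drop_subject"` removes any subject with a
#' missing call at the gene's variants. Drops are recorded in the return
#' value, never silent.
#'
#' @param x An [exat_genotypes()] object with labels.
#' @param variants Character vector of the gene's variant IDs (ordered as
#'   desired), or a bare count subset is not supported -- use IDs.
#' @param gene_id Optional gene identifier carried through to reports.
#' @param missing_policy One of `"fail"`, `"drop_variant"`, `"drop_subject"`.
#' @return A list of class `gene_tables`: `case` and `control` (lists of
#'   `subject_table`), `t` (variants retained), `gene_id`,
#'   `dropped_variants`, `dropped_subjects`, and `untestable` (`TRUE` when
#'   no variant survives the policy).
#' @export
build_gene_tables <- function(x, variants, gene_id = NULL,
                              missing_policy = c("fail", "drop_variant", "drop_subject")) {
  missing_policy <- match.arg(missing_policy)
  stopifnot(inherits(x, "exat_genotypes"))
  ic <- is_case(x)
  unknown <- setdiff(variants, colnames(x$counts))
  if (length(unknown) > 0L) {
    stop("unknown variants: ", paste(unknown, collapse = ", "))
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
      bad <- colnames(counts)[colSums(is.na(counts)) > 0L]
      dropped_variants <- bad
      counts <- counts[, setdiff(colnames(counts), bad), drop = FALSE]
    } else {
      bad <- rownames(counts)[rowSums(is.na(counts)) > 0L]
      dropped_subjects <- bad
      keep <- !(rownames(counts) %in% bad)
      counts <- counts[keep, , drop = FALSE]
      ic <- ic[keep]
    }
  }

  t <- ncol(counts)
  untestable <- t == 0L || nrow(counts) == 0L || !any(ic) || all(ic)
  make <- function(rows) {
    lapply(rows, function(s) build_subject_table(counts[s, ], subject_id = s))
  }
  structure(
    list(
      case = if (untestable) list() else make(rownames(counts)[ic]),
      control = if (untestable) list() else make(rownames(counts)[!ic]),
      t = t,
      gene_id = gene_id,
      dropped_variants = dropped_variants,
      dropped_subjects = dropped_subjects,
      untestable = untestable
    ),
    class = "gene_tables"
  )
}

#' @export
print.gene_tables <- function(x, ...) {
  cat(sprintf(
    "<gene_tables> %s: t = %d, %d case + %d control strata%s\n",
    x$gene_id %||% "(unnamed)", x$t, length(x$case), length(x$control),
    if (x$untestable) " [untestable]" else ""
  ))
  invisible(x)
}
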