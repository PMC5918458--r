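#' Genotype matrix with case/control labels
#'
#' Bundles a subjects-by-variants matrix of minor-allele counts with the
#' per-subject dichotomous phenotype and optional variant coordinates. This is
#' the container every analysis function in the package consumes.
#'
#' @param counts Integer matrix, subjects in rows and variants in columns.
#'   Non-missing entries must be 0, 1 or 2 (the number of minor alleles the
#'   subject carries at that site); `NA` marks a missing call.
#' @param labels Per-subject phenotype: a logical vector (`TRUE` = case), a
#'   0/1 numeric vector (1 = case), or a character/factor vector with values
#'   `"case"`/`"control"`. May be `NULL` for genotype-only containers; all
#'   testing functions require labels with both groups present.
#' @param subject_ids,variant_ids Unique identifiers; defaults are taken from
#'   `dimnames(counts)` or generated.
#' @param variant_info Optional `data.frame` with columns `variant_id`,
#'   `chrom`, `pos` (1-based) used for BED interval matching and for ordering
#'   variants within genes.
#'
#' @return An object of class `exat_genotypes`: a list with elements
#'   `counts`, `labels` (factor with levels `control`, `case` or `NULL`),
#'   and `variant_info`.
#' @examples
#' g <- exat_genotypes(matrix(c(0, 1, 2, 0), 2, 2), labels = c(1, 0))
#' g
#' @export
exat_genotypes <- function(counts, labels = NULL, subject_ids = NULL,
                           variant_ids = NULL, variant_info = NULL) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  n <- nrow(counts)
  m <- ncol(counts)
  if (n < 2L) {
    stop("at least 2 subjects are required")
  }
  subject_ids <- as.character(subject_ids %||% rownames(counts) %||% paste0("S", seq_len(n)))
  variant_ids <- as.character(variant_ids %||% colnames(counts) %||% paste0("V", seq_len(m)))
  if (length(subject_ids) != n || anyDuplicated(subject_ids)) {
    stop("subject_ids must be unique and match the number of rows")
  }
  if (length(variant_ids) != m || anyDuplicated(variant_ids)) {
    stop("variant_ids must be unique and match the number of columns")
  }
  dimnames(counts) <- list(subject_ids, variant_ids)

  bad <- which(!is.na(counts) & !(counts %in% 0:2), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf(
      "genotype of subject '%s' at variant '%s' is %s; minor-allele counts must be 0, 1 or 2",
      subject_ids[bad[1, 1]], variant_ids[bad[1, 2]], counts[bad[1, , drop = FALSE]]
    ))
  }

  if (!is.null(labels)) {
    labels <- as_phenotype(labels, n)
  }
  if (!is.null(variant_info)) {
    variant_info <- as.data.frame(variant_info)
    need <- c("variant_id", "chrom", "pos")
    if (!all(need %in% names(variant_info))) {
      stop("variant_info needs columns variant_id, chrom, pos")
    }
    if (!all(variant_ids %in% variant_info$variant_id)) {
      stop("variant_info must cover every variant in the matrix")
    }
    variant_info <- variant_info[match(variant_ids, variant_info$variant_id), , drop = FALSE]
    rownames(variant_info) <- NULL
  }

  structure(
    list(counts = counts, labels = labels, variant_info = variant_info),
    class = "exat_genotypes"
  )
}

as_phenotype <- function(labels, n) {
  if (length(labels) != n) {
    stop("labels must have one entry per subject")
  }
  if (is.logical(labels)) {
    lab <- ifelse(labels, "case", "control")
  } else if (is.numeric(labels)) {
    if (!all(labels %in% c(0, 1))) {
      stop("numeric labels must be 0 (control) or 1 (case)")
    }
    lab <- ifelse(labels == 1, "case", "control")
  } else {
    lab <- tolower(as.character(labels))
    if (!all(lab %in% c("case", "control"))) {
      stop("character labels must be 'case' or 'control'")
    }
  }
  factor(lab, levels = c("control", "case"))
}

#' @export
print.exat_genotypes <- function(x, ...) {
  cat(sprintf(
    "<exat_genotypes> %d subjects x %d variants\n",
    nrow(x$counts), ncol(x$counts)
  ))
  if (!is.null(x$labels)) {
    tab <- table(x$labels)
    cat(sprintf("  labels: %d control / %d case\n", tab[["control"]], tab[["case"]]))
  } else {
    cat("  labels: none\n")
  }
  nmiss <- sum(is.na(x$counts))
  if (nmiss > 0L) cat(sprintf("  missing calls: %d\n", nmiss))
  invisible(x)
}

#' @export
dim.exat_genotypes <- function(x) dim(x$counts)

is_case <- function(x) {
  if (is.null(x$labels)) {
    stop("phenotype labels are required for this operation")
  }
  ic <- x$labels == "case"
  if (!any(ic) || all(ic)) {
    stop("both case and control subjects are required")
  }
  ic
}

#' Read a genotype matrix from a TSV file
#'
#' Dialect: header row of variant IDs, first column of subject IDs, cells in
#' `{0, 1, 2, NA}`.
#'
#' @param path File path.
#' @param labels Optional phenotype (see [exat_genotypes()]) or the path of a
#'   two-column TSV `subject_id<TAB>label` (labels `case`/`control` or 0/1),
#'   matched to subjects by ID.
#' @return An [exat_genotypes()] object.
#' @export
read_genotype_tsv <- function(path, labels = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          colClasses = "character")
  subject_ids <- df[[1]]
  counts <- as.matrix(df[, -1, drop = FALSE])
  suppressWarnings(storage.mode(counts) <- "integer")
  if (is.character(labels) && length(labels) == 1L && file.exists(labels)) {
    labels <- read_labels_tsv(labels, subject_ids)
  }
  exat_genotypes(counts, labels = labels, subject_ids = subject_ids,
                 variant_ids = colnames(df)[-1])
}

#' Write a genotype matrix as TSV
#'
#' Inverse of [read_genotype_tsv()]; labels, if present, go to
#' `<path>.labels` in the two-column dialect.
#'
#' @param x An [exat_genotypes()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_genotype_tsv <- function(x, path) {
  df <- data.frame(subject_id = rownames(x$counts), x$counts,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(x$labels)) {
    utils::write.table(
      data.frame(subject_id = rownames(x$counts), label = as.character(x$labels)),
      paste0(path, ".labels"),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
  }
  invisible(path)
}

#' @rdname read_genotype_tsv
#' @param subject_ids Subject order to match the labels against.
#' @export
read_labels_tsv <- function(path, subject_ids) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          colClasses = "character")
  idx <- match(subject_ids, df[[1]])
  if (anyNA(idx)) {
    stop("label file is missing subjects: ",
         paste(subject_ids[is.na(idx)], collapse = ", "))
  }
  lab <- df[[2]][idx]
  suppressWarnings(num <- as.numeric(lab))
  if (!anyNA(num)) num else lab
}

#' Read genotypes from a VCF file
#'
#' Uses the GT field; phased and unphased calls are treated identically and
#' `./.` is missing. Multi-allelic sites are split into one bi-allelic record
#' per ALT allele (IDs suffixed `_<k>`); genotypes carrying a different ALT
#' allele are set to missing in that record. ALT dosage is re-oriented to
#' minor-allele counts: any variant whose pooled ALT frequency exceeds 0.5 is
#' flipped (`2 - dosage`), with a message naming the flipped variants.
#'
#' @inheritParams read_genotype_tsv
#' @return An [exat_genotypes()] object with `variant_info` populated from
#'   CHROM/POS.
#' @export
read_genotype_vcf <- function(path, labels = NULL) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF requires the vcfR package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  gt <- vcfR::extract.gt(v, element = "GT")
  subject_ids <- colnames(gt)
  n <- length(subject_ids)

  counts_cols <- list()
  info_rows <- list()
  for (r in seq_len(nrow(gt))) {
    alts <- strsplit(fix[r, "ALT"], ",", fixed = TRUE)[[1]]
    vid0 <- fix[r, "ID"]
    if (is.na(vid0) || vid0 == ".") {
      vid0 <- paste0(fix[r, "CHROM"], ":", fix[r, "POS"])
    }
    alleles <- strsplit(gt[r, ], "[/|]")
    for (k in seq_along(alts)) {
      dos <- vapply(alleles, function(a) {
        if (length(a) == 0L || anyNA(a) || any(a == ".")) return(NA_integer_)
        ai <- suppressWarnings(as.integer(a))
        if (anyNA(ai)) return(NA_integer_)
        if (any(!ai %in% c(0L, k))) return(NA_integer_)  # other ALT allele present
        sum(ai == k)
      }, integer(1))
      vid <- if (length(alts) > 1L) paste0(vid0, "_", k) else vid0
      counts_cols[[vid]] <- dos
      info_rows[[vid]] <- data.frame(
        variant_id = vid, chrom = fix[r, "CHROM"],
        pos = as.integer(fix[r, "POS"]), stringsAsFactors = FALSE
      )
    }
  }
  counts <- do.call(cbind, counts_cols)
  rownames(counts) <- subject_ids

  # orient to minor-allele counts
  freq <- colMeans(counts, na.rm = TRUE) / 2
  flip <- which(!is.na(freq) & freq > 0.5)
  if (length(flip) > 0L) {
    counts[, flip] <- 2L - counts[, flip]
    message("re-oriented to minor allele: ",
            paste(colnames(counts)[flip], collapse = ", "))
  }
  if (is.character(labels) && length(labels) == 1L && file.exists(labels)) {
    labels <- read_labels_tsv(labels, subject_ids)
  }
  exat_genotypes(counts, labels = labels, subject_ids = subject_ids,
                 variant_ids = colnames(counts),
                 variant_info = do.call(rbind, info_rows))
}

#' Read a gene-to-variant map
#'
#' Two dialects. A two-column TSV `gene_id<TAB>variant_id` (one row per pair)
#' is read directly. A BED file (`chrom  start  end  gene_id`, half-open
#' 0-based intervals) is matched against the 1-based variant positions in
#' `x$variant_info`: variant at position p belongs to the interval when
#' `start < p <= end`.
#'
#' @param path File path.
#' @param x An [exat_genotypes()] object; required for the BED dialect,
#'   optional for TSV (when given, map entries are validated and variants
#'   within each gene are ordered by genomic position, ties broken by ID).
#' @param format `"tsv"` or `"bed"`; guessed from the file extension.
#' @return Named list mapping `gene_id` to a character vector of variant IDs.
#' @export
read_gene_map <- function(path, x = NULL, format = c("auto", "tsv", "bed")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed" else "tsv"
  }
  if (format == "tsv") {
    df <- utils::read.table(path, header = FALSE, sep = "\t",
                            colClasses = "character")
    map <- split(df[[2]], df[[1]])
  } else {
    if (is.null(x) || is.null(x$variant_info)) {
      stop("BED gene maps need genotypes with variant_info (chrom/pos)")
    }
    bed <- utils::read.table(path, header = FALSE, sep = "\t")
    names(bed)[1:4] <- c("chrom", "start", "end", "gene_id")
    vi <- x$variant_info
    map <- lapply(split(bed, bed$gene_id), function(b) {
      hit <- logical(nrow(vi))
      for (r in seq_len(nrow(b))) {
        hit <- hit | (vi$chrom == b$chrom[r] & vi$pos > b$start[r] & vi$pos <= b$end[r])
      }
      vi$variant_id[hit]
    })
    map <- map[vapply(map, length, integer(1)) > 0L]
  }
  if (!is.null(x)) {
    map <- lapply(map, function(v) order_variants(v, x))
    known <- unlist(map, use.names = FALSE)
    missing <- setdiff(known, colnames(x$counts))
    if (length(missing) > 0L) {
      stop("gene map references unknown variants: ",
           paste(utils::head(missing, 5), collapse = ", "))
    }
  }
  map
}

# Deterministic within-gene variant order: genomic position when known,
# ties (and the no-coordinate case) broken by variant ID. The GCMH statistic
# is order-invariant; this only fixes report layout.
order_variants <- function(variant_ids, x) {
  vi <- x$variant_info
  if (is.null(vi)) {
    return(variant_ids)
  }
  idx <- match(variant_ids, vi$variant_id)
  if (anyNA(idx)) {
    return(variant_ids)
  }
  variant_ids[order(vi$chrom[idx], vi$pos[idx], variant_ids)]
}

validate_gene_map <- function(map, x) {
  if (length(map) == 0L) stop("empty gene map")
  if (is.null(names(map)) || anyDuplicated(names(map))) {
    stop("gene map must have unique gene_id names")
  }
  missing <- setdiff(unlist(map, use.names = FALSE), colnames(x$counts))
  if (length(missing) > 0L) {
    stop("gene map references unknown variants: ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  invisible(map)
}
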