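#' The log-ratio association statistic
#'
#' The gene-level test statistic is the log ratio of the GCMH statistics
#' computed separately in the two phenotype groups,
#' \deqn{T = \log(CMH_{case}) - \log(CMH_{control}),}
#' so a gene whose variant/minor-allele association differs in intensity
#' between groups pushes `T` away from 0. When either group's statistic is
#' at or below `tau` the log ratio is numerically meaningless and `T` is
#' reported undefined rather than infinite.
#'
#' @param case_tables,control_tables Lists of [build_subject_table()] strata
#'   for the two groups (same `t`), e.g. from [build_gene_tables()].
#' @param tau Positive threshold below which a group statistic counts as zero.
#' @return List with `cmh_case`, `cmh_control`, `T` (`NA` when undefined),
#'   `defined`, and the per-group `degenerate` flags.
#' @examples
#' g <- generate_ipmn_like_fixture(seed = 1, n_genes = 5)
#' tabs <- build_gene_tables(g$genotypes, g$gene_map[[2]])
#' exat_statistic(tabs$case, tabs$control)
#' @export
exat_statistic <- function(case_tables, control_tables, tau = 1e-12) {
  if (length(case_tables) == 0L || length(control_tables) == 0L) {
    stop("both phenotype groups must be non-empty")
  }
  gc_case <- gcmh_statistic(case_tables)
  gc_control <- gcmh_statistic(control_tables)
  if (gc_case$t != gc_control$t) {
    stop("case and control tables must share the same variant set")
  }
  defined <- gc_case$statistic > tau && gc_control$statistic > tau
  list(
    cmh_case = gc_case$statistic,
    cmh_control = gc_control$statistic,
    T = if (defined) log(gc_case$statistic) - log(gc_control$statistic) else NA_real_,
    defined = defined,
    degenerate_case = gc_case$degenerate,
    degenerate_control = gc_control$degenerate
  )
}

exat_result_row <- function(gene_id, t, cmh_case = NA_real_, cmh_control = NA_real_,
                            T = NA_real_, p_value = NA_real_, method, B = NA_integer_,
                            flags = "") {
  tibble::tibble(
    gene_id = gene_id %||% NA_character_, t = as.integer(t),
    cmh_case = cmh_case, cmh_control = cmh_control, T = T,
    p_value = p_value, method = method, B = as.integer(B), flags = flags
  )
}

#' Permutation p-value for one gene
#'
#' Case/control labels are reassigned uniformly at random `B` times,
#' preserving the group sizes, and the two-sided p-value is the
#' finite-sample-valid estimator
#' \deqn{p = (1 + \#\{b: |T_b| \ge |T_{obs}|\}) / (B_{def} + 1),}
#' where `B_def` counts permutations with a defined statistic; permutations
#' in which either group's GCMH falls to zero are excluded and their count
#' recorded in `flags`.
#'
#' @param x An [exat_genotypes()] object with both phenotype groups.
#' @param variants Variant IDs of the gene (at least 2 after the missing
#'   policy; single-variant genes belong to [fisher_single_snv()]).
#' @param B Number of permutations.
#' @param seed Optional integer seed; the caller's RNG stream is restored
#'   afterwards.
#' @param gene_id Optional identifier carried into the result.
#' @param missing_policy See [build_gene_tables()].
#' @param tau Zero-statistic threshold, see [exat_statistic()].
#' @return List with `result` (one-row tibble: `gene_id`, `t`, `cmh_case`,
#'   `cmh_control`, `T`, `p_value`, `method`, `B`, `flags`) and `null` (the
#'   permutation null: `B`, `T_perm`, `mu_hat`, `sigma_hat`, `n_undefined`).
#' @export
permutation_pvalue <- function(x, variants, B = 10000, seed = NULL,
                               gene_id = NULL, missing_policy = "fail",
                               tau = 1e-12) {
  gene_test(x, variants, gene_id, missing_policy, tau,
            mode = "permutation", B = B, seed = seed)
}

#' Normal-approximation p-value for one gene
#'
#' The permutation null of `T` is close to normal, so rather than running
#' thousands of permutations, a small number `B_small` is used to estimate
#' its first two moments and the p-value is the Gaussian tail
#' \deqn{p = 2\,(1 - \Phi(|T_{obs} - \hat\mu| / \hat\sigma)).}
#' When `sigma_hat` is 0 the p-value is 1 if `T_obs` equals `mu_hat` and
#' flagged undefined otherwise.
#'
#' @inheritParams permutation_pvalue
#' @param B_small Number of permutations used for moment estimation
#'   (at least 10).
#' @return As [permutation_pvalue()]; `null` carries `mu_hat`, `sigma_hat`.
#' @export
normal_approx_pvalue <- function(x, variants, B_small = 100, seed = NULL,
                                 gene_id = NULL, missing_policy = "fail",
                                 tau = 1e-12) {
  if (B_small < 10) {
    stop("B_small must be at least 10")
  }
  gene_test(x, variants, gene_id, missing_policy, tau,
            mode = "normal_approx", B = B_small, seed = seed)
}

gene_test <- function(x, variants, gene_id, missing_policy, tau, mode, B, seed) {
  gc <- gene_counts(x, variants, missing_policy, gene_id = gene_id)
  drop_flags <- join_flags(
    if (length(gc$dropped_variants) > 0L) {
      sprintf("dropped_variants=%d", length(gc$dropped_variants))
    } else "",
    if (length(gc$dropped_subjects) > 0L) {
      sprintf("dropped_subjects=%d", length(gc$dropped_subjects))
    } else ""
  )
  t <- ncol(gc$counts)
  if (t < 2L) {
    stop(sprintf("gene '%s' has t = %d variants after the missing policy; need t >= 2 (t = 1 is handled by fisher_single_snv())",
                 gene_id %||% "?", t))
  }
  if (sum(gc$ic) < 2L || sum(!gc$ic) < 2L) {
    stop("both groups need at least 2 subjects")
  }

  eng <- with_seed(seed, engine_gene(gc$counts, gc$ic, B = B, tau = tau))
  T_perm <- eng$T_perm
  n_undef <- sum(is.na(T_perm))
  defined <- !is.na(eng$T_obs)
  flags <- join_flags(
    drop_flags,
    if (!defined) "undefined_T" else "",
    if (eng$cmh_case <= tau) "zero_cmh_case" else "",
    if (eng$cmh_control <= tau) "zero_cmh_control" else "",
    if (n_undef > 0L) sprintf("excluded_perms=%d", n_undef) else ""
  )

  Tb <- T_perm[!is.na(T_perm)]
  mu_hat <- if (length(Tb) > 0L) mean(Tb) else NA_real_
  sigma_hat <- if (length(Tb) > 1L) stats::sd(Tb) else NA_real_

  p <- NA_real_
  if (defined) {
    if (mode == "permutation") {
      # the permutation law of T has atoms; count ties robustly against
      # order-of-operations rounding so exact ties are never dropped
      p <- (1 + sum(abs(Tb) >= abs(eng$T_obs) - 1e-9)) / (length(Tb) + 1)
    } else if (length(Tb) < 2L) {
      flags <- join_flags(flags, "all_perms_undefined")
    } else if (sigma_hat == 0) {
      if (eng$T_obs == mu_hat) {
        p <- 1
      } else {
        flags <- join_flags(flags, "zero_sigma_hat")
      }
    } else {
      p <- 2 * stats::pnorm(-abs(eng$T_obs - mu_hat) / sigma_hat)
    }
  }

  list(
    result = exat_result_row(
      gene_id = gene_id, t = t,
      cmh_case = eng$cmh_case, cmh_control = eng$cmh_control,
      T = eng$T_obs, p_value = p, method = mode, B = B, flags = flags
    ),
    null = list(B = B, T_perm = T_perm, mu_hat = mu_hat,
                sigma_hat = sigma_hat, n_undefined = n_undef)
  )
}

#' Fisher's exact test for a single-variant gene
#'
#' A gene with one variant cannot form the `t x 3` strata, so association
#' between phenotype and minor-allele count is tested directly on the
#' `2 x 3` group-by-genotype table with Fisher's exact test (two-sided
#' probability-ordering rule; genotype columns absent from the data are
#' collapsed away first).
#'
#' @inheritParams permutation_pvalue
#' @param variant A single variant ID.
#' @return One-row tibble in the [analyze_all()] layout.
#' @export
fisher_single_snv <- function(x, variant, gene_id = NULL,
                              missing_policy = "fail") {
  gc <- gene_counts(x, variant, missing_policy, gene_id = gene_id)
  if (ncol(gc$counts) != 1L) {
    stop("fisher_single_snv() is for genes with exactly one variant")
  }
  if (!any(gc$ic) || all(gc$ic)) {
    stop("both phenotype groups must be non-empty")
  }
  tab <- table(
    factor(ifelse(gc$ic, "case", "control"), levels = c("case", "control")),
    factor(gc$counts[, 1], levels = 0:2)
  )
  tab <- tab[, colSums(tab) > 0, drop = FALSE]
  p <- if (ncol(tab) < 2L) 1 else stats::fisher.test(tab)$p.value
  exat_result_row(gene_id = gene_id, t = 1L, p_value = p,
                  method = "fisher_exact", B = NA_integer_, flags = "")
}

#' Test every gene of a study
#'
#' Runs the gene-level test over a gene map: the permutation test or the
#' normal-approximation shortcut for genes with 2 or more variants, and
#' Fisher's exact test for single-variant genes. Genes that cannot be tested
#' (e.g. all variants dropped by the missing policy, or a zero group
#' statistic) are reported with flags, never dropped. Each gene gets its own
#' RNG stream derived from `seed` by a stable hash of the gene ID, so
#' results do not depend on analysis order and reruns with the same seed are
#' bit-identical.
#'
#' @inheritParams permutation_pvalue
#' @param gene_map Named list mapping gene IDs to variant-ID vectors, as
#'   from [read_gene_map()].
#' @param method `"normal_approx"` or `"permutation"` for multi-variant
#'   genes.
#' @param B Permutations per gene: the full count for `"permutation"`, the
#'   moment-estimation count for `"normal_approx"`.
#' @param adjust Add a Benjamini-Hochberg `p_adj_BH` column (off by
#'   default).
#' @return Tibble with one row per gene: `gene_id`, `t`, `cmh_case`,
#'   `cmh_control`, `T`, `p_value`, `method`, `B`, `flags`
#'   (and `p_adj_BH` when `adjust = TRUE`).
#' @examples
#' fx <- generate_ipmn_like_fixture(seed = 7, n_genes = 8)
#' analyze_all(fx$genotypes, fx$gene_map, method = "normal_approx",
#'             B = 50, seed = 1)
#' @export
analyze_all <- function(x, gene_map, method = c("normal_approx", "permutation"),
                        B = if (method == "permutation") 10000 else 100,
                        seed = NULL, missing_policy = "fail", adjust = FALSE,
                        tau = 1e-12) {
  method <- match.arg(method)
  validate_gene_map(gene_map, x)
  rows <- vector("list", length(gene_map))
  for (i in seq_along(gene_map)) {
    gid <- names(gene_map)[i]
    gseed <- if (is.null(seed)) NULL else gene_seed(seed, gid)
    rows[[i]] <- tryCatch({
      vars <- gene_map[[i]]
      eff_t <- effective_t(x, vars, missing_policy)
      if (eff_t == 0L) {
        exat_result_row(gene_id = gid, t = 0L, method = method,
                        flags = "untestable")
      } else if (eff_t == 1L) {
        v1 <- if (missing_policy == "drop_variant") {
          vars[colSums(is.na(x$counts[, vars, drop = FALSE])) == 0L][1]
        } else {
          vars[1]
        }
        fisher_single_snv(x, v1, gene_id = gid,
                          missing_policy = missing_policy)
      } else if (method == "permutation") {
        permutation_pvalue(x, vars, B = B, seed = gseed, gene_id = gid,
                           missing_policy = missing_policy, tau = tau)$result
      } else {
        normal_approx_pvalue(x, vars, B_small = B, seed = gseed, gene_id = gid,
                             missing_policy = missing_policy, tau = tau)$result
      }
    }, error = function(e) {
      exat_result_row(gene_id = gid, t = length(gene_map[[i]]), method = method,
                      flags = join_flags("untestable", conditionMessage(e)))
    })
  }
  out <- do.call(rbind, rows)
  if (adjust) {
    out$p_adj_BH <- stats::p.adjust(out$p_value, method = "BH")
  }
  out
}

# number of usable variants for a gene under the missing policy
effective_t <- function(x, vars, missing_policy) {
  counts <- x$counts[, vars, drop = FALSE]
  if (missing_policy == "drop_variant") {
    sum(colSums(is.na(counts)) == 0L)
  } else {
    length(vars)
  }
}

#' Agreement panel between the shortcut and reference p-values
#'
#' Computes, for each moment-estimation budget in `B_small`, the
#' normal-approximation p-values of every multi-variant gene and compares
#' them with reference permutation p-values at `B_ref` permutations:
#' squared correlation, Kolmogorov-Smirnov p-value between the two p-value
#' samples, mean squared error, and Pearson and Spearman correlations.
#'
#' @inheritParams analyze_all
#' @param B_ref Reference permutation count.
#' @param B_small Vector of moment-estimation budgets.
#' @return Tibble with one row per `B_small` value and columns `B_small`,
#'   `n_genes`, `r_squared`, `ks_pvalue`, `mse`, `pearson`, `spearman`.
#' @export
diagnose_approx <- function(x, gene_map, B_ref = 10000,
                            B_small = c(20, 30, 50, 100), seed = NULL,
                            missing_policy = "fail") {
  validate_gene_map(gene_map, x)
  multi <- gene_map[vapply(gene_map, function(v) {
    effective_t(x, v, missing_policy) >= 2L
  }, logical(1))]
  ref <- analyze_all(x, multi, method = "permutation", B = B_ref,
                     seed = seed, missing_policy = missing_policy)
  out <- lapply(seq_along(B_small), function(j) {
    approx <- analyze_all(x, multi, method = "normal_approx", B = B_small[j],
                          seed = if (is.null(seed)) NULL else seed + j,
                          missing_policy = missing_policy)
    ok <- !is.na(ref$p_value) & !is.na(approx$p_value)
    pa <- approx$p_value[ok]
    pr <- ref$p_value[ok]
    ks <- suppressWarnings(stats::ks.test(pa, pr))
    tibble::tibble(
      B_small = B_small[j],
      n_genes = sum(ok),
      r_squared = stats::cor(pa, pr)^2,
      ks_pvalue = ks$p.value,
      mse = mean((pa - pr)^2),
      pearson = stats::cor(pa, pr),
      spearman = stats::cor(pa, pr, method = "spearman")
    )
  })
  do.call(rbind, out)
}

#' Write an [analyze_all()] results table as TSV
#'
#' @param results Tibble from [analyze_all()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results_tsv <- function(results, path) {
  utils::write.table(results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
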