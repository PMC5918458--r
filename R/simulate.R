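# Synthetic genotype / phenotype generators and the type-I-error harness.
#
# The generators draw per-variant minor-allele frequencies from a
# rare-biased Beta spectrum truncated away from frequencies unobservable at
# the sample size, and genotypes under Hardy-Weinberg equilibrium, either
# independently across sites or with first-order haplotype correlation
# (a Gaussian-copula AR(1) on each of the subject's two haplotypes).
# Phenotype labels are always assigned by random permutation, independent of
# the genotypes, so every dataset is a draw from the null of no association.

rbeta_truncated <- function(k, shape1, shape2, lower, upper = 0.5) {
  f <- stats::rbeta(k, shape1, shape2)
  bad <- f < lower | f > upper
  while (any(bad)) {
    f[bad] <- stats::rbeta(sum(bad), shape1, shape2)
    bad <- f < lower | f > upper
  }
  f
}

# genotypes for one group of subjects: n x t, HWE, optionally AR(1)
# haplotype copula with parameter rho
draw_genotypes <- function(n, maf, ld_model = "independent", rho = 0.9) {
  t <- length(maf)
  if (ld_model == "independent" || t == 1L) {
    return(matrix(stats::rbinom(n * t, 2, rep(maf, each = n)), n, t))
  }
  thr <- stats::qnorm(maf)
  one_hap <- function() {
    z <- numeric(t)
    z[1] <- stats::rnorm(1)
    for (j in 2:t) z[j] <- rho * z[j - 1] + sqrt(1 - rho^2) * stats::rnorm(1)
    as.integer(z < thr)
  }
  counts <- matrix(0L, n, t)
  for (i in seq_len(n)) counts[i, ] <- one_hap() + one_hap()
  counts
}

#' Generate one null dataset for a variant region
#'
#' Emulates testing a randomly chosen ~5-kb region under the global null:
#' the number of variants is Poisson with mean `region_length_bp *
#' variant_density` (default 30 for 5 kb, a Watterson-scale site density for
#' human-diversity sequence at these sample sizes), per-variant MAFs come
#' from `Beta(maf_shape1, maf_shape2)` truncated to `[1/(2n), 0.5]`, and
#' genotypes follow Hardy-Weinberg, independently across sites or with
#' first-order haplotype correlation `rho`. Labels are a random permutation
#' with exactly `round(n * case_fraction)` cases, independent of the
#' genotypes. Draws in which fewer than 2 variants are polymorphic in the
#' sample are resampled (up to `max_retries`).
#'
#' @param n_subjects Number of subjects.
#' @param case_fraction Fraction of cases (default 0.5).
#' @param region_length_bp Region length in base pairs.
#' @param variant_density Expected variants per base pair.
#' @param n_variants Fixed variant count overriding the Poisson draw.
#' @param maf_shape1,maf_shape2 Beta shape parameters of the MAF spectrum
#'   (defaults 0.3 and 3, biased toward rare variants).
#' @param ld_model `"independent"` or `"markov"`.
#' @param rho First-order haplotype correlation for `ld_model = "markov"`.
#' @param seed Optional seed (caller's RNG stream restored afterwards).
#' @param max_retries Resampling cap for degenerate draws.
#' @return List with `genotypes` (an [exat_genotypes()] with labels) and
#'   `gene_map` (a single entry `region` covering all variants).
#' @examples
#' d <- generate_null_dataset(20, seed = 1)
#' d$genotypes
#' @export
generate_null_dataset <- function(n_subjects, case_fraction = 0.5,
                                  region_length_bp = 5000,
                                  variant_density = 0.006,
                                  n_variants = NULL,
                                  maf_shape1 = 0.3, maf_shape2 = 3,
                                  ld_model = c("independent", "markov"),
                                  rho = 0.9, seed = NULL, max_retries = 100) {
  ld_model <- match.arg(ld_model)
  stopifnot(n_subjects >= 4, case_fraction > 0, case_fraction < 1)
  with_seed(seed, {
    counts <- NULL
    for (try in seq_len(max_retries)) {
      t <- n_variants %||% max(2L, stats::rpois(1, region_length_bp * variant_density))
      maf <- rbeta_truncated(t, maf_shape1, maf_shape2, 1 / (2 * n_subjects))
      cand <- draw_genotypes(n_subjects, maf, ld_model, rho)
      if (sum(apply(cand, 2, stats::var) > 0) >= 2L) {
        counts <- cand
        break
      }
    }
    if (is.null(counts)) {
      stop("could not draw a region with at least 2 polymorphic variants")
    }
    n_case <- round(n_subjects * case_fraction)
    labels <- rep(0L, n_subjects)
    labels[sample.int(n_subjects, n_case)] <- 1L
    g <- exat_genotypes(counts, labels = labels,
                        subject_ids = sprintf("S%03d", seq_len(n_subjects)),
                        variant_ids = sprintf("v%03d", seq_len(ncol(counts))))
    list(genotypes = g, gene_map = list(region = colnames(g$counts)))
  })
}

#' Type-I-error simulation study
#'
#' Repeats `n_replicates` times: draw a null region dataset with
#' [generate_null_dataset()], test it, and record the p-value. The empirical
#' type I error at each `alpha` is the rejection proportion among replicates
#' with a defined p-value, with Monte-Carlo standard error
#' `sqrt(rate * (1 - rate) / n_effective)`. Replicates whose gene is
#' untestable are excluded from the denominator and counted.
#'
#' @param n_subjects Sample size per replicate.
#' @param n_replicates Number of simulated datasets.
#' @param alphas Nominal levels to evaluate.
#' @param method `"normal_approx"` (default, with `B` moment-estimation
#'   permutations) or `"permutation"`.
#' @param B Permutations per test.
#' @param seed Master seed for the whole study.
#' @param ... Passed to [generate_null_dataset()].
#' @return Tibble of class `type1_error_table` with columns `n_subjects`,
#'   `alpha`, `n_effective`, `n_reject`, `rate`, `se`; the number of
#'   excluded replicates is in `attr(, "n_excluded")` and the p-values in
#'   `attr(, "p_values")`.
#' @examples
#' type1_error_study(20, n_replicates = 20, B = 20, seed = 1)
#' @export
type1_error_study <- function(n_subjects, n_replicates = 1000,
                              alphas = c(0.05, 0.01, 0.001),
                              method = c("normal_approx", "permutation"),
                              B = if (method == "normal_approx") 100 else 1000,
                              seed = NULL, ...) {
  method <- match.arg(method)
  stopifnot(n_replicates >= 1, all(alphas > 0), all(alphas <= 1))
  pvals <- with_seed(seed, {
    vapply(seq_len(n_replicates), function(r) {
      d <- generate_null_dataset(n_subjects, ...)
      res <- tryCatch(
        if (method == "normal_approx") {
          normal_approx_pvalue(d$genotypes, d$gene_map$region, B_small = B)$result
        } else {
          permutation_pvalue(d$genotypes, d$gene_map$region, B = B)$result
        },
        error = function(e) NULL
      )
      if (is.null(res)) NA_real_ else res$p_value
    }, numeric(1))
  })
  ok <- !is.na(pvals)
  n_eff <- sum(ok)
  rows <- lapply(alphas, function(a) {
    nr <- sum(pvals[ok] <= a)
    rate <- nr / n_eff
    tibble::tibble(
      n_subjects = n_subjects, alpha = a, n_effective = n_eff,
      n_reject = nr, rate = rate, se = sqrt(rate * (1 - rate) / n_eff)
    )
  })
  out <- do.call(rbind, rows)
  attr(out, "n_excluded") <- n_replicates - n_eff
  attr(out, "p_values") <- pvals
  class(out) <- c("type1_error_table", class(out))
  out
}

#' Synthetic study shaped like a small targeted-sequencing panel
#'
#' Generates a full multi-gene study emulating a 44-subject targeted cancer
#' panel: gene sizes are log-normal around a median of 15 variants, clipped
#' to `[1, max_snv]`, with at least one single-variant gene (exercising the
#' Fisher fallback) and at least one gene with 100+ variants; MAFs follow
#' the rare-biased truncated Beta spectrum; genotypes are Hardy-Weinberg.
#' A fraction of genes can carry a case/control signal: for each such gene,
#' half of its variants get their case-group MAF shifted by
#' `effect_logodds` on the log-odds scale, which changes the heterogeneity
#' of per-variant MAFs in cases and hence the gene's partial-association
#' intensity.
#'
#' @param seed Seed; the same seed reproduces the fixture exactly.
#' @param n_subjects,n_cases Cohort size and number of cases (defaults
#'   44 and 21, i.e. a 21 case / 23 control split).
#' @param n_genes Number of genes.
#' @param median_snv,sdlog_snv,max_snv Gene-size distribution: sizes are
#'   `round(Lognormal(log(median_snv), sdlog_snv))` clipped to
#'   `[1, max_snv]`.
#' @param maf_shape1,maf_shape2 MAF spectrum shapes, see
#'   [generate_null_dataset()].
#' @param effect_fraction Fraction of (multi-variant) genes given a signal.
#' @param effect_logodds Case-MAF shift, on the log-odds scale, applied to
#'   half the variants of each signal gene.
#' @param ld_model,rho Within-gene LD, see [generate_null_dataset()].
#' @return List with `genotypes`, `gene_map`, and `effect_genes` (IDs of
#'   the signal genes, empty when `effect_fraction = 0`).
#' @examples
#' fx <- generate_ipmn_like_fixture(seed = 3, n_genes = 10)
#' lengths(fx$gene_map)
#' @export
generate_ipmn_like_fixture <- function(seed = NULL, n_subjects = 44,
                                       n_cases = 21, n_genes = 60,
                                       median_snv = 15, sdlog_snv = 1,
                                       max_snv = 188,
                                       maf_shape1 = 0.3, maf_shape2 = 3,
                                       effect_fraction = 0, effect_logodds = 2,
                                       ld_model = c("independent", "markov"),
                                       rho = 0.9) {
  ld_model <- match.arg(ld_model)
  stopifnot(n_genes >= 2, n_cases >= 2, n_subjects - n_cases >= 2)
  with_seed(seed, {
    sizes <- pmin(pmax(round(stats::rlnorm(n_genes, log(median_snv), sdlog_snv)), 1L), max_snv)
    if (!any(sizes == 1L)) sizes[1] <- 1L
    if (!any(sizes >= 100L)) sizes[2] <- 120L

    ic <- seq_len(n_subjects) %in% sample.int(n_subjects, n_cases)
    gene_ids <- sprintf("GENE%03d", seq_len(n_genes))
    multi <- which(sizes >= 2L)
    effect <- multi[seq_len(min(round(effect_fraction * n_genes), length(multi)))]

    blocks <- vector("list", n_genes)
    map <- vector("list", n_genes)
    info <- vector("list", n_genes)
    for (g in seq_len(n_genes)) {
      t <- sizes[g]
      f_ctl <- rbeta_truncated(t, maf_shape1, maf_shape2, 1 / (2 * n_subjects))
      f_cas <- f_ctl
      if (g %in% effect) {
        idx <- sample.int(t, ceiling(t / 2))
        f_cas[idx] <- stats::plogis(stats::qlogis(f_ctl[idx]) + effect_logodds)
      }
      counts <- matrix(0L, n_subjects, t)
      counts[ic, ] <- draw_genotypes(sum(ic), f_cas, ld_model, rho)
      counts[!ic, ] <- draw_genotypes(sum(!ic), f_ctl, ld_model, rho)
      vids <- sprintf("%s_v%03d", gene_ids[g], seq_len(t))
      blocks[[g]] <- counts
      map[[g]] <- vids
      info[[g]] <- data.frame(
        variant_id = vids, chrom = "chr1",
        pos = (g - 1L) * 50000L + sort(sample.int(5000L, t)),
        stringsAsFactors = FALSE
      )
    }
    names(map) <- gene_ids
    counts <- do.call(cbind, blocks)
    colnames(counts) <- unlist(map, use.names = FALSE)
    g <- exat_genotypes(
      counts, labels = as.integer(ic),
      subject_ids = sprintf("S%03d", seq_len(n_subjects)),
      variant_ids = colnames(counts),
      variant_info = do.call(rbind, info)
    )
    list(genotypes = g, gene_map = map, effect_genes = gene_ids[effect])
  })
}
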