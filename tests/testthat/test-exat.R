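sample_fixture <- function(seed = 101, n_genes = 6, effect_fraction = 0) {
  generate_ipmn_like_fixture(seed = seed, n_subjects = 16, n_cases = 8,
                             n_genes = n_genes, median_snv = 5, sdlog_snv = 0.4,
                             effect_fraction = effect_fraction)
}

test_that("the log-ratio statistic behaves as a log ratio", {
  fx <- sample_fixture()
  vars <- fx$gene_map[[3]]
  gt <- build_gene_tables(fx$genotypes, vars)
  s <- exat_statistic(gt$case, gt$control)
  expect_equal(s$T, log(s$cmh_case / s$cmh_control))

  # swapping the groups negates T
  s_swap <- exat_statistic(gt$control, gt$case)
  expect_equal(s_swap$T, -s$T)
  expect_equal(s_swap$cmh_case, s$cmh_control)

  # equal statistics give T = 0 (same tables in both slots)
  s_same <- exat_statistic(gt$case, gt$case)
  expect_equal(s_same$T, 0)

  expect_error(exat_statistic(list(), gt$control), "non-empty")
})

test_that("a zero group statistic makes T undefined, not infinite", {
  # controls carry constant genotype vectors -> control GCMH is exactly 0
  counts <- rbind(S1 = c(0L, 1L, 2L), S2 = c(2L, 1L, 0L),
                  S3 = c(1L, 1L, 1L), S4 = c(0L, 0L, 0L))
  colnames(counts) <- paste0("v", 1:3)
  x <- exat_genotypes(counts, labels = c(1, 1, 0, 0))
  gt <- build_gene_tables(x, colnames(counts))
  s <- exat_statistic(gt$case, gt$control)
  expect_false(s$defined)
  expect_true(is.na(s$T))
  expect_equal(s$cmh_control, 0)
})

test_that("permutation p-values agree with the exhaustive-partition oracle", {
  # 4 subjects (2/2): all 6 partitions enumerable
  set.seed(21)
  counts <- matrix(sample(0:2, 4 * 3, replace = TRUE, prob = c(.4, .4, .2)), 4, 3)
  while (is.na(tryCatch(oracle_T(counts, 1:2), error = function(e) NA))) {
    counts <- matrix(sample(0:2, 4 * 3, replace = TRUE, prob = c(.4, .4, .2)), 4, 3)
  }
  rownames(counts) <- paste0("S", 1:4)
  colnames(counts) <- paste0("v", 1:3)
  x <- exat_genotypes(counts, labels = c(1, 1, 0, 0))
  p_exact <- oracle_exhaustive_pvalue(counts, c(TRUE, TRUE, FALSE, FALSE))
  mc <- permutation_pvalue(x, colnames(counts), B = 10000, seed = 1)
  se <- sqrt(p_exact * (1 - p_exact) / 10000)
  expect_lt(abs(mc$result$p_value - p_exact), 3 * se + 2 / 10000)

  # identical groups: observed T = 0, p must be 1
  counts2 <- rbind(counts[1:2, ], counts[1:2, ])
  rownames(counts2) <- paste0("S", 1:4)
  x2 <- exat_genotypes(counts2, labels = c(1, 1, 0, 0))
  p <- permutation_pvalue(x2, colnames(counts2), B = 200, seed = 2)
  expect_equal(p$result$T, 0)
  expect_equal(p$result$p_value, 1)
})

test_that("permutation null is reproducible and excludes undefined draws", {
  fx <- sample_fixture()
  vars <- fx$gene_map[[2]]
  a <- permutation_pvalue(fx$genotypes, vars, B = 500, seed = 99)
  b <- permutation_pvalue(fx$genotypes, vars, B = 500, seed = 99)
  expect_identical(a, b)
  expect_equal(length(a$null$T_perm), 500)
  expect_equal(a$null$n_undefined, sum(is.na(a$null$T_perm)))
})

test_that("normal approximation applies the Gaussian tail to estimated moments", {
  fx <- sample_fixture()
  vars <- fx$gene_map[[4]]
  r <- normal_approx_pvalue(fx$genotypes, vars, B_small = 200, seed = 5)
  manual <- 2 * pnorm(-abs(r$result$T - r$null$mu_hat) / r$null$sigma_hat)
  expect_equal(r$result$p_value, manual)
  expect_gt(r$null$sigma_hat, 0)
  expect_error(normal_approx_pvalue(fx$genotypes, vars, B_small = 5), "at least 10")
})

test_that("permuted statistics are roughly symmetric around zero for a balanced null", {
  d <- generate_null_dataset(30, n_variants = 8, seed = 31)
  r <- permutation_pvalue(d$genotypes, d$gene_map$region, B = 3000, seed = 32)
  Tb <- r$null$T_perm[!is.na(r$null$T_perm)]
  skew <- mean((Tb - mean(Tb))^3) / sd(Tb)^3
  expect_lt(abs(skew), 0.35)
})

test_that("Fisher fallback matches hypergeometric and enumeration references", {
  # collapses to 2x2: classical two-sided Fisher
  counts <- matrix(c(0L, 0L, 0L, 1L, 1L, 0L, 0L, 1L, 1L, 0L), ncol = 1)
  rownames(counts) <- paste0("S", 1:10)
  colnames(counts) <- "v1"
  x <- exat_genotypes(counts, labels = c(1, 1, 1, 1, 1, 0, 0, 0, 0, 0))
  r <- fisher_single_snv(x, "v1")
  tab <- table(x$labels, factor(counts[, 1], levels = 0:1))
  # two-sided hypergeometric: sum of probabilities <= observed table's
  m <- sum(tab[, 2])
  probs <- dhyper(0:m, sum(tab["case", ]), sum(tab["control", ]), m)
  obs <- dhyper(tab["case", 2], sum(tab["case", ]), sum(tab["control", ]), m)
  expect_equal(r$p_value, sum(probs[probs <= obs * (1 + 1e-7)]), tolerance = 1e-10)
  expect_equal(r$method, "fisher_exact")

  # full 2x3 table against literal enumeration over all margin-preserving tables
  g3 <- c(0L, 1L, 2L, 0L, 0L, 1L, 0L, 2L, 1L, 0L)
  x3 <- exat_genotypes(matrix(g3, ncol = 1, dimnames = list(paste0("S", 1:10), "v1")),
                       labels = c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0))
  r3 <- fisher_single_snv(x3, "v1")
  tab3 <- table(x3$labels, factor(g3, levels = 0:2))
  p_enum <- local({
    rmar <- rowSums(tab3)
    cmar <- colSums(tab3)
    lprob <- function(tb) {
      sum(lfactorial(rmar)) + sum(lfactorial(cmar)) -
        lfactorial(sum(tb)) - sum(lfactorial(tb))
    }
    obs <- lprob(tab3)
    tot <- 0
    for (a in 0:min(rmar[1], cmar[1])) {
      for (b in 0:min(rmar[1] - a, cmar[2])) {
        cc <- rmar[1] - a - b
        if (cc <= cmar[3]) {
          tb <- rbind(c(a, b, cc), cmar - c(a, b, cc))
          if (lprob(tb) <= obs + 1e-7) tot <- tot + exp(lprob(tb))
        }
      }
    }
    tot
  })
  expect_equal(r3$p_value, p_enum, tolerance = 1e-10)

  # both groups identical and arranged as the most probable table
  xeq <- exat_genotypes(matrix(c(0L, 0L, 1L, 0L, 0L, 1L), ncol = 1,
                               dimnames = list(paste0("S", 1:6), "v1")),
                        labels = c(1, 1, 1, 0, 0, 0))
  expect_equal(fisher_single_snv(xeq, "v1")$p_value, 1)
})

test_that("analyze_all reports every gene, reproducibly, with flags", {
  fx <- generate_ipmn_like_fixture(seed = 41, n_subjects = 20, n_cases = 10,
                                   n_genes = 12, median_snv = 6, sdlog_snv = 0.8)
  res <- analyze_all(fx$genotypes, fx$gene_map, method = "normal_approx",
                     B = 40, seed = 7)
  expect_equal(nrow(res), 12)
  expect_setequal(res$gene_id, names(fx$gene_map))
  expect_true(all(res$p_value > 0 & res$p_value <= 1, na.rm = TRUE))
  expect_true(any(res$method == "fisher_exact"))  # the forced t = 1 gene

  res2 <- analyze_all(fx$genotypes, fx$gene_map, method = "normal_approx",
                      B = 40, seed = 7)
  expect_identical(res, res2)

  # per-gene seeding: results identical when the map order changes
  res3 <- analyze_all(fx$genotypes, rev(fx$gene_map), method = "normal_approx",
                      B = 40, seed = 7)
  expect_identical(res[order(res$gene_id), ], res3[order(res3$gene_id), ])

  # BH column and significance filtering
  resadj <- analyze_all(fx$genotypes, fx$gene_map, method = "normal_approx",
                        B = 40, seed = 7, adjust = TRUE)
  expect_equal(resadj$p_adj_BH, p.adjust(resadj$p_value, "BH"))
  expect_equal(sum(resadj$p_value <= 0.05, na.rm = TRUE),
               nrow(resadj[!is.na(resadj$p_value) & resadj$p_value <= 0.05, ]))
})

test_that("label swap leaves two-sided inference unchanged", {
  fx <- sample_fixture(seed = 55)
  vars <- fx$gene_map[[5]]
  x <- fx$genotypes
  flipped <- exat_genotypes(x$counts, labels = ifelse(x$labels == "case", 0, 1))
  gt <- build_gene_tables(x, vars)
  gtf <- build_gene_tables(flipped, vars)
  s <- exat_statistic(gt$case, gt$control)
  sf <- exat_statistic(gtf$case, gtf$control)
  expect_equal(sf$T, -s$T)

  # exhaustive two-sided p is exactly invariant under the swap
  counts <- x$counts[1:8, vars[1:4]]
  ic <- c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE)
  expect_equal(oracle_exhaustive_pvalue(counts, ic),
               oracle_exhaustive_pvalue(counts, !ic))
})

test_that("the agreement diagnostic returns the comparison panel", {
  fx <- generate_ipmn_like_fixture(seed = 61, n_subjects = 20, n_cases = 10,
                                   n_genes = 10, median_snv = 5, sdlog_snv = 0.5,
                                   effect_fraction = 0.3)
  panel <- diagnose_approx(fx$genotypes, fx$gene_map, B_ref = 400,
                           B_small = c(20, 50), seed = 3)
  expect_equal(nrow(panel), 2)
  expect_equal(panel$B_small, c(20, 50))
  expect_true(all(panel$r_squared >= 0 & panel$r_squared <= 1))
  expect_true(all(panel$mse >= 0))
  expect_equal(panel$r_squared, panel$pearson^2, tolerance = 1e-12)
})
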