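test_that("diversity statistics match direct counting on tiny cohorts", {
  # oracle: 10 individuals all heterozygous at one locus
  pan <- locus_panel("l1", "s1", 1L, 0.5)
  gm <- genotype_matrix(matrix(1L, 10, 1), pan,
                        individuals = sprintf("i%02d", 1:10),
                        population = rep("p1", 10))
  d <- locus_diversity(gm)
  expect_equal(d$ho, 1)
  expect_equal(d$he, 0.5 * 20 / 19)
  expect_equal(d$fis, 1 - 1 / (0.5 * 20 / 19))
  expect_equal(round(d$fis, 4), -0.9)
  expect_equal(d$maf, 0.5)
  # monomorphic locus: MAF 0, He 0, F_IS flagged missing
  gm0 <- genotype_matrix(matrix(0L, 5, 1), pan, population = rep("p1", 5))
  d0 <- locus_diversity(gm0)
  expect_equal(d0$he, 0)
  expect_equal(d0$maf, 0)
  expect_true(is.na(d0$fis))
  # hand-computed 4-individual mixed cell
  g <- matrix(c(0L, 1L, 1L, 2L), 4, 1)
  dd <- locus_diversity(genotype_matrix(g, pan, population = rep("p", 4)))
  p_hat <- mean(g) / 2
  expect_equal(dd$ho, 0.5)
  expect_equal(dd$he, 2 * p_hat * (1 - p_hat) * 8 / 7)
})

test_that("mean F_IS is near zero under Hardy-Weinberg simulation", {
  pan <- draw_allele_frequencies(5000, rng_seed = 41, loci_per_scaffold = 50L)
  gm <- hwe_parent_genotypes(pan, 200, rng_seed = 42)
  gm$population <- rep("p1", 200)
  d <- locus_diversity(gm)
  expect_lt(abs(mean(d$fis, na.rm = TRUE)), 0.01)
})

test_that("Nei differentiation hits its nulls, limits and symmetries", {
  pan <- draw_allele_frequencies(300, rng_seed = 51, loci_per_scaffold = 10L)
  # identical frequencies: pairwise ~ 0
  gm0 <- structured_populations(pan, 2, 0, 60, rng_seed = 52)
  r0 <- nei_differentiation(gm0)
  expect_lt(abs(r0$pairwise[1, 2]), 0.01)
  # fixed difference -> value -> 1
  panf <- locus_panel("l1", "s1", 1L, 0.5)
  gmf <- genotype_matrix(matrix(c(rep(0L, 50), rep(2L, 50)), 100, 1), panf,
                         population = rep(c("a", "b"), each = 50))
  rf <- nei_differentiation(gmf)
  expect_gt(rf$global, 0.95)
  # permutation invariance of labels + symmetric matrix
  gm3 <- structured_populations(pan, 3, 0.05, 30, rng_seed = 53)
  r3 <- nei_differentiation(gm3)
  expect_identical(r3$pairwise, t(r3$pairwise))
  perm <- sample(nrow(gm3$geno))
  gm3p <- subset_gm(gm3, individuals = perm)
  r3p <- nei_differentiation(gm3p)
  expect_equal(r3$pairwise, r3p$pairwise, tolerance = 1e-12)
  expect_equal(r3$global, r3p$global, tolerance = 1e-12)
  expect_true(all(r3$per_locus > -0.1 & r3$per_locus <= 1, na.rm = TRUE))
})

test_that("DAPC separates diverged groups and ranks loadings in [0, 100]", {
  pan <- draw_allele_frequencies(300, rng_seed = 61, loci_per_scaffold = 10L)
  gm <- structured_populations(pan, 2, 0.2, 40, rng_seed = 62)
  fit <- dapc_ordinate(gm, n_pcs = 20)
  expect_gte(mean(fit$loo_assignment == gm$population), 0.95)
  expect_equal(range(fit$loading_percentile), c(0, 100))
  # percentile ranks are a monotone transform of the loading scores
  ord <- order(fit$loading)
  expect_true(all(diff(fit$loading_percentile[ord]) >= 0))
  # shuffled labels -> near-chance assignment
  set.seed(63)
  gm_null <- gm
  gm_null$population <- sample(gm$population)
  fit0 <- dapc_ordinate(gm_null, n_pcs = 20)
  expect_lt(mean(fit0$loo_assignment == gm_null$population), 0.75)
  # determinism
  expect_identical(dapc_ordinate(gm, n_pcs = 20)$ind_coord, fit$ind_coord)
  expect_error(dapc_ordinate(subset_gm(gm, individuals = 1:40), n_pcs = 5),
               "2 groups")
})

test_that("the trimmed chi-square outlier scan recovers df and controls FDR", {
  # parameter recovery on synthetic chi-square data with known df = 4
  set.seed(71)
  fst <- 0.01 / 4 * rchisq(5000, df = 4)
  scan <- outlier_scan(fst)
  expect_lt(abs(scan$df - 4) / 4, 0.15)
  expect_lt(abs(scan$fst_bar - 0.01) / 0.01, 0.1)
  # neutral data: ~0 outliers at FDR 0.10
  expect_lte(sum(scan$outlier), 1L)
  # p-values approximately uniform on neutral data
  ks <- suppressWarnings(ks.test(scan$p_value, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("spiked loci are flagged with few false positives", {
  hits <- fp <- integer(10)
  for (r in 1:10) {
    set.seed(80 + r)
    fst <- 0.008 / 5 * rchisq(5000, df = 5)
    spike <- sample.int(5000, 20)
    fst[spike] <- fst[spike] + 10 * 0.008
    scan <- outlier_scan(fst)
    hits[r] <- sum(which(scan$outlier) %in% spike)
    fp[r] <- sum(!(which(scan$outlier) %in% spike))
  }
  expect_gte(mean(hits), 15)
  expect_lte(mean(fp), 2)
  expect_error(outlier_scan(rep(0.01, 10)), "50")
})

test_that("HDplot statistics flag paralog-like loci", {
  # direct arithmetic: n_A 64, n_B 36 -> D = 2.8
  pan <- locus_panel("l1", "s1", 1L, 0.5)
  gm <- genotype_matrix(matrix(1L, 1, 1), pan,
                        depth = matrix(100), ad_ref = matrix(64),
                        ad_alt = matrix(36))
  hd <- hdplot(gm)
  expect_equal(hd$d, 2.8)
  expect_equal(hd$h, 1)
  expect_true(hd$flag)  # H = 1 > 0.60
  # balanced reads at true SNPs rarely exceed |D| = 7
  pan2 <- draw_allele_frequencies(1000, rng_seed = 91,
                                  loci_per_scaffold = 20L)
  sim <- corrupt_genotypes(hwe_parent_genotypes(pan2, 100, rng_seed = 92),
                           error_rate = 0, missing_rate = 0, rng_seed = 93)
  hd2 <- hdplot(sim)
  expect_lt(mean(abs(hd2$d) > 7, na.rm = TRUE), 0.01)
  # duplicated-locus fixture: all het, 2:1 read skew -> flagged by H and D
  gm_dup <- genotype_matrix(matrix(1L, 50, 1), pan,
                            depth = matrix(30L, 50, 1),
                            ad_ref = matrix(20L, 50, 1),
                            ad_alt = matrix(10L, 50, 1))
  hd3 <- hdplot(gm_dup)
  expect_true(hd3$flag)
  expect_gt(abs(hd3$d), 7)
  # no heterozygotes -> D missing
  gm_hom <- genotype_matrix(matrix(0L, 5, 1), pan,
                            depth = matrix(10L, 5, 1),
                            ad_ref = matrix(10L, 5, 1),
                            ad_alt = matrix(0L, 5, 1))
  expect_true(is.na(hdplot(gm_hom)$d))
})

test_that("allele balance sits near 0.5 for unbiased reads", {
  pan <- draw_allele_frequencies(400, rng_seed = 94, loci_per_scaffold = 10L)
  sim <- corrupt_genotypes(hwe_parent_genotypes(pan, 80, rng_seed = 95),
                           error_rate = 0, missing_rate = 0, rng_seed = 96)
  ab <- allele_balance(sim)
  expect_gt(mean(ab$ab, na.rm = TRUE), 0.48)
  expect_lt(mean(ab$ab, na.rm = TRUE), 0.52)
  # all-ref reads at het calls -> AB 1 (flagged out of band)
  pan1 <- locus_panel("l1", "s1", 1L, 0.5)
  bad <- genotype_matrix(matrix(1L, 4, 1), pan1,
                         depth = matrix(10L, 4, 1),
                         ad_ref = matrix(10L, 4, 1),
                         ad_alt = matrix(0L, 4, 1))
  abb <- allele_balance(bad)
  expect_equal(abb$ab, 1)
  expect_false(abb$in_band)
  # no heterozygotes -> AB missing
  hom <- genotype_matrix(matrix(2L, 4, 1), pan1,
                         depth = matrix(10L, 4, 1),
                         ad_ref = matrix(0L, 4, 1),
                         ad_alt = matrix(10L, 4, 1))
  expect_true(is.na(allele_balance(hom)$ab))
})
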