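test_that("VCF round trip preserves dosages and all channels exactly", {
  pan <- draw_allele_frequencies(25, rng_seed = 1, loci_per_scaffold = 5L)
  gm <- corrupt_genotypes(hwe_parent_genotypes(pan, 8, rng_seed = 2),
                          error_rate = 0.02, missing_rate = 0.1,
                          rng_seed = 3)
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(gm, path)
  back <- read_vcf(path)
  expect_identical(unname(back$geno), unname(gm$geno))
  expect_equal(unname(back$gq), unname(gm$gq))
  expect_equal(unname(back$depth), unname(matrix(as.numeric(gm$depth),
                                                 nrow(gm$geno))))
  expect_equal(unname(back$ad_ref), unname(matrix(as.numeric(gm$ad_ref),
                                                  nrow(gm$geno))))
  expect_equal(unname(back$ad_alt), unname(matrix(as.numeric(gm$ad_alt),
                                                  nrow(gm$geno))))
  expect_identical(back$individuals, gm$individuals)
  expect_identical(back$panel$scaffold, gm$panel$scaffold)
  expect_identical(back$panel$position, gm$panel$position)
  # a second write of the read-back object is byte-identical
  path2 <- withr::local_tempfile(fileext = ".vcf")
  gm2 <- back
  gm2$geno <- back$geno
  write_vcf(gm, path)
  write_vcf(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("metadata TSV round trips", {
  meta <- data.frame(sample_id = c("a", "b"), population = "p1",
                     location = c("L1", "L2"), length_mm = c(55.5, 120),
                     cohort = c("age1", "age2"), stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_metadata(meta, path)
  expect_equal(read_metadata(path), meta)
})

test_that("filters apply in the fixed order with additive reports", {
  gm <- toy_gm()
  # GQ 9 at one called genotype masks it
  out <- apply_filters(gm, filter_config(site_mean_depth_min = NULL,
                                         site_missing_max = 1,
                                         individual_missing_max = 1))
  expect_equal(out$report$genotypes_masked_gq, 1L)
  expect_equal(sum(is.na(out$gm$geno)), sum(is.na(gm$geno)) + 1L)
  # disabled thresholds -> identity
  id <- apply_filters(gm, filter_config(gq_min = NULL,
                                        site_mean_depth_min = NULL,
                                        site_missing_max = NULL,
                                        individual_missing_max = NULL))
  expect_identical(id$gm$geno, gm$geno)
  # individual above the missingness cap is removed
  pan <- draw_allele_frequencies(10, rng_seed = 4)
  g <- hwe_parent_genotypes(pan, 4, rng_seed = 5)
  g$geno[1, 1:8] <- NA_integer_   # 80% missing
  f <- apply_filters(g, filter_config(individual_missing_max = 0.75,
                                      site_missing_max = NULL,
                                      site_mean_depth_min = NULL))
  expect_equal(f$report$individuals_removed, 1L)
  expect_equal(nrow(f$gm$geno), 3L)
  expect_equal(f$report$individuals_in,
               f$report$individuals_out + f$report$individuals_removed)
  # site with > 30% missing after masking is removed
  g2 <- hwe_parent_genotypes(pan, 10, rng_seed = 6)
  g2$geno[1:4, 1] <- NA_integer_  # 40% missing at site 1
  f2 <- apply_filters(g2, filter_config(site_mean_depth_min = NULL,
                                        individual_missing_max = NULL))
  expect_equal(f2$report$sites_removed_missing, 1L)
  expect_equal(ncol(f2$gm$geno), 9L)
  expect_equal(f2$report$sites_in,
               f2$report$sites_out + f2$report$sites_removed_missing +
                 f2$report$sites_removed_depth)
})

test_that("independent-locus selection obeys spacing and eligibility", {
  # worked instance: loci at 0.5, 1.5, 2.6 Mb on one scaffold
  pan <- locus_panel(c("a", "b", "c"), rep("s1", 3),
                     c(500000L, 1500000L, 2600000L), c(0.3, 0.4, 0.2))
  keep <- select_independent_loci(pan)
  expect_equal(keep, c("a", "c"))
  # distinct scaffolds: all kept
  pan2 <- locus_panel(c("a", "b", "c"), c("s1", "s2", "s3"),
                      rep(1L, 3), rep(0.3, 3))
  expect_equal(sort(select_independent_loci(pan2)), c("a", "b", "c"))
  # genotyping-rate ineligibility drops a locus
  gm <- genotype_matrix(
    rbind(c(0L, NA, 1L), c(1L, NA, 1L), c(0L, NA, 2L), c(2L, NA, 0L),
          c(1L, NA, 1L)),
    pan
  )
  keep2 <- select_independent_loci(pan, gm)
  expect_false("b" %in% keep2)
  # oracle: greedy result is pairwise >= spacing within scaffold, and
  # matches the brute-force maximum count on small instances
  set.seed(9)
  for (trial in 1:5) {
    pos <- sort(sample.int(8e6, 12))
    pant <- locus_panel(sprintf("t%02d", 1:12), rep("s", 12), pos,
                        runif(12, 0.1, 0.5))
    kept <- select_independent_loci(pant)
    kp <- sort(pant$position[pant$locus_id %in% kept])
    if (length(kp) > 1) expect_true(all(diff(kp) >= 2e6))
    # brute force: maximum subset with pairwise >= 2 Mb spacing
    best <- 0L
    for (mask in seq_len(2^12) - 1L) {
      sel <- pos[bitwAnd(mask, 2^(0:11)) > 0]
      if (length(sel) < 2 || all(diff(sel) >= 2e6)) {
        best <- max(best, length(sel))
      }
    }
    expect_equal(length(kept), best)
  }
})

test_that("family downsampling keeps the best-called member", {
  pan <- draw_allele_frequencies(20, rng_seed = 10)
  gm <- hwe_parent_genotypes(pan, 6, rng_seed = 11)
  gm$geno[2, 1:10] <- NA_integer_
  fams <- structure(
    list(families = list(gm$individuals[1:3], gm$individuals[4:5],
                         gm$individuals[6]),
         hs_links = data.frame(f1 = integer(), f2 = integer())),
    class = "sib_families"
  )
  ds <- downsample_families(gm, fams)
  expect_equal(nrow(ds$geno), 3L)
  expect_false(gm$individuals[2] %in% ds$individuals)  # low call rate
  # retained member has the family's max call rate
  rate <- rowMeans(!is.na(gm$geno))
  expect_equal(unname(rate[match(ds$individuals[1], gm$individuals)]),
               max(rate[1:3]))
  # singletons: identity
  single <- singleton_families(gm$individuals)
  expect_identical(downsample_families(gm, single)$geno, gm$geno)
  expect_error(downsample_families(gm, singleton_families(c("x", "y"))),
               "partition")
})

test_that("the length-mixture EM recovers components and converges", {
  model <- age_mixture(means = c(30, 70, 110, 150), sds = rep(8, 4))
  correct <- numeric(10)
  for (s in 1:10) {
    sim <- simulate_lengths(model, 400, rng_seed = 20 + s)
    fit <- assign_ages(sim$length_mm)
    correct[s] <- mean(fit$component == sim$component)
  }
  expect_gte(mean(correct), 0.95)
  # log-likelihood non-decreasing along the EM trace
  sim <- simulate_lengths(model, 300, rng_seed = 31)
  fit <- assign_ages(sim$length_mm)
  expect_true(all(diff(fit$loglik_trace) >= -1e-6))
  # permutation invariance of assignments
  perm <- sample(300)
  fit_p <- assign_ages(sim$length_mm[perm])
  expect_identical(fit_p$component, fit$component[perm])
  # degenerate input hits the variance floor and is flagged
  flat <- assign_ages(rep(100, 50))
  expect_true(flat$degenerate)
  expect_error(assign_ages(rnorm(10)), "at least")
})

test_that("the EM agrees with an independent mixture fitter", {
  skip_if_not_installed("mclust")
  suppressPackageStartupMessages(library(mclust))
  model <- age_mixture(means = c(30, 70, 110, 150), sds = rep(8, 4))
  sim <- simulate_lengths(model, 500, rng_seed = 55)
  fit <- assign_ages(sim$length_mm)
  mc <- Mclust(sim$length_mm, G = 4, modelNames = "V", verbose = FALSE)
  ord <- order(mc$parameters$mean)
  expect_equal(sort(fit$model$means), unname(sort(mc$parameters$mean)),
               tolerance = 0.05)
  # same partition up to label order
  relabel <- match(mc$classification, ord)
  expect_gte(mean(relabel == fit$component), 0.98)
})
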