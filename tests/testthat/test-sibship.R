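test_that("dyad likelihood matches brute-force enumeration to 1e-12", {
  # exhaustive oracle over parental genotype pairs, one and two loci
  for (p in c(0.1, 0.37, 0.5, 0.8)) {
    pan <- locus_panel("l1", "s1", 1L, p)
    for (g1 in 0:2) for (g2 in 0:2) for (r in c("FS", "HS", "U")) {
      got <- exp(dyad_loglik(g1, g2, pan, r))
      want <- oracle_dyad_prob(g1, g2, p, r)
      expect_equal(got, want, tolerance = 1e-12)
    }
  }
  # two loci multiply: independence across loci
  pan2 <- locus_panel(c("l1", "l2"), c("s1", "s2"), c(1L, 1L), c(0.3, 0.6))
  for (r in c("FS", "HS", "U")) {
    got <- dyad_loglik(c(1L, 2L), c(0L, 2L), pan2, r)
    want <- log(oracle_dyad_prob(1, 0, 0.3, r)) +
      log(oracle_dyad_prob(2, 2, 0.6, r))
    expect_equal(got, want, tolerance = 1e-12)
  }
  # worked values at p = 0.5, both homozygous reference
  pan5 <- locus_panel("l1", "s1", 1L, 0.5)
  expect_equal(exp(dyad_loglik(0L, 0L, pan5, "U")), 0.0625,
               tolerance = 1e-12)
  expect_equal(exp(dyad_loglik(0L, 0L, pan5, "FS")), 0.140625,
               tolerance = 1e-12)
})

test_that("dyad likelihood is exchangeable and skips missing loci", {
  pan <- locus_panel(paste0("l", 1:3), rep("s1", 3),
                     c(1L, 3000001L, 6000001L), c(0.2, 0.5, 0.7))
  g1 <- c(0L, NA, 2L); g2 <- c(1L, 1L, 2L)
  for (r in c("FS", "HS", "U")) {
    expect_identical(dyad_loglik(g1, g2, pan, r),
                     dyad_loglik(g2, g1, pan, r))
  }
  # the NA locus contributes nothing
  expect_equal(dyad_loglik(g1, g2, pan, "U"),
               dyad_loglik(c(0L, 0L, 2L), c(1L, NA, 2L), pan, "U"))
  expect_error(dyad_loglik(NA_integer_, 1L,
                           locus_panel("l", "s", 1L, 0.5), "U"),
               "jointly called")
})

test_that("simulated full sibs outscore unrelated under the FS model", {
  pan <- draw_allele_frequencies(500, rng_seed = 31)
  wins <- 0L
  for (rep in 1:20) {
    par <- hwe_parent_genotypes(pan, 2, rng_seed = 31 + rep)
    o1 <- mendelian_offspring(par$geno[1, ], par$geno[2, ])
    o2 <- mendelian_offspring(par$geno[1, ], par$geno[2, ])
    if (dyad_loglik(o1, o2, pan, "FS") > dyad_loglik(o1, o2, pan, "U")) {
      wins <- wins + 1L
    }
  }
  expect_gte(wins, 20L * 0.99)
})

test_that("dyad classification is accurate on simulated cohorts", {
  accs <- matrix(NA_real_, 10, 2, dimnames = list(NULL, c("FS", "U")))
  for (r in 1:10) {
    sim <- simulate_cohort(sim_config(100, n_loci = 500),
                           error_rate = 0.01, missing_rate = 0.02,
                           rng_seed = 100 + r)
    calls <- classify_dyads(sim$gm, epsilon = 0.01, min_shared_loci = 100L)
    conf <- confusion_metrics(sim$pedigree, calls)
    accs[r, "FS"] <- conf$per_class["FS", "accuracy"]
    accs[r, "U"] <- conf$per_class["U", "accuracy"]
  }
  expect_gte(mean(accs[, "FS"], na.rm = TRUE), 0.95)
  expect_gte(mean(accs[, "U"], na.rm = TRUE), 0.95)
})

test_that("classification edge cases: twins, singletons, ties", {
  pan <- draw_allele_frequencies(200, rng_seed = 8)
  g <- hwe_parent_genotypes(pan, 2, rng_seed = 9)$geno
  twin <- genotype_matrix(rbind(t1 = g[1, ], t2 = g[1, ]), pan)
  calls <- classify_dyads(twin, epsilon = 0.01, min_shared_loci = 1L)
  expect_equal(calls$call, "FS")
  # a single individual yields no dyads
  single <- genotype_matrix(g[1, , drop = FALSE], pan)
  expect_equal(nrow(classify_dyads(single)), 0L)
  # below min_shared_loci the pair is uncalled
  sparse <- genotype_matrix(
    rbind(a = c(1L, rep(NA_integer_, 199)), b = c(1L, rep(NA_integer_, 199))),
    pan
  )
  expect_equal(classify_dyads(sparse, min_shared_loci = 100L)$call,
               "uncalled")
})

test_that("family clustering merges cliques and repairs conflicts", {
  mk_calls <- function(df) {
    df$n_loci <- 500L
    class(df) <- c("dyad_calls", "data.frame")
    df
  }
  # clique: one family
  cl <- mk_calls(data.frame(
    id1 = c("A", "B", "A"), id2 = c("B", "C", "C"),
    llFS = c(-10, -10, -10), llHS = c(-12, -12, -12),
    llU = c(-20, -20, -20), call = "FS", stringsAsFactors = FALSE
  ))
  fam <- cluster_families(cl)
  expect_equal(lengths(fam$families), 3L)
  expect_setequal(fam$families[[1]], c("A", "B", "C"))
  # conflict: A-B, B-C called FS but A-C strongly U; C is peeled off
  cf <- mk_calls(data.frame(
    id1 = c("A", "B", "A"), id2 = c("B", "C", "C"),
    llFS = c(-10, -11.8, -40), llHS = c(-12, -12, -30),
    llU = c(-20, -12.1, -10),
    call = c("FS", "FS", "U"), stringsAsFactors = FALSE
  ))
  fam2 <- cluster_families(cf)
  sizes <- sort(lengths(fam2$families))
  expect_equal(sizes, c(1L, 2L))
  expect_setequal(fam2$families[[which(lengths(fam2$families) == 2)]],
                  c("A", "B"))
  # determinism
  expect_identical(cluster_families(cf), cluster_families(cf))
  # no edges: all singletons, 66 parent slots for 33 individuals
  ids <- sprintf("i%02d", 1:33)
  none <- mk_calls(data.frame(
    id1 = utils::combn(ids, 2)[1, ], id2 = utils::combn(ids, 2)[2, ],
    llFS = -30, llHS = -25, llU = -20, call = "U",
    stringsAsFactors = FALSE
  ))
  fam3 <- cluster_families(none)
  expect_equal(length(fam3$families), 33L)
  expect_equal(count_parents(fam3), 66L)
})

test_that("confusion metrics implement the stated definitions", {
  # 10 true FS of which 7 inferred FS -> FS FNR 0.3;
  # 8 inferred HS of which 6 true HS -> HS accuracy 0.75
  ped <- data.frame(
    offspring_id = sprintf("o%02d", 1:40),
    mother_id = c(rep("m1", 5), rep("m2", 5), sprintf("mm%d", 1:30)),
    father_id = c(rep("f1", 5), rep("f2", 5), sprintf("ff%d", 1:30)),
    stringsAsFactors = FALSE
  )
  pairs <- utils::combn(ped$offspring_id, 2)
  truth <- true_relationship(ped, pairs[1, ], pairs[2, ])
  call <- truth
  fs_idx <- which(truth == "FS")           # 2 families of 5 -> 20 FS dyads
  expect_equal(length(fs_idx), 20L)
  call[fs_idx[1:6]] <- "U"                 # miss 6 of 20 FS -> FNR 0.3
  u_idx <- which(truth == "U")
  call[u_idx[1:2]] <- "HS"                 # 2 false HS
  calls <- data.frame(id1 = pairs[1, ], id2 = pairs[2, ],
                      n_loci = 500L, llFS = 0, llHS = 0, llU = 0,
                      call = call, stringsAsFactors = FALSE)
  class(calls) <- c("dyad_calls", "data.frame")
  conf <- confusion_metrics(ped, calls)
  expect_equal(conf$per_class["FS", "fnr"], 0.3)
  expect_equal(conf$per_class["FS", "accuracy"], 1)
  expect_equal(sum(conf$table), ncol(pairs))
  # all correct -> accuracy 1 / FNR 0 everywhere
  perfect <- calls; perfect$call <- truth
  confp <- confusion_metrics(ped, perfect)
  expect_true(all(confp$per_class$accuracy == 1, na.rm = TRUE))
  expect_true(all(confp$per_class$fnr == 0, na.rm = TRUE))
})
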