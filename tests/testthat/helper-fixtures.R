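# Shared fixtures and independent oracles used across test files.

# Brute-force dyad-likelihood oracle: enumerate parental genotype pairs
# under HWE and Mendelian offspring draws. Independent of the k-coefficient
# implementation in the package.
oracle_offspring_dist <- function(m, f) {
  pm <- c((2 - m) / 2, m / 2)   # P(transmit REF), P(transmit ALT)
  pf <- c((2 - f) / 2, f / 2)
  d <- outer(pm, pf)
  c(d[1, 1], d[1, 2] + d[2, 1], d[2, 2])
}

oracle_hwe <- function(p) c((1 - p)^2, 2 * p * (1 - p), p^2)

oracle_dyad_prob <- function(g1, g2, p, rel) {
  h <- oracle_hwe(p)
  if (rel == "U") return(h[g1 + 1] * h[g2 + 1])
  tot <- 0
  for (m in 0:2) for (f in 0:2) {
    if (rel == "FS") {
      dm <- oracle_offspring_dist(m, f)
      tot <- tot + h[m + 1] * h[f + 1] * dm[g1 + 1] * dm[g2 + 1]
    } else if (rel == "HS" && f == 0) {
      # shared mother m; independent fathers integrated out
      p1 <- sum(vapply(0:2, function(f1)
        h[f1 + 1] * oracle_offspring_dist(m, f1)[g1 + 1], numeric(1)))
      p2 <- sum(vapply(0:2, function(f2)
        h[f2 + 1] * oracle_offspring_dist(m, f2)[g2 + 1], numeric(1)))
      tot <- tot + h[m + 1] * p1 * p2
    }
  }
  tot
}

# A tiny deterministic genotype matrix with full channels.
toy_gm <- function() {
  panel <- locus_panel(
    locus_id = paste0("l", 1:4),
    scaffold = c("s1", "s1", "s2", "s2"),
    position = c(100L, 2100000L, 50L, 99L),
    alt_freq = c(0.5, 0.25, 0.1, 0.5)
  )
  geno <- rbind(
    a = c(0L, 1L, 2L, NA),
    b = c(1L, 1L, 0L, 0L),
    c = c(2L, NA, 1L, 1L)
  )
  depth <- matrix(20L, 3, 4)
  ad_alt <- matrix(0L, 3, 4)
  ad_alt[geno == 1L] <- 10L
  ad_alt[geno == 2L] <- 20L
  ad_alt[is.na(geno)] <- NA_integer_
  depth[is.na(geno)] <- NA_integer_
  genotype_matrix(geno, panel,
                  gq = matrix(c(40, 40, 9, 40, 40, 40, 40, 40, 40, NA, 40, 40),
                              3, 4),
                  depth = depth, ad_ref = depth - ad_alt, ad_alt = ad_alt)
}
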