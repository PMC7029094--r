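# Summaries of a reconstructed cohort pedigree: contributing adults (N_s),
# reproductive success, group coancestry, and effective number of breeders
# (N_b) by sibship frequencies and by linkage disequilibrium.

# Assign latent parent identities to a sib_families object. Each family
# owns two parent slots; each half-sib link merges one still-free slot of
# each family (union-find). Returns per-family slot labels and the
# per-parent offspring counts.
resolve_parent_slots <- function(families) {
  stopifnot(inherits(families, "sib_families"))
  nf <- length(families$families)
  slot <- matrix(seq_len(2 * nf), nrow = nf)  # slot ids: [fam, 1:2]
  parent <- seq_len(2 * nf)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  used <- rep(FALSE, 2 * nf)
  links <- families$hs_links
  for (k in seq_len(nrow(links))) {
    f1 <- links$f1[k]; f2 <- links$f2[k]
    pick <- function(f) {
      s <- slot[f, ]
      if (!used[s[2]]) s[2] else s[1]
    }
    a <- pick(f1); b <- pick(f2)
    used[c(a, b)] <- TRUE
    ra <- find(a); rb <- find(b)
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  roots <- vapply(seq_len(2 * nf), find, integer(1))
  fam_size <- lengths(families$families)
  counts <- tapply(rep(fam_size, 2), roots[as.vector(slot)], sum)
  list(slot_root = matrix(roots[slot], nrow = nf),
       parent_counts = as.numeric(counts))
}

#' Number of contributing adults implied by a family structure
#'
#' Two parent slots per full-sib family, minus one for every slot merged by
#' a half-sib link. A cohort of singleton families with no links therefore
#' implies `2 * n` adults.
#'
#' @param families a `sib_families` object (see [cluster_families()],
#'   [singleton_families()]).
#' @return integer N_s.
#' @export
count_parents <- function(families) {
  length(resolve_parent_slots(families)$parent_counts)
}

#' Reproductive success of the inferred parents
#'
#' Offspring assigned to unsampled parents are tallied per latent parent
#' slot; the mean is `2 * n_offspring / N_s` by construction and the
#' variance is the sample variance of per-parent counts.
#'
#' @param families a `sib_families` object.
#' @param n_offspring cohort size; defaults to the family-size total.
#' @return list: `n_s`, `rs_mean`, `rs_variance`, `parent_counts`.
#' @export
reproductive_success <- function(families,
                                 n_offspring = sum(lengths(families$families))) {
  counts <- resolve_parent_slots(families)$parent_counts
  if (sum(lengths(families$families)) != n_offspring) {
    stop("n_offspring must equal the number of individuals in the families")
  }
  list(
    n_s = length(counts),
    rs_mean = 2 * n_offspring / length(counts),
    rs_variance = if (length(counts) > 1) stats::var(counts) else 0,
    parent_counts = counts
  )
}

#' Group coancestry from full- and half-sib dyad counts
#'
#' Cockerham-style group coancestry for a cohort of `n` individuals,
#' computed from its full-sib and half-sib dyad counts with per-dyad
#' coefficients 0.125 (FS) and 0.0625 (HS) over the `C(n, 2)` distinct
#' dyads; self-pairs are excluded and unrelated dyads contribute zero.
#'
#' @param n cohort size (>= 2).
#' @param n_fs_dyads,n_hs_dyads dyad counts (>= 0).
#' @return scalar coancestry in `[0, 0.125]`.
#' @export
coancestry_from_counts <- function(n, n_fs_dyads, n_hs_dyads) {
  stopifnot(n >= 2, n_fs_dyads >= 0, n_hs_dyads >= 0)
  total <- choose(n, 2)
  if (n_fs_dyads + n_hs_dyads > total) {
    warning("dyad counts exceed C(n, 2); treating printed counts as given")
  }
  (0.125 * n_fs_dyads + 0.0625 * n_hs_dyads) / total
}

#' Effective number of breeders from sibship frequencies
#'
#' From per-offspring parent assignments (true or latent):
#' `Q_mother` is the fraction of offspring dyads sharing a mother,
#' `Q_father` likewise; the effective parent numbers are `1 / Q`, and
#' `N_b = 4 / (1/N_f + 1/N_m)` (Wright's composition). The 95% CI is a
#' percentile bootstrap over offspring.
#'
#' @param mothers,fathers parent-id vectors, one entry per offspring.
#' @param ci_reps bootstrap resamples (default 500; 0 skips the CI).
#' @param rng_seed integer seed for the bootstrap.
#' @return list: `nb`, `q_mother`, `q_father`, `ci` (length-2 or NULL).
#'   `nb` is `Inf` when neither parent is ever shared.
#' @export
nb_sibship <- function(mothers, fathers, ci_reps = 500L, rng_seed = NULL) {
  n <- length(mothers)
  stopifnot(length(fathers) == n, n >= 2)
  point <- function(m, f) {
    nd <- choose(length(m), 2)
    qm <- sum(choose(table(m), 2)) / nd
    qf <- sum(choose(table(f), 2)) / nd
    if (qm == 0 || qf == 0) return(c(Inf, qm, qf))
    c(4 / (qm + qf), qm, qf)   # 4 / (1/(1/qm) + 1/(1/qf))
  }
  est <- point(mothers, fathers)
  ci <- NULL
  if (ci_reps > 0) {
    if (!is.null(rng_seed)) set.seed(rng_seed)
    boot <- replicate(ci_reps, {
      i <- sample.int(n, n, replace = TRUE)
      point(mothers[i], fathers[i])[1]
    })
    ci <- stats::quantile(boot, c(0.025, 0.975), names = FALSE)
  }
  list(nb = est[1], q_mother = est[2], q_father = est[3], ci = ci)
}

#' Effective number of breeders from linkage disequilibrium
#'
#' Burrows composite squared correlation of ALT dosages, averaged over
#' eligible locus pairs (interscaffold-only by default), bias-adjusted as
#' `r2' = r2 - (1/S + 3.19/S^2)` for sample size `S >= 30`, and inverted
#' under random mating as
#' `Nb = (1/3 + sqrt(1/9 - 2.76 r2')) / (2 r2')`.
#' Loci with minor allele frequency below `p_crit` are excluded. The 95% CI
#' is a delete-one jackknife over individuals on the `1/Nb` scale.
#'
#' @param gm a [genotype_matrix()].
#' @param p_crit MAF cutoff in `(0, 0.5)` (default 0.05).
#' @param pairs `"interscaffold"` (default) or `"all"`.
#' @param jackknife compute the CI (default TRUE).
#' @return list: `nb`, `r2`, `r2_adj`, `s`, `n_loci`, `n_pairs`, `ci`.
#'   `nb` is `Inf` (censored) when `r2'` is non-positive and `NA` when the
#'   discriminant is negative.
#' @export
nb_ld <- function(gm, p_crit = 0.05, pairs = c("interscaffold", "all"),
                  jackknife = TRUE) {
  pairs <- match.arg(pairs)
  stopifnot(p_crit > 0, p_crit < 0.5)
  S <- nrow(gm$geno)
  if (S < 30) stop("LD-based Nb requires at least 30 individuals")
  p_hat <- colMeans(gm$geno, na.rm = TRUE) / 2
  keep <- pmin(p_hat, 1 - p_hat) >= p_crit & !is.na(p_hat)
  X <- gm$geno[, keep, drop = FALSE]
  if (ncol(X) < 2) stop("fewer than 2 loci retained after the MAF filter")
  scaf <- gm$panel$scaffold[keep]
  eligible <- if (pairs == "interscaffold") {
    outer(scaf, scaf, "!=")
  } else {
    matrix(TRUE, ncol(X), ncol(X))
  }
  eligible[lower.tri(eligible, diag = TRUE)] <- FALSE
  if (!any(eligible)) stop("no eligible locus pairs under the pair scope")
  mean_r2 <- function(M) {
    r <- suppressWarnings(stats::cor(M, use = "pairwise.complete.obs"))
    mean(r[eligible]^2, na.rm = TRUE)
  }
  invert <- function(r2, s) {
    r2a <- r2 - (1 / s + 3.19 / s^2)
    if (is.na(r2a) || r2a <= 0) return(c(nb = Inf, r2a = r2a))
    disc <- 1 / 9 - 2.76 * r2a
    if (disc < 0) return(c(nb = NA_real_, r2a = r2a))
    c(nb = (1 / 3 + sqrt(disc)) / (2 * r2a), r2a = r2a)
  }
  r2 <- mean_r2(X)
  est <- invert(r2, S)
  ci <- NULL
  if (jackknife && is.finite(est["nb"])) {
    theta <- vapply(seq_len(S), function(i) {
      e <- invert(mean_r2(X[-i, , drop = FALSE]), S - 1)
      1 / e[["nb"]]
    }, numeric(1))
    theta <- theta[is.finite(theta)]
    m <- length(theta)
    se <- sqrt((m - 1) / m * sum((theta - mean(theta))^2))
    inv_ci <- 1 / est[["nb"]] + c(1.96, -1.96) * se
    ci <- 1 / pmax(inv_ci, 1e-12)
    ci <- sort(ci)
  }
  list(nb = est[["nb"]], r2 = r2, r2_adj = est[["r2a"]], s = S,
       n_loci = ncol(X), n_pairs = sum(eligible), ci = ci)
}
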