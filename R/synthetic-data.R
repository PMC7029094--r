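# Generators for every input the analyses consume: allele-frequency panels,
# HWE founders, Mendelian families, genotyping error/missingness with read
# counts, Balding-Nichols structured populations, and length-at-age mixtures.

#' Draw a panel of biallelic SNP allele frequencies
#'
#' Frequencies are drawn i.i.d. either from a truncated Beta distribution
#' (the default, a U-shaped spectrum typical of RAD SNP ascertainment) or
#' from an empirical histogram of observed frequencies. Loci are laid out on
#' artificial scaffolds so that consecutive loci are at least `spacing_bp`
#' apart, emulating an independent (unlinked) marker panel.
#'
#' @param n_loci number of loci (>= 1).
#' @param source either `"beta"` or `"empirical"`.
#' @param beta_shape length-2 positive shape parameters of the Beta source.
#' @param beta_trunc length-2 truncation interval for the Beta source.
#' @param empirical_freqs,empirical_weights frequencies and sampling weights
#'   of the empirical histogram source (weights default to uniform).
#' @param spacing_bp minimum spacing between consecutive loci (default 2 Mb).
#' @param loci_per_scaffold loci placed per artificial scaffold.
#' @param rng_seed integer seed.
#' @return A [locus_panel()] with `n_loci` rows.
#' @export
draw_allele_frequencies <- function(n_loci,
                                    source = c("beta", "empirical"),
                                    beta_shape = c(0.7, 0.7),
                                    beta_trunc = c(0.05, 0.95),
                                    empirical_freqs = NULL,
                                    empirical_weights = NULL,
                                    spacing_bp = 2e6,
                                    loci_per_scaffold = 10L,
                                    rng_seed = NULL) {
  stopifnot(n_loci >= 1)
  source <- match.arg(source)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  if (source == "beta") {
    stopifnot(all(beta_shape > 0), beta_trunc[1] < beta_trunc[2])
    # inverse-CDF sampling from the truncated beta
    lo <- stats::pbeta(beta_trunc[1], beta_shape[1], beta_shape[2])
    hi <- stats::pbeta(beta_trunc[2], beta_shape[1], beta_shape[2])
    u <- stats::runif(n_loci, lo, hi)
    freq <- stats::qbeta(u, beta_shape[1], beta_shape[2])
  } else {
    if (is.null(empirical_freqs) || length(empirical_freqs) == 0) {
      stop("empirical source requires a non-empty empirical_freqs histogram")
    }
    if (is.null(empirical_weights)) {
      empirical_weights <- rep(1, length(empirical_freqs))
    }
    freq <- sample(empirical_freqs, n_loci, replace = TRUE,
                   prob = empirical_weights)
  }
  n_scaf <- ceiling(n_loci / loci_per_scaffold)
  scaf_idx <- rep(seq_len(n_scaf), each = loci_per_scaffold)[seq_len(n_loci)]
  within <- stats::ave(seq_len(n_loci), scaf_idx, FUN = seq_along)
  locus_panel(
    locus_id = sprintf("snp_%05d", seq_len(n_loci)),
    scaffold = sprintf("scaffold_%03d", scaf_idx),
    position = as.integer(1 + (within - 1) * spacing_bp),
    alt_freq = freq
  )
}

#' Simulate founder genotypes in Hardy-Weinberg proportions
#'
#' Each parent's ALT dosage at each locus is drawn Binomial(2, alt_freq).
#' No missingness and no sequencing channels: founders are the idealised
#' adults whose gametes seed [mendelian_offspring()].
#'
#' @param panel a [locus_panel()].
#' @param n_parents number of founders (>= 2).
#' @param prefix id prefix for the founders.
#' @param rng_seed integer seed.
#' @return A [genotype_matrix()].
#' @export
hwe_parent_genotypes <- function(panel, n_parents, prefix = "parent",
                                 rng_seed = NULL) {
  stopifnot(n_parents >= 2)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  L <- nrow(panel)
  geno <- matrix(
    stats::rbinom(n_parents * L, 2L, rep(panel$alt_freq, each = n_parents)),
    nrow = n_parents, ncol = L
  )
  genotype_matrix(geno, panel,
                  individuals = sprintf("%s_%04d", prefix, seq_len(n_parents)))
}

#' Mendelian offspring of two parental genotype vectors
#'
#' Each parent transmits one of its two alleles uniformly at random,
#' independently per locus. A missing parental genotype makes the offspring
#' genotype missing at that locus.
#'
#' @param mother_g,father_g integer dosage vectors on the same panel.
#' @param rng_seed integer seed.
#' @return integer dosage vector of the same length.
#' @export
mendelian_offspring <- function(mother_g, father_g, rng_seed = NULL) {
  stopifnot(length(mother_g) == length(father_g))
  if (!is.null(rng_seed)) set.seed(rng_seed)
  L <- length(mother_g)
  miss <- is.na(mother_g) | is.na(father_g)
  # a parent with dosage g transmits ALT with probability g/2
  pm <- ifelse(miss, 0, mother_g / 2)
  pf <- ifelse(miss, 0, father_g / 2)
  out <- stats::rbinom(L, 1L, pm) + stats::rbinom(L, 1L, pf)
  out[miss] <- NA_integer_
  as.integer(out)
}

#' Corrupt genotypes with error, missingness and read-count channels
#'
#' Each called genotype is independently replaced by a Hardy-Weinberg draw
#' (probability `error_rate`) or masked (probability `missing_rate`). Depths
#' are drawn from a negative binomial (defaults: mean 30, dispersion 5,
#' matching a >= 10x mean-depth sequencing regime); heterozygote allele
#' depths are Binomial(depth, 0.5), homozygote reads all support the called
#' allele. GQ is drawn high for called genotypes.
#'
#' @param gm a [genotype_matrix()].
#' @param error_rate,missing_rate per-genotype rates in `[0, 1)`.
#' @param depth_mean,depth_dispersion negative-binomial depth model.
#' @param gq_called mean phred GQ assigned to called genotypes.
#' @param rng_seed integer seed.
#' @return A [genotype_matrix()] with gq/depth/allele-depth channels.
#' @export
corrupt_genotypes <- function(gm, error_rate = 0.01, missing_rate = 0.05,
                              depth_mean = 30, depth_dispersion = 5,
                              gq_called = 40, rng_seed = NULL) {
  stopifnot(error_rate >= 0, error_rate < 1, missing_rate >= 0, missing_rate < 1)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  geno <- gm$geno
  n <- length(geno)
  p <- rep(gm$panel$alt_freq, each = nrow(geno))
  err <- stats::runif(n) < error_rate & !is.na(geno)
  if (any(err)) {
    geno[err] <- stats::rbinom(sum(err), 2L, p[err])
  }
  miss <- stats::runif(n) < missing_rate
  geno[miss] <- NA_integer_
  depth <- matrix(
    stats::rnbinom(n, size = depth_dispersion, mu = depth_mean),
    nrow = nrow(geno)
  )
  depth[is.na(geno)] <- NA_integer_
  ad_alt <- matrix(NA_integer_, nrow(geno), ncol(geno))
  called <- !is.na(geno)
  ad_alt[called] <- stats::rbinom(sum(called), depth[called],
                                  geno[called] / 2)
  # homozygotes read only their own allele; hets are Binomial(depth, 0.5)
  ad_alt[called & geno == 0L] <- 0L
  ad_alt[called & geno == 2L] <- depth[called & geno == 2L]
  ad_ref <- depth - ad_alt
  gq <- matrix(NA_real_, nrow(geno), ncol(geno))
  gq[called] <- round(pmax(1, stats::rnorm(sum(called), gq_called, 5)))
  genotype_matrix(geno, gm$panel, individuals = gm$individuals,
                  gq = gq, depth = depth, ad_ref = ad_ref, ad_alt = ad_alt,
                  population = gm$population)
}

#' Simulate weakly structured populations (Balding-Nichols model)
#'
#' Population-specific allele frequencies are drawn from a Beta distribution
#' around the panel's ancestral frequencies with parameter `fst_target`
#' (shape `p(1-F)/F`, `(1-p)(1-F)/F`); genotypes are then Hardy-Weinberg
#' within each population. `fst_target = 0` copies the ancestral frequencies
#' into every population.
#'
#' @param panel a [locus_panel()] of ancestral frequencies.
#' @param n_pops number of populations (>= 2).
#' @param fst_target Balding-Nichols F parameter in `[0, 0.5)`.
#' @param n_per_pop individuals per population (recycled to `n_pops`).
#' @param rng_seed integer seed.
#' @return A [genotype_matrix()] with a `population` label per individual.
#' @export
structured_populations <- function(panel, n_pops, fst_target, n_per_pop,
                                   rng_seed = NULL) {
  stopifnot(fst_target >= 0, fst_target < 0.5)
  if (n_pops < 2) stop("at least two populations are required")
  if (!is.null(rng_seed)) set.seed(rng_seed)
  n_per_pop <- rep_len(n_per_pop, n_pops)
  L <- nrow(panel)
  geno_list <- vector("list", n_pops)
  for (k in seq_len(n_pops)) {
    p <- panel$alt_freq
    if (fst_target > 0) {
      ok <- p > 0 & p < 1
      F <- fst_target
      p[ok] <- stats::rbeta(sum(ok), p[ok] * (1 - F) / F,
                            (1 - p[ok]) * (1 - F) / F)
    }
    geno_list[[k]] <- matrix(
      stats::rbinom(n_per_pop[k] * L, 2L, rep(p, each = n_per_pop[k])),
      nrow = n_per_pop[k]
    )
  }
  geno <- do.call(rbind, geno_list)
  pops <- rep(sprintf("pop_%02d", seq_len(n_pops)), n_per_pop)
  genotype_matrix(
    geno, panel,
    individuals = sprintf("%s_ind_%03d", pops,
                          unlist(lapply(n_per_pop, seq_len))),
    population = pops
  )
}

#' Four-component Gaussian length-at-age mixture model
#'
#' @param means,sds component means and standard deviations (length-K, mm).
#' @param weights mixing proportions summing to 1.
#' @param ages age-class labels per component (ascending mean order).
#' @return An object of class `age_mixture`.
#' @export
age_mixture <- function(means = c(30, 70, 110, 150),
                        sds = c(8, 10, 12, 15),
                        weights = c(0.35, 0.3, 0.2, 0.15),
                        ages = c("0", "1", "2", "3+")) {
  K <- length(means)
  stopifnot(length(sds) == K, length(weights) == K, length(ages) == K,
            all(sds > 0), abs(sum(weights) - 1) < 1e-9)
  ord <- order(means)
  structure(
    list(K = K, means = means[ord], sds = sds[ord],
         weights = weights[ord], ages = ages),
    class = "age_mixture"
  )
}

#' Simulate body lengths from an age mixture
#'
#' @param model an [age_mixture()].
#' @param n number of larvae (>= 1).
#' @param rng_seed integer seed.
#' @return data.frame with `length_mm`, true `component` (1..K) and `age`.
#' @export
simulate_lengths <- function(model, n, rng_seed = NULL) {
  stopifnot(inherits(model, "age_mixture"))
  if (n < 1) stop("n must be >= 1")
  if (!is.null(rng_seed)) set.seed(rng_seed)
  comp <- sample.int(model$K, n, replace = TRUE, prob = model$weights)
  data.frame(
    length_mm = stats::rnorm(n, model$means[comp], model$sds[comp]),
    component = comp,
    age = model$ages[comp],
    stringsAsFactors = FALSE
  )
}
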