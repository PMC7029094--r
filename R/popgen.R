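# Population-genomic summaries: per-locus diversity, Nei differentiation,
# DAPC-style ordination with percentile-rank loadings, a trimmed
# chi-square F_ST outlier scan, and HDplot paralog statistics.

pop_labels <- function(gm, labels = NULL) {
  if (is.null(labels)) labels <- gm$population
  if (is.null(labels)) stop("population labels are required")
  stopifnot(length(labels) == nrow(gm$geno))
  as.character(labels)
}

#' Per-locus, per-population diversity statistics
#'
#' Observed heterozygosity, unbiased expected heterozygosity
#' `2 p q 2n / (2n - 1)`, Wright's `F_IS = 1 - H_o / H_e` (Nei convention;
#' `NA` where a cell is monomorphic) and minor allele frequency.
#'
#' @param gm a [genotype_matrix()].
#' @param labels per-individual population labels (defaults to
#'   `gm$population`).
#' @return data.frame: one row per locus x population with `n`, `ho`,
#'   `he`, `fis`, `maf`.
#' @export
locus_diversity <- function(gm, labels = NULL) {
  labels <- pop_labels(gm, labels)
  pops <- sort(unique(labels))
  out <- lapply(pops, function(pop) {
    G <- gm$geno[labels == pop, , drop = FALSE]
    n <- colSums(!is.na(G))
    p <- colMeans(G, na.rm = TRUE) / 2
    ho <- colMeans(G == 1L, na.rm = TRUE)
    he <- 2 * p * (1 - p) * (2 * n) / pmax(2 * n - 1, 1)
    fis <- ifelse(he > 0, 1 - ho / he, NA_real_)
    data.frame(locus_id = gm$panel$locus_id, population = pop,
               n = n, ho = ho, he = he, fis = fis,
               maf = pmin(p, 1 - p), row.names = NULL,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# Per-locus Nei & Chesser (1983) corrected Hs/Ht components across the
# populations in `labels`. Returns a data.frame with both corrected and
# uncorrected components per locus.
nei_components <- function(gm, labels) {
  pops <- sort(unique(labels))
  r <- length(pops)
  L <- ncol(gm$geno)
  percol <- function(f) {
    matrix(vapply(pops, function(pop)
      f(gm$geno[labels == pop, , drop = FALSE]), numeric(L)), nrow = L)
  }
  nmat <- percol(function(G) colSums(!is.na(G)))
  pmat <- percol(function(G) colMeans(G, na.rm = TRUE) / 2)
  homat <- percol(function(G) colMeans(G == 1L, na.rm = TRUE))
  n_tilde <- r / rowSums(1 / pmax(nmat, 1))        # harmonic mean sample size
  ho_bar <- rowMeans(homat)
  sum_p2 <- rowMeans(pmat^2 + (1 - pmat)^2)
  p_bar <- rowMeans(pmat)
  hs0 <- 1 - sum_p2
  ht0 <- 1 - (p_bar^2 + (1 - p_bar)^2)
  hs <- n_tilde / (n_tilde - 1) * (hs0 - ho_bar / (2 * n_tilde))
  ht <- ht0 + hs / (r * n_tilde) - ho_bar / (2 * r * n_tilde)
  data.frame(locus_id = gm$panel$locus_id, hs = hs, ht = ht,
             hs_uncorrected = hs0, ht_uncorrected = ht0,
             stringsAsFactors = FALSE)
}

#' Nei differentiation: pairwise and global G_ST, per-locus F_ST
#'
#' Nei & Chesser sample-size-corrected `H_S` and `H_T`;
#' `G_ST = (H_T - H_S) / H_T` per population pair and globally. The
#' multilocus value is a ratio of averages
#' (`sum(H_T - H_S) / sum(H_T)`) by default; `ratio_of_averages = FALSE`
#' averages per-locus ratios instead. Small negative per-locus values are
#' an expected property of the estimator and retained.
#'
#' @param gm a [genotype_matrix()].
#' @param labels per-individual population labels.
#' @param ratio_of_averages multilocus aggregation rule (default TRUE).
#' @return list of class `differentiation_result`: `pairwise` (symmetric
#'   matrix), `global`, `per_locus` (corrected F_ST),
#'   `per_locus_uncorrected`.
#' @export
nei_differentiation <- function(gm, labels = NULL, ratio_of_averages = TRUE) {
  labels <- pop_labels(gm, labels)
  pops <- sort(unique(labels))
  if (length(pops) < 2) stop("at least 2 populations are required")
  agg <- function(comp) {
    if (ratio_of_averages) {
      sum(comp$ht - comp$hs, na.rm = TRUE) / sum(comp$ht, na.rm = TRUE)
    } else {
      mean((comp$ht - comp$hs) / comp$ht, na.rm = TRUE)
    }
  }
  comp_all <- nei_components(gm, labels)
  pw <- matrix(0, length(pops), length(pops), dimnames = list(pops, pops))
  for (a in seq_along(pops)[-length(pops)]) for (b in (a + 1):length(pops)) {
    g <- nei_differentiation_pair(gm, labels, pops[c(a, b)], agg)
    pw[a, b] <- pw[b, a] <- g
  }
  structure(
    list(pairwise = pw, global = agg(comp_all),
         per_locus = (comp_all$ht - comp_all$hs) / comp_all$ht,
         per_locus_uncorrected =
           (comp_all$ht_uncorrected - comp_all$hs_uncorrected) /
           comp_all$ht_uncorrected,
         locus_id = comp_all$locus_id),
    class = "differentiation_result"
  )
}

nei_differentiation_pair <- function(gm, labels, pair, agg) {
  keep <- labels %in% pair
  sub <- gm
  sub$geno <- gm$geno[keep, , drop = FALSE]
  agg(nei_components(sub, labels[keep]))
}

#' DAPC-style ordination with percentile-rank locus loadings
#'
#' Missing dosages are mean-imputed per locus, the matrix is centred and
#' reduced by PCA, and linear discriminant analysis is run on the retained
#' principal components. Discriminant loadings are back-projected onto
#' loci, summarised as the sum of squared loadings across discriminant
#' axes, and reported as percentile ranks spanning `[0, 100]`. The
#' procedure is fully deterministic.
#'
#' @param gm a [genotype_matrix()].
#' @param labels per-individual group labels (>= 2 groups).
#' @param n_pcs principal components retained
#'   (`<= min(individuals - 1, loci)`).
#' @return list of class `dapc_result`: `ind_coord` (discriminant
#'   coordinates), `assignment` (predicted group), `loo_assignment`
#'   (leave-one-out), `loading_percentile` (per locus), `loading` (raw).
#' @export
dapc_ordinate <- function(gm, labels = NULL, n_pcs) {
  labels <- pop_labels(gm, labels)
  if (length(unique(labels)) < 2) stop("at least 2 groups are required")
  X <- gm$geno
  mode(X) <- "double"
  mu <- colMeans(X, na.rm = TRUE)
  for (j in seq_len(ncol(X))) X[is.na(X[, j]), j] <- mu[j]
  stopifnot(n_pcs >= 1, n_pcs <= min(nrow(X) - 1, ncol(X)))
  pca <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  scores <- pca$x[, seq_len(n_pcs), drop = FALSE]
  fit <- MASS::lda(scores, grouping = factor(labels))
  pred <- stats::predict(fit)
  loo <- MASS::lda(scores, grouping = factor(labels), CV = TRUE)$class
  locus_load <- pca$rotation[, seq_len(n_pcs), drop = FALSE] %*% fit$scaling
  score <- rowSums(locus_load^2)
  # ties.method = "min" so tied minima (e.g. monomorphic loci with zero
  # loading) anchor the scale at 0
  pct <- (rank(score, ties.method = "min") - 1) /
    (length(score) - 1) * 100
  structure(
    list(ind_coord = pred$x, assignment = as.character(pred$class),
         loo_assignment = as.character(loo),
         loading = score, loading_percentile = pct,
         locus_id = gm$panel$locus_id, n_pcs = n_pcs),
    class = "dapc_result"
  )
}

#' Trimmed chi-square F_ST outlier scan
#'
#' Infers the neutral F_ST distribution from the trimmed core of the
#' observed per-locus values by maximum likelihood, assuming
#' `Fst * df / Fst_bar ~ chi-square(df)` doubly truncated at the trim
#' quantiles, then computes right-tail p-values for every locus against
#' the fitted neutral distribution and flags outliers at a
#' Benjamini-Hochberg FDR. Mirrors the two-statistic design of
#' trimmed-likelihood outlier scans: the uncorrected statistic drives the
#' chi-square fit while the corrected one is reported per locus.
#'
#' @param fst per-locus F_ST vector (sample-size corrected, reported).
#' @param fst_uncorrected per-locus uncorrected F_ST driving the fit
#'   (defaults to `fst`).
#' @param trim fraction trimmed from each tail (default 0.05).
#' @param fdr false discovery rate for flags (default 0.10).
#' @param min_fst loci with uncorrected F_ST at or below this value are
#'   excluded from the fit (default 0, excluding non-positive values the
#'   chi-square model cannot represent; they receive p = 1).
#' @return list of class `outlier_scan`: `fst_bar`, `df`, `p_value`,
#'   `q_value`, `outlier` (logical), `n_fit`, `convergence`.
#' @export
outlier_scan <- function(fst, fst_uncorrected = fst, trim = 0.05,
                         fdr = 0.10, min_fst = 0) {
  stopifnot(length(fst) == length(fst_uncorrected), trim >= 0, trim < 0.5)
  usable <- is.finite(fst_uncorrected) & fst_uncorrected > min_fst
  if (sum(usable) < 50) stop("need >= 50 usable loci for a stable fit")
  x <- fst_uncorrected[usable]
  bounds <- stats::quantile(x, c(trim, 1 - trim), names = FALSE)
  core <- x[x >= bounds[1] & x <= bounds[2]]
  # truncated-ML fit of (fst_bar, df): x * df / fst_bar ~ chisq(df) on
  # [lo, hi]; optimise on log scale
  nll <- function(par) {
    fbar <- exp(par[1]); df <- exp(par[2])
    cc <- df / fbar
    z <- stats::pchisq(bounds[2] * cc, df) - stats::pchisq(bounds[1] * cc, df)
    if (!is.finite(z) || z <= 0) return(1e10)
    -sum(stats::dchisq(core * cc, df, log = TRUE) + log(cc)) +
      length(core) * log(z)
  }
  mm_df <- 2 * mean(core)^2 / max(stats::var(core), 1e-12)
  opt <- stats::optim(c(log(mean(core)), log(min(max(mm_df, 0.5), 100))),
                      nll, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-10))
  if (opt$convergence != 0) {
    stop("trimmed chi-square fit did not converge; optim code ",
         opt$convergence, ", value ", signif(opt$value, 6))
  }
  fst_bar <- exp(opt$par[1]); df <- exp(opt$par[2])
  p <- rep(1, length(fst))
  p[usable] <- stats::pchisq(fst_uncorrected[usable] * df / fst_bar, df,
                             lower.tail = FALSE)
  q <- rep(NA_real_, length(fst))
  q[usable] <- stats::p.adjust(p[usable], method = "BH")
  structure(
    list(fst = fst, fst_uncorrected = fst_uncorrected,
         fst_bar = fst_bar, df = df,
         p_value = p, q_value = q,
         outlier = !is.na(q) & q <= fdr,
         n_fit = length(core), convergence = opt$convergence),
    class = "outlier_scan"
  )
}

#' HDplot paralog statistics
#'
#' For each locus, over its heterozygous calls: `n_A` = summed REF reads,
#' `n_B` = summed ALT reads, read-ratio deviation
#' `D = (n_A - n_B) / sqrt(n_A + n_B)`, and `H` = proportion of called
#' genotypes that are heterozygous. Putative paralogs are flagged at
#' `H > h_max` or `|D| > d_max`.
#'
#' @param gm a [genotype_matrix()] with allele-depth channels.
#' @param h_max heterozygosity flag threshold (default 0.60).
#' @param d_max absolute read-ratio z-score threshold (default 7).
#' @return data.frame of class `hdplot_stats`: per locus `h`, `d`,
#'   `n_het`, `flag`.
#' @export
hdplot <- function(gm, h_max = 0.60, d_max = 7) {
  if (is.null(gm$ad_ref) || is.null(gm$ad_alt)) {
    stop("allele-depth channels (ad_ref, ad_alt) are required")
  }
  het <- !is.na(gm$geno) & gm$geno == 1L
  n_called <- colSums(!is.na(gm$geno))
  h <- colSums(het) / pmax(n_called, 1)
  ar <- gm$ad_ref; aa <- gm$ad_alt
  ar[!het] <- NA; aa[!het] <- NA
  n_a <- colSums(ar, na.rm = TRUE)
  n_b <- colSums(aa, na.rm = TRUE)
  d <- ifelse(colSums(het) > 0 & n_a + n_b > 0,
              (n_a - n_b) / sqrt(n_a + n_b), NA_real_)
  out <- data.frame(
    locus_id = gm$panel$locus_id, h = h, d = d, n_het = colSums(het),
    flag = h > h_max | (!is.na(d) & abs(d) > d_max),
    stringsAsFactors = FALSE
  )
  class(out) <- c("hdplot_stats", "data.frame")
  out
}

#' Per-SNP heterozygote allele read balance
#'
#' Mean REF-read fraction over heterozygous calls per SNP; `NA` where a
#' SNP has no heterozygotes. A well-behaved SNP sits near 0.5; the
#' `in_band` column flags values inside `[0.3, 0.7]`.
#'
#' @param gm a [genotype_matrix()] with allele depths.
#' @return data.frame: per locus `ab`, `n_het`, `in_band`.
#' @export
allele_balance <- function(gm) {
  if (is.null(gm$ad_ref) || is.null(gm$ad_alt)) {
    stop("allele-depth channels (ad_ref, ad_alt) are required")
  }
  het <- !is.na(gm$geno) & gm$geno == 1L
  frac <- gm$ad_ref / (gm$ad_ref + gm$ad_alt)
  frac[!het] <- NA
  ab <- colMeans(frac, na.rm = TRUE)
  ab[colSums(het) == 0] <- NA_real_
  data.frame(locus_id = gm$panel$locus_id, ab = ab,
             n_het = colSums(het),
             in_band = !is.na(ab) & ab >= 0.3 & ab <= 0.7,
             stringsAsFactors = FALSE)
}
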