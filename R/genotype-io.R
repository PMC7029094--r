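# Standard-format I/O and the panel's genotype/site/individual filters:
# VCF 4.2 (GT/GQ/DP/AD channels) via vcfR for parsing and a plain-text
# writer, metadata TSV, the staged filter pipeline, 2-Mb independent-locus
# selection, one-per-family downsampling and Gaussian-mixture ageing.

fmt_or_dot <- function(m, i, j) {
  if (is.null(m)) return(NULL)
  v <- m[i, j]
  ifelse(is.na(v), ".", format(v, trim = TRUE, scientific = FALSE))
}

#' Write a genotype matrix as plain-text VCF 4.2
#'
#' Emits GT plus whichever of GQ/DP/AD channels the object carries.
#' Synthetic loci are written with placeholder REF/ALT alleles (A/C);
#' dosage is the count of the ALT allele.
#'
#' @param gm a [genotype_matrix()].
#' @param path output path (`.vcf`, uncompressed).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  panel <- gm$panel
  fields <- c("GT",
              if (!is.null(gm$gq)) "GQ",
              if (!is.null(gm$depth)) "DP",
              if (!is.null(gm$ad_ref) && !is.null(gm$ad_alt)) "AD")
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=lampreykin",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    if ("GQ" %in% fields)
      '##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="Genotype quality">',
    if ("DP" %in% fields)
      '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    if ("AD" %in% fields)
      '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allele depths">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gm$individuals), collapse = "\t")
  )
  gt_code <- c("0/0", "0/1", "1/1")
  n <- nrow(gm$geno)
  body <- vapply(seq_len(nrow(panel)), function(j) {
    gt <- ifelse(is.na(gm$geno[, j]), "./.", gt_code[gm$geno[, j] + 1L])
    cols <- list(gt)
    if ("GQ" %in% fields) cols <- c(cols, list(fmt_or_dot(gm$gq, seq_len(n), j)))
    if ("DP" %in% fields) cols <- c(cols, list(fmt_or_dot(gm$depth, seq_len(n), j)))
    if ("AD" %in% fields) {
      ad <- paste(fmt_or_dot(gm$ad_ref, seq_len(n), j),
                  fmt_or_dot(gm$ad_alt, seq_len(n), j), sep = ",")
      ad[is.na(gm$ad_ref[, j]) & is.na(gm$ad_alt[, j])] <- "."
      cols <- c(cols, list(ad))
    }
    samples <- do.call(paste, c(cols, sep = ":"))
    paste(c(panel$scaffold[j], panel$position[j], panel$locus_id[j],
            "A", "C", ".", "PASS", ".", paste(fields, collapse = ":"),
            samples), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a multi-sample VCF into a genotype matrix
#'
#' Parses biallelic SNP records (via vcfR) into ALT dosages with GQ, DP
#' and allele-depth channels where present. Multiallelic records are
#' skipped with a message. Panel allele frequencies are estimated from the
#' sample dosages.
#'
#' @param path VCF file (plain or gzipped).
#' @return A [genotype_matrix()].
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- t(as.matrix(fix))
  multi <- grepl(",", fix[, "ALT"]) | nchar(fix[, "REF"]) != 1 |
    nchar(fix[, "ALT"]) != 1
  if (any(multi)) {
    message(sum(multi), " multiallelic/non-SNP record(s) skipped")
  }
  keep <- which(!multi)
  if (!length(keep)) stop("no biallelic SNP records in ", path)
  gt <- vcfR::extract.gt(v, element = "GT")[keep, , drop = FALSE]
  alt_count <- function(x) {
    x <- sub("\\|", "/", x)
    out <- rep(NA_integer_, length(x))
    out[x %in% c("0/0")] <- 0L
    out[x %in% c("0/1", "1/0")] <- 1L
    out[x %in% c("1/1")] <- 2L
    out
  }
  geno <- t(apply(gt, 1, alt_count))
  if (ncol(gt) == 1) geno <- matrix(geno, ncol = 1)
  geno <- t(geno)  # individuals x loci
  dimnames(geno) <- list(colnames(gt), NULL)
  chan <- function(el, fun = as.numeric) {
    if (!el %in% vcfR::vcf_field_names(v, tag = "FORMAT")$ID) return(NULL)
    m <- vcfR::extract.gt(v, element = el)[keep, , drop = FALSE]
    t(matrix(suppressWarnings(fun(m)), nrow = nrow(m),
             dimnames = dimnames(m)))
  }
  gq <- chan("GQ")
  dp <- chan("DP")
  ad_ref <- ad_alt <- NULL
  if ("AD" %in% vcfR::vcf_field_names(v, tag = "FORMAT")$ID) {
    ad <- vcfR::extract.gt(v, element = "AD")[keep, , drop = FALSE]
    ad_ref <- t(matrix(suppressWarnings(as.numeric(sub(",.*", "", ad))),
                       nrow = nrow(ad)))
    ad_alt <- t(matrix(suppressWarnings(as.numeric(sub(".*,", "", ad))),
                       nrow = nrow(ad)))
    ad_ref[t(ad) == "."] <- NA
    ad_alt[t(ad) == "."] <- NA
  }
  ids <- fix[keep, "ID"]
  if (anyNA(ids) || any(ids == ".")) {
    ids <- paste0(fix[keep, "CHROM"], "_", fix[keep, "POS"])
  }
  panel <- locus_panel(
    locus_id = ids, scaffold = fix[keep, "CHROM"],
    position = as.integer(fix[keep, "POS"]),
    alt_freq = pmin(pmax(colMeans(geno, na.rm = TRUE) / 2, 0), 1)
  )
  genotype_matrix(geno, panel, individuals = colnames(gt),
                  gq = gq, depth = dp, ad_ref = ad_ref, ad_alt = ad_alt)
}

#' Write / read the sample metadata table
#'
#' Tab-separated with columns `sample_id`, `population`, `location`,
#' `length_mm`, `cohort`.
#'
#' @param meta data.frame with (at least) those columns.
#' @param path TSV path.
#' @return `path` invisibly / the data.frame.
#' @export
write_metadata <- function(meta, path) {
  need <- c("sample_id", "population", "location", "length_mm", "cohort")
  stopifnot(all(need %in% names(meta)))
  utils::write.table(meta[, need], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_metadata
#' @export
read_metadata <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' Filter configuration for a RAD-capture SNP panel
#'
#' Defaults follow the panel's published regime: genotypes masked below
#' GQ 10; individuals dropped above 75% missing (50% for the
#' population-genetic subset); sites dropped below 10x mean depth or above
#' 30% missing; 2-Mb spacing and an 80% genotyping rate for the
#' independent pedigree panel.
#'
#' @param gq_min,site_mean_depth_min,site_missing_max
#'   genotype/site thresholds.
#' @param individual_missing_max per-individual missingness cap.
#' @param genotyping_rate_min,spacing_bp independent-panel selection rules.
#' @return list of class `filter_config`.
#' @export
filter_config <- function(gq_min = 10, site_mean_depth_min = 10,
                          site_missing_max = 0.30,
                          individual_missing_max = 0.75,
                          genotyping_rate_min = 0.80,
                          spacing_bp = 2e6) {
  stopifnot(site_missing_max >= 0, site_missing_max <= 1,
            individual_missing_max >= 0, individual_missing_max <= 1,
            genotyping_rate_min >= 0, genotyping_rate_min <= 1)
  structure(as.list(environment()), class = "filter_config")
}

#' Apply the staged genotype / individual / site filters
#'
#' Order is fixed (it changes survivor counts): (1) mask genotypes below
#' `gq_min`; (2) remove individuals above `individual_missing_max`
#' missing; (3) remove sites below `site_mean_depth_min` mean depth, then
#' sites above `site_missing_max` missing. Any threshold set to `NULL` (or
#' a channel that is absent) disables its stage.
#'
#' @param gm a [genotype_matrix()].
#' @param cfg a [filter_config()].
#' @return list: `gm` (filtered) and `report` (counts per stage).
#' @export
apply_filters <- function(gm, cfg = filter_config()) {
  rep0 <- list(
    genotypes_masked_gq = 0L,
    individuals_in = nrow(gm$geno), individuals_removed = 0L,
    sites_in = ncol(gm$geno), sites_removed_depth = 0L,
    sites_removed_missing = 0L
  )
  if (!is.null(cfg$gq_min) && !is.null(gm$gq)) {
    mask <- !is.na(gm$gq) & gm$gq < cfg$gq_min & !is.na(gm$geno)
    rep0$genotypes_masked_gq <- sum(mask)
    gm$geno[mask] <- NA_integer_
  }
  if (!is.null(cfg$individual_missing_max)) {
    miss_i <- rowMeans(is.na(gm$geno))
    drop_i <- miss_i > cfg$individual_missing_max
    rep0$individuals_removed <- sum(drop_i)
    if (any(drop_i)) gm <- subset_gm(gm, individuals = which(!drop_i))
  }
  if (!is.null(cfg$site_mean_depth_min) && !is.null(gm$depth)) {
    md <- colMeans(gm$depth, na.rm = TRUE)
    md[is.nan(md)] <- 0
    drop_s <- md < cfg$site_mean_depth_min
    rep0$sites_removed_depth <- sum(drop_s)
    if (any(drop_s)) gm <- subset_gm(gm, loci = which(!drop_s))
  }
  if (!is.null(cfg$site_missing_max)) {
    miss_s <- colMeans(is.na(gm$geno))
    drop_s <- miss_s > cfg$site_missing_max
    rep0$sites_removed_missing <- sum(drop_s)
    if (any(drop_s)) gm <- subset_gm(gm, loci = which(!drop_s))
  }
  rep0$individuals_out <- nrow(gm$geno)
  rep0$sites_out <- ncol(gm$geno)
  list(gm = gm, report = rep0)
}

#' Select an independent (spaced) locus panel
#'
#' Per scaffold, greedy left-to-right: keep the first locus genotyped in
#' more than `genotyping_rate_min` of individuals, then the next eligible
#' locus at least `spacing_bp` downstream, and so on. With
#' `maf_prefer = TRUE`, the highest-MAF eligible locus within each spacing
#' window is kept instead of the left-most.
#'
#' @param panel a [locus_panel()].
#' @param gm a [genotype_matrix()] on that panel (for genotyping rates and
#'   MAF); `NULL` treats every locus as eligible.
#' @param cfg a [filter_config()] supplying `spacing_bp` and
#'   `genotyping_rate_min`.
#' @param maf_prefer prefer high-MAF loci within spacing windows.
#' @return character vector of retained `locus_id`s.
#' @export
select_independent_loci <- function(panel, gm = NULL, cfg = filter_config(),
                                    maf_prefer = FALSE) {
  eligible <- rep(TRUE, nrow(panel))
  maf <- panel_maf(panel)
  if (!is.null(gm)) {
    rate <- colMeans(!is.na(gm$geno))
    eligible <- rate > cfg$genotyping_rate_min
    p <- colMeans(gm$geno, na.rm = TRUE) / 2
    maf <- pmin(p, 1 - p)
  }
  keep <- character(0)
  for (sc in unique(panel$scaffold)) {
    rows <- which(panel$scaffold == sc & eligible)
    rows <- rows[order(panel$position[rows])]
    last <- -Inf
    i <- 1L
    while (i <= length(rows)) {
      pos <- panel$position[rows[i]]
      if (pos - last < cfg$spacing_bp && is.finite(last)) { i <- i + 1L; next }
      if (maf_prefer) {
        # all eligible loci within one spacing window of this anchor
        win <- rows[panel$position[rows] >= pos &
                      panel$position[rows] < pos + cfg$spacing_bp]
        pick <- win[which.max(maf[win])]
      } else {
        pick <- rows[i]
      }
      keep <- c(keep, panel$locus_id[pick])
      last <- panel$position[pick]
      i <- i + 1L
    }
  }
  keep
}

#' Downsample a cohort to one member per full-sib family
#'
#' Keeps the member with the highest genotype call rate in each family
#' (ties broken by id order).
#'
#' @param gm a [genotype_matrix()].
#' @param families a `sib_families` object partitioning `gm$individuals`.
#' @return A [genotype_matrix()] with one individual per family.
#' @export
downsample_families <- function(gm, families) {
  members <- unlist(families$families)
  if (!setequal(members, gm$individuals) ||
      length(members) != length(gm$individuals)) {
    stop("families must partition the individuals of the genotype matrix")
  }
  rate <- rowMeans(!is.na(gm$geno))
  names(rate) <- gm$individuals
  keep <- vapply(families$families, function(f) {
    f <- sort(f)
    f[which.max(rate[f])]
  }, character(1))
  subset_gm(gm, individuals = match(keep, gm$individuals))
}

#' Fit a Gaussian length-at-age mixture and assign age classes
#'
#' EM fit of a K-component Gaussian mixture to larval body lengths:
#' convergence at `1e-8` relative change in log-likelihood, at most 500
#' iterations, variance floor `1e-4`. Two deterministic quantile-based
#' starts are run (component means anchored at the `(2k - 1) / 2K` sample
#' quantiles, and at the same levels of the data range) and the fit with
#' the higher final log-likelihood is kept; a single quantile start can
#' stall in a local optimum when mixing weights are uneven. Individuals
#' are assigned by maximum posterior; components map to age classes in
#' ascending-mean order.
#'
#' @param lengths numeric body lengths (mm), `>= 5 * K` observations.
#' @param K components (default 4: ages 0, 1, 2, 3+).
#' @param ages age labels, ascending.
#' @return list of class `age_fit`: `model` (an [age_mixture()]),
#'   `assignment` (age per individual), `component`, `posterior`,
#'   `loglik_trace`, `degenerate` (variance floor hit).
#' @export
assign_ages <- function(lengths, K = 4L, ages = c("0", "1", "2", "3+")) {
  stopifnot(length(ages) == K)
  x <- lengths[!is.na(lengths)]
  n <- length(x)
  if (n < 5 * K) stop("need at least ", 5 * K, " observations for K = ", K)
  run_em <- function(mu0) {
    mu <- mu0
    sig2 <- rep(max(stats::var(x) / K^2, 1e-4), K)
    w <- rep(1 / K, K)
    ll_old <- -Inf; trace <- numeric(0); converged <- FALSE
    post <- NULL
    for (iter in seq_len(500)) {
      dens <- vapply(seq_len(K), function(k)
        w[k] * stats::dnorm(x, mu[k], sqrt(sig2[k])), numeric(n))
      rowsum_d <- rowSums(dens)
      ll <- sum(log(pmax(rowsum_d, .Machine$double.xmin)))
      trace <- c(trace, ll)
      if (is.finite(ll_old) &&
          abs(ll - ll_old) <= 1e-8 * (abs(ll_old) + 1e-8)) {
        converged <- TRUE
        break
      }
      ll_old <- ll
      post <- dens / rowsum_d
      nk <- colSums(post)
      w <- nk / n
      mu <- colSums(post * x) / nk
      sig2 <- pmax(colSums(post * (x - rep(mu, each = n))^2) / nk, 1e-4)
    }
    list(mu = mu, sig2 = sig2, w = w, trace = trace,
         converged = converged, ll = trace[length(trace)])
  }
  levels <- (2 * seq_len(K) - 1) / (2 * K)
  starts <- list(
    stats::quantile(x, levels, names = FALSE),
    min(x) + levels * (max(x) - min(x))
  )
  fits <- lapply(starts, run_em)
  fits <- Filter(function(f) f$converged, fits)
  if (!length(fits)) {
    stop("EM did not converge in 500 iterations from any start")
  }
  best <- fits[[which.max(vapply(fits, `[[`, numeric(1), "ll"))]]
  mu <- best$mu; sig2 <- best$sig2; w <- best$w; trace <- best$trace
  ord <- order(mu)
  mu <- mu[ord]; sig2 <- sig2[ord]; w <- w[ord]
  dens <- vapply(seq_len(K), function(k)
    w[k] * stats::dnorm(x, mu[k], sqrt(sig2[k])), numeric(n))
  post <- dens / rowSums(dens)
  comp <- max.col(post, ties.method = "first")
  # map back onto the original vector (NA lengths stay NA)
  comp_full <- rep(NA_integer_, length(lengths))
  comp_full[!is.na(lengths)] <- comp
  structure(
    list(
      model = age_mixture(means = mu, sds = sqrt(sig2),
                          weights = w / sum(w), ages = ages),
      assignment = ages[comp_full], component = comp_full,
      posterior = post, loglik_trace = trace,
      degenerate = any(sig2 <= 1e-4 + 1e-12)
    ),
    class = "age_fit"
  )
}
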