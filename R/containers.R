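#' Construct a locus panel
#'
#' A locus panel describes the biallelic SNP loci a genotype matrix is scored
#' at: an identifier, a genomic coordinate (scaffold + 1-based position) and
#' the population ALT-allele frequency the locus was simulated (or estimated)
#' at. Monomorphic loci (frequency 0 or 1) are permitted and flagged, not
#' rejected, because panels derived from real VCFs can contain them.
#'
#' @param locus_id character vector of unique locus identifiers.
#' @param scaffold character vector of scaffold/chromosome names.
#' @param position integer vector of 1-based positions (strictly positive).
#' @param alt_freq numeric vector of ALT-allele frequencies in `[0, 1]`.
#' @return A `data.frame` of class `locus_panel` with one row per locus and a
#'   logical `monomorphic` column.
#' @export
locus_panel <- function(locus_id, scaffold, position, alt_freq) {
  n <- length(locus_id)
  stopifnot(
    length(scaffold) == n, length(position) == n, length(alt_freq) == n,
    !anyDuplicated(locus_id)
  )
  position <- as.integer(position)
  if (any(position < 1L)) stop("positions must be strictly positive (1-based)")
  if (anyDuplicated(paste(scaffold, position))) {
    stop("(scaffold, position) pairs must be unique")
  }
  if (any(alt_freq < 0 | alt_freq > 1)) stop("alt_freq must lie in [0, 1]")
  out <- data.frame(
    locus_id = as.character(locus_id),
    scaffold = as.character(scaffold),
    position = position,
    alt_freq = as.numeric(alt_freq),
    monomorphic = alt_freq <= 0 | alt_freq >= 1,
    stringsAsFactors = FALSE
  )
  class(out) <- c("locus_panel", "data.frame")
  out
}

#' Minor allele frequency of each panel locus
#'
#' @param panel a [locus_panel()].
#' @return numeric vector in `[0, 0.5]`.
#' @export
panel_maf <- function(panel) pmin(panel$alt_freq, 1 - panel$alt_freq)

#' Construct a genotype matrix with sequencing channels
#'
#' The central genotype container: individuals x loci ALT-allele dosages in
#' `{0, 1, 2, NA}`, with optional per-cell genotype quality (GQ, phred-like),
#' read depth (DP) and ref/alt allele depths (AD). Invariants enforced:
#' dimensions agree with the panel, dosages are in range, and
#' `depth = ad_ref + ad_alt` wherever allele depths are present.
#'
#' @param geno integer matrix (individuals x loci) of ALT dosages, NA = missing.
#' @param panel a [locus_panel()] with `ncol(geno)` rows.
#' @param individuals character vector of sample ids (defaults to rownames).
#' @param gq,depth,ad_ref,ad_alt optional numeric matrices of the same
#'   dimension as `geno`.
#' @param population optional character vector of per-individual population
#'   labels.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(geno, panel, individuals = rownames(geno),
                            gq = NULL, depth = NULL,
                            ad_ref = NULL, ad_alt = NULL,
                            population = NULL) {
  geno <- as.matrix(geno)
  if (is.null(individuals)) individuals <- paste0("ind_", seq_len(nrow(geno)))
  stopifnot(
    nrow(panel) == ncol(geno),
    length(individuals) == nrow(geno),
    !anyDuplicated(individuals)
  )
  ok <- geno %in% c(0L, 1L, 2L) | is.na(geno)
  if (!all(ok)) stop("dosages must be 0, 1, 2 or NA")
  storage.mode(geno) <- "integer"
  dimnames(geno) <- list(individuals, panel$locus_id)
  for (ch in list(gq = gq, depth = depth, ad_ref = ad_ref, ad_alt = ad_alt)) {
    if (!is.null(ch) && !identical(dim(ch), dim(geno))) {
      stop("channel dimensions must match the genotype matrix")
    }
  }
  if (!is.null(ad_ref) && !is.null(ad_alt) && !is.null(depth)) {
    have <- !is.na(ad_ref) & !is.na(ad_alt) & !is.na(depth)
    if (any(depth[have] != ad_ref[have] + ad_alt[have])) {
      stop("depth must equal ad_ref + ad_alt where allele depths are present")
    }
  }
  if (!is.null(population)) stopifnot(length(population) == length(individuals))
  structure(
    list(
      geno = geno, panel = panel, individuals = individuals,
      gq = gq, depth = depth, ad_ref = ad_ref, ad_alt = ad_alt,
      population = population
    ),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf(
    "genotype_matrix: %d individuals x %d loci (%.1f%% missing)%s\n",
    nrow(x$geno), ncol(x$geno), 100 * mean(is.na(x$geno)),
    if (is.null(x$population)) "" else
      sprintf(", %d populations", length(unique(x$population)))
  ))
  chans <- c("gq", "depth", "ad_ref", "ad_alt")[!vapply(
    list(x$gq, x$depth, x$ad_ref, x$ad_alt), is.null, logical(1)
  )]
  if (length(chans)) cat("channels:", paste(chans, collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$geno)

#' Subset a genotype matrix by individuals and/or loci
#'
#' @param gm a [genotype_matrix()].
#' @param individuals index/logical/character selector on individuals.
#' @param loci index/logical/character selector on loci.
#' @return A `genotype_matrix` restricted to the selection.
#' @export
subset_gm <- function(gm, individuals = NULL, loci = NULL) {
  i <- if (is.null(individuals)) seq_len(nrow(gm$geno)) else individuals
  if (is.character(i)) i <- match(i, gm$individuals)
  j <- if (is.null(loci)) seq_len(ncol(gm$geno)) else loci
  if (is.character(j)) j <- match(j, gm$panel$locus_id)
  sub <- function(m) if (is.null(m)) NULL else m[i, j, drop = FALSE]
  pan <- gm$panel[j, , drop = FALSE]
  class(pan) <- c("locus_panel", "data.frame")
  genotype_matrix(
    gm$geno[i, j, drop = FALSE], pan,
    individuals = gm$individuals[i],
    gq = sub(gm$gq), depth = sub(gm$depth),
    ad_ref = sub(gm$ad_ref), ad_alt = sub(gm$ad_alt),
    population = if (is.null(gm$population)) NULL else gm$population[i]
  )
}
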