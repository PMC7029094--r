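# Pairwise likelihood classification of offspring dyads into full-sib,
# half-sib and unrelated, from multilocus SNP genotypes and allele
# frequencies. The three relationships are characterised by their Cotterman
# IBD coefficients (k0, k1, k2): FS (0.25, 0.5, 0.25), HS (0.5, 0.5, 0),
# U (1, 0, 0). Genotyping error enters as a contamination mixture: with
# probability epsilon an observed genotype is an independent Hardy-Weinberg
# draw.

relationship_k <- function() {
  rbind(FS = c(k0 = 0.25, k1 = 0.5, k2 = 0.25),
        HS = c(k0 = 0.5,  k1 = 0.5, k2 = 0),
        U  = c(k0 = 1,    k1 = 0,   k2 = 0))
}

# Joint genotype-pair probabilities at one biallelic locus, by IBD state.
# p = ALT allele frequency; genotypes are ALT dosages. Returns a list of
# three L x 9 matrices (columns indexed g1 * 3 + g2 + 1).
ibd_joint_tables <- function(p) {
  q <- 1 - p
  P0 <- q^2; P1 <- 2 * p * q; P2 <- p^2   # HWE genotype probabilities
  hwe <- cbind(P0, P1, P2)
  # IBD 0: independence
  J0 <- cbind(P0 * P0, P0 * P1, P0 * P2,
              P1 * P0, P1 * P1, P1 * P2,
              P2 * P0, P2 * P1, P2 * P2)
  # IBD 1: one allele shared identically by descent
  J1 <- cbind(q^3, q^2 * p, 0,
              q^2 * p, p * q, p^2 * q,
              0, p^2 * q, p^3)
  # IBD 2: both alleles shared; genotypes must match
  J2 <- cbind(P0, 0, 0,
              0, P1, 0,
              0, 0, P2)
  list(J0 = J0, J1 = J1, J2 = J2, hwe = hwe)
}

# Per-locus log probability tables under each relationship, with the
# epsilon error mixture folded in:
#   P_obs = (1-e)^2 P(g1,g2|R) + (1 - (1-e)^2) P_hwe(g1) P_hwe(g2)
# (the cross terms collapse because the marginals of every IBD table are HWE).
dyad_logprob_tables <- function(p, epsilon = 0) {
  tab <- ibd_joint_tables(p)
  k <- relationship_k()
  keep <- (1 - epsilon)^2
  out <- vector("list", 3)
  names(out) <- rownames(k)
  for (r in rownames(k)) {
    J <- k[r, 1] * tab$J0 + k[r, 2] * tab$J1 + k[r, 3] * tab$J2
    out[[r]] <- log(keep * J + (1 - keep) * tab$J0)
  }
  out
}

#' Log-likelihood of a dyad under a kinship relationship
#'
#' Sums, over loci where both genotypes are called, the log of
#' `sum_m k_m P(g1, g2 | m alleles IBD, allele freq)`, with genotyping
#' error rate `epsilon` as a Hardy-Weinberg contamination mixture.
#' Symmetric in its two genotype arguments.
#'
#' @param g1,g2 integer ALT-dosage vectors on `panel`.
#' @param panel a [locus_panel()] supplying allele frequencies.
#' @param relationship `"FS"`, `"HS"` or `"U"`.
#' @param epsilon genotyping error rate in `[0, 0.1]`.
#' @return scalar log-likelihood.
#' @export
dyad_loglik <- function(g1, g2, panel, relationship = c("FS", "HS", "U"),
                        epsilon = 0) {
  relationship <- match.arg(relationship)
  stopifnot(length(g1) == nrow(panel), length(g2) == nrow(panel),
            epsilon >= 0, epsilon <= 0.1)
  shared <- !is.na(g1) & !is.na(g2)
  if (!any(shared)) stop("no jointly called loci for this dyad")
  tabs <- dyad_logprob_tables(panel$alt_freq, epsilon)
  idx <- cbind(which(shared), g1[shared] * 3L + g2[shared] + 1L)
  sum(tabs[[relationship]][idx])
}

#' Classify all dyads of a cohort as FS, HS or U
#'
#' Every unordered pair of individuals is scored under the three
#' relationship likelihoods and assigned the maximising label; exact ties
#' break toward the less related label (U over HS over FS). Pairs with
#' fewer than `min_shared_loci` jointly called loci are labelled
#' `"uncalled"` and carry `NA` likelihoods.
#'
#' @param gm a [genotype_matrix()] of the cohort.
#' @param panel optional [locus_panel()]; defaults to `gm$panel`. Allele
#'   frequencies of `NA` are re-estimated from the sample.
#' @param epsilon assumed genotyping error rate.
#' @param min_shared_loci minimum jointly called loci for a call
#'   (default 100, the smallest panel evaluated in the power study).
#' @return data.frame of class `dyad_calls`: `id1`, `id2`, `n_loci`,
#'   `llFS`, `llHS`, `llU`, `call`.
#' @export
classify_dyads <- function(gm, panel = gm$panel, epsilon = 0.01,
                           min_shared_loci = 100L) {
  n <- nrow(gm$geno)
  ids <- gm$individuals
  empty <- data.frame(id1 = character(), id2 = character(),
                      n_loci = integer(), llFS = numeric(),
                      llHS = numeric(), llU = numeric(),
                      call = character(), stringsAsFactors = FALSE)
  class(empty) <- c("dyad_calls", "data.frame")
  if (n < 2) return(empty)
  p <- panel$alt_freq
  if (anyNA(p)) p[is.na(p)] <- colMeans(gm$geno, na.rm = TRUE)[is.na(p)] / 2
  tabs <- dyad_logprob_tables(p, epsilon)
  # pre-transpose so each pair indexes contiguous per-locus columns
  geno <- gm$geno
  pairs <- utils::combn(n, 2)
  np <- ncol(pairs)
  ll <- matrix(NA_real_, np, 3, dimnames = list(NULL, c("FS", "HS", "U")))
  nshared <- integer(np)
  for (k in seq_len(np)) {
    i <- pairs[1, k]; j <- pairs[2, k]
    g1 <- geno[i, ]; g2 <- geno[j, ]
    shared <- which(!is.na(g1) & !is.na(g2))
    nshared[k] <- length(shared)
    if (length(shared) == 0) next
    idx <- cbind(shared, g1[shared] * 3L + g2[shared] + 1L)
    ll[k, 1] <- sum(tabs$FS[idx])
    ll[k, 2] <- sum(tabs$HS[idx])
    ll[k, 3] <- sum(tabs$U[idx])
  }
  # ties break toward less related: scan U, HS, FS in that order
  pick <- apply(ll[, c("U", "HS", "FS"), drop = FALSE], 1,
                function(x) if (anyNA(x)) NA_integer_ else which.max(x))
  call <- c("U", "HS", "FS")[pick]
  call[nshared < min_shared_loci] <- "uncalled"
  out <- data.frame(
    id1 = ids[pairs[1, ]], id2 = ids[pairs[2, ]],
    n_loci = nshared, llFS = ll[, "FS"], llHS = ll[, "HS"], llU = ll[, "U"],
    call = call, stringsAsFactors = FALSE
  )
  class(out) <- c("dyad_calls", "data.frame")
  out
}

#' Cluster dyad calls into full-sib families with half-sib links
#'
#' Full-sib families are the connected components of the FS-call graph,
#' followed by a transitivity repair: within each component every member's
#' mean full-sib support (`llFS - llU` averaged over the other members) is
#' computed, and members with negative support are peeled off (worst first,
#' recomputing after each removal) into singleton families. Half-sib links
#' between families are then declared where more than half of the
#' cross-family dyads are called HS; each link merges one latent parent
#' slot between the two families.
#'
#' @param calls a `dyad_calls` data.frame from [classify_dyads()].
#' @param individuals optional full roster (so uncalled singletons appear).
#' @return list of class `sib_families`: `families` (list of id vectors)
#'   and `hs_links` (data.frame `f1`, `f2` of family indices).
#' @export
cluster_families <- function(calls, individuals = NULL) {
  ids <- sort(unique(c(calls$id1, calls$id2, individuals)))
  n <- length(ids)
  idx <- function(x) match(x, ids)
  fs <- calls[calls$call == "FS", , drop = FALSE]
  # union-find over individuals for FS components
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (k in seq_len(nrow(fs))) {
    a <- find(idx(fs$id1[k])); b <- find(idx(fs$id2[k]))
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  comp <- vapply(seq_len(n), find, integer(1))
  fams <- split(ids, comp)
  # support lookup: llFS - llU per called pair
  key <- paste(pmin(calls$id1, calls$id2), pmax(calls$id1, calls$id2))
  support <- stats::setNames(calls$llFS - calls$llU, key)
  pair_support <- function(a, b) {
    s <- support[paste(min(a, b), max(a, b))]
    if (is.na(s)) 0 else s
  }
  repaired <- list()
  for (f in fams) {
    while (length(f) > 2) {
      votes <- vapply(f, function(m) {
        mean(vapply(setdiff(f, m), function(o) pair_support(m, o), numeric(1)))
      }, numeric(1))
      if (all(votes >= 0)) break
      worst <- f[which.min(votes)]
      repaired <- c(repaired, list(worst))
      f <- setdiff(f, worst)
    }
    repaired <- c(repaired, list(f))
  }
  fams <- repaired[order(vapply(repaired, function(f) f[1], character(1)))]
  # half-sib links between families: majority HS among cross dyads
  nf <- length(fams)
  call_lookup <- stats::setNames(calls$call, key)
  links <- list()
  if (nf >= 2) {
    for (a in seq_len(nf - 1)) for (b in (a + 1):nf) {
      cross <- outer(fams[[a]], fams[[b]], function(x, y)
        call_lookup[paste(pmin(x, y), pmax(x, y))])
      cross <- cross[!is.na(cross)]
      if (length(cross) && mean(cross == "HS") > 0.5) {
        links <- c(links, list(c(a, b)))
      }
    }
  }
  hs_links <- if (length(links)) {
    as.data.frame(do.call(rbind, links)) |> stats::setNames(c("f1", "f2"))
  } else data.frame(f1 = integer(), f2 = integer())
  structure(list(families = fams, hs_links = hs_links),
            class = "sib_families")
}

#' Build a family structure of singletons
#'
#' Convenience constructor for cohorts in which no related dyads were
#' detected: every individual is its own full-sib family with two private
#' parent slots.
#'
#' @param ids individual identifiers.
#' @return A `sib_families` object with no half-sib links.
#' @export
singleton_families <- function(ids) {
  structure(
    list(families = as.list(as.character(ids)),
         hs_links = data.frame(f1 = integer(), f2 = integer())),
    class = "sib_families"
  )
}

#' Score dyad calls against a known pedigree
#'
#' Accuracy per class is the proportion of dyads *inferred* as that class
#' whose true relationship matches (1 - false-positive rate); the
#' false-negative rate per class is the proportion of *true* dyads of that
#' class inferred as something else. Uncalled dyads are excluded.
#'
#' @param pedigree a `true_pedigree` data.frame (offspring, mother, father).
#' @param calls a `dyad_calls` data.frame.
#' @return list of class `dyad_confusion`: `table` (3x3 true x inferred
#'   counts) and `per_class` (accuracy, fnr).
#' @export
confusion_metrics <- function(pedigree, calls) {
  calls <- calls[calls$call != "uncalled", , drop = FALSE]
  lv <- c("FS", "HS", "U")
  truth <- true_relationship(pedigree, calls$id1, calls$id2)
  tab <- table(factor(truth, lv), factor(calls$call, lv))
  names(dimnames(tab)) <- c("true", "inferred")
  acc <- diag(tab) / colSums(tab)
  fnr <- 1 - diag(tab) / rowSums(tab)
  list(
    table = tab,
    per_class = data.frame(accuracy = as.numeric(acc),
                           fnr = as.numeric(fnr),
                           row.names = lv)
  ) |> structure(class = "dyad_confusion")
}
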