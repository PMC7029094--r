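# Polygamous breeding-matrix simulator for the pedigree power study:
# adults are split into sexes at a random 1-2 males-per-female ratio, each
# female mates with Poisson(3) males, her uniform(25k-100k) egg output is
# allocated across mates on a descending triangular schedule, unmated males
# are remated in the mirrored way, and sampled offspring carry their true
# parent ids in their names.

#' Split a parent pool into females and males
#'
#' Given a males-per-female ratio `r`, the female count is
#' `round(n_parents / (1 + r))` (round-half-even) with a floor of one parent
#' per sex; males take the remainder.
#'
#' @param n_parents total adults (>= 2).
#' @param sex_ratio_draw males-per-female ratio in `[1, 2]`.
#' @return named integer vector `c(n_females, n_males)`.
#' @export
split_sexes <- function(n_parents, sex_ratio_draw) {
  stopifnot(n_parents >= 2, sex_ratio_draw >= 1, sex_ratio_draw <= 2)
  n_f <- round(n_parents / (1 + sex_ratio_draw))
  n_f <- max(1L, min(as.integer(n_f), n_parents - 1L))
  c(n_females = n_f, n_males = as.integer(n_parents) - n_f)
}

#' Triangular allocation of offspring across mates
#'
#' A parent with `n_mates` mates and `n_offspring` offspring distributes
#' them in the descending proportions
#' `n_mates : n_mates - 1 : ... : 1` over `T = n_mates (n_mates + 1) / 2`,
#' i.e. mate `i` receives `n_offspring * (n_mates - i + 1) / T`.
#'
#' @param n_offspring total offspring (real, >= 0).
#' @param n_mates number of mates (>= 1).
#' @return numeric vector of length `n_mates` summing to `n_offspring`.
#' @export
allocate_offspring <- function(n_offspring, n_mates) {
  if (n_mates < 1) stop("n_mates must be >= 1")
  stopifnot(n_offspring >= 0)
  w <- n_mates:1
  n_offspring * w / sum(w)
}

#' Simulation configuration for one breeding-matrix scenario
#'
#' Defaults are the study conditions of the power analysis: sex ratio
#' uniform on `[1, 2]` males per female, Poisson(3) mate numbers, fecundity
#' uniform on `[25000, 100000]` eggs, 100 offspring sampled per matrix.
#'
#' @param n_parents total adults.
#' @param n_loci loci in the genotyping panel.
#' @param n_offspring_sampled offspring drawn from each matrix.
#' @param sex_ratio_range,mate_lambda,fecundity_range breeding parameters.
#' @param n_replicates replicate matrices per scenario.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_parents, n_loci = 500L, n_offspring_sampled = 100L,
                       sex_ratio_range = c(1, 2), mate_lambda = 3,
                       fecundity_range = c(25000, 100000),
                       n_replicates = 100L) {
  stopifnot(n_parents >= 2, mate_lambda > 0,
            sex_ratio_range[1] <= sex_ratio_range[2],
            fecundity_range[1] <= fecundity_range[2])
  structure(
    list(n_parents = as.integer(n_parents), n_loci = as.integer(n_loci),
         n_offspring_sampled = as.integer(n_offspring_sampled),
         sex_ratio_range = sex_ratio_range, mate_lambda = mate_lambda,
         fecundity_range = fecundity_range,
         n_replicates = as.integer(n_replicates)),
    class = "sim_config"
  )
}

# Poisson draw truncated to [1, cap]: a zero is clamped to one mate so no
# focal parent is left out of the matrix.
truncated_poisson <- function(n, lambda, cap) {
  pmin(pmax(stats::rpois(n, lambda), 1L), cap)
}

#' Build one polygamous breeding matrix
#'
#' Rows are females, columns are males, cells are expected offspring counts
#' (kept as reals; integerisation happens at offspring sampling). For each
#' female: a truncated Poisson(lambda) mate count, mates chosen uniformly
#' without replacement, mate order shuffled, fecundity drawn uniform, and
#' the triangular [allocate_offspring()] schedule written into her row.
#' Every male left with an all-zero column then mates in the mirrored way
#' (own fecundity, female mates), so the realised sex ratio is preserved.
#'
#' @param cfg a [sim_config()].
#' @param rng_seed integer seed.
#' @return list of class `breeding_matrix`: `matrix` (females x males),
#'   `fecundity` (per female), plus the sex split.
#' @export
build_breeding_matrix <- function(cfg, rng_seed = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.null(rng_seed)) set.seed(rng_seed)
  ratio <- stats::runif(1, cfg$sex_ratio_range[1], cfg$sex_ratio_range[2])
  split <- split_sexes(cfg$n_parents, ratio)
  n_f <- split[["n_females"]]; n_m <- split[["n_males"]]
  bm <- matrix(0, n_f, n_m,
               dimnames = list(sprintf("F%04d", seq_len(n_f)),
                               sprintf("M%04d", seq_len(n_m))))
  fec_f <- stats::runif(n_f, cfg$fecundity_range[1], cfg$fecundity_range[2])
  n_mates_f <- truncated_poisson(n_f, cfg$mate_lambda, n_m)
  for (i in seq_len(n_f)) {
    mates <- sample.int(n_m, n_mates_f[i])  # already in random order
    bm[i, mates] <- allocate_offspring(fec_f[i], n_mates_f[i])
  }
  mates_primary_male <- colSums(bm > 0)
  unmated <- which(colSums(bm) == 0)
  fec_m <- numeric(0)
  if (length(unmated)) {
    fec_m <- stats::runif(length(unmated), cfg$fecundity_range[1],
                          cfg$fecundity_range[2])
    n_mates_m <- truncated_poisson(length(unmated), cfg$mate_lambda, n_f)
    for (k in seq_along(unmated)) {
      mates <- sample.int(n_f, n_mates_m[k])
      bm[mates, unmated[k]] <- bm[mates, unmated[k]] +
        allocate_offspring(fec_m[k], n_mates_m[k])
    }
  }
  structure(
    list(matrix = bm, fecundity_female = fec_f, fecundity_male = fec_m,
         n_females = n_f, n_males = n_m, sex_ratio = ratio,
         mates_primary_female = n_mates_f,
         mates_primary_male = mates_primary_male),
    class = "breeding_matrix"
  )
}

#' Mate-count summaries of a breeding matrix
#'
#' `round = "primary"` (default) counts mates from the primary mating
#' round: each female's drawn mate number and each male's realised mate
#' count before unmated males are remated. This is the accounting whose
#' grand means sit at ~3 mates per female and ~2 per male under the
#' default breeding parameters; the remating round preserves the matrix
#' and the sex ratio but its added pairings are not part of the drawn
#' mate-number distribution. `round = "realized"` counts positive cells
#' of the final matrix instead (remating included).
#'
#' @param bm a [breeding_matrix][build_breeding_matrix()].
#' @param round `"primary"` or `"realized"`.
#' @return list with `per_female` and `per_male` integer vectors.
#' @export
mate_counts <- function(bm, round = c("primary", "realized")) {
  round <- match.arg(round)
  if (round == "primary") {
    list(per_female = bm$mates_primary_female,
         per_male = bm$mates_primary_male)
  } else {
    list(per_female = rowSums(bm$matrix > 0),
         per_male = colSums(bm$matrix > 0))
  }
}

#' Sample offspring from a breeding matrix
#'
#' Offspring are drawn multinomially with cell probabilities proportional to
#' expected counts. Offspring ids embed the true parent ids
#' (`"F0001xM0003_7"`), and the true pedigree map is returned alongside.
#'
#' @param bm a [breeding_matrix][build_breeding_matrix()].
#' @param n_sampled offspring to draw (>= 1).
#' @param rng_seed integer seed.
#' @return list: `offspring` data.frame (offspring_id, mother_id, father_id)
#'   and `pedigree` (the same, class `true_pedigree`).
#' @export
sample_offspring <- function(bm, n_sampled, rng_seed = NULL) {
  if (n_sampled < 1) stop("n_sampled must be >= 1")
  tot <- sum(bm$matrix)
  if (tot <= 0) stop("breeding matrix has no expected offspring")
  if (!is.null(rng_seed)) set.seed(rng_seed)
  counts <- stats::rmultinom(1, n_sampled, as.vector(bm$matrix))[, 1]
  cell <- rep(seq_along(counts), counts)
  fi <- (cell - 1) %% nrow(bm$matrix) + 1
  mi <- (cell - 1) %/% nrow(bm$matrix) + 1
  mothers <- rownames(bm$matrix)[fi]
  fathers <- colnames(bm$matrix)[mi]
  ped <- data.frame(
    offspring_id = sprintf("%sx%s_%d", mothers, fathers, seq_len(n_sampled)),
    mother_id = mothers, father_id = fathers,
    stringsAsFactors = FALSE
  )
  class(ped) <- c("true_pedigree", "data.frame")
  list(offspring = ped, pedigree = ped)
}

#' True dyad relationship from a pedigree
#'
#' FS = both parents shared, HS = exactly one, U = none.
#'
#' @param pedigree a `true_pedigree` data.frame.
#' @param id1,id2 offspring id vectors (recycled pairwise).
#' @return character vector in `{"FS", "HS", "U"}`.
#' @export
true_relationship <- function(pedigree, id1, id2) {
  i1 <- match(id1, pedigree$offspring_id)
  i2 <- match(id2, pedigree$offspring_id)
  if (anyNA(i1) || anyNA(i2)) stop("individual absent from pedigree")
  shared <- (pedigree$mother_id[i1] == pedigree$mother_id[i2]) +
    (pedigree$father_id[i1] == pedigree$father_id[i2])
  c("U", "HS", "FS")[shared + 1L]
}

#' Simulate one replicate dataset: parents, matrix, offspring genotypes
#'
#' Convenience wrapper chaining panel draw, HWE founders,
#' [build_breeding_matrix()], [sample_offspring()] and
#' [mendelian_offspring()], with optional genotype corruption.
#'
#' @param cfg a [sim_config()].
#' @param error_rate,missing_rate passed to [corrupt_genotypes()]
#'   (both 0 skips corruption).
#' @param rng_seed integer seed.
#' @return list: `gm` (offspring [genotype_matrix()]), `panel`, `pedigree`,
#'   `breeding_matrix`.
#' @export
simulate_cohort <- function(cfg, error_rate = 0, missing_rate = 0,
                            rng_seed = NULL) {
  if (!is.null(rng_seed)) set.seed(rng_seed)
  panel <- draw_allele_frequencies(cfg$n_loci)
  parents <- hwe_parent_genotypes(panel, cfg$n_parents)
  bm <- build_breeding_matrix(cfg)
  rownames(bm$matrix) <- parents$individuals[seq_len(bm$n_females)]
  colnames(bm$matrix) <- parents$individuals[bm$n_females + seq_len(bm$n_males)]
  off <- sample_offspring(bm, cfg$n_offspring_sampled)
  ped <- off$pedigree
  geno <- matrix(NA_integer_, nrow(ped), nrow(panel))
  for (k in seq_len(nrow(ped))) {
    geno[k, ] <- mendelian_offspring(
      parents$geno[ped$mother_id[k], ],
      parents$geno[ped$father_id[k], ]
    )
  }
  gm <- genotype_matrix(geno, panel, individuals = ped$offspring_id)
  if (error_rate > 0 || missing_rate > 0) {
    gm <- corrupt_genotypes(gm, error_rate, missing_rate)
  }
  list(gm = gm, panel = panel, pedigree = ped, breeding_matrix = bm)
}

#' Run the sibship power study over a design grid
#'
#' For every combination of parent and locus levels, simulates
#' `n_replicates` cohorts, classifies all offspring dyads with the pairwise
#' likelihood engine and scores accuracy and false-negative rate per
#' relationship class against the known pedigree.
#'
#' @param parent_levels,locus_levels design grid (defaults: the full study
#'   design 10/100/1000 parents x 100/200/500 loci).
#' @param n_replicates replicates per cell.
#' @param n_offspring_sampled offspring per cohort.
#' @param error_rate,missing_rate genotyping corruption applied to offspring.
#' @param epsilon genotyping error rate assumed by the classifier.
#' @param rng_seed integer seed.
#' @return data.frame: one row per replicate x relationship class with
#'   `accuracy` and `fnr`.
#' @export
run_power_study <- function(parent_levels = c(10L, 100L, 1000L),
                            locus_levels = c(100L, 200L, 500L),
                            n_replicates = 100L,
                            n_offspring_sampled = 100L,
                            error_rate = 0, missing_rate = 0,
                            epsilon = 0.01, rng_seed = 1L) {
  if (length(parent_levels) == 0 || length(locus_levels) == 0 ||
      n_replicates < 1) {
    stop("design must contain at least one parent level, locus level and replicate")
  }
  set.seed(rng_seed)
  grid <- expand.grid(n_parents = parent_levels, n_loci = locus_levels,
                      replicate = seq_len(n_replicates))
  rows <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    cfg <- sim_config(grid$n_parents[g], n_loci = grid$n_loci[g],
                      n_offspring_sampled = n_offspring_sampled)
    sim <- simulate_cohort(cfg, error_rate, missing_rate,
                           rng_seed = sample.int(.Machine$integer.max, 1))
    calls <- classify_dyads(sim$gm, epsilon = epsilon, min_shared_loci = 1L)
    conf <- confusion_metrics(sim$pedigree, calls)
    rows[[g]] <- data.frame(
      n_parents = grid$n_parents[g], n_loci = grid$n_loci[g],
      replicate = grid$replicate[g],
      class = rownames(conf$per_class),
      accuracy = conf$per_class$accuracy,
      fnr = conf$per_class$fnr,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Enumerate the size of a power-study design
#'
#' @inheritParams run_power_study
#' @return integer: number of simulated datasets the design implies.
#' @export
power_design_size <- function(parent_levels = c(10L, 100L, 1000L),
                              locus_levels = c(100L, 200L, 500L),
                              n_replicates = 100L) {
  length(parent_levels) * length(locus_levels) * as.integer(n_replicates)
}
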