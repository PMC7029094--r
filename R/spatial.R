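# Randomization test for spatial clustering of related dyads within
# sampling locations, location-pair dyad matrices, and cross-cohort Fisher
# comparisons.

#' Number of distinct dyads among genotyped individuals
#'
#' @param n_gt number of genotyped individuals (>= 2).
#' @return `C(n_gt, 2)`.
#' @export
dyad_total <- function(n_gt) {
  if (n_gt < 2) stop("n_gt must be >= 2")
  choose(n_gt, 2)
}

normalise_pairs <- function(related_pairs) {
  rp <- as.data.frame(related_pairs, stringsAsFactors = FALSE)
  stopifnot(ncol(rp) >= 2)
  data.frame(id1 = pmin(as.character(rp[[1]]), as.character(rp[[2]])),
             id2 = pmax(as.character(rp[[1]]), as.character(rp[[2]])),
             stringsAsFactors = FALSE)
}

#' Randomization test for within-location clustering of related dyads
#'
#' The observed statistic is the proportion of related dyads whose two
#' members were sampled at the same location. Under the null, the same
#' number of related labels is assigned uniformly without replacement
#' among all `C(n, 2)` dyads (`permute = "dyads"`), or location labels are
#' permuted over individuals (`permute = "locations"`); the p-value is the
#' proportion of null draws exceeding the observed statistic (strictly,
#' by default).
#'
#' @param ids individual identifiers.
#' @param locations sampling-location labels aligned with `ids`; entries
#'   with `NA` locations are dropped (with a message).
#' @param related_pairs two-column structure of related dyads (ids).
#' @param reps null draws (default 1000).
#' @param permute `"dyads"` (default) or `"locations"`.
#' @param strict use `>` (default, as in a one-sided randomization test)
#'   rather than `>=` when comparing null draws to the observed value.
#' @param rng_seed integer seed.
#' @return list of class `pnw_result`: `observed`, `null`, `p_value`,
#'   `n_gt`, `dyad_total`, `n_rw`.
#' @export
pnw_randomization <- function(ids, locations, related_pairs, reps = 1000L,
                              permute = c("dyads", "locations"),
                              strict = TRUE, rng_seed = NULL) {
  permute <- match.arg(permute)
  stopifnot(length(ids) == length(locations))
  ids <- as.character(ids)
  drop <- is.na(locations)
  if (any(drop)) {
    message(sum(drop), " individual(s) without a location label dropped")
    ids <- ids[!drop]; locations <- locations[!drop]
  }
  n <- length(ids)
  if (n < 2) stop("need at least 2 located individuals")
  if (length(unique(locations)) < 2) {
    warning("all individuals share one location; the test is degenerate")
  }
  rp <- normalise_pairs(related_pairs)
  rp <- rp[rp$id1 %in% ids & rp$id2 %in% ids, , drop = FALSE]
  n_rw <- nrow(rp)
  if (n_rw == 0) stop("no related dyads among located individuals; test undefined")
  loc <- stats::setNames(locations, ids)
  pairs <- utils::combn(ids, 2)
  same <- loc[pairs[1, ]] == loc[pairs[2, ]]
  key <- paste(pmin(pairs[1, ], pairs[2, ]), pmax(pairs[1, ], pairs[2, ]))
  related <- key %in% paste(rp$id1, rp$id2)
  observed <- sum(same & related) / n_rw
  if (!is.null(rng_seed)) set.seed(rng_seed)
  nd <- length(key)
  null <- if (permute == "dyads") {
    replicate(reps, sum(same[sample.int(nd, n_rw)]) / n_rw)
  } else {
    replicate(reps, {
      perm <- stats::setNames(sample(locations), ids)
      sum((perm[pairs[1, ]] == perm[pairs[2, ]])[related]) / n_rw
    })
  }
  p <- if (strict) mean(null > observed) else mean(null >= observed)
  structure(
    list(observed = observed, null = null, p_value = p,
         n_gt = n, dyad_total = nd, n_rw = n_rw, permute = permute),
    class = "pnw_result"
  )
}

#' Related-dyad counts per sampling-location pair
#'
#' Symmetric matrix whose cell `(i, j)` counts related dyads with one
#' member at location `i` and the other at `j`; the diagonal holds
#' within-location dyads. The upper triangle plus diagonal sums to the
#' number of related dyads.
#'
#' @inheritParams pnw_randomization
#' @return symmetric integer matrix with location dimnames.
#' @export
location_pair_matrix <- function(ids, locations, related_pairs) {
  ids <- as.character(ids)
  loc <- stats::setNames(as.character(locations), ids)
  rp <- normalise_pairs(related_pairs)
  l1 <- loc[rp$id1]; l2 <- loc[rp$id2]
  if (anyNA(l1) || anyNA(l2)) stop("unknown location label for a related dyad member")
  locs <- sort(unique(as.character(locations)))
  m <- matrix(0L, length(locs), length(locs), dimnames = list(locs, locs))
  for (k in seq_len(nrow(rp))) {
    a <- min(l1[k], l2[k]); b <- max(l1[k], l2[k])
    m[a, b] <- m[a, b] + 1L
    if (a != b) m[b, a] <- m[b, a] + 1L
  }
  m
}

#' Compare within-location clustering across cohorts (Fisher exact)
#'
#' For each cohort pair, a 2x2 table of related dyads (within-location vs
#' between-location, by cohort) is tested with a two-sided Fisher exact
#' test. Cohorts without related dyads are excluded with a warning.
#'
#' @param data_by_cohort named list; each element a list (or `pnw_result`)
#'   with scalar counts `within` and `between` (between = related dyads
#'   spanning locations). A `pnw_result` is converted automatically.
#' @return data.frame: `cohort1`, `cohort2`, `p_value` and the four counts.
#' @export
compare_cohorts <- function(data_by_cohort) {
  counts <- lapply(data_by_cohort, function(d) {
    if (inherits(d, "pnw_result")) {
      w <- round(d$observed * d$n_rw)
      c(within = w, between = d$n_rw - w)
    } else c(within = d$within, between = d$between)
  })
  ok <- vapply(counts, function(x) sum(x) > 0, logical(1))
  if (any(!ok)) {
    warning("cohort(s) without related dyads excluded: ",
            paste(names(counts)[!ok], collapse = ", "))
    counts <- counts[ok]
  }
  if (length(counts) < 2) stop("need at least 2 cohorts with related dyads")
  nm <- names(counts)
  cmb <- utils::combn(length(counts), 2)
  out <- lapply(seq_len(ncol(cmb)), function(k) {
    a <- counts[[cmb[1, k]]]; b <- counts[[cmb[2, k]]]
    p <- stats::fisher.test(rbind(a, b))$p.value
    data.frame(cohort1 = nm[cmb[1, k]], cohort2 = nm[cmb[2, k]],
               within1 = a[["within"]], between1 = a[["between"]],
               within2 = b[["within"]], between2 = b[["between"]],
               p_value = p, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
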