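# Multilocus linkage disequilibrium (index of association) and the
# parsimony-based homoplasy test.

# per-locus allele ids (collapsed distinct sequences after missing policy)
locus_alleles <- function(ds, loci = NULL) {
  if (is.null(loci)) loci <- names(ds$loci)
  sel <- ds$loci[loci]
  common <- sort(Reduce(intersect, lapply(sel, function(l) names(l$seq))))
  cols <- lapply(sel, function(l) {
    cl <- clean_seqs(l)[common]
    as.integer(factor(cl, levels = unique(cl)))
  })
  out <- do.call(cbind, cols)
  dimnames(out) <- list(common, names(sel))
  out
}

#' Index of association
#'
#' `I_A = V_O / V_E - 1` where, over all strain pairs, `D_ij` is the number
#' of loci at which the pair carries different alleles, `V_O` is the sample
#' variance of `D_ij` and `V_E` the sum of the per-locus sample variances of
#' the 0/1 allele mismatch indicators. Alleles are whole-locus collapsed
#' sequences (the MLST convention), not per-site states. Sample (n-1)
#' variances are used.
#'
#' @param ds an [mlst_dataset] (typically clone-corrected).
#' @param loci locus labels; default all.
#' @return the observed I_A (0 for a single locus by definition).
#' @export
index_of_association <- function(ds, loci = NULL) {
  al <- locus_alleles(ds, loci)
  if (nrow(al) < 2L) stop("need at least 2 strains")
  ia_from_alleles(al)
}

ia_from_alleles <- function(al) {
  n <- nrow(al)
  if (ncol(al) == 1L) return(0)
  per_locus <- apply(al, 2L, function(a) {
    d <- outer(a, a, "!=")
    as.numeric(d[upper.tri(d)])
  })
  D <- rowSums(per_locus)
  VO <- var(D)
  VE <- sum(apply(per_locus, 2L, var))
  if (VE == 0) return(0)
  VO / VE - 1
}

#' Permutation test for the index of association
#'
#' The null distribution is built by independently shuffling allele
#' assignments among strains at each locus, which preserves per-locus allele
#' frequencies exactly. One-sided p-value
#' `(1 + #(perm >= observed)) / (1 + n_perm)`.
#'
#' @param ds an [mlst_dataset]; expected to be clone-corrected (see
#'   [clone_correct()]) unless `force = TRUE`.
#' @param loci locus labels; default all.
#' @param n_perm number of permutations (default 1000).
#' @param seed optional RNG seed.
#' @param force allow non-clone-corrected input.
#' @return an object of class `ia_result` with `ia_observed`,
#'   `permutation_values`, `p_value`, `n_permutations`, `clone_corrected`.
#' @export
ia_permutation_test <- function(ds, loci = NULL, n_perm = 1000L, seed = NULL,
                                force = FALSE) {
  if (n_perm < 1L) stop("n_perm must be >= 1")
  cc <- isTRUE(attr(ds, "clone_corrected"))
  if (!cc && !force)
    stop("dataset is not clone-corrected; run clone_correct() or set force = TRUE")
  if (!is.null(seed)) set.seed(seed)
  al <- locus_alleles(ds, loci)
  obs <- ia_from_alleles(al)
  n <- nrow(al)
  perm <- vapply(seq_len(n_perm), function(i) {
    shuf <- apply(al, 2L, function(a) a[sample.int(n)])
    ia_from_alleles(shuf)
  }, numeric(1L))
  structure(list(ia_observed = obs, permutation_values = perm,
                 p_value = (1 + sum(perm >= obs)) / (1 + n_perm),
                 n_permutations = n_perm, clone_corrected = cc),
            class = "ia_result")
}

#' @export
print.ia_result <- function(x, ...) {
  cat(sprintf("<ia_result> I_A = %.4g, p = %.4g (%d permutations%s)\n",
              x$ia_observed, x$p_value, x$n_permutations,
              if (x$clone_corrected) ", clone-corrected" else ""))
  invisible(x)
}

# parsimony length of a character site matrix: NJ start plus SPR hill
# climbing, with optional random-start restarts; ties broken by first found
parsimony_length <- function(chm, n_restarts = 0L) {
  n <- nrow(chm)
  phy <- phangorn::phyDat(chm, type = "USER",
                          levels = c("A", "C", "G", "T"), ambiguity = "N")
  seqs <- apply(chm, 1L, paste0, collapse = "")
  d <- hamming_strings_cpp(unname(seqs))
  dimnames(d) <- list(rownames(chm), rownames(chm))
  start <- ape::nj(stats::as.dist(d))
  best <- suppressWarnings(
    phangorn::optim.parsimony(start, phy, method = "fitch",
                              rearrangements = "SPR", trace = 0))
  score <- phangorn::parsimony(best, phy)
  if (n_restarts > 0L) for (r in seq_len(n_restarts)) {
    rt <- ape::rtree(n, tip.label = sample(rownames(chm)))
    cand <- suppressWarnings(
      phangorn::optim.parsimony(rt, phy, method = "fitch",
                                rearrangements = "SPR", trace = 0))
    score <- min(score, phangorn::parsimony(cand, phy))
  }
  as.integer(score)
}

#' Homoplasy index
#'
#' Measures excess parsimony steps relative to the free-recombination
#' expectation: `H = (L_obs - L_min) / (L_free - L_min)` clamped to `[0, 1]`,
#' where `L_obs` is the parsimony length of the data (NJ start, SPR hill
#' climbing, random restarts), `L_min = sum(states - 1)` over sites, and
#' `L_free` is the mean parsimony length over datasets whose site columns
#' were independently permuted across strains. `H = 0` indicates a clonal
#' population, `H = 1` free recombination.
#'
#' @param aln a [locus_alignment] with >= 4 sequences and >= 2
#'   parsimony-informative sites.
#' @param n_shuffles column-shuffle replicates for the free-recombination
#'   expectation (default 20).
#' @param seed optional RNG seed.
#' @param n_restarts random-start restarts per tree search (default 3).
#' @return an object of class `homoplasy_result` with `h_index`,
#'   `observed_extra_steps`, `min_steps`, `expected_extra_steps_free`.
#'   `h_index` is `NA` when the shuffled data carry no extra steps.
#' @export
homoplasy_index <- function(aln, n_shuffles = 20L, seed = NULL,
                            n_restarts = 3L) {
  stopifnot(inherits(aln, "locus_alignment"))
  if (length(aln$seq) < 4L) stop("need at least 4 sequences")
  if (!is.null(seed)) set.seed(seed)
  m <- seq_matrix(aln)[, retained_columns(aln), drop = FALSE]
  nstates <- apply(m, 2L, function(col) length(unique(col)))
  var_cols <- nstates > 1L
  mv <- m[, var_cols, drop = FALSE]
  informative <- apply(mv, 2L, function(col) {
    tab <- table(col)
    sum(tab >= 2L) >= 2L
  })
  if (sum(informative) < 2L)
    stop("need at least 2 parsimony-informative sites")
  L_min <- sum(nstates[var_cols] - 1L)
  L_obs <- parsimony_length(mv, n_restarts = n_restarts)
  L_free <- mean(vapply(seq_len(n_shuffles), function(r) {
    shuf <- apply(mv, 2L, function(col) col[sample.int(nrow(mv))])
    rownames(shuf) <- rownames(mv)
    parsimony_length(shuf, n_restarts = 0L)
  }, numeric(1L)))
  h <- if (L_free - L_min <= 0) NA_real_ else
    min(max((L_obs - L_min) / (L_free - L_min), 0), 1)
  structure(list(h_index = h,
                 observed_extra_steps = L_obs - L_min,
                 min_steps = L_min,
                 expected_extra_steps_free = L_free - L_min),
            class = "homoplasy_result")
}

#' @export
print.homoplasy_result <- function(x, ...) {
  cat(sprintf("<homoplasy_result> H = %s (obs extra steps %d, min %d, free expectation %.2f)\n",
              if (is.na(x$h_index)) "not computable" else sprintf("%.3f", x$h_index),
              x$observed_extra_steps, x$min_steps,
              x$expected_extra_steps_free))
  invisible(x)
}
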