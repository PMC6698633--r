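# Diversity, neutrality and selection statistics for aligned haploid sequences.
# All statistics operate on the columns retained by the missing-data policy
# (complete deletion of columns containing N or -).

#' Pairwise difference (Hamming) matrix
#'
#' @param aln a [locus_alignment].
#' @return symmetric integer matrix of Hamming distances over retained
#'   columns; diagonal zero; dimnames are strain ids.
#' @export
pairwise_difference_matrix <- function(aln) {
  cl <- clean_seqs(aln)
  if (length(cl) < 2L) stop("need at least 2 sequences")
  D <- hamming_strings_cpp(unname(cl))
  dimnames(D) <- list(names(cl), names(cl))
  D
}

# number of segregating sites among retained columns
segregating_sites <- function(aln) {
  m <- seq_matrix(aln)[, retained_columns(aln), drop = FALSE]
  if (ncol(m) == 0L) return(0L)
  sum(apply(m, 2L, function(col) length(unique(col))) > 1L)
}

#' Nucleotide diversity (mean pairwise differences)
#'
#' @param aln a [locus_alignment].
#' @return list with `abs` (mean number of pairwise differences) and
#'   `per_site` (divided by the retained alignment length).
#' @export
nucleotide_diversity <- function(aln) {
  D <- pairwise_difference_matrix(aln)
  n <- nrow(D)
  pi_abs <- sum(D[upper.tri(D)]) / choose(n, 2L)
  L <- sum(retained_columns(aln))
  list(abs = pi_abs, per_site = if (L > 0L) pi_abs / L else 0)
}

#' Watterson's theta
#'
#' `S / a_{n-1}` with `a_m = sum(1/i, i = 1..m)`.
#'
#' @param aln a [locus_alignment].
#' @return list with `abs` and `per_site` values.
#' @export
watterson_theta <- function(aln) {
  n <- length(aln$seq)
  if (n < 2L) stop("need at least 2 sequences")
  S <- segregating_sites(aln)
  a1 <- sum(1 / seq_len(n - 1L))
  L <- sum(retained_columns(aln))
  list(abs = S / a1, per_site = if (L > 0L) S / a1 / L else 0)
}

# Tajima (1989) constants for sample size n
tajima_constants <- function(n) {
  a1 <- sum(1 / seq_len(n - 1L))
  a2 <- sum(1 / seq_len(n - 1L)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

# D from summary ingredients (used on both data and simulations)
tajima_d_from <- function(n, S, pi_abs) {
  if (S < 1L || n < 4L) return(NA_real_)
  k <- tajima_constants(n)
  (pi_abs - S / k$a1) / sqrt(k$e1 * S + k$e2 * S * (S - 1))
}

#' Tajima's D
#'
#' @param aln a [locus_alignment] with at least 4 sequences.
#' @return the D statistic, or `NA` when the alignment is monomorphic.
#' @export
tajimas_d <- function(aln) {
  n <- length(aln$seq)
  S <- segregating_sites(aln)
  if (S < 1L) return(NA_real_)
  tajima_d_from(n, S, nucleotide_diversity(aln)$abs)
}

# log unsigned Stirling numbers of the first kind, row n (k = 1..n); cached
stirling_cache <- new.env(parent = emptyenv())
log_stirling_row <- function(n) {
  key <- as.character(n)
  if (!is.null(stirling_cache[[key]])) return(stirling_cache[[key]])
  ls <- 0 # row for n = 1: |s(1,1)| = 1
  if (n > 1L) for (m in 2:n) {
    prev <- c(-Inf, ls, -Inf)   # index k = 0..m
    grow <- log(m - 1) + prev[seq_len(m) + 1L]   # (m-1)*|s(m-1,k)|
    keep <- prev[seq_len(m)]                     # |s(m-1,k-1)|
    hi <- pmax(grow, keep)
    ls <- ifelse(is.infinite(hi) & hi < 0, -Inf,
                 hi + log1p(exp(pmin(grow, keep) - hi)))
  }
  stirling_cache[[key]] <- ls
  ls
}

# log Ewens sampling probabilities P(K = k | theta, n), k = 1..n
ewens_log_probs <- function(n, theta) {
  if (theta <= 0) stop("theta must be positive")
  ls <- log_stirling_row(n)
  lp <- ls + seq_len(n) * log(theta) - sum(log(theta + 0:(n - 1L)))
  lp
}

# Fs from ingredients: theta estimate (pi), observed haplotype count, n
fs_from <- function(n, theta, k_obs) {
  if (theta <= 0 || k_obs <= 1L) return(NA_real_)
  lp <- ewens_log_probs(n, theta)
  mx <- max(lp)
  lse <- function(v) if (!length(v)) -Inf else {
    m <- max(v); m + log(sum(exp(v - m)))
  }
  log_Sp <- lse(lp[k_obs:n]) - lse(lp)      # P(K >= k_obs), normalised
  log_1mSp <- lse(lp[seq_len(k_obs - 1L)]) - lse(lp)
  log_Sp - log_1mSp
}

#' Fu's Fs
#'
#' `Fs = ln(S'/(1 - S'))` with `S' = P(K >= k_obs | theta = pi, n)` computed
#' by the Ewens sampling formula (log-space unsigned Stirling numbers of the
#' first kind; stable for n up to several hundred).
#'
#' @param aln a [locus_alignment].
#' @return the Fs statistic, or `NA` when the sample is monomorphic.
#' @export
fus_fs <- function(aln) {
  n <- length(aln$seq)
  if (n < 2L) stop("need at least 2 sequences")
  pi_abs <- nucleotide_diversity(aln)$abs
  k_obs <- length(collapse_haplotypes(aln)$seq)
  fs_from(n, pi_abs, k_obs)
}

# One neutral coalescent replicate conditional on S segregating sites:
# simulate a Kingman genealogy (single deme), drop S mutations on branches
# with probability proportional to branch length, and return mean pairwise
# differences and the resulting haplotype count.
sim_neutral_fixed_S <- function(n, S) {
  nn <- 2L * n - 1L
  parent <- integer(nn)
  ntime <- numeric(nn)
  active <- seq_len(n)
  nxt <- n + 1L
  t <- 0
  for (k in n:2) {
    t <- t + rexp(1L, k * (k - 1) / 2)
    pick <- sample.int(k, 2L)
    parent[active[pick]] <- nxt
    ntime[nxt] <- t
    active <- c(active[-pick], nxt)
    nxt <- nxt + 1L
  }
  nonroot <- seq_len(nn - 1L)
  blen <- ntime[parent[nonroot]] - ntime[nonroot]
  w <- c(rep(1L, n), integer(n - 1L))
  for (v in seq_len(nn - 1L)) w[parent[v]] <- w[parent[v]] + w[v]
  if (S > 0L) {
    mut <- sample.int(nn - 1L, S, replace = TRUE, prob = blen)
    counts <- w[mut]
    pi_abs <- sum(counts * (n - counts)) / choose(n, 2L)
    # haplotype classes: cut mutated branches, count tip components
    cut <- logical(nn); cut[unique(mut)] <- TRUE
    comp <- seq_len(nn)
    find <- function(x) { while (comp[x] != x) { comp[x] <<- comp[comp[x]]; x <- comp[x] }; x }
    for (v in nonroot) if (!cut[v]) {
      rv <- find(v); rp <- find(parent[v])
      if (rv != rp) comp[rv] <- rp
    }
    K <- length(unique(vapply(seq_len(n), find, integer(1L))))
  } else {
    pi_abs <- 0; K <- 1L
  }
  list(pi = pi_abs, K = K)
}

#' Neutrality tests with simulated significance
#'
#' Tajima's D and Fu's Fs with p-values from neutral coalescent simulation
#' conditional on the observed number of segregating sites. Both p-values are
#' lower-tail: the fraction of simulated statistics less than or equal to the
#' observed value, the convention used when screening for expansions (small
#' p = excess of rare variants).
#'
#' @param aln a [locus_alignment].
#' @param n_reps number of neutral replicates (default 1000).
#' @return list with `D`, `p_D`, `Fs`, `p_Fs`.
#' @export
neutrality_test <- function(aln, n_reps = 1000L) {
  n <- length(aln$seq)
  S <- segregating_sites(aln)
  D_obs <- tajimas_d(aln)
  Fs_obs <- fus_fs(aln)
  if (S < 1L) return(list(D = NA_real_, p_D = NA_real_,
                          Fs = NA_real_, p_Fs = NA_real_))
  D_sim <- Fs_sim <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    sim <- sim_neutral_fixed_S(n, S)
    D_sim[r] <- tajima_d_from(n, S, sim$pi)
    Fs_sim[r] <- if (sim$pi > 0 && sim$K > 1L) fs_from(n, sim$pi, sim$K) else NA_real_
  }
  list(D = D_obs,
       p_D = mean(D_sim <= D_obs, na.rm = TRUE),
       Fs = Fs_obs,
       p_Fs = if (is.na(Fs_obs)) NA_real_ else
         mean(Fs_sim <= Fs_obs, na.rm = TRUE))
}

#' Haplotype diversity
#'
#' `Hd = n/(n-1) * (1 - sum(f_i^2))` over haplotype frequencies.
#'
#' @param table a [collapse_haplotypes()] result (or a [locus_alignment],
#'   collapsed on the fly).
#' @return haplotype diversity in `[0, 1]`.
#' @export
haplotype_diversity <- function(table) {
  if (inherits(table, "locus_alignment")) table <- collapse_haplotypes(table)
  n <- table$n
  if (n < 2L) stop("need at least 2 sequences")
  f <- table$count / n
  n / (n - 1) * (1 - sum(f^2))
}

#' Hudson-style pairwise F_ST matrix
#'
#' `F_ST = 1 - H_w / H_b` per group pair, with `H_w` the average of the two
#' within-group mean pairwise differences and `H_b` the mean between-group
#' pairwise difference. Negative values are reported as computed; pairs with
#' `H_b = 0` are `NA`.
#'
#' @param aln a [locus_alignment].
#' @param groups named character/factor vector (names = strain ids) or a
#'   vector aligned with the sequences.
#' @return symmetric matrix of pairwise F_ST values.
#' @export
hudson_fst <- function(aln, groups) {
  D <- pairwise_difference_matrix(aln)
  ids <- rownames(D)
  g <- if (!is.null(names(groups))) groups[ids] else groups
  if (length(g) != nrow(D) || anyNA(g)) stop("groups must cover all strains")
  g <- as.character(g)
  lev <- unique(g)
  if (length(lev) < 2L) stop("need at least 2 groups")
  within_mean <- vapply(lev, function(a) {
    idx <- which(g == a)
    if (length(idx) < 2L) stop("group '", a, "' has fewer than 2 members")
    sub <- D[idx, idx, drop = FALSE]
    mean(sub[upper.tri(sub)])
  }, numeric(1L))
  out <- matrix(NA_real_, length(lev), length(lev), dimnames = list(lev, lev))
  diag(out) <- 0
  for (i in seq_along(lev)) for (j in seq_along(lev)) if (i < j) {
    hb <- mean(D[g == lev[i], g == lev[j], drop = FALSE])
    hw <- (within_mean[i] + within_mean[j]) / 2
    out[i, j] <- out[j, i] <- if (hb == 0) NA_real_ else 1 - hw / hb
  }
  out
}
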