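# Independent oracles and fixture builders used across the suite. These are
# deliberately naive re-derivations (brute force, enumeration, closed forms)
# kept separate from the package's own code paths.

aln_from <- function(seqs, ids = NULL, ...) {
  if (is.null(ids)) ids <- sprintf("t%02d", seq_along(seqs))
  locus_alignment(setNames(seqs, ids), ...)
}

# random alignment over ACGT (no missing data)
random_aln <- function(n, L, chars = c("A", "C", "G", "T")) {
  seqs <- vapply(seq_len(n), function(i)
    paste0(sample(chars, L, replace = TRUE), collapse = ""), character(1L))
  aln_from(seqs)
}

# brute-force Hamming matrix on raw strings
oracle_hamming <- function(seqs) {
  n <- length(seqs)
  D <- matrix(0L, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    a <- strsplit(seqs[i], "")[[1L]]
    b <- strsplit(seqs[j], "")[[1L]]
    D[i, j] <- sum(a != b)
  }
  D
}

# independent Tajima's D derivation (constants written out afresh)
oracle_tajima_d <- function(seqs) {
  n <- length(seqs)
  m <- do.call(rbind, strsplit(seqs, ""))
  S <- sum(apply(m, 2L, function(col) length(unique(col)) > 1L))
  if (S == 0L) return(NA_real_)
  D <- oracle_hamming(seqs)
  pi_hat <- mean(D[upper.tri(D)])
  a1 <- sum(1 / (1:(n - 1)))
  a2 <- sum(1 / (1:(n - 1))^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n * n + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / (a1 * a1)
  e1 <- c1 / a1
  e2 <- c2 / (a1 * a1 + a2)
  (pi_hat - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# exact Ewens probabilities for small n via recursively computed unsigned
# Stirling numbers (plain integer arithmetic, n <= 12)
oracle_ewens <- function(n, theta) {
  s <- matrix(0, n + 1L, n + 1L)
  s[1L, 1L] <- 1          # |s(0,0)| = 1
  for (m in 1:n) for (k in 1:m)
    s[m + 1L, k + 1L] <- s[m, k] + (m - 1) * s[m, k + 1L]
  denom <- prod(theta + 0:(n - 1))
  vapply(1:n, function(k) s[n + 1L, k + 1L] * theta^k / denom, numeric(1L))
}

oracle_fs <- function(seqs) {
  D <- oracle_hamming(seqs)
  n <- length(seqs)
  theta <- mean(D[upper.tri(D)])
  if (theta <= 0) return(NA_real_)
  k_obs <- length(unique(seqs))
  p <- oracle_ewens(n, theta)
  sp <- sum(p[k_obs:n])
  log(sp / (1 - sp))
}

# brute-force Kruskal MST weight (no tie handling needed for the weight)
oracle_mst_weight <- function(D) {
  n <- nrow(D)
  in_tree <- c(TRUE, rep(FALSE, n - 1L))
  w <- 0
  while (!all(in_tree)) {
    best <- Inf; bj <- NA
    for (i in which(in_tree)) for (j in which(!in_tree))
      if (D[i, j] < best) { best <- D[i, j]; bj <- j }
    in_tree[bj] <- TRUE
    w <- w + best
  }
  w
}

# exhaustive parsimony over all unrooted topologies (n <= 8)
oracle_parsimony <- function(chm) {
  phy <- phangorn::phyDat(chm, type = "USER",
                          levels = c("A", "C", "G", "T"))
  trees <- phangorn::allTrees(nrow(chm), rooted = FALSE,
                              tip.label = rownames(chm))
  min(vapply(trees, function(tr) phangorn::parsimony(tr, phy), numeric(1L)))
}

# Gillespie simulation of the pairwise infinite-island spatial-expansion
# process (independent of the closed form): returns one draw of the number
# of pairwise differences
oracle_spatial_pair <- function(tau, theta, M) {
  # one event decides the pre-expansion phase: coalesce (prob 1/(1+M)) or
  # scatter into distinct islands (no coalescence until tau); pairs reaching
  # tau uncoalesced coalesce in the single ancestral deme of size theta
  coal_time <- NA
  dt <- rexp(1L, (1 + M) / theta)
  if (dt < tau && runif(1L) < 1 / (1 + M)) coal_time <- dt
  if (is.na(coal_time)) coal_time <- tau + rexp(1L, 1 / theta)
  rpois(1L, coal_time)
}

# single-deme expansion scenario used in several tests: concatenated clonal
# locus with total mutation rate u_tot per generation
expansion_scenario <- function(n, tau, theta0, theta1, u_tot = 1e-3) {
  demographic_scenario(
    demes = data.frame(name = "p", size = theta1 / (2 * u_tot), growth = 0),
    events = data.frame(time = tau / (2 * u_tot), type = "size", from = "p",
                        to = NA, value = theta0 / (2 * u_tot)),
    samples = c(p = n),
    loci = data.frame(name = "concat", length = 1000L, mu = u_tot / 1000),
    label = "expansion")
}

constant_scenario <- function(n, theta, u_tot = 1e-3, L = 1000L) {
  demographic_scenario(
    demes = data.frame(name = "p", size = theta / (2 * u_tot), growth = 0),
    samples = c(p = n),
    loci = data.frame(name = "locus", length = L, mu = u_tot / L),
    label = "constant")
}

# small three-locus dataset with metadata for I/O and linkage tests
toy_dataset <- function() {
  l1 <- aln_from(c("ACGTACGTAC", "ACGTACGTAC", "ACGAACGTAC", "ACGAACGTAT"),
                 ids = c("s1", "s2", "s3", "s4"), name = "locA")
  l2 <- aln_from(c("TTTT", "TTTT", "TTCT", "TTCT"),
                 ids = c("s1", "s2", "s3", "s4"), name = "locB")
  meta <- data.frame(strain = c("s1", "s2", "s3", "s4"),
                     site = c("x", "x", "y", "y"),
                     country = c("China", "China", "Germany", "Germany"),
                     species = "MH",
                     clade = c("CI", "CI", "CII", "CII"))
  mlst_dataset(list(locA = l1, locB = l2), metadata = meta)
}
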