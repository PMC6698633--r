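toy4 <- c("AAA", "AAT", "ATT", "TTT")

test_that("pairwise differences match hand-enumerated values", {
  a <- aln_from(toy4)
  D <- pairwise_difference_matrix(a)
  expect_equal(sort(D[upper.tri(D)]), c(1L, 1L, 1L, 2L, 2L, 3L))
  expect_true(all(diag(D) == 0L))
  expect_equal(pairwise_difference_matrix(aln_from(c("AAA", "AAA")))[1L, 2L],
               0L)
  expect_equal(pairwise_difference_matrix(aln_from(c("AAA", "ATT")))[1L, 2L],
               2L)
})

test_that("nucleotide diversity equals mean pairwise differences", {
  a <- aln_from(toy4)
  pi <- nucleotide_diversity(a)
  expect_equal(pi$abs, 10 / 6)
  expect_equal(pi$per_site, 10 / 18)
  expect_equal(nucleotide_diversity(aln_from(c("AAA", "AAA")))$abs, 0)
  two <- aln_from(c("AAAAAAAAAA", "TTAAAAAAAA"))
  expect_equal(nucleotide_diversity(two)$per_site, 0.2)
  expect_error(nucleotide_diversity(aln_from("AAA")), "at least 2")
})

test_that("Watterson's theta follows S / a_{n-1}", {
  mono <- aln_from(c("AA", "AA", "AA"))
  expect_equal(watterson_theta(mono)$abs, 0)
  a <- aln_from(toy4)       # n = 4, S = 3
  expect_equal(watterson_theta(a)$abs, 3 / (1 + 1 / 2 + 1 / 3))
  two <- aln_from(c("AACCA", "TTGGT"))    # n = 2, S = 5, a_1 = 1
  expect_equal(watterson_theta(two)$abs, 5)
})

test_that("Tajima's D matches an independent oracle and sign expectations", {
  expect_true(is.na(tajimas_d(aln_from(c("AA", "AA", "AA", "AA")))))
  a <- aln_from(toy4)
  expect_equal(tajimas_d(a), oracle_tajima_d(toy4), tolerance = 1e-12)
  expect_equal(round(tajimas_d(a), 3), 0.168)
  # star-like excess of singletons: n = 20, every variant private
  seqs <- vapply(1:20, function(i) {
    s <- rep("A", 20)
    s[i] <- "T"
    paste0(s, collapse = "")
  }, character(1L))
  expect_lt(tajimas_d(aln_from(seqs)), 0)
})

test_that("Tajima's D agrees with the oracle to 1e-9 on random alignments", {
  set.seed(7)
  checked <- 0L
  while (checked < 100L) {
    a <- random_aln(sample(4:12, 1L), sample(5:50, 1L))
    d1 <- tajimas_d(a)
    if (is.na(d1)) next
    expect_equal(d1, oracle_tajima_d(unname(a$seq)), tolerance = 1e-9)
    checked <- checked + 1L
  }
})

test_that("Ewens probabilities are exact and sum to one", {
  # n = 3, theta = 2/3: P(K) = 0.45 / 0.45 / 0.10 by |s(3,k)| = {2, 3, 1}
  p <- exp(rhizopop:::ewens_log_probs(3L, 2 / 3))
  expect_equal(p, c(0.45, 0.45, 0.10), tolerance = 1e-12)
  for (n in c(2L, 5L, 8L, 12L)) for (theta in c(0.3, 1, 4)) {
    lp <- rhizopop:::ewens_log_probs(n, theta)
    expect_equal(sum(exp(lp)), 1, tolerance = 1e-10)
    expect_equal(exp(lp), oracle_ewens(n, theta), tolerance = 1e-9)
  }
})

test_that("Fu's Fs reproduces the exact Ewens example and scales to n = 286", {
  a <- aln_from(c("AA", "AA", "AT"))
  expect_equal(fus_fs(a), log(0.55 / 0.45), tolerance = 1e-12)
  expect_true(is.na(fus_fs(aln_from(c("AA", "AA", "AA")))))
  # large sample, many haplotypes under small theta -> strongly negative
  fs <- rhizopop:::fs_from(286L, 2, 74L)
  expect_true(is.finite(fs))
  expect_lt(fs, -20)
  # mid-size case still matches the exact-arithmetic oracle
  fs12 <- rhizopop:::fs_from(12L, 1.5, 7L)
  p12 <- oracle_ewens(12L, 1.5)
  sp12 <- sum(p12[7:12])
  expect_equal(fs12, log(sp12 / (1 - sp12)), tolerance = 1e-9)
})

test_that("haplotype diversity follows the unbiased formula", {
  expect_equal(haplotype_diversity(aln_from(c("AA", "AA", "AA"))), 0)
  expect_equal(haplotype_diversity(aln_from(c("AA", "AT"))), 1)
  expect_equal(haplotype_diversity(aln_from(c("AA", "AA", "AA", "AT"))), 0.5)
})

test_that("Hudson F_ST behaves at the calibration points", {
  # fixed differences, no within-variation -> 1
  a <- aln_from(c("AAAA", "AAAA", "TTTT", "TTTT"))
  g <- setNames(c("p", "p", "q", "q"), names(a$seq))
  expect_equal(hudson_fst(a, g)["p", "q"], 1)
  # constructed H_w = 1, H_b = 2 -> 0.5
  b <- aln_from(c("CA", "CT", "GG", "GC"))
  gb <- setNames(c("p", "p", "q", "q"), names(b$seq))
  expect_equal(hudson_fst(b, gb)["p", "q"], 0.5)
  # one panmictic pool split at random -> near 0 in expectation
  set.seed(3)
  vals <- replicate(40, {
    aln <- random_aln(16L, 30L)
    gg <- setNames(sample(rep(c("p", "q"), each = 8L)), names(aln$seq))
    hudson_fst(aln, gg)["p", "q"]
  })
  expect_lt(abs(mean(vals)), 0.05)
})

test_that("pi and theta_w are invariant under strain reordering and scale per site", {
  set.seed(11)
  a <- random_aln(10L, 40L)
  perm <- sample(seq_along(a$seq))
  b <- locus_alignment(a$seq[perm], name = "perm")
  expect_equal(nucleotide_diversity(a)$abs, nucleotide_diversity(b)$abs)
  expect_equal(watterson_theta(a)$abs, watterson_theta(b)$abs)
  L <- sum(retained_columns(a))
  expect_equal(nucleotide_diversity(a)$per_site * L,
               nucleotide_diversity(a)$abs)
  expect_equal(watterson_theta(a)$per_site * L, watterson_theta(a)$abs)
})

test_that("neutrality test p-values are reproducible and in range", {
  a <- aln_from(toy4)
  set.seed(5)
  r1 <- neutrality_test(a, n_reps = 200L)
  set.seed(5)
  r2 <- neutrality_test(a, n_reps = 200L)
  expect_identical(r1, r2)
  expect_true(r1$p_D >= 0 && r1$p_D <= 1)
  expect_true(r1$p_Fs >= 0 && r1$p_Fs <= 1)
})
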