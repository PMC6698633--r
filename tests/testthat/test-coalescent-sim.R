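test_that("single-deme calibration: E[pi] = theta and E[S] = theta * a_{n-1}", {
  set.seed(91)
  sc2 <- constant_scenario(2L, theta = 5)
  d2 <- replicate(2000L, ncol(simulate_dataset(sc2, render = FALSE)$loci[[1L]]$G))
  se2 <- sd(d2) / sqrt(length(d2))
  expect_lt(abs(mean(d2) - 5), 3 * se2)
  sc10 <- constant_scenario(10L, theta = 2)
  S10 <- replicate(2000L, ncol(simulate_dataset(sc10, render = FALSE)$loci[[1L]]$G))
  se10 <- sd(S10) / sqrt(length(S10))
  expect_lt(abs(mean(S10) - 2 * sum(1 / (1:9))), 3 * se10)
})

test_that("mean TMRCA for a pair in one deme of size N is about N", {
  set.seed(92)
  sc <- demographic_scenario(demes = data.frame(name = "p", size = 1000,
                                                growth = 0),
                             samples = c(p = 2L),
                             loci = data.frame(name = "l", length = 1L,
                                               mu = 0),
                             label = "tmrca")
  tm <- replicate(5000L, simulate_dataset(sc, render = FALSE)$loci[[1L]]$tmrca)
  se <- sd(tm) / sqrt(length(tm))
  expect_lt(abs(mean(tm) - 1000), 3 * se)
})

test_that("trifurcation with merge times near zero is panmixia", {
  tri <- demographic_scenario(
    demes = data.frame(name = c("a", "b", "c"), size = 1000, growth = 0),
    events = data.frame(time = c(1e-9, 2e-9), type = "merge",
                        from = c("a", "b"), to = "c", value = NA),
    samples = c(a = 5L, b = 5L, c = 5L),
    loci = data.frame(name = "l", length = 1000L, mu = 1e-6),
    label = "tri0")
  pan <- constant_scenario(15L, theta = 2)
  pi_of <- function(sc) {
    G <- simulate_dataset(sc, render = FALSE)$loci[[1L]]$G
    n <- nrow(G)
    if (ncol(G) == 0L) return(0)
    cs <- colSums(G)
    sum(cs * (n - cs)) / choose(n, 2L)
  }
  set.seed(93)
  p1 <- replicate(500L, pi_of(tri))
  p2 <- replicate(500L, pi_of(pan))
  expect_gt(suppressWarnings(wilcox.test(p1, p2)$p.value), 0.01)
})

test_that("site positions are unique within a locus and seeds reproduce bytes", {
  sc <- constant_scenario(10L, theta = 10)
  sim <- simulate_dataset(sc, seed = 99L)
  expect_false(any(duplicated(sim$loci[[1L]]$pos)))
  sim2 <- simulate_dataset(sc, seed = 99L)
  expect_identical(sim$loci, sim2$loci)
  expect_identical(sim$sequences, sim2$sequences)
  # rendered FASTA bytes identical through the writer
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_mlst(as_mlst(sim), d1)
  write_mlst(as_mlst(sim2), d2)
  expect_identical(readBin(file.path(d1, "locus.fasta"), "raw", 1e6),
                   readBin(file.path(d2, "locus.fasta"), "raw", 1e6))
})

test_that("scenario validation catches malformed inputs", {
  ok <- builtin_models()$model_10$build(
    c(N_CI = 1e4, N_CII = 1e4, N_CIII = 1e4, N_ANC = 1e4, t1 = 1e4,
      mu = 1e-8))
  expect_length(validate_scenario(ok), 0L)
  # unsorted events
  sc <- demographic_scenario(
    demes = data.frame(name = c("a", "b", "c"), size = 100, growth = 0),
    events = data.frame(time = c(50, 10), type = "merge",
                        from = c("a", "b"), to = c("c", "c"), value = NA),
    samples = c(a = 2L, b = 2L, c = 2L),
    loci = data.frame(name = "l", length = 10L, mu = 1e-8), label = "x")
  expect_match(validate_scenario(sc), "not sorted", all = FALSE)
  # orphan ghost deme
  sc2 <- demographic_scenario(
    demes = data.frame(name = c("a", "b", "ghost"), size = 100, growth = 0),
    events = data.frame(time = 10, type = "merge", from = "a", to = "b",
                        value = NA),
    samples = c(a = 2L, b = 2L, ghost = 0L),
    loci = data.frame(name = "l", length = 10L, mu = 1e-8), label = "x")
  expect_match(validate_scenario(sc2), "orphan", all = FALSE)
  # disconnected sampled demes refuse to simulate
  bad <- demographic_scenario(
    demes = data.frame(name = c("a", "b"), size = 100, growth = 0),
    samples = c(a = 2L, b = 2L),
    loci = data.frame(name = "l", length = 10L, mu = 1e-8), label = "bad")
  expect_error(simulate_dataset(bad), "cannot coalesce")
  expect_error(demographic_scenario(
    demes = data.frame(name = "a", size = 100, growth = 0),
    events = data.frame(time = -5, type = "size", from = "a", to = NA,
                        value = 10),
    samples = c(a = 2L),
    loci = data.frame(name = "l", length = 10L, mu = 1e-8), label = "x"),
    "strictly positive")
})

test_that("scenario YAML round-trips", {
  sc <- builtin_models()$model_10$build(
    c(N_CI = 2e4, N_CII = 3e4, N_CIII = 4e4, N_ANC = 5e4, t1 = 1e5,
      mu = 1e-8))
  p <- withr::local_tempfile(fileext = ".yaml")
  write_scenario_yaml(sc, p)
  sc2 <- read_scenario_yaml(p)
  expect_equal(sc2$demes$size, sc$demes$size)
  expect_equal(sc2$events$time, sc$events$time)
  expect_equal(as.integer(sc2$samples), as.integer(sc$samples))
  expect_equal(sc2$loci$mu, sc$loci$mu)
  sim <- simulate_dataset(sc2, seed = 1, render = FALSE)
  expect_equal(nrow(sim$loci[[1L]]$G), 266L)
})

test_that("growth rates shrink diversity backward in time as expected", {
  # strong forward growth: going back the deme collapses quickly, so
  # diversity is far below the constant-size expectation
  set.seed(94)
  gr <- demographic_scenario(
    demes = data.frame(name = "p", size = 1e5, growth = 0.01),
    samples = c(p = 10L),
    loci = data.frame(name = "l", length = 1000L, mu = 1e-6),
    label = "growth")
  S_g <- mean(replicate(300L,
    ncol(simulate_dataset(gr, render = FALSE)$loci[[1L]]$G)))
  S_c <- mean(replicate(300L,
    ncol(simulate_dataset(constant_scenario(10L, theta = 200),
                          render = FALSE)$loci[[1L]]$G)))
  expect_lt(S_g, S_c / 3)
})
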