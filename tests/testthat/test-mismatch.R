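test_that("observed spectra match hand counts", {
  sp <- observed_mismatch(aln_from(c("AAA", "AAT", "ATT", "TTT")))
  expect_equal(sp$freq, c(0, 0.5, 1 / 3, 1 / 6))
  expect_equal(sp$n_pairs, 6L)
  expect_equal(sp$mean, 10 / 6)
  mono <- observed_mismatch(aln_from(c("AA", "AA", "AA")))
  expect_equal(mono$freq, 1)
  two <- observed_mismatch(aln_from(c("AAA", "ATT")))
  expect_equal(two$freq, c(0, 0, 1))
})

test_that("constant-size spectrum equals the geometric closed form exactly", {
  sp <- expected_mismatch("constant", c(theta = 1), 10L)
  expect_equal(sp$freq[1:3], c(1 / 2, 1 / 4, 1 / 8))
  expect_equal(sp$freq, 1^(0:10) / 2^(1:11))
})

test_that("demographic expansion reproduces its limiting cases", {
  # theta0 = 0, theta1 -> infinity: Poisson(tau)
  sp <- expected_mismatch("demographic_expansion",
                          c(tau = 3, theta0 = 0, theta1 = 1e12), 25L)
  expect_equal(sp$freq, dpois(0:25, 3), tolerance = 1e-6)
  # tau -> 0: constant-size spectrum at theta0
  sp0 <- expected_mismatch("demographic_expansion",
                           c(tau = 0, theta0 = 2, theta1 = 50), 25L)
  expect_equal(sp0$freq, expected_mismatch("constant", c(theta = 2), 25L)$freq,
               tolerance = 1e-12)
  # spatial expansion with M -> 0 collapses to constant size at theta
  spm <- expected_mismatch("spatial_expansion",
                           c(tau = 4, theta = 2, M = 0), 25L)
  expect_equal(spm$freq, expected_mismatch("constant", c(theta = 2), 25L)$freq,
               tolerance = 1e-10)
})

test_that("every expected spectrum sums to 1 with adaptive truncation", {
  cases <- list(
    list("constant", c(theta = 0.5)),
    list("constant", c(theta = 8)),
    list("demographic_expansion", c(tau = 2, theta0 = 0.5, theta1 = 100)),
    list("demographic_expansion", c(tau = 10, theta0 = 2, theta1 = 1e4)),
    list("spatial_expansion", c(tau = 3, theta = 1, M = 5)),
    list("spatial_expansion", c(tau = 12, theta = 4, M = 0.5)))
  for (cs in cases) {
    d_max <- 200L
    total <- sum(expected_mismatch(cs[[1L]], cs[[2L]], d_max)$freq)
    while (1 - total > 1e-6 && d_max < 3000L) {
      d_max <- d_max * 2L
      total <- sum(expected_mismatch(cs[[1L]], cs[[2L]], d_max)$freq)
    }
    expect_equal(total, 1, tolerance = 1e-6)
  }
})

test_that("closed forms agree with coalescent-simulation oracles", {
  # constant and demographic expansion via the native engine (pairs, 1e4
  # replicates); spatial expansion via an independent Gillespie pair process
  set.seed(71)
  check_freq <- function(freq, draws, classes = 0:3) {
    n <- length(draws)
    for (k in classes) {
      phat <- mean(draws == k)
      se <- sqrt(max(phat * (1 - phat), 1e-6) / n)
      expect_lt(abs(phat - freq[k + 1L]), 3.2 * se + 1e-3)
    }
  }
  # constant theta = 2
  sc <- constant_scenario(2L, theta = 2)
  d_const <- replicate(10000L, ncol(simulate_dataset(sc, render = FALSE)$loci[[1L]]$G))
  check_freq(expected_mismatch("constant", c(theta = 2), 40L)$freq, d_const)
  # demographic expansion at two parameter points
  for (pp in list(c(tau = 2, theta0 = 0.5, theta1 = 100),
                  c(tau = 5, theta0 = 1, theta1 = 50))) {
    sc <- expansion_scenario(2L, pp["tau"], pp["theta0"], pp["theta1"])
    d_exp <- replicate(10000L,
      ncol(simulate_dataset(sc, render = FALSE)$loci[[1L]]$G))
    check_freq(expected_mismatch("demographic_expansion", pp, 60L)$freq,
               d_exp, classes = c(0:3, round(pp["tau"])))
  }
  # spatial expansion at two parameter points
  for (pp in list(c(tau = 3, theta = 1, M = 2),
                  c(tau = 6, theta = 2, M = 10))) {
    d_sp <- replicate(10000L, oracle_spatial_pair(pp["tau"], pp["theta"],
                                                  pp["M"]))
    check_freq(expected_mismatch("spatial_expansion", pp, 60L)$freq, d_sp,
               classes = c(0:3, round(pp["tau"])))
  }
})

test_that("raggedness follows the stated convention", {
  r1 <- raggedness(c(1.0))
  expect_equal(as.numeric(r1), 1)
  expect_match(attr(r1, "convention"), "d\\+1")
  expect_equal(as.numeric(raggedness(c(0.5, 0.5))), 0.25)
  # smooth wide unimodal vs two-spike of equal support
  smooth <- dpois(0:10, 5)
  spiky <- c(0.5, rep(0, 9L), 0.5)
  expect_lt(as.numeric(raggedness(smooth)), as.numeric(raggedness(spiky)))
})

test_that("fits recover parameters from exact model spectra", {
  sp <- expected_mismatch("constant", c(theta = 2), 60L)
  f <- fit_mismatch(sp, "constant")
  expect_equal(unname(f$params["theta"]), 2, tolerance = 0.01)
  expect_lt(f$ssd, 1e-8)
  spd <- expected_mismatch("demographic_expansion",
                           c(tau = 5, theta0 = 0.5, theta1 = 500), 60L)
  fd <- fit_mismatch(spd, "demographic_expansion")
  expect_equal(unname(fd$params["tau"]), 5, tolerance = 0.05)
  expect_lt(fd$ssd, 1e-8)
  sps <- expected_mismatch("spatial_expansion",
                           c(tau = 4, theta = 1, M = 20), 60L)
  fs <- fit_mismatch(sps, "spatial_expansion")
  expect_equal(unname(fs$params["tau"]), 4, tolerance = 0.2)
  expect_lt(fs$ssd, 1e-7)
  # monomorphic spectrum under the expansion model sits at the tau = 0
  # boundary
  mono <- observed_mismatch(aln_from(rep("AAAA", 12L)))
  fm <- fit_mismatch(mono, "demographic_expansion")
  expect_lt(unname(fm$params["tau"]), 0.05)
})

test_that("bootstrap goodness of fit is seeded, sane and powered", {
  set.seed(81)
  sc <- expansion_scenario(30L, tau = 5, theta0 = 0.5, theta1 = 50)
  sim <- simulate_dataset(sc, render = FALSE)
  sp <- rhizopop:::spectrum_from_sim(sim)
  fit <- suppressWarnings(fit_mismatch(sp, "demographic_expansion"))
  b1 <- bootstrap_gof(30L, fit, B = 60L, seed = 4)
  b2 <- bootstrap_gof(30L, fit, B = 60L, seed = 4)
  expect_identical(b1[c("p_ssd", "p_rag", "tau_ci")],
                   b2[c("p_ssd", "p_rag", "tau_ci")])
  expect_true(b1$p_ssd >= 0 && b1$p_ssd <= 1)
  expect_true(b1$tau_ci[1L] <= fit$params[["tau"]] &&
                b1$tau_ci[2L] >= fit$params[["tau"]])
  expect_warning(bootstrap_gof(30L, fit, B = 10L), "50 bootstrap")
  # power: a bimodal two-wave spectrum (pooled over many loci, hence
  # smooth) strongly rejects a demographic-expansion fit
  waves <- c(0.45, 0.02, 0.01, 0.01, 0.01, 0.30, 0.15, 0.03, 0.01, 0.01)
  spec2 <- rhizopop:::new_mismatch_spectrum(waves, n_pairs = choose(60, 2))
  fit2 <- fit_mismatch(spec2, "demographic_expansion")
  fit2 <- bootstrap_gof(60L, fit2, B = 100L, seed = 5, n_loci = 10L)
  expect_lt(fit2$p_ssd, 0.05)
})

test_that("time conversions follow tau = 2 mu t and the generation clock", {
  expect_equal(tau_to_generations(2.53, 1e-8, 3308), 2.53 / (2 * 1e-8 * 3308))
  expect_equal(round(tau_to_generations(2.53, 1e-8, 3308)), 38241)
  expect_equal(generations_to_years(16900), 563, tolerance = 0.01)
  expect_equal(tau_to_generations(0, 1e-8, 100), 0)
  expect_error(tau_to_generations(1, -1e-8, 100), "positive")
  expect_error(generations_to_years(-5), "positive")
  # mutation-scaled divergence times invert as T = t/mu
  expect_equal(scaled_time_to_generations(3.3, 1e-5), 330000)
  expect_error(scaled_time_to_generations(1, 0), "positive")
})
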