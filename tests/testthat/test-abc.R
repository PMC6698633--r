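# one-deme toy model used in several ABC tests: a single clade "P" whose
# size is the only free parameter (mu fixed through the builder)
toy_model <- function(label = "toy", nmin = 1e3, nmax = 1e5, n = 20L) {
  build <- function(par) {
    demographic_scenario(
      demes = data.frame(name = "P", size = par[["N"]], growth = 0),
      samples = c(P = n),
      loci = data.frame(name = "l", length = 1000L, mu = 1e-6),
      label = label)
  }
  abc_model(label,
            prior_spec(data.frame(name = "N", dist = "loguniform",
                                  min = nmin, max = nmax)),
            build, clades = "P")
}

# reference_table built directly from matrices (for analytic rejection toys)
fake_table <- function(label, params, stats) {
  structure(list(label = label, params = params, stats = stats,
                 n_sims = nrow(stats), n_dropped = 0L),
            class = "reference_table")
}

test_that("prior sampling matches its distributions and seeds", {
  spec <- prior_spec(data.frame(name = c("a", "b"),
                                dist = c("uniform", "loguniform"),
                                min = c(0, 1e-8), max = c(1, 1e-7)))
  x <- sample_priors(spec, 10000L, seed = 1)
  expect_lt(abs(mean(x[, "a"]) - 0.5), 3 * sd(x[, "a"]) / 100)
  expect_true(all(x[, "b"] >= 1e-8 & x[, "b"] <= 1e-7))
  y <- sample_priors(spec, 10000L, seed = 1)
  expect_identical(x, y)
  # YAML round-trip
  p <- withr::local_tempfile(fileext = ".yaml")
  write_priors_yaml(spec, p)
  spec2 <- read_priors_yaml(p)
  expect_equal(spec2$params$min, spec$params$min)
  expect_equal(spec2$params$dist, spec$params$dist)
  expect_error(prior_spec(data.frame(name = "a", dist = "uniform",
                                     min = 2, max = 1)), "min < max")
  expect_error(prior_spec(data.frame(name = "a", dist = "loguniform",
                                     min = 0, max = 1)), "min > 0")
})

test_that("reference tables simulate, stay finite and reproduce", {
  m <- toy_model()
  t1 <- build_reference_table(m, 100L, seed = 3)
  expect_equal(t1$n_sims, 100L)
  expect_true(all(is.finite(t1$stats)))
  t2 <- build_reference_table(m, 100L, seed = 3)
  expect_identical(t1$stats, t2$stats)
  # near-point-mass prior gives a near-constant parameter column
  m2 <- toy_model(nmin = 1e4, nmax = 1e4 + 1)
  t3 <- build_reference_table(m2, 50L, seed = 4)
  expect_lt(diff(range(t3$params[, "N"])), 2)
})

test_that("rejection keeps the closest simulations with pooled scaling", {
  set.seed(5)
  A <- fake_table("A", matrix(runif(1000), ncol = 1L,
                              dimnames = list(NULL, "p")),
                  matrix(rnorm(1000), ncol = 1L,
                         dimnames = list(NULL, "s")))
  B <- fake_table("B", matrix(runif(1000), ncol = 1L,
                              dimnames = list(NULL, "p")),
                  matrix(rnorm(1000, 5), ncol = 1L,
                         dimnames = list(NULL, "s")))
  obs <- c(s = 0)
  r_all <- abc_reject(obs, list(A, B), retain_frac = 1)
  expect_equal(r_all$n_retained, 2000L)
  r <- abc_reject(obs, list(A, B), retain_frac = 0.01)
  expect_equal(r$n_retained, 20L)
  # the retained set is dominated by the model centred on the observation
  expect_gte(nrow(r$retained$A$params), 19L)
  # a row equal to the observation is retained with distance 0
  A2 <- fake_table("A2", matrix(1, 1L, 1L, dimnames = list(NULL, "p")),
                   matrix(0, 1L, 1L, dimnames = list(NULL, "s")))
  r2 <- abc_reject(obs, list(A2, B), retain_frac = 0.001)
  expect_equal(nrow(r2$retained$A2$stats), 1L)
  expect_equal(r2$retained$A2$dist, 0)
})

test_that("zero-variance statistics are excluded with a warning", {
  A <- fake_table("A", matrix(runif(200), ncol = 1L,
                              dimnames = list(NULL, "p")),
                  cbind(s1 = rnorm(200), s2 = rep(3, 200)))
  expect_warning(r <- abc_reject(c(s1 = 0, s2 = 3), list(A), 0.1),
                 "zero-variance")
  expect_identical(names(which(!r$usable)), "s2")
})

test_that("GLM model choice separates models and honours the >3 Bayes rule", {
  set.seed(6)
  mk <- function(center, label) {
    p <- matrix(runif(4000), ncol = 1L, dimnames = list(NULL, "p"))
    s <- matrix(rnorm(4000, center + 0.1 * p[, 1L]), ncol = 1L,
                dimnames = list(NULL, "s"))
    fake_table(label, p, s)
  }
  A <- mk(0, "A"); B <- mk(5, "B")
  rej <- abc_reject(c(s = 0), list(A, B), retain_frac = 0.02)
  ch <- glm_model_choice(rej)
  expect_equal(sum(ch$posterior), 1)
  expect_gt(ch$posterior["A"], 0.99)
  expect_gt(ch$bayes_factors["A", "B"], 3)
  # reciprocity (checked where both models retain simulations)
  Bnear <- mk(1.2, "Bnear")
  rej_n <- abc_reject(c(s = 0.6), list(A, Bnear), retain_frac = 0.25)
  ch_n <- glm_model_choice(rej_n)
  expect_equal(ch_n$bayes_factors["A", "Bnear"] *
                 ch_n$bayes_factors["Bnear", "A"], 1, tolerance = 1e-9)
  # statistically identical models split the posterior about evenly
  post_a <- replicate(10, {
    C1 <- mk(0, "C1"); C2 <- mk(0, "C2")
    rr <- abc_reject(c(s = 0), list(C1, C2), retain_frac = 0.02)
    suppressWarnings(glm_model_choice(rr))$posterior[1L]
  })
  expect_lt(abs(mean(post_a) - 0.5), 0.1)
})

test_that("goodness-of-fit p-value ranks by marginal density with a strict cut", {
  set.seed(7)
  A <- fake_table("A", matrix(runif(2000), ncol = 1L,
                              dimnames = list(NULL, "p")),
                  matrix(rnorm(2000), ncol = 1L, dimnames = list(NULL, "s")))
  rej_c <- abc_reject(c(s = 0), list(A), retain_frac = 0.25)
  ch_c <- glm_model_choice(rej_c)
  p_center <- gof_pvalue(ch_c, rej_c, "A")
  expect_gt(p_center, 0.5)
  expect_false(attr(p_center, "excluded"))
  rej_f <- abc_reject(c(s = 10), list(A), retain_frac = 0.25)
  ch_f <- glm_model_choice(rej_f)
  p_far <- gof_pvalue(ch_f, rej_f, "A")
  expect_lt(p_far, 0.05)
  expect_true(attr(p_far, "excluded"))
  expect_identical(attr(p_center, "excluded"),
                   as.logical(p_center < 0.05))
})

test_that("parameter estimation recovers an identifiable toy and respects support", {
  set.seed(8)
  n <- 20000L
  theta <- runif(n, 0, 10)
  tab <- fake_table("T", matrix(theta, ncol = 1L,
                                dimnames = list(NULL, "theta")),
                    matrix(theta + rnorm(n, 0, 0.1), ncol = 1L,
                           dimnames = list(NULL, "s")))
  spec <- prior_spec(data.frame(name = "theta", dist = "uniform",
                                min = 0, max = 10))
  rej <- abc_reject(c(s = 5), list(tab), retain_frac = 0.01)
  post <- estimate_parameters(rej, "T", spec)
  s <- post$summaries$theta
  expect_lt(abs(s["mode"] - 5), 0.25)
  expect_true(s["hdi_lo"] >= 0 && s["hdi_hi"] <= 10)
  expect_true(all(post$draws[, "theta"] >= 0 & post$draws[, "theta"] <= 10))
  # a pure-noise statistic leaves the posterior close to the prior
  tab2 <- fake_table("U", matrix(theta, ncol = 1L,
                                 dimnames = list(NULL, "theta")),
                     matrix(rnorm(n), ncol = 1L, dimnames = list(NULL, "s")))
  rej2 <- abc_reject(c(s = 0), list(tab2), retain_frac = 0.05)
  post2 <- estimate_parameters(rej2, "U", spec)
  ks <- suppressWarnings(ks.test(post2$draws[, "theta"], "punif", 0, 10))
  expect_lt(unname(ks$statistic), 0.1)
})

test_that("model-choice validation behaves at its two calibration poles", {
  set.seed(9)
  # two strongly separated one-deme models
  mA <- toy_model("small", nmin = 8e2, nmax = 1.2e3)
  mB <- toy_model("large", nmin = 8e4, nmax = 1.2e5)
  tA <- build_reference_table(mA, 600L)
  tB <- build_reference_table(mB, 600L)
  val <- validate_model_choice(list(mA, mB), list(tA, tB), n_pods = 40L,
                               retain_frac = 0.02, seed = 10)
  expect_lt(val$type_I_error["small"], 0.1)
  expect_lt(val$type_I_error["large"], 0.1)
  expect_true(all(abs(rowSums(val$assignment) - 1) < 1e-9))
  expect_true(all(val$type_II_error >= 0 & val$type_II_error <= 1))
  # two identical models: type I error near 1/2
  mC <- toy_model("twin1", nmin = 1e4, nmax = 2e4)
  mD <- toy_model("twin2", nmin = 1e4, nmax = 2e4)
  mD$label <- "twin2"
  tC <- build_reference_table(mC, 400L)
  tD <- build_reference_table(mD, 400L)
  val2 <- validate_model_choice(list(mC, mD), list(tC, tD), n_pods = 60L,
                                retain_frac = 0.05, seed = 11)
  expect_lt(abs(mean(val2$type_I_error) - 0.5), 0.2)
})

test_that("posterior-quantile coverage is uniform when well-specified and not when biased", {
  set.seed(12)
  m <- local({
    build <- function(par) demographic_scenario(
      demes = data.frame(name = c("A", "B", "ANC"), size = 5e3, growth = 0),
      events = data.frame(time = rep(par[["t1"]], 2L), type = "merge",
                          from = c("A", "B"), to = "ANC", value = NA),
      samples = c(A = 10L, B = 10L, ANC = 0L),
      loci = data.frame(name = paste0("l", 1:3), length = 1000L, mu = 2e-7),
      label = "split")
    abc_model("split", prior_spec(data.frame(name = "t1", dist = "uniform",
                                             min = 1e3, max = 1e5)),
              build, clades = c("A", "B"))
  })
  tab <- build_reference_table(m, 2500L)
  cov_ok <- validate_coverage(m, tab, n_pods = 60L, retain_frac = 0.03,
                              seed = 13)
  expect_gt(cov_ok$ks_p["t1"], 0.01)
  expect_true(all(cov_ok$quantiles >= 0 & cov_ok$quantiles <= 1))
  cov_bad <- validate_coverage(m, tab, n_pods = 60L, retain_frac = 0.03,
                               seed = 13, shift = 1.3)
  expect_lt(cov_bad$ks_p["t1"], 0.01)
})

test_that("posterior predictive envelopes cover a well-fitting observation", {
  set.seed(14)
  m <- toy_model()
  tab <- build_reference_table(m, 1500L)
  obs <- rhizopop:::stats_from_sim(
    simulate_dataset(m$build(c(N = 2e4)), render = FALSE), m$clades)
  rej <- abc_reject(obs, list(tab), retain_frac = 0.05)
  post <- suppressWarnings(estimate_parameters(rej, "toy", m$priors))
  pp <- posterior_predictive(post, m, obs, n_sims = 80L, seed = 15)
  expect_true(mean(pp$inside) > 0.6)
  expect_true(all(pp$lower <= pp$upper))
})

test_that("built-in three-clade models simulate and validate cleanly", {
  ms <- builtin_models()
  expect_named(ms, c("model_09", "model_10", "model_14a", "model_14b",
                     "model_20"))
  for (m in ms) {
    par <- sample_priors(m$priors, 1L, seed = 16)[1L, ]
    sc <- m$build(par)
    expect_length(validate_scenario(sc), 0L)
  }
  sim <- simulate_dataset(ms$model_10$build(sample_priors(
    ms$model_10$priors, 1L, seed = 17)[1L, ]), seed = 18, render = FALSE)
  expect_equal(length(sim$deme), 266L)
  st <- rhizopop:::stats_from_sim(sim, ms$model_10$clades)
  expect_length(st, 21L)
  expect_identical(names(st), summary_stat_names())
})

test_that("observed and simulated summary panels agree on rendered data", {
  ms <- builtin_models()
  par <- sample_priors(ms$model_10$priors, 1L, seed = 19)[1L, ]
  sim <- simulate_dataset(ms$model_10$build(par), seed = 20, render = TRUE)
  st_sim <- rhizopop:::stats_from_sim(sim, ms$model_10$clades)
  ds <- as_mlst(sim)
  st_obs <- summary_stats(ds, clades = c("CI", "CII", "CIII"))
  expect_equal(unname(st_obs), unname(st_sim), tolerance = 1e-9)
})
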