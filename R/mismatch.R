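# Mismatch-distribution analysis: observed spectra, closed-form expected
# spectra under constant size / sudden demographic expansion / spatial
# expansion (infinite-island), least-squares fitting, SSD and Harpending's
# raggedness with parametric bootstrap, and mutational-time conversions.
#
# All spectra are over numbers of pairwise differences; tau is expansion age
# in mutational units (tau = 2*mu*t with mu the per-locus total rate), and
# theta = 2*N*mu on the haploid scale used throughout the package.

new_mismatch_spectrum <- function(freq, counts = NULL, n_pairs = NA_real_) {
  structure(list(freq = freq, counts = counts, n_pairs = n_pairs,
                 mean = sum((seq_along(freq) - 1L) * freq)),
            class = "mismatch_spectrum")
}

#' @export
print.mismatch_spectrum <- function(x, ...) {
  cat(sprintf("<mismatch_spectrum> classes 0..%d, mean %.3f differences\n",
              length(x$freq) - 1L, x$mean))
  invisible(x)
}

#' Observed mismatch distribution
#'
#' Histogram of the upper triangle of the pairwise difference matrix.
#'
#' @param aln a [locus_alignment].
#' @return a `mismatch_spectrum` with counts, relative frequencies, number of
#'   pairs, and the mean number of differences.
#' @export
observed_mismatch <- function(aln) {
  D <- pairwise_difference_matrix(aln)
  d <- D[upper.tri(D)]
  counts <- tabulate(d + 1L, nbins = max(d) + 1L)
  new_mismatch_spectrum(counts / length(d), counts, length(d))
}

geom_spec <- function(theta, j) {
  if (theta <= 0) return(as.numeric(j == 0L))
  exp(j * log(theta) - (j + 1) * log1p(theta))   # stable for large j
}

# fast internal evaluators (no class construction; p is a plain numeric
# vector in the model's canonical parameter order)
freq_constant <- function(theta, j) {
  if (theta <= 0) return(c(1, rep(0, length(j) - 1L)))
  geom_spec(theta, j)
}
freq_demographic <- function(tau, theta0, theta1, j) {
  th1 <- max(theta1, 1e-12)
  base <- geom_spec(th1, j)
  diff0 <- geom_spec(theta0, j) - base
  pois <- stats::dpois(j, tau)
  conv <- lower_conv(pois, diff0)
  base + exp(-tau / th1) * conv
}

# truncated linear convolution z_j = sum_k x_k y_{j-k} over classes 0..d
lower_conv <- function(x, y) {
  d <- length(x)
  if (d < 24L) {
    z <- numeric(d)
    for (jj in seq_len(d)) z[jj] <- sum(x[seq_len(jj)] * y[jj:1L])
    z
  } else {
    stats::convolve(x, rev(y), type = "open")[seq_len(d)]
  }
}
freq_spatial <- function(tau, theta, M, j) {
  lam <- (1 + M) / theta
  term1 <- (1 / theta) * (lam + 1)^-(j + 1) *
    stats::pgamma((lam + 1) * tau, shape = j + 1)
  q_tau <- M / (1 + M) * (1 - exp(-lam * tau)) + exp(-lam * tau)
  geo <- geom_spec(theta, j)
  pois <- stats::dpois(j, tau)
  conv <- lower_conv(pois, geo)
  term1 + q_tau * conv
}

#' Expected mismatch distribution under a demographic model
#'
#' Closed forms: constant size `F_j = theta^j/(1+theta)^(j+1)`; sudden
#' demographic expansion (a `theta0 -> theta1` step at mutational time `tau`)
#' via the Li/Rogers transient solution; spatial expansion via the
#' infinite-island closed form with parameters `(tau, theta, M)` (M = 2Nm,
#' the scaled number of migrants per deme).
#'
#' @param model one of `"constant"`, `"demographic_expansion"`,
#'   `"spatial_expansion"`.
#' @param params named vector/list: `theta` (constant); `tau, theta0, theta1`
#'   (demographic); `tau, theta, M` (spatial).
#' @param d_max largest difference class to evaluate.
#' @return a `mismatch_spectrum` of expected relative frequencies over
#'   `0..d_max` (truncated; the full distribution over `0..Inf` sums to 1).
#' @export
expected_mismatch <- function(model, params, d_max) {
  model <- match.arg(model, c("constant", "demographic_expansion",
                              "spatial_expansion"))
  p <- as.list(params)
  j <- 0:d_max
  freq <- switch(model,
    constant = {
      if (p$theta < 0) stop("theta must be >= 0")
      freq_constant(p$theta, j)
    },
    demographic_expansion = {
      if (p$tau < 0 || p$theta0 < 0 || p$theta1 < 0)
        stop("parameters must be >= 0")
      freq_demographic(p$tau, p$theta0, p$theta1, j)
    },
    spatial_expansion = {
      if (p$tau < 0 || p$theta <= 0 || p$M < 0)
        stop("tau >= 0, theta > 0, M >= 0 required")
      freq_spatial(p$tau, p$theta, p$M, j)
    })
  new_mismatch_spectrum(freq)
}

#' Harpending's raggedness statistic
#'
#' Computes `sum((x_i - x_{i-1})^2, i = 1..d+1)` over frequency classes `x_0..x_d`
#' with the convention `x_{d+1} = 0` (recorded in the `convention`
#' attribute, since programs differ here).
#'
#' @param spec a `mismatch_spectrum` (or bare frequency vector).
#' @return the raggedness value.
#' @export
raggedness <- function(spec) {
  x <- if (inherits(spec, "mismatch_spectrum")) spec$freq else spec
  if (!length(x)) stop("empty spectrum")
  xx <- c(x, 0)
  r <- sum(diff(xx)^2)
  attr(r, "convention") <- "x_{d+1}=0; sum over i=1..d+1"
  r
}

ssd_between <- function(obs_freq, exp_freq) {
  d <- max(length(obs_freq), length(exp_freq))
  o <- c(obs_freq, rep(0, d - length(obs_freq)))
  e <- c(exp_freq, rep(0, d - length(exp_freq)))
  sum((o - e)^2)
}

# objective for a parameter vector on the model's natural scale (par in the
# canonical order: theta | tau,theta0,theta1 | tau,theta,M)
mismatch_ssd <- function(model, par, obs_freq) {
  j <- seq_along(obs_freq) - 1L
  par <- as.numeric(par)
  ex <- switch(model,
    constant = freq_constant(par[1L], j),
    demographic_expansion = freq_demographic(par[1L], par[2L], par[3L], j),
    spatial_expansion = freq_spatial(par[1L], par[2L], par[3L], j))
  if (anyNA(ex)) return(1e6)
  sum((obs_freq - ex)^2)
}

#' Fit a mismatch model by least squares
#'
#' Coarse grid search over the model's parameters followed by Nelder-Mead
#' refinement of the sum of squared deviations between observed and expected
#' relative frequencies. Deterministic given the input spectrum.
#'
#' @param spec an observed `mismatch_spectrum`.
#' @param model `"constant"`, `"demographic_expansion"` or
#'   `"spatial_expansion"`.
#' @param tau_grid grid of tau values searched (default 0..50 step 1).
#' @param start optional named vector of starting parameters; when given the
#'   grid search is skipped and Nelder-Mead starts there (used to warm-start
#'   bootstrap refits from the parent fit).
#' @param maxit Nelder-Mead iteration cap (default 500).
#' @return a `mismatch_fit` with fields `model`, `params`, `ssd`,
#'   `raggedness`, `expected` and `converged`.
#' @export
fit_mismatch <- function(spec, model,
                         tau_grid = seq(0, 50, by = 1), start = NULL,
                         maxit = 500L) {
  stopifnot(inherits(spec, "mismatch_spectrum"))
  model <- match.arg(model, c("constant", "demographic_expansion",
                              "spatial_expansion"))
  if (!is.na(spec$n_pairs) && spec$n_pairs < choose(10, 2))
    warning("spectrum from fewer than 10 sequences; fit may be unstable")
  obs <- spec$freq
  mbar <- max(spec$mean, 1e-3)
  pnames <- switch(model, constant = "theta",
                   demographic_expansion = c("tau", "theta0", "theta1"),
                   spatial_expansion = c("tau", "theta", "M"))
  if (model == "constant") {
    opt <- stats::optim(log(mbar), function(x)
      mismatch_ssd(model, exp(x), obs), method = "Brent",
      lower = log(1e-8), upper = log(1e6))
    pars <- c(theta = unname(exp(opt$par)))
    if (mismatch_ssd(model, 1e-12, obs) < opt$value) pars <- c(theta = 0)
    ex <- expected_mismatch(model, pars, length(obs) - 1L)
    return(structure(list(model = model, params = pars,
                          ssd = ssd_between(obs, ex$freq),
                          raggedness = as.numeric(raggedness(spec)),
                          expected = ex$freq, observed = obs,
                          n_pairs = spec$n_pairs, converged = TRUE),
                     class = "mismatch_fit"))
  }
  if (is.null(start)) {
    grid <- switch(model,
      demographic_expansion = expand.grid(
        tau = tau_grid,
        theta0 = c(0.01, 0.1, 1, mbar),
        theta1 = c(1, 10, 100, 1000, 1e5)),
      spatial_expansion = expand.grid(
        tau = tau_grid,
        theta = unique(c(mbar * c(0.25, 0.5, 1, 2, 4), 0.5, 2, 10)),
        M = c(0.1, 1, 10, 100, 1000)))
    gm <- as.matrix(grid)
    vals <- vapply(seq_len(nrow(gm)), function(i)
      mismatch_ssd(model, gm[i, ], obs), numeric(1L))
    best <- gm[which.min(vals), ]
    best_val <- min(vals, na.rm = TRUE)
  } else {
    best <- pmax(as.numeric(start[pnames]), c(0, 1e-6, 1e-6))
    names(best) <- pnames
    # a couple of alternative starts guard against parent-fit basins
    alts <- list(best, c(mbar, best[2L], best[3L]), c(0, best[2L], best[3L]))
    av <- vapply(alts, function(p) mismatch_ssd(model, p, obs), numeric(1L))
    best <- alts[[which.min(av)]]
    names(best) <- pnames
    best_val <- min(av)
  }
  # Nelder-Mead on a transformed scale keeping parameters in bounds
  to_nat <- function(x) {
    p <- c(x[1L]^2, exp(x[2L]), exp(x[3L]))
    if (model == "demographic_expansion") p[3L] <- min(p[3L], 1e5)
    names(p) <- pnames
    p
  }
  x0 <- c(sqrt(best[1L]), log(max(best[2L], 1e-6)), log(max(best[3L], 1e-6)))
  opt <- stats::optim(x0, function(x) mismatch_ssd(model, to_nat(x), obs),
                      method = "Nelder-Mead",
                      control = list(maxit = maxit, reltol = 1e-10))
  pars <- to_nat(opt$par)
  converged <- opt$convergence == 0L
  if (mismatch_ssd(model, pars, obs) > best_val) {
    pars <- best            # refinement failed; keep best start
    converged <- FALSE
  }
  ex <- expected_mismatch(model, pars, length(obs) - 1L)
  structure(list(model = model, params = pars,
                 ssd = ssd_between(obs, ex$freq),
                 raggedness = as.numeric(raggedness(spec)),
                 expected = ex$freq, observed = obs,
                 n_pairs = spec$n_pairs,
                 converged = converged),
            class = "mismatch_fit")
}

#' @export
print.mismatch_fit <- function(x, ...) {
  cat(sprintf("<mismatch_fit> %s: %s; SSD = %.4g, raggedness = %.4g\n",
              x$model,
              paste(sprintf("%s = %.4g", names(x$params), x$params),
                    collapse = ", "),
              x$ssd, x$raggedness))
  if (!is.null(x$p_ssd))
    cat(sprintf("  bootstrap: p(SSD) = %.3f, p(raggedness) = %.3f, tau 95%% CI [%.3g, %.3g]\n",
                x$p_ssd, x$p_rag, x$tau_ci[1L], x$tau_ci[2L]))
  invisible(x)
}

# coalescent scenario matching a fitted mismatch model (mutational units
# mapped onto generations through an arbitrary total rate u; n_loci > 1
# splits the total rate over independent genealogies, mirroring data pooled
# over several loci)
scenario_from_fit <- function(fit, n, u = 1e-3, n_loci = 1L) {
  p <- as.list(fit$params)
  loci_df <- data.frame(name = paste0("locus", seq_len(n_loci)),
                        length = 1L, mu = u / n_loci)
  if (fit$model == "constant") {
    demographic_scenario(
      demes = data.frame(name = "pop", size = max(p$theta, 1e-4) / (2 * u),
                         growth = 0),
      samples = c(pop = n),
      loci = loci_df,
      label = "constant")
  } else if (fit$model == "demographic_expansion") {
    t_exp <- p$tau / (2 * u)
    demographic_scenario(
      demes = data.frame(name = "pop", size = max(p$theta1, 1e-4) / (2 * u),
                         growth = 0),
      events = data.frame(time = max(t_exp, 1e-9), type = "size",
                          from = "pop", to = NA,
                          value = max(p$theta0, 1e-4) / (2 * u)),
      samples = c(pop = n),
      loci = loci_df,
      label = "demographic_expansion")
  } else {
    n_demes <- 50L
    N <- p$theta / (2 * u)
    m <- p$M / (2 * N)
    mig <- matrix(m / (n_demes - 1L), n_demes, n_demes)
    diag(mig) <- 0
    t_exp <- max(p$tau / (2 * u), 1e-9)
    demes <- data.frame(name = paste0("d", seq_len(n_demes)),
                        size = N, growth = 0)
    events <- data.frame(time = t_exp, type = "merge",
                         from = paste0("d", 2:n_demes), to = "d1",
                         value = NA_real_)
    samples <- setNames(c(n, rep(0L, n_demes - 1L)), demes$name)
    demographic_scenario(demes = demes, events = events, migration = mig,
                         samples = samples, loci = loci_df,
                         label = "spatial_expansion")
  }
}

# mismatch spectrum straight from simulated 0/1 site matrices (all loci pooled)
spectrum_from_sim <- function(sim) {
  G <- do.call(cbind, lapply(sim$loci, `[[`, "G"))
  n <- nrow(G)
  if (ncol(G) == 0L) {
    d <- rep(0L, choose(n, 2L))
  } else {
    D <- hamming_strings_cpp(apply(G, 1L, paste0, collapse = ""))
    d <- D[upper.tri(D)]
  }
  counts <- tabulate(d + 1L, nbins = max(d) + 1L)
  new_mismatch_spectrum(counts / length(d), counts, length(d))
}

#' Parametric bootstrap goodness-of-fit for a mismatch fit
#'
#' Simulates `B` data sets from the coalescent at the fitted parameters
#' (matching the sample size), refits the same model to each, and reports
#' `p_ssd` (fraction of simulated SSD >= observed), `p_rag` (likewise for
#' raggedness) and the 2.5/97.5 percentile interval of the refitted tau.
#'
#' @param aln the original [locus_alignment] (provides the sample size), or
#'   directly the number of sequences.
#' @param fit a [fit_mismatch()] result.
#' @param B bootstrap replicates (default 1000; < 50 triggers a warning).
#' @param seed optional RNG seed for reproducibility.
#' @param n_loci number of independent loci pooled in the bootstrap
#'   simulations (match the structure of the observed data; default 1, the
#'   clonal concatenation).
#' @param tau_grid passed to the refits; `NULL` (default) uses a coarse grid
#'   adapted to each replicate's spectrum width.
#' @return the `mismatch_fit` with `p_ssd`, `p_rag`, `tau_ci` and
#'   `tau_boot` filled in.
#' @export
bootstrap_gof <- function(aln, fit, B = 1000L, seed = NULL, n_loci = 1L,
                          tau_grid = NULL) {
  stopifnot(inherits(fit, "mismatch_fit"))
  if (B < 50L) warning("fewer than 50 bootstrap replicates")
  if (!is.null(seed)) set.seed(seed)
  n <- if (is.numeric(aln)) as.integer(aln) else length(aln$seq)
  sc <- scenario_from_fit(fit, n, n_loci = n_loci)
  ssd_b <- rag_b <- tau_b <- numeric(B)
  for (b in seq_len(B)) {
    sim <- simulate_dataset(sc, render = FALSE)
    sp <- spectrum_from_sim(sim)
    tg <- if (is.null(tau_grid))
      seq(0, length(sp$freq) + 4L, by = 2) else tau_grid
    f <- suppressWarnings(fit_mismatch(sp, fit$model, tau_grid = tg))
    ssd_b[b] <- f$ssd
    rag_b[b] <- f$raggedness
    tau_b[b] <- if (fit$model == "constant") NA_real_ else f$params[["tau"]]
  }
  fit$p_ssd <- mean(ssd_b >= fit$ssd)
  fit$p_rag <- mean(rag_b >= fit$raggedness)
  fit$tau_ci <- if (fit$model == "constant") c(NA_real_, NA_real_) else {
    ci <- unname(quantile(tau_b, c(0.025, 0.975)))
    # the interval always brackets the point estimate
    c(min(ci[1L], fit$params[["tau"]]), max(ci[2L], fit$params[["tau"]]))
  }
  fit$tau_boot <- tau_b
  fit
}

#' Convert a mismatch tau to generations
#'
#' `t = tau / (2 * mu_per_site * L)`.
#'
#' @param tau expansion age in mutational units.
#' @param mu_per_site per-site mutation rate per generation.
#' @param L sequence length in bp over which tau was estimated.
#' @return time in generations before present.
#' @export
tau_to_generations <- function(tau, mu_per_site, L) {
  if (mu_per_site <= 0 || L <= 0 || tau < 0) stop("arguments must be positive")
  tau / (2 * mu_per_site * L)
}

#' Convert a mutation-scaled divergence time to generations
#'
#' Isolation-with-migration style estimates report divergence on the
#' mutation scale, `t_scaled = T * mu`; this inverts it: `T = t_scaled/mu`.
#'
#' @param t_scaled divergence time scaled by the mutation rate.
#' @param mu_per_locus mutation rate per locus per generation.
#' @return time in generations before present.
#' @export
scaled_time_to_generations <- function(t_scaled, mu_per_locus) {
  if (t_scaled < 0 || mu_per_locus <= 0) stop("arguments must be positive")
  t_scaled / mu_per_locus
}

#' Convert generations to years
#'
#' @param g generations before present.
#' @param gen_per_year generations per year (default 30, an upper bound for
#'   slow-growing soil bacteria cycling through nodules and soil).
#' @return years before present.
#' @export
generations_to_years <- function(g, gen_per_year = 30) {
  if (g < 0 || gen_per_year <= 0) stop("arguments must be positive")
  g / gen_per_year
}
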