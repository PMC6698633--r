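# Validation of the ABC pipeline with pseudo-observed data sets (PODs):
# type I/II error of model choice, posterior-predictive envelopes, and
# posterior-quantile coverage of parameter estimation.

#' Type I and II error of ABC model choice
#'
#' For each model, simulates PODs from prior draws, runs the rejection +
#' GLM model-choice procedure against the supplied reference tables, and
#' records which model attains the highest posterior probability. Type I
#' error of a model is the proportion of its own PODs for which it does not
#' win; type II error is the proportion of other models' PODs erroneously
#' assigned to it.
#'
#' @param models list of [abc_model] objects (order matching `tables`).
#' @param tables list of [build_reference_table()] results.
#' @param n_pods PODs per model (default 1000).
#' @param retain_frac rejection retention fraction.
#' @param seed optional RNG seed.
#' @return an object of class `abc_validation` with `assignment` (row =
#'   generating model, column = chosen model, rows summing to 1),
#'   `type_I_error`, `type_II_error`, `n_pods`.
#' @export
validate_model_choice <- function(models, tables, n_pods = 1000L,
                                  retain_frac = 0.005, seed = NULL) {
  stopifnot(length(models) == length(tables))
  if (!is.null(seed)) set.seed(seed)
  labs <- vapply(models, `[[`, character(1L), "label")
  M <- length(models)
  assignment <- matrix(0, M, M, dimnames = list(labs, labs))
  for (g in seq_len(M)) {
    pod_par <- sample_priors(models[[g]]$priors, n_pods)
    for (i in seq_len(n_pods)) {
      pod <- tryCatch({
        sim <- simulate_dataset(models[[g]]$build(pod_par[i, ]),
                                render = FALSE)
        stats_from_sim(sim, models[[g]]$clades)
      }, error = function(e) NULL)
      if (is.null(pod)) next
      rej <- suppressWarnings(abc_reject(pod, tables, retain_frac))
      ch <- suppressWarnings(glm_model_choice(rej))
      win <- which.max(ch$posterior)
      assignment[g, win] <- assignment[g, win] + 1
    }
    assignment[g, ] <- assignment[g, ] / max(sum(assignment[g, ]), 1)
  }
  type_I <- 1 - diag(assignment)
  type_II <- vapply(seq_len(M), function(m)
    mean(assignment[-m, m]), numeric(1L))
  structure(list(assignment = assignment,
                 type_I_error = setNames(type_I, labs),
                 type_II_error = setNames(type_II, labs),
                 n_pods = n_pods),
            class = "abc_validation")
}

#' @export
print.abc_validation <- function(x, ...) {
  cat(sprintf("<abc_validation> %d PODs per model\n", x$n_pods))
  for (m in names(x$type_I_error))
    cat(sprintf("  %s: type I %.3f, type II %.3f\n", m,
                x$type_I_error[m], x$type_II_error[m]))
  invisible(x)
}

#' Posterior-quantile coverage validation
#'
#' Simulates PODs with known parameter values under one model, estimates the
#' regression-adjusted posterior for each, computes the posterior CDF value
#' of the truth (its posterior quantile), and tests the quantiles for
#' uniformity with Kolmogorov-Smirnov tests. A well-calibrated posterior
#' yields uniform quantiles.
#'
#' @param model an [abc_model].
#' @param table its [build_reference_table()] result.
#' @param n_pods number of PODs (default 1000).
#' @param retain_frac rejection retention fraction.
#' @param seed optional RNG seed.
#' @param shift multiplicative bias deliberately applied to the adjusted
#'   draws (1 = none); used to verify that the test detects a biased
#'   posterior.
#' @return an object of class `abc_coverage`: per-parameter KS p-values and
#'   the matrix of posterior quantiles.
#' @export
validate_coverage <- function(model, table, n_pods = 1000L,
                              retain_frac = 0.01, seed = NULL, shift = 1) {
  if (!is.null(seed)) set.seed(seed)
  pnames <- model$priors$params$name
  pod_par <- sample_priors(model$priors, n_pods)
  Q <- matrix(NA_real_, n_pods, length(pnames),
              dimnames = list(NULL, pnames))
  for (i in seq_len(n_pods)) {
    pod <- tryCatch({
      sim <- simulate_dataset(model$build(pod_par[i, ]), render = FALSE)
      stats_from_sim(sim, model$clades)
    }, error = function(e) NULL)
    if (is.null(pod)) next
    rej <- suppressWarnings(abc_reject(pod, list(table), retain_frac))
    post <- tryCatch(suppressWarnings(
      estimate_parameters(rej, model$label, model$priors)),
      error = function(e) NULL)
    if (is.null(post)) next
    for (j in seq_along(pnames)) {
      x <- post$draws[, j] * shift
      w <- post$weights / sum(post$weights)
      Q[i, j] <- sum(w[x <= pod_par[i, j]])
    }
  }
  ok <- !is.na(Q[, 1L])
  ks <- vapply(seq_along(pnames), function(j)
    suppressWarnings(ks.test(Q[ok, j], "punif")$p.value), numeric(1L))
  structure(list(ks_p = setNames(ks, pnames), quantiles = Q[ok, , drop = FALSE],
                 n_pods = sum(ok)),
            class = "abc_coverage")
}

#' @export
print.abc_coverage <- function(x, ...) {
  cat(sprintf("<abc_coverage> %d PODs; KS uniformity p-values:\n", x$n_pods))
  for (nm in names(x$ks_p)) cat(sprintf("  %s: %.3g\n", nm, x$ks_p[nm]))
  invisible(x)
}

#' Posterior-predictive envelope
#'
#' Resamples parameter vectors from the adjusted posterior, simulates each,
#' and reports the 2.5/97.5 percentile envelope of every summary statistic
#' together with whether the observed value falls inside.
#'
#' @param post an [estimate_parameters()] result.
#' @param model the matching [abc_model].
#' @param obs observed summary vector.
#' @param n_sims number of posterior-predictive simulations (default 200).
#' @param seed optional RNG seed.
#' @return data frame with statistic, lower, upper, observed, inside.
#' @export
posterior_predictive <- function(post, model, obs, n_sims = 200L,
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  w <- post$weights / sum(post$weights)
  idx <- sample.int(nrow(post$draws), n_sims, replace = TRUE, prob = w)
  sims <- matrix(NA_real_, n_sims, length(obs),
                 dimnames = list(NULL, names(obs)))
  for (i in seq_len(n_sims)) {
    row <- tryCatch({
      sim <- simulate_dataset(model$build(post$draws[idx[i], ]),
                              render = FALSE)
      stats_from_sim(sim, model$clades)
    }, error = function(e) NULL)
    if (!is.null(row)) sims[i, ] <- row
  }
  lo <- apply(sims, 2L, quantile, 0.025, na.rm = TRUE)
  hi <- apply(sims, 2L, quantile, 0.975, na.rm = TRUE)
  data.frame(statistic = names(obs), lower = lo, upper = hi,
             observed = as.numeric(obs),
             inside = obs >= lo & obs <= hi, row.names = NULL)
}
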