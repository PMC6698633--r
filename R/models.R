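# Built-in demographic scenarios for the three-clade symbiotic-gene system,
# plus the default wide priors. Sizes are gene copies (haploid scale), times
# generations before present, mu per site per generation and shared across
# loci and models.

#' Default symbiotic locus table
#'
#' The five symbiotic loci at their printed alignment lengths.
#'
#' @param mu per-site mutation rate per generation (default 1e-8).
#' @return data frame with columns `name`, `length`, `mu`.
#' @export
symbiotic_loci <- function(mu = 1e-8) {
  data.frame(name = c("nodA", "nodC", "nifA", "nifH", "nolT"),
             length = c(535L, 798L, 693L, 686L, 596L),
             mu = mu)
}

#' Default housekeeping locus table
#'
#' @param mu per-site mutation rate per generation (default 1e-7, ten times
#'   the symbiotic default, reproducing the order-of-magnitude diversity
#'   contrast between the two gene classes).
#' @return data frame with columns `name`, `length`, `mu`.
#' @export
housekeeping_loci <- function(mu = 1e-7) {
  data.frame(name = c("recA", "atpD", "glnII", "dnaJ", "rpoA", "gryB"),
             length = c(475L, 468L, 658L, 758L, 684L, 713L),
             mu = mu)
}

default_prior_rows <- function(times, sizes) {
  rbind(
    data.frame(name = sizes, dist = "loguniform", min = 1e3, max = 1e6),
    data.frame(name = times, dist = "uniform", min = 1e3, max = 1e6),
    data.frame(name = "mu", dist = "loguniform", min = 0.5e-8, max = 2e-8))
}

#' Built-in ABC models for the three-clade system
#'
#' Four scenarios relating clades CI, CII and CIII:
#' * `model_09`: stepwise divergence with CIII ancestral -- CII splits from
#'   CIII at `t1`, CI at `t2 > t1` (the builder sorts the two drawn times).
#' * `model_10`: simultaneous trifurcation of the three clades at `t1`.
#' * `model_14a`: an unsampled (ghost) deme splits from the ancestral
#'   population; CII derives from the ghost at `t1`.
#' * `model_14b`: as 14a but the ghost splits from CIII.
#' * `model_20`: two-deme split (Chinese vs North American subclades of
#'   CIII) at `t1`.
#'
#' Default priors: divergence times uniform(1e3, 1e6) generations, deme
#' sizes log-uniform(1e3, 1e6) gene copies, `mu` log-uniform(0.5e-8, 2e-8)
#' per site per generation, shared across models.
#'
#' @param sample_sizes per-clade sample counts (default 82/97/87; for
#'   `model_20`, the first two entries of `subclade_sizes` are used).
#' @param loci locus table (default [symbiotic_loci()]; the `mu` column is
#'   overridden by the prior draw).
#' @param subclade_sizes sample sizes for `model_20` (default 31 Chinese, 9
#'   North American).
#' @return named list of [abc_model] objects.
#' @export
builtin_models <- function(sample_sizes = c(CI = 82L, CII = 97L, CIII = 87L),
                           loci = symbiotic_loci(),
                           subclade_sizes = c(CN = 31L, NAm = 9L)) {
  clades3 <- c("CI", "CII", "CIII")
  mk_loci <- function(mu) transform(loci, mu = mu)

  b10 <- function(par) {
    demographic_scenario(
      demes = data.frame(name = c("CI", "CII", "CIII", "ANC"),
                         size = c(par[["N_CI"]], par[["N_CII"]],
                                  par[["N_CIII"]], par[["N_ANC"]]),
                         growth = 0),
      events = data.frame(time = rep(par[["t1"]], 3L), type = "merge",
                          from = c("CI", "CII", "CIII"), to = "ANC",
                          value = NA_real_),
      samples = c(sample_sizes, ANC = 0L),
      loci = mk_loci(par[["mu"]]), label = "model_10")
  }
  b09 <- function(par) {
    tt <- sort(c(par[["t1"]], par[["t2"]]))
    demographic_scenario(
      demes = data.frame(name = c("CI", "CII", "CIII"),
                         size = c(par[["N_CI"]], par[["N_CII"]],
                                  par[["N_CIII"]]),
                         growth = 0),
      events = data.frame(
        time = c(tt[1L], tt[2L], tt[2L]),
        type = c("merge", "merge", "size"),
        from = c("CII", "CI", "CIII"),
        to = c("CIII", "CIII", NA),
        value = c(NA, NA, par[["N_ANC"]])),
      samples = c(sample_sizes),
      loci = mk_loci(par[["mu"]]), label = "model_09")
  }
  b14a <- function(par) {
    tt <- sort(c(par[["t1"]], par[["t2"]]))
    demographic_scenario(
      demes = data.frame(name = c("CI", "CII", "CIII", "GHOST", "ANC"),
                         size = c(par[["N_CI"]], par[["N_CII"]],
                                  par[["N_CIII"]], par[["N_GHOST"]],
                                  par[["N_ANC"]]),
                         growth = 0),
      events = data.frame(
        time = c(tt[1L], tt[2L], tt[2L], tt[2L]),
        type = "merge",
        from = c("CII", "CI", "CIII", "GHOST"),
        to = c("GHOST", "ANC", "ANC", "ANC"),
        value = NA_real_),
      samples = c(sample_sizes, GHOST = 0L, ANC = 0L),
      loci = mk_loci(par[["mu"]]), label = "model_14a")
  }
  b14b <- function(par) {
    tt <- sort(c(par[["t1"]], par[["tg"]], par[["t2"]]))
    demographic_scenario(
      demes = data.frame(name = c("CI", "CII", "CIII", "GHOST"),
                         size = c(par[["N_CI"]], par[["N_CII"]],
                                  par[["N_CIII"]], par[["N_GHOST"]]),
                         growth = 0),
      events = data.frame(
        time = c(tt[1L], tt[2L], tt[3L], tt[3L]),
        type = c("merge", "merge", "merge", "size"),
        from = c("CII", "GHOST", "CI", "CIII"),
        to = c("GHOST", "CIII", "CIII", NA),
        value = c(NA, NA, NA, par[["N_ANC"]])),
      samples = c(sample_sizes, GHOST = 0L),
      loci = mk_loci(par[["mu"]]), label = "model_14b")
  }
  b20 <- function(par) {
    demographic_scenario(
      demes = data.frame(name = c("CN", "NAm", "ANC"),
                         size = c(par[["N_CN"]], par[["N_NAm"]],
                                  par[["N_ANC"]]),
                         growth = 0),
      events = data.frame(time = rep(par[["t1"]], 2L), type = "merge",
                          from = c("CN", "NAm"), to = "ANC",
                          value = NA_real_),
      samples = c(subclade_sizes, ANC = 0L),
      loci = mk_loci(par[["mu"]]), label = "model_20")
  }

  list(
    model_09 = abc_model("model_09",
      prior_spec(default_prior_rows(c("t1", "t2"),
                                    c("N_CI", "N_CII", "N_CIII", "N_ANC"))),
      b09, clades3),
    model_10 = abc_model("model_10",
      prior_spec(default_prior_rows("t1",
                                    c("N_CI", "N_CII", "N_CIII", "N_ANC"))),
      b10, clades3),
    model_14a = abc_model("model_14a",
      prior_spec(default_prior_rows(c("t1", "t2"),
                                    c("N_CI", "N_CII", "N_CIII", "N_GHOST",
                                      "N_ANC"))),
      b14a, clades3),
    model_14b = abc_model("model_14b",
      prior_spec(default_prior_rows(c("t1", "tg", "t2"),
                                    c("N_CI", "N_CII", "N_CIII", "N_GHOST",
                                      "N_ANC"))),
      b14b, clades3),
    model_20 = abc_model("model_20",
      prior_spec(default_prior_rows("t1", c("N_CN", "N_NAm", "N_ANC"))),
      b20, c("CN", "NAm")))
}
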