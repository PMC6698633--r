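# Study-like synthetic data: a three-clade, eleven-locus MLST dataset
# emulating 286 haploid strains (227 Chinese, 48 German, 11 North American)
# with clades of 82/97/87 strains plus 20 admixed strains, simultaneous
# clade divergence, and a 100-fold expansion in Clade II.

#' Configuration for the study emulator
#'
#' Defaults encode the emulated study design: clade sample sizes 82/97/87
#' (plus 20 extra strains labelled `admixed`), five symbiotic loci and six
#' housekeeping loci at their printed lengths, a simultaneous three-clade
#' divergence at 204,300 generations, a 100-fold demographic expansion in
#' Clade II at 3,690 generations, and a per-site mutation rate of 1e-8 per
#' generation with a 10x multiplier for housekeeping loci. Present-day deme
#' sizes are arbitrary defaults chosen to land within an order of magnitude
#' of the observed per-site diversities.
#'
#' @param clade_sizes named sizes of the three clades.
#' @param n_admixed extra strains (split across demes, labelled `admixed`).
#' @param divergence_time generations before present.
#' @param expansion_time Clade II expansion time (must precede divergence).
#' @param expansion_fold fold change of the Clade II size at the expansion.
#' @param mu symbiotic per-site mutation rate per generation.
#' @param housekeeping_multiplier mutation-rate multiplier for housekeeping
#'   loci (reproduces their higher diversity; recombination not modelled).
#' @param sizes present-day deme sizes (gene copies) for CI, CII, CIII; the
#'   ancestral deme uses the CIII size.
#' @return an object of class `study_config`.
#' @export
study_config <- function(clade_sizes = c(CI = 82L, CII = 97L, CIII = 87L),
                         n_admixed = 20L,
                         divergence_time = 204300,
                         expansion_time = 3690,
                         expansion_fold = 100,
                         mu = 1e-8,
                         housekeeping_multiplier = 10,
                         sizes = c(CI = 5e4, CII = 1.5e5, CIII = 1.6e5)) {
  if (any(clade_sizes <= 0) || any(sizes <= 0)) stop("sizes must be > 0")
  if (expansion_time >= divergence_time)
    stop("expansion must postdate the divergence (expansion_time < divergence_time)")
  if (expansion_fold <= 1) stop("expansion_fold must be > 1")
  structure(list(clade_sizes = clade_sizes, n_admixed = n_admixed,
                 divergence_time = divergence_time,
                 expansion_time = expansion_time,
                 expansion_fold = expansion_fold, mu = mu,
                 housekeeping_multiplier = housekeeping_multiplier,
                 sizes = sizes),
            class = "study_config")
}

# scenario behind the emulator: trifurcation + Clade II expansion
study_scenario <- function(cfg, samples, loci) {
  demographic_scenario(
    demes = data.frame(name = c("CI", "CII", "CIII", "ANC"),
                       size = c(cfg$sizes[["CI"]], cfg$sizes[["CII"]],
                                cfg$sizes[["CIII"]], cfg$sizes[["CIII"]]),
                       growth = 0),
    events = data.frame(
      time = c(cfg$expansion_time, rep(cfg$divergence_time, 3L)),
      type = c("size", "merge", "merge", "merge"),
      from = c("CII", "CI", "CII", "CIII"),
      to = c(NA, "ANC", "ANC", "ANC"),
      value = c(cfg$sizes[["CII"]] / cfg$expansion_fold, NA, NA, NA)),
    samples = c(samples, ANC = 0L),
    loci = loci, label = "study_emulation")
}

SPECIES_LABELS <- c("MA", "MH", "ML", "MM", "MR", "MQ", "MS", "MC")

#' Generate a study-like MLST dataset
#'
#' Simulates the trifurcation scenario with the Clade II expansion, renders
#' all eleven loci (five symbiotic, six housekeeping), and assembles strain
#' metadata with country compositions mimicking the study: Clade I mostly
#' Chinese with 2 North American strains, Clade II entirely Chinese, Clade
#' III mixed German / North American / Chinese, admixed strains Chinese.
#' Totals: 227 Chinese, 48 German, 11 North American strains under the
#' default configuration.
#'
#' @param cfg a [study_config()].
#' @param seed RNG seed (identical seeds give identical datasets).
#' @return list with `dataset` (an [mlst_dataset]) and `truth` (the
#'   generating parameter record, sufficient to score recovery).
#' @export
generate_study_like_dataset <- function(cfg = study_config(), seed = NULL) {
  stopifnot(inherits(cfg, "study_config"))
  if (!is.null(seed)) set.seed(seed)
  extra <- c(7L, 7L, 6L)
  if (cfg$n_admixed != 20L) {
    base <- cfg$n_admixed %/% 3L
    extra <- c(base + (cfg$n_admixed %% 3L > 0L),
               base + (cfg$n_admixed %% 3L > 1L), base)
  }
  samples <- cfg$clade_sizes + extra
  loci <- rbind(symbiotic_loci(mu = cfg$mu),
                housekeeping_loci(mu = cfg$mu * cfg$housekeeping_multiplier))
  sc <- study_scenario(cfg, samples, loci)
  sim <- simulate_dataset(sc, render = TRUE)
  n <- length(sim$deme)
  ids <- sprintf("RP%03d", seq_len(n))
  # clade labels: first clade_sizes[k] samples of each deme keep the clade
  # label, the remainder are 'admixed'
  clade <- character(n)
  country <- character(n)
  offset <- 0L
  comp_CIII <- function(k) {          # 48 DE, 9 NAm, rest CN
    c(rep("Germany", min(48L, k)),
      rep("NorthAmerica", min(9L, max(0L, k - 48L))),
      rep("China", max(0L, k - 57L)))
  }
  for (i in seq_along(samples)) {
    k_cl <- cfg$clade_sizes[i]
    k_tot <- samples[i]
    idx <- offset + seq_len(k_tot)
    clade[idx] <- c(rep(names(samples)[i], k_cl),
                    rep("admixed", k_tot - k_cl))
    country[idx] <- switch(names(samples)[i],
      CI = c(rep("NorthAmerica", 2L), rep("China", k_tot - 2L)),
      CII = rep("China", k_tot),
      CIII = c(comp_CIII(k_cl), rep("China", k_tot - k_cl)))
    offset <- offset + k_tot
  }
  site <- ifelse(country == "China",
                 paste0("CN", sprintf("%02d", 1L + (seq_len(n) %% 12L))),
                 ifelse(country == "Germany", "Freiburg", "Berkeley"))
  species <- sample(SPECIES_LABELS, n, replace = TRUE)
  meta <- data.frame(strain = ids, site = site, country = country,
                     species = species, clade = clade,
                     stringsAsFactors = FALSE)
  loci_aln <- lapply(seq_along(sim$sequences), function(i)
    locus_alignment(setNames(sim$sequences[[i]], ids),
                    name = names(sim$sequences)[i]))
  names(loci_aln) <- names(sim$sequences)
  ds <- mlst_dataset(loci_aln, metadata = meta)
  truth <- list(divergence_time = cfg$divergence_time,
                expansion_time = cfg$expansion_time,
                expansion_fold = cfg$expansion_fold,
                mu = cfg$mu,
                housekeeping_multiplier = cfg$housekeeping_multiplier,
                sizes = as.list(cfg$sizes),
                clade_sizes = as.list(cfg$clade_sizes),
                n_admixed = cfg$n_admixed,
                seed = seed)
  list(dataset = ds, truth = truth)
}

#' Write a study-like dataset to disk
#'
#' Emits one FASTA per locus, the metadata TSV, and the ground-truth record
#' as JSON.
#'
#' @param out a [generate_study_like_dataset()] result.
#' @param dir output directory.
#' @return invisibly, the written paths.
#' @export
write_study_dataset <- function(out, dir) {
  paths <- write_mlst(out$dataset, dir)
  tp <- file.path(dir, "truth.json")
  jsonlite::write_json(out$truth, tp, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, tp))
}
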