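# Tabular reports: per-locus diversity/neutrality summary and per-group
# mismatch-distribution summaries, with TSV writers.

#' Per-locus diversity and neutrality summary
#'
#' One row per locus: sample size, allele (haplotype) count, segregating
#' sites, haplotype diversity, nucleotide diversity and Watterson's theta
#' (per site), Tajima's D and Fu's Fs with optional simulated p-values, and
#' pN/pS plus dN/dS for coding loci.
#'
#' @param ds an [mlst_dataset].
#' @param loci locus labels; default all.
#' @param n_reps neutral replicates for the D and Fs p-values (0 = skip).
#' @return data frame, one row per locus.
#' @export
diversity_summary <- function(ds, loci = NULL, n_reps = 0L) {
  stopifnot(inherits(ds, "mlst_dataset"))
  if (is.null(loci)) loci <- names(ds$loci)
  rows <- lapply(loci, function(nm) {
    l <- ds$loci[[nm]]
    hap <- collapse_haplotypes(l)
    pi <- nucleotide_diversity(l)
    th <- watterson_theta(l)
    sel <- if (l$coding) tryCatch(pn_ps_dn_ds(l), error = function(e) NULL)
           else NULL
    nt <- if (n_reps > 0L) neutrality_test(l, n_reps = n_reps) else
      list(D = tajimas_d(l), p_D = NA_real_, Fs = fus_fs(l),
           p_Fs = NA_real_)
    data.frame(locus = nm, n = length(l$seq),
               alleles = length(hap$seq),
               S = segregating_sites(l),
               Hd = haplotype_diversity(hap),
               pi_per_site = pi$per_site,
               theta_w_per_site = th$per_site,
               tajima_d = nt$D, p_tajima_d = nt$p_D,
               fu_fs = nt$Fs, p_fu_fs = nt$p_Fs,
               pn_ps = if (is.null(sel)) NA_real_ else sel$pn_ps,
               dn_ds = if (is.null(sel)) NA_real_ else sel$dn_ds)
  })
  do.call(rbind, rows)
}

#' Per-group mismatch-distribution report
#'
#' Fits the demographic- and spatial-expansion models to each group's
#' mismatch spectrum and reports tau with bootstrap confidence intervals,
#' SSD and raggedness with bootstrap p-values, plus Tajima's D and Fu's Fs.
#'
#' @param ds an [mlst_dataset].
#' @param loci locus labels; default all.
#' @param group_col metadata column defining groups (default `"clade"`), or
#'   `NULL` for a single all-strains group.
#' @param groups group labels to include (default: all observed).
#' @param B bootstrap replicates (0 = skip bootstrap).
#' @param seed optional RNG seed.
#' @return data frame, one row per group and expansion model.
#' @export
mismatch_report <- function(ds, loci = NULL, group_col = "clade",
                            groups = NULL, B = 200L, seed = NULL) {
  stopifnot(inherits(ds, "mlst_dataset"))
  if (!is.null(seed)) set.seed(seed)
  conc <- suppressMessages(concatenate(ds, loci))
  grp <- if (is.null(group_col)) rep("All", length(conc$seq)) else
    ds$meta[[group_col]][match(names(conc$seq), ds$meta$strain)]
  if (is.null(groups)) groups <- unique(grp)
  rows <- list()
  for (g in groups) {
    sub <- conc
    sub$seq <- conc$seq[grp == g]
    if (length(sub$seq) < 3L) next
    spec <- observed_mismatch(sub)
    nt <- list(D = tajimas_d(sub), Fs = fus_fs(sub))
    for (model in c("demographic_expansion", "spatial_expansion")) {
      fit <- fit_mismatch(spec, model)
      if (B > 0L) fit <- bootstrap_gof(sub, fit, B = B)
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, n = length(sub$seq), model = model,
        mean_differences = spec$mean,
        tau = unname(fit$params[["tau"]]),
        tau_lo = if (B > 0L) fit$tau_ci[1L] else NA_real_,
        tau_hi = if (B > 0L) fit$tau_ci[2L] else NA_real_,
        ssd = fit$ssd,
        p_ssd = if (B > 0L) fit$p_ssd else NA_real_,
        raggedness = fit$raggedness,
        p_rag = if (B > 0L) fit$p_rag else NA_real_,
        tajima_d = nt$D, fu_fs = nt$Fs)
    }
  }
  do.call(rbind, rows)
}

#' Write a report data frame as TSV
#'
#' @param df a data frame.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_report_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
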