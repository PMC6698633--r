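# Nei-Gojobori (1986) counting of synonymous and nonsynonymous polymorphism
# and diversity in coding alignments. Codon iteration starts at the reading
# frame offset and stops at the last complete codon; codons containing masked
# characters (N or -) in any sequence are excluded whole, so the frame is
# preserved (the column-wise complete-deletion policy would shift it).

.codon_env <- new.env(parent = emptyenv())

# codon -> amino acid (standard code), built once via ape's translator
codon_aa <- function() {
  if (!is.null(.codon_env$aa)) return(.codon_env$aa)
  b <- c("A", "C", "G", "T")
  codons <- as.vector(outer(outer(b, b, paste0), b, paste0))
  m <- matrix(unlist(strsplit(codons, "")), ncol = 3L, byrow = TRUE)
  aa <- as.character(ape::trans(ape::as.DNAbin(m)))
  aa <- apply(aa, 1L, paste0, collapse = "")
  .codon_env$aa <- setNames(aa, codons)
  .codon_env$aa
}

# fraction of the 9 one-step changes of a codon that are synonymous
syn_fraction <- function(codon) {
  aa <- codon_aa()
  ref <- aa[[codon]]
  s <- 0
  for (p in 1:3) for (alt in setdiff(c("A", "C", "G", "T"),
                                     substr(codon, p, p))) {
    mut <- codon
    substr(mut, p, p) <- alt
    if (aa[[mut]] == ref) s <- s + 1 / 3
  }
  s
}

# pathway-averaged synonymous/nonsynonymous difference counts for a codon pair
ng_pair_counts <- function(c1, c2) {
  if (c1 == c2) return(c(0, 0))
  key <- paste(sort(c(c1, c2)), collapse = "|")
  hit <- .codon_env$pairs[[key]]
  if (!is.null(hit)) return(hit)
  aa <- codon_aa()
  diffpos <- which(strsplit(c1, "")[[1L]] != strsplit(c2, "")[[1L]])
  paths <- if (length(diffpos) == 1L) list(diffpos) else
    asplit(perms(diffpos), 1L)
  count_path <- function(ord) {
    cur <- c1
    sd <- nd <- 0
    ok <- TRUE
    for (p in ord) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (aa[[nxt]] == "*" || aa[[cur]] == "*") ok <- FALSE
      if (aa[[nxt]] == aa[[cur]]) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    c(sd, nd, ok)
  }
  res <- vapply(paths, count_path, numeric(3L))
  keep <- res[3L, ] > 0
  if (!any(keep)) keep <- rep(TRUE, ncol(res))  # all pathways hit a stop
  out <- rowMeans(res[1:2, keep, drop = FALSE])
  .codon_env$pairs[[key]] <- out
  out
}

perms <- function(v) {
  if (length(v) == 1L) return(matrix(v, 1L))
  out <- NULL
  for (i in seq_along(v))
    out <- rbind(out, cbind(v[i], perms(v[-i])))
  out
}

#' Synonymous/nonsynonymous polymorphism and diversity (Nei-Gojobori)
#'
#' Computes per-site potential synonymous and nonsynonymous site totals
#' (fractional, averaged over sequences), classifies each polymorphic site as
#' synonymous or nonsynonymous against the consensus codon, and computes
#' pairwise Nei-Gojobori proportions with pathway averaging for codons
#' differing at several positions. No multiple-hit correction is applied
#' (within-population divergence is assumed small); polymorphism counts can
#' be reported raw instead of per potential site via `normalize = FALSE`.
#'
#' @param aln a coding [locus_alignment] (`coding = TRUE` with a frame).
#' @param normalize divide polymorphism counts by potential-site totals
#'   (default) rather than reporting raw counts.
#' @return list with `p_n`, `p_s`, `pn_ps`, `d_n`, `d_s`, `dn_ds`,
#'   `syn_sites`, `nonsyn_sites`, `n_codons`; ratios are `NA` when their
#'   denominator is zero.
#' @export
pn_ps_dn_ds <- function(aln, normalize = TRUE) {
  stopifnot(inherits(aln, "locus_alignment"))
  if (!aln$coding) stop("locus is not flagged as coding")
  if (length(aln$seq) < 2L) stop("need at least 2 sequences")
  if (is.null(.codon_env$pairs)) .codon_env$pairs <- new.env(parent = emptyenv())
  aa <- codon_aa()
  m <- seq_matrix(aln)
  ncod <- (aln$length - aln$frame) %/% 3L
  if (ncod < 1L) stop("no complete codon in frame")
  cmat <- vapply(seq_len(ncod), function(j) {
    cols <- aln$frame + (3L * (j - 1L) + 1L):(3L * j)
    paste0(m[, cols[1L]], m[, cols[2L]], m[, cols[3L]])
  }, character(nrow(m)))
  if (nrow(m) == 1L) cmat <- matrix(cmat, nrow = 1L)
  valid <- grepl("^[ACGT]{3}$", cmat)
  is_stop <- matrix(FALSE, nrow(cmat), ncol(cmat))
  is_stop[valid] <- aa[cmat[valid]] == "*"
  if (any(is_stop))
    warning("premature stop codon(s) observed; affected codon column(s) excluded")
  keep_cod <- colSums(!valid | is_stop) == 0L
  cmat <- cmat[, keep_cod, drop = FALSE]
  if (ncol(cmat) == 0L) stop("no usable codons after exclusions")
  # potential sites, averaged over sequences
  uniq <- unique(as.vector(cmat))
  sfrac <- vapply(uniq, syn_fraction, numeric(1L))
  syn_sites <- mean(rowSums(matrix(sfrac[match(cmat, uniq)], nrow(cmat))))
  nonsyn_sites <- 3 * ncol(cmat) - syn_sites
  # polymorphic-site classification against the consensus codon
  ps <- pn <- 0L
  for (j in seq_len(ncol(cmat))) {
    col <- cmat[, j]
    tab <- sort(table(col), decreasing = TRUE)
    cons <- names(tab)[order(-tab, names(tab))][1L]
    for (p in 1:3) {
      bases <- unique(substr(col, p, p))
      ref <- substr(cons, p, p)
      alts <- setdiff(bases, ref)
      if (!length(alts)) next
      syn_all <- all(vapply(alts, function(a) {
        mut <- cons
        substr(mut, p, p) <- a
        aa[[mut]] == aa[[cons]]
      }, logical(1L)))
      if (syn_all) ps <- ps + 1L else pn <- pn + 1L
    }
  }
  # pairwise proportions over distinct codon-haplotypes, weighted by counts
  hap_key <- apply(cmat, 1L, paste0, collapse = "")
  tabh <- table(hap_key)
  haps <- names(tabh)
  wts <- as.numeric(tabh)
  sd_tot <- nd_tot <- w_tot <- 0
  if (length(haps) > 1L) {
    hm <- do.call(rbind, lapply(haps, function(h) {
      i <- match(h, hap_key)
      cmat[i, ]
    }))
    for (a in seq_along(haps)) for (b in seq_along(haps)) if (a < b) {
      w <- wts[a] * wts[b]
      dif <- which(hm[a, ] != hm[b, ])
      sd <- nd <- 0
      for (j in dif) {
        cc <- ng_pair_counts(hm[a, j], hm[b, j])
        sd <- sd + cc[1L]; nd <- nd + cc[2L]
      }
      sd_tot <- sd_tot + w * sd
      nd_tot <- nd_tot + w * nd
      w_tot <- w_tot + w
    }
  }
  n <- nrow(cmat)
  n_pairs <- choose(n, 2L)
  mean_sd <- sd_tot / n_pairs
  mean_nd <- nd_tot / n_pairs
  p_s <- if (normalize) ps / syn_sites else as.numeric(ps)
  p_n <- if (normalize) pn / nonsyn_sites else as.numeric(pn)
  d_s <- mean_sd / syn_sites
  d_n <- mean_nd / nonsyn_sites
  list(p_n = p_n, p_s = p_s,
       pn_ps = if (p_s > 0) p_n / p_s else NA_real_,
       d_n = d_n, d_s = d_s,
       dn_ds = if (d_s > 0) d_n / d_s else NA_real_,
       syn_sites = syn_sites, nonsyn_sites = nonsyn_sites,
       n_codons = ncol(cmat))
}
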