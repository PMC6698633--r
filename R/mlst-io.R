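# Data model and I/O for multilocus aligned sequence datasets.
#
# A locus_alignment stores one aligned locus as a named character vector of
# uppercase sequences over {A,C,G,T,N,-}; an mlst_dataset bundles several loci
# sharing one strain-id universe with per-strain metadata. Coordinates are
# 0-based half-open internally; user-facing reports are 1-based inclusive.

VALID_CHARS <- c("A", "C", "G", "T", "N", "-")

#' Construct a locus alignment
#'
#' @param seqs named character vector of aligned sequences (equal length,
#'   characters in `A,C,G,T,N,-`, case-insensitive; stored uppercase).
#' @param name locus label.
#' @param coding logical; is this a protein-coding locus?
#' @param frame reading-frame offset (0, 1 or 2) of the first complete codon,
#'   used only when `coding = TRUE`.
#' @return an object of class `locus_alignment`.
#' @export
locus_alignment <- function(seqs, name = "locus", coding = FALSE, frame = 0L) {
  if (length(seqs) == 0L) stop("empty alignment")
  if (is.null(names(seqs)) || anyNA(names(seqs)) || any(names(seqs) == ""))
    stop("all sequences must be named by strain id")
  if (anyDuplicated(names(seqs)))
    stop("duplicate strain id within locus '", name, "': ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  seqs <- toupper(seqs)
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L)
    stop("alignment error in locus '", name, "': sequences of unequal length (",
         paste(unique(lens), collapse = ", "), ")")
  bad <- grepl(paste0("[^", paste(VALID_CHARS, collapse = ""), "]"), seqs)
  if (any(bad))
    stop("invalid characters in locus '", name, "' for strain(s): ",
         paste(head(names(seqs)[bad], 5L), collapse = ", "))
  if (!frame %in% 0:2) stop("frame must be 0, 1 or 2")
  structure(list(name = name, length = unname(lens[1L]), seq = seqs,
                 coding = isTRUE(coding), frame = as.integer(frame)),
            class = "locus_alignment")
}

#' @export
print.locus_alignment <- function(x, ...) {
  cat(sprintf("<locus_alignment> %s: %d sequences x %d bp%s\n", x$name,
              length(x$seq), x$length,
              if (x$coding) sprintf(" (coding, frame %d)", x$frame) else ""))
  invisible(x)
}

#' Columns retained under the missing-data policy
#'
#' Complete deletion: any alignment column containing `N` or `-` in any
#' sequence is excluded before statistics and haplotype collapsing.
#'
#' @param aln a [locus_alignment].
#' @return logical vector over alignment columns; `TRUE` = retained.
#' @export
retained_columns <- function(aln) {
  m <- seq_matrix(aln)
  keep <- colSums(m == "N" | m == "-") == 0L
  keep
}

# alignment as n x L character matrix
seq_matrix <- function(aln) {
  m <- matrix(unlist(strsplit(aln$seq, "", fixed = TRUE), use.names = FALSE),
              nrow = length(aln$seq), ncol = aln$length, byrow = TRUE)
  rownames(m) <- names(aln$seq)
  m
}

# sequences restricted to retained columns, as strings (names kept)
clean_seqs <- function(aln) {
  keep <- retained_columns(aln)
  if (all(keep)) return(aln$seq)
  m <- seq_matrix(aln)[, keep, drop = FALSE]
  setNames(apply(m, 1L, paste0, collapse = ""), names(aln$seq))
}

#' Read one FASTA file per locus into an MLST dataset
#'
#' Strain ids are the first whitespace-delimited token of each FASTA header.
#' Records within a file must be equal length (pre-aligned input).
#'
#' @param paths character vector of FASTA file paths, one per locus.
#' @param locus_names labels, defaulting to file base names.
#' @param coding logical vector (recycled) marking coding loci.
#' @param frame integer vector (recycled) of reading-frame offsets.
#' @return an object of class `mlst_dataset`.
#' @export
read_loci_fasta <- function(paths, locus_names = NULL, coding = FALSE,
                            frame = 0L) {
  if (length(paths) == 0L) stop("no input files")
  if (is.null(locus_names))
    locus_names <- sub("\\.(fa|fasta|fna)$", "", basename(paths))
  coding <- rep_len(coding, length(paths))
  frame <- rep_len(as.integer(frame), length(paths))
  loci <- vector("list", length(paths))
  for (i in seq_along(paths)) {
    dna <- ape::read.FASTA(paths[i])
    seqs <- vapply(as.character(dna), paste0, character(1L), collapse = "")
    names(seqs) <- sub("\\s.*$", "", names(dna))
    loci[[i]] <- locus_alignment(seqs, name = locus_names[i],
                                 coding = coding[i], frame = frame[i])
  }
  names(loci) <- locus_names
  mlst_dataset(loci)
}

#' Bundle locus alignments into an MLST dataset
#'
#' @param loci named list of [locus_alignment] objects.
#' @param metadata optional data frame with columns
#'   `strain, site, country, species` and optionally `clade`.
#' @return an object of class `mlst_dataset`.
#' @export
mlst_dataset <- function(loci, metadata = NULL) {
  if (length(loci) == 0L) stop("no loci")
  stopifnot(all(vapply(loci, inherits, logical(1L), "locus_alignment")))
  if (is.null(names(loci)))
    names(loci) <- vapply(loci, `[[`, character(1L), "name")
  strains <- sort(unique(unlist(lapply(loci, function(l) names(l$seq)))))
  ds <- structure(list(loci = loci, strains = strains, meta = NULL),
                  class = "mlst_dataset")
  if (!is.null(metadata)) ds <- attach_metadata(ds, metadata) else {
    ds$meta <- data.frame(strain = strains, site = NA_character_,
                          country = NA_character_, species = NA_character_,
                          clade = "unassigned", stringsAsFactors = FALSE)
  }
  ds
}

#' @export
print.mlst_dataset <- function(x, ...) {
  cat(sprintf("<mlst_dataset> %d strains, %d loci (%s)\n", length(x$strains),
              length(x$loci), paste(names(x$loci), collapse = ", ")))
  if (!all(x$meta$clade == "unassigned"))
    cat("  clades:", paste(sprintf("%s=%d", names(table(x$meta$clade)),
                                   table(x$meta$clade)), collapse = " "), "\n")
  invisible(x)
}

#' Attach strain metadata from a TSV table
#'
#' @param ds an [mlst_dataset].
#' @param table path to a tab-separated file with header
#'   `strain<TAB>site<TAB>country<TAB>species[<TAB>clade]`, or an equivalent
#'   data frame. Strains absent from the table are flagged `"unassigned"`;
#'   rows for unknown strains are ignored with a warning.
#' @return the dataset with metadata joined by strain id.
#' @export
attach_metadata <- function(ds, table) {
  stopifnot(inherits(ds, "mlst_dataset"))
  tab <- if (is.character(table)) {
    read.delim(table, sep = "\t", stringsAsFactors = FALSE,
               colClasses = "character")
  } else as.data.frame(table, stringsAsFactors = FALSE)
  req <- c("strain", "site", "country", "species")
  if (!all(req %in% names(tab)))
    stop("metadata must have columns strain, site, country, species[, clade]")
  if (!"clade" %in% names(tab)) tab$clade <- "unassigned"
  unknown <- setdiff(tab$strain, ds$strains)
  if (length(unknown))
    warning("ignoring metadata rows for unknown strain(s): ",
            paste(head(unknown, 5L), collapse = ", "))
  tab <- tab[tab$strain %in% ds$strains, , drop = FALSE]
  meta <- data.frame(strain = ds$strains, stringsAsFactors = FALSE)
  idx <- match(meta$strain, tab$strain)
  for (col in c("site", "country", "species", "clade"))
    meta[[col]] <- tab[[col]][idx]
  meta$clade[is.na(meta$clade)] <- "unassigned"
  ds$meta <- meta
  ds
}

#' Concatenate loci into a single alignment
#'
#' Strains missing from any selected locus are excluded (logged via message).
#' Locus boundaries within the concatenation are recorded in the
#' `boundaries` attribute (1-based inclusive start/end per locus).
#'
#' @param ds an [mlst_dataset].
#' @param locus_subset locus labels; default all loci.
#' @return a [locus_alignment] of the concatenated sequences.
#' @export
concatenate <- function(ds, locus_subset = NULL) {
  stopifnot(inherits(ds, "mlst_dataset"))
  if (is.null(locus_subset)) locus_subset <- names(ds$loci)
  if (length(locus_subset) == 0L) stop("empty locus subset")
  missing_loci <- setdiff(locus_subset, names(ds$loci))
  if (length(missing_loci)) stop("unknown loci: ",
                                 paste(missing_loci, collapse = ", "))
  sel <- ds$loci[locus_subset]
  common <- Reduce(intersect, lapply(sel, function(l) names(l$seq)))
  dropped <- setdiff(ds$strains, common)
  if (length(dropped))
    message(length(dropped),
            " strain(s) missing at least one selected locus; excluded")
  if (length(common) == 0L) stop("no strain present in every selected locus")
  common <- sort(common)
  pieces <- lapply(sel, function(l) l$seq[common])
  cat_seq <- do.call(paste0, pieces)
  names(cat_seq) <- common
  lens <- vapply(sel, `[[`, numeric(1L), "length")
  ends <- cumsum(lens)
  out <- locus_alignment(cat_seq, name = paste(locus_subset, collapse = "+"))
  attr(out, "boundaries") <- data.frame(locus = locus_subset,
                                        start = c(1L, head(ends, -1L) + 1L),
                                        end = ends, row.names = NULL)
  out
}

#' Collapse an alignment into distinct haplotypes
#'
#' Distinctness is exact string equality after the missing-data policy
#' (complete deletion of columns containing `N` or `-`). Haplotypes are
#' ordered by decreasing count, ties broken by lexicographic sequence.
#'
#' @param aln a [locus_alignment].
#' @return an object of class `haplotype_table` with fields `seq` (haplotype
#'   strings over retained columns), `count`, `members` (strain id lists),
#'   `n` (total strains) and `retained` (logical column mask).
#' @export
collapse_haplotypes <- function(aln) {
  stopifnot(inherits(aln, "locus_alignment"))
  keep <- retained_columns(aln)
  cl <- clean_seqs(aln)
  groups <- split(names(cl), factor(cl, levels = unique(cl)))
  seqs <- names(groups)
  counts <- lengths(groups)
  ord <- order(-counts, seqs)
  structure(list(seq = seqs[ord], count = unname(counts[ord]),
                 members = unname(groups[ord]), n = length(cl),
                 retained = keep,
                 boundaries = attr(aln, "boundaries")),
            class = "haplotype_table")
}

#' @export
print.haplotype_table <- function(x, ...) {
  cat(sprintf("<haplotype_table> %d haplotypes from %d strains (%d retained sites)\n",
              length(x$seq), x$n, sum(nchar(x$seq[1L]))))
  invisible(x)
}

#' Clone-correct a dataset
#'
#' Retains exactly one representative (the lowest strain id) of each
#' multilocus haplotype within each group defined by `by`.
#'
#' @param ds an [mlst_dataset].
#' @param by grouping key: `"global"`, `"site"`, `"country"` or `"clade"`.
#' @return the clone-corrected [mlst_dataset]; the `clone_corrected`
#'   attribute is set to `TRUE`.
#' @export
clone_correct <- function(ds, by = "global") {
  stopifnot(inherits(ds, "mlst_dataset"))
  by <- match.arg(by, c("global", "site", "country", "clade"))
  grp <- if (by == "global") rep("all", length(ds$strains)) else {
    v <- ds$meta[[by]][match(ds$strains, ds$meta$strain)]
    if (all(is.na(v))) stop("grouping key '", by, "' absent from metadata")
    ifelse(is.na(v), "<NA>", v)
  }
  conc <- suppressMessages(concatenate(ds))
  cl <- clean_seqs(conc)
  grp <- grp[match(names(cl), ds$strains)]
  keycols <- paste(grp, cl, sep = "\r")
  keep_ids <- vapply(split(names(cl), keycols),
                     function(ids) sort(ids)[1L], character(1L))
  keep_ids <- sort(unname(keep_ids))
  out <- ds
  out$loci <- lapply(ds$loci, function(l) {
    l$seq <- l$seq[names(l$seq) %in% keep_ids]
    l
  })
  out$strains <- keep_ids
  out$meta <- ds$meta[ds$meta$strain %in% keep_ids, , drop = FALSE]
  rownames(out$meta) <- NULL
  attr(out, "clone_corrected") <- TRUE
  out
}

#' Write an MLST dataset as one FASTA per locus plus a metadata TSV
#'
#' @param ds an [mlst_dataset].
#' @param dir output directory (created if needed).
#' @return invisibly, the written file paths.
#' @export
write_mlst <- function(ds, dir) {
  stopifnot(inherits(ds, "mlst_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0L)
  for (nm in names(ds$loci)) {
    p <- file.path(dir, paste0(nm, ".fasta"))
    l <- ds$loci[[nm]]
    writeLines(paste0(">", names(l$seq), "\n", l$seq), p)
    paths <- c(paths, p)
  }
  mp <- file.path(dir, "metadata.tsv")
  write.table(ds$meta, mp, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(paths, mp))
}
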