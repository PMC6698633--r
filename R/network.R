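# Minimum spanning network over multilocus haplotypes: Kruskal construction
# with tie retention, so all edges that join previously unconnected
# components at the current minimal weight are kept, yielding a network
# rather than a tree.

#' Build a minimum spanning network
#'
#' Distances are nucleotide mismatches between haplotype sequences (computed
#' on the retained columns). At each weight threshold, every edge joining
#' components that were disconnected at the start of that threshold is
#' retained; edges beyond a strict minimum spanning tree are flagged
#' `co_minimal`. Edge ordering is deterministic (weight, then lexicographic
#' endpoints).
#'
#' @param table a [collapse_haplotypes()] result with >= 2 haplotypes.
#' @param meta optional metadata data frame (columns `strain` plus any of
#'   `country`, `clade`, `species`) used to annotate nodes with composition
#'   strings.
#' @return an object of class `haplotype_network` with `nodes` (id, count,
#'   compositions), `edges` (from, to, weight, spanning, co_minimal) and
#'   `mst_weight` (total weight of a strict minimum spanning tree).
#' @export
build_msn <- function(table, meta = NULL) {
  stopifnot(inherits(table, "haplotype_table"))
  k <- length(table$seq)
  if (k < 2L) stop("need at least 2 haplotypes")
  ids <- sprintf("H%02d", seq_len(k))
  D <- hamming_strings_cpp(table$seq)
  pairs <- which(upper.tri(D), arr.ind = TRUE)
  ed <- data.frame(from = ids[pairs[, 1L]], to = ids[pairs[, 2L]],
                   weight = D[pairs], stringsAsFactors = FALSE)
  ed <- ed[order(ed$weight, ed$from, ed$to), , drop = FALSE]
  rownames(ed) <- NULL
  # union-find
  comp <- seq_len(k)
  find <- function(x) { while (comp[x] != x) { comp[x] <<- comp[comp[x]]; x <- comp[x] }; x }
  spanning <- logical(nrow(ed))
  co_minimal <- logical(nrow(ed))
  mst_weight <- 0
  idx_from <- match(ed$from, ids)
  idx_to <- match(ed$to, ids)
  for (w in sort(unique(ed$weight))) {
    at_w <- which(ed$weight == w)
    # membership frozen at the start of this weight class
    snapshot <- vapply(seq_len(k), find, integer(1L))
    joins <- at_w[snapshot[idx_from[at_w]] != snapshot[idx_to[at_w]]]
    first_tree <- logical(length(joins))
    for (j in seq_along(joins)) {
      e <- joins[j]
      ra <- find(idx_from[e]); rb <- find(idx_to[e])
      if (ra != rb) {           # strict MST edge (first-found)
        comp[ra] <- rb
        mst_weight <- mst_weight + w
        first_tree[j] <- TRUE
      }
    }
    spanning[joins] <- TRUE
    co_minimal[joins] <- !first_tree
  }
  ed$spanning <- spanning
  ed$co_minimal <- co_minimal
  nodes <- data.frame(id = ids, count = table$count, stringsAsFactors = FALSE)
  if (!is.null(meta)) {
    for (col in intersect(c("country", "clade", "species"), names(meta))) {
      nodes[[col]] <- vapply(table$members, function(mem) {
        v <- meta[[col]][match(mem, meta$strain)]
        tab <- sort(table(v), decreasing = TRUE)
        paste(sprintf("%s:%d", names(tab), tab), collapse = ",")
      }, character(1L))
    }
  }
  structure(list(nodes = nodes, edges = ed, mst_weight = mst_weight),
            class = "haplotype_network")
}

#' @export
print.haplotype_network <- function(x, ...) {
  cat(sprintf("<haplotype_network> %d nodes, %d spanning edges (%d co-minimal), MST weight %d\n",
              nrow(x$nodes), sum(x$edges$spanning), sum(x$edges$co_minimal),
              x$mst_weight))
  invisible(x)
}

#' Write a haplotype network as GraphML
#'
#' Only the spanning (network) edges are written; node attributes carry the
#' haplotype counts and any composition strings.
#'
#' @param net a [build_msn()] result.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_msn_graphml <- function(net, path) {
  ed <- net$edges[net$edges$spanning, , drop = FALSE]
  g <- igraph::graph_from_data_frame(ed[, c("from", "to")], directed = FALSE,
                                     vertices = net$nodes)
  igraph::E(g)$weight <- ed$weight
  igraph::E(g)$co_minimal <- as.integer(ed$co_minimal)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Write the network edge list as TSV
#'
#' @param net a [build_msn()] result.
#' @param path output file.
#' @param spanning_only keep only spanning edges (default `TRUE`).
#' @return invisibly, `path`.
#' @export
write_msn_edges <- function(net, path, spanning_only = TRUE) {
  ed <- if (spanning_only) net$edges[net$edges$spanning, , drop = FALSE] else
    net$edges
  write.table(ed, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
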