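# Declarative multi-deme coalescent scenarios.
#
# Time runs backward in generations before present. Sizes are numbers of gene
# copies on the haploid scale (a pair of lineages in a deme of size N
# coalesces at rate 1/N per generation, so theta per locus = 2*N*mu*L).

EVENT_TYPES <- c(merge = 0L, size = 1L, growth = 2L, migration = 3L)

#' Define a demographic scenario
#'
#' @param demes data frame with columns `name`, `size` (present-day gene
#'   copies) and optionally `growth` (forward-time exponential growth rate
#'   per generation; 0 = constant).
#' @param events data frame (possibly empty) with columns `time` (generations
#'   before present, > 0), `type` (`"merge"`, `"size"`, `"growth"`,
#'   `"migration"`), `from`, `to` (deme names; `to` is the ancestral deme for
#'   merges, the destination for migration changes, `NA` otherwise) and
#'   `value` (new size / growth rate / migration rate; `NA` for merges).
#' @param migration square matrix of per-lineage backward migration rates
#'   (row = source deme, per generation); default zero.
#' @param samples named integer vector of present-day sample counts per deme.
#' @param loci data frame with columns `name`, `length` (bp) and `mu`
#'   (per-site mutation rate per generation).
#' @param label model name.
#' @return an object of class `demographic_scenario`.
#' @export
demographic_scenario <- function(demes, events = NULL, migration = NULL,
                                 samples, loci, label = "scenario") {
  stopifnot(is.data.frame(demes), all(c("name", "size") %in% names(demes)))
  if (is.null(demes$growth)) demes$growth <- 0
  demes$name <- as.character(demes$name)
  if (anyDuplicated(demes$name)) stop("duplicate deme names")
  if (any(demes$size <= 0)) stop("deme sizes must be > 0")
  D <- nrow(demes)
  if (is.null(migration)) migration <- matrix(0, D, D)
  migration <- as.matrix(migration)
  if (!all(dim(migration) == D)) stop("migration matrix must be demes x demes")
  diag(migration) <- 0
  if (is.null(events))
    events <- data.frame(time = numeric(0L), type = character(0L),
                         from = character(0L), to = character(0L),
                         value = numeric(0L))
  events$type <- as.character(events$type)
  if (!all(events$type %in% names(EVENT_TYPES)))
    stop("unknown event type(s): ",
         paste(setdiff(events$type, names(EVENT_TYPES)), collapse = ", "))
  if (nrow(events) && any(events$time <= 0))
    stop("event times must be strictly positive")
  samples <- samples[match(demes$name, names(samples))]
  samples[is.na(samples)] <- 0L
  names(samples) <- demes$name
  if (sum(samples) < 2L) stop("total sample size must be >= 2")
  stopifnot(is.data.frame(loci),
            all(c("name", "length", "mu") %in% names(loci)))
  structure(list(demes = demes, events = events, migration = migration,
                 samples = samples, loci = loci, label = label),
            class = "demographic_scenario")
}

#' @export
print.demographic_scenario <- function(x, ...) {
  cat(sprintf("<demographic_scenario> '%s': %d deme(s), %d event(s), %d locus/loci, n = %d\n",
              x$label, nrow(x$demes), nrow(x$events), nrow(x$loci),
              sum(x$samples)))
  invisible(x)
}

#' Diagnose a scenario without simulating
#'
#' Checks invariants (sorted positive event times, coalescibility of all
#' sampled demes, orphan demes) and reports the merge structure.
#'
#' @param sc a [demographic_scenario].
#' @return character vector of diagnostics; empty when well-formed. The
#'   `merge_depth` attribute carries the time of the last merge.
#' @export
validate_scenario <- function(sc) {
  stopifnot(inherits(sc, "demographic_scenario"))
  diag_out <- character(0L)
  ev <- sc$events
  if (nrow(ev) && is.unsorted(ev$time))
    diag_out <- c(diag_out, "events are not sorted by time")
  if (nrow(ev) && any(ev$time <= 0))
    diag_out <- c(diag_out, "event times must be strictly positive")
  bad_demes <- setdiff(c(ev$from, ev$to[ev$type %in% c("merge", "migration")]),
                       c(sc$demes$name, NA))
  if (length(bad_demes))
    diag_out <- c(diag_out, paste0("events reference unknown deme(s): ",
                                   paste(bad_demes, collapse = ", ")))
  # connectivity: demes linked by merges or positive migration (initial or
  # via migration events) must place all sampled demes in one component
  D <- nrow(sc$demes)
  adj <- (sc$migration > 0)
  if (nrow(ev)) {
    for (i in seq_len(nrow(ev))) {
      if (ev$type[i] == "merge") {
        a <- match(ev$from[i], sc$demes$name)
        b <- match(ev$to[i], sc$demes$name)
        if (!is.na(a) && !is.na(b)) adj[a, b] <- adj[b, a] <- TRUE
      }
      if (ev$type[i] == "migration" && !is.na(ev$value[i]) && ev$value[i] > 0) {
        a <- match(ev$from[i], sc$demes$name)
        b <- match(ev$to[i], sc$demes$name)
        if (!is.na(a)) {
          if (is.na(b)) adj[a, ] <- TRUE else adj[a, b] <- adj[b, a] <- TRUE
        }
      }
    }
  }
  comp <- seq_len(D)
  repeat {
    changed <- FALSE
    for (a in seq_len(D)) for (b in seq_len(D)) if (adj[a, b]) {
      m <- min(comp[a], comp[b])
      if (comp[a] != m || comp[b] != m) { comp[a] <- comp[b] <- m; changed <- TRUE }
    }
    if (!changed) break
  }
  sampled <- which(sc$samples > 0)
  if (length(unique(comp[sampled])) > 1L)
    diag_out <- c(diag_out,
                  "sampled demes cannot coalesce: no merge or migration connects them")
  orphan <- which(sc$samples == 0 & rowSums(adj) == 0 & colSums(adj) == 0)
  if (length(orphan))
    diag_out <- c(diag_out, paste0("orphan deme(s) with no merge, migration or samples: ",
                                   paste(sc$demes$name[orphan], collapse = ", ")))
  merge_times <- ev$time[ev$type == "merge"]
  attr(diag_out, "merge_depth") <- if (length(merge_times)) max(merge_times) else 0
  diag_out
}

#' Read a scenario from a YAML file
#'
#' The YAML mirrors the [demographic_scenario()] arguments: `label`, `demes`
#' (list of `name/size/growth`), `events` (list of
#' `time/type/from/to/value`), `migration` (row-major list of rows,
#' optional), `samples` (name: count), `loci` (list of `name/length/mu`).
#'
#' @param path YAML file path.
#' @return a [demographic_scenario].
#' @export
read_scenario_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  demes <- do.call(rbind, lapply(y$demes, function(d)
    data.frame(name = d$name, size = d$size,
               growth = if (is.null(d$growth)) 0 else d$growth)))
  events <- if (length(y$events)) do.call(rbind, lapply(y$events, function(e)
    data.frame(time = e$time, type = e$type,
               from = if (is.null(e$from)) NA_character_ else e$from,
               to = if (is.null(e$to)) NA_character_ else e$to,
               value = if (is.null(e$value)) NA_real_ else e$value))) else NULL
  migration <- if (!is.null(y$migration))
    do.call(rbind, lapply(y$migration, unlist)) else NULL
  loci <- do.call(rbind, lapply(y$loci, function(l)
    data.frame(name = l$name, length = l$length, mu = l$mu)))
  demographic_scenario(demes = demes, events = events, migration = migration,
                       samples = unlist(y$samples), loci = loci,
                       label = if (is.null(y$label)) "scenario" else y$label)
}

#' Write a scenario to YAML
#'
#' @param sc a [demographic_scenario].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_scenario_yaml <- function(sc, path) {
  y <- list(label = sc$label,
            demes = lapply(seq_len(nrow(sc$demes)), function(i)
              as.list(sc$demes[i, ])),
            events = if (nrow(sc$events)) lapply(seq_len(nrow(sc$events)),
              function(i) as.list(sc$events[i, ])) else list(),
            migration = if (any(sc$migration > 0))
              lapply(seq_len(nrow(sc$migration)), function(i)
                as.numeric(sc$migration[i, ])) else NULL,
            samples = as.list(sc$samples),
            loci = lapply(seq_len(nrow(sc$loci)), function(i)
              as.list(sc$loci[i, ])))
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Simulate a dataset under a scenario
#'
#' Independent coalescent genealogies per locus under the structured
#' coalescent with the scenario's events, Poisson mutations at rate
#' `mu * length` per generation on branches, and infinite-sites placement.
#' Deterministic given `seed`.
#'
#' @param sc a [demographic_scenario].
#' @param seed optional RNG seed.
#' @param render also render nucleotide sequences (reference of `A`s, derived
#'   state drawn uniformly from the three alternatives). Statistics never
#'   depend on the rendering; disable for speed in large simulation studies.
#' @return an object of class `sim_dataset`: per-locus 0/1 derived-allele
#'   matrices with relative site positions, deme of origin per sample,
#'   scenario, and (optionally) rendered sequences.
#' @export
simulate_dataset <- function(sc, seed = NULL, render = TRUE) {
  stopifnot(inherits(sc, "demographic_scenario"))
  diagnostics <- validate_scenario(sc)
  fatal <- grepl("cannot coalesce|unknown deme|strictly positive",
                 diagnostics)
  if (any(fatal)) stop("invalid scenario: ",
                       paste(diagnostics[fatal], collapse = "; "))
  if (!is.null(seed)) set.seed(seed)
  ev <- sc$events
  ord <- if (nrow(ev)) order(ev$time) else integer(0L)
  evm <- if (nrow(ev)) {
    cbind(time = ev$time[ord],
          type = EVENT_TYPES[ev$type[ord]],
          a = match(ev$from[ord], sc$demes$name),
          b = ifelse(is.na(ev$to[ord]), 0L,
                     match(ev$to[ord], sc$demes$name)),
          value = ifelse(is.na(ev$value[ord]), 0, ev$value[ord]))
  } else matrix(numeric(0L), 0L, 5L)
  res <- coalsim_cpp(sc$demes$size, sc$demes$growth, sc$migration,
                     as.integer(sc$samples), evm,
                     sc$loci$mu * sc$loci$length)
  names(res) <- sc$loci$name
  deme_of <- rep(sc$demes$name, sc$samples)
  out <- structure(list(loci = res, deme = deme_of, scenario = sc,
                        seed = seed), class = "sim_dataset")
  if (render) out$sequences <- render_sequences(out)
  out
}

#' @export
print.sim_dataset <- function(x, ...) {
  S <- vapply(x$loci, function(l) ncol(l$G), integer(1L))
  cat(sprintf("<sim_dataset> '%s': n = %d, %d loci, S = %s\n",
              x$scenario$label, length(x$deme), length(x$loci),
              paste(S, collapse = "/")))
  invisible(x)
}

# render 0/1 matrices as nucleotide sequences over an all-'A' reference
render_sequences <- function(sim) {
  sc <- sim$scenario
  out <- vector("list", length(sim$loci))
  for (i in seq_along(sim$loci)) {
    G <- sim$loci[[i]]$G
    L <- sc$loci$length[i]
    S <- ncol(G)
    if (S > L) stop("more segregating sites than positions at locus ",
                    sc$loci$name[i])
    base <- matrix("A", nrow(G), L)
    if (S > 0L) {
      pos <- sort(sample.int(L, S))
      alt <- sample(c("C", "G", "T"), S, replace = TRUE)
      ordc <- order(sim$loci[[i]]$pos)
      for (s in seq_len(S)) {
        carriers <- G[, ordc[s]] == 1L
        base[carriers, pos[s]] <- alt[s]
      }
    }
    out[[i]] <- apply(base, 1L, paste0, collapse = "")
  }
  names(out) <- sc$loci$name
  out
}

#' Convert a simulated dataset to an MLST dataset
#'
#' Sample ids are generated as `s001, s002, ...`; the deme of origin becomes
#' the `clade` metadata column.
#'
#' @param sim a [simulate_dataset()] result with rendered sequences.
#' @param coding logical vector (recycled over loci).
#' @return an [mlst_dataset].
#' @export
as_mlst <- function(sim, coding = FALSE) {
  stopifnot(inherits(sim, "sim_dataset"))
  if (is.null(sim$sequences)) sim$sequences <- render_sequences(sim)
  n <- length(sim$deme)
  ids <- sprintf("s%03d", seq_len(n))
  coding <- rep_len(coding, length(sim$sequences))
  loci <- lapply(seq_along(sim$sequences), function(i)
    locus_alignment(setNames(sim$sequences[[i]], ids),
                    name = names(sim$sequences)[i], coding = coding[i]))
  names(loci) <- names(sim$sequences)
  meta <- data.frame(strain = ids, site = "sim", country = "sim",
                     species = "sim", clade = sim$deme,
                     stringsAsFactors = FALSE)
  mlst_dataset(loci, metadata = meta)
}
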