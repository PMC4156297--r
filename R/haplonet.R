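#' Collapse aligned sequences to haplotypes
#'
#' Haplotypes are equivalence classes of identical sequences (see
#' [merge_identical()] for the two identity policies); the class frequency
#' is the number of member sequences and the representative is the first
#' member in input order.
#'
#' @param aln a [dna_alignment()].
#' @param missing_policy `"exact"` or `"missing-compatible"`.
#' @param scope optional label subset (e.g. ingroup only).
#' @return a `haplotype_set`: list with `alignment` (one representative per
#'   haplotype) and `table` (data.frame `id`, `representative`, `frequency`,
#'   `members`, `taxa`).
#' @export
collapse_haplotypes <- function(aln, missing_policy = c("exact", "missing-compatible"),
                                scope = NULL) {
  missing_policy <- match.arg(missing_policy)
  if (!is.null(scope)) aln <- aln[match(scope, seq_labels(aln)), ]
  mg <- merge_identical(aln, missing_policy)
  reps <- seq_labels(mg$alignment)
  taxa <- if (!is.null(aln$taxon_map)) {
    vapply(mg$members[reps], function(mem) {
      paste(sort(unique(aln$taxon_map$taxon[aln$taxon_map$label %in% mem])),
            collapse = ",")
    }, character(1))
  } else rep(NA_character_, length(reps))
  tab <- data.frame(
    id = paste0("H", seq_along(reps)),
    representative = reps,
    frequency = lengths(mg$members[reps]),
    members = vapply(mg$members[reps], paste, character(1), collapse = ","),
    taxa = taxa,
    stringsAsFactors = FALSE, row.names = NULL)
  structure(list(alignment = mg$alignment, table = tab),
            class = "haplotype_set")
}

#' @export
print.haplotype_set <- function(x, ...) {
  cat("haplotype set:", nrow(x$table), "haplotypes from",
      sum(x$table$frequency), "sequences\n")
  invisible(x)
}

# integer mismatch counts between haplotype representatives
.haplo_dist <- function(aln, gap_policy = c("missing", "fifth-state")) {
  gap_policy <- match.arg(gap_policy)
  m <- iupac_mask(aln$seqs)
  if (gap_policy == "fifth-state") m[aln$seqs == "-"] <- 16L
  n <- nrow(m)
  d <- matrix(0L, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(max(n - 1L, 0L))) {
    for (j in (i + 1L):n) {
      comp <- m[i, ] > 0L & m[j, ] > 0L
      d[i, j] <- d[j, i] <- sum(bitwAnd(m[i, comp], m[j, comp]) == 0L)
    }
  }
  d
}

#' Build a statistical-parsimony (TCS-style) haplotype network
#'
#' Agglomerative construction under a fixed connection limit: at each step
#' length j = 1, 2, ..., `limit`, every pair of haplotypes lying in
#' different components whose mutational distance equals j is connected by
#' a path carrying j - 1 inferred (unsampled) intermediate nodes. All
#' alternative equal-length connections arising at the same j are retained,
#' which is what produces reticulations (loops). Components that cannot be
#' joined within the limit stay disconnected.
#'
#' @param haps a `haplotype_set` from [collapse_haplotypes()].
#' @param limit maximum number of mutational steps for a connection
#'   (classically 30 when fixed, rather than derived from the 95\%
#'   parsimony probability criterion).
#' @param gap_policy `"missing"` (gaps and `?` excluded from mismatch
#'   counts) or `"fifth-state"` (gap is a fifth character state).
#' @return a `haplotype_network`: list with `nodes` (data.frame `id`,
#'   `sampled`, `frequency`, `representative`, `members`, `taxa`), `edges`
#'   (data.frame `from`, `to`), `limit`, `distances` (sampled haplotype
#'   mismatch matrix), and `graph` (igraph object).
#' @export
build_parsimony_network <- function(haps, limit = 30L,
                                    gap_policy = c("missing", "fifth-state")) {
  gap_policy <- match.arg(gap_policy)
  tab <- haps$table
  H <- nrow(tab)
  D <- .haplo_dist(haps$alignment, gap_policy)
  nodes <- data.frame(id = tab$id, sampled = TRUE, frequency = tab$frequency,
                      representative = tab$representative, members = tab$members,
                      taxa = tab$taxa, stringsAsFactors = FALSE)
  edges <- data.frame(from = character(0), to = character(0),
                      stringsAsFactors = FALSE)
  comp <- seq_len(H)
  n_inferred <- 0L
  if (H > 1L) {
    for (j in seq_len(limit)) {
      new_pairs <- which(D == j & upper.tri(D), arr.ind = TRUE)
      if (nrow(new_pairs)) {
        cross <- comp[new_pairs[, 1]] != comp[new_pairs[, 2]]
        new_pairs <- new_pairs[cross, , drop = FALSE]
      }
      if (!nrow(new_pairs)) next
      for (r in seq_len(nrow(new_pairs))) {
        a <- tab$id[new_pairs[r, 1]]; b <- tab$id[new_pairs[r, 2]]
        if (j == 1L) {
          edges <- rbind(edges, data.frame(from = a, to = b))
        } else {
          mids <- paste0("m", n_inferred + seq_len(j - 1L))
          n_inferred <- n_inferred + j - 1L
          nodes <- rbind(nodes, data.frame(
            id = mids, sampled = FALSE, frequency = 0L,
            representative = NA_character_, members = NA_character_,
            taxa = NA_character_, stringsAsFactors = FALSE))
          path <- c(a, mids, b)
          edges <- rbind(edges, data.frame(from = path[-length(path)],
                                           to = path[-1]))
        }
      }
      # merge the components joined at this step length
      for (r in seq_len(nrow(new_pairs))) {
        ca <- comp[new_pairs[r, 1]]; cb <- comp[new_pairs[r, 2]]
        comp[comp == cb] <- ca
      }
    }
  }
  vattr <- nodes
  vattr$sampled <- as.integer(vattr$sampled)  # DOT export chokes on logicals
  g <- igraph::graph_from_data_frame(edges, directed = FALSE, vertices = vattr)
  structure(list(nodes = nodes, edges = edges, limit = as.integer(limit),
                 distances = D, graph = g),
            class = "haplotype_network")
}

#' @export
print.haplotype_network <- function(x, ...) {
  s <- network_summary(x)
  cat("haplotype network:", s$n_sampled, "sampled +", s$n_inferred,
      "inferred nodes,", nrow(x$edges), "edges,", s$n_components,
      "component(s), limit", x$limit, "\n")
  invisible(x)
}

#' Summarise a haplotype network
#'
#' @param net a `haplotype_network`.
#' @return list with `n_sampled`, `n_inferred`, `n_components`, `n_edges`,
#'   and `path_lengths` — the table of graph path lengths between pairs of
#'   sampled haplotypes in the same component (the number of mutational
#'   steps separating them in the network).
#' @export
network_summary <- function(net) {
  g <- net$graph
  comps <- igraph::components(g)
  sampled <- net$nodes$id[net$nodes$sampled]
  pl <- numeric(0)
  if (length(sampled) > 1L) {
    dm <- igraph::distances(g, v = sampled, to = sampled)
    vals <- dm[upper.tri(dm)]
    pl <- vals[is.finite(vals)]
  }
  list(n_sampled = sum(net$nodes$sampled),
       n_inferred = sum(!net$nodes$sampled),
       n_components = comps$no,
       n_edges = nrow(net$edges),
       path_lengths = if (length(pl)) table(pl) else table(numeric(0)))
}

#' Export a haplotype network
#'
#' @param net a `haplotype_network`.
#' @param path output file path.
#' @param format `"graphml"`, `"dot"`, or `"node-table"` (tab-separated
#'   node attributes).
#' @export
export_network <- function(net, path, format = c("graphml", "dot", "node-table")) {
  format <- match.arg(format)
  if (format == "node-table") {
    utils::write.table(net$nodes, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    igraph::write_graph(net$graph, path, format = format)
  }
  invisible(path)
}
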