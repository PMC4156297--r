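#' Read species trees with per-branch population-size annotations
#'
#' Parses a list of Newick strings (one per line) or a NEXUS trees block
#' (with optional Translate table), where branches may carry bracketed
#' metadata of the form `[&dmv=0.005]`, `[&dmv={0.005}]` or
#' `[&theta=0.005]` immediately after the tip label or closing parenthesis
#' — the convention of posterior tree files written by Bayesian
#' species-tree software. The first number of a braced list is used. Trees
#' without annotations get `default_theta` on every branch.
#'
#' @param path file path.
#' @param default_theta theta assigned to unannotated branches.
#' @return list of [species_tree_sample()] objects.
#' @export
read_species_trees <- function(path, default_theta = 0.005) {
  lines <- readLines(path, warn = FALSE)
  is_nexus <- any(grepl("^#NEXUS", lines, ignore.case = TRUE))
  translate <- NULL
  if (is_nexus) {
    txt <- paste(lines, collapse = "\n")
    # translate table: "translate\n 1 name1,\n 2 name2;"
    tm <- regmatches(txt, regexpr("(?is)translate.*?;", txt, perl = TRUE))
    if (length(tm)) {
      body <- sub("(?is)^translate", "", tm, perl = TRUE)
      body <- gsub(";", "", body)
      items <- strsplit(body, ",")[[1]]
      items <- trimws(items)
      items <- items[nzchar(items)]
      kv <- do.call(rbind, strsplit(items, "\\s+"))
      translate <- stats::setNames(kv[, 2], kv[, 1])
    }
    tlines <- grep("^\\s*tree\\s", lines, ignore.case = TRUE, value = TRUE)
    newicks <- sub("^[^=]*=\\s*", "", tlines)
    newicks <- sub("^\\s*\\[&[UR]\\]\\s*", "", newicks)
  } else {
    newicks <- lines[grepl(";", lines)]
  }
  if (!length(newicks)) stop("no trees found in ", path)
  lapply(newicks, .parse_annotated_newick, translate = translate,
         default_theta = default_theta)
}

.parse_annotated_newick <- function(s, translate = NULL, default_theta = 0.005) {
  s <- trimws(s)
  anns <- character(0)
  # replace each [&...] with a parseable label marker __A<i>
  repeat {
    m <- regexpr("\\[&[^]]*\\]", s)
    if (m == -1L) break
    anns <- c(anns, substr(s, m + 2L, m + attr(m, "match.length") - 2L))
    s <- paste0(substr(s, 1L, m - 1L), "__A", length(anns),
                substr(s, m + attr(m, "match.length"), nchar(s)))
  }
  tr <- ape::read.tree(text = s)
  if (is.null(tr)) stop("could not parse tree string")
  theta_of <- function(labels) {
    out <- rep(NA_real_, length(labels))
    hit <- regmatches(labels, regexec("__A(\\d+)$", labels))
    for (i in seq_along(hit)) {
      if (length(hit[[i]]) == 2L) {
        ann <- anns[as.integer(hit[[i]][2])]
        v <- regmatches(ann, regexec("(?:dmv|theta)\\s*=\\s*\\{?\\s*([0-9.eE+-]+)", ann))[[1]]
        if (length(v) == 2L) out[i] <- as.numeric(v[2])
      }
    }
    out
  }
  tip_theta <- theta_of(tr$tip.label)
  tr$tip.label <- sub("__A\\d+$", "", tr$tip.label)
  node_theta <- rep(NA_real_, tr$Nnode)
  if (!is.null(tr$node.label)) {
    node_theta <- theta_of(tr$node.label)
    tr$node.label <- NULL
  }
  if (!is.null(translate)) {
    hit <- translate[tr$tip.label]
    tr$tip.label <- ifelse(is.na(hit), tr$tip.label, unname(hit))
  }
  theta <- c(tip_theta, node_theta)
  theta[is.na(theta)] <- default_theta
  species_tree_sample(tr, theta)
}

#' Write species trees with theta annotations
#'
#' Writes a NEXUS trees block in which every branch carries a
#' `[&dmv=...]` annotation, readable by [read_species_trees()].
#'
#' @param samples list of [species_tree_sample()] objects.
#' @param path output path.
#' @export
write_species_trees <- function(samples, path) {
  if (inherits(samples, "species_tree_sample")) samples <- list(samples)
  render <- function(s) {
    tr <- s$tree
    ntip <- ape::Ntip(tr)
    kids <- function(node) tr$edge[tr$edge[, 1] == node, 2]
    blen <- function(node) tr$edge.length[match(node, tr$edge[, 2])]
    rec <- function(node) {
      ann <- sprintf("[&dmv=%.10g]", s$theta[node])
      if (node <= ntip) {
        paste0(tr$tip.label[node], ann, ":", format(blen(node), digits = 10))
      } else {
        inner <- paste(vapply(kids(node), rec, character(1)), collapse = ",")
        tail <- if (is.na(blen(node))) "" else
          paste0(":", format(blen(node), digits = 10))
        paste0("(", inner, ")", ann, tail)
      }
    }
    paste0(rec(ntip + 1L), ";")
  }
  lines <- c("#NEXUS", "BEGIN TREES;",
             sprintf("  TREE sample_%d = [&R] %s", seq_along(samples),
                     vapply(samples, render, character(1))),
             "END;")
  writeLines(lines, path)
  invisible(path)
}
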