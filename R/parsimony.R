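#' Per-site minimum and maximum parsimony steps
#'
#' `site_min_steps` returns, for every column, the minimum number of state
#' changes any tree requires: (size of the smallest base set intersecting
#' every non-missing leaf's IUPAC set) - 1, found by exhaustive search over
#' the 15 nonempty subsets of \{A,C,G,T\}. `site_max_steps` returns the
#' maximum steps needed on any tree (the star-tree/worst-case bound):
#' (number of leaves with a non-missing state) - (largest number of leaves
#' whose state set contains a single shared base). `N`, `-` and `?` count
#' as missing.
#'
#' @param aln a [dna_alignment()].
#' @return integer vector, one entry per column.
#' @keywords internal
site_min_steps <- function(aln) {
  m <- aln_masks(aln)
  m[aln$seqs == "N"] <- 0L
  L <- ncol(m)
  out <- integer(L)
  todo <- colSums(m > 0L) > 0L
  subsets <- order(mask_popcount(1:15))  # subsets of {A,C,G,T} by size
  sizes <- mask_popcount(1:15)[subsets]
  for (k in seq_along(subsets)) {
    if (!any(todo)) break
    S <- subsets[k]
    covered <- colSums(matrix(m[, todo, drop = FALSE] == 0L |
                                bitwAnd(m[, todo, drop = FALSE], S) > 0L,
                              nrow = nrow(m))) == nrow(m)
    hit <- which(todo)[covered]
    out[hit] <- sizes[k] - 1L
    todo[hit] <- FALSE
  }
  out
}

#' @rdname site_min_steps
#' @keywords internal
site_max_steps <- function(aln) {
  m <- aln_masks(aln)
  m[aln$seqs == "N"] <- 0L
  n_eff <- colSums(m > 0L)
  counts <- sapply(c(1L, 2L, 4L, 8L), function(b) {
    hit <- bitwAnd(m, b) > 0L
    dim(hit) <- dim(m)
    colSums(hit)
  })
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1L)
  g <- n_eff - apply(counts, 1, max)
  g[n_eff == 0L] <- 0L
  as.integer(pmax(g, 0L))
}

#' Classify alignment columns for parsimony
#'
#' A column is *variable* when it shows at least two distinct states and
#' *parsimony informative* when at least two states are each carried by at
#' least two sequences. By default only unambiguous states (A, C, G, T)
#' enter the tallies and ambiguity codes are ignored, matching common
#' practice; with `count_ambiguous = TRUE` a column is variable whenever no
#' single base is compatible with every non-missing character (ambiguity
#' sets included), while the informative rule still counts unambiguous
#' states only.
#'
#' @param aln a [dna_alignment()].
#' @param count_ambiguous logical; see Details.
#' @return list with `class` (factor per column: constant /
#'   variable_uninformative / parsimony_informative), `n_variable`,
#'   `n_informative`.
#' @export
classify_sites <- function(aln, count_ambiguous = FALSE) {
  m <- aln_masks(aln)
  m[aln$seqs == "N"] <- 0L
  pc <- mask_popcount(m); dim(pc) <- dim(m)
  state_counts <- sapply(c(1L, 2L, 4L, 8L), function(b)
    colSums(m == b))
  if (is.null(dim(state_counts))) state_counts <- matrix(state_counts, nrow = 1L)
  n_states <- rowSums(state_counts >= 1L)
  variable <- n_states >= 2L
  if (count_ambiguous) variable <- variable | site_min_steps(aln) >= 1L
  informative <- rowSums(state_counts >= 2L) >= 2L
  cls <- ifelse(informative, "parsimony_informative",
                ifelse(variable, "variable_uninformative", "constant"))
  list(class = factor(cls, levels = c("constant", "variable_uninformative",
                                      "parsimony_informative")),
       n_variable = sum(variable),
       n_informative = sum(informative))
}

# expand a per-pattern vector to per-site using the phyDat index
.expand_patterns <- function(x, data) x[attr(data, "index")]

#' Fitch parsimony length of a tree
#'
#' Sum over columns of Fitch small-parsimony steps, with leaf state sets
#' given by the IUPAC codes and `-`/`?`/`N` as the full state set. The
#' length is independent of rooting.
#'
#' @param tree a `phylo` whose tip labels match the alignment labels.
#' @param aln a [dna_alignment()].
#' @param per_site logical; return the per-column step vector instead of
#'   the total.
#' @return integer total steps, or integer vector when `per_site = TRUE`.
#' @export
fitch_length <- function(tree, aln, per_site = FALSE) {
  if (!setequal(tree$tip.label, seq_labels(aln))) {
    stop("tree tip labels do not match alignment labels")
  }
  data <- as_phyDat(aln)
  if (per_site) {
    s <- phangorn::fitch(tree, data, site = "site")
    as.integer(.expand_patterns(s, data))
  } else {
    as.integer(phangorn::fitch(tree, data))
  }
}

#' Consistency and retention indices of a tree on an alignment
#'
#' Per site, `m` is the minimum steps on any tree, `s` the observed Fitch
#' steps on `tree` and `g` the maximum steps (star-tree bound). Over
#' variable sites, CI = sum(m)/sum(s) and RI = (sum(g) - sum(s)) /
#' (sum(g) - sum(m)). Sites with `g == m` cannot express homoplasy and
#' contribute zero to both RI sums; constant sites contribute only to the
#' tree length.
#'
#' @param tree a `phylo` over the alignment's labels.
#' @param aln a [dna_alignment()].
#' @return a `parsimony_stats` list: `tree_length`, `CI`, `RI`,
#'   `n_variable`, `n_informative`, and per-site vectors `min_steps`,
#'   `obs_steps`, `max_steps`.
#' @export
ci_ri <- function(tree, aln) {
  s <- fitch_length(tree, aln, per_site = TRUE)
  m <- site_min_steps(aln)
  g <- site_max_steps(aln)
  cls <- classify_sites(aln)
  variable <- m >= 1L
  if (sum(s[variable]) == 0L) stop("CI undefined: no observed steps")
  CI <- sum(m[variable]) / sum(s[variable])
  denom <- sum(g[variable]) - sum(m[variable])
  RI <- if (denom > 0) (sum(g[variable]) - sum(s[variable])) / denom else NA_real_
  structure(list(tree_length = sum(s), CI = CI, RI = RI,
                 n_variable = cls$n_variable, n_informative = cls$n_informative,
                 min_steps = m, obs_steps = s, max_steps = g),
            class = "parsimony_stats")
}

#' @export
print.parsimony_stats <- function(x, ...) {
  cat(sprintf("tree length %d  CI %.3f  RI %s  (%d variable, %d informative sites)\n",
              x$tree_length, x$CI,
              ifelse(is.na(x$RI), "NA", sprintf("%.3f", x$RI)),
              x$n_variable, x$n_informative))
  invisible(x)
}

# does `tree` contain the (unrooted) split clade-vs-rest? Constraints on
# fewer than 2 present members are trivially satisfied.
.has_split <- function(tree, clade) {
  tips <- tree$tip.label
  c2 <- intersect(clade, tips)
  if (length(c2) < 2L || length(c2) > length(tips) - 2L) return(TRUE)
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  idx <- sort(match(c2, labs))
  comp <- sort(setdiff(seq_along(labs), idx))
  for (s in pp) {
    s <- sort(s)
    if (identical(s, idx) || identical(s, comp)) return(TRUE)
  }
  FALSE
}

.satisfies_constraint <- function(tree, constraint) {
  all(vapply(constraint, function(cl) .has_split(tree, cl), logical(1)))
}

# all placements of `tip` on the edges of unrooted topology `tree`
# (edge lengths 1 throughout; topology is what matters)
.all_placements <- function(tree, tip) {
  out <- vector("list", nrow(tree$edge))
  for (e in seq_len(nrow(tree$edge))) {
    out[[e]] <- suppressWarnings(
      phytools::bind.tip(tree, tip, where = tree$edge[e, 2], position = 0.5))
  }
  for (i in seq_along(out)) out[[i]]$edge.length <- rep(1, nrow(out[[i]]$edge))
  class(out) <- "multiPhylo"
  out
}

# stepwise random addition honouring an optional constraint
.stepwise_addition <- function(data, constraint = NULL) {
  labs <- names(data)
  ord <- sample(labs)
  tr <- ape::read.tree(text = paste0("(", ord[1], ":1,", ord[2], ":1,", ord[3], ":1);"))
  for (tip in ord[-(1:3)]) {
    cand <- .all_placements(tr, tip)
    if (!is.null(constraint)) {
      ok <- vapply(cand, .satisfies_constraint, logical(1), constraint = constraint)
      if (!any(ok)) stop("constraint error: no placement of '", tip,
                         "' satisfies the constraint")
      cand <- cand[ok]
      class(cand) <- "multiPhylo"
    }
    sc <- phangorn::fitch(cand, data)
    best <- which(sc == min(sc))
    tr <- cand[[best[sample.int(length(best), 1L)]]]
  }
  tr
}

# NNI hill-climbing with constraint filtering
.nni_climb <- function(tree, data, constraint = NULL, max_rounds = 200L) {
  cur <- tree
  cur_sc <- phangorn::fitch(cur, data)
  for (r in seq_len(max_rounds)) {
    nb <- phangorn::nni(cur)
    if (!is.null(constraint)) {
      ok <- vapply(nb, .satisfies_constraint, logical(1), constraint = constraint)
      if (!any(ok)) break
      nb <- nb[ok]
      class(nb) <- "multiPhylo"
    }
    sc <- phangorn::fitch(nb, data)
    if (min(sc) >= cur_sc) break
    best <- which(sc == min(sc))
    cur <- nb[[best[sample.int(length(best), 1L)]]]
    cur_sc <- min(sc)
  }
  cur$edge.length <- NULL
  cur
}

# deduplicate topologies
.unique_topologies <- function(trees) {
  if (length(trees) <= 1L) return(trees)
  keep <- 1L
  for (i in 2L:length(trees)) {
    dup <- FALSE
    for (j in keep) {
      if (ape::dist.topo(ape::unroot(trees[[i]]), ape::unroot(trees[[j]])) == 0) {
        dup <- TRUE; break
      }
    }
    if (!dup) keep <- c(keep, i)
  }
  out <- trees[keep]
  class(out) <- "multiPhylo"
  out
}

# enumerate all unrooted topologies over the given labels by sequential
# insertion (used for exhaustive searches; 7 taxa -> 945 trees)
.enumerate_topologies <- function(labs) {
  stopifnot(length(labs) >= 3L)
  trees <- list(ape::read.tree(text = paste0("(", labs[1], ":1,", labs[2], ":1,",
                                             labs[3], ":1);")))
  for (tip in labs[-(1:3)]) {
    trees <- unlist(lapply(trees, function(tr) .all_placements(tr, tip)),
                    recursive = FALSE)
  }
  class(trees) <- "multiPhylo"
  trees
}

#' Heuristic / exhaustive maximum parsimony search
#'
#' Random-addition stepwise insertion followed by hill-climbing branch
#' swapping (NNI, or phangorn's SPR for unconstrained searches), repeated
#' from `n_starts` random starting orders; all distinct topologies at the
#' best length found are returned. With `exhaustive = TRUE` (at most 8
#' taxa) every unrooted topology is scored instead. Constrained searches
#' only accept placements and rearrangements preserving each constrained
#' clade as an unrooted split.
#'
#' @param aln a [dna_alignment()] with >= 4 sequences.
#' @param n_starts number of random-addition starts.
#' @param swap `"spr"` or `"nni"`.
#' @param constraint optional list of character vectors (clades that must
#'   be monophyletic in the unrooted sense).
#' @param seed optional integer seed.
#' @param exhaustive score every topology instead of searching.
#' @return list `trees` (multiPhylo of distinct best topologies) and
#'   `length` (best Fitch length).
#' @export
mp_search <- function(aln, n_starts = 10L, swap = c("spr", "nni"),
                      constraint = NULL, seed = NULL, exhaustive = FALSE) {
  swap <- match.arg(swap)
  if (n_seq(aln) < 4L) stop("need at least 4 sequences")
  if (!is.null(seed)) set.seed(seed)
  if (!is.null(constraint)) {
    bad <- setdiff(unlist(constraint), seq_labels(aln))
    if (length(bad)) stop("constraint error: unknown labels: ",
                          paste(bad, collapse = ", "))
  }
  data <- as_phyDat(aln)
  if (exhaustive) {
    if (n_seq(aln) > 8L) stop("exhaustive search limited to 8 taxa")
    trees <- .enumerate_topologies(seq_labels(aln))
    if (!is.null(constraint)) {
      ok <- vapply(trees, .satisfies_constraint, logical(1), constraint = constraint)
      if (!any(ok)) stop("constraint error: incompatible with label set")
      trees <- trees[ok]
      class(trees) <- "multiPhylo"
    }
    sc <- phangorn::fitch(trees, data)
    best <- trees[sc == min(sc)]
    class(best) <- "multiPhylo"
    best <- lapply(best, function(tr) { tr$edge.length <- NULL; tr })
    class(best) <- "multiPhylo"
    return(list(trees = .unique_topologies(best), length = as.integer(min(sc))))
  }
  found <- list()
  best_len <- Inf
  for (s in seq_len(n_starts)) {
    if (is.null(constraint) && swap == "spr") {
      tr <- phangorn::random.addition(data)
      tr <- phangorn::optim.parsimony(tr, data, method = "fitch",
                                      rearrangements = "SPR", trace = 0)
      tr$edge.length <- NULL
      len <- phangorn::fitch(tr, data)
    } else {
      tr <- .stepwise_addition(data, constraint)
      tr <- .nni_climb(tr, data, constraint)
      len <- phangorn::fitch(tr, data)
    }
    if (len < best_len) {
      best_len <- len
      found <- list(tr)
    } else if (len == best_len) {
      found <- c(found, list(tr))
    }
  }
  class(found) <- "multiPhylo"
  list(trees = .unique_topologies(found), length = as.integer(best_len))
}

#' Strict consensus of a set of trees
#'
#' @param trees a `multiPhylo`.
#' @return a `phylo`: the strict consensus.
#' @export
strict_consensus <- function(trees) ape::consensus(trees, p = 1)

#' Nonparametric bootstrap support for splits
#'
#' Columns are resampled with replacement; one fast heuristic search
#' (random stepwise addition, optionally followed by NNI swapping) is run
#' per replicate and the frequency of each split among replicate best trees
#' is reported.
#'
#' @param aln a [dna_alignment()].
#' @param n_reps number of bootstrap replicates.
#' @param seed optional integer seed.
#' @param fast logical; skip branch swapping after stepwise addition (the
#'   "fast" bootstrap).
#' @return data.frame with `split` (sorted member labels joined by `|`,
#'   side not containing the first label), `size`, `support` (percent).
#' @export
bootstrap_support <- function(aln, n_reps = 100L, seed = NULL, fast = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  data <- as_phyDat(aln)
  labs <- seq_labels(aln)
  tally <- new.env(parent = emptyenv())
  for (r in seq_len(n_reps)) {
    cols <- sample.int(n_col(aln), n_col(aln), replace = TRUE)
    rep_aln <- dna_alignment(aln$seqs[, cols, drop = FALSE])
    rep_data <- as_phyDat(rep_aln)
    tr <- .stepwise_addition(rep_data)
    if (!fast) tr <- .nni_climb(tr, rep_data)
    tr <- ape::root(tr, outgroup = labs[1], resolve.root = TRUE)
    pp <- ape::prop.part(tr)
    plabs <- attr(pp, "labels")
    for (cl in pp) {
      if (length(cl) <= 1L || length(cl) >= length(plabs) - 1L) next
      key <- paste(sort(plabs[cl]), collapse = "|")
      tally[[key]] <- (if (is.null(tally[[key]])) 0L else tally[[key]]) + 1L
    }
  }
  keys <- ls(tally)
  out <- data.frame(
    split = keys,
    size = lengths(strsplit(keys, "|", fixed = TRUE)),
    support = vapply(keys, function(k) 100 * tally[[k]] / n_reps, numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  out[order(-out$support), , drop = FALSE]
}

# best parsimony length of a column subset via one quick heuristic search
.best_length <- function(data, cols) {
  sub <- subset(data, select = cols, site.pattern = FALSE)
  tr <- .stepwise_addition(sub)
  tr <- .nni_climb(tr, sub)
  phangorn::fitch(tr, sub)
}

#' Incongruence length difference (partition homogeneity) test
#'
#' The observed statistic is D = L(combined) - L(A) - L(B), where L are
#' best parsimony lengths over the union of the two column sets and each
#' partition separately. Sites are randomly reassigned to pseudo-partitions
#' of the original sizes in each replicate and the add-one permutation
#' p-value `(1 + #\{D_rep >= D_obs\}) / (n_reps + 1)` is returned. With 7
#' or fewer taxa partition lengths are exact (exhaustive topology
#' enumeration); otherwise a quick heuristic search is used.
#'
#' @param aln a [dna_alignment()].
#' @param partA,partB disjoint integer column vectors.
#' @param n_reps number of permutation replicates.
#' @param seed optional integer seed.
#' @return list `D_obs`, `p`, `D_perm` (replicate statistics).
#' @export
ild_test <- function(aln, partA, partB, n_reps = 99L, seed = NULL) {
  partA <- as.integer(partA); partB <- as.integer(partB)
  if (length(intersect(partA, partB))) stop("partitions overlap")
  if (!is.null(seed)) set.seed(seed)
  data <- as_phyDat(aln)
  for (p in list(partA, partB)) {
    sub <- aln[, p]
    if (classify_sites(sub)$n_variable == 0L) {
      warning("degenerate partition: no variable sites")
    }
  }
  pool <- c(partA, partB)
  nA <- length(partA)
  D_perm <- numeric(n_reps)
  if (n_seq(aln) <= 7L) {
    # exact: per-tree per-site step matrix makes every subset length a
    # row-sum minimum (Fitch length is additive over columns)
    topos <- .enumerate_topologies(seq_labels(aln))
    idx <- attr(data, "index")
    S <- t(vapply(topos, function(tr)
      as.numeric(phangorn::fitch(tr, data, site = "site")[idx]),
      numeric(n_col(aln))))
    len <- function(cols) min(rowSums(S[, cols, drop = FALSE]))
    Lc <- len(pool)
    D_obs <- Lc - len(partA) - len(partB)
    for (r in seq_len(n_reps)) {
      perm <- sample(pool)
      D_perm[r] <- Lc - len(perm[seq_len(nA)]) - len(perm[-seq_len(nA)])
    }
  } else {
    Lc <- .best_length(data, pool)
    D_obs <- Lc - .best_length(data, partA) - .best_length(data, partB)
    for (r in seq_len(n_reps)) {
      perm <- sample(pool)
      D_perm[r] <- Lc - .best_length(data, perm[seq_len(nA)]) -
        .best_length(data, perm[-seq_len(nA)])
    }
  }
  list(D_obs = D_obs, p = (1 + sum(D_perm >= D_obs)) / (n_reps + 1),
       D_perm = D_perm)
}

#' Tab-separated parsimony statistics report
#'
#' Writes the dataset statistics a parsimony analysis conventionally
#' reports: sequence counts, alignment width, variable and informative
#' sites, number of best trees, tree length, CI and RI.
#'
#' @param aln a [dna_alignment()].
#' @param search result of [mp_search()].
#' @param path output path.
#' @export
write_parsimony_report <- function(aln, search, path) {
  stats <- ci_ri(search$trees[[1]], aln)
  rows <- c(
    sprintf("No. of sequences\t%d", n_seq(aln)),
    sprintf("Characters in the alignment\t%d", n_col(aln)),
    sprintf("No. of variable sites\t%d", stats$n_variable),
    sprintf("No. of parsimony informative characters\t%d", stats$n_informative),
    sprintf("No. of most parsimonious trees\t%d", length(search$trees)),
    sprintf("Tree length in parsimony\t%d", search$length),
    sprintf("Consistency index\t%.3f", stats$CI),
    sprintf("Retention index\t%.3f", stats$RI))
  writeLines(rows, path)
  invisible(path)
}
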