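# Independent brute-force oracles and small fixture builders used across
# the suite. Everything here is deliberately naive: enumeration and direct
# counting, never the package's own algorithms.

rand_aln <- function(n, L, labels = sprintf("t%d", seq_len(n)),
                     alphabet = c("A", "C", "G", "T")) {
  m <- matrix(sample(alphabet, n * L, replace = TRUE), nrow = n,
              dimnames = list(labels, NULL))
  dna_alignment(m)
}

# plain character-mismatch count over positions where both are in ACGT
oracle_hamming <- function(a, b) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- 0L; d <- 0L
  for (i in seq_along(av)) {
    if (av[i] %in% c("A", "C", "G", "T") && bv[i] %in% c("A", "C", "G", "T")) {
      n <- n + 1L
      if (av[i] != bv[i]) d <- d + 1L
    }
  }
  c(diff = d, comparable = n)
}

# O(n^2) all-pairs identity classes
oracle_identity_classes <- function(strings) {
  cls <- integer(length(strings))
  nxt <- 0L
  for (i in seq_along(strings)) {
    hit <- 0L
    if (i > 1L) for (j in seq_len(i - 1L)) {
      if (strings[j] == strings[i]) { hit <- cls[j]; break }
    }
    if (hit == 0L) { nxt <- nxt + 1L; hit <- nxt }
    cls[i] <- hit
  }
  cls
}

iupac_sets <- list(A = "A", C = "C", G = "G", T = "T",
                   R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                   W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                   B = c("C", "G", "T"), D = c("A", "G", "T"),
                   H = c("A", "C", "T"), V = c("A", "C", "G"),
                   N = c("A", "C", "G", "T"))

# exhaustive small-parsimony steps of one column: minimize over every
# assignment of A/C/G/T to the internal nodes; a leaf edge costs 0 iff the
# leaf's IUPAC set contains the parent state (missing = free)
oracle_fitch_column <- function(tree, states) {
  ntip <- length(tree$tip.label)
  internal <- ntip + seq_len(tree$Nnode)
  k <- length(internal)
  bases <- c("A", "C", "G", "T")
  A <- as.matrix(expand.grid(rep(list(1:4), k)))  # 4^k assignments
  cost <- numeric(nrow(A))
  for (e in seq_len(nrow(tree$edge))) {
    par <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    pi <- match(par, internal)
    if (ch > ntip) {
      ci <- match(ch, internal)
      cost <- cost + (A[, pi] != A[, ci])
    } else {
      st <- states[[tree$tip.label[ch]]]
      if (is.null(st) || !length(st)) next  # missing leaf: free
      compat <- bases[A[, pi]] %in% st
      cost <- cost + !compat
    }
  }
  min(cost)
}

oracle_fitch_length <- function(tree, aln) {
  tot <- 0L
  for (j in seq_len(n_col(aln))) {
    states <- lapply(seq_labels(aln), function(l) {
      ch <- aln$seqs[l, j]
      if (ch %in% c("-", "?")) character(0) else iupac_sets[[ch]]
    })
    names(states) <- seq_labels(aln)
    tot <- tot + oracle_fitch_column(tree, states)
  }
  tot
}

# enumerate all unrooted topologies over labels (test-side copy of the
# textbook sequential-insertion enumeration, scored independently)
oracle_all_topologies <- function(labels) {
  trees <- list(ape::read.tree(text = sprintf("(%s:1,%s:1,%s:1);",
                                              labels[1], labels[2], labels[3])))
  for (tip in labels[-(1:3)]) {
    nxt <- list()
    for (tr in trees) {
      for (e in seq_len(nrow(tr$edge))) {
        t2 <- suppressWarnings(
          phytools::bind.tip(tr, tip, where = tr$edge[e, 2], position = 0.5))
        t2$edge.length <- rep(1, nrow(t2$edge))
        nxt[[length(nxt) + 1L]] <- t2
      }
    }
    trees <- nxt
  }
  trees
}

# brute-force JC69 likelihood of one site by summing over internal states
oracle_jc_site_lik <- function(tree, states_per_tip) {
  ntip <- length(tree$tip.label)
  internal <- ntip + seq_len(tree$Nnode)
  bases <- c("A", "C", "G", "T")
  pmat <- function(t) {
    p_same <- 1 / 4 + 3 / 4 * exp(-4 * t / 3)
    p_diff <- 1 / 4 - 1 / 4 * exp(-4 * t / 3)
    m <- matrix(p_diff, 4, 4); diag(m) <- p_same
    m
  }
  A <- as.matrix(expand.grid(rep(list(1:4), length(internal))))
  total <- 0
  for (r in seq_len(nrow(A))) {
    prob <- 1 / 4  # root state prior (root = first internal node)
    ok <- TRUE
    for (e in seq_len(nrow(tree$edge))) {
      par <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
      ps <- A[r, match(par, internal)]
      P <- pmat(tree$edge.length[e])
      if (ch > ntip) {
        prob <- prob * P[ps, A[r, match(ch, internal)]]
      } else {
        st <- states_per_tip[[tree$tip.label[ch]]]
        prob <- prob * sum(P[ps, match(st, bases)])
      }
      if (prob == 0) { ok <- FALSE; break }
    }
    if (ok) total <- total + prob
  }
  total
}

# small two-locus scenario kept cheap enough for repeated use in tests
small_scenario <- function(seed, ...) {
  generate_scenario(
    n_species = 4L, tree_height = 0.01, outgroup_stem = 0.05,
    samples_per_species = c(sp1 = 3L, sp2 = 3L, sp3 = 2L, sp4 = 2L, out1 = 2L),
    loci = list(
      nuclear = locus_config(sub_model("JC69"), 200, mu_rel = 1.016, h = 2,
                             ploidy = 2L),
      plastid = locus_config(sub_model("JC69"), 250, mu_rel = 0.385, h = 1,
                             ploidy = 1L)),
    seed = seed, ...)
}
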