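test_that("site classification separates constant, uninformative and informative", {
  aln <- dna_alignment(c(a = "AAAA", b = "AACA", c = "ACTA", d = "ACTA"))
  cls <- classify_sites(aln)
  expect_equal(as.character(cls$class),
               c("constant", "parsimony_informative", "variable_uninformative",
                 "constant"))
  expect_equal(cls$n_variable, 2L)
  expect_equal(cls$n_informative, 1L)
  # ambiguity codes are ignored by default, counted as potential variation
  # under the flag
  aln2 <- dna_alignment(c(a = "R", b = "A", c = "A", d = "A"))
  expect_equal(classify_sites(aln2)$n_variable, 0L)
  expect_equal(classify_sites(aln2, count_ambiguous = TRUE)$n_variable, 0L)
  aln3 <- dna_alignment(c(a = "Y", b = "A", c = "A", d = "A"))
  expect_equal(classify_sites(aln3)$n_variable, 0L)
  expect_equal(classify_sites(aln3, count_ambiguous = TRUE)$n_variable, 1L)
})

test_that("fitch length matches hand cases and ignores missing columns", {
  aln <- dna_alignment(c(a = "A-", b = "A?", c = "C-", d = "C?"))
  tr <- ape::read.tree(text = "((a,b),(c,d));")
  expect_equal(fitch_length(tr, aln), 1L)
  expect_equal(fitch_length(tr, aln, per_site = TRUE), c(1L, 0L))
  expect_error(fitch_length(tr, dna_alignment(c(a = "A", b = "A", x = "A", y = "A"))),
               "labels")
})

test_that("fitch length equals the exhaustive internal-state oracle", {
  set.seed(31)
  for (i in 1:5) {
    aln <- rand_aln(6, 12, alphabet = c("A", "C", "G", "T", "R", "Y", "-"))
    tr <- ape::rtree(6, tip.label = seq_labels(aln))
    expect_equal(fitch_length(tr, aln), oracle_fitch_length(tr, aln))
  }
})

test_that("fitch length is invariant under rerooting and leaf order", {
  set.seed(32)
  aln <- rand_aln(7, 20)
  tr <- ape::rtree(7, tip.label = seq_labels(aln))
  l0 <- fitch_length(tr, aln)
  for (tip in c("t2", "t5")) {
    expect_equal(fitch_length(ape::root(ape::unroot(tr), tip,
                                        resolve.root = TRUE), aln), l0)
  }
  perm <- sample(seq_len(n_seq(aln)))
  expect_equal(fitch_length(tr, aln[perm, ]), l0)
})

test_that("CI and RI match hand-enumerated values and their boundary cases", {
  # A,C,A,C on ((a1,c1),(a2,c2)): m=1, s=2, g=2 -> site CI 0.5, RI 0
  ax <- dna_alignment(c(a1 = "A", c1 = "C", a2 = "A", c2 = "C"))
  trx <- ape::read.tree(text = "((a1,c1),(a2,c2));")
  st <- ci_ri(trx, ax)
  expect_equal(st$min_steps, 1L)
  expect_equal(st$obs_steps, 2L)
  expect_equal(st$max_steps, 2L)
  expect_equal(st$CI, 0.5)
  expect_equal(st$RI, 0)
  # homoplasy-free data on the true tree: CI = RI = 1
  ah <- dna_alignment(c(a = "AAT", b = "AAT", c = "CCT", d = "CGT"))
  trh <- ape::read.tree(text = "((a,b),(c,d));")
  sth <- ci_ri(trh, ah)
  expect_equal(sth$CI, 1)
  expect_equal(sth$RI, 1)
  expect_equal(sth$tree_length, sum(sth$min_steps))
  expect_error(ci_ri(trh, dna_alignment(c(a = "A", b = "A", c = "A", d = "A"))),
               "undefined")
})

test_that("mp_search finds the global optimum (verified exhaustively)", {
  set.seed(33)
  # 4 taxa: best of the 3 unrooted topologies
  aln4 <- dna_alignment(c(a = "AAAACC", b = "AAAACC", c = "CCCCAA", d = "CCCCAT"))
  ex <- mp_search(aln4, exhaustive = TRUE)
  expect_equal(ex$length, 7L)
  h <- mp_search(aln4, n_starts = 3, seed = 1)
  expect_equal(h$length, ex$length)
  # 6-7 taxa: heuristic equals the independent exhaustive oracle
  for (n in c(6L, 7L)) {
    aln <- rand_aln(n, 15)
    topos <- oracle_all_topologies(seq_labels(aln))
    oracle_best <- min(vapply(topos, oracle_fitch_length, numeric(1), aln = aln))
    expect_equal(mp_search(aln, exhaustive = TRUE)$length, oracle_best)
    heur <- mp_search(aln, n_starts = 5, seed = n)
    expect_gte(heur$length, oracle_best)   # never below the optimum
    expect_equal(heur$length, oracle_best) # and recovers it on these sizes
  }
})

test_that("constrained searches honour the constraint and cost extra steps", {
  set.seed(34)
  aln <- dna_alignment(c(a = "AAAAAA", b = "AAAAAC", c = "CCCCCA", d = "CCCCCC",
                         e = "AACCCC"))
  free <- mp_search(aln, exhaustive = TRUE)
  con <- list(ac = c("a", "c"))
  forced <- mp_search(aln, exhaustive = TRUE, constraint = con)
  expect_gte(forced$length, free$length)
  expect_true(all(vapply(forced$trees, phylodiscord:::.satisfies_constraint,
                         logical(1), constraint = con)))
  heur <- mp_search(aln, n_starts = 5, seed = 2, constraint = con)
  expect_equal(heur$length, forced$length)
  expect_error(mp_search(aln, constraint = list(c("a", "zz"))), "constraint")
})

test_that("bootstrap support is high for a clean split and low without signal", {
  # every column supports ab|cd
  aln <- dna_alignment(c(a = strrep("A", 20), b = strrep("A", 20),
                         c = strrep("C", 20), d = strrep("C", 20)))
  bs <- bootstrap_support(aln, n_reps = 30, seed = 3)
  key <- paste(sort(c("c", "d")), collapse = "|")
  expect_equal(bs$support[bs$split == key], 100)
  # constant alignment: no split reaches high support
  alnc <- dna_alignment(c(a = strrep("A", 20), b = strrep("A", 20),
                          c = strrep("A", 20), d = strrep("A", 20)))
  bsc <- bootstrap_support(alnc, n_reps = 30, seed = 4)
  if (nrow(bsc)) expect_true(all(bsc$support <= 60))
})

test_that("bootstrap support approaches 100% with growing planted signal", {
  set.seed(35)
  make_aln <- function(ncols) {
    base <- rand_aln(8, 10)$seqs
    planted <- matrix(rep(c(rep("A", 4), rep("C", 4)), ncols), nrow = 8)
    dna_alignment(cbind(base, planted))
  }
  key <- paste(sort(sprintf("t%d", 5:8)), collapse = "|")
  sup <- vapply(c(2, 30), function(k) {
    bs <- bootstrap_support(make_aln(k), n_reps = 25, seed = k)
    if (key %in% bs$split) bs$support[bs$split == key] else 0
  }, numeric(1))
  expect_gt(sup[2], sup[1] - 1e-9)
  expect_gte(sup[2], 90)
})

test_that("the ILD test separates congruent from conflicting partitions", {
  set.seed(36)
  # congruent: partition B duplicates partition A's signal
  blockA <- c(a = "AAAATT", b = "AAAATT", c = "TTTTAA", d = "TTTTAA",
              e = "TATATA", f = "ATATAT")
  aln_cong <- dna_alignment(setNames(paste0(blockA, blockA), names(blockA)))
  cong <- ild_test(aln_cong, 1:6, 7:12, n_reps = 99, seed = 1)
  expect_gte(cong$p, 0.5)
  # conflicting: the two halves support incompatible trees
  t1 <- ape::read.tree(text = "((a,b),(c,d),(e,f));")
  t2 <- ape::read.tree(text = "((a,f),(c,e),(b,d));")
  sim <- function(tr, seed) {
    set.seed(seed)
    tr$edge.length <- rep(0.15, nrow(tr$edge))
    d <- phangorn::simSeq(tr, l = 60)
    dna_alignment(toupper(as.character(d)))
  }
  a1 <- sim(t1, 10); a2 <- sim(t2, 11)
  conf <- concatenate_alignments(a1, a2)
  res <- ild_test(conf, 1:60, 61:120, n_reps = 99, seed = 2)
  expect_lte(res$p, 0.05)
  expect_gt(res$D_obs, 0)
  # degenerate partition warns but still runs
  alnd <- dna_alignment(c(a = "AAAT", b = "AAAA", c = "AAAC", d = "AAAG"))
  expect_warning(ild_test(alnd, 1:3, 4L, n_reps = 9, seed = 3), "degenerate")
})

test_that("strict consensus and the parsimony report writer work", {
  aln <- dna_alignment(c(a = "AATT", b = "AATA", c = "TTAT", d = "TTAA"))
  s <- mp_search(aln, exhaustive = TRUE)
  cons <- strict_consensus(s$trees)
  expect_s3_class(cons, "phylo")
  f <- tempfile()
  write_parsimony_report(aln, s, f)
  rows <- readLines(f)
  expect_true(any(grepl("^Tree length in parsimony\t", rows)))
  expect_true(any(grepl("^Consistency index\t", rows)))
})
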