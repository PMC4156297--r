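test_that("alignment construction enforces its invariants", {
  aln <- dna_alignment(c(s1 = "ACGU", s2 = "acg-"))
  expect_equal(n_seq(aln), 2L)
  expect_equal(n_col(aln), 4L)
  expect_equal(unname(aln$seqs["s1", 4]), "T")   # U normalised to T
  expect_equal(unname(aln$seqs["s2", ]), c("A", "C", "G", "-"))
  expect_error(dna_alignment(c(a = "ACGT", b = "ACGTA")), "shape")
  expect_error(dna_alignment(c(a = "ACXT", b = "ACGT")), "alphabet")
  expect_error(dna_alignment(matrix("A", 2, 1, dimnames = list(c("a", "a"), NULL))),
               "uniqueness|duplicate")
})

test_that("read/write round-trips entries and partitions in all formats", {
  aln <- dna_alignment(c(seq_one = "ACGR-T?N", seq_two = "ACGTMTGA"),
                       partitions = list(ITS1 = c(1, 5), ITS2 = c(6, 8)))
  for (fmt in c("fasta", "phylip-relaxed", "nexus")) {
    f <- tempfile()
    write_alignment(aln, f, fmt)
    back <- read_alignment(f, fmt)
    expect_equal(seq_strings(back), seq_strings(aln), info = fmt)
    if (fmt == "nexus") {
      expect_equal(back$partitions, aln$partitions)
    }
  }
})

test_that("NEXUS charsets are read as 1-based inclusive column ranges", {
  f <- tempfile(fileext = ".nex")
  writeLines(c("#NEXUS", "BEGIN DATA;",
               "  DIMENSIONS NTAX=2 NCHAR=8;",
               "  FORMAT DATATYPE=DNA MISSING=? GAP=- INTERLEAVE=NO;",
               "  MATRIX", "    a  ACGTACGT", "    b  ACGTACGA", "  ;", "END;",
               "BEGIN SETS;", "  charset ITS1 = 1-5;", "  charset ITS2 = 6-8;",
               "END;"), f)
  aln <- read_alignment(f, "nexus")
  expect_equal(aln$partitions$ITS1, c(1L, 5L))
  expect_equal(diff(aln$partitions$ITS1) + 1L, 5L)  # 5 columns covered
  expect_equal(aln$partitions$ITS2, c(6L, 8L))
})

test_that("p_distance follows the pairwise-deletion disjoint-set rule", {
  expect_equal(p_distance("ACGT", "ACGT"), 0)
  expect_equal(p_distance("ACGT", "ACGA"), 0.25)
  # ambiguity: R vs A overlap -> match; R vs Y disjoint -> mismatch
  expect_equal(p_distance("RA", "AA"), 0)
  expect_equal(p_distance("RA", "YA"), 0.5)
  # gaps and ? excluded from the denominator
  expect_equal(p_distance("A-GT", "ACGA"), 1 / 3)
  expect_equal(p_distance("A?GT", "ACGA"), 1 / 3)
  expect_error(p_distance("--", "AC"), "undefined")
  expect_error(p_distance("AC", "ACG"), "length")
})

test_that("p_distance matches a brute-force counter on random unambiguous pairs", {
  set.seed(41)
  for (i in 1:20) {
    a <- paste(sample(c("A", "C", "G", "T"), 50, TRUE), collapse = "")
    b <- paste(sample(c("A", "C", "G", "T"), 50, TRUE), collapse = "")
    o <- oracle_hamming(a, b)
    expect_equal(p_distance(a, b), o["diff"] / o["comparable"],
                 ignore_attr = TRUE)
    expect_equal(p_distance(a, b), p_distance(b, a))
    expect_gte(p_distance(a, b), 0)
    expect_lte(p_distance(a, b), 1)
  }
})

test_that("merge_identical collapses exactly the identity classes", {
  aln <- dna_alignment(c(a = "ACGT", b = "ACGT", c = "ACGA", d = "ACGA",
                         e = "TTTT"))
  m <- merge_identical(aln)
  expect_equal(n_seq(m$alignment), 3L)
  expect_equal(m$members$a, c("a", "b"))
  expect_equal(sum(lengths(m$members)), 5L)
  # all-distinct input is untouched
  aln2 <- dna_alignment(c(x = "AC", y = "AG", z = "AT"))
  m2 <- merge_identical(aln2)
  expect_equal(seq_strings(m2$alignment), seq_strings(aln2))
  expect_equal(unname(lengths(m2$members)), c(1L, 1L, 1L))
})

test_that("merge_identical agrees with the all-pairs oracle and is idempotent", {
  set.seed(7)
  for (i in 1:10) {
    strs <- replicate(12, paste(sample(c("A", "C"), 4, TRUE), collapse = ""))
    names(strs) <- sprintf("s%d", 1:12)
    aln <- dna_alignment(strs)
    m <- merge_identical(aln)
    expect_equal(n_seq(m$alignment), max(oracle_identity_classes(strs)))
    expect_equal(sum(lengths(m$members)), 12L)
    m2 <- merge_identical(m$alignment)
    expect_equal(seq_strings(m2$alignment), seq_strings(m$alignment))
  }
})

test_that("missing-compatible merging joins sequences that differ only by gaps", {
  aln <- dna_alignment(c(a = "ACGT", b = "AC-T", c = "AGGT"))
  expect_equal(n_seq(merge_identical(aln, "exact")$alignment), 3L)
  m <- merge_identical(aln, "missing-compatible")
  expect_equal(n_seq(m$alignment), 2L)
  expect_equal(m$members$a, c("a", "b"))
})

test_that("concatenation sums widths, shifts partitions and rejects label mismatch", {
  a <- dna_alignment(c(x = "ACGT", y = "ACGA"), partitions = list(p1 = c(1, 4)))
  b <- dna_alignment(c(y = "GGGGGGGGGG", x = "TTTTTTTTTT"),
                     partitions = list(p2 = c(3, 7)))
  cc <- concatenate_alignments(a, b)
  expect_equal(n_col(cc), 14L)
  expect_equal(cc$partitions$p2, c(7L, 11L))      # shifted by n_col(a)
  expect_equal(seq_strings(cc)[["x"]], "ACGTTTTTTTTTTT")
  expect_error(concatenate_alignments(a, dna_alignment(c(x = "AA", z = "CC"))),
               "join error.*y|join error.*z")
  # concatenating an empty-column alignment changes nothing
  e <- dna_alignment(matrix(character(0), nrow = 2, ncol = 0,
                            dimnames = list(c("x", "y"), NULL)))
  expect_equal(seq_strings(concatenate_alignments(a, e)), seq_strings(a))
})

test_that("taxon maps attach, validate and round-trip", {
  tm <- data.frame(label = c("x", "y"), taxon = c("sp1", "out"),
                   ingroup = c(TRUE, FALSE))
  aln <- dna_alignment(c(x = "AC", y = "GT"), taxon_map = tm)
  expect_equal(ingroup_labels(aln), "x")
  f <- tempfile()
  write_taxon_map(tm, f)
  back <- read_taxon_map(f)
  expect_equal(back$ingroup, c(TRUE, FALSE))
  expect_error(set_taxon_map(dna_alignment(c(z = "AA")), tm), "lacks")
})
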