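test_that("ribotype mixing follows the homogenization model", {
  set.seed(101)
  a <- "AAAAAAAAAA"; b <- "CCCCCAAAAA"
  # c = 0: ambiguity count equals the ribotype Hamming distance
  m0 <- apply_ribotype_mixing(a, b, 0)
  expect_equal(sum(strsplit(m0, "")[[1]] == "M"), 5L)
  # c = 1: no ambiguity codes at all
  m1 <- apply_ribotype_mixing(a, b, 1)
  expect_false(any(strsplit(m1, "")[[1]] %in% names(iupac_sets)[5:15]))
  # identical sites copied through
  expect_equal(substr(m0, 6, 10), "AAAAA")
  # expected ambiguity count is (1 - c) * d
  cnt <- replicate(400, {
    m <- apply_ribotype_mixing(a, b, 0.4)
    sum(strsplit(m, "")[[1]] == "M")
  })
  expect_equal(mean(cnt), 0.6 * 5, tolerance = 0.1)
  expect_error(apply_ribotype_mixing("AA", "AAA", 0), "length")
})

test_that("the same seed reproduces a bundle byte for byte", {
  b1 <- small_scenario(seed = 99)
  b2 <- small_scenario(seed = 99)
  expect_identical(seq_strings(b1$alignments$nuclear),
                   seq_strings(b2$alignments$nuclear))
  expect_identical(seq_strings(b1$alignments$plastid),
                   seq_strings(b2$alignments$plastid))
  expect_identical(ape::write.tree(b1$gene_trees$nuclear),
                   ape::write.tree(b2$gene_trees$nuclear))
  expect_identical(b1$species_tree$theta, b2$species_tree$theta)
  b3 <- small_scenario(seed = 100)
  expect_false(identical(seq_strings(b1$alignments$nuclear),
                         seq_strings(b3$alignments$nuclear)))
})

test_that("a zero-proportion hybridization event is a null event", {
  ev <- data.frame(donor = "sp1", recipient = "sp2", time = 0.002, gamma = 0)
  b0 <- small_scenario(seed = 55)
  bg <- small_scenario(seed = 55, hybridization = ev)
  expect_identical(seq_strings(b0$alignments$nuclear),
                   seq_strings(bg$alignments$nuclear))
  expect_length(bg$hybrid_individuals$nuclear, 0L)
  expect_error(small_scenario(seed = 1, hybridization = data.frame(
    donor = "sp1", recipient = "sp2", time = 99, gamma = 0.5)), "infeasible")
})

test_that("bundle structure is internally consistent", {
  b <- small_scenario(seed = 23)
  expect_setequal(seq_labels(b$alignments$nuclear), names(b$species_map))
  expect_setequal(seq_labels(b$alignments$plastid), names(b$species_map))
  expect_equal(n_col(b$alignments$nuclear), 200L)
  expect_equal(n_col(b$alignments$plastid), 250L)
  # plastid tips = one lineage per individual; nuclear gene tree has 2x
  expect_equal(ape::Ntip(b$gene_trees$plastid), length(b$species_map))
  expect_equal(ape::Ntip(b$gene_trees$nuclear), 2L * length(b$species_map))
  # mixed individuals really carry ambiguity codes when c < 1
  b0 <- small_scenario(seed = 23, homogenization = 0)
  rep <- detect_ips(b0$alignments$nuclear, seq_labels(b0$alignments$nuclear))
  carriers <- rep$per_sequence$label[rep$per_sequence$n_ips > 0]
  expect_setequal(carriers, b0$mixed_individuals$label)
  # outgroup labels flagged as outgroup in the taxon map
  tm <- b$alignments$nuclear$taxon_map
  expect_true(all(!tm$ingroup[grepl("^out", tm$label)]))
  expect_true(all(tm$ingroup[grepl("^sp", tm$label)]))
})

test_that("homogenization erases additivity as c approaches 1", {
  ips_total <- vapply(c(0, 0.5, 1), function(cc) {
    b <- small_scenario(seed = 31, homogenization = cc)
    rep <- detect_ips(b$alignments$nuclear, seq_labels(b$alignments$nuclear))
    sum(rep$per_sequence$n_ips)
  }, numeric(1))
  expect_true(all(diff(ips_total) <= 0))
  expect_equal(ips_total[3], 0)
  # at c = 0 the IPS count per individual equals the ribotype distance
  b0 <- small_scenario(seed = 31, homogenization = 0)
  rep0 <- detect_ips(b0$alignments$nuclear, seq_labels(b0$alignments$nuclear))
  for (r in seq_len(nrow(b0$mixed_individuals))) {
    lab <- b0$mixed_individuals$label[r]
    expect_equal(rep0$per_sequence$n_ips[rep0$per_sequence$label == lab],
                 b0$mixed_individuals$distance[r])
  }
})

test_that("pseudo-posterior jitter behaves as documented", {
  set.seed(103)
  tr <- ape::read.tree(text = "((A:0.01,B:0.01):0.02,C:0.03);")
  truth <- species_tree_sample(tr, 0.005)
  # jitter 0: exact copies
  p0 <- make_pseudo_posterior(truth, 3, 0, seed = 1)
  for (s in p0) {
    expect_identical(ape::write.tree(s$tree), ape::write.tree(truth$tree))
    expect_identical(s$theta, truth$theta)
  }
  # lognormal mean correction: sampled theta means converge to the truth
  pp <- make_pseudo_posterior(truth, 3000, 0.3, seed = 2)
  mean_theta <- mean(vapply(pp, function(s) s$theta[1], numeric(1)))
  expect_equal(mean_theta, 0.005, tolerance = 0.02)
  # heights stay ultrametric with parent above child
  for (s in pp[1:20]) expect_true(ape::is.ultrametric(s$tree))
})

test_that("gene-tree discordance increases with theta", {
  set.seed(104)
  tr <- ape::read.tree(text = "(((A:0.004,B:0.004):0.002,C:0.006):0.004,D:0.01);")
  disc <- vapply(c(0.0005, 0.003, 0.02), function(th) {
    s <- species_tree_sample(tr, th)
    bad <- 0L
    for (i in 1:60) {
      g <- simulate_gene_tree(s, c(A = 1, B = 1, C = 1, D = 1), h = 1)
      tm <- ape::cophenetic.phylo(g) / 2
      # the species tree's internal split is AB|CD
      if (!(tm["A_1", "B_1"] < min(tm["A_1", "C_1"], tm["A_1", "D_1"],
                                   tm["B_1", "C_1"], tm["B_1", "D_1"]))) {
        bad <- bad + 1L
      }
    }
    bad / 60
  }, numeric(1))
  expect_true(all(diff(disc) >= 0))
  expect_lt(disc[1], 0.1)
  expect_gt(disc[3], 0.3)
})

test_that("truth bundles write to readable plain-text files", {
  b <- small_scenario(seed = 71)
  d <- tempfile()
  write_truth_bundle(b, d)
  expect_true(all(file.exists(file.path(d, c(
    "nuclear.fasta", "plastid.fasta", "nuclear_genetree.nwk",
    "species_tree.nex", "taxon_map.tsv", "truth_manifest.tsv")))))
  back <- read_alignment(file.path(d, "nuclear.fasta"),
                         taxon_map = file.path(d, "taxon_map.tsv"))
  expect_equal(seq_strings(back), seq_strings(b$alignments$nuclear))
  st <- read_species_trees(file.path(d, "species_tree.nex"))[[1]]
  expect_equal(st$theta, b$species_tree$theta, tolerance = 1e-8)
})
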