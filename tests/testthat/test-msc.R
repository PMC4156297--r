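# shared fixture: two shallow sister species and a distant one
msc_fixture <- function(theta = 0.004) {
  tr <- ape::read.tree(text = "((A:0.01,B:0.01):0.03,C:0.04);")
  species_tree_sample(tr, theta)
}

test_that("species_tree_sample validates its inputs", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  expect_s3_class(species_tree_sample(tr, 0.01), "species_tree_sample")
  expect_error(species_tree_sample(tr, -1), "positive")
  expect_error(species_tree_sample(tr, c(1, 2)), "per node")
  expect_error(species_tree_sample(ape::unroot(tr), 0.01), "rooted")
})

test_that("within-species TMRCA matches coalescent expectations", {
  set.seed(81)
  s <- msc_fixture(0.004)
  # two lineages: mean pairwise time = theta * h
  tm2 <- replicate(2000, {
    g <- simulate_gene_tree(s, c(A = 2), h = 1)
    max(ape::node.depth.edgelength(g))
  })
  expect_equal(mean(tm2), 0.004, tolerance = 0.08)
  # heredity scalar doubles it
  tm2h <- replicate(2000, {
    g <- simulate_gene_tree(s, c(A = 2), h = 2)
    max(ape::node.depth.edgelength(g))
  })
  expect_equal(mean(tm2h), 0.008, tolerance = 0.08)
})

test_that("cross-species coalescence collapses to the divergence time as theta -> 0", {
  set.seed(82)
  s <- species_tree_sample(ape::read.tree(text = "((A:0.01,B:0.01):0.03,C:0.04);"),
                           1e-7)
  for (i in 1:20) {
    g <- simulate_gene_tree(s, c(A = 1, B = 1), h = 1)
    expect_equal(max(ape::node.depth.edgelength(g)), 0.01, tolerance = 1e-3)
  }
})

test_that("every simulated gene tree satisfies the MSC constraint", {
  set.seed(83)
  s <- msc_fixture(0.01)  # sizeable theta -> plenty of deep coalescence
  div <- matrix(0.04, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  div["A", "B"] <- div["B", "A"] <- 0.01
  diag(div) <- 0
  for (i in 1:30) {
    g <- simulate_gene_tree(s, c(A = 2, B = 2, C = 2), h = 1)
    sp <- attr(g, "species")
    tm <- ape::cophenetic.phylo(g) / 2   # pairwise TMRCA on an ultrametric tree
    for (x in rownames(tm)) for (y in colnames(tm)) {
      if (x != y) expect_gte(tm[x, y], div[sp[x], sp[y]] - 1e-9)
    }
  }
})

test_that("sequence simulation honours the model, rate and stationarity", {
  set.seed(84)
  g <- ape::read.tree(text = "(x:0.1,y:0.1);")
  # mu_rel = 0: identical sequences
  a0 <- simulate_alignment(g, sub_model("JC69"), length = 100, mu_rel = 0)
  expect_equal(length(unique(seq_strings(a0))), 1L)
  # JC expected p-distance at d = 0.2
  a <- simulate_alignment(g, sub_model("JC69"), length = 20000, mu_rel = 1)
  expect_equal(p_distance(seq_strings(a)[["x"]], seq_strings(a)[["y"]]),
               3 / 4 * (1 - exp(-4 * 0.2 / 3)), tolerance = 0.05)
  # base composition converges to the stationary frequencies
  bf <- c(0.4, 0.3, 0.2, 0.1)
  ab <- simulate_alignment(g, sub_model("GTR", base_freq = bf), length = 20000)
  freq <- table(factor(ab$seqs, levels = c("A", "C", "G", "T"))) / length(ab$seqs)
  expect_equal(as.numeric(freq), bf, tolerance = 0.03)
})

test_that("minimum inter-species distances match a brute-force scan", {
  set.seed(85)
  aln <- rand_aln(9, 40)
  smap <- setNames(rep(c("A", "B", "C"), each = 3), seq_labels(aln))
  res <- min_interspecies_distance(aln, smap)
  for (r in seq_len(nrow(res))) {
    ii <- names(smap)[smap == res$species1[r]]
    jj <- names(smap)[smap == res$species2[r]]
    best <- Inf
    for (x in ii) for (y in jj) {
      best <- min(best, p_distance(seq_strings(aln)[[x]], seq_strings(aln)[[y]]))
    }
    expect_equal(res$min_dist[r], best)
  }
  # a shared identical haplotype gives distance 0
  aln2 <- dna_alignment(c(a1 = "ACGT", b1 = "ACGT"))
  r2 <- min_interspecies_distance(aln2, c(a1 = "A", b1 = "B"))
  expect_equal(r2$min_dist, 0)
  expect_error(min_interspecies_distance(aln2, c(a1 = "A", b1 = "B"),
                                         pairs = cbind("A", "Z")), "absent")
})

test_that("posterior-predictive p-values behave at the extremes and monotonically", {
  set.seed(86)
  s <- msc_fixture(0.004)
  post <- make_pseudo_posterior(s, 40, 0.05, seed = 1)
  g <- simulate_gene_tree(s, c(A = 2, B = 2, C = 1), h = 1)
  obs <- simulate_alignment(g, sub_model("JC69"), length = 300)
  smap <- attr(g, "species")
  res <- posterior_predictive_test(post, obs, smap, seed = 2)
  expect_true(all(res$p >= 0 & res$p <= 1))
  expect_equal(attr(res, "n_sim"), 40L)
  expect_equal(res$flagged, res$p < 0.05)
  # an observation farther than every simulation: p = 1
  far <- dna_alignment(rbind(
    A_1 = rep("A", 300), A_2 = rep("A", 300),
    B_1 = rep("C", 300), B_2 = rep("C", 300), C_1 = rep("G", 300)))
  res_far <- posterior_predictive_test(post, far, smap, seed = 3)
  expect_true(all(res_far$p == 1))
  # burn-in and thinning
  expect_error(posterior_predictive_test(post, obs, smap, burn_in = 40), "zero")
  res_thin <- posterior_predictive_test(post, obs, smap, thinning = 10, seed = 4)
  expect_equal(attr(res_thin, "n_sim"), 4L)
  # p is monotone nondecreasing in the observed distance: shrinking one
  # pair's observed minimum (same seed, hence same simulations) cannot
  # raise its p-value
  near <- obs
  near$seqs["A_1", ] <- near$seqs["B_1", ]
  res_near <- posterior_predictive_test(post, near, smap, seed = 2)
  pick <- function(r) r$p[r$species1 == "A" & r$species2 == "B"]
  expect_lte(pick(res_near), pick(res))
})

test_that("the result writer mirrors the tabular format", {
  set.seed(87)
  s <- msc_fixture()
  post <- make_pseudo_posterior(s, 10, 0, seed = 1)
  g <- simulate_gene_tree(s, c(A = 1, B = 1), h = 1)
  obs <- simulate_alignment(g, length = 100)
  res <- posterior_predictive_test(post, obs, attr(g, "species"), seed = 5)
  f <- tempfile()
  write_hyb_test(res, f, gene = "cp")
  tab <- read.delim(f, check.names = FALSE)
  expect_equal(names(tab), c("Gene", "Individual 1", "Individual 2",
                             "Obs. Distance", "p-value"))
  expect_equal(tab$Gene[1], "cp")
})
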