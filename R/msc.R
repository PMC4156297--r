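#' Annotated species tree sample
#'
#' A rooted, ultrametric species tree with branch lengths in expected
#' substitutions per site, carrying one population-size parameter theta per
#' branch (including the stem above the root, which extends indefinitely).
#' Theta is parameterized as the mean pairwise within-branch coalescence
#' time in substitutions/site for a locus with heredity scalar 1 — the
#' convention of `dmv`-annotated trees written by Bayesian species-tree
#' software: a pair of lineages in a branch with parameter theta coalesces
#' at rate 1 / (theta * h).
#'
#' @param tree rooted `phylo` with branch lengths (ultrametric).
#' @param theta positive numeric: either a single value recycled to every
#'   branch, or a vector indexed by node number (1..Ntip+Nnode; entry i is
#'   the branch above node i, the root entry being the root stem).
#' @return a `species_tree_sample`.
#' @export
species_tree_sample <- function(tree, theta) {
  if (!inherits(tree, "phylo")) stop("tree must be a phylo")
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  n_nodes <- ape::Ntip(tree) + tree$Nnode
  if (length(theta) == 1L) theta <- rep(theta, n_nodes)
  if (length(theta) != n_nodes) {
    stop("theta must have one entry per node (", n_nodes, ")")
  }
  if (any(!is.finite(theta)) || any(theta <= 0)) stop("theta must be positive")
  structure(list(tree = tree, theta = as.numeric(theta)),
            class = "species_tree_sample")
}

#' @export
print.species_tree_sample <- function(x, ...) {
  cat("species tree sample:", ape::Ntip(x$tree), "species, height",
      signif(max(.node_heights(x$tree)), 4), "subst/site, theta range",
      paste(signif(range(x$theta), 3), collapse = "-"), "\n")
  invisible(x)
}

# node heights above the tips (requires ultrametric tips)
.node_heights <- function(tree) {
  depth <- ape::node.depth.edgelength(tree)
  max(depth) - depth
}

#' Simulate a gene tree under the multispecies coalescent
#'
#' Lineages sampled in the tip species coalesce within species-tree
#' branches at rate `k (k - 1) / (2 theta h)` for `k` lineages (so a pair
#' has expected coalescence time `theta * h`), are handed to the ancestral
#' branch at each speciation node, and finish in the root stem. Optional
#' hybridization pulses move each lineage present in the recipient species
#' at the event time to the donor species with probability `gamma` —
#' the simplest gene-flow mechanism a posterior-predictive distance test is
#' sensitive to. No migration occurs otherwise, so every coalescence
#' between lineages of two species is at least as old as their divergence.
#'
#' @param s a [species_tree_sample()].
#' @param samples_per_species named integer vector: tip species -> number
#'   of sampled lineages. Sample labels are `<species>_<i>`.
#' @param h heredity scalar of the locus (about 2 for biparental nuclear,
#'   1 for maternally inherited plastid markers in this parameterization).
#' @param events optional data.frame with columns `donor`, `recipient`,
#'   `time`, `gamma` describing hybridization pulses (times in
#'   substitutions/site above the tips).
#' @return a rooted `phylo` gene tree with coalescence-time branch lengths
#'   and a `species` attribute (named character: sample label -> species).
#' @export
simulate_gene_tree <- function(s, samples_per_species, h = 1, events = NULL) {
  tree <- s$tree
  tips <- tree$tip.label
  if (is.null(names(samples_per_species)) || length(samples_per_species) == 0L) {
    stop("samples_per_species must be a nonempty named vector")
  }
  bad <- setdiff(names(samples_per_species), tips)
  if (length(bad)) stop("unknown species: ", paste(bad, collapse = ", "))
  samples_per_species <- samples_per_species[samples_per_species > 0]
  if (!length(samples_per_species)) stop("no lineages to simulate")
  heights <- .node_heights(tree)
  ntip <- ape::Ntip(tree)
  root <- ntip + 1L
  parent <- rep(NA_integer_, ntip + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]

  # lineage registry: newick fragment + height + descendant tips per lineage
  frag <- list(); lin_h <- numeric(0); lin_id <- 0L
  tipset <- list()
  containers <- vector("list", ntip + tree$Nnode)  # node id -> lineage ids
  species_of <- character(0)
  moved_tips <- character(0)
  for (sp in names(samples_per_species)) {
    node <- match(sp, tips)
    n <- samples_per_species[[sp]]
    ids <- lin_id + seq_len(n)
    lin_id <- lin_id + n
    labs <- paste0(sp, "_", seq_len(n))
    for (k in seq_len(n)) {
      frag[[ids[k]]] <- labs[k]
      lin_h[ids[k]] <- 0
      tipset[[ids[k]]] <- labs[k]
    }
    containers[[node]] <- ids
    species_of[labs] <- sp
  }

  coalesce_in <- function(ids, theta_h, t0, t1) {
    # returns surviving lineage ids after running the coalescent in [t0,t1)
    t <- t0
    while (length(ids) >= 2L) {
      k <- length(ids)
      rate <- k * (k - 1) / (2 * theta_h)
      t <- t + stats::rexp(1L, rate)
      if (t >= t1) break
      pick <- sample.int(k, 2L)
      u <- ids[pick[1]]; v <- ids[pick[2]]
      lin_id <<- lin_id + 1L
      frag[[lin_id]] <<- sprintf("(%s:%.10g,%s:%.10g)", frag[[u]],
                                 t - lin_h[u], frag[[v]], t - lin_h[v])
      lin_h[lin_id] <<- t
      tipset[[lin_id]] <<- c(tipset[[u]], tipset[[v]])
      ids <- c(ids[-pick], lin_id)
    }
    ids
  }

  # species branch containing species `sp`'s ancestry at time t
  branch_at <- function(sp, t) {
    node <- match(sp, tips)
    while (!is.na(parent[node]) && heights[parent[node]] <= t) node <- parent[node]
    node
  }

  ev <- data.frame(time = heights[(ntip + 1L):(ntip + tree$Nnode)],
                   node = (ntip + 1L):(ntip + tree$Nnode),
                   type = "node", stringsAsFactors = FALSE)
  if (!is.null(events) && nrow(events)) {
    if (any(events$gamma < 0 | events$gamma > 1)) stop("gamma must be in [0,1]")
    if (any(events$time < 0 | events$time >= max(heights))) {
      stop("infeasible event time")
    }
    # null pulses must not perturb the RNG stream
    events <- events[events$gamma > 0 & events$donor != events$recipient, ,
                     drop = FALSE]
  }
  if (!is.null(events) && nrow(events)) {
    ev <- rbind(ev, data.frame(time = events$time, node = NA_integer_,
                               type = "hyb", stringsAsFactors = FALSE))
  }
  ev <- ev[order(ev$time), , drop = FALSE]
  hyb_i <- 0L

  t0 <- 0
  for (r in seq_len(nrow(ev))) {
    t1 <- ev$time[r]
    for (node in which(!vapply(containers, is.null, logical(1)))) {
      th <- s$theta[node] * h
      containers[[node]] <- coalesce_in(containers[[node]], th, t0, t1)
    }
    if (ev$type[r] == "node") {
      node <- ev$node[r]
      kids <- tree$edge[tree$edge[, 1] == node, 2]
      pooled <- unlist(containers[kids])
      containers[kids] <- list(NULL)
      if (length(pooled)) containers[[node]] <- pooled
    } else {
      hyb_i <- hyb_i + 1L
      e <- events[order(events$time), , drop = FALSE][hyb_i, ]
      from <- branch_at(e$recipient, t1)
      to <- branch_at(e$donor, t1)
      if (from != to && length(containers[[from]])) {
        move <- stats::runif(length(containers[[from]])) < e$gamma
        if (any(move)) {
          moved_tips <- c(moved_tips,
                          unlist(tipset[containers[[from]][move]]))
          containers[[to]] <- c(containers[[to]], containers[[from]][move])
          containers[[from]] <- containers[[from]][!move]
          if (!length(containers[[from]])) containers[from] <- list(NULL)
        }
      }
    }
    t0 <- t1
  }
  # root stem: coalesce everything that is left
  ids <- unlist(containers)
  surv <- coalesce_in(ids, s$theta[root] * h, t0, Inf)
  stopifnot(length(surv) == 1L)
  g <- ape::read.tree(text = paste0(frag[[surv]], ";"))
  attr(g, "species") <- species_of
  attr(g, "moved_tips") <- unique(moved_tips)
  g
}

#' Simulate an alignment along a gene tree
#'
#' Sites evolve independently under the given substitution model, with
#' branch durations multiplied by the locus-relative mutation rate.
#' Discrete-gamma site rates and invariant sites are drawn per site.
#'
#' @param g a `phylo` gene tree with branch lengths (substitutions/site).
#' @param model a [sub_model()]; `"empirical"` base frequencies fall back
#'   to equal (there is no data to count from).
#' @param length number of sites.
#' @param mu_rel relative mutation rate multiplier of the locus.
#' @return a [dna_alignment()] over the gene-tree tip labels.
#' @export
simulate_alignment <- function(g, model = sub_model("JC69"), length = 500L,
                               mu_rel = 1) {
  stopifnot(length >= 1L)
  bf <- if (is.numeric(model$base_freq)) model$base_freq else rep(0.25, 4)
  tr <- g
  tr$edge.length <- g$edge.length * mu_rel
  # per-site rate categories
  rates <- rep(1, length)
  if (!is.null(model$shape)) {
    cat_rates <- phangorn::discrete.gamma(model$shape, model$k)
    rates <- cat_rates[sample.int(model$k, length, replace = TRUE)]
  }
  if (model$p_inv > 0) {
    rates[stats::runif(length) < model$p_inv] <- 0
  }
  out <- matrix("A", nrow = ape::Ntip(tr), ncol = length,
                dimnames = list(tr$tip.label, NULL))
  zero <- rates == 0
  if (any(zero)) {
    bases <- sample(c("A", "C", "G", "T"), sum(zero), replace = TRUE, prob = bf)
    out[, zero] <- matrix(rep(bases, each = nrow(out)), nrow = nrow(out))
  }
  for (r in unique(rates[!zero])) {
    cols <- which(rates == r & !zero)
    sim <- phangorn::simSeq(tr, l = length(cols), Q = model$rates, bf = bf,
                            rate = r)
    chars <- toupper(as.character(sim))
    out[rownames(chars), cols] <- chars
  }
  dna_alignment(out)
}

#' Minimum inter-species sequence distances
#'
#' For each unordered pair of species, the minimum uncorrected p-distance
#' (see [p_distance()]) over all cross-species sequence pairs, with the
#' individual pair attaining it.
#'
#' @param aln a [dna_alignment()].
#' @param species_map named character vector: sequence label -> species.
#' @param pairs optional 2-column matrix/data.frame of species pairs to
#'   restrict to.
#' @return data.frame `species1`, `species2`, `min_dist`, `ind1`, `ind2`.
#' @export
min_interspecies_distance <- function(aln, species_map, pairs = NULL) {
  labs <- seq_labels(aln)
  species_map <- species_map[names(species_map) %in% labs]
  sps <- sort(unique(species_map))
  if (length(sps) < 2L) stop("need at least two species present in the alignment")
  if (is.null(pairs)) {
    pairs <- t(utils::combn(sps, 2L))
  } else {
    pairs <- as.matrix(pairs)
    absent <- setdiff(unique(as.vector(pairs)), sps)
    if (length(absent)) stop("species absent from alignment: ",
                             paste(absent, collapse = ", "))
  }
  D <- p_distance_matrix(aln[match(names(species_map), labs), ])
  out <- data.frame(species1 = pairs[, 1], species2 = pairs[, 2],
                    min_dist = NA_real_, ind1 = NA_character_,
                    ind2 = NA_character_, stringsAsFactors = FALSE)
  for (r in seq_len(nrow(pairs))) {
    i <- names(species_map)[species_map == pairs[r, 1]]
    j <- names(species_map)[species_map == pairs[r, 2]]
    sub <- D[i, j, drop = FALSE]
    k <- arrayInd(which.min(sub), dim(sub))
    out$min_dist[r] <- sub[k]
    out$ind1[r] <- i[k[1]]
    out$ind2[r] <- j[k[2]]
  }
  out
}

#' Posterior-predictive test for hybridization
#'
#' For each retained species tree of a posterior sample, one replicate
#' dataset is simulated under the multispecies coalescent without
#' migration (gene tree, then sequences with the locus model, relative
#' rate and heredity scalar), and the minimum inter-species distance is
#' recorded for every species pair. The posterior-predictive p-value of a
#' pair is the plain proportion of simulated minima less than or equal to
#' the observed minimum; pairs with p below `alpha` are flagged as
#' potential hybridization. Incomplete lineage sorting alone is accounted
#' for by the null model, so small observed distances flag gene flow.
#'
#' @param posterior list of [species_tree_sample()] objects.
#' @param observed a [dna_alignment()] of the locus being tested.
#' @param species_map named character vector: label -> species (labels not
#'   present in the alignment are ignored; species not in the species
#'   trees are an error).
#' @param model,mu_rel,h locus configuration: substitution model
#'   ([sub_model()]), relative mutation rate and heredity scalar.
#' @param burn_in number of leading posterior samples to discard.
#' @param thinning keep every `thinning`-th tree after burn-in.
#' @param seed optional integer seed.
#' @param alpha flagging level.
#' @return a `hyb_test_result` data.frame: `species1`, `species2`,
#'   `obs_min_dist`, `ind1`, `ind2`, `p`, `flagged`, sorted by `p`, with
#'   attribute `n_sim`.
#' @export
posterior_predictive_test <- function(posterior, observed, species_map,
                                      model = sub_model("JC69"), mu_rel = 1,
                                      h = 1, burn_in = 0L, thinning = 1L,
                                      seed = NULL, alpha = 0.05) {
  if (!length(posterior)) stop("empty posterior")
  keep <- seq_along(posterior)
  if (burn_in > 0L) keep <- keep[-seq_len(min(burn_in, length(keep)))]
  if (!length(keep)) stop("zero retained posterior samples")
  keep <- keep[seq(1L, length(keep), by = thinning)]
  if (!is.null(seed)) set.seed(seed)
  species_map <- species_map[names(species_map) %in% seq_labels(observed)]
  n_samples <- table(species_map)
  sps_tree <- posterior[[keep[1]]]$tree$tip.label
  absent <- setdiff(names(n_samples), sps_tree)
  if (length(absent)) stop("species not in the species trees: ",
                           paste(absent, collapse = ", "))
  obs <- min_interspecies_distance(observed, species_map)
  n_sim <- length(keep)
  sims <- matrix(0, nrow(obs), n_sim)
  spp <- stats::setNames(as.integer(n_samples), names(n_samples))
  for (b in seq_len(n_sim)) {
    g <- simulate_gene_tree(posterior[[keep[b]]], spp, h = h)
    a <- simulate_alignment(g, model, length = n_col(observed), mu_rel = mu_rel)
    gmap <- attr(g, "species")
    sim <- min_interspecies_distance(a, gmap)
    key <- paste(sim$species1, sim$species2)
    sims[, b] <- sim$min_dist[match(paste(obs$species1, obs$species2), key)]
  }
  obs$p <- rowMeans(sims <= obs$min_dist)
  obs$flagged <- obs$p < alpha
  names(obs)[names(obs) == "min_dist"] <- "obs_min_dist"
  obs <- obs[order(obs$p, obs$obs_min_dist), , drop = FALSE]
  rownames(obs) <- NULL
  attr(obs, "n_sim") <- n_sim
  class(obs) <- c("hyb_test_result", class(obs))
  obs
}

#' Write a hybridization test result table
#'
#' Tab-separated table with columns Gene, Individual 1, Individual 2,
#' Obs. Distance, p-value.
#'
#' @param result a `hyb_test_result`.
#' @param path output path.
#' @param gene locus name written in the Gene column.
#' @export
write_hyb_test <- function(result, path, gene = "locus") {
  tab <- data.frame(Gene = gene,
                    `Individual 1` = result$ind1,
                    `Individual 2` = result$ind2,
                    `Obs. Distance` = result$obs_min_dist,
                    `p-value` = result$p, check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
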