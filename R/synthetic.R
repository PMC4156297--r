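#' Mix two ribotypes into one IUPAC-coded consensus sequence
#'
#' Emulates direct sequencing of an individual carrying two intra-genomic
#' ribotypes of a multi-copy marker under partial concerted evolution: at
#' every site where the ribotypes differ, with probability `c` the site is
#' homogenized to one parent base (chosen uniformly), otherwise it is
#' written as the IUPAC code of the two bases. Identical sites are copied
#' through. `c = 0` gives a fully additive pattern, `c = 1` a completely
#' homogenized contig.
#'
#' @param ribotype_a,ribotype_b equal-length sequence strings.
#' @param c homogenization probability in `[0, 1]`.
#' @return a sequence string with IUPAC ambiguity codes at the retained
#'   heterozygous sites.
#' @export
apply_ribotype_mixing <- function(ribotype_a, ribotype_b, c = 0) {
  stopifnot(c >= 0, c <= 1)
  a <- strsplit(ribotype_a, "")[[1]]
  b <- strsplit(ribotype_b, "")[[1]]
  if (length(a) != length(b)) stop("ribotypes differ in length")
  out <- a
  diff <- which(a != b)
  for (j in diff) {
    if (stats::runif(1) < c) {
      out[j] <- if (stats::runif(1) < 0.5) a[j] else b[j]
    } else {
      out[j] <- iupac_unmask(bitwOr(iupac_mask(a[j]), iupac_mask(b[j])))
    }
  }
  paste(out, collapse = "")
}

#' Locus configuration for scenario generation
#'
#' @param model a [sub_model()].
#' @param length alignment length in sites.
#' @param mu_rel relative mutation rate of the locus.
#' @param h heredity scalar (2 biparental nuclear, 1 plastid).
#' @param ploidy lineages sampled per individual (2 for a nuclear
#'   multi-copy marker whose two ribotypes are observed as one IUPAC-coded
#'   consensus, 1 for a haploid plastid marker).
#' @return a `locus_config` list.
#' @export
locus_config <- function(model, length, mu_rel = 1, h = 1, ploidy = 1L) {
  stopifnot(length >= 1L, mu_rel >= 0, h > 0, ploidy %in% c(1L, 2L))
  structure(list(model = model, length = as.integer(length),
                 mu_rel = mu_rel, h = h, ploidy = as.integer(ploidy)),
            class = "locus_config")
}

.default_loci <- function() {
  list(
    nuclear = locus_config(sub_model("SYM", shape = 0.5), 653,
                           mu_rel = 1.016, h = 2, ploidy = 2L),
    plastid = locus_config(sub_model("TVM", rates = c(1, 2, 1.5, 0.8, 2, 1),
                                     shape = 0.3, p_inv = 0.5), 960,
                           mu_rel = 0.385, h = 1, ploidy = 1L)
  )
}

#' Generate a complete synthetic two-locus study with known truth
#'
#' Draws a pure-birth ingroup species tree, attaches a divergent outgroup,
#' assigns per-branch population sizes, simulates per-locus gene trees
#' under the multispecies coalescent (optionally with hybridization
#' pulses) and sequences under the locus models, and — for the nuclear
#' locus — collapses each individual's two allele sequences into one
#' IUPAC-coded consensus with tunable concerted-evolution homogenization.
#' The same seed yields a byte-identical bundle.
#'
#' @param n_species number of ingroup species.
#' @param birth_rate pure-birth speciation rate (shapes the ingroup tree;
#'   heights are rescaled to `tree_height`).
#' @param tree_height ingroup crown height in substitutions/site.
#' @param outgroup_stem extra stem depth of the outgroup above the ingroup
#'   crown (substitutions/site).
#' @param theta_range range from which per-branch theta values are drawn
#'   uniformly.
#' @param loci named list of [locus_config()]s; the default pair emulates a
#'   fast biparental nuclear ribosomal locus (653 sites, relative rate
#'   1.016, heredity scalar 2) and a slower plastid spacer (960 sites,
#'   relative rate 0.385, heredity scalar 1).
#' @param samples_per_species named integer vector of individuals per
#'   species, or NULL to draw uneven sizes (1-8 per ingroup species, 2 for
#'   the outgroup).
#' @param hybridization optional data.frame `donor`, `recipient`, `time`,
#'   `gamma` of gene-flow pulses (applied to every locus).
#' @param homogenization concerted-evolution probability `c` applied to
#'   nuclear allele pairs.
#' @param seed integer seed; every random choice derives from it.
#' @return a `truth_bundle`: list with `species_tree`
#'   ([species_tree_sample()]), `gene_trees`, `alignments` (per locus;
#'   [dna_alignment()] with taxon map), `species_map`, `loci`,
#'   `hybrid_individuals` (per locus), `mixed_individuals` (data.frame
#'   `label`, `distance` and the two parental `ribotype_a`, `ribotype_b`),
#'   and `config`.
#' @export
generate_scenario <- function(n_species = 6L, birth_rate = 1, tree_height = 0.012,
                              outgroup_stem = 0.08,
                              theta_range = c(0.002, 0.006),
                              loci = .default_loci(),
                              samples_per_species = NULL,
                              hybridization = NULL,
                              homogenization = 0.5,
                              seed = 1L) {
  stopifnot(n_species >= 1L, homogenization >= 0, homogenization <= 1)
  set.seed(seed)
  # ingroup pure-birth tree rescaled to the target crown height
  if (n_species >= 2L) {
    ing <- ape::rphylo(n_species, birth_rate, 0)
    ing$tip.label <- paste0("sp", seq_len(n_species))
    ing$edge.length <- ing$edge.length * tree_height /
      max(ape::node.depth.edgelength(ing))
    ing_nwk <- ape::write.tree(ing)
    ing_nwk <- sub(";$", "", ing_nwk)
  } else {
    ing_nwk <- paste0("sp1:", tree_height)
  }
  root_h <- tree_height + outgroup_stem
  nwk <- if (n_species >= 2L) {
    sprintf("(%s:%.10g,out1:%.10g);", ing_nwk, outgroup_stem, root_h)
  } else {
    sprintf("(sp1:%.10g,out1:%.10g);", root_h, root_h)
  }
  sp_tree <- ape::read.tree(text = nwk)
  n_nodes <- ape::Ntip(sp_tree) + sp_tree$Nnode
  theta <- stats::runif(n_nodes, theta_range[1], theta_range[2])
  st <- species_tree_sample(sp_tree, theta)

  species <- sp_tree$tip.label
  if (is.null(samples_per_species)) {
    samples_per_species <- stats::setNames(
      c(sample(1:8, n_species, replace = TRUE), 2L), species)
  } else {
    stopifnot(all(names(samples_per_species) %in% species))
    samples_per_species <- samples_per_species[
      intersect(species, names(samples_per_species))]
  }

  gene_trees <- list(); alignments <- list()
  hybrid_individuals <- list()
  mixed <- data.frame(label = character(0), distance = integer(0),
                      ribotype_a = character(0), ribotype_b = character(0),
                      stringsAsFactors = FALSE)
  species_map <- character(0)
  for (sp in names(samples_per_species)) {
    labs <- paste0(sp, "_", seq_len(samples_per_species[[sp]]))
    species_map[labs] <- sp
  }
  tmap <- data.frame(label = names(species_map),
                     taxon = unname(species_map),
                     ingroup = !grepl("^out", species_map),
                     population = unname(species_map),
                     stringsAsFactors = FALSE)

  for (loc in names(loci)) {
    cfg <- loci[[loc]]
    lineages <- samples_per_species * cfg$ploidy
    g <- simulate_gene_tree(st, lineages, h = cfg$h, events = hybridization)
    raw <- simulate_alignment(g, cfg$model, length = cfg$length,
                              mu_rel = cfg$mu_rel)
    if (cfg$ploidy == 2L) {
      # two alleles per individual -> one IUPAC consensus sequence
      seqs <- character(0)
      strs <- seq_strings(raw)
      for (sp in names(samples_per_species)) {
        for (j in seq_len(samples_per_species[[sp]])) {
          a <- strs[[paste0(sp, "_", 2L * j - 1L)]]
          b <- strs[[paste0(sp, "_", 2L * j)]]
          lab <- paste0(sp, "_", j)
          d <- sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
          if (d > 0L) {
            mixed <- rbind(mixed, data.frame(
              label = lab, distance = d, ribotype_a = a, ribotype_b = b,
              stringsAsFactors = FALSE))
          }
          seqs[lab] <- apply_ribotype_mixing(a, b, homogenization)
        }
      }
      aln <- dna_alignment(seqs)
      hyb_ind <- unique(vapply(attr(g, "moved_tips"), function(x) {
        i <- as.integer(sub(".*_", "", x))
        paste0(sub("_[0-9]+$", "", x), "_", ceiling(i / 2))
      }, character(1)))
    } else {
      aln <- raw[match(names(species_map), seq_labels(raw)), ]
      hyb_ind <- attr(g, "moved_tips")
    }
    aln <- set_taxon_map(aln, tmap)
    gene_trees[[loc]] <- g
    alignments[[loc]] <- aln
    hybrid_individuals[[loc]] <- unname(hyb_ind)
  }

  structure(list(species_tree = st, gene_trees = gene_trees,
                 alignments = alignments, species_map = species_map,
                 loci = loci, hybrid_individuals = hybrid_individuals,
                 mixed_individuals = mixed,
                 config = list(n_species = n_species, birth_rate = birth_rate,
                               tree_height = tree_height,
                               outgroup_stem = outgroup_stem,
                               theta_range = theta_range,
                               samples_per_species = samples_per_species,
                               hybridization = hybridization,
                               homogenization = homogenization, seed = seed)),
            class = "truth_bundle")
}

#' @export
print.truth_bundle <- function(x, ...) {
  cat("synthetic study:", ape::Ntip(x$species_tree$tree), "species,",
      length(x$species_map), "individuals,", length(x$alignments), "loci\n")
  cat("mixed individuals:", nrow(x$mixed_individuals),
      " hybrid-affected:", length(unique(unlist(x$hybrid_individuals))), "\n")
  invisible(x)
}

#' Pseudo-posterior of species trees around a truth
#'
#' Stands in for a Bayesian species-tree posterior sample: each draw copies
#' the true topology, rescales all node heights by one multiplicative
#' lognormal factor (preserving ultrametricity) and perturbs every branch
#' theta by an independent lognormal factor. Factors use `meanlog =
#' -jitter^2/2` so their expectation is 1 and sampled theta means converge
#' to the truth.
#'
#' @param truth a [species_tree_sample()].
#' @param n_samples number of draws.
#' @param jitter relative standard deviation (lognormal sdlog); 0 gives
#'   exact copies.
#' @param seed optional integer seed.
#' @return list of [species_tree_sample()] objects.
#' @export
make_pseudo_posterior <- function(truth, n_samples, jitter = 0.1, seed = NULL) {
  stopifnot(jitter >= 0, n_samples >= 1L)
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(n_samples), function(i) {
    tr <- truth$tree
    f <- stats::rlnorm(1, -jitter^2 / 2, jitter)
    tr$edge.length <- tr$edge.length * f
    th <- truth$theta * stats::rlnorm(length(truth$theta), -jitter^2 / 2, jitter)
    species_tree_sample(tr, th)
  })
}

#' Write a truth bundle to plain-text files
#'
#' Writes per-locus FASTA alignments and Newick gene trees, the annotated
#' species tree, the taxon map and a tab-separated truth manifest (mixed
#' and hybrid-affected individuals) into a directory.
#'
#' @param bundle a `truth_bundle`.
#' @param dir output directory.
#' @return vector of written paths, invisibly.
#' @export
write_truth_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (loc in names(bundle$alignments)) {
    p <- file.path(dir, paste0(loc, ".fasta"))
    write_alignment(bundle$alignments[[loc]], p, "fasta")
    pt <- file.path(dir, paste0(loc, "_genetree.nwk"))
    ape::write.tree(bundle$gene_trees[[loc]], pt)
    paths <- c(paths, p, pt)
  }
  pst <- file.path(dir, "species_tree.nex")
  write_species_trees(bundle$species_tree, pst)
  ptm <- file.path(dir, "taxon_map.tsv")
  write_taxon_map(bundle$alignments[[1]]$taxon_map, ptm)
  pmf <- file.path(dir, "truth_manifest.tsv")
  man <- rbind(
    if (nrow(bundle$mixed_individuals)) {
      data.frame(kind = "mixed", label = bundle$mixed_individuals$label,
                 detail = bundle$mixed_individuals$distance)
    },
    if (length(unlist(bundle$hybrid_individuals))) {
      data.frame(kind = "hybrid",
                 label = unique(unlist(bundle$hybrid_individuals)),
                 detail = NA)
    })
  if (is.null(man)) man <- data.frame(kind = character(0), label = character(0),
                                      detail = character(0))
  utils::write.table(man, pmf, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(paths, pst, ptm, pmf))
}
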