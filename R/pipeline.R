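#' Pipeline configuration
#'
#' Assembles and validates the configuration for [run_report()]. Inputs
#' may be file paths (read with [read_alignment()] /
#' [read_species_trees()]) or in-memory objects.
#'
#' @param nuclear,plastid the two locus alignments (paths or
#'   [dna_alignment()]s); either may be NULL, but stages that need a
#'   missing input are errors.
#' @param taxon_map path or data.frame (see [read_taxon_map()]); attached
#'   to both alignments.
#' @param posterior path to an annotated species-tree sample file or a
#'   list of [species_tree_sample()]s (needed by the `hybtest` stage).
#' @param out_dir output directory for stage tables.
#' @param stages character vector of enabled stages, from: `polymorphism`,
#'   `split`, `parsimony`, `ild`, `spectrum`, `network`, `topotest`,
#'   `hybtest`.
#' @param scope label scope for polymorphism analysis (`"ingroup"` or
#'   `"all"`).
#' @param tcs_limit connection limit of the haplotype network.
#' @param ild_reps,bootstrap_reps,rell_reps replicate counts.
#' @param mp_starts random-addition starts for parsimony searches.
#' @param burn_in,thinning posterior handling for the hybridization test.
#' @param alpha flagging level for the hybridization test.
#' @param hyb_locus which locus the hybridization test simulates
#'   (`"plastid"` or `"nuclear"`).
#' @param hyb_model,hyb_mu_rel,hyb_h locus simulation configuration.
#' @param splits named list of splits for the spectrum stage (each a list
#'   with `ingroup`/`outgroup` label vectors); NULL uses the taxon map's
#'   ingroup/outgroup partition.
#' @param constraints named list of clade constraints (character vectors of
#'   labels) for the topology-test stage.
#' @param seed master seed; each stage derives its own RNG stream from it
#'   and the stage name, so toggling stages does not shift randomness.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(nuclear = NULL, plastid = NULL, taxon_map = NULL,
                            posterior = NULL, out_dir = tempfile("report"),
                            stages = c("polymorphism", "split", "parsimony",
                                       "ild", "spectrum", "network"),
                            scope = c("ingroup", "all"), tcs_limit = 30L,
                            ild_reps = 99L, bootstrap_reps = 0L,
                            rell_reps = 1000L, mp_starts = 5L,
                            burn_in = 0L, thinning = 1L, alpha = 0.05,
                            hyb_locus = c("plastid", "nuclear"),
                            hyb_model = sub_model("JC69"), hyb_mu_rel = 1,
                            hyb_h = 1, splits = NULL, constraints = NULL,
                            seed = 1L) {
  scope <- match.arg(scope)
  hyb_locus <- match.arg(hyb_locus)
  known <- c("polymorphism", "split", "parsimony", "ild", "spectrum",
             "network", "topotest", "hybtest")
  bad <- setdiff(stages, known)
  if (length(bad)) stop("unknown stages: ", paste(bad, collapse = ", "))
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0,1)")
  for (p in list(nuclear, plastid, taxon_map, posterior)) {
    if (is.character(p) && length(p) == 1L && !file.exists(p)) {
      stop("config error: file not found: ", p)
    }
  }
  if ("hybtest" %in% stages && is.null(posterior)) {
    stop("config error: hybtest stage enabled but no posterior given")
  }
  structure(list(nuclear = nuclear, plastid = plastid, taxon_map = taxon_map,
                 posterior = posterior, out_dir = out_dir, stages = stages,
                 scope = scope, tcs_limit = tcs_limit, ild_reps = ild_reps,
                 bootstrap_reps = bootstrap_reps, rell_reps = rell_reps,
                 mp_starts = mp_starts, burn_in = burn_in,
                 thinning = thinning, alpha = alpha, hyb_locus = hyb_locus,
                 hyb_model = hyb_model, hyb_mu_rel = hyb_mu_rel,
                 hyb_h = hyb_h, splits = splits, constraints = constraints,
                 seed = seed),
            class = "pipeline_config")
}

# independent, stable RNG stream per stage
.stage_seed <- function(master, stage) {
  (as.integer(master) * 2654435L + sum(utf8ToInt(stage)) * 97L) %% 2147483647L
}

.load_aln <- function(x, taxon_map) {
  if (is.null(x)) return(NULL)
  aln <- if (is.character(x)) read_alignment(x) else x
  if (!is.null(taxon_map)) {
    tm <- if (is.character(taxon_map)) read_taxon_map(taxon_map) else taxon_map
    aln <- set_taxon_map(aln, tm)
  }
  aln
}

#' Run the discordance-diagnosis workflow
#'
#' Executes the enabled stages in dependency order — polymorphism
#' detection, APS-based dataset splitting, parsimony statistics, the ILD
#' test, supporting-position spectra, the haplotype network, RELL topology
#' tests and the posterior-predictive hybridization test — writing one
#' tab-separated table per stage plus a plain-text summary into the
#' configured output directory. A failing stage is recorded and its
#' dependents are skipped; unrelated stages still run.
#'
#' @param cfg a [pipeline_config()].
#' @return a `pipeline_report` list with per-stage results, `errors`
#'   (named list of condition messages) and `out_dir`; written files are
#'   deterministic given the config and seed.
#' @export
run_report <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- list(errors = list(), out_dir = cfg$out_dir)
  on_stage <- function(name) name %in% cfg$stages
  fail <- function(name, e) res$errors[[name]] <<- conditionMessage(e)

  nuc <- tryCatch(.load_aln(cfg$nuclear, cfg$taxon_map),
                  error = function(e) { fail("input", e); NULL })
  pla <- tryCatch(.load_aln(cfg$plastid, cfg$taxon_map),
                  error = function(e) { fail("input", e); NULL })

  need <- function(x, what) if (is.null(x)) stop(what, " input required") else x

  if (on_stage("polymorphism")) {
    res$polymorphism <- tryCatch({
      aln <- need(nuc, "nuclear")
      scope <- if (cfg$scope == "ingroup") ingroup_labels(aln) else seq_labels(aln)
      rep <- classify_aps(detect_ips(aln, scope), aln)
      write_polymorphism_report(rep, cfg$out_dir)
      rep
    }, error = function(e) { fail("polymorphism", e); NULL })
  }

  nuc_free <- nuc
  if (on_stage("split")) {
    res$split <- tryCatch({
      rep <- if (!is.null(res$polymorphism)) res$polymorphism else
        stop("polymorphism stage required")
      sp <- split_by_aps(need(nuc, "nuclear"), rep)
      write_alignment(sp$aps_free, file.path(cfg$out_dir, "aps_free.fasta"), "fasta")
      if (n_seq(sp$aps_bearing) > 0L) {
        write_alignment(sp$aps_bearing,
                        file.path(cfg$out_dir, "aps_bearing.fasta"), "fasta")
      }
      sp
    }, error = function(e) { fail("split", e); NULL })
    if (!is.null(res$split)) nuc_free <- res$split$aps_free
  }

  if (on_stage("parsimony")) {
    res$parsimony <- tryCatch({
      set.seed(.stage_seed(cfg$seed, "parsimony"))
      out <- list()
      sets <- list()
      if (!is.null(nuc_free)) sets$nuclear <- nuc_free
      if (!is.null(pla)) sets$plastid <- pla
      if (!is.null(nuc_free) && !is.null(pla)) {
        # pair each APS-free nuclear sequence with its plastid counterpart
        common <- intersect(seq_labels(nuc_free), seq_labels(pla))
        sets$concatenated <- concatenate_alignments(
          nuc_free[match(common, seq_labels(nuc_free)), ],
          pla[match(common, seq_labels(pla)), ])
      }
      for (nm in names(sets)) {
        aln <- sets[[nm]]
        mg <- merge_identical(aln)$alignment
        if (n_seq(mg) < 4L || classify_sites(mg)$n_variable == 0L) {
          out[[nm]] <- list(skipped = sprintf(
            "%d distinct sequences, %d variable sites", n_seq(mg),
            classify_sites(mg)$n_variable))
          next
        }
        s <- mp_search(mg, n_starts = cfg$mp_starts,
                       exhaustive = n_seq(mg) <= 7L)
        write_parsimony_report(mg, s,
                               file.path(cfg$out_dir, paste0("parsimony_", nm, ".tsv")))
        out[[nm]] <- list(search = s, stats = ci_ri(s$trees[[1]], mg))
      }
      out
    }, error = function(e) { fail("parsimony", e); NULL })
  }

  if (on_stage("ild")) {
    res$ild <- tryCatch({
      a <- need(nuc_free, "nuclear"); b <- need(pla, "plastid")
      common <- intersect(seq_labels(a), seq_labels(b))
      a <- a[match(common, seq_labels(a)), ]
      b <- b[match(common, seq_labels(b)), ]
      cc <- concatenate_alignments(a, b)
      mg <- merge_identical(cc)$alignment
      it <- ild_test(mg, seq_len(n_col(a)), n_col(a) + seq_len(n_col(b)),
                     n_reps = cfg$ild_reps,
                     seed = .stage_seed(cfg$seed, "ild"))
      writeLines(c(sprintf("D_obs\t%g", it$D_obs), sprintf("p\t%g", it$p)),
                 file.path(cfg$out_dir, "ild.tsv"))
      it
    }, error = function(e) { fail("ild", e); NULL })
  }

  if (on_stage("spectrum")) {
    res$spectrum <- tryCatch({
      aln <- need(nuc_free, "nuclear")
      splits <- cfg$splits
      if (is.null(splits)) {
        ing <- ingroup_labels(aln)
        outg <- setdiff(seq_labels(aln), ing)
        if (!length(outg)) stop("no outgroup labels for the default split")
        splits <- list(ingroup_vs_outgroup = list(ingroup = ing, outgroup = outg))
      }
      tab <- spectrum_table(aln, splits)
      write_spectrum_table(tab, file.path(cfg$out_dir, "spectrum.tsv"))
      tab
    }, error = function(e) { fail("spectrum", e); NULL })
  }

  if (on_stage("network")) {
    res$network <- tryCatch({
      aln <- need(pla, "plastid")
      haps <- collapse_haplotypes(aln, scope = if (cfg$scope == "ingroup")
        ingroup_labels(aln) else NULL)
      net <- build_parsimony_network(haps, limit = cfg$tcs_limit)
      export_network(net, file.path(cfg$out_dir, "network_nodes.tsv"), "node-table")
      export_network(net, file.path(cfg$out_dir, "network.dot"), "dot")
      net
    }, error = function(e) { fail("network", e); NULL })
  }

  if (on_stage("topotest")) {
    res$topotest <- tryCatch({
      aln <- merge_identical(need(nuc_free, "nuclear"))$alignment
      if (is.null(cfg$constraints)) stop("topotest requires constraints")
      set.seed(.stage_seed(cfg$seed, "topotest"))
      trees <- list(best = constrained_search(aln, NULL,
                                              n_starts = cfg$mp_starts,
                                              exhaustive = n_seq(aln) <= 7L))
      for (nm in names(cfg$constraints)) {
        trees[[nm]] <- constrained_search(aln, cfg$constraints[nm],
                                          n_starts = cfg$mp_starts,
                                          exhaustive = n_seq(aln) <= 7L)
      }
      rep <- topology_test_report(aln, trees, n_boot = cfg$rell_reps,
                                  seed = .stage_seed(cfg$seed, "rell"))
      utils::write.table(rep$table, file.path(cfg$out_dir, "topotest.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      rep
    }, error = function(e) { fail("topotest", e); NULL })
  }

  if (on_stage("hybtest")) {
    res$hybtest <- tryCatch({
      post <- cfg$posterior
      if (is.character(post)) post <- read_species_trees(post)
      aln <- if (cfg$hyb_locus == "plastid") need(pla, "plastid") else
        need(nuc, "nuclear")
      if (is.null(aln$taxon_map)) stop("hybtest requires a taxon map")
      smap <- stats::setNames(aln$taxon_map$taxon, aln$taxon_map$label)
      ht <- posterior_predictive_test(
        post, aln, smap, model = cfg$hyb_model, mu_rel = cfg$hyb_mu_rel,
        h = cfg$hyb_h, burn_in = cfg$burn_in, thinning = cfg$thinning,
        seed = .stage_seed(cfg$seed, "hybtest"), alpha = cfg$alpha)
      write_hyb_test(ht, file.path(cfg$out_dir, "hybtest.tsv"),
                     gene = cfg$hyb_locus)
      ht
    }, error = function(e) { fail("hybtest", e); NULL })
  }

  # summary
  lines <- c("discordance report", paste("stages:", paste(cfg$stages, collapse = ", ")))
  if (!is.null(res$polymorphism)) {
    lines <- c(lines, sprintf("polymorphic columns: %d  APS columns: %d",
                              nrow(res$polymorphism$columns),
                              sum(res$polymorphism$columns$aps)))
  }
  if (!is.null(res$ild)) lines <- c(lines, sprintf("ILD p = %g", res$ild$p))
  if (!is.null(res$network)) {
    s <- network_summary(res$network)
    lines <- c(lines, sprintf("haplotypes: %d (%d components)",
                              s$n_sampled, s$n_components))
  }
  if (!is.null(res$hybtest)) {
    fl <- res$hybtest[res$hybtest$flagged, , drop = FALSE]
    lines <- c(lines, sprintf("flagged species pairs (p < %g): %s", cfg$alpha,
                              if (nrow(fl)) paste(fl$species1, fl$species2,
                                                  sep = "-", collapse = ", ")
                              else "none"))
  }
  if (length(res$errors)) {
    lines <- c(lines, paste("stage errors:",
                            paste(names(res$errors), collapse = ", ")))
  }
  writeLines(lines, file.path(cfg$out_dir, "summary.txt"))
  class(res) <- "pipeline_report"
  res
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(readLines(file.path(x$out_dir, "summary.txt")), sep = "\n")
  invisible(x)
}

# published reference values for the original ITS/cpDNA study datasets
.reference_values <- function() {
  data.frame(
    dataset = c("ITS_1", "ITS_1", "ITS_1", "ITS_1",
                "ITS_2", "ITS_2", "ITS_2",
                "cpDNA", "cpDNA", "cpDNA", "cpDNA", "cpDNA", "cpDNA",
                "ITS_cpDNA"),
    statistic = c("n_sequences", "n_columns", "n_variable", "n_informative",
                  "n_polymorphic_columns", "n_aps_columns", "max_ips",
                  "n_sequences", "n_merged", "n_columns", "n_variable",
                  "n_informative", "n_ingroup_haplotypes",
                  "n_columns"),
    expected = c(117, 653, 167, 138,
                 148, 42, 16,
                 219, 112, 960, 101, 60, 34,
                 1613),
    stringsAsFactors = FALSE)
}

#' Recompute benchmark statistics from the original supplementary alignments
#'
#' When the original study's supplementary alignment files are available
#' locally (as `ITS_1`, `ITS_2`, `cpDNA` and `ITS_cpDNA` files in FASTA,
#' NEXUS or relaxed PHYLIP format), recomputes the headline dataset
#' statistics — sequence counts, alignment widths, variable/informative
#' sites, polymorphic and APS column counts, merged sequence and ingroup
#' haplotype counts — and tabulates them against the published reference
#' values. Missing files are reported as skipped rows rather than errors.
#'
#' @param dir directory containing the alignment files (basenames matched
#'   case-insensitively against the dataset names).
#' @param taxon_map optional taxon map path or data.frame; without it,
#'   scope-dependent statistics use all sequences.
#' @param tcs_limit connection limit for the haplotype count.
#' @return data.frame `dataset`, `statistic`, `expected`, `computed`,
#'   `match` (NA where skipped).
#' @export
validate_against_supplementary <- function(dir, taxon_map = NULL,
                                           tcs_limit = 30L) {
  ref <- .reference_values()
  ref$computed <- NA_real_
  find_file <- function(ds) {
    files <- list.files(dir, full.names = TRUE)
    hit <- files[grepl(paste0("^", ds, "\\."), basename(files),
                       ignore.case = TRUE)]
    if (length(hit)) hit[1] else NULL
  }
  alns <- list()
  for (ds in unique(ref$dataset)) {
    f <- find_file(ds)
    if (!is.null(f)) {
      alns[[ds]] <- tryCatch(read_alignment(f, taxon_map = taxon_map),
                             error = function(e) NULL)
    }
  }
  for (r in seq_len(nrow(ref))) {
    ds <- ref$dataset[r]; aln <- alns[[ds]]
    if (is.null(aln)) next
    ref$computed[r] <- switch(ref$statistic[r],
      n_sequences = n_seq(aln),
      n_columns = n_col(aln),
      n_variable = classify_sites(aln)$n_variable,
      n_informative = classify_sites(aln)$n_informative,
      n_merged = n_seq(merge_identical(aln)$alignment),
      n_polymorphic_columns = nrow(detect_ips(aln)$columns),
      n_aps_columns = sum(classify_aps(detect_ips(aln), aln)$columns$aps),
      max_ips = max(detect_ips(aln)$per_sequence$n_ips),
      n_ingroup_haplotypes = nrow(collapse_haplotypes(
        aln, scope = ingroup_labels(aln))$table),
      NA_real_)
  }
  ref$match <- ifelse(is.na(ref$computed), NA, ref$computed == ref$expected)
  ref
}
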