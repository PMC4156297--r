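#' Read an alignment from FASTA, NEXUS or relaxed PHYLIP
#'
#' FASTA is read with \pkg{seqinr}, relaxed (whitespace-separated) PHYLIP
#' with \pkg{phangorn}, and NEXUS DATA blocks with \pkg{ape}. `charset`
#' statements in a NEXUS SETS (or ASSUMPTIONS) block populate the
#' alignment's partitions; NEXUS ranges are 1-based inclusive and are kept
#' in that convention. Labels are preserved verbatim; `U` is normalised to
#' `T`.
#'
#' @param path file path.
#' @param format one of `"fasta"`, `"nexus"`, `"phylip-relaxed"`; the
#'   default `"auto"` guesses from the file extension (.fa/.fasta/.fas ->
#'   fasta, .nex/.nexus -> nexus, .phy/.phylip -> phylip-relaxed).
#' @param taxon_map optional path to a taxon map file (see
#'   [read_taxon_map()]) or a taxon map data.frame.
#' @return a [dna_alignment()].
#' @export
read_alignment <- function(path, format = c("auto", "fasta", "nexus", "phylip-relaxed"),
                           taxon_map = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(sub(".*\\.", "", path))
    format <- switch(ext,
      fa = , fasta = , fas = "fasta",
      nex = , nexus = "nexus",
      phy = , phylip = "phylip-relaxed",
      stop("cannot guess alignment format from extension '.", ext, "'"))
  }
  if (!file.exists(path)) stop("file not found: ", path)
  parts <- NULL
  if (format == "fasta") {
    recs <- seqinr::read.fasta(path, forceDNAtolower = FALSE, as.string = FALSE)
    labs <- names(recs)
    lens <- lengths(recs)
    if (length(unique(lens)) > 1L) {
      stop("alignment-shape error: sequence lengths differ (",
           paste(unique(lens), collapse = ", "), ")")
    }
    seqs <- do.call(rbind, lapply(recs, as.character))
    rownames(seqs) <- labs
  } else if (format == "phylip-relaxed") {
    d <- phangorn::read.phyDat(path, format = "sequential", type = "DNA")
    seqs <- as.character(d)
  } else {
    recs <- ape::read.nexus.data(path)
    lens <- lengths(recs)
    if (length(unique(lens)) > 1L) {
      stop("alignment-shape error: sequence lengths differ (",
           paste(unique(lens), collapse = ", "), ")")
    }
    seqs <- do.call(rbind, recs)
    rownames(seqs) <- names(recs)
    parts <- .parse_nexus_charsets(path)
  }
  aln <- dna_alignment(seqs, partitions = parts)
  if (!is.null(taxon_map)) {
    if (is.character(taxon_map)) taxon_map <- read_taxon_map(taxon_map)
    aln <- set_taxon_map(aln, taxon_map)
  }
  aln
}

# charset NAME = a-b [c-d ...];  (1-based inclusive; only contiguous ranges
# are supported, matching the partition model)
.parse_nexus_charsets <- function(path) {
  txt <- readLines(path, warn = FALSE)
  hits <- grep("^\\s*charset\\s", txt, ignore.case = TRUE, value = TRUE)
  if (!length(hits)) return(NULL)
  parts <- list()
  for (h in hits) {
    h <- sub(";.*$", "", h)
    nm <- sub("^\\s*charset\\s+([^=\\s]+)\\s*=.*$", "\\1", h,
              ignore.case = TRUE, perl = TRUE)
    rng <- sub("^[^=]*=\\s*", "", h)
    m <- regmatches(rng, regexec("^\\s*(\\d+)\\s*-\\s*(\\d+)\\s*$", rng))[[1]]
    if (length(m) == 3L) {
      parts[[nm]] <- c(as.integer(m[2]), as.integer(m[3]))
    } else if (grepl("^\\s*\\d+\\s*$", rng)) {
      parts[[nm]] <- rep(as.integer(trimws(rng)), 2L)
    } else {
      warning("charset '", nm, "' is not a contiguous range; skipped")
    }
  }
  if (length(parts)) parts else NULL
}

#' Write an alignment to FASTA, NEXUS or relaxed PHYLIP
#'
#' The NEXUS writer emits a DATA block and, when the alignment has
#' partitions, a SETS block with one `charset` per partition, so that
#' [read_alignment()] round-trips entries and partitions.
#'
#' @param aln a [dna_alignment()].
#' @param path output file path.
#' @param format `"fasta"`, `"nexus"` or `"phylip-relaxed"`.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path, format = c("fasta", "nexus", "phylip-relaxed")) {
  format <- match.arg(format)
  strs <- seq_strings(aln)
  if (format == "fasta") {
    writeLines(paste0(">", names(strs), "\n", strs), path)
  } else if (format == "phylip-relaxed") {
    writeLines(c(paste(length(strs), n_col(aln)),
                 paste(names(strs), strs)), path)
  } else {
    lines <- c(
      "#NEXUS",
      "BEGIN DATA;",
      sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;", n_seq(aln), n_col(aln)),
      "  FORMAT DATATYPE=DNA MISSING=? GAP=- INTERLEAVE=NO;",
      "  MATRIX",
      sprintf("    %s  %s", names(strs), strs),
      "  ;",
      "END;")
    if (length(aln$partitions)) {
      lines <- c(lines, "BEGIN SETS;",
                 sprintf("  charset %s = %d-%d;", names(aln$partitions),
                         vapply(aln$partitions, `[`, 1L, 1),
                         vapply(aln$partitions, `[`, 1L, 2)),
                 "END;")
    }
    writeLines(lines, path)
  }
  invisible(path)
}

#' Read / write a taxon map
#'
#' A taxon map is a tab-separated file with 3 or 4 columns: label, taxon,
#' ingroup flag (`in` / `out`) and optionally a population code.
#'
#' @param path file path.
#' @return data.frame with columns `label`, `taxon`, `ingroup` (logical)
#'   and `population` (if present).
#' @export
read_taxon_map <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, quote = "",
                           comment.char = "#")
  if (ncol(tab) < 3L) stop("taxon map needs >= 3 tab-separated columns")
  names(tab)[1:3] <- c("label", "taxon", "ingroup")
  if (ncol(tab) >= 4L) names(tab)[4] <- "population"
  bad <- !tab$ingroup %in% c("in", "out")
  if (any(bad)) stop("ingroup flag must be 'in' or 'out'; got: ",
                     paste(unique(tab$ingroup[bad]), collapse = ", "))
  tab$ingroup <- tab$ingroup == "in"
  tab
}

#' @rdname read_taxon_map
#' @param taxon_map data.frame as returned by [read_taxon_map()].
#' @export
write_taxon_map <- function(taxon_map, path) {
  out <- taxon_map
  out$ingroup <- ifelse(out$ingroup, "in", "out")
  cols <- intersect(c("label", "taxon", "ingroup", "population"), names(out))
  utils::write.table(out[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
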