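#' Detect intra-individual polymorphic sites (IPS)
#'
#' An alignment position is an intra-individual polymorphic site for a
#' sequence when that sequence carries a 2- or 3-base IUPAC ambiguity code
#' there (R, Y, S, W, K, M, B, D, H, V), as produced by direct sequencing of
#' a mixture of ribotypes. `N` is treated as a failed base call (missing),
#' not as a polymorphism. A column is polymorphic when at least one scoped
#' sequence carries an ambiguity code there.
#'
#' @param aln a [dna_alignment()].
#' @param scope character vector of labels to analyse; defaults to the
#'   ingroup labels of the taxon map (all labels when no map is attached).
#' @return a `polymorphism_report`: list with
#'   \describe{
#'     \item{columns}{data.frame, one row per polymorphic column: `column`,
#'       `states` (unambiguous states seen in scope, collapsed string),
#'       `carriers` (comma-separated labels with an ambiguity code),
#'       `aps` (logical, filled by [classify_aps()]).}
#'     \item{per_sequence}{data.frame `label`, `n_ips`, `n_aps`.}
#'     \item{per_site_flags}{logical matrix scope x columns, TRUE where the
#'       sequence has an IPS; attribute basis for APS classification.}
#'     \item{scope}{the analysed labels.}
#'   }
#' @examples
#' aln <- dna_alignment(c(a = "ACRT", b = "ACAT", c = "ACGT"))
#' rep <- detect_ips(aln)
#' rep$columns$column  # 3
#' @export
detect_ips <- function(aln, scope = ingroup_labels(aln)) {
  if (length(scope) == 0L) stop("scope error: empty label scope")
  bad <- setdiff(scope, seq_labels(aln))
  if (length(bad)) stop("scope error: labels not in alignment: ",
                        paste(bad, collapse = ", "))
  sub <- aln$seqs[scope, , drop = FALSE]
  m <- iupac_mask(sub)
  m[sub == "N"] <- 0L                      # N is missing, never IPS
  pc <- mask_popcount(m)
  ips <- pc >= 2L                          # 2- and 3-base codes
  dim(ips) <- dim(m)
  poly_cols <- which(apply(ips, 2, any))
  dim(pc) <- dim(m)
  cols <- data.frame(
    column = poly_cols,
    states = vapply(poly_cols, function(j) {
      paste(sort(unique(sub[pc[, j] == 1L, j])), collapse = "")
    }, character(1)),
    carriers = vapply(poly_cols, function(j) {
      paste(scope[ips[, j]], collapse = ",")
    }, character(1)),
    aps = rep(NA, length(poly_cols)),
    stringsAsFactors = FALSE
  )
  per_seq <- data.frame(label = scope,
                        n_ips = as.integer(rowSums(ips)),
                        n_aps = NA_integer_,
                        stringsAsFactors = FALSE)
  structure(list(columns = cols, per_sequence = per_seq,
                 per_site_flags = ips, scope = scope,
                 aps_flags = NULL, n_col = n_col(aln)),
            class = "polymorphism_report")
}

#' @export
print.polymorphism_report <- function(x, ...) {
  cat("polymorphism report:", length(x$scope), "sequences in scope,",
      x$n_col, "columns\n")
  cat("polymorphic columns:", nrow(x$columns), "\n")
  if (!is.null(x$aps_flags)) {
    cat("APS columns:", sum(x$columns$aps), "\n")
    cat("per-sequence IPS range:", paste(range(x$per_sequence$n_ips), collapse = "-"),
        " APS range:", paste(range(x$per_sequence$n_aps), collapse = "-"), "\n")
  }
  invisible(x)
}

#' Classify additive polymorphic sites (APS)
#'
#' An ambiguity code at (column, sequence) is additive when every
#' constituent base of the code also occurs as an unambiguous state at the
#' same column in at least one *other* scoped sequence — the signature of an
#' individual carrying two parental ribotypes whose variants segregate in
#' the sampled accessions. A column is an APS column when at least one
#' scoped sequence is additive there.
#'
#' @param report a `polymorphism_report` from [detect_ips()].
#' @param aln the same alignment the report was computed from.
#' @return the report with `columns$aps`, `per_sequence$n_aps` and an
#'   `aps_flags` matrix filled in.
#' @examples
#' aln <- dna_alignment(c(a = "R", b = "A", c = "G"))
#' rep <- classify_aps(detect_ips(aln), aln)
#' rep$columns$aps  # TRUE: both A and G occur unambiguously elsewhere
#' @export
classify_aps <- function(report, aln) {
  if (!inherits(report, "polymorphism_report")) stop("not a polymorphism report")
  if (report$n_col != n_col(aln)) {
    stop("consistency error: report and alignment disagree on column count")
  }
  if (length(setdiff(report$scope, seq_labels(aln)))) {
    stop("consistency error: report scope not contained in alignment labels")
  }
  scope <- report$scope
  sub <- aln$seqs[scope, , drop = FALSE]
  m <- iupac_mask(sub)
  m[sub == "N"] <- 0L
  pc <- mask_popcount(m)
  dim(pc) <- dim(m)
  aps <- matrix(FALSE, nrow(m), ncol(m), dimnames = dimnames(report$per_site_flags))
  for (j in report$columns$column) {
    unamb <- pc[, j] == 1L
    carriers <- which(report$per_site_flags[, j])
    for (i in carriers) {
      others <- unamb
      others[i] <- FALSE
      # union of unambiguous states in other accessions at this column
      seen <- Reduce(bitwOr, m[others, j], 0L)
      aps[i, j] <- bitwAnd(m[i, j], seen) == m[i, j]
    }
  }
  report$aps_flags <- aps
  report$columns$aps <- apply(aps[, report$columns$column, drop = FALSE], 2, any)
  report$per_sequence$n_aps <- as.integer(rowSums(aps))
  report
}

#' Split an alignment into APS-free and APS-bearing subsets
#'
#' Reproduces the standard practice of analysing homogenised (APS-free)
#' ribosomal sequences separately from heterogeneous ones: scoped sequences
#' with zero APS stay, together with all out-of-scope sequences, in the
#' APS-free alignment; scoped sequences with at least one APS move to the
#' APS-bearing alignment.
#'
#' @param aln a [dna_alignment()].
#' @param report an APS-classified `polymorphism_report` for `aln`.
#' @return list `aps_free`, `aps_bearing` of `dna_alignment`s.
#' @export
split_by_aps <- function(aln, report) {
  if (is.null(report$aps_flags)) stop("report not APS-classified; run classify_aps()")
  bearing <- report$per_sequence$label[report$per_sequence$n_aps > 0L]
  keep <- setdiff(seq_labels(aln), bearing)
  list(aps_free = aln[match(keep, seq_labels(aln)), ],
       aps_bearing = aln[match(bearing, seq_labels(aln)), ])
}

#' Write per-column and per-sequence polymorphism tables
#'
#' @param report an (ideally APS-classified) `polymorphism_report`.
#' @param dir output directory (created if needed).
#' @return paths of the two tab-separated tables and the summary file.
#' @export
write_polymorphism_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(dir, "polymorphic_columns.tsv")
  p2 <- file.path(dir, "per_sequence_counts.tsv")
  p3 <- file.path(dir, "polymorphism_summary.txt")
  utils::write.table(report$columns, p1, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(report$per_sequence, p2, sep = "\t", quote = FALSE, row.names = FALSE)
  summ <- c(
    sprintf("columns\t%d", report$n_col),
    sprintf("scope_sequences\t%d", length(report$scope)),
    sprintf("polymorphic_columns\t%d", nrow(report$columns)),
    if (!is.null(report$aps_flags)) sprintf("aps_columns\t%d", sum(report$columns$aps)),
    sprintf("max_ips_per_sequence\t%d", if (nrow(report$per_sequence)) max(report$per_sequence$n_ips) else 0L),
    if (!is.null(report$aps_flags))
      sprintf("max_aps_per_sequence\t%d", max(report$per_sequence$n_aps))
  )
  writeLines(summ, p3)
  invisible(c(p1, p2, p3))
}
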