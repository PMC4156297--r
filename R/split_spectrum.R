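#' Classify supporting positions for a bipartition
#'
#' Tabulates, for a functional ingroup / functional outgroup split, the
#' three classical categories of supporting alignment positions:
#' \describe{
#'   \item{symmetric}{exactly two states overall, each side fixed for a
#'     different one — the position supports both sides of the split.}
#'   \item{asymmetric}{one side fixed for a state the other side lacks,
#'     while the other side shows two or more states — supports only the
#'     fixed side.}
#'   \item{noisy}{one side fixed for a state that also occurs in at least
#'     one sequence of the other side — convergence, chance similarity or
#'     an autapomorphic pattern rather than split support. A constant
#'     column is noisy for both sides and is counted once.}
#' }
#' Ambiguity codes, `N`, `-` and `?` are excluded from the state tallies; a
#' side is "fixed" only when all its resolved characters agree and at least
#' one character is resolved. Columns where either side has no resolved
#' state are skipped.
#'
#' @param aln a [dna_alignment()].
#' @param ingroup,outgroup character vectors of labels forming the split
#'   (must not overlap; need not cover all labels).
#' @return a `support_spectrum`: list with column index vectors
#'   `symmetric`, `asymmetric_ingroup`, `asymmetric_outgroup`, `noisy`, a
#'   `counts` vector, and `supporting` counts per side (symmetric +
#'   asymmetric, the conventional headline number).
#' @examples
#' aln <- dna_alignment(c(i1 = "AAC", i2 = "AAC", o1 = "CAG", o2 = "CTG"))
#' classify_supporting_positions(aln, c("i1", "i2"), c("o1", "o2"))$counts
#' @export
classify_supporting_positions <- function(aln, ingroup, outgroup) {
  if (length(intersect(ingroup, outgroup))) {
    stop("split error: ingroup and outgroup overlap")
  }
  bad <- setdiff(c(ingroup, outgroup), seq_labels(aln))
  if (length(bad)) stop("split error: unknown labels: ", paste(bad, collapse = ", "))
  if (!length(ingroup) || !length(outgroup)) stop("split error: empty side")
  m <- aln_masks(aln)
  m[aln$seqs == "N"] <- 0L
  resolved <- mask_popcount(m) == 1L
  dim(resolved) <- dim(m)
  m[!resolved] <- 0L

  side_states <- function(rows, j) unique(m[rows, j][m[rows, j] > 0L])
  irows <- match(ingroup, seq_labels(aln))
  orows <- match(outgroup, seq_labels(aln))

  sym <- integer(0); asym_in <- integer(0); asym_out <- integer(0); noisy <- integer(0)
  for (j in seq_len(ncol(m))) {
    si <- side_states(irows, j)
    so <- side_states(orows, j)
    if (!length(si) || !length(so)) next
    fi <- length(si) == 1L
    fo <- length(so) == 1L
    if (fi && fo) {
      if (si != so) sym <- c(sym, j) else noisy <- c(noisy, j)
    } else if (fi) {
      if (si %in% so) noisy <- c(noisy, j) else asym_in <- c(asym_in, j)
    } else if (fo) {
      if (so %in% si) noisy <- c(noisy, j) else asym_out <- c(asym_out, j)
    }
  }
  counts <- c(symmetric = length(sym),
              asymmetric_ingroup = length(asym_in),
              asymmetric_outgroup = length(asym_out),
              noisy = length(noisy))
  structure(list(ingroup = ingroup, outgroup = outgroup,
                 symmetric = sym, asymmetric_ingroup = asym_in,
                 asymmetric_outgroup = asym_out, noisy = noisy,
                 counts = counts,
                 supporting = c(ingroup = length(sym) + length(asym_in),
                                outgroup = length(sym) + length(asym_out))),
            class = "support_spectrum")
}

#' @export
print.support_spectrum <- function(x, ...) {
  cat("supporting-position spectrum (", length(x$ingroup), "ingroup vs",
      length(x$outgroup), "outgroup labels )\n")
  print(x$counts)
  cat("supporting (symmetric + asymmetric): ingroup", x$supporting["ingroup"],
      "/ outgroup", x$supporting["outgroup"], "\n")
  invisible(x)
}

#' Spectrum table over a list of named splits
#'
#' @param aln a [dna_alignment()].
#' @param splits named list; each element a list/pair with elements
#'   `ingroup` and `outgroup` (character label vectors).
#' @return data.frame with one row per split: category counts and the
#'   per-side supporting totals (the bar heights of a split spectrum, with
#'   the ingroup side conventionally drawn above the axis and the outgroup
#'   side below).
#' @export
spectrum_table <- function(aln, splits) {
  if (!length(splits)) {
    return(data.frame(split = character(0), symmetric = integer(0),
                      asymmetric_ingroup = integer(0),
                      asymmetric_outgroup = integer(0), noisy = integer(0),
                      supporting_ingroup = integer(0),
                      supporting_outgroup = integer(0)))
  }
  rows <- lapply(names(splits), function(nm) {
    sp <- splits[[nm]]
    spec <- classify_supporting_positions(aln, sp$ingroup, sp$outgroup)
    data.frame(split = nm,
               symmetric = spec$counts[["symmetric"]],
               asymmetric_ingroup = spec$counts[["asymmetric_ingroup"]],
               asymmetric_outgroup = spec$counts[["asymmetric_outgroup"]],
               noisy = spec$counts[["noisy"]],
               supporting_ingroup = spec$supporting[["ingroup"]],
               supporting_outgroup = spec$supporting[["outgroup"]],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write a spectrum table to a tab-separated file
#'
#' @param tab data.frame from [spectrum_table()].
#' @param path output path.
#' @export
write_spectrum_table <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
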