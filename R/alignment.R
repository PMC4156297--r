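#' DNA alignment container
#'
#' An S3 class holding an aligned set of IUPAC-coded DNA sequences together
#' with named column partitions (e.g. ITS1, 5.8S, ITS2, cpDNA) and an
#' optional taxon map assigning each sequence label to a taxon, a population
#' code and an ingroup/outgroup flag.
#'
#' Sequences are stored as a character matrix (rows = sequences, columns =
#' alignment positions) of uppercase single characters over the IUPAC DNA
#' alphabet plus `-` (gap) and `?` (missing); `U` is normalised to `T` on
#' construction. Partitions are named 1-based inclusive column ranges.
#'
#' @param seqs character matrix with unique rownames, or a named character
#'   vector of equal-length sequence strings.
#' @param partitions named list of length-2 integer vectors `c(start, end)`
#'   (1-based, inclusive), or NULL.
#' @param taxon_map data.frame with columns `label`, `taxon`, `ingroup`
#'   (logical) and optionally `population`, or NULL.
#' @return an object of class `dna_alignment`.
#' @examples
#' aln <- dna_alignment(c(s1 = "ACGT", s2 = "ACGA"))
#' n_seq(aln); n_col(aln)
#' @export
dna_alignment <- function(seqs, partitions = NULL, taxon_map = NULL) {
  if (!is.matrix(seqs)) {
    if (is.null(names(seqs))) stop("sequences must be named")
    lens <- nchar(seqs)
    if (length(unique(lens)) > 1L) {
      stop("alignment-shape error: sequence lengths differ (",
           paste(unique(lens), collapse = ", "), ")")
    }
    labs <- names(seqs)
    seqs <- if (lens[1] == 0L) {
      matrix(character(0), nrow = length(labs), ncol = 0L)
    } else {
      do.call(rbind, strsplit(unname(seqs), ""))
    }
    rownames(seqs) <- labs
  }
  if (is.null(rownames(seqs))) {
    if (nrow(seqs) == 0L) {
      dimnames(seqs) <- list(character(0), NULL)
    } else {
      stop("sequence matrix must have rownames")
    }
  }
  if (anyDuplicated(rownames(seqs))) {
    stop("uniqueness error: duplicate labels: ",
         paste(unique(rownames(seqs)[duplicated(rownames(seqs))]), collapse = ", "))
  }
  seqs[] <- toupper(seqs)
  seqs[seqs == "U"] <- "T"
  bad <- !(seqs %in% c(names(.IUPAC_SETS), "-", "?"))
  if (any(bad)) {
    idx <- which(bad)[1]
    pos <- arrayInd(idx, dim(seqs))
    stop("alphabet error: illegal character '", seqs[idx], "' in sequence '",
         rownames(seqs)[pos[1]], "' at column ", pos[2])
  }
  obj <- structure(list(seqs = seqs, partitions = NULL, taxon_map = NULL),
                   class = "dna_alignment")
  if (!is.null(partitions)) obj <- set_partitions(obj, partitions)
  if (!is.null(taxon_map)) obj <- set_taxon_map(obj, taxon_map)
  obj
}

#' @export
print.dna_alignment <- function(x, ...) {
  cat("dna_alignment:", n_seq(x), "sequences x", n_col(x), "columns\n")
  if (length(x$partitions)) {
    cat("partitions:",
        paste(sprintf("%s[%d-%d]", names(x$partitions),
                      vapply(x$partitions, `[`, 1L, 1),
                      vapply(x$partitions, `[`, 1L, 2)), collapse = ", "), "\n")
  }
  if (!is.null(x$taxon_map)) {
    cat("taxon map:", sum(x$taxon_map$ingroup), "ingroup /",
        sum(!x$taxon_map$ingroup), "outgroup labels\n")
  }
  invisible(x)
}

#' @rdname dna_alignment
#' @param aln a `dna_alignment`.
#' @export
n_seq <- function(aln) nrow(aln$seqs)

#' @rdname dna_alignment
#' @export
n_col <- function(aln) ncol(aln$seqs)

#' @rdname dna_alignment
#' @export
seq_labels <- function(aln) rownames(aln$seqs)

#' Attach partitions to an alignment
#'
#' @param aln a `dna_alignment`.
#' @param partitions named list of `c(start, end)` 1-based inclusive ranges.
#' @export
set_partitions <- function(aln, partitions) {
  stopifnot(is.list(partitions), !is.null(names(partitions)))
  L <- n_col(aln)
  cov <- integer(L)
  for (nm in names(partitions)) {
    p <- as.integer(partitions[[nm]])
    if (length(p) != 2L || p[1] < 1L || p[2] > L || p[1] > p[2]) {
      stop("partition '", nm, "' out of bounds for ", L, " columns")
    }
    cov[p[1]:p[2]] <- cov[p[1]:p[2]] + 1L
    partitions[[nm]] <- p
  }
  if (any(cov > 1L)) stop("partitions overlap")
  aln$partitions <- partitions
  aln
}

#' Attach a taxon map to an alignment
#'
#' @param aln a `dna_alignment`.
#' @param taxon_map data.frame with columns `label`, `taxon`, `ingroup`
#'   (logical or "in"/"out"), optional `population`.
#' @export
set_taxon_map <- function(aln, taxon_map) {
  taxon_map <- as.data.frame(taxon_map)
  stopifnot(all(c("label", "taxon", "ingroup") %in% names(taxon_map)))
  if (is.character(taxon_map$ingroup)) {
    taxon_map$ingroup <- taxon_map$ingroup == "in"
  }
  missing <- setdiff(seq_labels(aln), taxon_map$label)
  if (length(missing)) {
    stop("taxon map lacks labels: ", paste(missing, collapse = ", "))
  }
  aln$taxon_map <- taxon_map[match(seq_labels(aln), taxon_map$label), , drop = FALSE]
  rownames(aln$taxon_map) <- NULL
  aln
}

#' Labels flagged as ingroup
#'
#' @param aln a `dna_alignment` with a taxon map.
#' @return character vector of ingroup labels; all labels when no taxon map
#'   is attached.
#' @export
ingroup_labels <- function(aln) {
  if (is.null(aln$taxon_map)) return(seq_labels(aln))
  aln$taxon_map$label[aln$taxon_map$ingroup]
}

#' Subset an alignment
#'
#' @param x a `dna_alignment`.
#' @param i row (label) index; @param j column index.
#' @param ... ignored.
#' @details Column subsetting drops partitions unless the selection is a
#'   contiguous prefix-preserving range; partitions wholly inside the kept
#'   range are retained and shifted.
#' @export
`[.dna_alignment` <- function(x, i, j, ...) {
  seqs <- x$seqs
  if (!missing(i)) seqs <- seqs[i, , drop = FALSE]
  parts <- x$partitions
  if (!missing(j)) {
    jj <- seq_len(ncol(seqs))[j]
    seqs <- seqs[, j, drop = FALSE]
    if (!is.null(parts)) {
      if (length(jj) && all(diff(jj) == 1L)) {
        keep <- list()
        for (nm in names(parts)) {
          p <- parts[[nm]]
          if (p[1] >= jj[1] && p[2] <= jj[length(jj)]) {
            keep[[nm]] <- p - jj[1] + 1L
          }
        }
        parts <- if (length(keep)) keep else NULL
      } else {
        parts <- NULL
      }
    }
  }
  out <- dna_alignment(seqs)
  if (!is.null(parts)) out <- set_partitions(out, parts)
  if (!is.null(x$taxon_map)) {
    out$taxon_map <- x$taxon_map[match(rownames(seqs), x$taxon_map$label), ,
                                 drop = FALSE]
    rownames(out$taxon_map) <- NULL
  }
  out
}

#' Sequences as strings
#'
#' @param aln a `dna_alignment`.
#' @return named character vector of sequence strings.
#' @export
seq_strings <- function(aln) {
  out <- apply(aln$seqs, 1, paste, collapse = "")
  if (n_col(aln) == 0L) out <- stats::setNames(rep("", n_seq(aln)), seq_labels(aln))
  out
}

#' Integer mask matrix of an alignment
#' @keywords internal
aln_masks <- function(aln) {
  m <- iupac_mask(aln$seqs)
  # N is a failed call, not information: mask it as missing except where
  # callers explicitly ask for Fitch-style full state sets
  dimnames(m) <- dimnames(aln$seqs)
  m
}

#' Uncorrected p-distance between two aligned sequences
#'
#' Pairwise-deletion proportion of differing sites. Positions where either
#' sequence is gap (`-`) or missing (`?`) are excluded. IUPAC ambiguity
#' codes are compared by set-disjointness: two characters differ only when
#' their base sets share no base (so R vs A matches, R vs Y differs). This
#' is conservative for minimum-distance hybridization tests.
#'
#' @param a,b equal-length sequence strings or character vectors.
#' @return proportion of differing sites among comparable sites.
#' @examples
#' p_distance("ACGT", "ACGA")  # 0.25
#' p_distance("RCGT", "ACGT")  # 0
#' @export
p_distance <- function(a, b) {
  if (length(a) == 1L) a <- strsplit(a, "")[[1]]
  if (length(b) == 1L) b <- strsplit(b, "")[[1]]
  if (length(a) != length(b)) stop("sequences differ in length")
  ma <- iupac_mask(toupper(a))
  mb <- iupac_mask(toupper(b))
  comp <- ma > 0L & mb > 0L
  n <- sum(comp)
  if (n == 0L) stop("undefined distance: no comparable positions")
  sum(bitwAnd(ma[comp], mb[comp]) == 0L) / n
}

#' All pairwise p-distances of an alignment
#'
#' @param aln a `dna_alignment`.
#' @return symmetric matrix of uncorrected p-distances (see [p_distance()]).
#' @export
p_distance_matrix <- function(aln) {
  m <- iupac_mask(aln$seqs)
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      comp <- m[i, ] > 0L & m[j, ] > 0L
      nc <- sum(comp)
      if (nc == 0L) stop("undefined distance between '", rownames(m)[i],
                         "' and '", rownames(m)[j], "'")
      d[i, j] <- d[j, i] <- sum(bitwAnd(m[i, comp], m[j, comp]) == 0L) / nc
    }
  }
  d
}

#' Merge identical sequences
#'
#' Collapses an alignment to one representative per equivalence class, as is
#' commonly done before parsimony searches to reduce computation time.
#' Under `exact` policy two sequences are equivalent when they are
#' character-for-character identical. Under `missing-compatible` a sequence
#' joins an existing class when, at every column, its character equals the
#' representative's or at least one of the two is missing (`-`/`?`);
#' classes are formed greedily in input order (this relation is not
#' transitive).
#'
#' @param aln a `dna_alignment`.
#' @param missing_policy `"exact"` or `"missing-compatible"`.
#' @return list with `alignment` (one representative per class, first member
#'   as representative, input order) and `members` (named list:
#'   representative label -> member labels).
#' @export
merge_identical <- function(aln, missing_policy = c("exact", "missing-compatible")) {
  missing_policy <- match.arg(missing_policy)
  if (n_seq(aln) == 0L) stop("empty alignment")
  labs <- seq_labels(aln)
  if (missing_policy == "exact") {
    key <- seq_strings(aln)
    reps <- !duplicated(key)
    members <- split(labs, match(key, key[reps]))
    names(members) <- labs[reps][as.integer(names(members))]
  } else {
    m <- iupac_mask(aln$seqs)
    m[aln$seqs == "N"] <- 0L  # N is missing for merging, like '-' and '?'
    rep_idx <- integer(0)
    assign <- integer(n_seq(aln))
    for (i in seq_len(n_seq(aln))) {
      hit <- 0L
      for (k in seq_along(rep_idx)) {
        r <- rep_idx[k]
        ok <- m[i, ] == 0L | m[r, ] == 0L | aln$seqs[i, ] == aln$seqs[r, ]
        if (all(ok)) { hit <- k; break }
      }
      if (hit == 0L) { rep_idx <- c(rep_idx, i); hit <- length(rep_idx) }
      assign[i] <- hit
    }
    members <- split(labs, assign)
    names(members) <- labs[rep_idx][as.integer(names(members))]
    reps <- seq_len(n_seq(aln)) %in% rep_idx
  }
  out <- aln[which(reps), ]
  members <- members[seq_labels(out)]
  list(alignment = out, members = members)
}

#' Concatenate two alignments by label
#'
#' @param a,b `dna_alignment` objects over the same label set (labels are
#'   matched exactly; a label present in only one input is an error).
#' @return a `dna_alignment` of width `n_col(a) + n_col(b)`; partitions of
#'   `b` are shifted by `n_col(a)`; `a`'s taxon map is carried over.
#' @export
concatenate_alignments <- function(a, b) {
  la <- seq_labels(a); lb <- seq_labels(b)
  offenders <- c(setdiff(la, lb), setdiff(lb, la))
  if (length(offenders)) {
    stop("join error: labels present in only one alignment: ",
         paste(sort(unique(offenders)), collapse = ", "))
  }
  bseq <- b$seqs[match(la, lb), , drop = FALSE]
  seqs <- cbind(a$seqs, bseq)
  parts <- a$partitions
  if (!is.null(b$partitions)) {
    shifted <- lapply(b$partitions, function(p) p + n_col(a))
    parts <- c(if (is.null(parts)) list() else parts, shifted)
  }
  out <- dna_alignment(seqs)
  if (!is.null(parts) && length(parts)) out <- set_partitions(out, parts)
  if (!is.null(a$taxon_map)) out$taxon_map <- a$taxon_map
  out
}

#' Convert to phangorn's phyDat representation
#'
#' @param aln a `dna_alignment` with at least one column.
#' @return a `phyDat` object; IUPAC ambiguity codes become partial state
#'   sets, `-`/`?`/`N` the full state set.
#' @export
as_phyDat <- function(aln) {
  phangorn::phyDat(aln$seqs, type = "DNA")
}
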