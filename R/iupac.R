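#' IUPAC nucleotide ambiguity algebra
#'
#' The package represents every alignment character as a 4-bit mask over the
#' bases A, C, G, T (A = 1, C = 2, G = 4, T = 8). IUPAC ambiguity codes map
#' to the union of their constituent bases; gap (`-`) and `?` carry mask 0
#' and are treated as missing data. `N` maps to all four bases but is
#' classified as missing for polymorphism detection (an N in a chromatogram
#' is a failed base call, not an intra-individual polymorphism).
#'
#' @name iupac
#' @keywords internal
NULL

# code -> constituent base sets; U is an alias of T
.IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T", U = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

.BASE_BITS <- c(A = 1L, C = 2L, G = 4L, T = 8L)

.iupac_mask_table <- local({
  tab <- integer(256)
  for (code in names(.IUPAC_SETS)) {
    m <- sum(.BASE_BITS[.IUPAC_SETS[[code]]])
    tab[utf8ToInt(code) + 1L] <- m
    tab[utf8ToInt(tolower(code)) + 1L] <- m
  }
  # '-' and '?' stay 0 (missing)
  tab
})

.mask_to_code <- local({
  v <- character(16)
  for (code in setdiff(names(.IUPAC_SETS), "U")) {
    v[sum(.BASE_BITS[.IUPAC_SETS[[code]]])] <- code
  }
  v
})

#' Convert characters to IUPAC bit masks
#'
#' @param x character vector (or matrix) of single alignment characters.
#' @return integer vector (or matrix) of 4-bit base masks; 0 for missing
#'   (`-`, `?`).
#' @keywords internal
iupac_mask <- function(x) {
  m <- .iupac_mask_table[utf8ToInt(paste(x, collapse = "")) + 1L]
  if (is.matrix(x)) {
    dim(m) <- dim(x)
    dimnames(m) <- dimnames(x)
  }
  m
}

#' Convert bit masks back to IUPAC characters
#'
#' @param m integer vector of masks in 0:15; 0 becomes `-`.
#' @keywords internal
iupac_unmask <- function(m) {
  out <- rep("-", length(m))
  nz <- m > 0L
  out[nz] <- .mask_to_code[m[nz]]
  out
}

#' The IUPAC code table
#'
#' @return named list mapping each IUPAC DNA code (including single bases
#'   and N) to its set of constituent bases. Gap and `?` are not codes.
#' @examples
#' iupac_table()$R  # "A" "G"
#' @export
iupac_table <- function() .IUPAC_SETS[setdiff(names(.IUPAC_SETS), "U")]

# number of set bits for masks 0:15
.POPCOUNT <- as.integer(colSums(sapply(0:15, function(m) bitwAnd(m, c(1L, 2L, 4L, 8L)) > 0L)))

#' @keywords internal
mask_popcount <- function(m) .POPCOUNT[m + 1L]

.ALLOWED_CHARS <- c(names(.IUPAC_SETS), tolower(names(.IUPAC_SETS)), "-", "?")
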