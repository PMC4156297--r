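#' Specify a nucleotide substitution model
#'
#' Supported families: JC69, K80, HKY85, SYM, TVM and GTR, optionally with
#' discrete-gamma rate variation (mean-of-category rates) and a proportion
#' of invariant sites. Base frequencies are fixed equal for JC69, K80 and
#' SYM and empirical (counted from the data) for HKY85, TVM and GTR unless
#' given explicitly. Exchangeabilities are in the order AC, AG, AT, CG,
#' CT, GT; TVM constrains AG = CT.
#'
#' @param family model family name.
#' @param rates optional length-6 exchangeability vector.
#' @param kappa transition/transversion rate ratio for K80/HKY85 (used when
#'   `rates` is NULL).
#' @param base_freq `"equal"`, `"empirical"`, or a length-4 numeric summing
#'   to 1 (order A, C, G, T).
#' @param shape gamma shape alpha (NULL for no rate variation).
#' @param k number of discrete gamma categories.
#' @param p_inv proportion of invariant sites.
#' @return a `sub_model` list.
#' @export
sub_model <- function(family = c("JC69", "K80", "HKY85", "SYM", "TVM", "GTR"),
                      rates = NULL, kappa = 2, base_freq = NULL,
                      shape = NULL, k = 4L, p_inv = 0) {
  family <- match.arg(family)
  if (is.null(rates)) {
    rates <- switch(family,
      JC69 = rep(1, 6),
      K80 = , HKY85 = c(1, kappa, 1, 1, kappa, 1),
      SYM = , TVM = , GTR = rep(1, 6))
  }
  if (length(rates) != 6L || any(rates <= 0)) stop("need 6 positive rates")
  if (family == "TVM" && !isTRUE(all.equal(rates[2], rates[5]))) {
    stop("TVM requires AG == CT exchangeability")
  }
  if (is.null(base_freq)) {
    base_freq <- if (family %in% c("JC69", "K80", "SYM")) "equal" else "empirical"
  }
  if (is.numeric(base_freq)) {
    stopifnot(length(base_freq) == 4L, isTRUE(all.equal(sum(base_freq), 1)))
  }
  if (p_inv < 0 || p_inv >= 1) stop("p_inv must be in [0, 1)")
  structure(list(family = family, rates = rates, base_freq = base_freq,
                 shape = shape, k = if (is.null(shape)) 1L else as.integer(k),
                 p_inv = p_inv),
            class = "sub_model")
}

# resolve base frequencies for a concrete alignment
.model_bf <- function(model, aln) {
  if (is.numeric(model$base_freq)) return(model$base_freq)
  if (identical(model$base_freq, "equal")) return(rep(0.25, 4))
  m <- iupac_mask(aln$seqs)
  counts <- vapply(c(1L, 2L, 4L, 8L), function(b) sum(m == b), numeric(1))
  if (sum(counts) == 0) return(rep(0.25, 4))
  counts / sum(counts)
}

.pml_fit <- function(tree, aln, model) {
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  data <- as_phyDat(aln)
  phangorn::pml(tree, data, bf = .model_bf(model, aln), Q = model$rates,
                inv = model$p_inv,
                k = if (is.null(model$shape)) 1L else model$k,
                shape = if (is.null(model$shape)) 1 else model$shape)
}

#' Per-site log-likelihoods under a substitution model
#'
#' Felsenstein pruning over the tree, with IUPAC ambiguity codes as partial
#' leaf state vectors (1 for every compatible base), discrete-gamma
#' categories averaged and invariant sites mixed in. The result is
#' invariant under rerooting of an unrooted tree.
#'
#' @param tree a `phylo` with branch lengths over the alignment labels.
#' @param aln a [dna_alignment()].
#' @param model a [sub_model()].
#' @return numeric vector of per-site log-likelihoods (one per column).
#' @export
site_loglik <- function(tree, aln, model = sub_model("JC69")) {
  fit <- .pml_fit(tree, aln, model)
  as.numeric(fit$siteLik[attr(fit$data, "index")])
}

#' Maximum-likelihood branch lengths for a fixed topology
#'
#' Iterative per-branch optimization (as implemented by
#' \code{phangorn::optim.pml}) until the relative log-likelihood change
#' drops below `tol`; the total log-likelihood is nondecreasing across
#' sweeps.
#'
#' @param tree a `phylo` over the alignment labels; branch lengths are used
#'   as the starting point (absent lengths start at 0.1).
#' @param aln a [dna_alignment()].
#' @param model a [sub_model()].
#' @param tol relative log-likelihood convergence tolerance.
#' @return list `tree` (with ML branch lengths) and `logLik`.
#' @export
optimize_branch_lengths <- function(tree, aln, model = sub_model("JC69"),
                                    tol = 1e-8) {
  if (is.null(tree$edge.length)) tree$edge.length <- rep(0.1, nrow(tree$edge))
  if (ape::Ntip(tree) == 2L) {
    # two taxa: a single path length; optimize it directly
    ll <- function(d) {
      tr <- tree
      tr$edge.length <- rep(d / nrow(tree$edge), nrow(tree$edge))
      as.numeric(.pml_fit(tr, aln, model)$logLik)
    }
    opt <- stats::optimize(ll, c(1e-9, 10), maximum = TRUE, tol = tol)
    tree$edge.length <- rep(opt$maximum / nrow(tree$edge), nrow(tree$edge))
    return(list(tree = tree, logLik = opt$objective))
  }
  if (ape::is.rooted(tree)) tree <- ape::unroot(tree)
  fit <- .pml_fit(tree, aln, model)
  fit <- phangorn::optim.pml(fit, optEdge = TRUE,
                             control = phangorn::pml.control(epsilon = tol,
                                                             maxit = 50L,
                                                             trace = 0))
  list(tree = fit$tree, logLik = as.numeric(fit$logLik))
}

#' Best constraint-compatible tree
#'
#' Finds the best tree compatible with the given clade constraints under
#' the parsimony criterion (delegating to [mp_search()]), as a topology for
#' subsequent branch-length optimization and topology testing.
#'
#' @param aln a [dna_alignment()].
#' @param constraint list of character vectors (clades to enforce), or NULL
#'   for an unconstrained search.
#' @param n_starts,seed,exhaustive passed to [mp_search()].
#' @return a `phylo` (the first best topology found).
#' @export
constrained_search <- function(aln, constraint = NULL, n_starts = 10L,
                               seed = NULL, exhaustive = FALSE) {
  res <- mp_search(aln, n_starts = n_starts, constraint = constraint,
                   seed = seed, exhaustive = exhaustive)
  res$trees[[1]]
}

#' RELL-based weighted KH and SH topology tests
#'
#' Resamples per-site log-likelihoods (RELL bootstrap — no re-optimization)
#' to compare candidate topologies against the best one. The weighted
#' Kishino-Hasegawa test standardizes each pairwise log-likelihood
#' difference by its bootstrap standard deviation and reports a two-sided
#' p-value against the best tree from the centred bootstrap distribution.
#' The weighted Shimodaira-Hasegawa test uses, for each tree, the maximum
#' standardized difference over all trees, with the null distribution
#' obtained from centred replicates.
#'
#' @param M matrix of per-site log-likelihoods, one row per candidate tree
#'   (rownames are tree labels), one column per site.
#' @param n_boot number of RELL bootstrap replicates.
#' @param seed optional integer seed.
#' @return data.frame with `tree`, `logLik`, `delta` (against the best
#'   tree) and `p_wkh`, `p_wsh`.
#' @export
rell_tests <- function(M, n_boot = 1000L, seed = NULL) {
  if (!is.matrix(M) || nrow(M) < 2L) stop("need a matrix with >= 2 tree rows")
  if (!all(is.finite(M))) stop("non-finite site log-likelihoods")
  if (is.null(rownames(M))) rownames(M) <- paste0("tree", seq_len(nrow(M)))
  if (!is.null(seed)) set.seed(seed)
  L <- ncol(M); K <- nrow(M)
  tot <- rowSums(M)
  best <- which.max(tot)
  # RELL replicate totals: K x n_boot
  B <- matrix(0, K, n_boot)
  for (b in seq_len(n_boot)) {
    w <- tabulate(sample.int(L, L, replace = TRUE), nbins = L)
    B[, b] <- as.numeric(M %*% w)
  }
  p_wkh <- numeric(K); p_wsh <- numeric(K)
  # pairwise bootstrap sds
  sd_pair <- function(i, j) stats::sd(B[i, ] - B[j, ])
  S <- matrix(0, K, K)
  for (i in seq_len(K - 1L)) for (j in (i + 1L):K) {
    S[i, j] <- S[j, i] <- sd_pair(i, j)
  }
  for (t in seq_len(K)) {
    # WKH versus the best tree
    if (t == best) {
      p_wkh[t] <- 1
    } else {
      d_obs <- tot[best] - tot[t]
      d_b <- B[best, ] - B[t, ]
      s <- S[best, t]
      if (s == 0) {
        warning("zero-variance log-likelihood difference for '",
                rownames(M)[t], "'; p = 1")
        p_wkh[t] <- 1
      } else {
        z_b <- (d_b - mean(d_b)) / s
        p_wkh[t] <- mean(abs(z_b) >= abs(d_obs / s))
      }
    }
    # WSH: max standardized difference over all trees
    others <- setdiff(seq_len(K), t)
    ok <- others[S[others, t] > 0]
    if (!length(ok)) {
      p_wsh[t] <- 1
      next
    }
    s_obs <- max((tot[ok] - tot[t]) / S[ok, t])
    cen <- B[ok, , drop = FALSE] - B[rep(t, length(ok)), , drop = FALSE]
    cen <- cen - rowMeans(cen)
    stat_b <- apply(cen / S[ok, t], 2, max)
    p_wsh[t] <- mean(stat_b >= s_obs)
  }
  data.frame(tree = rownames(M), logLik = tot, delta = tot[best] - tot,
             p_wkh = p_wkh, p_wsh = p_wsh,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Topology test report for a set of candidate trees
#'
#' Optimizes branch lengths for each candidate topology, assembles the
#' site log-likelihood matrix and runs the RELL weighted KH / SH tests.
#'
#' @param aln a [dna_alignment()].
#' @param trees named list of `phylo` topologies (branch lengths optional).
#' @param model a [sub_model()].
#' @param n_boot,seed passed to [rell_tests()].
#' @return list `table` (the [rell_tests()] data.frame, with `-ln L` style
#'   deltas relative to the best tree) and `site_loglik` (the trees x sites
#'   matrix).
#' @export
topology_test_report <- function(aln, trees, model = sub_model("JC69"),
                                 n_boot = 1000L, seed = NULL) {
  stopifnot(length(trees) >= 2L)
  if (is.null(names(trees))) names(trees) <- paste0("tree", seq_along(trees))
  M <- matrix(0, length(trees), n_col(aln),
              dimnames = list(names(trees), NULL))
  for (nm in names(trees)) {
    opt <- optimize_branch_lengths(trees[[nm]], aln, model)
    M[nm, ] <- site_loglik(opt$tree, aln, model)
  }
  list(table = rell_tests(M, n_boot = n_boot, seed = seed), site_loglik = M)
}

#' Write a site log-likelihood matrix
#'
#' Tab-separated sites x trees table, in the spirit of the per-site
#' likelihood files consumed by topology-testing tools.
#'
#' @param M trees x sites matrix (as from [topology_test_report()]).
#' @param path output path.
#' @export
write_site_loglik <- function(M, path) {
  utils::write.table(t(M), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = rownames(M))
  invisible(path)
}
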