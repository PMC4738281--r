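#' Neighbor-joining tree from a distance matrix
#'
#' Canonical NJ agglomeration (Q-criterion joining with the standard
#' branch-length formulas, via [ape::nj()]), followed by a
#' Kuhner–Felsenstein clean-up of negative branch-length estimates: a
#' negative branch is clamped to zero and its deficit transferred to the
#' adjacent (sibling) branch so the local path lengths are preserved. On an
#' additive matrix NJ is consistent: the returned tree reproduces the input
#' distances exactly.
#'
#' @param dm symmetric distance matrix (ids as dimnames), `n >= 3`.
#' @return an unrooted `ape::phylo` with non-negative branch lengths.
#' @export
buildNJ <- function(dm) {
  ids <- .checkDistanceMatrix(dm)
  if (nrow(dm) < 3L) stop("NJ requires at least 3 taxa")
  tree <- ape::nj(dm)
  .clampNegativeBranches(tree)
}

# Kuhner-Felsenstein convention: zero out negative estimates, moving the
# deficit onto a sibling branch (first sibling in edge order). Iterates until
# no negative branch remains.
.clampNegativeBranches <- function(tree) {
  if (is.null(tree$edge.length)) return(tree)
  for (iter in seq_len(100L)) {
    neg <- which(tree$edge.length < 0)
    if (length(neg) == 0L) break
    e <- neg[1L]
    parent <- tree$edge[e, 1L]
    deficit <- tree$edge.length[e]
    tree$edge.length[e] <- 0
    sib <- which(tree$edge[, 1L] == parent)
    sib <- sib[sib != e]
    if (length(sib) > 0L)
      tree$edge.length[sib[1L]] <- tree$edge.length[sib[1L]] + deficit
  }
  tree$edge.length[tree$edge.length < 0] <- 0
  tree
}

#' Neighbor-joining with nonparametric bootstrap supports
#'
#' Builds the reference NJ tree from the full alignment, then for each
#' replicate resamples alignment columns with replacement, recomputes the K2P
#' matrix and NJ tree, and counts how often each internal bipartition of the
#' reference tree is recovered. Support is attached as
#' `100 * recovered / replicates` in `$node.label`. Replicates in which the
#' resampled matrix saturates are skipped (with a message); more than 10%
#' skipped is an error.
#'
#' @param aln a [BarcodeAlignment-class].
#' @param replicates number of bootstrap replicates (`>= 1`); the study
#'   default for barcode NJ trees is 1000.
#' @param seed root seed; each replicate draws its own substream seed from it,
#'   so results are reproducible and independent of evaluation order.
#' @return the reference NJ tree with `$node.label` holding integer supports.
#' @export
bootstrapNJ <- function(aln, replicates = 1000L, seed = NULL) {
  stopifnot(is(aln, "BarcodeAlignment"))
  replicates <- as.integer(replicates)
  if (replicates < 1L) stop("'replicates' must be >= 1")
  ref <- buildNJ(k2pMatrix(aln))
  L <- alignmentWidth(aln)
  chars <- as.character(aln@seqs)
  mat <- matrix(unlist(strsplit(chars, "", fixed = TRUE), use.names = FALSE),
                nrow = length(chars), byrow = TRUE)
  rownames(mat) <- names(aln@seqs)
  seeds <- .substreamSeeds(seed, replicates)
  boots <- vector("list", replicates)
  skipped <- 0L
  for (b in seq_len(replicates)) {
    set.seed(seeds[b])
    cols <- sample.int(L, L, replace = TRUE)
    baln <- BarcodeAlignment(apply(mat[, cols, drop = FALSE], 1L, paste,
                                   collapse = ""))
    tr <- tryCatch(buildNJ(k2pMatrix(baln)), error = function(e) NULL)
    if (is.null(tr)) {
      skipped <- skipped + 1L
      next
    }
    boots[[b]] <- tr
  }
  if (skipped > 0L) {
    message("bootstrapNJ: skipped ", skipped, " saturated replicate(s)")
    if (skipped > 0.1 * replicates)
      stop("more than 10% of bootstrap replicates were saturated (",
           skipped, "/", replicates, ")")
  }
  boots <- boots[!vapply(boots, is.null, logical(1L))]
  counts <- ape::prop.clades(ref, boots, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  ref$node.label <- as.character(round(100 * counts / replicates))
  ref
}

#' UPGMA tree from a distance matrix
#'
#' Average-linkage agglomeration; the age of each internal node is half the
#' cluster-join distance, so the output is ultrametric by construction. Used
#' as the fallback ultrametric input for the GMYC model when no chronogram is
#' available.
#'
#' @param dm symmetric distance matrix, `n >= 2`.
#' @return a rooted ultrametric `ape::phylo`.
#' @export
buildUPGMA <- function(dm) {
  .checkDistanceMatrix(dm)
  if (nrow(dm) < 2L) stop("UPGMA requires at least 2 taxa")
  phangorn::upgma(stats::as.dist(dm))
}

#' Branching times of an ultrametric tree
#'
#' Internal node ages (time before present) sorted in decreasing order, the
#' first being the root age. Exact ties are broken by subtracting a jitter
#' smaller than `1e-9` times the root age (reported via a message) so the
#' sequence is strictly decreasing, as the diversification-rate likelihoods
#' require.
#'
#' @param tree a rooted ultrametric `ape::phylo` with `n >= 3` tips.
#' @param tol relative ultrametricity tolerance.
#' @return numeric vector of `n - 1` node ages, strictly decreasing.
#' @export
branchingTimes <- function(tree, tol = 1e-6) {
  if (!inherits(tree, "phylo")) stop("'tree' must be an ape 'phylo' object")
  if (length(tree$tip.label) < 3L)
    stop("branching times require at least 3 tips")
  .nodeAges(tree, tol = tol)  # validates ultrametricity
  bt <- sort(unname(ape::branching.times(tree)), decreasing = TRUE)
  if (anyDuplicated(bt)) {
    message("branchingTimes: breaking ", sum(duplicated(bt)),
            " tie(s) with jitter")
    eps <- 1e-10 * bt[1L]
    while (anyDuplicated(bt)) {
      dup <- which(duplicated(bt))
      bt[dup] <- bt[dup] - eps
      bt <- sort(bt, decreasing = TRUE)
    }
  }
  bt
}
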