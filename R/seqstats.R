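#' Average base composition of an alignment
#'
#' Per-sequence base fractions over `{A, C, G, T}` (gaps and `N` excluded from
#' the denominator), averaged across sequences. COI barcodes are typically
#' strongly AT-biased, and this is the statistic that shows it.
#'
#' @param aln a [BarcodeAlignment-class].
#' @return named numeric vector with elements `T`, `C`, `A`, `G` summing to 1.
#' @examples
#' baseComposition(BarcodeAlignment(c(a = "AATT", b = "AGTT")))
#' @export
baseComposition <- function(aln) {
  stopifnot(is(aln, "BarcodeAlignment"))
  m <- .encodeAlignment(aln)
  tot <- rowSums(!is.na(m))
  if (any(tot == 0L))
    stop("sequence '", rownames(m)[tot == 0L][1L],
         "' has no unambiguous bases")
  frac <- sapply(c(T = 3L, C = 1L, A = 0L, G = 2L),
                 function(code) rowSums(m == code, na.rm = TRUE) / tot)
  if (nSamples(aln) == 1L) frac <- matrix(frac, nrow = 1L,
                                          dimnames = list(NULL, c("T", "C", "A", "G")))
  colMeans(frac)
}

#' Classify alignment columns
#'
#' Per column, over unambiguous bases only: a *conserved* site carries one
#' state, a *variable* site at least two, and a *parsimony-informative* site
#' at least two states each present in at least two sequences. Columns with
#' fewer than one unambiguous base (all gap/`N`) are excluded from the
#' classifiable sites.
#'
#' @param aln a [BarcodeAlignment-class] with at least two sequences.
#' @return named integer vector: `conserved`, `variable`,
#'   `parsimony_informative`, `total_sites` (alignment length).
#' @examples
#' aln <- BarcodeAlignment(c(a = "ACGTA", b = "ACGTT", c = "ACGAA", d = "ACGAT"))
#' classifySites(aln)
#' @export
classifySites <- function(aln) {
  stopifnot(is(aln, "BarcodeAlignment"))
  if (nSamples(aln) < 2L)
    stop("site classification requires at least two sequences")
  m <- .encodeAlignment(aln)
  counts <- sapply(c(0L, 1L, 2L, 3L), function(code)
    colSums(m == code, na.rm = TRUE))  # columns x 4 bases
  nStates <- rowSums(counts > 0L)
  conserved <- sum(nStates == 1L)
  variable <- sum(nStates >= 2L)
  pi <- sum(rowSums(counts >= 2L) >= 2L & nStates >= 2L)
  c(conserved = conserved, variable = variable,
    parsimony_informative = pi, total_sites = alignmentWidth(aln))
}

#' Kimura 2-parameter distance between two sequences
#'
#' Comparison is restricted to columns where both sequences carry an
#' unambiguous base (pairwise deletion). With transition proportion `P` and
#' transversion proportion `Q` over the compared columns, the distance is
#' `d = -(1/2) log(1 - 2P - Q) - (1/4) log(1 - 2Q)`. Saturated pairs (either
#' logarithm undefined) raise an error rather than returning a capped value.
#'
#' @param seqI,seqJ equal-length nucleotide strings (or single-element named
#'   character vectors).
#' @return the K2P distance (non-negative scalar).
#' @examples
#' s1 <- paste(rep("A", 100), collapse = "")
#' s2 <- paste(c(rep("G", 10), rep("C", 10), rep("A", 80)), collapse = "")
#' k2pDistance(s1, s2)  # P = 0.1, Q = 0.1
#' @export
k2pDistance <- function(seqI, seqJ) {
  aln <- BarcodeAlignment(c(i = as.character(seqI)[1L],
                            j = as.character(seqJ)[1L]))
  m <- .encodeAlignment(aln)
  d <- abs(m[1L, ] - m[2L, ])
  ok <- !is.na(d)
  L <- sum(ok)
  if (L == 0L) stop("no columns with unambiguous bases in both sequences")
  P <- sum(d[ok] == 2L) / L
  Q <- sum(d[ok] %% 2L == 1L) / L
  .k2pFromPQ(P, Q)
}

#' Pairwise K2P distance matrix
#'
#' All pairwise [k2pDistance()] values with pairwise deletion, computed via
#' base-indicator cross-products so the cost is a handful of matrix products.
#' Any saturated or incomparable pair raises an error naming the pair.
#'
#' @param aln a [BarcodeAlignment-class] with at least two sequences.
#' @return symmetric numeric matrix with zero diagonal and sample ids as
#'   dimnames.
#' @export
k2pMatrix <- function(aln) {
  stopifnot(is(aln, "BarcodeAlignment"))
  n <- nSamples(aln)
  if (n < 2L) stop("K2P matrix requires at least two sequences")
  m <- .encodeAlignment(aln)
  ids <- rownames(m)
  A <- (m == 0L); A[is.na(A)] <- FALSE; storage.mode(A) <- "double"
  C <- (m == 1L); C[is.na(C)] <- FALSE; storage.mode(C) <- "double"
  G <- (m == 2L); G[is.na(G)] <- FALSE; storage.mode(G) <- "double"
  T_ <- (m == 3L); T_[is.na(T_)] <- FALSE; storage.mode(T_) <- "double"
  V <- A + C + G + T_
  compared <- tcrossprod(V)                       # columns valid in both
  same <- tcrossprod(A) + tcrossprod(C) + tcrossprod(G) + tcrossprod(T_)
  ti <- tcrossprod(A, G) + tcrossprod(G, A) + tcrossprod(C, T_) +
    tcrossprod(T_, C)
  tv <- compared - same - ti
  offdiag <- upper.tri(compared)
  if (any(compared[offdiag] == 0)) {
    bad <- which(compared == 0 & offdiag, arr.ind = TRUE)[1L, ]
    stop("no comparable columns between '", ids[bad[1L]], "' and '",
         ids[bad[2L]], "'")
  }
  P <- ti / compared
  Q <- tv / compared
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (any(w1[offdiag] <= 0) || any(w2[offdiag] <= 0)) {
    bad <- which((w1 <= 0 | w2 <= 0) & offdiag, arr.ind = TRUE)[1L, ]
    stop("K2P distance undefined (saturation) between '", ids[bad[1L]],
         "' and '", ids[bad[2L]], "'")
  }
  dm <- -0.5 * log(w1) - 0.25 * log(w2)
  dm[!is.finite(dm)] <- 0
  diag(dm) <- 0
  dm <- (dm + t(dm)) / 2   # enforce exact symmetry against rounding
  dimnames(dm) <- list(ids, ids)
  dm
}
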