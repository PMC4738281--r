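# Internal helpers shared across modules.

# Integer encoding used by the distance machinery: purines get even codes and
# pyrimidines odd codes, so |diff| == 2 is a transition and an odd diff a
# transversion. Gaps, N and anything ambiguous become NA.
.BASE_CODES <- c(A = 0L, G = 2L, C = 1L, T = 3L)

# BarcodeAlignment -> integer matrix (samples x columns), NA for non-ACGT
.encodeAlignment <- function(aln) {
  stopifnot(is(aln, "BarcodeAlignment"))
  chars <- as.character(aln@seqs)
  m <- matrix(.BASE_CODES[unlist(strsplit(chars, "", fixed = TRUE),
                                 use.names = FALSE)],
              nrow = length(chars), byrow = TRUE)
  rownames(m) <- names(aln@seqs)
  m
}

# Kimura 2-parameter distance from transition/transversion proportions.
# Raises on saturation (the correction's logs would be undefined).
.k2pFromPQ <- function(P, Q, what = "sequence pair") {
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0)
    stop("K2P distance undefined (saturation) for ", what,
         sprintf(": P = %.4g, Q = %.4g", P, Q))
  -0.5 * log(w1) - 0.25 * log(w2)
}

# Validate a symmetric K2P distance matrix with id dimnames.
.checkDistanceMatrix <- function(dm) {
  if (!is.matrix(dm) || !is.numeric(dm))
    stop("distance matrix must be a numeric matrix")
  if (nrow(dm) != ncol(dm)) stop("distance matrix must be square")
  ids <- rownames(dm)
  if (is.null(ids) || is.null(colnames(dm)) || !identical(ids, colnames(dm)))
    stop("distance matrix must carry identical row and column ids")
  if (anyDuplicated(ids)) stop("distance matrix ids must be unique")
  if (any(!is.finite(dm))) stop("distance matrix entries must be finite")
  if (any(dm < 0)) stop("distances must be non-negative")
  if (max(abs(dm - t(dm))) > 1e-12) stop("distance matrix must be symmetric")
  invisible(ids)
}

# Connected components of an undirected graph given as a logical adjacency
# matrix; returns an integer component label per vertex.
.components <- function(adj) {
  n <- nrow(adj)
  comp <- integer(n)
  cur <- 0L
  for (v in seq_len(n)) {
    if (comp[v] != 0L) next
    cur <- cur + 1L
    queue <- v
    comp[v] <- cur
    while (length(queue) > 0L) {
      u <- queue[[1L]]
      queue <- queue[-1L]
      nb <- which(adj[u, ] & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

# Deterministic per-replicate substream seeds derived from one root seed.
.substreamSeeds <- function(seed, n) {
  if (!is.null(seed)) set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

# Node ages of an ultrametric tree (tips at age 0), checked against the
# relative tolerance of the ultrametric invariant.
.nodeAges <- function(tree, tol = 1e-6, what = "tree") {
  if (!inherits(tree, "phylo")) stop(what, " must be an ape 'phylo' object")
  if (is.null(tree$edge.length)) stop(what, " must have branch lengths")
  depths <- ape::node.depth.edgelength(tree)
  ntip <- length(tree$tip.label)
  total <- max(depths[seq_len(ntip)])
  if (total <= 0) stop(what, " has zero depth")
  if (diff(range(depths[seq_len(ntip)])) > tol * total)
    stop(what, " is not ultrametric within relative tolerance ", tol)
  ages <- total - depths
  ages[seq_len(ntip)] <- 0
  ages
}
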