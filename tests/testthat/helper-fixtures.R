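# Small fixtures built in code, shared across test files.

# deterministic sequence pair with exact transition/transversion counts
makePQPair <- function(nTi, nTv, len = 1000L) {
  s1 <- rep("A", len)
  s2 <- s1
  if (nTi > 0L) s2[seq_len(nTi)] <- "G"                       # transitions
  if (nTv > 0L) s2[nTi + seq_len(nTv)] <- "C"                 # transversions
  c(i = paste(s1, collapse = ""), j = paste(s2, collapse = ""))
}

# random additive (tree-metric) distance matrix via a random topology with
# positive branch lengths; returns list(dm, tree)
makeAdditiveMatrix <- function(nTaxa, seed) {
  set.seed(seed)
  tree <- ape::rtree(nTaxa, br = function(n) stats::runif(n, 0.05, 1))
  tree <- ape::unroot(tree)
  dm <- ape::cophenetic.phylo(tree)
  ids <- sort(rownames(dm))
  list(dm = dm[ids, ids], tree = tree)
}

# alignment in which every variable column supports the split ab | cd
# (one split column in five; the rest constant, so no pair saturates)
makeConcordantAlignment <- function(nCols = 60L) {
  split <- c(a = "A", b = "A", c = "G", d = "G")
  const <- c(a = "T", b = "T", c = "T", d = "T")
  cols <- rep(list(split, const, const, const, const),
              length.out = nCols)
  seqs <- vapply(names(split), function(id)
    paste(vapply(cols, `[[`, character(1L), id), collapse = ""),
    character(1L))
  BarcodeAlignment(seqs)
}

# two clean clusters in distance space: intra <= intraMax, inter >= interMin
makeTwoClusterMatrix <- function(n1 = 4L, n2 = 4L, intra = 0.004,
                                 inter = 0.09) {
  n <- n1 + n2
  ids <- sprintf("s%02d", seq_len(n))
  dm <- matrix(inter, n, n, dimnames = list(ids, ids))
  dm[seq_len(n1), seq_len(n1)] <- intra
  dm[n1 + seq_len(n2), n1 + seq_len(n2)] <- intra
  # mild deterministic jitter so distances are not all tied
  jit <- outer(seq_len(n), seq_len(n), function(i, j) 1e-4 * ((i * 7 + j * 3) %% 5))
  dm <- dm + (jit + t(jit)) / 2
  diag(dm) <- 0
  dm
}

# small metadata table for constructed ecology examples
makeToyMetadata <- function(ids, site, elevation, host, feeding,
                            lat = NULL, lon = NULL) {
  data.frame(sample_id = ids, site_id = site,
             latitude = if (is.null(lat)) rep(30, length(ids)) else lat,
             longitude = if (is.null(lon)) rep(100, length(ids)) else lon,
             elevation = elevation, host_genus = host,
             feeding_site = feeding, stringsAsFactors = FALSE)
}

# default synthetic dataset used by several files (cached per test run)
defaultDataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generateDataset(simulationConfig(),
                                                  seed = 4242L)
    cache
  }
})
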