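#' Majority-rule consensus of species partitions
#'
#' A pair of samples is called conspecific when it is conspecific in a strict
#' majority of the input partitions; with an even number of partitions a tie
#' counts as conspecific (lumping, the conservative choice for species
#' counts). The final species are the connected components of the resulting
#' conspecificity graph, i.e. its transitive closure; every pair whose
#' majority vote is overturned by the closure is reported via a message and
#' in the `"overturned"` attribute.
#'
#' @param partitions a list of two or more [SpeciesPartition-class] objects
#'   over the identical sample set.
#' @return a [SpeciesPartition-class]; attribute `"overturned"` holds the
#'   number of pairs voted non-conspecific but joined by transitivity.
#' @examples
#' p1 <- SpeciesPartition(c(a = "x", b = "x", c = "y"))
#' p2 <- SpeciesPartition(c(a = "x", b = "x", c = "y"))
#' p3 <- SpeciesPartition(c(a = "x", b = "z", c = "z"))
#' nSpecies(consensusPartition(list(p1, p2, p3)))  # majority keeps ab | c
#' @export
consensusPartition <- function(partitions) {
  if (!is.list(partitions) || length(partitions) < 2L)
    stop("need at least two partitions")
  if (!all(vapply(partitions, is, logical(1L), "SpeciesPartition")))
    stop("all elements must be SpeciesPartition objects")
  ids <- sort(sampleIds(partitions[[1L]]))
  for (p in partitions[-1L])
    if (!setequal(sampleIds(p), ids))
      stop("partitions cover different sample sets")
  n <- length(ids)
  npart <- length(partitions)
  votes <- matrix(0L, n, n)
  for (p in partitions) {
    a <- speciesAssignments(p)[ids]
    votes <- votes + outer(a, a, "==")
  }
  conspecific <- 2L * votes >= npart  # strict majority; ties lump
  comp <- .components(conspecific)
  overturned <- sum(outer(comp, comp, "==") & !conspecific) / 2L
  if (overturned > 0L)
    message("consensusPartition: transitive closure joined ", overturned,
            " pair(s) against their majority vote")
  labels <- stats::setNames(sprintf("cons%03d", comp), ids)
  out <- SpeciesPartition(labels)
  attr(out, "overturned") <- overturned
  out
}
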