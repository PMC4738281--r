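#' Distance-threshold clustering on a supported NJ tree
#'
#' The NJ-tree clustering rule for candidate species: the (midpoint-rooted)
#' tree is traversed from the root, and a clade is accepted as one candidate
#' species iff
#' \enumerate{
#'   \item its maximum intra-clade K2P distance is below `distThreshold`,
#'   \item the minimum K2P distance between its members and the members of
#'     its sister clade is at least `distThreshold` (vacuous at the root), and
#'   \item its bootstrap support is at least `supportMin` (vacuous for tips
#'     and for nodes without a support label).
#' }
#' Traversal recurses into rejected clades; tips reached without acceptance
#' become singleton species. Every sample is covered exactly once. The
#' defaults are the barcode conventions of 2% COI divergence and bootstrap
#' support above 70.
#'
#' @param tree an `ape::phylo` whose tips match `rownames(dm)`; internal node
#'   labels, when present, are read as bootstrap supports in `[0, 100]`. An
#'   unrooted tree (e.g. from [bootstrapNJ()]) is midpoint-rooted first.
#' @param dm symmetric K2P distance matrix.
#' @param distThreshold divergence threshold in substitutions/site
#'   (default 0.02).
#' @param supportMin minimum bootstrap support (default 70).
#' @return a [SpeciesPartition-class] covering all samples.
#' @export
clusterByThreshold <- function(tree, dm, distThreshold = 0.02,
                               supportMin = 70) {
  ids <- .checkDistanceMatrix(dm)
  if (!inherits(tree, "phylo")) stop("'tree' must be an ape 'phylo' object")
  if (!setequal(tree$tip.label, ids))
    stop("tree tips and distance-matrix ids do not match")
  if (distThreshold < 0 || distThreshold > 1)
    stop("'distThreshold' must be in [0, 1]")
  if (supportMin < 0 || supportMin > 100)
    stop("'supportMin' must be in [0, 100]")
  if (!ape::is.rooted(tree))
    tree <- phangorn::midpoint(tree, node.labels = "support")
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  kids <- split(tree$edge[, 2L], tree$edge[, 1L])
  tipsBelow <- .tipsBelow(tree)
  support <- function(node) {
    if (node <= ntip) return(NA_real_)
    lab <- tree$node.label[node - ntip]
    if (is.null(lab) || length(lab) == 0L || is.na(lab) || !nzchar(lab))
      return(NA_real_)
    suppressWarnings(as.numeric(lab))
  }
  labels <- stats::setNames(character(length(ids)), ids)
  counter <- 0L
  newLabel <- function() {
    counter <<- counter + 1L
    sprintf("sp%03d", counter)
  }
  visit <- function(node, sisterTips) {
    tips <- tree$tip.label[tipsBelow[[node]]]
    if (node <= ntip) {
      labels[tips] <<- newLabel()
      return(invisible(NULL))
    }
    condA <- length(tips) < 2L ||
      max(dm[tips, tips]) < distThreshold
    condB <- is.null(sisterTips) ||
      min(dm[tips, sisterTips, drop = FALSE]) >= distThreshold
    sup <- support(node)
    condC <- is.na(sup) || sup >= supportMin
    if (condA && condB && condC) {
      labels[tips] <<- newLabel()
      return(invisible(NULL))
    }
    ch <- kids[[as.character(node)]]
    for (i in seq_along(ch)) {
      sis <- unlist(lapply(ch[-i], function(s) tree$tip.label[tipsBelow[[s]]]))
      visit(ch[i], sis)
    }
    invisible(NULL)
  }
  visit(root, NULL)
  SpeciesPartition(labels[ids])
}

# List of tip indices below each node (tips below themselves).
.tipsBelow <- function(tree) {
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  out <- vector("list", ntip + nnode)
  for (i in seq_len(ntip)) out[[i]] <- i
  edges <- tree$edge[order(tree$edge[, 1L], decreasing = TRUE), , drop = FALSE]
  # postorder accumulation: children have larger numbers than... not in
  # general, so iterate until stable instead
  pending <- rev(unique(edges[, 1L]))
  done <- rep(FALSE, ntip + nnode)
  done[seq_len(ntip)] <- TRUE
  while (length(pending) > 0L) {
    remaining <- integer(0L)
    for (node in pending) {
      ch <- tree$edge[tree$edge[, 1L] == node, 2L]
      if (all(done[ch])) {
        out[[node]] <- sort(unlist(out[ch]))
        done[node] <- TRUE
      } else remaining <- c(remaining, node)
    }
    pending <- remaining
  }
  out
}
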