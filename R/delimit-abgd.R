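#' ABGD configuration
#'
#' Parameters of the Automatic Barcode Gap Discovery procedure: the prior
#' bounds on intraspecific divergence, the number of log-spaced prior values
#' scanned, and the minimum relative width a gap must have to count.
#'
#' @param pMin,pMax prior intraspecific divergence bounds,
#'   `0 < pMin < pMax < 1` (defaults 0.001 and 0.1).
#' @param nSteps number of log-spaced prior values in `[pMin, pMax]`
#'   (default 10).
#' @param relativeGapX minimum gap width as a multiple of the local slope
#'   (default 1.5).
#' @param slopeWindow number of preceding inter-distance gaps averaged into
#'   the local slope (default 10).
#' @return a validated list of class `abgdConfig`.
#' @export
abgdConfig <- function(pMin = 0.001, pMax = 0.1, nSteps = 10L,
                       relativeGapX = 1.5, slopeWindow = 10L) {
  if (!(pMin > 0 && pMin < pMax && pMax < 1))
    stop("need 0 < pMin < pMax < 1")
  if (nSteps < 1L) stop("'nSteps' must be >= 1")
  if (relativeGapX <= 0) stop("'relativeGapX' must be positive")
  structure(list(pMin = pMin, pMax = pMax, nSteps = as.integer(nSteps),
                 relativeGapX = relativeGapX,
                 slopeWindow = as.integer(slopeWindow)),
            class = "abgdConfig")
}

# First barcode gap reaching beyond `prior` in a sorted distance vector, or
# NA. Distances at or below the prior are presumed intraspecific, so a gap
# is eligible when its upper edge exceeds the prior (its lower edge may sit
# below it). The local slope at gap j is the mean width of the preceding
# min(slopeWindow, available) gaps; a gap counts when it is strictly wider
# than relativeGapX * slope (and strictly positive).
.firstGap <- function(dSorted, prior, config) {
  m <- length(dSorted)
  if (m < 2L) return(NA_real_)
  gaps <- diff(dSorted)
  for (j in seq_len(m - 1L)) {
    if (dSorted[j + 1L] <= prior) next
    w <- min(config$slopeWindow, j - 1L)
    slope <- if (w > 0L) mean(gaps[(j - w):(j - 1L)]) else 0
    if (gaps[j] > 0 && gaps[j] > config$relativeGapX * slope)
      return(dSorted[j])  # lower edge of the gap
  }
  NA_real_
}

# One round of gap splitting for a set of ids; returns a list of id groups
# (length 1 when no gap is found).
.abgdSplit <- function(dm, ids, prior, config) {
  if (length(ids) < 3L) return(list(ids))
  sub <- dm[ids, ids, drop = FALSE]
  dSorted <- sort(sub[upper.tri(sub)])
  edge <- .firstGap(dSorted, prior, config)
  if (is.na(edge)) return(list(ids))
  adj <- sub <= edge
  comp <- .components(adj)
  if (max(comp) == 1L) return(list(ids))
  split(ids, comp)
}

#' Automatic Barcode Gap Discovery partitions
#'
#' For each prior intraspecific divergence `p` on a log-spaced grid, the
#' sorted pairwise distances are scanned above `p` for the first gap whose
#' width exceeds `relativeGapX` times the local slope; samples are then
#' partitioned into connected components of the graph linking pairs whose
#' distance lies below the gap's lower edge, and the procedure is re-applied
#' recursively inside each component until no further split occurs. Priors at
#' which no gap is found return the single-group partition (with a message).
#'
#' @param dm symmetric K2P distance matrix for at least 3 samples.
#' @param config an [abgdConfig()].
#' @return a list with one element per prior, each a list with `prior` (the
#'   prior value) and `partition` (a [SpeciesPartition-class]). The attribute
#'   `"modal"` holds the index of the modal partition across priors (see
#'   [abgdModalPartition()]).
#' @export
abgdPartitions <- function(dm, config = abgdConfig()) {
  ids <- .checkDistanceMatrix(dm)
  if (nrow(dm) < 3L) stop("ABGD requires at least 3 samples")
  if (!inherits(config, "abgdConfig")) stop("'config' must be an abgdConfig")
  priors <- exp(seq(log(config$pMin), log(config$pMax),
                    length.out = config$nSteps))
  out <- vector("list", length(priors))
  for (k in seq_along(priors)) {
    prior <- priors[k]
    groups <- list(ids)
    repeat {
      nxt <- list()
      changed <- FALSE
      for (g in groups) {
        parts <- .abgdSplit(dm, g, prior, config)
        if (length(parts) > 1L) changed <- TRUE
        nxt <- c(nxt, parts)
      }
      groups <- nxt
      if (!changed) break
    }
    if (length(groups) == 1L)
      message(sprintf("abgdPartitions: no barcode gap at prior %.4g", prior))
    labels <- stats::setNames(character(length(ids)), ids)
    for (i in seq_along(groups))
      labels[groups[[i]]] <- sprintf("abgd%03d", i)
    out[[k]] <- list(prior = prior, partition = SpeciesPartition(labels[ids]))
  }
  key <- vapply(out, function(x) .partitionKey(x$partition), character(1L))
  tab <- table(key)
  modalKey <- names(tab)[which.max(tab)]
  attr(out, "modal") <- which(key == modalKey)[1L]
  class(out) <- "abgdResult"
  out
}

#' Modal ABGD partition across priors
#'
#' Convenience selector: the partition (up to label renaming) returned by the
#' largest number of prior values; ties resolve to the smallest such prior.
#'
#' @param x the result of [abgdPartitions()].
#' @return a [SpeciesPartition-class].
#' @export
abgdModalPartition <- function(x) {
  if (!inherits(x, "abgdResult")) stop("'x' must come from abgdPartitions()")
  x[[attr(x, "modal")]]$partition
}

# Canonical label-free key for comparing partitions.
.partitionKey <- function(partition) {
  a <- speciesAssignments(partition)
  a <- a[order(names(a))]
  canon <- match(a, unique(a))
  paste(canon, collapse = ",")
}

#' @export
print.abgdResult <- function(x, ...) {
  cat("ABGD partitions across", length(x), "priors\n")
  for (el in x)
    cat(sprintf("  prior %.4g -> %d groups\n", el$prior,
                nSpecies(el$partition)))
  cat("  modal partition:", nSpecies(abgdModalPartition(x)), "groups\n")
  invisible(x)
}
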