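#' Sample identifiers
#'
#' @param x a [BarcodeAlignment-class] or [SpeciesPartition-class].
#' @return character vector of sample ids.
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname sampleIds
#' @export
setMethod("sampleIds", "BarcodeAlignment", function(x) names(x@seqs))

#' @rdname sampleIds
#' @export
setMethod("sampleIds", "SpeciesPartition", function(x) names(x@assignments))

#' Number of delimited species
#'
#' @param x a [SpeciesPartition-class] or [GMYCResult-class].
#' @return integer count of distinct species labels (for a GMYC fit, the
#'   entity count at the maximum-likelihood threshold).
#' @export
setGeneric("nSpecies", function(x) standardGeneric("nSpecies"))

#' @rdname nSpecies
#' @export
setMethod("nSpecies", "SpeciesPartition",
          function(x) length(unique(x@assignments)))

#' @rdname nSpecies
#' @export
setMethod("nSpecies", "GMYCResult", function(x) x@entities)

#' Species assignments as a vector
#'
#' @param x a [SpeciesPartition-class].
#' @return named character vector `sample_id -> species_label`.
#' @export
setGeneric("speciesAssignments",
           function(x) standardGeneric("speciesAssignments"))

#' @rdname speciesAssignments
#' @export
setMethod("speciesAssignments", "SpeciesPartition", function(x) x@assignments)

#' Alignment width (number of columns)
#'
#' @param x a [BarcodeAlignment-class].
#' @return integer alignment length.
#' @export
setGeneric("alignmentWidth", function(x) standardGeneric("alignmentWidth"))

#' @rdname alignmentWidth
#' @export
setMethod("alignmentWidth", "BarcodeAlignment",
          function(x) Biostrings::width(x@seqs)[1L])

#' Number of samples in an alignment
#'
#' @param x a [BarcodeAlignment-class].
#' @return integer sequence count.
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' @rdname nSamples
#' @export
setMethod("nSamples", "BarcodeAlignment", function(x) length(x@seqs))

#' @export
setMethod("as.character", "BarcodeAlignment",
          function(x, ...) as.character(x@seqs))

#' @export
setMethod("show", "BarcodeAlignment", function(object) {
  cat("BarcodeAlignment:", nSamples(object), "sequences x",
      alignmentWidth(object), "columns\n")
  ids <- sampleIds(object)
  shown <- utils::head(ids, 5L)
  cat("  samples:", paste(shown, collapse = ", "),
      if (length(ids) > 5L) "..." else "", "\n")
})

#' @export
setMethod("show", "SpeciesPartition", function(object) {
  cat("SpeciesPartition:", length(object@assignments), "samples in",
      nSpecies(object), "species\n")
  tab <- sort(table(object@assignments), decreasing = TRUE)
  cat("  largest species:",
      paste(sprintf("%s (%d)", utils::head(names(tab), 3L),
                    utils::head(as.integer(tab), 3L)), collapse = ", "), "\n")
})

#' @export
setMethod("show", "GMYCResult", function(object) {
  cat("GMYC single-threshold fit\n")
  cat(sprintf("  ML entities: %d (CI %d-%d) at threshold age %.6g\n",
              object@entities, object@ciEntities[1L], object@ciEntities[2L],
              object@threshold))
  cat(sprintf("  lnL(GMYC) = %.4f, lnL(null) = %.4f, LR = %.4f, p = %.4g\n",
              object@lnLGmyc, object@lnLNull, object@statistic, object@pValue))
})

#' @export
setMethod("show", "DivRateResult", function(object) {
  cat("Diversification rate-model comparison\n")
  print(object@fits, row.names = FALSE)
  cat(sprintf("  deltaAIC_RC = %.4f (best model: %s)\n",
              object@deltaAICrc, object@bestModel))
})

#' @export
setMethod("show", "RCResult", function(object) {
  sig <- object@table[object@table$significant, , drop = FALSE]
  cat("Relative cladogenesis test:", nrow(object@table), "nodes tested,",
      nrow(sig), "significant at alpha =", object@alpha, "\n")
  if (nrow(sig) > 0L) print(utils::head(sig, 10L), row.names = FALSE)
})

#' @export
setMethod("show", "SyntheticDataset", function(object) {
  cat("SyntheticDataset:", nSamples(object@alignment), "barcodes,",
      nSpecies(object@partition), "true species\n")
})

#' @export
setMethod("as.data.frame", "SpeciesPartition", function(x, ...) {
  data.frame(sample_id = names(x@assignments),
             species_label = unname(x@assignments),
             stringsAsFactors = FALSE)
})
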