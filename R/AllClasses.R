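#' @import methods
#' @importFrom Biostrings DNAStringSet width
NULL

#' Aligned barcode sequences
#'
#' An S4 container for a fixed-length nucleotide alignment, the barcode matrix
#' every downstream analysis consumes. Wraps a [Biostrings::DNAStringSet] and
#' enforces that all sequences have equal length and that sample identifiers
#' are unique and non-empty. Characters other than `A`, `C`, `G`, `T`, `N`
#' and `-` are normalised to `N` at construction; `U` is mapped to `T` and
#' lowercase to uppercase.
#'
#' @slot seqs a [Biostrings::DNAStringSet] with one named entry per sample.
#'
#' @seealso [readFastaAlignment()], [k2pMatrix()], [classifySites()]
#' @export
setClass("BarcodeAlignment", slots = c(seqs = "DNAStringSet"))

setValidity("BarcodeAlignment", function(object) {
  s <- object@seqs
  if (length(s) < 1L) return("alignment must contain at least one sequence")
  ids <- names(s)
  if (is.null(ids) || any(is.na(ids)) || any(!nzchar(ids)))
    return("every sequence must carry a non-empty sample identifier")
  if (anyDuplicated(ids))
    return(paste0("duplicate sample identifiers: ",
                  paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  w <- Biostrings::width(s)
  if (length(unique(w)) != 1L) {
    bad <- ids[w != w[1L]][1L]
    return(paste0("ragged alignment: sequence '", bad, "' has length ",
                  w[ids == bad][1L], ", expected ", w[1L]))
  }
  if (w[1L] < 1L) return("alignment length must be >= 1")
  TRUE
})

#' Construct a BarcodeAlignment
#'
#' @param x a named character vector of equal-length nucleotide strings, or a
#'   [Biostrings::DNAStringSet].
#' @return a [BarcodeAlignment-class] object.
#' @examples
#' aln <- BarcodeAlignment(c(a = "ACGT", b = "ACGA"))
#' alignmentWidth(aln)
#' @export
BarcodeAlignment <- function(x) {
  if (is(x, "DNAStringSet")) x <- as.character(x)
  if (!is.character(x)) stop("'x' must be a character vector or DNAStringSet")
  ids <- names(x)
  if (is.null(ids)) stop("sequences must be named by sample identifier")
  w <- nchar(x)
  if (length(unique(w)) != 1L) {
    bad <- which(w != w[1L])[1L]
    stop("ragged alignment: sequence '", ids[bad], "' has length ", w[bad],
         ", expected ", w[1L])
  }
  x <- toupper(x)
  x <- chartr("U", "T", x)
  x <- gsub("[^ACGTN-]", "N", x)
  new("BarcodeAlignment", seqs = Biostrings::DNAStringSet(x))
}

#' A species partition
#'
#' Assignment of every sample to a candidate-species label: the output of the
#' delimitation methods and the grouping key for all ecological summaries.
#'
#' @slot assignments named character vector, `sample_id -> species_label`.
#' @seealso [clusterByThreshold()], [abgdPartitions()], [gmycFit()],
#'   [consensusPartition()]
#' @export
setClass("SpeciesPartition", slots = c(assignments = "character"))

setValidity("SpeciesPartition", function(object) {
  a <- object@assignments
  if (length(a) < 1L) return("partition must cover at least one sample")
  ids <- names(a)
  if (is.null(ids) || any(!nzchar(ids))) return("sample ids must be non-empty")
  if (anyDuplicated(ids))
    return("every sample must appear exactly once in a partition")
  if (any(is.na(a)) || any(!nzchar(a))) return("species labels must be non-empty")
  TRUE
})

#' Construct a SpeciesPartition
#'
#' @param assignments named character vector mapping sample ids to species
#'   labels.
#' @return a [SpeciesPartition-class] object.
#' @examples
#' p <- SpeciesPartition(c(s1 = "spA", s2 = "spA", s3 = "spB"))
#' nSpecies(p)
#' @export
SpeciesPartition <- function(assignments) {
  new("SpeciesPartition", assignments = assignments)
}

#' Single-threshold GMYC fit
#'
#' Result of fitting the generalized mixed Yule coalescent model: the
#' maximum-likelihood threshold age separating between-species (Yule) from
#' within-species (coalescent) branching, the implied number of independent
#' entities with its confidence set, the likelihood-ratio test against the
#' single-process null, and the fitted rate parameters.
#'
#' @slot threshold ML threshold age (time before present).
#' @slot entities number of entities (clusters plus singletons) at the ML
#'   threshold.
#' @slot ciEntities integer length-2: min and max entity counts over thresholds
#'   within 1.92 log-likelihood units of the maximum.
#' @slot lnLGmyc,lnLNull maximized log-likelihoods of mixed and null models.
#' @slot statistic likelihood-ratio statistic `2 * (lnLGmyc - lnLNull)`.
#' @slot pValue chi-squared (df = 3) p-value.
#' @slot parameters fitted `(lambda_div, p_div, lambda_coal, p_coal)`.
#' @slot nullParameters fitted `(lambda, p)` of the null model.
#' @slot profile data.frame with one row per candidate threshold: age,
#'   maximized lnL, entity/cluster/singleton counts.
#' @slot partition the [SpeciesPartition-class] induced by the ML threshold.
#' @export
setClass("GMYCResult",
         slots = c(threshold = "numeric", entities = "integer",
                   ciEntities = "integer", lnLGmyc = "numeric",
                   lnLNull = "numeric", statistic = "numeric",
                   pValue = "numeric", parameters = "numeric",
                   nullParameters = "numeric", profile = "data.frame",
                   partition = "SpeciesPartition"))

#' Diversification rate-model comparison
#'
#' Maximum-likelihood fits of the five LASER-style diversification models to a
#' set of branching times, together with the rate-constancy statistic
#' `deltaAICrc = AIC_RC - AIC_RV` (best rate-constant minus best rate-variable
#' AIC; positive values favour rate variation).
#'
#' @slot fits data.frame with one row per model: `model`, `lnL`, `nParams`,
#'   `AIC`.
#' @slot params named list of fitted parameter vectors, one per model.
#' @slot deltaAICrc the rate-constancy statistic.
#' @slot bestModel name of the model with the lowest AIC.
#' @seealso [fitRateModels()], [deltaAICrc()]
#' @export
setClass("DivRateResult",
         slots = c(fits = "data.frame", params = "list",
                   deltaAICrc = "numeric", bestModel = "character"))

#' Relative cladogenesis test result
#'
#' Per-node probabilities, under the equal-rates Markov null, that a lineage
#' alive at that node's age left at least the observed number of descendants,
#' with Bonferroni adjustment over all nodes tested.
#'
#' @slot table data.frame with one row per internal node: `node`, `age`, `k`
#'   (lineages alive immediately after the split), `tipsLarger`/`tipsSmaller`
#'   (daughter-clade tip counts), `pRaw`, `pAdjusted`, `significant`.
#' @slot alpha significance level applied to the adjusted p-values.
#' @slot nTests Bonferroni divisor (number of node tests performed).
#' @seealso [rcTest()]
#' @export
setClass("RCResult",
         slots = c(table = "data.frame", alpha = "numeric", nTests = "integer"))

#' Synthetic barcode dataset
#'
#' A simulated barcode study with known truth: the alignment, the true species
#' partition, the per-sample ecological metadata, and the species and gene
#' trees that generated them.
#'
#' @slot alignment a [BarcodeAlignment-class].
#' @slot partition the true [SpeciesPartition-class].
#' @slot metadata per-sample metadata data.frame (see [readSampleMetadata()]
#'   for the schema).
#' @slot geneTree,speciesTree `ape::phylo` trees (the gene tree is ultrametric,
#'   branch lengths in substitutions/site).
#' @slot config the [simulationConfig()] that produced the dataset.
#' @seealso [generateDataset()]
#' @export
setClass("SyntheticDataset",
         slots = c(alignment = "BarcodeAlignment",
                   partition = "SpeciesPartition",
                   metadata = "data.frame",
                   geneTree = "ANY", speciesTree = "ANY",
                   config = "list"))
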