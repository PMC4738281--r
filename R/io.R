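#' Read an aligned FASTA file of barcodes
#'
#' Reads a FASTA file and validates it into a [BarcodeAlignment-class]:
#' lowercase is normalised to uppercase, `U` is mapped to `T`, and ambiguity
#' codes other than `N` are mapped to `N`. All records must have the same
#' length and unique identifiers (the first whitespace-delimited token of the
#' header line).
#'
#' @param path path to a FASTA file.
#' @return a [BarcodeAlignment-class].
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">a", "ACGT", ">b", "ACGA"), f)
#' readFastaAlignment(f)
#' @export
readFastaAlignment <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty FASTA file: ", path)
  hdr <- grepl("^>", lines)
  if (!hdr[1L]) stop("not a FASTA file (first line is not a header): ", path)
  ids <- sub("\\s.*$", "", sub("^>", "", lines[hdr]))
  rec <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], rec[!hdr]),
                 function(x) paste(x, collapse = ""), character(1L))
  if (length(seqs) != length(ids)) stop("FASTA record without sequence in ", path)
  if (anyDuplicated(ids))
    stop("duplicate FASTA identifiers: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  names(seqs) <- ids
  BarcodeAlignment(seqs)
}

#' Write a BarcodeAlignment to FASTA
#'
#' @param aln a [BarcodeAlignment-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeFastaAlignment <- function(aln, path) {
  stopifnot(is(aln, "BarcodeAlignment"))
  Biostrings::writeXStringSet(aln@seqs, filepath = path, width = 70L)
  invisible(path)
}

#' Read and write Newick trees
#'
#' Thin validated wrappers around [ape::read.tree()] / [ape::write.tree()].
#' Internal node labels are preserved; when they are integers in `[0, 100]`
#' they are interpreted downstream as bootstrap supports. Branch lengths must
#' be present and non-negative.
#'
#' @param path a Newick file path.
#' @return for `readNewickTree`, an `ape::phylo`; `writeNewickTree` returns
#'   `path` invisibly.
#' @examples
#' f <- tempfile(fileext = ".nwk")
#' writeLines("((A:1,B:1)95:1,C:2);", f)
#' tr <- readNewickTree(f)
#' tr$node.label
#' @export
readNewickTree <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) stop("Newick parse error in ", path,
                                            ": ", conditionMessage(e)))
  if (is.null(tree)) stop("Newick parse error in ", path)
  if (is.null(tree$edge.length))
    stop("tree in ", path, " has no branch lengths")
  if (any(tree$edge.length < 0))
    stop("negative branch length in ", path)
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip labels in ", path)
  tree
}

#' @rdname readNewickTree
#' @param tree an `ape::phylo` object.
#' @export
writeNewickTree <- function(tree, path) {
  if (!inherits(tree, "phylo")) stop("'tree' must be an ape 'phylo' object")
  ape::write.tree(tree, file = path, digits = 12)
  invisible(path)
}

.META_REQUIRED <- c("sample_id", "site_id", "latitude", "longitude",
                    "elevation", "host_genus", "feeding_site")

#' Validate a sample metadata table
#'
#' Checks the per-sample ecological record schema: required columns present,
#' unique non-empty `sample_id`, numeric `elevation >= 0`, latitude in
#' `[-90, 90]` and longitude in `[-180, 180]`. Extra columns (e.g.
#' `host_species`, `collection_date`) are preserved untouched.
#'
#' @param meta a data.frame.
#' @return the validated data.frame (invisibly for `validateMetadata`).
#' @export
validateMetadata <- function(meta) {
  if (!is.data.frame(meta)) stop("metadata must be a data.frame")
  missing <- setdiff(.META_REQUIRED, names(meta))
  if (length(missing) > 0L)
    stop("metadata is missing required column(s): ",
         paste(missing, collapse = ", "))
  if (anyDuplicated(meta$sample_id))
    stop("duplicate sample_id in metadata: ",
         paste(unique(meta$sample_id[duplicated(meta$sample_id)]),
               collapse = ", "))
  if (any(!nzchar(as.character(meta$sample_id))))
    stop("empty sample_id in metadata")
  for (col in c("latitude", "longitude", "elevation")) {
    v <- suppressWarnings(as.numeric(meta[[col]]))
    bad <- which(is.na(v) & !is.na(meta[[col]]))
    if (length(bad) > 0L)
      stop("non-numeric ", col, " in metadata row ", bad[1L])
    if (anyNA(v)) stop("missing ", col, " in metadata row ", which(is.na(v))[1L])
    meta[[col]] <- v
  }
  if (any(meta$elevation < 0))
    stop("negative elevation in metadata row ", which(meta$elevation < 0)[1L])
  if (any(abs(meta$latitude) > 90))
    stop("latitude outside [-90, 90] in metadata row ",
         which(abs(meta$latitude) > 90)[1L])
  if (any(abs(meta$longitude) > 180))
    stop("longitude outside [-180, 180] in metadata row ",
         which(abs(meta$longitude) > 180)[1L])
  invisible(meta)
}

#' Read a per-sample metadata TSV
#'
#' The table must be tab-separated with a header row containing at least
#' `sample_id`, `site_id`, `latitude`, `longitude`, `elevation`, `host_genus`
#' and `feeding_site`. Coordinates are decimal degrees (WGS84), elevation is
#' in metres. Extra columns are kept as-is.
#'
#' @param path path to the TSV file.
#' @return a validated data.frame, one row per sample.
#' @export
readSampleMetadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  meta <- utils::read.delim(path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE, check.names = FALSE)
  out <- validateMetadata(meta)
  out
}

#' @rdname readSampleMetadata
#' @param meta a metadata data.frame.
#' @export
writeSampleMetadata <- function(meta, path) {
  validateMetadata(meta)
  utils::write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write species partitions as two-column TSV
#'
#' The on-disk format is a header row `sample_id<TAB>species_label` followed
#' by one row per sample.
#'
#' @param path file path.
#' @return for `readPartition`, a [SpeciesPartition-class].
#' @export
readPartition <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.delim(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  if (!all(c("sample_id", "species_label") %in% names(d)))
    stop("partition file must have columns sample_id and species_label")
  SpeciesPartition(stats::setNames(as.character(d$species_label),
                                   as.character(d$sample_id)))
}

#' @rdname readPartition
#' @param partition a [SpeciesPartition-class].
#' @export
writePartition <- function(partition, path) {
  stopifnot(is(partition, "SpeciesPartition"))
  utils::write.table(as.data.frame(partition), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a distance matrix as square TSV
#'
#' @param dm symmetric distance matrix with id dimnames.
#' @param path output path.
#' @export
writeDistanceMatrix <- function(dm, path) {
  .checkDistanceMatrix(dm)
  utils::write.table(cbind(sample_id = rownames(dm), as.data.frame(dm)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
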