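# Divergence and richness summaries stratified by elevation, host plant,
# feeding site and geography.

.defaultBands <- function() seq(1500, 5000, by = 500)

.bandLabels <- function(bands) {
  paste0(bands[-length(bands)], "-", bands[-1L])
}

# mean/sd/count of a distance vector, NA-safe for empty input
.pairStats <- function(d) {
  if (length(d) == 0L)
    return(c(mean = NA_real_, sd = NA_real_, n = 0))
  c(mean = mean(d), sd = if (length(d) > 1L) stats::sd(d) else 0, n = length(d))
}

.alignEcologyInputs <- function(dm, partition, metadata) {
  ids <- .checkDistanceMatrix(dm)
  if (!setequal(ids, sampleIds(partition)))
    stop("distance matrix and partition cover different samples")
  if (!all(ids %in% metadata$sample_id))
    stop("metadata is missing sample(s): ",
         paste(utils::head(setdiff(ids, metadata$sample_id), 3L),
               collapse = ", "))
  metadata[match(ids, metadata$sample_id), , drop = FALSE]
}

#' Intra- and interspecific divergence by elevation band
#'
#' Each individual is assigned to the half-open band `[low, high)` containing
#' its own collection elevation. Within each band, the intraspecific summary
#' is taken over conspecific pairs and the interspecific summary over
#' heterospecific pairs, both individuals collected in the band. Individuals
#' whose elevation falls outside every band are excluded with a message.
#'
#' @param dm symmetric K2P distance matrix.
#' @param partition a [SpeciesPartition-class] over the same samples.
#' @param metadata validated metadata table (see [readSampleMetadata()]).
#' @param bands band edges in metres; the default is 500-m bands between
#'   1500 and 5000 m.
#' @return data.frame with one row per band: `band`, `n_individuals`,
#'   `n_species`, `inter_mean`, `inter_sd`, `inter_pairs`, `intra_mean`,
#'   `intra_sd`, `intra_pairs` (NA means no such pairs exist in the band).
#' @export
divergenceByBand <- function(dm, partition, metadata,
                             bands = .defaultBands()) {
  meta <- .alignEcologyInputs(dm, validatePartitionInput(partition), metadata)
  sp <- speciesAssignments(partition)[meta$sample_id]
  idx <- findInterval(meta$elevation, bands, rightmost.closed = FALSE)
  outside <- idx < 1L | idx >= length(bands)
  if (any(outside))
    message("divergenceByBand: excluded ", sum(outside),
            " individual(s) with elevation outside all bands")
  labs <- .bandLabels(bands)
  rows <- lapply(seq_along(labs), function(b) {
    sel <- which(idx == b & !outside)
    res <- data.frame(band = labs[b], n_individuals = length(sel),
                      n_species = length(unique(sp[sel])),
                      inter_mean = NA_real_, inter_sd = NA_real_,
                      inter_pairs = 0L, intra_mean = NA_real_,
                      intra_sd = NA_real_, intra_pairs = 0L)
    if (length(sel) >= 2L) {
      sub <- dm[meta$sample_id[sel], meta$sample_id[sel], drop = FALSE]
      same <- outer(sp[sel], sp[sel], "==")
      ut <- upper.tri(sub)
      inter <- .pairStats(sub[ut & !same])
      intra <- .pairStats(sub[ut & same])
      res$inter_mean <- inter["mean"]; res$inter_sd <- inter["sd"]
      res$inter_pairs <- inter["n"]
      res$intra_mean <- intra["mean"]; res$intra_sd <- intra["sd"]
      res$intra_pairs <- intra["n"]
    }
    res
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

validatePartitionInput <- function(partition) {
  if (!is(partition, "SpeciesPartition"))
    stop("'partition' must be a SpeciesPartition")
  partition
}

#' Intra- and interspecific divergence by ecological variables
#'
#' Every pair of individuals is labelled by the 2x2x2 combination of three
#' factors: allopatric vs sympatric (different vs same `site_id`), same vs
#' different `feeding_site`, and hosts in one genus vs different genera
#' (equal vs unequal `host_genus`). Within each combination, intraspecific
#' (conspecific) and interspecific pair distances are summarised. Pairs
#' involving a missing factor value are excluded with a message.
#'
#' @inheritParams divergenceByBand
#' @return data.frame with one row per factor combination: `geography`,
#'   `feeding`, `host`, pair counts and mean/sd of inter- and intraspecific
#'   K2P distance.
#' @export
divergenceByEnvironment <- function(dm, partition, metadata) {
  meta <- .alignEcologyInputs(dm, validatePartitionInput(partition), metadata)
  ids <- meta$sample_id
  sp <- speciesAssignments(partition)[ids]
  ok <- !is.na(meta$site_id) & nzchar(as.character(meta$site_id)) &
    !is.na(meta$feeding_site) & nzchar(as.character(meta$feeding_site)) &
    !is.na(meta$host_genus) & nzchar(as.character(meta$host_genus))
  if (any(!ok))
    message("divergenceByEnvironment: excluded ", sum(!ok),
            " individual(s) with missing factor values")
  sel <- which(ok)
  site <- as.character(meta$site_id)[sel]
  feed <- as.character(meta$feeding_site)[sel]
  host <- as.character(meta$host_genus)[sel]
  sub <- dm[ids[sel], ids[sel], drop = FALSE]
  spS <- sp[sel]
  ut <- upper.tri(sub)
  geoF <- ifelse(outer(site, site, "=="), "sympatric", "allopatric")
  feedF <- ifelse(outer(feed, feed, "=="), "same feeding site",
                  "different feeding site")
  hostF <- ifelse(outer(host, host, "=="), "hosts in one genus",
                  "hosts in different genera")
  sameSp <- outer(spS, spS, "==")
  cells <- expand.grid(geography = c("allopatric", "sympatric"),
                       feeding = c("same feeding site",
                                   "different feeding site"),
                       host = c("hosts in one genus",
                                "hosts in different genera"),
                       stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    inCell <- ut & geoF == cells$geography[i] & feedF == cells$feeding[i] &
      hostF == cells$host[i]
    inter <- .pairStats(sub[inCell & !sameSp])
    intra <- .pairStats(sub[inCell & sameSp])
    data.frame(cells[i, , drop = FALSE],
               inter_mean = inter["mean"], inter_sd = inter["sd"],
               inter_pairs = inter["n"],
               intra_mean = intra["mean"], intra_sd = intra["sd"],
               intra_pairs = intra["n"])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Species richness per elevation band
#'
#' A species counts in every half-open band `[low, high)` that intersects its
#' observed elevation range (the `[min, max]` of its collection records). An
#' endemic species is one collected at a single sample site.
#'
#' @inheritParams divergenceByBand
#' @return data.frame with one row per band: `band`, `total_species`,
#'   `endemic_species`.
#' @export
richnessByBand <- function(partition, metadata, bands = .defaultBands()) {
  validatePartitionInput(partition)
  sp <- speciesAssignments(partition)
  meta <- metadata[match(names(sp), metadata$sample_id), , drop = FALSE]
  if (anyNA(meta$sample_id)) stop("metadata is missing partitioned samples")
  ranges <- do.call(rbind, lapply(split(meta$elevation, sp[meta$sample_id]),
                                  range))
  endemic <- vapply(split(as.character(meta$site_id), sp[meta$sample_id]),
                    function(s) length(unique(s)) == 1L, logical(1L))
  lo <- bands[-length(bands)]
  hi <- bands[-1L]
  out <- data.frame(band = .bandLabels(bands), total_species = 0L,
                    endemic_species = 0L)
  for (b in seq_along(lo)) {
    inBand <- ranges[, 1L] < hi[b] & ranges[, 2L] >= lo[b]
    out$total_species[b] <- sum(inBand)
    out$endemic_species[b] <- sum(inBand & endemic)
  }
  out
}

#' Species richness per host plant genus
#'
#' Distinct species per host genus; a species collected from several genera
#' is counted in each.
#'
#' @inheritParams divergenceByBand
#' @return data.frame with one row per host genus: `host_genus`,
#'   `total_species`, `endemic_species`, `n_samples`.
#' @export
richnessByHost <- function(partition, metadata) {
  validatePartitionInput(partition)
  sp <- speciesAssignments(partition)
  meta <- metadata[match(names(sp), metadata$sample_id), , drop = FALSE]
  endemicSp <- names(which(vapply(
    split(as.character(meta$site_id), sp[meta$sample_id]),
    function(s) length(unique(s)) == 1L, logical(1L))))
  hosts <- sort(unique(as.character(meta$host_genus)))
  rows <- lapply(hosts, function(h) {
    sel <- meta$host_genus == h
    spHere <- unique(sp[meta$sample_id[sel]])
    data.frame(host_genus = h, total_species = length(spHere),
               endemic_species = sum(spHere %in% endemicSp),
               n_samples = sum(sel))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Species richness on a latitude/longitude grid
#'
#' Counts distinct species with at least one record per grid cell. The grid
#' origin sits at integer degrees, so a cell is
#' `[i * cellDeg, (i + 1) * cellDeg)` in each coordinate. This is the numeric
#' layer behind a species-density map; rendering is out of scope.
#'
#' @inheritParams divergenceByBand
#' @param cellDeg cell size in decimal degrees (`> 0`).
#' @return data.frame with one row per occupied cell: `cell_lat`, `cell_lon`
#'   (lower-left corner), `richness`.
#' @export
gridRichness <- function(partition, metadata, cellDeg = 1) {
  validatePartitionInput(partition)
  if (cellDeg <= 0) stop("'cellDeg' must be positive")
  sp <- speciesAssignments(partition)
  meta <- metadata[match(names(sp), metadata$sample_id), , drop = FALSE]
  cellLat <- floor(meta$latitude / cellDeg) * cellDeg
  cellLon <- floor(meta$longitude / cellDeg) * cellDeg
  key <- paste(cellLat, cellLon, sep = "|")
  agg <- tapply(sp[meta$sample_id], key, function(s) length(unique(s)))
  parts <- strsplit(names(agg), "|", fixed = TRUE)
  out <- data.frame(
    cell_lat = vapply(parts, function(p) as.numeric(p[1L]), numeric(1L)),
    cell_lon = vapply(parts, function(p) as.numeric(p[2L]), numeric(1L)),
    richness = as.integer(agg))
  out[order(out$cell_lat, out$cell_lon), , drop = FALSE]
}

#' Species occupancy across sample sites
#'
#' Histogram of species over the number of distinct sites they occupy, with
#' the two headline counts: species found at exactly one site and species
#' found at more than ten sites.
#'
#' @inheritParams divergenceByBand
#' @return a list with `histogram` (data.frame `n_sites`, `n_species`),
#'   `singleSite` and `moreThanTenSites` counts.
#' @export
occupancySummary <- function(partition, metadata) {
  validatePartitionInput(partition)
  sp <- speciesAssignments(partition)
  meta <- metadata[match(names(sp), metadata$sample_id), , drop = FALSE]
  nSites <- vapply(split(as.character(meta$site_id), sp[meta$sample_id]),
                   function(s) length(unique(s)), integer(1L))
  tab <- table(nSites)
  list(histogram = data.frame(n_sites = as.integer(names(tab)),
                              n_species = as.integer(tab)),
       singleSite = sum(nSites == 1L),
       moreThanTenSites = sum(nSites > 10L))
}
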