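#' Simulation configuration
#'
#' Study conditions for the synthetic barcode generator. The defaults mirror
#' a high-elevation conifer-aphid barcode survey: 658-bp COI-like sequences
#' with strongly AT-biased composition (T 0.39, C 0.15, A 0.36, G 0.10),
#' shallow within-species coalescent variation (`theta = 0.002`
#' substitutions/site), species divergences up to twice the 0.10 root depth,
#' a minimum species age (`stemMin`) reproducing the barcode gap between
#' intraspecific (~0.001-0.005) and interspecific (>= 0.05) distances,
#' sampling sites spread over elevations 1500-5000 m, six conifer host
#' genera, and three feeding sites.
#'
#' @param nSpecies number of species on the simulated species tree.
#' @param individualsPerSpecies individuals sampled per species (scalar or
#'   length-2 range sampled uniformly per species).
#' @param yuleRate per-lineage speciation rate of the Yule species tree (the
#'   tree is subsequently rescaled, so this shapes only relative node ages).
#' @param treeDepth root age of the species tree in substitutions/site.
#' @param stemMin minimum species age in substitutions/site: raw Yule node
#'   ages are mapped affinely into `[stemMin, treeDepth]`, so every
#'   between-species divergence is at least `2 * stemMin`.
#' @param theta within-species coalescent scale in substitutions/site
#'   (`E[TMRCA] = theta * (1 - 1/m)` for `m` sampled individuals).
#' @param seqLength alignment length in columns.
#' @param kappa transition/transversion rate ratio of the two-class
#'   substitution process.
#' @param baseFreqs root base frequencies, named `T`, `C`, `A`, `G`.
#' @param nSites number of sampling sites available to the metadata
#'   simulator.
#' @param elevationRange elevation bounds for sites, in metres.
#' @param hostGenera character vector of host genera.
#' @param hostWeights sampling weights for `hostGenera`.
#' @param feedingSites character vector of feeding-site categories.
#' @param lonRange,latRange bounding box for site coordinates, decimal
#'   degrees.
#' @param seed root seed for [generateDataset()].
#' @return a validated list of class `simConfig`.
#' @export
simulationConfig <- function(nSpecies = 20L,
                             individualsPerSpecies = 5L,
                             yuleRate = 1,
                             treeDepth = 0.10,
                             stemMin = 0.025,
                             theta = 0.002,
                             seqLength = 658L,
                             kappa = 8,
                             baseFreqs = c(T = 0.39, C = 0.15,
                                           A = 0.36, G = 0.10),
                             nSites = 25L,
                             elevationRange = c(1500, 5000),
                             hostGenera = c("Picea", "Abies", "Pinus",
                                            "Cupressaceae", "Larix",
                                            "Tsuga"),
                             hostWeights = c(0.34, 0.24, 0.14, 0.10,
                                             0.09, 0.09),
                             feedingSites = c("young-twig", "old-branch",
                                              "trunk"),
                             lonRange = c(98, 105),
                             latRange = c(26, 34),
                             seed = NULL) {
  if (nSpecies < 2L) stop("'nSpecies' must be >= 2")
  if (any(individualsPerSpecies < 1L)) stop("individuals per species >= 1")
  if (yuleRate <= 0 || treeDepth <= 0 || theta <= 0 || kappa <= 0)
    stop("rates and scales must be positive")
  if (stemMin < 0 || stemMin >= treeDepth)
    stop("'stemMin' must lie in [0, treeDepth)")
  if (seqLength < 1L) stop("'seqLength' must be >= 1")
  if (!setequal(names(baseFreqs), c("T", "C", "A", "G")))
    stop("'baseFreqs' must be named T, C, A, G")
  if (abs(sum(baseFreqs) - 1) > 1e-9) stop("'baseFreqs' must sum to 1")
  if (length(hostWeights) != length(hostGenera))
    stop("'hostWeights' must match 'hostGenera'")
  structure(list(nSpecies = as.integer(nSpecies),
                 individualsPerSpecies = as.integer(individualsPerSpecies),
                 yuleRate = yuleRate, treeDepth = treeDepth,
                 stemMin = stemMin, theta = theta,
                 seqLength = as.integer(seqLength), kappa = kappa,
                 baseFreqs = baseFreqs[c("T", "C", "A", "G")],
                 nSites = as.integer(nSites),
                 elevationRange = elevationRange, hostGenera = hostGenera,
                 hostWeights = hostWeights / sum(hostWeights),
                 feedingSites = feedingSites, lonRange = lonRange,
                 latRange = latRange, seed = seed),
            class = "simConfig")
}

# Forward Yule simulation from two root lineages; returns a phylo plus the
# raw (unscaled) split times so the inter-event waiting times remain
# testable against their Exp(k * lambda) expectation.
.simulateYuleRaw <- function(nTips, lambda) {
  splitTime <- numeric(nTips - 1L)     # time after root of each split
  splitTime[1L] <- 0
  # active lineages: parent internal node index and birth time
  parent <- c(1L, 1L)
  birth <- c(0, 0)
  nextNode <- 2L
  edges <- NULL
  lengthsOut <- NULL
  now <- 0
  while (length(parent) < nTips) {
    k <- length(parent)
    now <- now + stats::rexp(1L, rate = k * lambda)
    pick <- sample.int(k, 1L)
    splitTime[nextNode] <- now
    edges <- rbind(edges, c(parent[pick], nextNode))
    lengthsOut <- c(lengthsOut, now - birth[pick])
    parent <- c(parent[-pick], nextNode, nextNode)
    birth <- c(birth[-pick], now, now)
    nextNode <- nextNode + 1L
  }
  tail <- stats::rexp(1L, rate = nTips * lambda)
  depth <- now + tail
  tipId <- seq_along(parent)
  for (i in tipId) {
    edges <- rbind(edges, c(parent[i], nTips + i))  # temp tip ids offset
    lengthsOut <- c(lengthsOut, depth - birth[i])
  }
  # renumber into ape convention: tips 1..n, internals n+1..2n-1 (root first)
  isTip <- edges[, 2L] > nTips
  newId <- integer(2L * nTips)
  newId[edges[isTip, 2L]] <- seq_len(nTips)
  internals <- sort(unique(c(edges[, 1L], edges[!isTip, 2L])))
  newId[internals] <- nTips + seq_along(internals)
  tree <- list(edge = cbind(newId[edges[, 1L]], newId[edges[, 2L]]),
               edge.length = lengthsOut,
               tip.label = sprintf("sp%03d", seq_len(nTips)),
               Nnode = nTips - 1L)
  class(tree) <- "phylo"
  tree <- ape::reorder.phylo(tree, "cladewise")
  list(tree = tree, splitTimes = splitTime, depth = depth)
}

#' Simulate a species tree
#'
#' Pure-birth (Yule) species tree with `nSpecies` tips: exponential waiting
#' times at rate `k * lambda` between splits and a uniformly chosen lineage
#' at each split, plus an `Exp(n * lambda)` tail to the present. Node ages
#' are then mapped affinely onto `[stemMin, treeDepth]` so the root sits at
#' `treeDepth` and no species is younger than `stemMin` — the barcode-gap
#' regime of a delimitable community. With `lambda2` and `shiftTime` set, the
#' speciation rate switches from `lambda` to `lambda2` at `shiftTime` after
#' the root and no rescaling is applied (for studying rate-shift inference).
#'
#' @param nSpecies number of tips (`>= 2`).
#' @param lambda per-lineage speciation rate.
#' @param treeDepth,stemMin see [simulationConfig()]; ignored when a rate
#'   shift is requested.
#' @param lambda2,shiftTime optional second rate and switch time (measured
#'   forward from the root).
#' @param seed optional seed.
#' @return an ultrametric `ape::phylo`; attribute `"rawWaits"` holds
#'   `k * lambda * (inter-event waiting time)` for each split, which are
#'   standard exponentials under the model.
#' @export
simulateSpeciesTree <- function(nSpecies, lambda = 1, treeDepth = 0.10,
                                stemMin = 0.025, lambda2 = NULL,
                                shiftTime = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nSpecies <- as.integer(nSpecies)
  if (nSpecies < 2L) stop("'nSpecies' must be >= 2")
  if (is.null(lambda2)) {
    sim <- .simulateYuleRaw(nSpecies, lambda)
    tree <- sim$tree
    waits <- diff(c(sim$splitTimes, sim$depth))
    k <- 2:nSpecies
    rawWaits <- c(waits[-length(waits)] * k[-length(k)] * lambda,
                  waits[length(waits)] * nSpecies * lambda)
    if (!is.null(treeDepth)) {
      rootRaw <- max(sim$depth - sim$splitTimes)  # raw root age
      # anchored affine map: the root lands on treeDepth and every node age
      # stays strictly above stemMin (ages scale proportionally otherwise)
      ageMap <- function(a) stemMin + a * (treeDepth - stemMin) / rootRaw
      tree <- .rescaleNodeAges(tree, ageMap)
    }
    attr(tree, "rawWaits") <- rawWaits
    return(tree)
  }
  if (is.null(shiftTime)) stop("'shiftTime' required with 'lambda2'")
  # two-rate forward simulation in natural time units, no rescaling
  parent <- c(1L, 1L); birth <- c(0, 0); nextNode <- 2L
  edges <- NULL; lens <- NULL; now <- 0
  while (length(parent) < nSpecies) {
    k <- length(parent)
    rate <- if (now >= shiftTime) lambda2 else lambda
    wait <- stats::rexp(1L, rate = k * rate)
    if (now < shiftTime && now + wait > shiftTime) {
      # memorylessness: redraw the residual at the new rate
      now <- shiftTime
      next
    }
    now <- now + wait
    pick <- sample.int(k, 1L)
    edges <- rbind(edges, c(parent[pick], nextNode))
    lens <- c(lens, now - birth[pick])
    parent <- c(parent[-pick], nextNode, nextNode)
    birth <- c(birth[-pick], now, now)
    nextNode <- nextNode + 1L
  }
  rateNow <- if (now >= shiftTime) lambda2 else lambda
  depth <- now + stats::rexp(1L, rate = nSpecies * rateNow)
  for (i in seq_along(parent)) {
    edges <- rbind(edges, c(parent[i], nSpecies + i))
    lens <- c(lens, depth - birth[i])
  }
  isTip <- edges[, 2L] > nSpecies
  newId <- integer(2L * nSpecies)
  newId[edges[isTip, 2L]] <- seq_len(nSpecies)
  internals <- sort(unique(c(edges[, 1L], edges[!isTip, 2L])))
  newId[internals] <- nSpecies + seq_along(internals)
  tree <- list(edge = cbind(newId[edges[, 1L]], newId[edges[, 2L]]),
               edge.length = lens,
               tip.label = sprintf("sp%03d", seq_len(nSpecies)),
               Nnode = nSpecies - 1L)
  class(tree) <- "phylo"
  tree <- ape::reorder.phylo(tree, "cladewise")
  attr(tree, "shiftAge") <- depth - shiftTime
  tree
}

# Apply a monotone map to the node ages of an ultrametric tree.
.rescaleNodeAges <- function(tree, ageMap) {
  ages <- .nodeAges(tree, tol = 1e-6)
  ntip <- length(tree$tip.label)
  newAges <- ages
  idx <- (ntip + 1L):(ntip + tree$Nnode)
  newAges[idx] <- ageMap(ages[idx])
  tree$edge.length <- newAges[tree$edge[, 1L]] - newAges[tree$edge[, 2L]]
  tree
}

#' Simulate a gene tree inside a species tree
#'
#' Within each species tip, a neutral coalescent over its sampled individuals
#' (coalescence rate `j (j - 1) / theta` for `j` lineages, so
#' `E[TMRCA] = theta (1 - 1/m)`), censored to coalesce below the species'
#' stem: a species whose within-species TMRCA would exceed its terminal
#' branch is resampled (a message reports the total number of resamples).
#' The between-species topology and node ages are inherited unchanged, so
#' species remain monophyletic in the gene tree and the output is
#' ultrametric.
#'
#' @param speciesTree ultrametric `ape::phylo` from [simulateSpeciesTree()].
#' @param individualsPerSpecies scalar or length-2 range.
#' @param theta coalescent scale in substitutions/site.
#' @param seed optional seed.
#' @return an ultrametric `ape::phylo` with tips `<species>_<k>`; the true
#'   partition is recoverable from the tip-label prefixes.
#' @export
simulateGeneTree <- function(speciesTree, individualsPerSpecies = 5L,
                             theta = 0.002, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (!inherits(speciesTree, "phylo")) stop("'speciesTree' must be a phylo")
  ages <- .nodeAges(speciesTree, tol = 1e-6, what = "species tree")
  ntip <- length(speciesTree$tip.label)
  stemLen <- speciesTree$edge.length[match(seq_len(ntip),
                                           speciesTree$edge[, 2L])]
  mRange <- range(as.integer(individualsPerSpecies))
  resamples <- 0L
  coalNewick <- function(labels, theta, maxDepth) {
    m <- length(labels)
    if (m == 1L) return(list(str = labels, age = 0))
    repeat {
      nodes <- as.list(labels)
      nodeAge <- rep(0, m)
      age <- 0
      ok <- TRUE
      for (j in m:2) {
        age <- age + stats::rexp(1L, rate = j * (j - 1L) / theta)
        if (age >= maxDepth) { ok <- FALSE; break }
        pair <- sample.int(length(nodes), 2L)
        merged <- sprintf("(%s:%.12g,%s:%.12g)",
                          nodes[[pair[1L]]], age - nodeAge[pair[1L]],
                          nodes[[pair[2L]]], age - nodeAge[pair[2L]])
        nodes[[pair[1L]]] <- merged
        nodeAge[pair[1L]] <- age
        nodes <- nodes[-pair[2L]]
        nodeAge <- nodeAge[-pair[2L]]
      }
      if (ok) return(list(str = nodes[[1L]], age = age))
      resamples <<- resamples + 1L
    }
  }
  # recursive newick assembly over the species tree
  kids <- split(speciesTree$edge[, 2L], speciesTree$edge[, 1L])
  build <- function(node, parentAge) {
    if (node <= ntip) {
      label <- speciesTree$tip.label[node]
      m <- if (mRange[1L] == mRange[2L]) mRange[1L] else
        sample(mRange[1L]:mRange[2L], 1L)
      sub <- coalNewick(sprintf("%s_%d", label, seq_len(m)), theta,
                        parentAge)
      return(sprintf("%s:%.12g", sub$str, parentAge - sub$age))
    }
    ch <- kids[[as.character(node)]]
    inner <- paste(vapply(ch, build, character(1L), parentAge = ages[node]),
                   collapse = ",")
    if (is.na(parentAge))
      sprintf("(%s);", inner)
    else
      sprintf("(%s):%.12g", inner, parentAge - ages[node])
  }
  root <- ntip + 1L
  txt <- build(root, NA_real_)
  if (resamples > 0L)
    message("simulateGeneTree: resampled ", resamples,
            " species coalescent(s) exceeding the stem")
  ape::read.tree(text = txt)
}

#' Evolve sequences along a tree
#'
#' Site-independent two-class (transition/transversion) substitution process
#' with rate ratio `kappa`, branch lengths in expected substitutions per
#' site, and the root sequence drawn from `baseFreqs`. Because the process
#' is symmetric, pairwise K2P estimates are consistent for the path lengths
#' regardless of the (AT-biased) root composition.
#'
#' @param tree `ape::phylo` with branch lengths in substitutions/site.
#' @param seqLength number of sites.
#' @param kappa transition/transversion rate ratio.
#' @param baseFreqs named root base frequencies (`T`, `C`, `A`, `G`).
#' @param seed optional seed.
#' @return a [BarcodeAlignment-class] with one sequence per tip.
#' @export
evolveSequences <- function(tree, seqLength = 658L, kappa = 8,
                            baseFreqs = c(T = 0.39, C = 0.15, A = 0.36,
                                          G = 0.10), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (!inherits(tree, "phylo")) stop("'tree' must be a phylo")
  if (is.null(tree$edge.length)) stop("'tree' must have branch lengths")
  bases <- c("A", "C", "G", "T")
  freqs <- baseFreqs[c("A", "C", "G", "T")]
  beta <- 1 / (kappa + 2)
  alpha <- kappa * beta
  pmatK80 <- function(t) {
    e1 <- exp(-4 * beta * t)
    e2 <- exp(-2 * (alpha + beta) * t)
    same <- 0.25 + 0.25 * e1 + 0.5 * e2
    ti <- 0.25 + 0.25 * e1 - 0.5 * e2
    tv <- 0.25 - 0.25 * e1
    # rows/cols in order A, C, G, T; transitions A<->G and C<->T
    matrix(c(same, tv, ti, tv,
             tv, same, tv, ti,
             ti, tv, same, tv,
             tv, ti, tv, same), 4L, 4L, byrow = TRUE)
  }
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  tree <- ape::reorder.phylo(tree, "cladewise")
  nNode <- ntip + tree$Nnode
  seqs <- vector("list", nNode)
  seqs[[root]] <- sample.int(4L, seqLength, replace = TRUE, prob = freqs)
  for (e in seq_len(nrow(tree$edge))) {
    parentSeq <- seqs[[tree$edge[e, 1L]]]
    P <- pmatK80(tree$edge.length[e])
    child <- parentSeq
    for (b in 1:4) {
      idx <- which(parentSeq == b)
      if (length(idx) > 0L)
        child[idx] <- sample.int(4L, length(idx), replace = TRUE,
                                 prob = P[b, ])
    }
    seqs[[tree$edge[e, 2L]]] <- child
  }
  out <- vapply(seq_len(ntip), function(i)
    paste(bases[seqs[[i]]], collapse = ""), character(1L))
  names(out) <- tree$tip.label
  BarcodeAlignment(out)
}

#' Simulate ecological metadata for a partition
#'
#' Gives each species a small home set of sampling sites (drawn from a shared
#' site pool, so sympatric co-occurrence arises whenever species share a
#' site), a host genus, and a feeding site, then assigns each individual a
#' site from its species' set. Site coordinates are drawn inside the
#' configured bounding box and site elevations uniformly inside the
#' elevation range, so all factor combinations of the divergence-by-
#' environment analysis are realizable.
#'
#' @param partition a [SpeciesPartition-class] (typically the truth of a
#'   simulated dataset).
#' @param config a [simulationConfig()].
#' @param seed optional seed.
#' @return a metadata data.frame passing [validateMetadata()].
#' @export
simulateMetadata <- function(partition, config = simulationConfig(),
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(is(partition, "SpeciesPartition"))
  sp <- speciesAssignments(partition)
  species <- unique(sp)
  nSites <- config$nSites
  sites <- data.frame(
    site_id = sprintf("site%03d", seq_len(nSites)),
    latitude = round(stats::runif(nSites, config$latRange[1L],
                                  config$latRange[2L]), 4L),
    longitude = round(stats::runif(nSites, config$lonRange[1L],
                                   config$lonRange[2L]), 4L),
    elevation = round(stats::runif(nSites, config$elevationRange[1L],
                                   config$elevationRange[2L])))
  spSites <- lapply(species, function(s)
    sample.int(nSites, min(nSites, 1L + stats::rpois(1L, 1))))
  names(spSites) <- species
  spHost <- stats::setNames(
    sample(config$hostGenera, length(species), replace = TRUE,
           prob = config$hostWeights), species)
  spFeed <- stats::setNames(
    sample(config$feedingSites, length(species), replace = TRUE), species)
  siteIdx <- vapply(names(sp), function(id) {
    pool <- spSites[[sp[[id]]]]
    if (length(pool) == 1L) pool else sample(pool, 1L)
  }, integer(1L))
  dates <- sprintf("%d-%02d-%02d", sample(2002:2013, length(sp), TRUE),
                   sample(4:10, length(sp), TRUE),
                   sample(1:28, length(sp), TRUE))
  meta <- data.frame(
    sample_id = names(sp),
    site_id = sites$site_id[siteIdx],
    latitude = sites$latitude[siteIdx],
    longitude = sites$longitude[siteIdx],
    elevation = sites$elevation[siteIdx],
    host_genus = unname(spHost[sp]),
    host_species = NA_character_,
    feeding_site = unname(spFeed[sp]),
    collection_date = dates)
  validateMetadata(meta)
  meta
}

#' Generate a complete synthetic barcode dataset
#'
#' Composes the four simulators — species tree, gene tree, sequences,
#' metadata — under one root seed, optionally writing the six standard files
#' (`seqs.fasta`, `species_tree.nwk`, `gene_tree.nwk`, `metadata.tsv`,
#' `truth_partition.tsv`, `config.txt`) to a directory.
#'
#' @param config a [simulationConfig()].
#' @param dir optional output directory (created if missing).
#' @param seed root seed; overrides `config$seed`.
#' @return a [SyntheticDataset-class].
#' @export
generateDataset <- function(config = simulationConfig(), dir = NULL,
                            seed = NULL) {
  if (!inherits(config, "simConfig")) stop("'config' must be a simulationConfig")
  if (is.null(seed)) seed <- config$seed
  if (is.null(seed)) seed <- 1L
  seeds <- .substreamSeeds(seed, 4L)
  spTree <- simulateSpeciesTree(config$nSpecies, lambda = config$yuleRate,
                                treeDepth = config$treeDepth,
                                stemMin = config$stemMin, seed = seeds[1L])
  geneTree <- simulateGeneTree(spTree, config$individualsPerSpecies,
                               theta = config$theta, seed = seeds[2L])
  aln <- evolveSequences(geneTree, seqLength = config$seqLength,
                         kappa = config$kappa,
                         baseFreqs = config$baseFreqs, seed = seeds[3L])
  labels <- sub("_[0-9]+$", "", sampleIds(aln))
  partition <- SpeciesPartition(stats::setNames(labels, sampleIds(aln)))
  meta <- simulateMetadata(partition, config, seed = seeds[4L])
  ds <- new("SyntheticDataset", alignment = aln, partition = partition,
            metadata = meta, geneTree = geneTree, speciesTree = spTree,
            config = unclass(config))
  if (!is.null(dir)) writeDataset(ds, dir)
  ds
}

#' Write a synthetic dataset to a directory
#'
#' @param ds a [SyntheticDataset-class].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
writeDataset <- function(ds, dir) {
  stopifnot(is(ds, "SyntheticDataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeFastaAlignment(ds@alignment, file.path(dir, "seqs.fasta"))
  writeNewickTree(ds@speciesTree, file.path(dir, "species_tree.nwk"))
  writeNewickTree(ds@geneTree, file.path(dir, "gene_tree.nwk"))
  writeSampleMetadata(ds@metadata, file.path(dir, "metadata.tsv"))
  writePartition(ds@partition, file.path(dir, "truth_partition.tsv"))
  cfg <- ds@config
  lines <- vapply(names(cfg), function(k)
    paste0(k, "\t", paste(format(cfg[[k]]), collapse = ",")), character(1L))
  writeLines(lines, file.path(dir, "config.txt"))
  invisible(dir)
}
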