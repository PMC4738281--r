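# Constructed toy set: 6 samples, 3 species, 2 sites, 2 hosts, 2 feeding
# sites, distances set by hand so every summary is checkable by enumeration.
makeToySet <- function() {
  ids <- c("a1", "a2", "b1", "b2", "c1", "c2")
  sp <- SpeciesPartition(stats::setNames(c("A", "A", "B", "B", "C", "C"),
                                         ids))
  dm <- matrix(0.10, 6, 6, dimnames = list(ids, ids))
  dm[1, 2] <- dm[2, 1] <- 0.001
  dm[3, 4] <- dm[4, 3] <- 0.002
  dm[5, 6] <- dm[6, 5] <- 0.003
  dm[1, 3] <- dm[3, 1] <- 0.08
  diag(dm) <- 0
  meta <- makeToyMetadata(
    ids,
    site = c("s1", "s1", "s1", "s2", "s2", "s2"),
    elevation = c(1600, 1700, 1800, 2600, 2700, 2800),
    host = c("Picea", "Picea", "Picea", "Abies", "Abies", "Abies"),
    feeding = c("trunk", "trunk", "young-twig", "young-twig", "trunk",
                "trunk"),
    lat = c(30.2, 30.2, 30.2, 31.7, 31.7, 31.7),
    lon = c(100.1, 100.1, 100.1, 101.9, 101.9, 101.9))
  list(ids = ids, partition = sp, dm = dm, meta = meta)
}

test_that("divergence by band matches pair enumeration", {
  fx <- makeToySet()
  out <- divergenceByBand(fx$dm, fx$partition, fx$meta)
  b1 <- out[out$band == "1500-2000", ]
  # band 1500-2000 holds a1, a2, b1: one intra pair (0.001), two inter
  expect_equal(b1$n_individuals, 3)
  expect_equal(b1$n_species, 2)
  expect_equal(b1$intra_mean, 0.001)
  expect_equal(b1$intra_pairs, 1)
  expect_equal(b1$inter_mean, mean(c(0.08, 0.10)))
  expect_equal(b1$inter_sd, stats::sd(c(0.08, 0.10)))
  expect_equal(b1$inter_pairs, 2)
  b2 <- out[out$band == "2500-3000", ]
  expect_equal(b2$n_individuals, 3)
  expect_equal(b2$intra_mean, 0.003)
  expect_equal(b2$inter_mean, 0.10)
  # empty band reports zero pairs and NA means
  b3 <- out[out$band == "4500-5000", ]
  expect_equal(b3$n_individuals, 0)
  expect_true(is.na(b3$inter_mean))
})

test_that("a band holding a single species has no interspecific summary", {
  ids <- c("x1", "x2")
  dm <- matrix(c(0, 0.002, 0.002, 0), 2, 2, dimnames = list(ids, ids))
  part <- SpeciesPartition(stats::setNames(c("X", "X"), ids))
  meta <- makeToyMetadata(ids, c("s1", "s1"), c(3200, 3300),
                          c("Picea", "Picea"), c("trunk", "trunk"))
  out <- divergenceByBand(dm, part, meta)
  row <- out[out$band == "3000-3500", ]
  expect_equal(row$intra_pairs, 1)
  expect_equal(row$inter_pairs, 0)
  expect_true(is.na(row$inter_mean))
})

test_that("out-of-band individuals are excluded with a message", {
  fx <- makeToySet()
  meta <- fx$meta
  meta$elevation[1] <- 800
  expect_message(out <- divergenceByBand(fx$dm, fx$partition, meta),
                 "outside")
  expect_equal(out$n_individuals[out$band == "1500-2000"], 2)
})

test_that("divergence by environment fills the 2x2x2 cells by enumeration", {
  fx <- makeToySet()
  out <- divergenceByEnvironment(fx$dm, fx$partition, fx$meta)
  expect_equal(nrow(out), 8)
  # total classified pairs = all 15 pairs (complete metadata)
  expect_equal(sum(out$inter_pairs) + sum(out$intra_pairs), 15)
  cell <- function(g, f, h) out[out$geography == g & out$feeding == f &
                                  out$host == h, ]
  # sympatric/same feeding/one genus: pairs (a1,a2) intra and (c1,c2) intra
  r <- cell("sympatric", "same feeding site", "hosts in one genus")
  expect_equal(r$intra_pairs, 2)
  expect_equal(r$intra_mean, mean(c(0.001, 0.003)))
  expect_equal(r$inter_pairs, 0)
  # sympatric/different feeding/one genus: (a1,b1), (a2,b1) at s1 on Picea
  # and (b2,c1), (b2,c2) at s2 on Abies, all interspecific
  r2 <- cell("sympatric", "different feeding site", "hosts in one genus")
  expect_equal(r2$inter_pairs, 4)
  expect_equal(r2$inter_mean, mean(c(0.08, 0.10, 0.10, 0.10)))
  # intraspecific B pair spans sites and feeding sites, different... b1 s1
  # young-twig Picea vs b2 s2 young-twig Abies: allopatric/same/different
  r3 <- cell("allopatric", "same feeding site", "hosts in different genera")
  expect_equal(r3$intra_pairs, 1)
  expect_equal(r3$intra_mean, 0.002)
})

test_that("single-site single-host data populate only one environment cell", {
  ids <- c("x1", "x2", "y1")
  dm <- matrix(0.07, 3, 3, dimnames = list(ids, ids))
  dm[1, 2] <- dm[2, 1] <- 0.001; diag(dm) <- 0
  part <- SpeciesPartition(stats::setNames(c("X", "X", "Y"), ids))
  meta <- makeToyMetadata(ids, rep("s1", 3), rep(2000, 3), rep("Picea", 3),
                          rep("trunk", 3))
  out <- divergenceByEnvironment(dm, part, meta)
  filled <- out[out$inter_pairs + out$intra_pairs > 0, ]
  expect_equal(nrow(filled), 1)
  expect_equal(filled$geography, "sympatric")
  expect_equal(filled$feeding, "same feeding site")
  expect_equal(filled$host, "hosts in one genus")
})

test_that("pairs with missing factor values are excluded with a message", {
  fx <- makeToySet()
  meta <- fx$meta
  meta$feeding_site[1] <- NA
  expect_message(out <- divergenceByEnvironment(fx$dm, fx$partition, meta),
                 "missing")
  expect_equal(sum(out$inter_pairs) + sum(out$intra_pairs), choose(5, 2))
})

test_that("richness by band uses species elevation ranges and endemism", {
  fx <- makeToySet()
  out <- richnessByBand(fx$partition, fx$meta)
  # species A range 1600-1700 (band 1), B 1800-2600 (bands 1..3), C 2700-2800
  expect_equal(out$total_species[out$band == "1500-2000"], 2)
  expect_equal(out$total_species[out$band == "2000-2500"], 1)
  expect_equal(out$total_species[out$band == "2500-3000"], 2)
  expect_equal(sum(out$total_species), 5)
  # endemism: A (one site) and C (one site); B spans two sites
  expect_equal(out$endemic_species[out$band == "1500-2000"], 1)
  expect_equal(out$endemic_species[out$band == "2000-2500"], 0)
  expect_equal(out$endemic_species[out$band == "2500-3000"], 1)
  expect_true(all(out$endemic_species <= out$total_species))
})

test_that("a species collected at 2600 and 3200 m spans two bands", {
  ids <- c("z1", "z2")
  part <- SpeciesPartition(stats::setNames(c("Z", "Z"), ids))
  meta <- makeToyMetadata(ids, c("s1", "s2"), c(2600, 3200),
                          c("Larix", "Larix"), c("trunk", "trunk"))
  out <- richnessByBand(part, meta)
  expect_equal(out$total_species[out$band == "2500-3000"], 1)
  expect_equal(out$total_species[out$band == "3000-3500"], 1)
  expect_equal(sum(out$total_species), 2)
  expect_equal(sum(out$endemic_species), 0)  # two sites: not endemic
})

test_that("richness by host counts species per genus, multi-host counted in each", {
  ids <- c("a1", "a2", "b1", "c1")
  part <- SpeciesPartition(stats::setNames(c("A", "A", "B", "C"), ids))
  meta <- makeToyMetadata(ids, c("s1", "s2", "s1", "s3"),
                          rep(2000, 4),
                          c("Picea", "Abies", "Picea", "Picea"),
                          rep("trunk", 4))
  out <- richnessByHost(part, meta)
  expect_equal(out$total_species[out$host_genus == "Picea"], 3)
  expect_equal(out$total_species[out$host_genus == "Abies"], 1)
  expect_equal(out$n_samples[out$host_genus == "Picea"], 3)
  # all species on one genus -> single row
  meta$host_genus <- "Tsuga"
  expect_equal(nrow(richnessByHost(part, meta)), 1)
})

test_that("grid richness equals brute-force point-in-cell counts", {
  fx <- makeToySet()
  out <- gridRichness(fx$partition, fx$meta, cellDeg = 1)
  expect_equal(nrow(out), 2)
  expect_equal(out$richness[out$cell_lat == 30 & out$cell_lon == 100], 2)
  expect_equal(out$richness[out$cell_lat == 31 & out$cell_lon == 101], 2)
  # synthetic clustered sampling vs brute force
  ds <- defaultDataset()
  g <- gridRichness(ds@partition, ds@metadata, cellDeg = 0.5)
  sp <- speciesAssignments(ds@partition)
  meta <- ds@metadata
  brute <- table(paste(floor(meta$latitude / 0.5) * 0.5,
                       floor(meta$longitude / 0.5) * 0.5))
  for (i in seq_len(nrow(g))) {
    key <- meta$latitude >= g$cell_lat[i] &
      meta$latitude < g$cell_lat[i] + 0.5 &
      meta$longitude >= g$cell_lon[i] & meta$longitude < g$cell_lon[i] + 0.5
    expect_equal(g$richness[i], length(unique(sp[meta$sample_id[key]])))
  }
  expect_error(gridRichness(fx$partition, fx$meta, cellDeg = 0), "positive")
})

test_that("occupancy summary histograms species over site counts", {
  fx <- makeToySet()
  occ <- occupancySummary(fx$partition, fx$meta)
  # A: 1 site, B: 2 sites, C: 1 site
  expect_equal(occ$singleSite, 2)
  expect_equal(occ$moreThanTenSites, 0)
  expect_equal(occ$histogram$n_species[occ$histogram$n_sites == 1], 2)
  expect_equal(occ$histogram$n_species[occ$histogram$n_sites == 2], 1)
  expect_equal(sum(occ$histogram$n_species), 3)
})

test_that("interspecific means exceed intraspecific means on synthetic data", {
  ds <- defaultDataset()
  dm <- k2pMatrix(ds@alignment)
  out <- divergenceByBand(dm, ds@partition, ds@metadata)
  filled <- out[out$inter_pairs > 0 & out$intra_pairs > 0, ]
  expect_gt(nrow(filled), 0)
  expect_true(all(filled$inter_mean > filled$intra_mean))
  env <- divergenceByEnvironment(dm, ds@partition, ds@metadata)
  both <- env[env$inter_pairs > 0 & env$intra_pairs > 0, ]
  expect_true(all(both$inter_mean > both$intra_mean))
  # pair bookkeeping: cells sum to all pairs with complete metadata
  expect_equal(sum(env$inter_pairs) + sum(env$intra_pairs),
               choose(nSamples(ds@alignment), 2))
})
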