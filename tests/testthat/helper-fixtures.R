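# Shared fixture builders. Everything is generated in code; the only file
# fixture is the small drug SDF under inst/extdata (3D structures with
# explicit hydrogens, used for descriptor cross-checks).

drugsPath <- function() {
  system.file("extdata", "drugs.sdf", package = "DecompAlign")
}

# a flat aromatic six-ring of carbons
benzeneFixture <- function() {
  ang <- (0:5) * pi / 3
  Molecule3D(rep("C", 6), cbind(1.39 * cos(ang), 1.39 * sin(ang), 0),
             bonds = cbind(1:6, c(2:6, 1), 4L), name = "benzene")
}

# ethanol-like chain C-C-O with idealized coordinates
ethanolFixture <- function() {
  Molecule3D(c("C", "C", "O"),
             rbind(c(0, 0, 0), c(1.52, 0, 0), c(2.0, 1.33, 0)),
             bonds = rbind(c(1, 2, 1), c(2, 3, 1)), name = "ethanol")
}

# methane with explicit hydrogens (tetrahedral)
methaneFixture <- function() {
  h <- 1.09 / sqrt(3)
  Molecule3D(c("C", "H", "H", "H", "H"),
             rbind(c(0, 0, 0), c(h, h, h), c(-h, -h, h), c(-h, h, -h),
                   c(h, -h, -h)),
             bonds = cbind(rep(1L, 4), 2:5, 1L), name = "methane")
}

toyWorldFixture <- function(seed = 5L, nTargets = 4L) {
  rc <- runConfig(seed = seed, nTargets = nTargets)
  buildToyWorld(rc)
}

# one-record curation batch around a planted dumbbell, for training tests
dumbbellBatchFixture <- function(seed = 2L) {
  world <- toyWorldConfig(seed = seed)
  db <- makeToyLigand(world, 3, plantedPartition = TRUE)
  pocket <- makeToyPocket(world, 1)
  priors <- estimatePriors(db$decomposed)
  rec <- list(targetId = "toy1", ligand = db$mol, pocket = pocket,
              decomposed = db$decomposed, priors = priors, reward = NULL)
  new("CurationBatch", records = list(rec), batchSizeB = 1L,
      subsetSizeB = 1L)
}

# random simplex rows
randomSimplex <- function(n, K) {
  M <- matrix(stats::rexp(n * K), n, K)
  M / rowSums(M)
}
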