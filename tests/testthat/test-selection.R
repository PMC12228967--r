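test_that("validity filtering removes exactly the planted corruptions", {
  world <- toyWorldConfig(seed = 44)
  base <- makeToyLigand(world, 1)
  pocket <- makeToyPocket(world, 1)
  # all-valid list passes through unchanged
  clean <- perturbationSampler(base, pocket, 10, seed = 1,
                               temperature = 0.5, corruptFraction = 0)
  kept <- filterValid(clean)
  expect_length(kept, 10L)
  expect_identical(attr(kept, "removed"), integer(0))
  # 100 samples with 20 corrupted at known indices
  mixed <- perturbationSampler(base, pocket, 100, seed = 2,
                               temperature = 0.5, corruptFraction = 0.2)
  planted <- attr(mixed, "corrupted")
  expect_length(planted, 20L)
  kept <- filterValid(mixed)
  expect_identical(attr(kept, "removed"), planted)
  expect_length(kept, 80L)
  # order is preserved
  expect_identical(vapply(kept, molName, ""),
                   vapply(mixed[-planted], molName, ""))
  # a hand-made disconnected record is removed
  bad <- Molecule3D(c("C", "C", "C", "C"),
                    rbind(c(0, 0, 0), c(1.5, 0, 0), c(8, 0, 0),
                          c(9.5, 0, 0)),
                    bonds = rbind(c(1, 2, 1), c(3, 4, 1)))
  expect_length(filterValid(list(bad)), 0L)
})

test_that("best_of_k equals brute-force argmax with low-index ties", {
  world <- toyWorldFixture()
  pocket <- world$pockets[[1]]
  mkSet <- function(rewards) {
    mol <- benzeneFixture()
    w <- rewardWeights(0, 0, 1)
    cands <- lapply(rewards, function(r)
      list(mol = mol, pose = NULL,
           reward = rewardVector(0.5, 0.5, -5, r, w)))
    new("CandidateSet", targetId = "t", pocket = pocket,
        candidates = cands, KRequested = length(rewards))
  }
  expect_equal(bestOfK(mkSet(c(0.2, 0.9, 0.5)))$index, 2L)
  expect_equal(bestOfK(mkSet(c(0.7, 0.7)))$index, 1L)
  set.seed(77)
  for (rep in 1:1000) {
    r <- round(runif(10), 3)
    expect_equal(bestOfK(mkSet(r))$index, which(r == max(r))[1])
  }
  empty <- new("CandidateSet", targetId = "none", pocket = pocket,
               candidates = list(), KRequested = 5L)
  expect_error(bestOfK(empty), "no valid candidate")
})

test_that("best_of_n selects the known best and mutates nothing", {
  world <- toyWorldFixture()
  pocket <- world$pockets[[1]]
  base <- world$ligands[[1]]
  gen <- perturbationGenerator(base)
  w <- rewardWeights(1, 0, 0)
  # N = 1 returns the single valid draw
  one <- bestOfN(gen, surrogateScorer(), w, samplerConfig(N = 1, seed = 3),
                 pocket)
  expect_equal(one$index, 1L)
  expect_equal(one$nValid, 1L)
  # deterministic generator: the draw with the oracle-computed best QED
  # must be returned
  planted <- perturbationSampler(base, pocket, 20, seed = 42,
                                 temperature = 1)
  for (k in 1:20) planted[[k]]@name <- paste0("draw", k)
  validPlanted <- filterValid(planted)
  qeds <- vapply(validPlanted, computeQED, numeric(1))
  bestName <- molName(validPlanted[[which.max(qeds)]])
  plantedGen <- function(pocket, count, seed, temperature) planted[1:count]
  res <- bestOfN(plantedGen, surrogateScorer(), w,
                 samplerConfig(N = 20, seed = 1), pocket)
  expect_equal(res$index, which.max(qeds))
  expect_identical(molName(res$mol), bestName)
  # generator/model state is untouched (hash of a stateful closure env)
  model <- newDenoiser()
  sch <- noiseSchedule(50)
  dgen <- diffusionGenerator(model, world$priors[[1]], 10L, sch)
  hashBefore <- digest_params <- paste(model@params, collapse = ",")
  invisible(bestOfN(dgen, surrogateScorer(), w,
                    samplerConfig(N = 3, seed = 5), pocket))
  expect_identical(paste(model@params, collapse = ","), hashBefore)
  # zero valid draws errors
  noneGen <- function(pocket, count, seed, temperature)
    lapply(seq_len(count), function(k)
      Molecule3D(c("C", "C"), rbind(c(0, 0, 0), c(9, 9, 9))))
  expect_error(bestOfN(noneGen, surrogateScorer(), w,
                       samplerConfig(N = 4, seed = 1), pocket),
               "no valid sample")
})

test_that("curation batches dominate their cohorts and log skips", {
  world <- toyWorldFixture(seed = 5, nTargets = 4)
  w <- rewardWeights(1, 0, 0)
  generators <- lapply(world$targets, function(tid)
    perturbationGenerator(world$ligands[[tid]]))
  names(generators) <- world$targets
  gen <- function(pocket, count, seed, temperature)
    generators[[pocket@name]](pocket, count, seed, temperature)
  batch <- buildCurationBatch(world$targets, world$pockets, gen,
                              surrogateScorer(), w,
                              samplerConfig(K = 10, seed = 9),
                              batchSizeB = 128L)
  expect_s4_class(batch, "CurationBatch")
  expect_equal(batch@batchSizeB, 128L)
  expect_equal(batch@subsetSizeB, length(batch@records))
  expect_equal(length(batch@records), 4L)
  for (rec in batch@records) {
    expect_true(all(rec$reward@reward >= rec$cohortRewards - 1e-12))
    expect_s4_class(rec$decomposed, "DecomposedLigand")
    expect_s4_class(rec$priors, "DecompPriors")
    # relocation placed the winner at its pose's heavy-atom CoM
    expect_true(is(rec$ligand, "Molecule3D"))
  }
  # a target whose generator always fails validity is skipped, not fatal
  badGen <- function(pocket, count, seed, temperature) {
    if (pocket@name == world$targets[2])
      lapply(seq_len(count), function(k)
        Molecule3D(c("C", "C"), rbind(c(0, 0, 0), c(9, 9, 9))))
    else gen(pocket, count, seed, temperature)
  }
  partial <- buildCurationBatch(world$targets, world$pockets, badGen,
                                surrogateScorer(), w,
                                samplerConfig(K = 5, seed = 9))
  expect_equal(length(partial@records), 3L)
  expect_named(attr(partial, "skipped"), world$targets[2])
})
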