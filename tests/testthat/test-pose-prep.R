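test_that("stripNonHeavy removes hydrogens and their bonds only", {
  m <- methaneFixture()
  s <- stripNonHeavy(m)
  expect_identical(atomElements(s), "C")
  expect_equal(nrow(s@bonds), 0L)
  # hydrogen-free input is untouched
  b <- benzeneFixture()
  expect_identical(stripNonHeavy(b)@coords, b@coords)
  # mixed fixture from the drug library: heavy-heavy bonds intact
  asp <- readSDF(drugsPath())[[1]]
  nH <- sum(atomElements(asp) == "H")
  expect_gt(nH, 0)
  clean <- stripNonHeavy(asp)
  expect_equal(nAtoms(clean), nAtoms(asp) - nH)
  heavyBonds <- sum(asp@elements[asp@bonds[, 1]] != "H" &
                    asp@elements[asp@bonds[, 2]] != "H")
  expect_equal(nrow(clean@bonds), heavyBonds)
  expect_error(stripNonHeavy(Molecule3D(c("H", "H"),
                                        rbind(c(0, 0, 0), c(0.7, 0, 0)),
                                        bonds = cbind(1, 2, 1))),
               "no heavy atoms")
})

test_that("center of mass is the mass-weighted mean", {
  one <- Molecule3D("N", rbind(c(1, 2, 3)))
  expect_equal(centerOfMass(one), c(1, 2, 3))
  two <- Molecule3D(c("C", "C"), rbind(c(0, 0, 0), c(2, 0, 0)),
                    bonds = cbind(1, 2, 1))
  expect_equal(centerOfMass(two), c(1, 0, 0))
  # heteroatomic: compare against the sum formula computed directly
  m <- ethanolFixture()
  masses <- c(12.011, 12.011, 15.999)
  manual <- colSums(m@coords * masses) / sum(masses)
  expect_equal(centerOfMass(m), manual, tolerance = 1e-9,
               ignore_attr = TRUE)
  # unweighted mode is the plain centroid
  expect_equal(centerOfMass(m, weighted = FALSE), colMeans(m@coords),
               ignore_attr = TRUE)
})

test_that("relocation matches explicit vector arithmetic", {
  world <- toyWorldConfig(seed = 8)
  lig <- makeToyLigand(world, 1)
  pose <- makeToyLigand(world, 2)
  # already at the pose CoM: zero translation
  aligned <- relocateToPose(lig, lig)
  expect_equal(aligned@coords, lig@coords, tolerance = 1e-12)
  # known offset: every atom shifts by exactly the CoM difference
  shifted <- lig
  atomCoords(shifted) <- lig@coords + rep(c(5, 0, 0), each = nAtoms(lig))
  back <- relocateToPose(shifted, pose)
  expectedShift <- centerOfMass(stripNonHeavy(pose)) - centerOfMass(shifted)
  expect_equal(back@coords - shifted@coords,
               matrix(expectedShift, nAtoms(lig), 3, byrow = TRUE),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("relocation preserves internal geometry and is idempotent", {
  world <- toyWorldConfig(seed = 13)
  for (i in 1:100) {
    lig <- makeToyLigand(world, i)
    pose <- makeToyLigand(world, i + 200)
    out <- relocateToPose(lig, pose)
    expect_lt(max(abs(centerOfMass(out) -
                      centerOfMass(stripNonHeavy(pose)))), 1e-9)
    dl <- dist(lig@coords); dr <- dist(out@coords)
    expect_lt(max(abs(dl - dr)), 1e-9)
    twice <- relocateToPose(out, pose)
    expect_lt(max(abs(twice@coords - out@coords)), 1e-9)
  }
})

test_that("relocation commutes with joint translation of both inputs", {
  world <- toyWorldConfig(seed = 17)
  lig <- makeToyLigand(world, 1); pose <- makeToyLigand(world, 5)
  tr <- c(3.3, -7.1, 11.8)
  ligT <- lig; atomCoords(ligT) <- lig@coords +
    rep(tr, each = nAtoms(lig))
  poseT <- pose; atomCoords(poseT) <- pose@coords +
    rep(tr, each = nAtoms(pose))
  a <- relocateToPose(lig, pose)
  b <- relocateToPose(ligT, poseT)
  expect_equal(b@coords, a@coords + rep(tr, each = nAtoms(lig)),
               tolerance = 1e-9)
})

test_that("adaptive decomposition recovers planted dumbbell partitions", {
  world <- toyWorldConfig(seed = 23)
  for (i in 1:10) {
    db <- makeToyLigand(world, i, plantedPartition = TRUE)
    pocket <- makeToyPocket(world, i)
    # positioning near the pocket is the caller's responsibility: seat
    # the dumbbell across the cavity as the pipeline would
    dec <- adaptiveDecompose(seatLigand(db$mol, pocket), pocket)
    canon <- function(d) {
      arms <- lapply(d@armAtomSets, sort)
      list(arms = arms[order(vapply(arms, min, 1L))],
           scaffold = sort(d@scaffoldAtomSet))
    }
    expect_equal(canon(dec), canon(db$decomposed))
  }
})

test_that("decomposition floor cases behave as specified", {
  world <- toyWorldConfig(seed = 3)
  pocket <- makeToyPocket(world, 1)
  ring <- benzeneFixture()   # single ring seated at the cavity centre
  dec <- adaptiveDecompose(ring, pocket)
  expect_length(dec@armAtomSets, 1L)
  expect_length(dec@scaffoldAtomSet, 0L)
  # 50 Angstrom away with only 2 relaxations: single-arm fallback
  far <- ring
  atomCoords(far) <- ring@coords + rep(c(50, 0, 0), each = 6)
  decFar <- adaptiveDecompose(far, pocket,
                              extractionParams(maxRelaxations = 2L))
  expect_length(decFar@armAtomSets, 1L)
  expect_identical(sort(decFar@armAtomSets[[1]]), 1:6)
  expect_length(decFar@scaffoldAtomSet, 0L)
})

test_that("decomposition always yields a valid partition (fuzz)", {
  world <- toyWorldConfig(seed = 37)
  for (i in 1:120) {
    lig <- makeToyLigand(world, i)
    pocket <- makeToyPocket(world, (i %% 6) + 1)
    dec <- adaptiveDecompose(lig, pocket)
    expect_s4_class(dec, "DecomposedLigand")  # validity enforces partition
    expect_gte(length(dec@armAtomSets), 1L)
    all_idx <- c(unlist(dec@armAtomSets), dec@scaffoldAtomSet)
    expect_setequal(all_idx, seq_len(nAtoms(lig)))
    expect_equal(anyDuplicated(all_idx), 0L)
  }
})

test_that("decomposition is invariant under joint rigid translation", {
  world <- toyWorldConfig(seed = 41)
  lig <- makeToyLigand(world, 4)
  pocket <- makeToyPocket(world, 4)
  dec1 <- adaptiveDecompose(lig, pocket)
  tr <- c(-12, 4, 8)
  lig2 <- lig; atomCoords(lig2) <- lig@coords + rep(tr, each = nAtoms(lig))
  pocket2 <- pocket
  pocket2@coords <- pocket@coords + rep(tr, each = nAtoms(pocket))
  dec2 <- adaptiveDecompose(lig2, pocket2)
  expect_identical(lapply(dec1@armAtomSets, sort),
                   lapply(dec2@armAtomSets, sort))
  expect_identical(dec1@scaffoldAtomSet, dec2@scaffoldAtomSet)
})
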