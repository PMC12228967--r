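# Synthetic fixture and surrogate module: toy pockets, grammar-built
# ligands with known properties, a deterministic geometric docking
# surrogate, and a stochastic perturbation sampler. Everything is fully
# deterministic under fixed seeds, so the whole framework can be
# exercised with no external data.

#' Configuration of the toy world
#'
#' @param seed integer world seed.
#' @param nTargets number of targets (default 8).
#' @param pocketRadius radius of the pocket shell in Angstrom
#'   (default 7).
#' @param ligandSizeRange admissible heavy-atom counts (default 9..16).
#' @param fragmentGrammar allowed building blocks; subsets of
#'   `c("benzene", "pyridine", "cyclopentane", "chain")`.
#' @param dockCalibration scale factor of the surrogate potential,
#'   chosen so that well-seated toy ligands reach but do not trivially
#'   pass the -8.18 success threshold.
#' @return A validated list with class `"ToyWorldConfig"`.
#' @export
toyWorldConfig <- function(seed = 1L, nTargets = 8L, pocketRadius = 7,
                           ligandSizeRange = c(9L, 16L),
                           fragmentGrammar = c("benzene", "pyridine",
                                               "cyclopentane", "chain"),
                           dockCalibration = 0.15) {
  stopifnot(pocketRadius > 0, ligandSizeRange[1] >= 2,
            ligandSizeRange[2] >= ligandSizeRange[1], nTargets >= 1)
  structure(list(seed = as.integer(seed), nTargets = as.integer(nTargets),
                 pocketRadius = pocketRadius,
                 ligandSizeRange = as.integer(ligandSizeRange),
                 fragmentGrammar = fragmentGrammar,
                 dockCalibration = dockCalibration),
            class = "ToyWorldConfig")
}

# unit vectors roughly uniform on the upper part of a sphere (deterministic
# Fibonacci lattice)
.shellDirections <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 1.4 * i / n)          # cap: polar angle up to ~110 deg
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Build a toy protein pocket
#'
#' A hemispherical shell of pseudo-atoms (C/N/O) of the configured
#' radius with a concave cavity around the origin; deterministic for a
#' given (seed, index) and distinct across indices.
#'
#' @param config a [toyWorldConfig()].
#' @param index target index (1-based).
#' @return A [ProteinPocket] named `toy<index>`.
#' @export
makeToyPocket <- function(config, index) {
  nShell <- 60L
  R <- config$pocketRadius
  dirs <- .shellDirections(nShell)
  withSeed(deriveSeed(config$seed, "pocket", index), {
    radii <- R + stats::runif(nShell, -0.5, 0.5)
    coords <- dirs * radii
    # a seeded rigid rotation makes pockets differ across indices
    ang <- stats::runif(3, 0, 2 * pi)
    coords <- coords %*% .rotationMatrix(ang)
    elements <- sample(c("C", "N", "O"), nShell, replace = TRUE,
                       prob = c(0.6, 0.2, 0.2))
  })
  ProteinPocket(elements, coords,
                resid = paste0("GLY", rep(seq_len(nShell %/% 4 + 1),
                                          each = 4)[seq_len(nShell)]),
                atomNames = "CA", name = paste0("toy", index))
}

.rotationMatrix <- function(ang) {
  cx <- cos(ang[1]); sx <- sin(ang[1])
  cy <- cos(ang[2]); sy <- sin(ang[2])
  cz <- cos(ang[3]); sz <- sin(ang[3])
  Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  Rx %*% Ry %*% Rz
}

# --- ligand assembly --------------------------------------------------------

# ring template: n atoms on a circle, given bond length
.ringTemplate <- function(elements, aromatic, bondLength) {
  n <- length(elements)
  r <- bondLength / (2 * sin(pi / n))
  ang <- 2 * pi * (seq_len(n) - 1) / n
  coords <- cbind(r * cos(ang), r * sin(ang), 0)
  bonds <- cbind(seq_len(n), c(seq_len(n)[-1], 1L),
                 if (aromatic) 4L else 1L)
  list(elements = elements, coords = coords, bonds = bonds)
}

.fragmentTemplate <- function(kind) {
  switch(kind,
    benzene = .ringTemplate(rep("C", 6), TRUE, 1.39),
    pyridine = .ringTemplate(c("N", rep("C", 5)), TRUE, 1.36),
    cyclopentane = .ringTemplate(rep("C", 5), FALSE, 1.53),
    chain = {
      k <- 3L
      coords <- cbind(1.25 * (seq_len(k) - 1),
                      0.5 * (seq_len(k) %% 2), 0)
      list(elements = rep("C", k), coords = coords,
           bonds = if (k > 1) cbind(seq_len(k - 1), 2:k, 1L) else
             matrix(integer(0), 0, 3))
    },
    stopf("unknown fragment kind '%s'", kind))
}

# append fragment `frag` to molecule parts, translated by `offset`;
# returns updated parts and the index range of the new atoms
.appendFragment <- function(parts, frag, offset) {
  base <- length(parts$elements)
  parts$elements <- c(parts$elements, frag$elements)
  parts$coords <- rbind(parts$coords,
                        sweep(frag$coords, 2, -offset))
  if (nrow(frag$bonds) > 0)
    parts$bonds <- rbind(parts$bonds,
                         cbind(frag$bonds[, 1] + base,
                               frag$bonds[, 2] + base, frag$bonds[, 3]))
  parts$ranges <- c(parts$ranges, list(base + seq_along(frag$elements)))
  parts
}

#' Build a toy ligand from the fragment grammar
#'
#' Assembles one or two ring/chain units joined by a short linker, with
#' optional heteroatom substituents, using idealized geometry plus
#' seeded coordinate jitter and a random rigid rotation. All products
#' are valence-valid and connected. With `plantedPartition = TRUE` a
#' two-ring "dumbbell" (two rings joined by a three-atom linker) is
#' built and the ground-truth arm/scaffold partition is returned with
#' it.
#'
#' @param config a [toyWorldConfig()].
#' @param index ligand index (fans the world seed out).
#' @param plantedPartition logical; request the dumbbell with known
#'   partition.
#' @return A [Molecule3D]; when `plantedPartition` is TRUE, a list with
#'   elements `mol` and `decomposed` (a [DecomposedLigand] holding the
#'   planted partition).
#' @export
makeToyLigand <- function(config, index, plantedPartition = FALSE) {
  seed <- deriveSeed(config$seed, "ligand", index)
  ringKinds <- intersect(config$fragmentGrammar,
                         c("benzene", "pyridine", "cyclopentane"))
  if (length(ringKinds) == 0) ringKinds <- "benzene"
  out <- withSeed(seed, {
    parts <- list(elements = character(0),
                  coords = matrix(numeric(0), 0, 3),
                  bonds = matrix(integer(0), 0, 3), ranges = list())
    if (plantedPartition) {
      kinds <- c(sample(setdiff(ringKinds, "chain"), 1),
                 "chain",
                 sample(setdiff(ringKinds, "chain"), 1))
    } else {
      twoRings <- stats::runif(1) < 0.5 && "chain" %in%
        config$fragmentGrammar
      kinds <- if (twoRings)
        c(sample(ringKinds, 1), "chain", sample(ringKinds, 1))
      else sample(ringKinds, 1)
    }
    xOffset <- 0
    for (kind in kinds) {
      frag <- .fragmentTemplate(kind)
      span <- diff(range(frag$coords[, 1]))
      parts <- .appendFragment(parts, frag,
                               offset = c(xOffset - min(frag$coords[, 1]) +
                                          (if (xOffset > 0) 1.5 else 0), 0, 0))
      xOffset <- max(parts$coords[, 1])
    }
    # join consecutive fragments: rightmost atom of one to leftmost of next
    if (length(parts$ranges) > 1) {
      for (k in seq_len(length(parts$ranges) - 1)) {
        left <- parts$ranges[[k]]
        right <- parts$ranges[[k + 1]]
        a <- left[which.max(parts$coords[left, 1])]
        b <- right[which.min(parts$coords[right, 1])]
        parts$bonds <- rbind(parts$bonds, c(a, b, 1L))
      }
    }
    # substituents on ring atoms that still have a free valence
    target <- sample(seq(config$ligandSizeRange[1],
                         config$ligandSizeRange[2]), 1)
    ringAtoms <- unlist(parts$ranges[vapply(kinds, function(k)
      k != "chain", logical(1))])
    busy <- unique(as.vector(parts$bonds[, 1:2]))
    degree <- tabulate(as.vector(parts$bonds[, 1:2]),
                       nbins = length(parts$elements))
    free <- ringAtoms[degree[ringAtoms] <= 2]
    nSub <- min(max(0, target - length(parts$elements)), length(free), 3)
    if (nSub > 0) {
      at <- sample(free, nSub)
      for (a in at) {
        ringIdx <- which(vapply(parts$ranges, function(r) a %in% r,
                                logical(1)))
        cen <- colMeans(parts$coords[parts$ranges[[ringIdx]], ,
                                     drop = FALSE])
        dirv <- parts$coords[a, ] - cen
        nrm <- sqrt(sum(dirv^2))
        dirv <- if (nrm > 1e-8) dirv / nrm else c(0, 0, 1)
        el <- sample(c("C", "N", "O", "S"), 1,
                     prob = c(0.4, 0.25, 0.25, 0.1))
        parts$elements <- c(parts$elements, el)
        parts$coords <- rbind(parts$coords, parts$coords[a, ] + 1.45 * dirv)
        parts$bonds <- rbind(parts$bonds,
                             c(a, length(parts$elements), 1L))
        # the substituent belongs to its ring's fragment
        parts$ranges[[ringIdx]] <- c(parts$ranges[[ringIdx]],
                                     length(parts$elements))
      }
    }
    # seeded jitter and rigid rotation; recentre on the origin
    coords <- parts$coords + matrix(stats::rnorm(length(parts$coords),
                                                 sd = 0.03),
                                    nrow(parts$coords), 3)
    coords <- sweep(coords, 2, colMeans(coords))
    coords <- coords %*% .rotationMatrix(stats::runif(3, 0, 2 * pi))
    mol <- Molecule3D(parts$elements, coords, bonds = parts$bonds,
                      name = paste0("lig", index))
    list(mol = mol, ranges = parts$ranges, kinds = kinds)
  })
  if (!plantedPartition) return(out$mol)
  arms <- out$ranges[out$kinds != "chain"]
  scaffold <- unlist(out$ranges[out$kinds == "chain"])
  list(mol = out$mol,
       decomposed = decomposedLigand(out$mol, arms, scaffold))
}

#' Seat a ligand across the pocket cavity
#'
#' Rotates the ligand about its centroid so that its longest principal
#' axis lies in the plane orthogonal to the pocket's cap direction (the
#' direction of the pocket-atom centroid). An elongated ligand then
#' hugs the cavity walls with both ends instead of sticking out of the
#' cavity mouth — the configuration the decomposition's proximity rules
#' presume. Purely a rigid rotation; internal geometry is unchanged.
#'
#' @param mol a [Molecule3D] centred near the cavity.
#' @param pocket a [ProteinPocket].
#' @return The rotated [Molecule3D].
#' @export
seatLigand <- function(mol, pocket) {
  centroid <- colMeans(mol@coords)
  X <- sweep(mol@coords, 2, centroid)
  v <- eigen(stats::cov(X), symmetric = TRUE)$vectors[, 1]
  u <- colMeans(pocket@coords)
  u <- u / sqrt(sum(u^2))
  w <- v - sum(v * u) * u
  if (sqrt(sum(w^2)) < 1e-8) {
    w <- c(u[2], -u[1], 0)
    if (sqrt(sum(w^2)) < 1e-8) w <- c(0, u[3], -u[2])
  }
  w <- w / sqrt(sum(w^2))
  # Rodrigues rotation taking v onto w
  axis <- c(v[2] * w[3] - v[3] * w[2], v[3] * w[1] - v[1] * w[3],
            v[1] * w[2] - v[2] * w[1])
  s <- sqrt(sum(axis^2)); cth <- sum(v * w)
  out <- mol
  if (s > 1e-12) {
    k <- axis / s
    Km <- rbind(c(0, -k[3], k[2]), c(k[3], 0, -k[1]), c(-k[2], k[1], 0))
    R <- diag(3) + s * Km + (1 - cth) * (Km %*% Km)
    out@coords <- X %*% t(R) + matrix(centroid, nrow(X), 3, byrow = TRUE)
  }
  out
}

#' Deterministic geometric surrogate docking score
#'
#' A smooth contact potential summed over ligand/pocket heavy-atom
#' pairs: an attractive Gaussian well centred at 3.5 Angstrom and a
#' steep quadratic clash penalty below 2.5 Angstrom, scaled by a
#' calibration constant so that seated toy ligands land roughly in
#' \[-12, 0\]. Lower is better; a ligand far from the pocket scores ~0.
#' The score is invariant under joint rigid motion of ligand and pocket
#' and sensitive to translations of the ligand alone.
#'
#' @param ligand a [Molecule3D].
#' @param pocket a [ProteinPocket].
#' @param calibration scale factor (default 0.25, the toy-world
#'   calibration).
#' @return Numeric score (lower = better).
#' @export
surrogateDockScore <- function(ligand, pocket, calibration = 0.15) {
  lig <- ligand@coords[ligand@elements != "H", , drop = FALSE]
  if (nrow(lig) == 0) stopf("ligand has no heavy atoms")
  d <- crossDist(lig, pocket@coords)
  well <- -exp(-(d - 3.5)^2 / 2)
  wall <- ifelse(d < 2.5, 4 * (2.5 - d)^2, 0)
  calibration * sum(well + wall)
}

#' Stochastic perturbation sampler around a base ligand
#'
#' Generates `count` variants of `base` by seeded coordinate jitter
#' (scale proportional to `temperature`) and occasional
#' grammar-consistent element swaps at terminal atoms. A configurable
#' fraction of the outputs is deliberately corrupted (one bridge bond
#' removed, disconnecting the graph) to exercise validity filtering;
#' the corrupted positions are recorded in the `"corrupted"` attribute.
#'
#' @param base a valid [Molecule3D].
#' @param pocket the target pocket (unused by this simple sampler but
#'   part of the generator contract).
#' @param count number of samples.
#' @param seed integer seed (same seed, same output list).
#' @param temperature non-negative diversity control; 0 with no
#'   corruption returns exact copies.
#' @param corruptFraction fraction in \[0, 1\] of outputs to corrupt.
#' @return List of [Molecule3D] with attribute `"corrupted"`.
#' @export
perturbationSampler <- function(base, pocket, count, seed,
                                temperature = 1, corruptFraction = 0) {
  nCorrupt <- min(count, ceiling(count * corruptFraction))
  withSeed(deriveSeed(seed, "perturb"), {
    corruptIdx <- if (nCorrupt > 0) sort(sample.int(count, nCorrupt))
      else integer(0)
    out <- vector("list", count)
    for (k in seq_len(count)) {
      mol <- base
      if (temperature > 0) {
        mol@coords <- mol@coords +
          matrix(stats::rnorm(length(mol@coords), sd = 0.05 * temperature),
                 nrow(mol@coords), 3)
        # occasional element swap at a terminal heavy atom
        if (stats::runif(1) < 0.5) {
          deg <- tabulate(as.vector(mol@bonds[, 1:2]),
                          nbins = length(mol@elements))
          term <- which(deg == 1 & mol@elements != "H")
          if (length(term) > 0) {
            a <- if (length(term) == 1) term else sample(term, 1)
            mol@elements[a] <- sample(setdiff(c("C", "N", "O", "S"),
                                              mol@elements[a]), 1)
          }
        }
      }
      if (k %in% corruptIdx) {
        g <- molGraph(mol, heavyOnly = TRUE)
        br <- as.integer(igraph::bridges(g))
        if (length(br) > 0) {
          e <- br[1]
          ends <- igraph::ends(g, e, names = FALSE)
          orig <- igraph::V(g)$orig[ends]
          hit <- (mol@bonds[, 1] == orig[1] & mol@bonds[, 2] == orig[2]) |
                 (mol@bonds[, 1] == orig[2] & mol@bonds[, 2] == orig[1])
          mol@bonds <- mol@bonds[!hit, , drop = FALSE]
        } else {
          # no bridge (single ring): drop an atom's bonds instead
          mol@bonds <- mol@bonds[-c(1, 2), , drop = FALSE]
        }
      }
      mol@name <- sprintf("%s_v%02d", base@name, k)
      out[[k]] <- mol
    }
    attr(out, "corrupted") <- corruptIdx
    out
  })
}

#' Generator factory: perturbation sampler with bound base ligand
#'
#' Wraps [perturbationSampler()] into the generator contract
#' `(pocket, count, seed, temperature)`.
#'
#' @param base base [Molecule3D].
#' @param corruptFraction passed through to the sampler.
#' @return A generator function.
#' @export
perturbationGenerator <- function(base, corruptFraction = 0) {
  force(base); force(corruptFraction)
  function(pocket, count, seed, temperature)
    perturbationSampler(base, pocket, count, seed, temperature,
                        corruptFraction)
}

#' Generator factory: diffusion sampler with bound model and priors
#'
#' Wraps [sampleLigand()] into the generator contract; each draw uses a
#' seed derived from the generator seed and the draw index.
#'
#' @param model a [DenoiserModel].
#' @param priors a [DecompPriors] describing the fragment layout.
#' @param nAtoms atoms per sample.
#' @param schedule a [NoiseSchedule].
#' @param mode forward-process mode.
#' @return A generator function `(pocket, count, seed, temperature)`.
#' @export
diffusionGenerator <- function(model, priors, nAtoms, schedule,
                               mode = "ddpm") {
  force(model); force(priors); force(nAtoms); force(schedule); force(mode)
  function(pocket, count, seed, temperature) {
    lapply(seq_len(count), function(k)
      sampleLigand(model, pocket, priors, nAtoms, schedule,
                   seed = deriveSeed(seed, "draw", k), mode = mode,
                   name = sprintf("dsample%02d", k)))
  }
}

#' Write a complete toy world to disk
#'
#' Emits pockets as PDB, base ligands and their (surrogate) docking
#' poses as SDF, and a JSON manifest mapping targets to files — enough
#' to drive the ranking and alignment commands from files alone.
#'
#' @param config a [toyWorldConfig()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the manifest path.
#' @export
makeFixtures <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  for (i in seq_len(config$nTargets)) {
    pocket <- makeToyPocket(config, i)
    ligand <- makeToyLigand(config, i)
    pocketFile <- file.path(dir, sprintf("pocket_%02d.pdb", i))
    ligandFile <- file.path(dir, sprintf("ligand_%02d.sdf", i))
    writePocketPDB(pocket, pocketFile)
    writeSDF(ligand, ligandFile)
    manifest[[pocket@name]] <- list(
      target_id = pocket@name,
      pocket_pdb = basename(pocketFile),
      ligand_sdf = basename(ligandFile))
  }
  manifestPath <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, manifestPath, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(manifestPath)
}
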