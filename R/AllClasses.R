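# Central S4 data model. Coordinates are Angstrom throughout; atom indices
# are 1-based in R objects and converted at I/O boundaries.

#' @include AllGenerics.R
NULL

#' Bond order vocabulary
#'
#' The explicit bond categories carried by [Molecule3D]. The fifth category
#' of the diffusion model, "non-bonded", is the implicit absence of a bond
#' record.
#' @export
BOND_ORDERS <- c("single", "double", "triple", "aromatic")

#' Bond categories of the categorical diffusion
#'
#' Non-bonded plus the four explicit orders; `Kb = 5`.
#' @export
BOND_CATEGORIES <- c("non-bonded", BOND_ORDERS)

#' A 3D small molecule
#'
#' Element-typed atoms with 3D coordinates and typed bonds. The unit that
#' flows through every stage of the toolkit.
#'
#' @slot elements character vector of element symbols, one per atom.
#' @slot coords numeric n x 3 matrix of coordinates (Angstrom).
#' @slot charges integer vector of formal charges (default 0; carried but
#'   not used by any computation).
#' @slot bonds integer m x 3 matrix with columns `i`, `j`, `order`
#'   (order codes 1 = single, 2 = double, 3 = triple, 4 = aromatic).
#' @slot name identifier string.
#' @export
setClass("Molecule3D",
  representation(elements = "character", coords = "matrix",
                 charges = "integer", bonds = "matrix", name = "character"),
  prototype(elements = character(0),
            coords = matrix(numeric(0), 0, 3),
            charges = integer(0),
            bonds = matrix(integer(0), 0, 3,
                           dimnames = list(NULL, c("i", "j", "order"))),
            name = "mol"))

setValidity("Molecule3D", function(object) {
  n <- length(object@elements)
  msgs <- character(0)
  if (!is.numeric(object@coords) || ncol(object@coords) != 3L)
    msgs <- c(msgs, "coords must be an n x 3 numeric matrix")
  else {
    if (nrow(object@coords) != n)
      msgs <- c(msgs, "coords rows must match number of elements")
    if (n > 0 && !all(is.finite(object@coords)))
      msgs <- c(msgs, "all coordinates must be finite")
  }
  if (length(object@charges) != n)
    msgs <- c(msgs, "charges must have one entry per atom")
  b <- object@bonds
  if (ncol(b) != 3L) {
    msgs <- c(msgs, "bonds must have columns i, j, order")
  } else if (nrow(b) > 0) {
    if (any(b[, 1] == b[, 2]))
      msgs <- c(msgs, "bond endpoints must be distinct atoms")
    if (any(b[, 1:2] < 1L) || any(b[, 1:2] > n))
      msgs <- c(msgs, "bond endpoints must be valid atom indices")
    if (any(!(b[, 3] %in% 1:4)))
      msgs <- c(msgs, "bond order codes must be in 1..4")
    key <- paste(pmin(b[, 1], b[, 2]), pmax(b[, 1], b[, 2]))
    if (anyDuplicated(key))
      msgs <- c(msgs, "duplicate bonds are not allowed")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a Molecule3D
#'
#' @param elements character vector of element symbols.
#' @param coords numeric n x 3 matrix of coordinates in Angstrom.
#' @param bonds integer m x 3 matrix (or data frame) with 1-based atom
#'   indices `i`, `j` and bond `order`; order may be given as a code in
#'   1..4 or as one of `r toString(BOND_ORDERS)`.
#' @param charges integer formal charges, default all zero.
#' @param name identifier string.
#' @return A validated [Molecule3D] object.
#' @examples
#' m <- Molecule3D(c("C", "O"), rbind(c(0, 0, 0), c(1.43, 0, 0)),
#'                 bonds = cbind(1, 2, 1), name = "toy")
#' nAtoms(m)
#' @export
Molecule3D <- function(elements, coords, bonds = NULL, charges = NULL,
                       name = "mol") {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  colnames(coords) <- c("x", "y", "z")
  if (is.null(charges)) charges <- integer(length(elements))
  if (is.null(bonds) || NROW(bonds) == 0) {
    bonds <- matrix(integer(0), 0, 3)
  } else {
    bonds <- as.matrix(as.data.frame(bonds))
    if (is.character(bonds[, 3]) ||
        (is.data.frame(bonds) && is.character(bonds[[3]]))) {
      ord <- match(bonds[, 3], BOND_ORDERS)
      bonds <- cbind(as.integer(bonds[, 1]), as.integer(bonds[, 2]), ord)
    }
    storage.mode(bonds) <- "integer"
  }
  dimnames(bonds) <- list(NULL, c("i", "j", "order"))
  new("Molecule3D", elements = as.character(elements), coords = coords,
      charges = as.integer(charges), bonds = bonds, name = name)
}

#' Protein binding-site atoms
#'
#' Conditioning context for decomposition, scoring and diffusion.
#'
#' @slot elements character element symbols.
#' @slot coords numeric n x 3 coordinate matrix (Angstrom).
#' @slot resid character residue identifiers.
#' @slot atomNames character PDB atom names.
#' @slot name identifier string.
#' @export
setClass("ProteinPocket",
  representation(elements = "character", coords = "matrix",
                 resid = "character", atomNames = "character",
                 name = "character"))

setValidity("ProteinPocket", function(object) {
  n <- length(object@elements)
  if (n == 0) return("pocket must contain at least one atom")
  if (nrow(object@coords) != n || ncol(object@coords) != 3L)
    return("coords must be an n x 3 matrix matching elements")
  if (!all(is.finite(object@coords)))
    return("all coordinates must be finite")
  if (length(object@resid) != n || length(object@atomNames) != n)
    return("resid and atomNames must have one entry per atom")
  TRUE
})

#' Construct a ProteinPocket
#'
#' @param elements character element symbols.
#' @param coords numeric n x 3 coordinate matrix (Angstrom).
#' @param resid residue identifiers (recycled if length 1).
#' @param atomNames PDB-style atom names (recycled if length 1).
#' @param name identifier string.
#' @return A validated [ProteinPocket].
#' @export
ProteinPocket <- function(elements, coords, resid = "UNK1",
                          atomNames = "X", name = "pocket") {
  n <- length(elements)
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  colnames(coords) <- c("x", "y", "z")
  new("ProteinPocket", elements = as.character(elements), coords = coords,
      resid = rep_len(as.character(resid), n),
      atomNames = rep_len(as.character(atomNames), n), name = name)
}

#' Weights of the multi-objective reward
#'
#' Non-negative weights for drug-likeness (QED), normalized synthetic
#' accessibility and normalized docking score; at least one must be
#' positive. The reward of a candidate is the weighted sum of the three
#' components.
#'
#' @slot wQED,wSA,wDock non-negative reals.
#' @export
setClass("RewardWeights",
  representation(wQED = "numeric", wSA = "numeric", wDock = "numeric"))

setValidity("RewardWeights", function(object) {
  w <- c(object@wQED, object@wSA, object@wDock)
  if (length(w) != 3 || any(!is.finite(w)) || any(w < 0))
    return("weights must be three finite non-negative numbers")
  if (sum(w) <= 0) return("at least one weight must be positive")
  TRUE
})

#' Construct reward weights
#'
#' @param wQED,wSA,wDock non-negative weights; default `(1, 0, 0)`, the
#'   configuration that performed best in the source study's ablation.
#' @return A validated [RewardWeights].
#' @export
rewardWeights <- function(wQED = 1, wSA = 0, wDock = 0)
  new("RewardWeights", wQED = wQED, wSA = wSA, wDock = wDock)

#' Per-candidate objective values and reward
#'
#' @slot qed QED in \[0, 1\].
#' @slot saNorm normalized synthetic accessibility in \[0, 1\]
#'   (higher = easier to synthesize).
#' @slot dockRaw raw docking score (lower is better).
#' @slot dockNorm min-max normalized docking score in \[0, 1\]
#'   (higher is better).
#' @slot reward weighted sum of the components.
#' @slot weights the [RewardWeights] used to build the reward.
#' @export
setClass("RewardVector",
  representation(qed = "numeric", saNorm = "numeric", dockRaw = "numeric",
                 dockNorm = "numeric", reward = "numeric",
                 weights = "RewardWeights"))

setValidity("RewardVector", function(object) {
  inUnit <- function(x) is.finite(x) && x >= 0 && x <= 1
  if (!inUnit(object@qed)) return("qed must lie in [0, 1]")
  if (!inUnit(object@saNorm)) return("saNorm must lie in [0, 1]")
  if (!inUnit(object@dockNorm)) return("dockNorm must lie in [0, 1]")
  if (!is.finite(object@dockRaw)) return("dockRaw must be finite")
  w <- object@weights
  expected <- w@wQED * object@qed + w@wSA * object@saNorm +
    w@wDock * object@dockNorm
  if (abs(object@reward - expected) > 1e-9)
    return("reward must equal the weighted sum of its components")
  TRUE
})

#' Decomposed ligand: arms and scaffold
#'
#' Partition of the ligand atoms into at least one arm and at most one
#' (possibly empty) scaffold set. Arm sets and the scaffold set are
#' disjoint and jointly cover all atoms.
#'
#' @slot armAtomSets list of integer vectors of 1-based atom indices.
#' @slot scaffoldAtomSet integer vector (possibly empty).
#' @slot ligand the decomposed [Molecule3D].
#' @export
setClass("DecomposedLigand",
  representation(armAtomSets = "list", scaffoldAtomSet = "integer",
                 ligand = "Molecule3D"))

setValidity("DecomposedLigand", function(object) {
  n <- nAtoms(object@ligand)
  if (length(object@armAtomSets) < 1) return("at least one arm is required")
  all_idx <- c(unlist(object@armAtomSets), object@scaffoldAtomSet)
  if (anyDuplicated(all_idx))
    return("arm and scaffold sets must be disjoint")
  if (!setequal(all_idx, seq_len(n)))
    return("arm and scaffold sets must cover all ligand atoms")
  TRUE
})

#' Per-fragment diffusion priors
#'
#' Data-dependent priors of the decomposed diffusion process: one position
#' mean and covariance per fragment, plus the atom-to-fragment assignment.
#'
#' @slot mu list of K fragment centers (3-vectors, Angstrom).
#' @slot sigma list of K symmetric positive-definite 3 x 3 covariance
#'   matrices (Angstrom squared).
#' @slot assignment integer vector mapping each atom to its fragment in
#'   `1..K` (the one-hot matrix H in row form).
#' @export
setClass("DecompPriors",
  representation(mu = "list", sigma = "list", assignment = "integer"))

setValidity("DecompPriors", function(object) {
  K <- length(object@mu)
  if (length(object@sigma) != K) return("mu and sigma must have equal length")
  if (K == 0) return("at least one fragment is required")
  if (length(object@assignment) == 0)
    return("assignment must cover at least one atom")
  if (any(!(object@assignment %in% seq_len(K))))
    return("every atom must be assigned to an existing fragment")
  for (k in seq_len(K)) {
    if (any(!is.finite(object@mu[[k]])) || length(object@mu[[k]]) != 3)
      return("each mu must be a finite 3-vector")
    S <- object@sigma[[k]]
    if (!isTRUE(all.equal(S, t(S), tolerance = 1e-8)))
      return("each sigma must be symmetric")
    if (min(eigen(S, symmetric = TRUE, only.values = TRUE)$values) < -1e-10)
      return("each sigma must be positive semi-definite")
  }
  TRUE
})

#' Noise schedule of the diffusion process
#'
#' Per-step corruption rates `lambda_t` with the usual bookkeeping
#' `alpha_t = 1 - lambda_t` and `alphaBar_t = prod(alpha_s, s <= t)`.
#'
#' @slot lambda numeric vector of per-step rates in (0, 1).
#' @slot alpha `1 - lambda`.
#' @slot alphaBar cumulative products of `alpha` (strictly decreasing).
#' @export
setClass("NoiseSchedule",
  representation(lambda = "numeric", alpha = "numeric", alphaBar = "numeric"))

setValidity("NoiseSchedule", function(object) {
  lam <- object@lambda
  if (length(lam) < 1) return("schedule needs at least one step")
  if (any(lam <= 0) || any(lam >= 1)) return("lambda must lie in (0, 1)")
  if (max(abs(object@alpha - (1 - lam))) > 1e-12)
    return("alpha must equal 1 - lambda")
  if (max(abs(object@alphaBar - cumprod(object@alpha))) > 1e-12)
    return("alphaBar must be the cumulative product of alpha")
  if (any(diff(object@alphaBar) >= 0))
    return("alphaBar must be strictly decreasing")
  TRUE
})

#' Construct a noise schedule
#'
#' The default is a linear `lambda_t` ramp over `T = 100` steps with
#' endpoints scaled so that the cumulative signal retention
#' `alphaBar_T` is driven close to zero (about 5e-5), the property a
#' generative schedule must have for sampling to start from pure prior
#' noise. (The classic 1e-4..0.02 endpoints belong to 1000-step
#' schedules; at desk scale they would leave a third of the signal
#' intact at `T`.)
#'
#' @param Tsteps number of diffusion steps (default 100, desk scale).
#' @param lambdaMin,lambdaMax endpoints of a linear `lambda_t` ramp
#'   (defaults 0.001 and 0.2).
#' @param lambda optionally a full vector of per-step rates, overriding
#'   the linear ramp.
#' @return A validated [NoiseSchedule].
#' @examples
#' sch <- noiseSchedule(100)
#' range(alphaBar(sch))
#' @export
noiseSchedule <- function(Tsteps = 100L, lambdaMin = 0.001, lambdaMax = 0.2,
                          lambda = NULL) {
  if (is.null(lambda)) lambda <- seq(lambdaMin, lambdaMax, length.out = Tsteps)
  alpha <- 1 - lambda
  new("NoiseSchedule", lambda = lambda, alpha = alpha,
      alphaBar = cumprod(alpha))
}

#' Number of steps of a schedule
#' @param schedule a [NoiseSchedule].
#' @return Integer number of steps `T`.
#' @export
scheduleSteps <- function(schedule) length(schedule@lambda)

#' Cumulative signal retention `alphaBar_t`
#' @param schedule a [NoiseSchedule].
#' @param t optional time index (vectorized); `t = 0` returns 1.
#' @return Numeric `alphaBar` values.
#' @export
alphaBar <- function(schedule, t = NULL) {
  if (is.null(t)) return(schedule@alphaBar)
  ifelse(t == 0, 1, schedule@alphaBar[pmax(t, 1)])
}

#' Diffusion state at time t
#'
#' Positions in the prior-centered frame plus per-atom and per-pair
#' category simplices.
#'
#' @slot positions n x 3 matrix, prior-centered frame (Angstrom).
#' @slot atomProbs n x Ka matrix, each row a simplex over atom types.
#' @slot bondProbs p x 5 matrix, each row a simplex over bond categories
#'   (columns follow [BOND_CATEGORIES]); rows correspond to `pairIndex`.
#' @slot pairIndex p x 2 integer matrix of unordered atom pairs (i < j).
#' @slot t integer time index.
#' @export
setClass("DiffusionState",
  representation(positions = "matrix", atomProbs = "matrix",
                 bondProbs = "matrix", pairIndex = "matrix", t = "integer"))

setValidity("DiffusionState", function(object) {
  if (ncol(object@bondProbs) != 5L)
    return("bond simplices must have exactly 5 categories")
  bad <- function(P) nrow(P) > 0 &&
    (any(P < -1e-12) || max(abs(rowSums(P) - 1)) > 1e-9)
  if (bad(object@atomProbs)) return("atom rows must be simplices")
  if (bad(object@bondProbs)) return("bond rows must be simplices")
  if (nrow(object@bondProbs) != nrow(object@pairIndex))
    return("bondProbs rows must match pairIndex rows")
  TRUE
})

#' Loss weights of the overall diffusion loss
#'
#' @param gammaV,gammaB non-negative weights of the atom-type and
#'   bond-type reconstruction losses. Defaults 100 each, the convention
#'   of decomposed-diffusion training at full scale.
#' @return A validated list with class `"LossWeights"`.
#' @export
lossWeights <- function(gammaV = 100, gammaB = 100) {
  stopifnot(is.finite(gammaV), is.finite(gammaB), gammaV >= 0, gammaB >= 0)
  structure(list(gammaV = gammaV, gammaB = gammaB), class = "LossWeights")
}

#' Sampling configuration for Best-of-K / Best-of-N
#'
#' @param K candidates generated per target for Best-of-K curation
#'   (default 10).
#' @param N draws for Best-of-N selection (default 20).
#' @param temperature diversity temperature passed to generators that
#'   support it (the toy generator maps it to coordinate-jitter scale).
#' @param seed integer run seed.
#' @return A validated list with class `"SamplerConfig"`.
#' @export
samplerConfig <- function(K = 10L, N = 20L, temperature = 1, seed = 1L) {
  stopifnot(K >= 1, N >= 1, temperature > 0)
  structure(list(K = as.integer(K), N = as.integer(N),
                 temperature = temperature, seed = as.integer(seed)),
            class = "SamplerConfig")
}

#' Adaptive extraction parameters for arm/scaffold decomposition
#'
#' @param cutoff pocket-contact cutoff in Angstrom (default 4).
#' @param radius fragment-compactness radius in Angstrom (default 6).
#' @param cutoffStep,radiusStep relaxation increments in Angstrom
#'   (default 0.5 each).
#' @param maxRelaxations bound on the relaxation loop (default 8).
#' @return A validated list with class `"ExtractionParams"`.
#' @export
extractionParams <- function(cutoff = 4, radius = 6, cutoffStep = 0.5,
                             radiusStep = 0.5, maxRelaxations = 8L) {
  stopifnot(cutoff > 0, radius > 0, cutoffStep > 0, radiusStep > 0,
            maxRelaxations >= 1)
  structure(list(cutoff = cutoff, radius = radius, cutoffStep = cutoffStep,
                 radiusStep = radiusStep,
                 maxRelaxations = as.integer(maxRelaxations)),
            class = "ExtractionParams")
}

#' A reward-ranked candidate cohort for one target
#'
#' @slot targetId identifier of the target.
#' @slot pocket the conditioning [ProteinPocket].
#' @slot candidates list of entries, each a list with elements `mol`
#'   ([Molecule3D]), `pose` ([Molecule3D] or NULL) and `reward`
#'   ([RewardVector]).
#' @slot KRequested number of samples requested (candidates kept after
#'   validity filtering may be fewer).
#' @export
setClass("CandidateSet",
  representation(targetId = "character", pocket = "ProteinPocket",
                 candidates = "list", KRequested = "integer"))

setValidity("CandidateSet", function(object) {
  if (object@KRequested < 1) return("KRequested must be positive")
  if (length(object@candidates) > object@KRequested)
    return("cannot keep more candidates than were requested")
  for (cand in object@candidates) {
    if (!is(cand$mol, "Molecule3D") || !is(cand$reward, "RewardVector"))
      return("each candidate needs a Molecule3D and a RewardVector")
  }
  ws <- unique(t(vapply(object@candidates, function(cand) {
    w <- cand$reward@weights; c(w@wQED, w@wSA, w@wDock)
  }, numeric(3))))
  if (NROW(ws) > 1)
    return("all candidate rewards must use the same weights")
  TRUE
})

#' A curated Best-of-K fine-tuning batch
#'
#' One record per successfully curated target: the relocated winner, its
#' pocket, its arm/scaffold decomposition and the estimated priors.
#'
#' @slot records list of lists with elements `targetId`, `ligand`,
#'   `pocket`, `decomposed`, `priors`, `reward`.
#' @slot batchSizeB configured batch size B.
#' @slot subsetSizeB number of curated records b (`<= B`).
#' @export
setClass("CurationBatch",
  representation(records = "list", batchSizeB = "integer",
                 subsetSizeB = "integer"))

setValidity("CurationBatch", function(object) {
  if (object@subsetSizeB != length(object@records))
    return("subsetSizeB must equal the number of records")
  if (object@subsetSizeB > object@batchSizeB)
    return("subset size b must not exceed batch size B")
  TRUE
})

#' Trainable denoiser of the decomposed diffusion model
#'
#' A small distance-featurized predictor over ligand and pocket atoms.
#' Given a noisy [DiffusionState] it predicts the clean positions,
#' atom-type simplices and bond-type simplices. Architectural fidelity to
#' any particular equivariant network is not claimed; the prediction
#' contract is what the rest of the toolkit consumes.
#'
#' @slot atomVocab character vector of generatable element symbols.
#' @slot params named numeric parameter vector.
#' @slot trainLog data frame of training-loss traces (possibly empty).
#' @export
setClass("DenoiserModel",
  representation(atomVocab = "character", params = "numeric",
                 trainLog = "data.frame"))

setValidity("DenoiserModel", function(object) {
  if (length(object@atomVocab) < 2)
    return("atom vocabulary needs at least two types")
  if (any(!is.finite(object@params))) return("parameters must be finite")
  TRUE
})

# --- show methods -----------------------------------------------------------

setMethod("show", "Molecule3D", function(object) {
  cat(sprintf("Molecule3D '%s': %d atoms, %d bonds\n", object@name,
              length(object@elements), nrow(object@bonds)))
  tab <- table(object@elements)
  cat("  formula:", paste0(names(tab), ifelse(tab > 1, tab, ""),
                           collapse = ""), "\n")
})

setMethod("show", "ProteinPocket", function(object) {
  cat(sprintf("ProteinPocket '%s': %d atoms, %d residues\n", object@name,
              length(object@elements), length(unique(object@resid))))
})

setMethod("show", "RewardVector", function(object) {
  cat(sprintf(
    "RewardVector: reward %.4f (QED %.3f, SAnorm %.3f, dock %.2f -> %.3f)\n",
    object@reward, object@qed, object@saNorm, object@dockRaw,
    object@dockNorm))
})

setMethod("show", "DecomposedLigand", function(object) {
  cat(sprintf("DecomposedLigand: %d arm(s) (%s atoms), scaffold %d atoms\n",
              length(object@armAtomSets),
              paste(lengths(object@armAtomSets), collapse = "+"),
              length(object@scaffoldAtomSet)))
})

setMethod("show", "NoiseSchedule", function(object) {
  cat(sprintf(
    "NoiseSchedule: T = %d, lambda in [%.2g, %.2g], alphaBar_T = %.4g\n",
    length(object@lambda), min(object@lambda), max(object@lambda),
    utils::tail(object@alphaBar, 1)))
})

setMethod("show", "CandidateSet", function(object) {
  cat(sprintf("CandidateSet '%s': %d/%d valid candidates\n",
              object@targetId, length(object@candidates),
              object@KRequested))
})

setMethod("show", "CurationBatch", function(object) {
  cat(sprintf("CurationBatch: b = %d records (B = %d)\n",
              object@subsetSizeB, object@batchSizeB))
})

setMethod("show", "DenoiserModel", function(object) {
  cat(sprintf("DenoiserModel: vocab {%s}, %d parameters, %d logged steps\n",
              paste(object@atomVocab, collapse = ","),
              length(object@params), nrow(object@trainLog)))
})

# --- accessors --------------------------------------------------------------

#' @describeIn Molecule3D number of atoms
#' @param x object.
#' @export
setMethod("nAtoms", "Molecule3D", function(x) length(x@elements))

#' @describeIn ProteinPocket number of atoms
#' @param x object.
#' @export
setMethod("nAtoms", "ProteinPocket", function(x) length(x@elements))

#' @export
setMethod("atomElements", "Molecule3D", function(x) x@elements)

#' @export
setMethod("atomElements", "ProteinPocket", function(x) x@elements)

#' @export
setMethod("atomCoords", "Molecule3D", function(x) x@coords)

#' @export
setMethod("atomCoords", "ProteinPocket", function(x) x@coords)

#' @export
setMethod("atomCoords<-", "Molecule3D", function(x, value) {
  value <- as.matrix(value)
  storage.mode(value) <- "double"
  colnames(value) <- c("x", "y", "z")
  x@coords <- value
  validObject(x)
  x
})

#' @export
setMethod("bondTable", "Molecule3D", function(x) {
  data.frame(i = x@bonds[, 1], j = x@bonds[, 2],
             order = BOND_ORDERS[x@bonds[, 3]])
})

#' @export
setMethod("molName", "Molecule3D", function(x) x@name)

#' @export
setMethod("molName", "ProteinPocket", function(x) x@name)

#' @export
setMethod("rewardValue", "RewardVector", function(x) x@reward)
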