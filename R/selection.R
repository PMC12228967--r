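# Best-of-K ranking and curation (reward-ranked fine-tuning data
# collection and ranking steps) and Best-of-N selection.

#' Filter chemically valid molecules
#'
#' Keeps molecules that pass reconstruction-style validity checks: a
#' connected graph, at least two heavy atoms, and valences resolvable
#' for every atom (see [isValidMolecule()]). Order is preserved; an
#' empty result is legal.
#'
#' @param samples list of [Molecule3D].
#' @return Sub-list of valid molecules, with attribute `"removed"`
#'   holding the dropped indices.
#' @export
filterValid <- function(samples) {
  ok <- vapply(samples, isValidMolecule, logical(1))
  out <- samples[ok]
  attr(out, "removed") <- which(!ok)
  out
}

#' Score a cohort of candidates for one target
#'
#' Applies the docking scorer to every candidate, min-max normalizes the
#' docking scores across the cohort, computes QED and normalized SA, and
#' assembles a [CandidateSet].
#'
#' @param mols list of valid [Molecule3D] (one target's cohort).
#' @param pocket the target [ProteinPocket].
#' @param scorer docking scorer `(mol, pocket) -> list(score, pose)`.
#' @param weights a [RewardWeights].
#' @param targetId identifier for the target.
#' @param KRequested the number of samples originally requested.
#' @return A [CandidateSet].
#' @export
scoreCohort <- function(mols, pocket, scorer, weights,
                        targetId = "target", KRequested = length(mols)) {
  docked <- lapply(mols, scorer, pocket = pocket)
  raw <- vapply(docked, function(d) d$score, numeric(1))
  norm <- if (length(raw) > 0) normalizeDockScores(raw) else numeric(0)
  candidates <- vector("list", length(mols))
  for (k in seq_along(mols)) {
    candidates[[k]] <- list(
      mol = mols[[k]], pose = docked[[k]]$pose,
      reward = scoreCandidate(mols[[k]], raw[k], norm[k], weights))
  }
  new("CandidateSet", targetId = targetId, pocket = pocket,
      candidates = candidates, KRequested = as.integer(KRequested))
}

#' Best-of-K: the reward-argmax of a candidate set
#'
#' Ties break to the lowest candidate index, making selection
#' deterministic.
#'
#' @param set a [CandidateSet] with at least one candidate.
#' @return List with `index` (position in the candidate list) and `mol`
#'   (the winning [Molecule3D]), plus `pose` and `reward`.
#' @export
bestOfK <- function(set) {
  if (length(set@candidates) == 0)
    stopf("no valid candidate for target '%s'", set@targetId)
  rewards <- vapply(set@candidates, function(cand) cand$reward@reward,
                    numeric(1))
  idx <- which.max(rewards)   # which.max returns the first maximum
  cand <- set@candidates[[idx]]
  list(index = idx, mol = cand$mol, pose = cand$pose,
       reward = cand$reward)
}

#' Best-of-N selection without fine-tuning
#'
#' Draws `N` samples from the generator, drops invalid ones, scores the
#' valid cohort (docking normalization over the N valid draws of this
#' target) and returns the reward-argmax. No model state is modified.
#'
#' @param generator candidate source
#'   `(pocket, count, seed, temperature) -> list of Molecule3D`.
#' @param scorer docking scorer `(mol, pocket) -> list(score, pose)`.
#' @param weights a [RewardWeights].
#' @param config a [samplerConfig()]; `config$N` draws are taken and
#'   `config$seed`/`config$temperature` are passed to the generator.
#' @param pocket the target [ProteinPocket].
#' @param targetId identifier used in error messages.
#' @return List with `mol`, `reward`, `index` (among valid draws) and
#'   `nValid`.
#' @export
bestOfN <- function(generator, scorer, weights, config, pocket,
                    targetId = "target") {
  draws <- generator(pocket, config$N, config$seed, config$temperature)
  valid <- filterValid(draws)
  if (length(valid) == 0)
    stopf("no valid sample among %d draws for target '%s'", config$N,
          targetId)
  set <- scoreCohort(valid, pocket, scorer, weights, targetId = targetId,
                     KRequested = config$N)
  best <- bestOfK(set)
  c(best[c("mol", "reward", "index")], list(nValid = length(valid)))
}

#' Build a curated fine-tuning batch over many targets
#'
#' For each target: generate `K` candidates, filter invalid samples,
#' score the survivors, keep the reward-argmax, relocate it onto its
#' docking pose, decompose it against the pocket and estimate the
#' fragment priors. Targets with zero valid candidates are skipped (and
#' reported via the `"skipped"` attribute), never aborting the batch.
#'
#' @param targets character vector of target identifiers.
#' @param pockets named list of [ProteinPocket], indexed by target id.
#' @param generator candidate source
#'   `(pocket, count, seed, temperature) -> list of Molecule3D`.
#' @param scorer docking scorer `(mol, pocket) -> list(score, pose)`.
#' @param weights a [RewardWeights].
#' @param config a [samplerConfig()] (uses `K`, `temperature`, `seed`).
#' @param extraction an [extractionParams()] list for the decomposition.
#' @param batchSizeB configured batch size B (default 128).
#' @return A [CurationBatch]; attribute `"skipped"` lists skipped
#'   targets with reasons.
#' @export
buildCurationBatch <- function(targets, pockets, generator, scorer,
                               weights, config = samplerConfig(),
                               extraction = extractionParams(),
                               batchSizeB = 128L) {
  records <- list()
  skipped <- character(0)
  for (tid in targets) {
    pocket <- pockets[[tid]]
    if (is.null(pocket)) {
      skipped[tid] <- "no pocket"
      next
    }
    res <- tryCatch({
      draws <- generator(pocket, config$K, deriveSeed(config$seed, tid),
                         config$temperature)
      valid <- filterValid(draws)
      if (length(valid) == 0) stopf("no valid candidate")
      set <- scoreCohort(valid, pocket, scorer, weights, targetId = tid,
                         KRequested = config$K)
      best <- bestOfK(set)
      ligand <- if (!is.null(best$pose))
        relocateToPose(best$mol, best$pose) else best$mol
      decomposed <- adaptiveDecompose(ligand, pocket, extraction)
      priors <- estimatePriors(decomposed)
      list(targetId = tid, ligand = ligand, pocket = pocket,
           decomposed = decomposed, priors = priors, reward = best$reward,
           cohortRewards = vapply(set@candidates,
                                  function(cand) cand$reward@reward,
                                  numeric(1)))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      skipped[tid] <- conditionMessage(res)
    } else {
      records[[length(records) + 1L]] <- res
    }
  }
  batch <- new("CurationBatch", records = records,
               batchSizeB = as.integer(batchSizeB),
               subsetSizeB = length(records))
  attr(batch, "skipped") <- skipped
  batch
}
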