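# Multi-objective reward: per-candidate metric values, per-cohort
# normalization of docking scores, and the weighted-sum reward used to
# rank candidates.

#' Min-max normalize docking scores within one candidate cohort
#'
#' Docking scores of the K candidates generated for one target are scaled
#' to \[0, 1\] and inverted, so the best (most negative) score maps to 1
#' and the worst to 0. When all scores are equal the cohort is flat and
#' every entry maps to 0.5, keeping the cohort rankable by the other
#' objectives.
#'
#' @param scores numeric vector of raw docking scores (lower is better)
#'   for the candidates of a single target.
#' @return Numeric vector in \[0, 1\], anti-concordant with the input.
#' @examples
#' normalizeDockScores(c(-9, -7, -5))  # 1.0, 0.5, 0.0
#' @export
normalizeDockScores <- function(scores) {
  if (length(scores) == 0) stopf("empty docking-score cohort")
  if (any(!is.finite(scores))) stopf("non-finite docking score in cohort")
  lo <- min(scores); hi <- max(scores)
  if (hi == lo) return(rep(0.5, length(scores)))
  (hi - scores) / (hi - lo)
}

#' Score a candidate molecule against the multi-objective reward
#'
#' Computes QED and normalized SA on the molecule and combines them with
#' the cohort-normalized docking score into the weighted-sum reward.
#'
#' @param mol a [Molecule3D].
#' @param dockRaw raw docking score of the candidate (lower is better).
#' @param dockNorm cohort-normalized docking score, produced by
#'   [normalizeDockScores()] over the candidate's own target cohort.
#' @param weights a [RewardWeights].
#' @return A [RewardVector].
#' @export
scoreCandidate <- function(mol, dockRaw, dockNorm, weights) {
  qed <- computeQED(mol)
  sa <- computeSANorm(mol)
  reward <- weights@wQED * qed + weights@wSA * sa + weights@wDock * dockNorm
  new("RewardVector", qed = qed, saNorm = sa, dockRaw = dockRaw,
      dockNorm = dockNorm, reward = reward, weights = weights)
}

#' Assemble a reward vector from precomputed components
#'
#' @param qed QED in \[0, 1\].
#' @param saNorm normalized SA in \[0, 1\].
#' @param dockRaw raw docking score.
#' @param dockNorm normalized docking score in \[0, 1\].
#' @param weights a [RewardWeights].
#' @return A [RewardVector].
#' @export
rewardVector <- function(qed, saNorm, dockRaw, dockNorm, weights) {
  reward <- weights@wQED * qed + weights@wSA * saNorm +
    weights@wDock * dockNorm
  new("RewardVector", qed = qed, saNorm = saNorm, dockRaw = dockRaw,
      dockNorm = dockNorm, reward = reward, weights = weights)
}

#' Drug-design success flag
#'
#' A molecule counts as a success when QED exceeds 0.25, normalized SA
#' exceeds 0.59 and the docking score is below -8.18, all inequalities
#' strict.
#'
#' @param qed QED value.
#' @param saNorm normalized SA value.
#' @param vina docking score.
#' @return Logical scalar.
#' @examples
#' successFlag(0.5, 0.7, -9)      # TRUE
#' successFlag(0.25, 0.7, -9)     # FALSE: boundary is strict
#' @export
successFlag <- function(qed, saNorm, vina) {
  stopifnot(is.finite(qed), is.finite(saNorm), is.finite(vina))
  qed > 0.25 && saNorm > 0.59 && vina < -8.18
}

#' A docking-scorer function from the surrogate potential
#'
#' Builds a scorer satisfying the pluggable contract: given a molecule
#' and pocket, return `list(score = <lower better>, pose = <Molecule3D>)`.
#' The surrogate has no pose search, so the pose is the ligand itself.
#'
#' @param calibration scale factor of the surrogate potential (see
#'   [surrogateDockScore()]).
#' @return A function `(mol, pocket) -> list(score, pose)`.
#' @export
surrogateScorer <- function(calibration = 0.15) {
  function(mol, pocket) {
    list(score = surrogateDockScore(mol, pocket, calibration = calibration),
         pose = mol)
  }
}

#' A docking-scorer adapter around an external command
#'
#' Shells out to a user-supplied docking executable; the command receives
#' a ligand SDF path and a pocket PDB path and must print the affinity
#' (a single number, lower = better) on stdout. Intended for real docking
#' backends; not exercised by the test-suite.
#'
#' @param command path to the executable.
#' @param args extra arguments placed before the two file paths.
#' @return A function `(mol, pocket) -> list(score, pose = NULL)`.
#' @export
externalScorer <- function(command, args = character(0)) {
  force(command); force(args)
  function(mol, pocket) {
    ligF <- tempfile(fileext = ".sdf")
    pocF <- tempfile(fileext = ".pdb")
    on.exit(unlink(c(ligF, pocF)))
    writeSDF(mol, ligF)
    writePocketPDB(pocket, pocF)
    out <- system2(command, c(args, ligF, pocF), stdout = TRUE)
    score <- suppressWarnings(as.numeric(utils::tail(out, 1)))
    if (is.na(score)) stopf("external scorer returned no numeric affinity")
    list(score = score, pose = NULL)
  }
}
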