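# Reverse (generative) process: from prior noise to a molecule, guided
# by the denoiser's predictions and the posterior kernels of the forward
# processes.

# vectorized categorical sampling: one draw per simplex row
.sampleRows <- function(P) {
  n <- nrow(P); K <- ncol(P)
  if (n == 0) return(integer(0))
  u <- stats::runif(n) * rowSums(P)
  cat <- rep(1L, n)
  acc <- P[, 1]
  for (k in seq_len(K - 1) + 1L) {
    move <- u > acc
    cat[move] <- k
    acc <- acc + P[, k]
  }
  cat
}

# distribute nAtoms over the priors' fragments proportionally to the
# original fragment sizes (largest-remainder rounding)
.fragmentAssignment <- function(priors, nAtoms) {
  sizes <- tabulate(priors@assignment, nbins = length(priors@mu))
  if (nAtoms == length(priors@assignment)) return(priors@assignment)
  quota <- sizes / sum(sizes) * nAtoms
  base <- floor(quota)
  rem <- nAtoms - sum(base)
  if (rem > 0) {
    extra <- order(quota - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  rep(seq_along(base), base)
}

#' Sample a ligand from the diffusion model
#'
#' Starts from prior noise (positions `N(0, Sigma_frag)` in the
#' prior-centered frame, atom and bond categories uniform) and iterates
#' `t = T..1`. Positions follow the stochastic reverse kernel of the
#' chosen forward mode. Atom-type categories are sampled ancestrally
#' from the categorical posterior evaluated at the model's clean-state
#' prediction (so element composition reflects the model distribution);
#' bond-type simplices are propagated in expectation through the same
#' posterior — bond identity is then a near-deterministic function of
#' the sampled geometry, which keeps the bond network coherent. At the
#' end, positions are un-shifted by the priors and all categories are
#' discretized by argmax (ties break to the lowest category index);
#' non-bonded pairs are dropped. The output may still fail chemical
#' validity; callers filter with [filterValid()].
#'
#' @param model a [DenoiserModel].
#' @param pocket the conditioning [ProteinPocket].
#' @param priors a [DecompPriors] describing the fragment layout to
#'   sample into.
#' @param nAtoms number of atoms to generate (respected exactly; if it
#'   differs from the priors' atom count, atoms are redistributed over
#'   fragments proportionally).
#' @param schedule a [NoiseSchedule].
#' @param seed integer seed; fixed seed + fixed model gives an identical
#'   molecule.
#' @param mode forward-process mode, `"ddpm"` (default) or
#'   `"as-printed"`.
#' @param name name for the returned molecule.
#' @return A [Molecule3D].
#' @export
sampleLigand <- function(model, pocket, priors, nAtoms, schedule,
                         seed = 1L, mode = c("ddpm", "as-printed"),
                         name = "sample") {
  mode <- match.arg(mode)
  assignment <- .fragmentAssignment(priors, nAtoms)
  samplePriors <- new("DecompPriors", mu = priors@mu, sigma = priors@sigma,
                      assignment = as.integer(assignment))
  Ka <- length(model@atomVocab)
  Tn <- scheduleSteps(schedule)
  chols <- .priorChol(samplePriors)
  lambda <- schedule@lambda
  fragIdx <- split(seq_len(nAtoms), assignment)
  applyChol <- function(M, scale = 1) {
    for (f in names(fragIdx)) {
      idx <- fragIdx[[f]]
      M[idx, ] <- (M[idx, , drop = FALSE] %*%
                     chols[[as.integer(f)]]) * scale
    }
    M
  }
  withSeed(seed, {
    x <- applyChol(matrix(stats::rnorm(3 * nAtoms), nAtoms, 3))
    pairs <- atomPairs(nAtoms)
    vProbs <- oneHotRows(sample.int(Ka, nAtoms, replace = TRUE), Ka)
    bProbs <- matrix(1 / 5, nrow(pairs), 5)
    for (t in seq(Tn, 1L)) {
      state <- diffusionState(x, vProbs, bProbs, pairs, t = t)
      pred <- predictDenoiser(model, state, pocket, samplePriors, schedule)
      abPrev <- alphaBar(schedule, t - 1L)
      if (mode == "ddpm") {
        ab_t <- alphaBar(schedule, t)
        a_t <- schedule@alpha[t]
        mean_x <- (sqrt(abPrev) * lambda[t] * pred$x0 +
                   sqrt(a_t) * (1 - abPrev) * x) / (1 - ab_t)
        varScale <- lambda[t] * (1 - abPrev) / (1 - ab_t)
      } else {
        Lt <- sum(lambda[seq_len(t)]); Lprev <- Lt - lambda[t]
        mean_x <- (Lprev * x + lambda[t] * pred$x0) / Lt
        varScale <- lambda[t] * Lprev / Lt
      }
      if (varScale > 0) {
        noise <- applyChol(matrix(stats::rnorm(3 * nAtoms), nAtoms, 3),
                           scale = sqrt(varScale))
        x <- mean_x + noise
      } else {
        x <- mean_x
      }
      vPost <- categoricalPosterior(vProbs, pred$v0, t, schedule, Ka)
      vProbs <- oneHotRows(.sampleRows(vPost), Ka)
      bProbs <- categoricalPosterior(bProbs, pred$b0, t, schedule, 5L)
    }
  })
  elements <- model@atomVocab[max.col(vProbs, ties.method = "first")]
  bcat <- max.col(bProbs, ties.method = "first")
  keep <- which(bcat > 1L)
  bonds <- if (length(keep) > 0)
    cbind(pairs[keep, 1], pairs[keep, 2], bcat[keep] - 1L) else NULL
  Molecule3D(elements, priorUnshift(x, samplePriors), bonds = bonds,
             name = name)
}
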