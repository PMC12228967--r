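# Per-fragment priors of the decomposed diffusion process and the
# prior-centered coordinate shift.

#' Estimate per-fragment priors from a decomposed ligand
#'
#' Maximum-likelihood estimates per fragment: `mu` is the mean of the
#' member-atom coordinates, `sigma` the sample covariance regularized by
#' `epsilon * I` (single-atom fragments get `epsilon * I` exactly), and
#' the assignment records each atom's fragment. Fragments are ordered
#' arms first, scaffold last.
#'
#' @param decomposed a [DecomposedLigand].
#' @param epsilon diagonal regularization in Angstrom squared
#'   (default 1e-3).
#' @return A [DecompPriors].
#' @export
estimatePriors <- function(decomposed, epsilon = 1e-3) {
  sets <- decomposed@armAtomSets
  if (length(decomposed@scaffoldAtomSet) > 0)
    sets <- c(sets, list(decomposed@scaffoldAtomSet))
  coords <- decomposed@ligand@coords
  K <- length(sets)
  mu <- vector("list", K); sigma <- vector("list", K)
  assignment <- integer(nrow(coords))
  for (k in seq_len(K)) {
    idx <- sets[[k]]
    assignment[idx] <- k
    xc <- coords[idx, , drop = FALSE]
    mu[[k]] <- unname(colMeans(xc))
    S <- if (nrow(xc) > 1) unname(stats::cov(xc)) else matrix(0, 3, 3)
    sigma[[k]] <- S + diag(epsilon, 3)
  }
  new("DecompPriors", mu = mu, sigma = sigma, assignment = assignment)
}

#' Shift positions to the prior-centered frame
#'
#' Subtracts each atom's fragment mean: `xShifted_i = x_i - mu[frag(i)]`.
#'
#' @param positions n x 3 coordinate matrix.
#' @param priors a [DecompPriors] whose assignment covers the n atoms.
#' @return n x 3 matrix of prior-centered positions.
#' @export
priorShift <- function(positions, priors) {
  muMat <- do.call(rbind, priors@mu)[priors@assignment, , drop = FALSE]
  positions - muMat
}

#' Invert the prior-centered shift
#'
#' @param positions n x 3 matrix in the prior-centered frame.
#' @param priors a [DecompPriors].
#' @return n x 3 matrix of original-frame positions; exact inverse of
#'   [priorShift()].
#' @export
priorUnshift <- function(positions, priors) {
  muMat <- do.call(rbind, priors@mu)[priors@assignment, , drop = FALSE]
  positions + muMat
}

# per-fragment Cholesky factors (upper triangular), cached per call site
.priorChol <- function(priors) {
  lapply(priors@sigma, chol)
}
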