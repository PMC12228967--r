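# Forward diffusion processes and reconstruction losses of the
# decomposed diffusion model. Positions diffuse as Gaussians scaled by
# the per-fragment prior covariance in the prior-centered frame;
# atom and bond types diffuse as categorical distributions mixed with the
# uniform distribution.

#' Forward position process
#'
#' Diffuses prior-centered positions from time 0 to time `t`. Two modes
#' are provided because the conditional kernel can be written with or
#' without mean shrinkage:
#' \describe{
#'   \item{`"ddpm"` (default)}{`x_t | x_{t-1} ~ N(sqrt(alpha_t) x_{t-1},
#'     lambda_t Sigma)`, giving the marginal
#'     `N(sqrt(alphaBar_t) x_0, (1 - alphaBar_t) Sigma)`. This is the
#'     form the `alphaBar` bookkeeping implies and the one consumed by
#'     the categorical-style posterior coefficients.}
#'   \item{`"as-printed"`}{`x_t | x_{t-1} ~ N(x_{t-1}, lambda_t Sigma)`
#'     with no shrinkage, giving the marginal
#'     `N(x_0, (sum_{s<=t} lambda_s) Sigma)`.}
#' }
#' Both return one sample plus the analytic marginal parameters.
#'
#' @param x0Shifted n x 3 matrix of prior-centered clean positions.
#' @param t time index in `1..T`.
#' @param schedule a [NoiseSchedule].
#' @param priors a [DecompPriors] assigning each atom a fragment
#'   covariance.
#' @param mode `"ddpm"` or `"as-printed"`.
#' @param seed integer seed for the Gaussian draw.
#' @return List with `sample` (n x 3), `mean` (n x 3), and `covScale`
#'   (scalar multiplying each atom's fragment covariance).
#' @export
forwardPosition <- function(x0Shifted, t, schedule, priors,
                            mode = c("ddpm", "as-printed"), seed = 1L) {
  mode <- match.arg(mode)
  Tn <- scheduleSteps(schedule)
  if (t < 1 || t > Tn) stopf("t must lie in 1..%d", Tn)
  if (mode == "ddpm") {
    ab <- alphaBar(schedule, t)
    meanMat <- sqrt(ab) * x0Shifted
    covScale <- 1 - ab
  } else {
    meanMat <- x0Shifted
    covScale <- sum(schedule@lambda[seq_len(t)])
  }
  n <- nrow(x0Shifted)
  chols <- .priorChol(priors)
  noise <- withSeed(seed, matrix(stats::rnorm(3 * n), n, 3))
  for (f in seq_along(chols)) {
    idx <- which(priors@assignment == f)
    if (length(idx) == 0) next
    noise[idx, ] <- (noise[idx, , drop = FALSE] %*% chols[[f]]) *
      sqrt(covScale)
  }
  list(sample = meanMat + noise, mean = meanMat, covScale = covScale)
}

#' Forward categorical process
#'
#' Mixes a category simplex with the uniform distribution. One step maps
#' `p_{t-1}` to `(1 - lambda_t) p_{t-1} + lambda_t / K`; the closed-form
#' marginal from time 0 is `alphaBar_t p_0 + (1 - alphaBar_t) / K`.
#'
#' @param p0 simplex vector (or matrix with one simplex per row).
#' @param t target time index.
#' @param schedule a [NoiseSchedule].
#' @param Kcat number of categories (atom types `Ka` or the 5 bond
#'   categories).
#' @param from time index of the input simplex: 0 (default) applies the
#'   closed-form marginal, `t - 1` applies a single step.
#' @return Simplex (vector or row matrix) at time `t`.
#' @export
forwardCategorical <- function(p0, t, schedule, Kcat, from = 0L) {
  if (Kcat < 2) stopf("need at least two categories")
  if (from == 0L) {
    ab <- alphaBar(schedule, t)
    ab * p0 + (1 - ab) / Kcat
  } else if (from == t - 1L) {
    lam <- schedule@lambda[t]
    (1 - lam) * p0 + lam / Kcat
  } else {
    stopf("from must be 0 or t-1")
  }
}

#' Posterior of the uniform-noise categorical diffusion
#'
#' The standard posterior over the category at time `t - 1` given the
#' state at `t` and a (predicted or true) clean distribution:
#' `c(p_t, p_0) = normalize((alpha_t p_t + (1 - alpha_t)/K) *
#' (alphaBar_{t-1} p_0 + (1 - alphaBar_{t-1})/K))`, the coefficients
#' depending on `alphaBar` as required.
#'
#' @param pT simplex at time `t` (vector or row matrix).
#' @param p0 clean simplex (same shape).
#' @param t time index `>= 1`.
#' @param schedule a [NoiseSchedule].
#' @param Kcat number of categories.
#' @return Posterior simplex (same shape as the inputs).
#' @export
categoricalPosterior <- function(pT, p0, t, schedule, Kcat) {
  if (Kcat < 2) stopf("need at least two categories")
  a <- schedule@alpha[t]
  abPrev <- alphaBar(schedule, t - 1L)
  u <- (a * pT + (1 - a) / Kcat) * (abPrev * p0 + (1 - abPrev) / Kcat)
  if (is.matrix(u)) {
    Z <- rowSums(u)
    if (any(Z <= 0)) stopf("degenerate categorical posterior")
    u / Z
  } else {
    Z <- sum(u)
    if (Z <= 0) stopf("degenerate categorical posterior")
    u / Z
  }
}

# KL divergence between rows of two simplex matrices (natural log,
# 0 log 0 := 0)
.klRows <- function(P, Q) {
  terms <- P * (log(pmax(P, 1e-300)) - log(pmax(Q, 1e-300)))
  terms[P == 0] <- 0
  rowSums(terms)
}

#' Reconstruction loss terms at time t
#'
#' `Lx` is the squared Euclidean distance between true and predicted
#' clean positions, summed over atoms. `Lv` and `Lb` are KL divergences
#' between the categorical posteriors computed with the true and the
#' predicted clean distributions, summed over atoms and atom pairs. The
#' overall loss is `Lx + gammaV Lv + gammaB Lb`.
#'
#' @param stateT a [DiffusionState] at time `t` (provides `v_t`, `b_t`).
#' @param truth list with `x0` (n x 3, prior-centered), `v0` (n x Ka
#'   simplex rows) and `b0` (p x 5 simplex rows).
#' @param pred list with `x0`, `v0`, `b0` of the same shapes.
#' @param schedule a [NoiseSchedule].
#' @param weights a [lossWeights()] list.
#' @return List with `Lx`, `Lv`, `Lb`, `Ltotal`.
#' @export
lossTerms <- function(stateT, truth, pred, schedule,
                      weights = lossWeights()) {
  t <- stateT@t
  Lx <- sum((truth$x0 - pred$x0)^2)
  Ka <- ncol(stateT@atomProbs)
  qv <- categoricalPosterior(stateT@atomProbs, truth$v0, t, schedule, Ka)
  pv <- categoricalPosterior(stateT@atomProbs, pred$v0, t, schedule, Ka)
  Lv <- sum(.klRows(qv, pv))
  if (nrow(stateT@bondProbs) > 0) {
    qb <- categoricalPosterior(stateT@bondProbs, truth$b0, t, schedule, 5L)
    pb <- categoricalPosterior(stateT@bondProbs, pred$b0, t, schedule, 5L)
    Lb <- sum(.klRows(qb, pb))
  } else Lb <- 0
  list(Lx = Lx, Lv = Lv, Lb = Lb,
       Ltotal = Lx + weights$gammaV * Lv + weights$gammaB * Lb)
}

#' Build a DiffusionState
#'
#' @param positions n x 3 matrix (prior-centered frame).
#' @param atomProbs n x Ka simplex rows.
#' @param bondProbs p x 5 simplex rows over [BOND_CATEGORIES].
#' @param pairIndex p x 2 matrix of atom pairs (i < j); defaults to all
#'   pairs of the n atoms.
#' @param t integer time index.
#' @return A validated [DiffusionState].
#' @export
diffusionState <- function(positions, atomProbs, bondProbs,
                           pairIndex = NULL, t = 1L) {
  if (is.null(pairIndex)) pairIndex <- atomPairs(nrow(positions))
  new("DiffusionState", positions = positions, atomProbs = atomProbs,
      bondProbs = bondProbs, pairIndex = pairIndex, t = as.integer(t))
}

# one-hot simplex rows from integer categories
oneHotRows <- function(codes, K) {
  M <- matrix(0, length(codes), K)
  M[cbind(seq_along(codes), codes)] <- 1
  M
}

# molecule -> (x0 shifted, one-hot atom rows, one-hot bond rows) given a
# vocabulary and priors
moleculeToTruth <- function(mol, priors, vocab) {
  v <- match(mol@elements, vocab)
  if (anyNA(v))
    stopf("element(s) outside vocabulary: %s",
          paste(setdiff(mol@elements, vocab), collapse = ","))
  n <- length(v)
  pairs <- atomPairs(n)
  bcodes <- rep(1L, nrow(pairs))  # 1 = non-bonded
  if (nrow(mol@bonds) > 0) {
    key <- paste(pmin(mol@bonds[, 1], mol@bonds[, 2]),
                 pmax(mol@bonds[, 1], mol@bonds[, 2]))
    pkey <- paste(pairs[, 1], pairs[, 2])
    hit <- match(key, pkey)
    bcodes[hit] <- mol@bonds[, 3] + 1L  # shift past non-bonded
  }
  list(x0 = priorShift(mol@coords, priors),
       v0 = oneHotRows(v, length(vocab)),
       b0 = oneHotRows(bcodes, 5L),
       pairIndex = pairs)
}
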