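# The trainable denoiser: a deliberately small, distance-featurized
# predictor satisfying the prediction contract (noisy state -> clean
# positions, atom-type simplices, bond-type simplices). Its parameters
# are few enough for analytic gradients (see finetune.R) while still
# giving the fine-tuning loop real degrees of freedom: a time-dependent
# position gain, atom-type logits fed by the noisy type state, and
# bond-type logits fed by the noisy bond state plus interatomic-distance
# features.

.LOGEPS <- 1e-4

# radial basis features of an interatomic distance (Angstrom): a covalent
# window around typical bond lengths and a mid-range window
.bondDistFeatures <- function(d) {
  cbind(f1 = exp(-(d - 1.45)^2 / (2 * 0.35^2)),
        f2 = exp(-(d - 2.50)^2 / (2 * 0.50^2)))
}

.softmaxRows <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

# parameter vector layout for vocabulary size Ka:
# wx0 wx1 wx2 hx | av bv[1..Ka] wv[1..Ka] wvT[1..Ka] |
# ab bb[1..5] wb[5 x 2] wbT[1..5]
# wv weights a pocket-proximity feature into the atom-type logits
# (breaking the per-atom symmetry of the type predictions); wvT/wbT
# weight a noise-level feature (1 - sqrt(alphaBar_t)) so that
# calibration of the heads at heavily corrupted states does not leak
# into their behaviour at clean states
.paramNames <- function(Ka) {
  c("wx0", "wx1", "wx2", "hx", "av", "avT", paste0("bv", seq_len(Ka)),
    paste0("wv", seq_len(Ka)), paste0("wvT", seq_len(Ka)),
    "ab", "abT", paste0("bb", 1:5),
    paste0("wb", rep(1:5, 2), "_", rep(1:2, each = 5)),
    paste0("wbT", 1:5))
}

# pairwise distance-relaxation messages: each atom is nudged along the
# directions to its near neighbours by a kernel with a restoring term
# toward the reference bond length r0 and a repulsive bump at
# second-neighbour range, so relaxed point sets form chain/ring-like
# arrangements rather than close-packed clusters
.relaxMessages <- function(pos, r0 = 1.5, width = 1.0,
                           rep0 = 1.9, repWidth = 0.25,
                           repStrength = 0.3, maxNeighbors = 3L) {
  n <- nrow(pos)
  if (n < 2) return(matrix(0, n, 3))
  d <- crossDist(pos, pos)
  diag(d) <- Inf
  M <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    near <- order(d[i, ])[seq_len(min(maxNeighbors, n - 1L))]
    coef <- numeric(n)
    # restoring force toward r0 for the nearest neighbours only --
    # capping the coordination keeps relaxed point sets chain/ring-like
    coef[near] <- (d[i, near] - r0) *
      exp(-(d[i, near] - r0)^2 / (2 * width^2))
    # soft repulsion from everything else at second-neighbour range
    others <- setdiff(which(d[i, ] < rep0 + 3 * repWidth), near)
    coef[others] <- coef[others] -
      repStrength * exp(-(d[i, others] - rep0)^2 / (2 * repWidth^2))
    w <- coef / pmax(d[i, ], 1e-8)
    M[i, ] <- colSums(w * pos) - sum(w) * pos[i, ]
  }
  M
}

#' Create a denoiser model
#'
#' The fresh model is seeded to play the role of the pre-trained
#' checkpoint the alignment loop starts from at full scale: the position
#' head is the identity-style predictor `x0hat = sqrt(alphaBar_t) x_t`
#' plus a fixed-strength geometric relaxation, atom-type logits follow
#' the element composition of the toy-world grammar, and bond logits
#' encode a geometric bond prior (pairs at covalent distance favour a
#' single bond, distant pairs favour non-bonded). Fine-tuning moves the
#' statistical heads; the relaxation strength stays fixed (see
#' [finetuneDenoiser()]).
#'
#' @param atomVocab character vector of generatable elements
#'   (default C, N, O, S).
#' @param composition prior probabilities of the vocabulary elements
#'   used for the initial atom-logit biases (recycled/normalized);
#'   defaults to the toy-world grammar composition.
#' @return A [DenoiserModel].
#' @export
newDenoiser <- function(atomVocab = c("C", "N", "O", "S"),
                        composition = NULL) {
  Ka <- length(atomVocab)
  if (is.null(composition)) {
    composition <- c(C = 0.88, N = 0.07, O = 0.04, S = 0.01)[atomVocab]
    composition[is.na(composition)] <- 0.05
  }
  composition <- composition / sum(composition)
  wv <- c(C = 0, N = 1.2, O = 1.2, S = 0.4)[atomVocab]
  wv[is.na(wv)] <- 0
  params <- c(0, 1, 0,                       # wx: g(t) = sqrt(alphaBar_t)
              1.0,                           # hx: distance relaxation
              0, 0, log(composition),        # av, avT, bv
              wv,                            # wv: polar atoms face pocket
              rep(0, Ka),                    # wvT: noise-level correction
              0, 0,                          # ab, abT
              6, -2, -5, -8, -5,             # bb: sparse bonds by default
              -8, 8, 5, 2, 5,                # wb[,1]: covalent window
              2, -2, -2, -2, -2,             # wb[,2]: mid-range repulsion
              rep(0, 5))                     # wbT: noise-level correction
  names(params) <- .paramNames(Ka)
  new("DenoiserModel", atomVocab = atomVocab, params = params,
      trainLog = data.frame())
}

#' Parameters of a denoiser
#' @param model a [DenoiserModel].
#' @return Named numeric vector.
#' @export
denoiserParams <- function(model) model@params

# internal: unpack the parameter vector
.unpackParams <- function(model) {
  p <- model@params
  Ka <- length(model@atomVocab)
  list(wx = p[1:3], hx = p[[4]], av = p[[5]], avT = p[[6]],
       bv = p[6 + seq_len(Ka)],
       wv = p[6 + Ka + seq_len(Ka)], wvT = p[6 + 2 * Ka + seq_len(Ka)],
       ab = p[[6 + 3 * Ka + 1]], abT = p[[6 + 3 * Ka + 2]],
       bb = p[6 + 3 * Ka + 2 + 1:5],
       wb = matrix(p[6 + 3 * Ka + 7 + 1:10], 5, 2),
       wbT = p[6 + 3 * Ka + 17 + 1:5])
}

#' Predict clean structure from a noisy diffusion state
#'
#' @param model a [DenoiserModel].
#' @param state a [DiffusionState] at time `t`.
#' @param pocket the conditioning [ProteinPocket] (part of the contract;
#'   the default model conditions on geometry through the priors).
#' @param priors a [DecompPriors].
#' @param schedule a [NoiseSchedule].
#' @return List with `x0` (n x 3, prior-centered), `v0` (n x Ka simplex
#'   rows), `b0` (p x 5 simplex rows), plus the intermediate features
#'   used by the gradient computation.
#' @export
predictDenoiser <- function(model, state, pocket, priors, schedule) {
  par <- .unpackParams(model)
  ab_t <- alphaBar(schedule, state@t)
  gain <- par$wx[1] + par$wx[2] * sqrt(ab_t) + par$wx[3] * ab_t
  pos <- priorUnshift(state@positions, priors)
  relax <- .relaxMessages(pos)
  x0 <- gain * state@positions + par$hx * relax
  Fv <- log(state@atomProbs + .LOGEPS)
  # geometric features are computed from the model's own denoised
  # positions (gradients stopped), so their distribution is the same
  # during training on noisy states and during reverse sampling
  posHat <- priorUnshift(x0, priors)
  # pocket-proximity feature in (0, 1), larger for atoms facing the
  # pocket surface
  dPocket <- apply(crossDist(posHat, pocket@coords), 1, min)
  Gv <- exp(-dPocket / 4)
  tFeat <- 1 - sqrt(ab_t)
  Zv <- (par$av + par$avT * tFeat) * Fv +
    matrix(par$bv + tFeat * par$wvT, nrow(Fv), length(par$bv),
           byrow = TRUE) + outer(Gv, par$wv)
  v0 <- .softmaxRows(Zv)
  pi <- state@pairIndex
  d <- sqrt(rowSums((posHat[pi[, 1], , drop = FALSE] -
                     posHat[pi[, 2], , drop = FALSE])^2))
  Fd <- .bondDistFeatures(d)
  Fb <- log(state@bondProbs + .LOGEPS)
  Zb <- (par$ab + par$abT * tFeat) * Fb +
    matrix(par$bb + tFeat * par$wbT, nrow(Fb), 5, byrow = TRUE) +
    Fd %*% t(par$wb)
  b0 <- .softmaxRows(Zb)
  list(x0 = x0, v0 = v0, b0 = b0,
       gain = gain, gainBasis = c(1, sqrt(ab_t), ab_t), relax = relax,
       tFeat = tFeat, Fv = Fv, Gv = Gv, Fb = Fb, Fd = Fd, Zv = Zv,
       Zb = Zb)
}

#' Save a denoiser model as a JSON artifact
#'
#' The artifact records the vocabulary, parameter vector, an optional
#' schedule and a configuration hash, all in one plain-text JSON file.
#'
#' @param model a [DenoiserModel].
#' @param path output path.
#' @param schedule optionally the [NoiseSchedule] used with the model.
#' @return Invisibly, `path`.
#' @export
saveDenoiser <- function(model, path, schedule = NULL) {
  obj <- list(atomVocab = model@atomVocab,
              params = as.list(model@params),
              configHash = deriveSeed(1L, paste(model@atomVocab,
                                                collapse = "")))
  if (!is.null(schedule)) obj$lambda <- schedule@lambda
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' Load a denoiser model from a JSON artifact
#'
#' @param path path written by [saveDenoiser()].
#' @return List with `model` ([DenoiserModel]) and `schedule`
#'   ([NoiseSchedule] or NULL).
#' @export
loadDenoiser <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  params <- unlist(obj$params)
  model <- new("DenoiserModel", atomVocab = obj$atomVocab,
               params = params, trainLog = data.frame())
  schedule <- if (!is.null(obj$lambda))
    noiseSchedule(lambda = obj$lambda) else NULL
  list(model = model, schedule = schedule)
}
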