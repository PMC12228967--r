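# Synthetic accessibility. The raw score lives on the conventional
# 1 (easy) .. 10 (hard) scale and is built from graph-complexity terms:
# ring count and fusion, macrocycles, heteroatom load, sp3 branching,
# stereo-prone centres and molecule size. The fragment-frequency database
# of the original contribution-based method is replaced by these
# closed-form terms, calibrated so that simple drug-like molecules land
# in the 1-3 band; see the methods vignette for the calibration.

#' Raw synthetic-accessibility estimate
#'
#' @param mol a [Molecule3D].
#' @return Raw score clipped to \[1, 10\]; higher = harder to make.
#' @export
computeSARaw <- function(mol) {
  if (!isValidMolecule(mol))
    stopf("molecule '%s' is not chemically interpretable", mol@name)
  g <- molGraph(mol, heavyOnly = TRUE)
  nHeavy <- igraph::vcount(g)
  rings <- ringCount(mol)
  # ring systems = connected components of the ring-atom subgraph
  inRing <- inRingAtoms(g)
  nSystems <- if (any(inRing)) {
    sub <- igraph::induced_subgraph(g, which(inRing))
    igraph::components(sub)$no
  } else 0L
  fused <- max(0L, rings - nSystems)
  # macrocycle: a ring system whose smallest cycle exceeds 8 atoms
  macro <- 0
  if (any(inRing)) {
    sub <- igraph::induced_subgraph(g, which(inRing))
    girth <- suppressWarnings(igraph::girth(sub)$girth)
    if (is.finite(girth) && girth > 8) macro <- 1
  }
  hetero <- mean(igraph::V(g)$element != "C")
  deg <- igraph::degree(g)
  ctx <- .atomContext(mol)
  heavyIdx <- igraph::V(g)$orig
  sp3 <- vapply(heavyIdx, function(i)
    ctx[[i]]$el == "C" && !ctx[[i]]$aromatic && ctx[[i]]$nDouble == 0 &&
      ctx[[i]]$nTriple == 0, logical(1))
  branch <- sum(deg >= 3 & sp3)
  # stereo-prone: sp3 carbons with 3+ distinct heavy neighbours
  stereo <- sum(deg >= 3 & sp3 & vapply(heavyIdx, function(i)
    length(unique(ctx[[i]]$nbEl)) >= 2, logical(1)))
  size <- 0.02 * max(0, nHeavy - 25)^1.2
  tiny <- if (nHeavy < 4) 0.8 else 0      # tiny fragments are not "1.0 easy"
  raw <- 1 + 0.35 * rings + 0.5 * fused + 1.0 * macro + 1.2 * hetero +
    0.2 * branch + 0.15 * stereo + size + tiny
  min(10, max(1, raw))
}

#' Normalized synthetic accessibility
#'
#' Maps the raw 1..10 scale to \[0, 1\] via `(10 - s) / 9`, so higher
#' values mean more synthesizable (raw 1 maps to 1, raw 10 maps to 0).
#'
#' @param mol a [Molecule3D].
#' @return Normalized SA in \[0, 1\].
#' @export
computeSANorm <- function(mol) {
  (10 - computeSARaw(mol)) / 9
}

#' Map a raw SA score to the normalized scale
#'
#' @param s raw score on the 1..10 scale.
#' @return `(10 - s) / 9`.
#' @export
saNormalize <- function(s) (10 - s) / 9
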