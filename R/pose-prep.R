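# Data preparation: heavy-atom cleaning, center-of-mass relocation of a
# generated ligand onto its docking pose, and adaptive arm/scaffold
# decomposition against the pocket.

#' Remove non-heavy atoms from a molecule
#'
#' Drops all hydrogens and their incident bonds; heavy-atom order is
#' preserved.
#'
#' @param mol a [Molecule3D].
#' @return A [Molecule3D] containing only heavy atoms.
#' @export
stripNonHeavy <- function(mol) {
  keep <- which(mol@elements != "H")
  if (length(keep) == 0)
    stopf("molecule '%s' has no heavy atoms", mol@name)
  map <- match(seq_along(mol@elements), keep)
  b <- mol@bonds
  if (nrow(b) > 0) {
    ok <- !is.na(map[b[, 1]]) & !is.na(map[b[, 2]])
    b <- b[ok, , drop = FALSE]
    if (nrow(b) > 0) b <- cbind(map[b[, 1]], map[b[, 2]], b[, 3])
  }
  Molecule3D(mol@elements[keep], mol@coords[keep, , drop = FALSE],
             bonds = if (nrow(b)) b else NULL,
             charges = mol@charges[keep], name = mol@name)
}

#' Center of mass of a molecule
#'
#' Mass-weighted mean of the atom coordinates using standard atomic
#' masses; an unweighted-centroid mode is available since "center of
#' mass" is used loosely in parts of the field.
#'
#' @param mol a [Molecule3D] with at least one atom.
#' @param weighted logical; `FALSE` gives the unweighted centroid.
#' @return Numeric 3-vector (Angstrom).
#' @export
centerOfMass <- function(mol, weighted = TRUE) {
  n <- length(mol@elements)
  if (n == 0) stopf("cannot take the center of mass of an empty molecule")
  w <- if (weighted) atomMasses(mol) else rep(1, n)
  unname(drop(crossprod(mol@coords, w)) / sum(w))
}

#' Relocate a ligand onto the center of mass of its docking pose
#'
#' The pose is heavy-atom-cleaned first; the ligand is then rigidly
#' translated so its center of mass coincides with the cleaned pose's
#' center of mass. Topology and all internal distances are unchanged.
#'
#' @param ligand a [Molecule3D].
#' @param pose the docking pose (or reference ligand) whose cleaned
#'   center of mass defines the target position.
#' @param weighted passed to [centerOfMass()].
#' @return The translated ligand.
#' @export
relocateToPose <- function(ligand, pose, weighted = TRUE) {
  poseClean <- stripNonHeavy(pose)
  shift <- centerOfMass(poseClean, weighted) -
    centerOfMass(ligand, weighted)
  out <- ligand
  out@coords <- sweep(ligand@coords, 2, -shift)
  out
}

#' Construct a DecomposedLigand
#'
#' @param ligand a [Molecule3D].
#' @param armAtomSets list of integer index vectors, one per arm.
#' @param scaffoldAtomSet integer index vector (possibly empty).
#' @return A validated [DecomposedLigand].
#' @export
decomposedLigand <- function(ligand, armAtomSets,
                             scaffoldAtomSet = integer(0)) {
  new("DecomposedLigand",
      armAtomSets = lapply(armAtomSets, function(x) sort(as.integer(x))),
      scaffoldAtomSet = sort(as.integer(scaffoldAtomSet)),
      ligand = ligand)
}

# cut the heavy-atom graph at acyclic single bonds that join ring systems
# or join a ring system to a chain of >= 2 atoms; returns a list of atom
# index sets (original molecule indices)
.cutFragments <- function(mol) {
  g <- molGraph(mol, heavyOnly = TRUE)
  nv <- igraph::vcount(g)
  orig <- igraph::V(g)$orig
  if (igraph::ecount(g) == 0)
    return(lapply(seq_len(nv), function(i) orig[i]))
  inRing <- inRingAtoms(g)
  bridges <- as.integer(igraph::bridges(g))
  cut <- integer(0)
  for (e in bridges) {
    if (igraph::E(g)$order[e] != 1L) next
    ends <- igraph::ends(g, e, names = FALSE)
    u <- ends[1]; v <- ends[2]
    if (inRing[u] && inRing[v]) { cut <- c(cut, e); next }
    if (!inRing[u] && !inRing[v]) next
    ringEnd <- if (inRing[u]) u else v
    chainEnd <- if (inRing[u]) v else u
    # size of the component on the chain side after removing the bond
    g2 <- igraph::delete_edges(g, e)
    comp <- igraph::components(g2)$membership
    if (sum(comp == comp[chainEnd]) >= 2) cut <- c(cut, e)
  }
  g2 <- igraph::delete_edges(g, cut)
  comp <- igraph::components(g2)$membership
  unname(split(orig[seq_len(nv)], comp))
}

#' Adaptive arm/scaffold decomposition of a ligand against a pocket
#'
#' Cuts the ligand graph at acyclic single bonds joining ring systems or
#' joining a ring system to a chain of at least two atoms. A fragment
#' becomes an arm when one of its atoms lies within `cutoff` Angstrom of
#' a pocket atom while also lying within `radius` Angstrom of the
#' fragment's own centroid. Remaining fragments form the (single)
#' scaffold set. If no fragment qualifies as an arm, both parameters are
#' relaxed by their step sizes and the proximity test is retried, at most
#' `maxRelaxations` times; if still no arm qualifies, the whole ligand
#' becomes a single arm with an empty scaffold.
#'
#' @param ligand a valid [Molecule3D], already positioned near the pocket
#'   (the caller's responsibility; see [relocateToPose()]).
#' @param pocket a [ProteinPocket].
#' @param params an [extractionParams()] list.
#' @return A [DecomposedLigand].
#' @export
adaptiveDecompose <- function(ligand, pocket,
                              params = extractionParams()) {
  if (length(ligand@elements) == 0 || !all(is.finite(ligand@coords)))
    stopf("invalid ligand for decomposition")
  frags <- .cutFragments(ligand)
  heavyCoords <- ligand@coords
  pocketCoords <- pocket@coords
  cutoff <- params$cutoff; radius <- params$radius
  for (attempt in 0:params$maxRelaxations) {
    armFlags <- vapply(frags, function(idx) {
      fc <- heavyCoords[idx, , drop = FALSE]
      centroid <- colMeans(fc)
      dPocket <- crossDist(fc, pocketCoords)
      dCentroid <- sqrt(rowSums(sweep(fc, 2, centroid)^2))
      any(apply(dPocket, 1, min) <= cutoff & dCentroid <= radius)
    }, logical(1))
    if (any(armFlags)) {
      arms <- frags[armFlags]
      scaffold <- sort(unlist(frags[!armFlags], use.names = FALSE))
      return(decomposedLigand(ligand, arms,
                              if (is.null(scaffold)) integer(0) else scaffold))
    }
    cutoff <- cutoff + params$cutoffStep
    radius <- radius + params$radiusStep
  }
  # relaxation exhausted: single arm covering the whole ligand
  decomposedLigand(ligand, list(seq_along(ligand@elements)), integer(0))
}
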