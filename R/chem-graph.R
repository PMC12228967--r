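# Molecular-graph utilities shared by validity filtering, descriptors and
# decomposition. All of them operate on the explicit heavy-atom graph;
# hydrogens present in a Molecule3D are handled explicitly, hydrogens not
# present are inferred from standard valences.

# standard atomic masses (u) for the elements in scope
.ATOMIC_MASS <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                  S = 32.06, P = 30.974, F = 18.998, Cl = 35.45,
                  Br = 79.904, I = 126.904, Se = 78.971, B = 10.81)

# allowed valence states per element (smallest compatible state is used
# when inferring implicit hydrogens)
.VALENCES <- list(H = 1, C = 4, N = 3, O = 2, S = c(2, 4, 6),
                  P = c(3, 5), F = 1, Cl = 1, Br = 1, I = 1, Se = c(2, 4, 6),
                  B = 3)

#' Atomic masses of a molecule's atoms
#' @param mol a [Molecule3D].
#' @return Numeric vector of standard atomic masses (u).
#' @keywords internal
atomMasses <- function(mol) {
  m <- .ATOMIC_MASS[mol@elements]
  if (any(is.na(m)))
    stopf("unknown element(s): %s",
          paste(unique(mol@elements[is.na(m)]), collapse = ", "))
  unname(m)
}

# igraph representation; vertices carry element, edges carry order code
molGraph <- function(mol, heavyOnly = FALSE) {
  keep <- if (heavyOnly) which(mol@elements != "H") else
    seq_along(mol@elements)
  map <- match(seq_along(mol@elements), keep)
  b <- mol@bonds
  if (nrow(b) > 0) {
    ok <- !is.na(map[b[, 1]]) & !is.na(map[b[, 2]])
    b <- b[ok, , drop = FALSE]
  }
  g <- igraph::make_empty_graph(n = length(keep), directed = FALSE)
  if (nrow(b) > 0)
    g <- igraph::add_edges(g, rbind(map[b[, 1]], map[b[, 2]]))
  igraph::V(g)$element <- mol@elements[keep]
  igraph::V(g)$orig <- keep
  if (nrow(b) > 0) igraph::E(g)$order <- b[, 3] else
    g <- igraph::set_edge_attr(g, "order", value = integer(0))
  g
}

# per-atom sum of explicit bond orders. Aromatic bonds count 1.5 at C/N,
# 1.0 at O/S/Se (two-electron donors in aromatic rings), and 1.0 at any
# atom that also carries an exocyclic double/triple bond (Kekule
# convention for ring atoms like the carbonyl carbons of purinones).
bondOrderSums <- function(mol) {
  n <- length(mol@elements)
  s <- numeric(n)
  b <- mol@bonds
  if (nrow(b) == 0) return(s)
  lonePair <- c("O", "S", "Se")
  hasMultiple <- logical(n)
  multi <- b[b[, 3] %in% c(2L, 3L), 1:2, drop = FALSE]
  hasMultiple[unique(as.vector(multi))] <- TRUE
  nArom <- integer(n); nOther <- integer(n)
  arom <- b[b[, 3] == 4L, 1:2, drop = FALSE]
  for (a in as.vector(arom)) nArom[a] <- nArom[a] + 1L
  for (a in as.vector(b[b[, 3] != 4L, 1:2, drop = FALSE]))
    nOther[a] <- nOther[a] + 1L
  for (r in seq_len(nrow(b))) {
    ord <- b[r, 3]
    if (ord != 4L) {
      s[b[r, 1]] <- s[b[r, 1]] + ord
      s[b[r, 2]] <- s[b[r, 2]] + ord
    }
  }
  for (a in seq_len(n)) {
    if (nArom[a] == 0L) next
    el <- mol@elements[a]
    w <- if (el %in% lonePair || hasMultiple[a]) {
      # lone-pair donors and ring atoms with exocyclic multiple bonds:
      # Kekule-style single contributions
      nArom[a]
    } else if (el == "N" && nArom[a] + nOther[a] >= 3) {
      # three-connected aromatic N is pyrrole-type
      nArom[a]
    } else {
      # first two aromatic bonds 1.5 each, ring-fusion extras 1.0
      1.5 * min(nArom[a], 2L) + max(0L, nArom[a] - 2L)
    }
    s[a] <- s[a] + w
  }
  s
}

# implicit hydrogen count per atom; NA when no valence state can
# accommodate the explicit bonds
implicitHCounts <- function(mol) {
  sums <- bondOrderSums(mol)
  vapply(seq_along(mol@elements), function(i) {
    el <- mol@elements[i]
    states <- .VALENCES[[el]]
    if (is.null(states)) return(NA_real_)
    need <- ceiling(sums[i] - 1e-9)
    ok <- states[states >= need]
    if (length(ok) == 0) return(NA_real_)
    # aromatic atoms with x.5 order sums round down to the nearest integer
    max(0, floor(ok[1] - sums[i] + 1e-9))
  }, numeric(1))
}

#' Check chemical validity of a molecule
#'
#' A molecule is considered valid when it has at least two heavy atoms,
#' its full atom graph is connected, every explicit hydrogen has exactly
#' one single bond, and every atom's explicit bond orders fit one of its
#' element's valence states (aromatic bonds counting 1.5).
#'
#' @param mol a [Molecule3D].
#' @return Logical scalar.
#' @export
isValidMolecule <- function(mol) {
  n <- length(mol@elements)
  heavy <- which(mol@elements != "H")
  if (length(heavy) < 2) return(FALSE)
  if (!all(mol@elements %in% names(.VALENCES))) return(FALSE)
  g <- molGraph(mol)
  if (igraph::components(g)$no != 1) return(FALSE)
  # explicit hydrogens: exactly one single bond
  b <- mol@bonds
  if (nrow(b) > 0) {
    hIdx <- which(mol@elements == "H")
    if (length(hIdx) > 0) {
      deg <- igraph::degree(g)
      if (any(deg[hIdx] != 1)) return(FALSE)
      hb <- b[b[, 1] %in% hIdx | b[, 2] %in% hIdx, , drop = FALSE]
      if (nrow(hb) > 0 && any(hb[, 3] != 1L)) return(FALSE)
    }
  }
  !anyNA(implicitHCounts(mol))
}

# logical per-atom flag: lies on at least one cycle
inRingAtoms <- function(g) {
  flags <- logical(igraph::vcount(g))
  if (igraph::ecount(g) == 0) return(flags)
  br <- igraph::bridges(g)
  cyc <- igraph::E(g)[setdiff(seq_len(igraph::ecount(g)), as.integer(br))]
  if (length(cyc) > 0) {
    ends <- igraph::ends(g, cyc, names = FALSE)
    flags[unique(as.vector(ends))] <- TRUE
  }
  flags
}

# number of rings (circuit rank) in the subgraph of aromatic bonds
aromaticRingCount <- function(mol) {
  b <- mol@bonds
  arom <- b[b[, 3] == 4L, , drop = FALSE]
  if (nrow(arom) == 0) return(0L)
  verts <- sort(unique(as.vector(arom[, 1:2])))
  g <- igraph::graph_from_edgelist(
    cbind(match(arom[, 1], verts), match(arom[, 2], verts)),
    directed = FALSE)
  comp <- igraph::components(g)$no
  as.integer(nrow(arom) - length(verts) + comp)
}

# total circuit rank of the heavy-atom graph
ringCount <- function(mol) {
  g <- molGraph(mol, heavyOnly = TRUE)
  igraph::ecount(g) - igraph::vcount(g) + igraph::components(g)$no
}

# rotatable bonds: acyclic single bonds between heavy atoms that each have
# at least two heavy neighbours (basic definition, no amide exclusion)
rotatableBondCount <- function(mol) {
  g <- molGraph(mol, heavyOnly = TRUE)
  if (igraph::ecount(g) == 0) return(0L)
  deg <- igraph::degree(g)
  br <- as.integer(igraph::bridges(g))
  count <- 0L
  for (e in br) {
    if (igraph::E(g)$order[e] != 1L) next
    ends <- igraph::ends(g, e, names = FALSE)
    if (deg[ends[1]] >= 2 && deg[ends[2]] >= 2) count <- count + 1L
  }
  count
}

# neighbours (original atom indices) of atom i in the full graph
atomNeighbors <- function(mol, i) {
  b <- mol@bonds
  if (nrow(b) == 0) return(integer(0))
  c(b[b[, 1] == i, 2], b[b[, 2] == i, 1])
}
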