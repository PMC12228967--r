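# Physicochemical descriptors computed natively on the molecular graph.
# Hydrogens may be explicit or implicit; implicit counts are inferred from
# standard valences (see chem-graph.R).

# per-atom context used by several classifiers
.atomContext <- function(mol) {
  n <- length(mol@elements)
  b <- mol@bonds
  ctx <- vector("list", n)
  implicitH <- implicitHCounts(mol)
  for (i in seq_len(n)) {
    nb <- integer(0); ord <- integer(0)
    if (nrow(b) > 0) {
      sel1 <- b[, 1] == i; sel2 <- b[, 2] == i
      nb <- c(b[sel1, 2], b[sel2, 1])
      ord <- c(b[sel1, 3], b[sel2, 3])
    }
    nbEl <- mol@elements[nb]
    heavy <- nbEl != "H"
    ctx[[i]] <- list(
      el = mol@elements[i],
      nb = nb[heavy], nbEl = nbEl[heavy], ord = ord[heavy],
      nH = sum(!heavy) + (if (is.na(implicitH[i])) 0 else implicitH[i]),
      aromatic = any(ord == 4L),
      nSingle = sum(ord == 1L & heavy), nDouble = sum(ord == 2L & heavy),
      nTriple = sum(ord == 3L & heavy), nArom = sum(ord == 4L & heavy))
  }
  ctx
}

#' Molecular weight
#'
#' Standard atomic masses; implicit hydrogens (inferred from valences)
#' are included.
#'
#' @param mol a [Molecule3D].
#' @return Molecular weight in u.
#' @export
molecularWeight <- function(mol) {
  hs <- implicitHCounts(mol)
  hs[is.na(hs)] <- 0
  sum(atomMasses(mol)) + sum(hs) * .ATOMIC_MASS[["H"]]
}

#' Hydrogen-bond acceptor count
#'
#' Lipinski-style count: number of nitrogen and oxygen atoms.
#'
#' @param mol a [Molecule3D].
#' @return Integer count.
#' @export
countHBA <- function(mol) sum(mol@elements %in% c("N", "O"))

#' Hydrogen-bond donor count
#'
#' Number of hydrogens (explicit plus implicit) attached to nitrogen or
#' oxygen.
#'
#' @param mol a [Molecule3D].
#' @return Integer count.
#' @export
countHBD <- function(mol) {
  ctx <- .atomContext(mol)
  sum(vapply(ctx, function(a)
    if (a$el %in% c("N", "O")) a$nH else 0, numeric(1)))
}

# topological polar surface area, Ertl fragment contributions for neutral
# N and O environments (the common subset; S and P do not contribute, as
# in the standard TPSA definition)
#' Topological polar surface area
#' @param mol a [Molecule3D].
#' @return TPSA in Angstrom squared.
#' @export
tpsa <- function(mol) {
  ctx <- .atomContext(mol)
  contrib <- vapply(ctx, function(a) {
    if (a$el == "N") {
      if (a$aromatic) {
        if (a$nH >= 1) return(15.79)
        if (a$nArom >= 3) return(4.41)
        if (a$nDouble >= 1) return(8.39)
        if (a$nSingle >= 1) return(4.93)
        return(12.89)
      }
      if (a$nH >= 2) return(26.02)
      if (a$nH == 1) {
        if (a$nDouble >= 1) return(23.85)
        return(12.03)
      }
      if (a$nTriple >= 1) return(23.79)
      if (a$nDouble >= 2) return(11.68)
      if (a$nDouble == 1) return(12.36)
      return(3.24)
    }
    if (a$el == "O") {
      if (a$aromatic) return(13.14)
      if (a$nH >= 1) return(20.23)
      if (a$nDouble >= 1) return(17.07)
      return(9.23)
    }
    0
  }, numeric(1))
  sum(contrib)
}

# --- Wildman-Crippen logP (subset for H, C, N, O, S, F, Cl, Br, I) ---------

.CRIPPEN <- c(C1 = 0.1441, C2 = 0, C3 = -0.2035, C4 = -0.2051,
              C5 = -0.2783, C6 = 0.1551, C7 = 0.0017, C8 = 0.08452,
              C9 = -0.1444, C10 = -0.0516, C11 = 0.1193, C12 = -0.0967,
              C13 = -0.5443, C14 = 0, C15 = 0.245, C18 = 0.1581,
              C19 = 0.2955, C20 = 0.2713, C21 = 0.136, C22 = 0.4619,
              C23 = 0.5437, C24 = 0.1893, C25 = -0.8186, C26 = 0.264,
              CS = 0.08129,
              H1 = 0.123, H2 = -0.2677, H3 = 0.2142, H4 = 0.298,
              HS = 0.1125,
              N1 = -1.019, N2 = -0.7096, N3 = -1.027, N4 = -0.5188,
              N5 = 0.08387, N6 = 0.1836, N7 = -0.3187, N8 = -0.4458,
              N9 = 0.01508, N11 = -0.3239, NS = -0.4806,
              O1 = 0.1552, O2 = -0.2893, O3 = -0.0684, O4 = -0.4195,
              O5 = 0.0335, O8 = 0.1788, O9 = -0.1526, O10 = 0.1129,
              O11 = 0.4833, OS = -0.1188,
              S1 = 0.6482, S2 = -0.0024, S3 = 0.6237,
              F = 0.4202, Cl = 0.6895, Br = 0.8456, I = 0.8857)

.HETERO <- c("N", "O", "S", "P", "F", "Cl", "Br", "I", "Se")

# classify one carbon atom into a Wildman-Crippen type
.crippenC <- function(a, ctx) {
  aromNb <- vapply(a$nb, function(j) ctx[[j]]$aromatic, logical(1))
  if (a$aromatic) {
    if (a$nDouble >= 1 && any(a$nbEl[a$ord == 2L] %in% c("C", "N", "O")))
      return("C25")
    if (a$nH >= 1) return("C18")
    if (a$nArom >= 3) return("C19")
    sub <- which(a$ord != 4L)
    if (length(sub) == 0) return("C18")
    j <- sub[1]
    if (aromNb[j]) return("C20")
    switch(a$nbEl[j], C = "C21", N = "C22", O = "C23", S = "C24",
           F = "C14", Cl = "C15", "C13")
  } else if (a$nTriple >= 1) {
    "C7"
  } else if (a$nDouble >= 1) {
    dblTo <- a$nbEl[a$ord == 2L]
    if (any(dblTo %in% .HETERO)) return("C5")
    if (any(aromNb)) return("C26")
    "C6"
  } else {
    hasHet <- any(a$nbEl %in% .HETERO)
    if (hasHet) return(if (a$nH >= 2) "C3" else "C4")
    if (any(aromNb)) {
      return(switch(as.character(min(a$nH, 3)),
                    `3` = if (all(a$nbEl[aromNb] == "C")) "C8" else "C9",
                    `2` = "C10", `1` = "C11", `0` = "C12"))
    }
    if (a$nH >= 2) "C1" else "C2"
  }
}

.crippenN <- function(a, ctx) {
  aromNb <- vapply(a$nb, function(j) ctx[[j]]$aromatic, logical(1))
  if (a$aromatic) return("N11")
  if (a$nH >= 2) return(if (any(aromNb)) "N3" else "N1")
  if (a$nH == 1) {
    if (a$nDouble >= 1) return("N5")
    if (any(aromNb)) return("N4")
    return("N2")
  }
  if (a$nTriple >= 1) return("N9")
  if (a$nDouble == 1 && a$nSingle >= 1) return("N6")
  if (a$nDouble >= 2) return("NS")
  if (any(aromNb)) return("N8")
  if (a$nSingle >= 3) return("N7")
  "NS"
}

.crippenO <- function(a, ctx) {
  if (a$aromatic) return("O1")
  if (a$nH >= 1) return("O2")
  if (a$nDouble >= 1) {
    j <- a$nb[a$ord == 2L][1]
    ca <- ctx[[j]]
    if (ca$el %in% c("N", "O")) return("O5")
    if (ca$el != "C") return("OS")
    if (ca$aromatic) return("O8")
    # classify via the carbonyl carbon's other heavy neighbours
    # (nbEl includes this oxygen itself, hence the -1)
    nbHet <- sum(ca$nbEl %in% .HETERO) - 1L
    if (nbHet >= 2) return("O11")
    aromC <- any(vapply(ca$nb, function(k) ctx[[k]]$aromatic, logical(1)))
    if (aromC) return("O10")
    return("O9")
  }
  if (a$nSingle >= 2) {
    aromNb <- vapply(a$nb, function(j) ctx[[j]]$aromatic, logical(1))
    return(if (any(aromNb)) "O4" else "O3")
  }
  "OS"
}

# contribution of one (explicit or implicit) hydrogen attached to atom i
.crippenH <- function(i, ctx) {
  a <- ctx[[i]]
  if (a$el %in% c("C")) return("H1")
  if (a$el == "N") return("H3")
  if (a$el == "O") {
    for (j in a$nb) {
      nb <- ctx[[j]]
      if (nb$el == "N") return("H3")
      if (nb$el %in% c("O", "S")) return("H4")
      if (nb$el == "C" && nb$nDouble >= 1 &&
          any(nb$nbEl[nb$ord == 2L] %in% c("C", "N", "O", "S")))
        return("H4")
    }
    return("H2")
  }
  if (a$el == "S") return("H2")
  "HS"
}

#' Wildman-Crippen octanol/water logP
#'
#' Atom-contribution logP with the published contribution values for the
#' H/C/N/O/S/halogen environments in scope (a faithful subset of the full
#' published typing; uncommon environments fall back to the per-element
#' defaults).
#'
#' @param mol a [Molecule3D].
#' @return Estimated logP.
#' @export
crippenLogP <- function(mol) {
  ctx <- .atomContext(mol)
  total <- 0
  for (i in seq_along(ctx)) {
    a <- ctx[[i]]
    type <- switch(a$el,
      C = .crippenC(a, ctx),
      N = .crippenN(a, ctx),
      O = .crippenO(a, ctx),
      S = if (a$aromatic) "S3" else if (any(a$nbEl %in% c("N", "O")) &&
                                        a$nDouble >= 1) "S2" else "S1",
      H = .crippenH(if (length(a$nb)) a$nb[1] else i, ctx),
      F = "F", Cl = "Cl", Br = "Br", I = "I",
      NULL)
    if (!is.null(type)) total <- total + .CRIPPEN[[type]]
    if (a$el != "H" && a$nH > 0) {
      # implicit hydrogens (explicit ones are their own atoms)
      nExplicitH <- sum(mol@elements[atomNeighbors(mol, i)] == "H")
      nImp <- a$nH - nExplicitH
      if (nImp > 0) total <- total + nImp * .CRIPPEN[[.crippenH(i, ctx)]]
    }
  }
  unname(total)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- structural alerts ------------------------------------------------------

#' Structural alert count
#'
#' A reduced, graph-expressible set of the common "unwanted functionality"
#' alerts: heteroatom-heteroatom single bonds (O-O, N-N, S-S), aldehydes,
#' thiols, acyl halides, nitro-like nitrogens, three-membered
#' heterocycles, Michael-acceptor enones and aryl esters.
#'
#' @param mol a [Molecule3D].
#' @return Integer number of alerts triggered.
#' @export
countAlerts <- function(mol) {
  ctx <- .atomContext(mol)
  b <- mol@bonds
  alerts <- 0L
  el <- mol@elements
  # heteroatom-heteroatom single bonds
  if (nrow(b) > 0) {
    for (pair in list(c("O", "O"), c("N", "N"), c("S", "S"))) {
      hit <- b[, 3] == 1L &
        ((el[b[, 1]] == pair[1] & el[b[, 2]] == pair[2]) |
         (el[b[, 1]] == pair[2] & el[b[, 2]] == pair[1]))
      if (any(hit)) alerts <- alerts + sum(hit)
    }
  }
  for (i in seq_along(ctx)) {
    a <- ctx[[i]]
    if (a$el == "C" && !a$aromatic && a$nDouble >= 1 &&
        any(a$nbEl[a$ord == 2L] == "O")) {
      if (a$nH >= 1) alerts <- alerts + 1L                    # aldehyde
      if (any(a$nbEl %in% c("F", "Cl", "Br", "I")))
        alerts <- alerts + 1L                                 # acyl halide
      # aryl ester: carbonyl C - O - aromatic c
      for (j in a$nb[a$nbEl == "O" & a$ord == 1L]) {
        oNb <- ctx[[j]]
        if (any(vapply(oNb$nb, function(k) ctx[[k]]$aromatic, logical(1))))
          alerts <- alerts + 1L
      }
      # enone: C=C conjugated to C=O
      for (j in a$nb[a$nbEl == "C" & a$ord == 1L]) {
        if (ctx[[j]]$nDouble >= 1 && any(ctx[[j]]$nbEl[ctx[[j]]$ord == 2L] == "C"))
          alerts <- alerts + 1L
      }
    }
    if (a$el == "S" && !a$aromatic && a$nH >= 1) alerts <- alerts + 1L
    if (a$el == "N" && sum(a$nbEl == "O") >= 2) alerts <- alerts + 1L
  }
  # three-membered rings containing a heteroatom
  g <- molGraph(mol, heavyOnly = TRUE)
  if (igraph::vcount(g) >= 3 && igraph::ecount(g) >= 3) {
    tri <- igraph::triangles(g)
    if (length(tri) > 0) {
      tri <- matrix(as.integer(tri), ncol = 3, byrow = TRUE)
      elsHeavy <- igraph::V(g)$element
      alerts <- alerts + sum(apply(tri, 1, function(v)
        any(elsHeavy[v] %in% c("N", "O", "S"))))
    }
  }
  alerts
}
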