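#' Number of atoms
#'
#' @param x a [Molecule3D] or [ProteinPocket] object.
#' @return Integer atom count.
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))

#' Element symbols of the atoms
#'
#' @param x a [Molecule3D] or [ProteinPocket] object.
#' @return Character vector of element symbols, one per atom.
#' @export
setGeneric("atomElements", function(x) standardGeneric("atomElements"))

#' Atom coordinates in Angstrom
#'
#' @param x a [Molecule3D] or [ProteinPocket] object.
#' @return Numeric matrix with one row per atom and columns x, y, z.
#' @export
setGeneric("atomCoords", function(x) standardGeneric("atomCoords"))

#' Replace atom coordinates
#'
#' @param x a [Molecule3D] or [ProteinPocket] object.
#' @param value numeric n x 3 matrix of coordinates in Angstrom.
#' @return The object with updated coordinates.
#' @export
setGeneric("atomCoords<-", function(x, value) standardGeneric("atomCoords<-"))

#' Bond table of a molecule
#'
#' @param x a [Molecule3D] object.
#' @return Data frame with columns `i`, `j` (1-based atom indices) and
#'   `order` (one of `"single"`, `"double"`, `"triple"`, `"aromatic"`).
#' @export
setGeneric("bondTable", function(x) standardGeneric("bondTable"))

#' Name of a molecule or pocket
#'
#' @param x a [Molecule3D] or [ProteinPocket] object.
#' @return Character identifier.
#' @export
setGeneric("molName", function(x) standardGeneric("molName"))

#' Reward value of a scored candidate
#'
#' @param x a [RewardVector] object.
#' @return Numeric scalar reward.
#' @export
setGeneric("rewardValue", function(x) standardGeneric("rewardValue"))
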