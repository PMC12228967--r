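# Quantitative estimate of drug-likeness: the weighted geometric mean of
# eight asymmetric-double-sigmoid desirability functions, with the
# published fitted parameters and mean-optimal weights.

# ADS parameters (A, B, C, D, E, F, DMAX) per descriptor
.QED_ADS <- list(
  MW     = c(2.817065973, 392.5754953, 290.7489764, 2.419764353,
             49.22325677, 65.37051707, 104.9805561),
  ALOGP  = c(3.172690585, 137.8624751, 2.534937431, 4.581497897,
             0.822739154, 0.576295591, 131.3186604),
  HBA    = c(2.948620388, 160.4605972, 3.615294657, 4.435986202,
             0.290141953, 1.300669958, 148.7763046),
  HBD    = c(1.618662227, 1010.051101, 0.985094388, 0.000000001,
             0.713820843, 0.920922555, 258.1632616),
  PSA    = c(1.876861559, 125.2232657, 62.90773554, 87.83366614,
             12.01999824, 28.51324732, 104.5686167),
  ROTB   = c(0.010000000, 272.4121427, 2.558379970, 1.565547684,
             1.271567166, 2.758063707, 105.4420403),
  AROM   = c(3.217788970, 957.7374108, 2.274627939, 0.000000001,
             1.317690384, 0.375760881, 312.3372610),
  ALERTS = c(0.010000000, 1199.094025, -0.09002883, 0.000000001,
             0.185904477, 0.875193782, 417.7253140))

# mean-optimal weights of the original publication
.QED_WEIGHTS <- c(MW = 0.66, ALOGP = 0.46, HBA = 0.05, HBD = 0.61,
                  PSA = 0.06, ROTB = 0.65, AROM = 0.48, ALERTS = 0.95)

#' Asymmetric double sigmoid desirability
#'
#' The desirability function underlying QED, evaluated with the published
#' parameter set for one descriptor.
#'
#' @param x descriptor value.
#' @param descriptor one of `"MW"`, `"ALOGP"`, `"HBA"`, `"HBD"`, `"PSA"`,
#'   `"ROTB"`, `"AROM"`, `"ALERTS"`.
#' @return Desirability in (0, 1\].
#' @export
qedADS <- function(x, descriptor) {
  p <- .QED_ADS[[descriptor]]
  if (is.null(p)) stopf("unknown QED descriptor: %s", descriptor)
  a <- p[1]; b <- p[2]; cc <- p[3]; d <- p[4]; e <- p[5]; f <- p[6]
  dmax <- p[7]
  e1 <- 1 + exp(-(x - cc + d / 2) / e)
  e2 <- 1 + exp(-(x - cc - d / 2) / f)
  (a + b / e1 * (1 - 1 / e2)) / dmax
}

#' QED from a descriptor vector
#'
#' Weighted geometric mean of the eight desirabilities; useful when the
#' descriptors are supplied externally.
#'
#' @param mw molecular weight (u).
#' @param alogp octanol/water logP.
#' @param hba,hbd hydrogen-bond acceptor/donor counts.
#' @param psa topological polar surface area (Angstrom squared).
#' @param rotb rotatable bond count.
#' @param arom aromatic ring count.
#' @param alerts structural alert count.
#' @return QED value in (0, 1).
#' @export
qedFromDescriptors <- function(mw, alogp, hba, hbd, psa, rotb, arom,
                               alerts) {
  x <- c(MW = mw, ALOGP = alogp, HBA = hba, HBD = hbd, PSA = psa,
         ROTB = rotb, AROM = arom, ALERTS = alerts)
  d <- vapply(names(x), function(nm) qedADS(x[[nm]], nm), numeric(1))
  exp(sum(.QED_WEIGHTS * log(d)) / sum(.QED_WEIGHTS))
}

#' QED descriptor vector of a molecule
#'
#' @param mol a [Molecule3D].
#' @return Named list with elements MW, ALOGP, HBA, HBD, PSA, ROTB, AROM,
#'   ALERTS.
#' @export
qedProperties <- function(mol) {
  list(MW = molecularWeight(mol), ALOGP = crippenLogP(mol),
       HBA = countHBA(mol), HBD = countHBD(mol), PSA = tpsa(mol),
       ROTB = rotatableBondCount(mol), AROM = aromaticRingCount(mol),
       ALERTS = countAlerts(mol))
}

#' Drug-likeness (QED) of a molecule
#'
#' Computes the eight descriptors on the molecular graph and combines
#' them with the published desirability functions and weights. The value
#' is already in \[0, 1\]; higher is more drug-like.
#'
#' @param mol a [Molecule3D].
#' @return QED in (0, 1).
#' @examples
#' ring <- Molecule3D(rep("C", 6),
#'   cbind(1.39 * cos(seq(0, 5) * pi / 3), 1.39 * sin(seq(0, 5) * pi / 3), 0),
#'   bonds = cbind(1:6, c(2:6, 1), 4), name = "benzene")
#' computeQED(ring)
#' @export
computeQED <- function(mol) {
  if (!isValidMolecule(mol))
    stopf("molecule '%s' is not chemically interpretable", mol@name)
  p <- qedProperties(mol)
  qedFromDescriptors(p$MW, p$ALOGP, p$HBA, p$HBD, p$PSA, p$ROTB, p$AROM,
                     p$ALERTS)
}
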