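# Evaluation metrics: summary statistics with success rate, the
# accumulated score, and the bond-distance Jensen-Shannon divergence.

#' Accumulated score
#'
#' Equal-weight summation of the three core metrics with the docking
#' score normalized by dividing by -10 so it lands in \[0, 1\] for
#' typical affinities: `qed + sa + vina / (-10)`. Rounding happens only
#' at presentation (3 decimals conventionally).
#'
#' @param qedMean mean (or median) QED.
#' @param saMean mean (or median) normalized SA.
#' @param vinaMean mean (or median) docking score.
#' @return Numeric accumulated score (unrounded).
#' @examples
#' round(accumulatedScore(0.494, 0.653, -7.018), 3)  # 1.849
#' @export
accumulatedScore <- function(qedMean, saMean, vinaMean) {
  stopifnot(is.finite(qedMean), is.finite(saMean), is.finite(vinaMean))
  qedMean + saMean + vinaMean / (-10)
}

#' Summarize evaluation records
#'
#' Means and medians per metric plus the success rate. The success-rate
#' denominator is the number of evaluated (valid) molecules; the raw
#' generation count, when known, travels alongside as `nGenerated`.
#'
#' @param records data frame with columns `qed`, `saNorm`, `vina`
#'   (docking score used for the success threshold) and optionally
#'   `vinaMin`, `vinaDock`.
#' @param nGenerated optional raw generation count before validity
#'   filtering.
#' @return List of class `"MetricSummary"`: per-metric `mean` and
#'   `median` vectors, `successRate`, `nMolecules`, `nGenerated`,
#'   `accumulated` (from the means).
#' @export
summarizeMetrics <- function(records, nGenerated = NA_integer_) {
  records <- as.data.frame(records)
  if (nrow(records) == 0) stopf("cannot summarize zero records")
  needed <- c("qed", "saNorm", "vina")
  if (!all(needed %in% names(records)))
    stopf("records need columns: %s", paste(needed, collapse = ", "))
  metrics <- intersect(c("vina", "vinaMin", "vinaDock", "qed", "saNorm"),
                       names(records))
  means <- vapply(metrics, function(m) mean(records[[m]]), numeric(1))
  medians <- vapply(metrics, function(m) stats::median(records[[m]]),
                    numeric(1))
  flags <- mapply(successFlag, records$qed, records$saNorm, records$vina)
  structure(list(
    mean = means, median = medians,
    successRate = mean(flags),
    nMolecules = nrow(records), nGenerated = nGenerated,
    accumulated = accumulatedScore(means[["qed"]], means[["saNorm"]],
                                   means[["vina"]])),
    class = "MetricSummary")
}

#' @export
print.MetricSummary <- function(x, ...) {
  cat("MetricSummary over", x$nMolecules, "molecules\n")
  tab <- rbind(mean = x$mean, median = x$median)
  print(round(tab, 3))
  cat(sprintf("success rate: %.1f%%   accumulated: %.3f\n",
              100 * x$successRate, x$accumulated))
  invisible(x)
}

# collect lengths of bonds matching (element pair, order) in a molecule
.matchingBondLengths <- function(mol, el1, el2, order) {
  b <- mol@bonds
  if (nrow(b) == 0) return(numeric(0))
  ordCode <- match(order, BOND_ORDERS)
  e1 <- mol@elements[b[, 1]]; e2 <- mol@elements[b[, 2]]
  hit <- b[, 3] == ordCode &
    ((e1 == el1 & e2 == el2) | (e1 == el2 & e2 == el1))
  if (!any(hit)) return(numeric(0))
  d <- mol@coords[b[hit, 1], , drop = FALSE] -
       mol@coords[b[hit, 2], , drop = FALSE]
  sqrt(rowSums(d^2))
}

# fixed-bin histogram of bond lengths, out-of-range clipped to edge bins
.bondHist <- function(lengths, breaks) {
  lengths <- pmin(pmax(lengths, breaks[1] + 1e-12),
                  breaks[length(breaks)] - 1e-12)
  h <- graphics::hist(lengths, breaks = breaks, plot = FALSE)
  h$counts / sum(h$counts)
}

#' Jensen-Shannon divergence of two histograms
#'
#' Base-2 logarithms, so the value lies in \[0, 1\]; `0 log 0 := 0`.
#'
#' @param p,q probability vectors of equal length.
#' @return JSD in \[0, 1\].
#' @export
jsDivergence <- function(p, q) {
  stopifnot(length(p) == length(q))
  m <- (p + q) / 2
  kl <- function(a, b) {
    t <- a * (log2(a) - log2(b))
    sum(t[a > 0])
  }
  (kl(p, m) + kl(q, m)) / 2
}

#' Bond-distance Jensen-Shannon divergence
#'
#' Collects the Euclidean lengths of all bonds matching the query
#' (element pair unordered, one bond category) in a generated and a
#' reference molecule set, histograms both on fixed bins, and returns
#' the base-2 Jensen-Shannon divergence of the two distributions.
#'
#' @param generated,reference non-empty lists of [Molecule3D].
#' @param bondQuery length-3 character vector
#'   `c(element1, element2, order)`, e.g. `c("C", "C", "single")` or
#'   `c("C", "N", "aromatic")`.
#' @param breaks histogram bin edges in Angstrom; default fixed 0.02
#'   Angstrom bins over \[0.8, 3.0\], with out-of-range lengths clipped
#'   to the edge bins.
#' @return JSD in \[0, 1\] (0 when the binned histograms coincide).
#' @export
bondDistanceJSD <- function(generated, reference, bondQuery,
                            breaks = seq(0.8, 3.0, by = 0.02)) {
  stopifnot(length(bondQuery) == 3)
  if (length(generated) == 0 || length(reference) == 0)
    stopf("both molecule sets must be non-empty")
  if (!(bondQuery[3] %in% BOND_ORDERS))
    stopf("unknown bond category '%s'", bondQuery[3])
  collect <- function(mols) unlist(lapply(mols, .matchingBondLengths,
                                          el1 = bondQuery[1],
                                          el2 = bondQuery[2],
                                          order = bondQuery[3]))
  lg <- collect(generated)
  lr <- collect(reference)
  if (length(lg) == 0)
    stopf("no %s-%s %s bonds in the generated set", bondQuery[1],
          bondQuery[2], bondQuery[3])
  if (length(lr) == 0)
    stopf("no %s-%s %s bonds in the reference set", bondQuery[1],
          bondQuery[2], bondQuery[3])
  jsDivergence(.bondHist(lg, breaks), .bondHist(lr, breaks))
}

#' Bond-distance JSD table for several bond types
#'
#' @param generated,reference lists of [Molecule3D].
#' @param queries list of length-3 character vectors as in
#'   [bondDistanceJSD()]; defaults to the common organic bond types.
#' @param breaks histogram bin edges.
#' @return Data frame with columns `bond` and `jsd` (NA when a bond type
#'   is absent from either set).
#' @export
bondJSDTable <- function(generated, reference, queries = NULL,
                         breaks = seq(0.8, 3.0, by = 0.02)) {
  if (is.null(queries)) {
    queries <- list(c("C", "C", "single"), c("C", "C", "double"),
                    c("C", "N", "single"), c("C", "N", "double"),
                    c("C", "O", "single"), c("C", "O", "double"),
                    c("C", "C", "aromatic"), c("C", "N", "aromatic"))
  }
  sym <- c(single = "-", double = "=", triple = "#", aromatic = ":")
  rows <- lapply(queries, function(qr) {
    val <- tryCatch(bondDistanceJSD(generated, reference, qr, breaks),
                    error = function(e) NA_real_)
    data.frame(bond = paste0(qr[1], sym[[qr[3]]], qr[2]), jsd = val)
  })
  do.call(rbind, rows)
}
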