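# Readers and writers for the two formats the toolkit touches: SDF (V2000)
# for ligands and docking poses, PDB (ATOM/HETATM) for protein pockets.
# Parsing itself is delegated to ChemmineR and bio3d; this layer converts
# to and from the in-memory S4 types (0-/1-based index conversion happens
# inside those packages).

# charge code column of a V2000 atom block -> formal charge
.SDF_CHARGE <- c(`0` = 0L, `1` = 3L, `2` = 2L, `3` = 1L, `4` = 0L,
                 `5` = -1L, `6` = -2L, `7` = -3L)

.sdfToMolecule <- function(sdf, id, index) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  n <- nrow(ab)
  if (is.null(n) || n == 0) stopf("record %d: empty atom block", index)
  elements <- sub("_.*$", "", rownames(ab))
  coords <- unname(ab[, 1:3, drop = FALSE])
  charges <- integer(n)
  if ("C5" %in% colnames(ab)) {
    code <- as.character(ab[, "C5"])
    known <- code %in% names(.SDF_CHARGE)
    charges[known] <- .SDF_CHARGE[code[known]]
  }
  bonds <- NULL
  if (!is.null(bb) && nrow(bb) > 0) {
    bi <- as.integer(bb[, 1]); bj <- as.integer(bb[, 2])
    bo <- as.integer(bb[, 3])
    if (any(bi < 1) || any(bj < 1) || any(bi > n) || any(bj > n))
      stopf("record %d: bond block references atom outside 1..%d", index, n)
    if (any(!(bo %in% 1:4)))
      stopf("record %d: unsupported bond order code", index)
    bonds <- cbind(bi, bj, bo)
  }
  Molecule3D(elements, coords, bonds = bonds,
             charges = charges, name = id)
}

# minimal V2000 parser for the degenerate records (single atom, no
# bonds) that the delegated parser cannot represent
.parseRecordText <- function(lines, index) {
  counts <- lines[4]
  n <- suppressWarnings(as.integer(substr(counts, 1, 3)))
  nb <- suppressWarnings(as.integer(substr(counts, 4, 6)))
  if (is.na(n) || n < 1) stopf("record %d: bad counts line", index)
  elements <- character(n); coords <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    ln <- lines[4 + i]
    coords[i, ] <- as.numeric(c(substr(ln, 1, 10), substr(ln, 11, 20),
                                substr(ln, 21, 30)))
    elements[i] <- trimws(substr(ln, 31, 34))
  }
  bonds <- NULL
  if (!is.na(nb) && nb > 0) {
    bonds <- t(vapply(seq_len(nb), function(r) {
      ln <- lines[4 + n + r]
      as.integer(c(substr(ln, 1, 3), substr(ln, 4, 6), substr(ln, 7, 9)))
    }, integer(3)))
    if (any(bonds[, 1:2] < 1) || any(bonds[, 1:2] > n))
      stopf("record %d: bond block references atom outside 1..%d",
            index, n)
  }
  Molecule3D(elements, coords, bonds = bonds, name = trimws(lines[1]))
}

#' Read molecules from an SDF file
#'
#' Reads a V2000 SDF into a list of [Molecule3D]. Aromatic bonds
#' (MDL code 4) map to the `"aromatic"` category; coordinates and bond
#' orders are preserved. Records that cannot be interpreted are skipped
#' with a warning naming the record index; the remaining records are
#' still returned (attribute `"errors"` carries the messages).
#'
#' @param path path to an existing SDF file.
#' @return List of [Molecule3D] (empty for an empty file), with an
#'   `"errors"` attribute listing per-record failures.
#' @export
readSDF <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0 || all(trimws(lines) == "")) {
    out <- list(); attr(out, "errors") <- character(0); return(out)
  }
  ends <- grep("^\\$\\$\\$\\$", lines)
  if (length(ends) == 0) ends <- length(lines)
  starts <- c(1L, head(ends, -1) + 1L)
  chunks <- mapply(function(s, e) lines[s:e], starts, ends,
                   SIMPLIFY = FALSE)
  chunks <- chunks[vapply(chunks, function(ch)
    any(trimws(ch) != "" & !grepl("^\\$\\$\\$\\$", ch)), logical(1))]
  isDegenerate <- vapply(chunks, function(ch) {
    n <- suppressWarnings(as.integer(substr(ch[4], 1, 3)))
    nb <- suppressWarnings(as.integer(substr(ch[4], 4, 6)))
    isTRUE(is.na(n) | is.na(nb) | n < 2 | nb < 1)
  }, logical(1))
  out <- vector("list", length(chunks))
  errors <- character(0)
  # normal records go through the delegated parser in one pass
  if (any(!isDegenerate)) {
    tmp <- tempfile(fileext = ".sdf")
    writeLines(unlist(chunks[!isDegenerate]), tmp)
    sdfset <- suppressWarnings(
      ChemmineR::read.SDFset(tmp, skipErrors = TRUE))
    unlink(tmp)
    ids <- ChemmineR::sdfid(sdfset)
    normalPos <- which(!isDegenerate)
    for (k in seq_along(sdfset)) {
      idx <- normalPos[k]
      mol <- tryCatch(.sdfToMolecule(sdfset[[k]], ids[k], idx),
                      error = function(e) e)
      out[[idx]] <- mol
    }
  }
  for (idx in which(isDegenerate)) {
    out[[idx]] <- tryCatch(.parseRecordText(chunks[[idx]], idx),
                           error = function(e) e)
  }
  keep <- logical(length(out))
  for (idx in seq_along(out)) {
    if (inherits(out[[idx]], "error") || is.null(out[[idx]])) {
      msg <- sprintf("record %d: %s", idx,
                     if (is.null(out[[idx]])) "unparsable" else
                       conditionMessage(out[[idx]]))
      msg <- sub(sprintf("^record %d: record %d: ", idx, idx),
                 sprintf("record %d: ", idx), msg)
      errors <- c(errors, msg)
      warning(msg, call. = FALSE)
    } else {
      keep[idx] <- TRUE
    }
  }
  out <- out[keep]
  attr(out, "errors") <- errors
  out
}

.moleculeToSDF <- function(mol) {
  n <- length(mol@elements)
  ab <- cbind(C1 = mol@coords[, 1], C2 = mol@coords[, 2],
              C3 = mol@coords[, 3],
              matrix(0, n, 13, dimnames = list(NULL, paste0("C", 5:17))))
  chgCode <- match(mol@charges, c(3L, 2L, 1L, NA, -1L, -2L, -3L))
  chgCode[is.na(chgCode) | mol@charges == 0L] <- 0L
  ab[, "C5"] <- chgCode
  rownames(ab) <- paste(mol@elements, seq_len(n), sep = "_")
  nb <- nrow(mol@bonds)
  bb <- cbind(mol@bonds[, 1, drop = TRUE], mol@bonds[, 2, drop = TRUE],
              mol@bonds[, 3, drop = TRUE], rep(0L, nb))
  bb <- matrix(as.numeric(bb), nrow = nb, ncol = 4,
               dimnames = list(NULL, paste0("C", 1:4)))
  hdr <- c(Molecule_Name = mol@name, Source = "  DecompAlign", Comment = "",
           Counts_Line = sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                                 n, nb))
  new("SDF", header = hdr, atomblock = ab, bondblock = bb,
      datablock = character(0))
}

# direct V2000 record text; used for the degenerate records (single
# atom, no bonds) that the delegated writer does not format correctly
.emitRecordText <- function(mol) {
  n <- length(mol@elements)
  nb <- nrow(mol@bonds)
  lines <- c(mol@name, "  DecompAlign", "",
             sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nb))
  for (i in seq_len(n))
    lines <- c(lines, sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                              mol@coords[i, 1], mol@coords[i, 2],
                              mol@coords[i, 3], mol@elements[i]))
  for (r in seq_len(nb))
    lines <- c(lines, sprintf("%3d%3d%3d  0", mol@bonds[r, 1],
                              mol@bonds[r, 2], mol@bonds[r, 3]))
  c(lines, "M  END", "$$$$")
}

#' Write molecules to an SDF file
#'
#' Inverse of [readSDF()]: the written file round-trips atom count,
#' element multiset, bond multiset and coordinates (to the printed
#' precision, well below 1e-4 Angstrom).
#'
#' @param mols a [Molecule3D] or list of them (an empty list writes a
#'   valid empty file).
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
writeSDF <- function(mols, path) {
  if (is(mols, "Molecule3D")) mols <- list(mols)
  ok <- tryCatch({ file.create(path) }, warning = function(w) FALSE)
  if (!isTRUE(ok)) stopf("cannot write to %s", path)
  if (length(mols) == 0) return(invisible(path))
  text <- unlist(lapply(mols, function(m) {
    if (length(m@elements) < 2 || nrow(m@bonds) < 1)
      .emitRecordText(m)
    else
      ChemmineR::sdf2str(.moleculeToSDF(m))
  }))
  writeLines(text, path)
  invisible(path)
}

# element inference from PDB atom names when the element column is blank:
# strip digits/primes, recognize two-letter halogens/metals, else first
# letter.
.TWO_LETTER <- c("CL", "BR", "SE", "FE", "ZN", "MG", "NA", "MN", "CU", "CA")

.inferElement <- function(atomName) {
  nm <- toupper(gsub("[0-9' ]", "", atomName))
  el2 <- substr(nm, 1, 2)
  # protein atom names like "CA" (alpha carbon) are element C; only accept
  # two-letter elements when the name is exactly the element symbol
  if (nm %in% .TWO_LETTER && !(nm %in% c("CA", "CD", "CE", "NE", "ND",
                                          "OD", "OE", "SD", "SG", "CG",
                                          "CB", "NZ", "OG", "OH", "NH"))) {
    return(paste0(substr(el2, 1, 1), tolower(substr(el2, 2, 2))))
  }
  substr(nm, 1, 1)
}

#' Read a protein pocket from a PDB file
#'
#' Keeps ATOM and HETATM records. Element symbols come from the element
#' column when present and are otherwise inferred from atom names.
#'
#' @param path path to a PDB file.
#' @param name identifier for the pocket (defaults to the file name).
#' @return A [ProteinPocket].
#' @export
readPocketPDB <- function(path, name = NULL) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                  error = function(e)
                    stopf("no ATOM/HETATM records in %s", path))
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0)
    stopf("no ATOM/HETATM records in %s", path)
  elesy <- at$elesy
  missing <- is.na(elesy) | trimws(elesy) == ""
  elements <- character(nrow(at))
  elements[!missing] <- trimws(elesy[!missing])
  elements[missing] <- vapply(at$elety[missing], .inferElement, "")
  elements <- paste0(toupper(substr(elements, 1, 1)),
                     tolower(substr(elements, 2, 10)))
  ProteinPocket(
    elements = elements,
    coords = cbind(at$x, at$y, at$z),
    resid = paste0(at$resid, at$resno),
    atomNames = at$elety,
    name = if (is.null(name)) basename(path) else name)
}

#' Write a protein pocket to a PDB file
#'
#' @param pocket a [ProteinPocket].
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
writePocketPDB <- function(pocket, path) {
  n <- nAtoms(pocket)
  resid3 <- substr(gsub("[0-9]", "", pocket@resid), 1, 3)
  resid3[resid3 == ""] <- "UNK"
  resno <- suppressWarnings(as.integer(gsub("[^0-9]", "", pocket@resid)))
  resno[is.na(resno)] <- seq_len(n)[is.na(resno)]
  bio3d::write.pdb(file = path,
                   xyz = as.vector(t(pocket@coords)),
                   type = rep("ATOM", n),
                   resno = resno, resid = resid3,
                   eleno = seq_len(n), elety = pocket@atomNames,
                   elesy = pocket@elements, chain = rep("A", n))
  invisible(path)
}
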