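## PDB-format parsing/writing and crystal packing contact enumeration.

.WATER_NAMES <- c("HOH", "WAT", "DOD")

#' Read a PDB-format crystal structure
#'
#' Parses ATOM/HETATM fixed-column records plus CRYST1 (unit cell and space
#' group), REMARK 2 (resolution) and HELIX/SHEET annotations. Hydrogens and
#' alternate locations other than blank/"A" are discarded; waters are flagged
#' hetero. Symmetry operators are resolved from the space-group symbol via
#' the built-in table (see \code{\link{supportedSpaceGroups}}).
#'
#' @param pdbText PDB file content as a single string or character vector of
#'   lines.
#' @return A \linkS4class{StructureModel}.
#' @examples
#' txt <- paste("CRYST1   10.000   10.000   10.000  90.00  90.00  90.00 P 1",
#'   "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
#'   sep = "\n")
#' readStructure(txt)
#' @export
readStructure <- function(pdbText) {
  lines <- if (length(pdbText) == 1L) strsplit(pdbText, "\n", fixed = TRUE)[[1]]
           else pdbText
  rec <- substr(lines, 1, 6)
  atomLines <- lines[rec %in% c("ATOM  ", "HETATM")]
  if (!length(atomLines)) stop("no ATOM or HETATM records found")

  fld <- function(x, a, b) trimws(substr(x, a, b))
  serial <- as.integer(fld(atomLines, 7, 11))
  name <- fld(atomLines, 13, 16)
  altloc <- fld(atomLines, 17, 17)
  resname <- fld(atomLines, 18, 20)
  chain <- fld(atomLines, 22, 22)
  resseq <- as.integer(fld(atomLines, 23, 26))
  icode <- fld(atomLines, 27, 27)
  x <- as.numeric(fld(atomLines, 31, 38))
  y <- as.numeric(fld(atomLines, 39, 46))
  z <- as.numeric(fld(atomLines, 47, 54))
  element <- toupper(fld(atomLines, 77, 78))
  noEl <- !nzchar(element)
  if (any(noEl))  # infer from atom name, skipping leading digits
    element[noEl] <- substr(gsub("^[0-9]*", "", name[noEl]), 1, 1)
  hetRec <- substr(atomLines, 1, 6) == "HETATM"
  water <- resname %in% .WATER_NAMES

  keep <- !(element %in% c("H", "D")) & altloc %in% c("", "A")
  df <- data.frame(serial = serial, name = name, element = element,
                   chain = chain, resname = resname, resseq = resseq,
                   icode = icode, x = x, y = y, z = z,
                   hetero = hetRec | water, water = water)[keep, ]
  row.names(df) <- NULL

  # 0-based residue ordinals per chain over non-water residues
  df$ordinal <- NA_integer_
  for (ch in unique(df$chain)) {
    sel <- df$chain == ch & !df$water
    rkey <- paste(df$resseq[sel], df$icode[sel])
    df$ordinal[sel] <- match(rkey, unique(rkey)) - 1L
  }
  df$vdw <- suppressWarnings(vdwRadius(df$element, df$serial))
  df$polarity <- ifelse(df$element == "C", "nonpolar",
                        ifelse(df$element %in% c("N", "O", "S"), "polar",
                               NA_character_))

  # unit cell + space group
  cell <- numeric(0); sg <- NA_character_; ops <- list()
  cl <- lines[rec == "CRYST1"]
  if (length(cl)) {
    cl <- cl[1]
    vals <- suppressWarnings(as.numeric(c(
      substr(cl, 7, 15), substr(cl, 16, 24), substr(cl, 25, 33),
      substr(cl, 34, 40), substr(cl, 41, 47), substr(cl, 48, 54))))
    if (anyNA(vals) || any(vals[1:3] <= 0) ||
        any(vals[4:6] <= 0 | vals[4:6] >= 180))
      stop("malformed CRYST1 record: '", trimws(cl), "'")
    cell <- vals
    sg <- .normalizeSpaceGroup(substr(cl, 56, 66))
    ops <- spaceGroupOperators(sg)
  }

  resolution <- NA_real_
  rl <- grep("^REMARK   2 RESOLUTION", lines, value = TRUE)
  if (length(rl)) {
    m <- regmatches(rl[1],
                    regexpr("RESOLUTION\\.\\s+([0-9.]+)", rl[1]))
    if (length(m))
      resolution <- as.numeric(sub("RESOLUTION\\.\\s+", "", m))
  }

  # HELIX/SHEET -> per-residue assignments (by chain + resseq range)
  ss <- data.frame(chain = character(0), ordinal = integer(0),
                   ss = character(0))
  ssAdd <- function(ch, from, to, kind) {
    sel <- df$chain == ch & !df$water & !df$hetero &
      df$resseq >= from & df$resseq <= to
    ords <- unique(df$ordinal[sel])
    if (length(ords))
      rbind(ss, data.frame(chain = ch, ordinal = ords, ss = kind))
    else ss
  }
  for (hl in lines[rec == "HELIX "])
    ss <- ssAdd(fld(hl, 20, 20), as.integer(fld(hl, 22, 25)),
                as.integer(fld(hl, 34, 37)), "helix")
  for (sl in lines[rec == "SHEET "])
    ss <- ssAdd(fld(sl, 22, 22), as.integer(fld(sl, 23, 26)),
                as.integer(fld(sl, 34, 37)), "strand")

  nModels <- max(1L, sum(rec == "MODEL "))
  prot <- !df$hetero & !df$water
  isCa <- any(prot) && all(df$name[prot] == "CA")

  new("StructureModel", atoms = df, cell = cell, spaceGroup = sg,
      symOps = ops, resolution = resolution, ssRecords = ss,
      nModelsInAsu = nModels, isCalphaOnly = isCa)
}

#' Write a StructureModel back to PDB text
#'
#' Emits CRYST1, REMARK 2 and fixed-column ATOM/HETATM records so that
#' \code{readStructure(writeStructure(x))} reproduces the atom table, cell
#' and space group.
#'
#' @param structure a \linkS4class{StructureModel}.
#' @return A single string of PDB text.
#' @export
writeStructure <- function(structure) {
  out <- character(0)
  if (length(structure@cell)) {
    out <- c(out, sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f %-11s",
                          structure@cell[1], structure@cell[2],
                          structure@cell[3], structure@cell[4],
                          structure@cell[5], structure@cell[6],
                          structure@spaceGroup))
  }
  if (!is.na(structure@resolution))
    out <- c(out, sprintf("REMARK   2 RESOLUTION.%9.2f ANGSTROMS.",
                          structure@resolution))
  a <- structure@atoms
  recName <- ifelse(a$hetero, "HETATM", "ATOM  ")
  pad <- function(nm) ifelse(nchar(nm) >= 4, substr(nm, 1, 4),
                             sprintf(" %-3s", nm))
  out <- c(out, sprintf("%s%5d %s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                        recName, a$serial, pad(a$name), "", a$resname,
                        a$chain, a$resseq, a$icode, a$x, a$y, a$z, 1, 0,
                        a$element))
  paste(c(out, "END"), collapse = "\n")
}

#' One-letter sequence of a chain
#'
#' @param structure a \linkS4class{StructureModel}.
#' @param chain chain identifier.
#' @return Single string of one-letter codes in residue-ordinal order
#'   (unknown residue types become \code{X}).
#' @export
chainSequence <- function(structure, chain) {
  a <- structure@atoms
  sel <- a$chain == chain & !a$hetero & !a$water
  if (!any(sel)) stop("no protein atoms in chain '", chain, "'")
  res <- a[sel, c("ordinal", "resname")]
  res <- res[!duplicated(res$ordinal), ]
  res <- res[order(res$ordinal), ]
  one <- .AA3[res$resname]
  one[is.na(one)] <- "X"
  paste(one, collapse = "")
}

#' Expand crystal symmetry into neighbour molecules
#'
#' Applies every symmetry operator combined with lattice translations within
#' \code{± shell} cells to the reference molecule, and keeps the images
#' (excluding the identity image with zero shift) that have at least one
#' protein atom within \code{contactCutoff} of a reference protein atom.
#' Transforms are rigid: every mate preserves all intramolecular distances.
#'
#' @param structure a \linkS4class{StructureModel} with a valid cell.
#' @param shell number of lattice layers to search (default 2).
#' @param contactCutoff heavy-atom distance (angstrom) defining "in contact"
#'   for mate retention (default 5).
#' @return List of \linkS4class{SymmetryMate} objects.
#' @export
expandSymmetry <- function(structure, shell = 2L, contactCutoff = 5) {
  if (!length(structure@cell))
    stop("structure has no unit cell; supply a CRYST1 record")
  stopifnot(shell >= 1L)
  M <- cellMatrix(structure@cell)
  Minv <- solve(M)
  a <- structure@atoms
  mol <- a[!a$water, , drop = FALSE]         # waters excluded from geometry
  prot <- !mol$hetero
  refXyz <- as.matrix(mol[prot, c("x", "y", "z")])
  cen <- colMeans(refXyz)
  circum <- sqrt(max(colSums((t(refXyz) - cen)^2)))
  shifts <- as.matrix(expand.grid(-shell:shell, -shell:shell, -shell:shell))
  mates <- list()
  for (k in seq_along(structure@symOps)) {
    op <- structure@symOps[[k]]
    ident <- .isIdentityOp(op)
    for (s in seq_len(nrow(shifts))) {
      sh <- as.integer(shifts[s, ])
      if (ident && all(sh == 0L)) next
      xyz <- .applySymOp(as.matrix(mol[, c("x", "y", "z")]), op, sh, M, Minv)
      mateProt <- xyz[prot, , drop = FALSE]
      cen2 <- colMeans(mateProt)
      if (sqrt(sum((cen2 - cen)^2)) > 2 * circum + contactCutoff) next
      # min cross distance check
      nc <- .neighborCounts(refXyz, mateProt, contactCutoff, strict = FALSE,
                            method = "brute")
      if (sum(nc) == 0L) next
      mate <- mol
      mate$x <- xyz[, 1]; mate$y <- xyz[, 2]; mate$z <- xyz[, 3]
      mates[[length(mates) + 1L]] <-
        new("SymmetryMate", opIndex = k, latticeShift = sh, atoms = mate)
    }
  }
  mates
}

## canonical fingerprint of an interface: sorted unordered contacting serial
## pairs; identical for the two lattice-translated views of one interface
.contactFingerprint <- function(refXyz, refSerial, mateXyz, mateSerial,
                                cutoff) {
  pr <- .pairsWithin(refXyz, mateXyz, cutoff, strict = FALSE)
  if (!nrow(pr)) return(NA_character_)
  a <- refSerial[pr$i]; b <- mateSerial[pr$j]
  key <- paste(pmin(a, b), pmax(a, b), sep = "-")
  paste(sort(unique(key)), collapse = ";")
}

## assemble a ContactPair from two atom tables (ASA bookkeeping included)
.buildContactPair <- function(refAtoms, prtAtoms, provenance,
                              opIndex = NA_integer_,
                              latticeShift = c(NA_integer_, NA_integer_,
                                               NA_integer_),
                              probeRadius = 1.4, nPoints = 960L) {
  refAtoms$id <- paste0("A|", refAtoms$serial)
  prtAtoms$id <- paste0("B|", prtAtoms$serial)
  refAtoms$rid <- paste("A", refAtoms$chain, refAtoms$ordinal, sep = "|")
  prtAtoms$rid <- paste("B", prtAtoms$chain, prtAtoms$ordinal, sep = "|")
  isoA <- computeAsa(refAtoms, probeRadius, nPoints)
  isoB <- computeAsa(prtAtoms, probeRadius, nPoints)
  both <- rbind(refAtoms, prtAtoms)
  comp <- computeAsa(both, probeRadius, nPoints)
  ia <- max(0, (isoA@total + isoB@total - comp@total) / 2)
  new("ContactPair", reference = refAtoms, partner = prtAtoms,
      partnerProvenance = provenance, opIndex = as.integer(opIndex),
      latticeShift = as.integer(latticeShift),
      asaIsolated = c(isoA@perAtom, isoB@perAtom),
      asaComplex = comp@perAtom, interfaceArea = ia)
}

#' Enumerate crystal packing contacts
#'
#' Generates all neighbour molecules by symmetry (\code{\link{expandSymmetry}}),
#' merges duplicate images of the same physical interface (lattice-translated
#' or inverse views, identified by a canonical fingerprint of contacting atom
#' serial pairs), and returns one \linkS4class{ContactPair} per distinct
#' reference/neighbour interface, each carrying isolated and complexed ASA
#' and the interface area.
#'
#' @inheritParams expandSymmetry
#' @param probeRadius,nPoints forwarded to \code{\link{computeAsa}}.
#' @return List of \linkS4class{ContactPair}, ordered by operator index and
#'   lattice shift. An isolated molecule yields an empty list.
#' @export
enumeratePackingContacts <- function(structure, contactCutoff = 5,
                                     shell = 2L, probeRadius = 1.4,
                                     nPoints = 960L) {
  mates <- expandSymmetry(structure, shell, contactCutoff)
  if (!length(mates)) return(list())
  ord <- order(vapply(mates, function(m) m@opIndex, integer(1)),
               vapply(mates, function(m) m@latticeShift[1], integer(1)),
               vapply(mates, function(m) m@latticeShift[2], integer(1)),
               vapply(mates, function(m) m@latticeShift[3], integer(1)))
  mates <- mates[ord]
  a <- structure@atoms
  ref <- a[!a$hetero & !a$water, , drop = FALSE]
  refXyz <- as.matrix(ref[, c("x", "y", "z")])
  seen <- character(0)
  out <- list()
  for (m in mates) {
    ma <- m@atoms
    mp <- ma[!ma$hetero & !ma$water, , drop = FALSE]
    fp <- .contactFingerprint(refXyz, ref$serial,
                              as.matrix(mp[, c("x", "y", "z")]), mp$serial,
                              contactCutoff)
    if (is.na(fp) || fp %in% seen) next
    seen <- c(seen, fp)
    out[[length(out) + 1L]] <- .buildContactPair(
      ref, mp,
      sprintf("op%d shift(%s)", m@opIndex,
              paste(m@latticeShift, collapse = ",")),
      m@opIndex, m@latticeShift, probeRadius, nPoints)
  }
  out
}

#' Largest packing contact of an entry
#'
#' Returns the contact with the maximal interface area; ties are broken by
#' the lowest operator index, then lexicographically smallest lattice shift,
#' so the selection is deterministic and independent of input order.
#'
#' @param contacts non-empty list of \linkS4class{ContactPair}.
#' @return A single \linkS4class{ContactPair}.
#' @export
selectLargestContact <- function(contacts) {
  if (!length(contacts)) stop("no packing contacts found")
  ia <- vapply(contacts, function(p) p@interfaceArea, numeric(1))
  opi <- vapply(contacts, function(p)
    if (is.na(p@opIndex)) .Machine$integer.max else p@opIndex, integer(1))
  sh <- t(vapply(contacts, function(p) {
    s <- p@latticeShift
    if (anyNA(s)) c(0L, 0L, 0L) else s
  }, integer(3)))
  ord <- order(-ia, opi, sh[, 1], sh[, 2], sh[, 3])
  contacts[[ord[1]]]
}

#' Contact pair from two chains of one model
#'
#' Builds a \linkS4class{ContactPair} for a two-chain complex (e.g. a weak
#' transient dimer or a synthetic toy dimer), with the first chain as the
#' reference side.
#'
#' @param structure a \linkS4class{StructureModel}.
#' @param chainA,chainB chain identifiers.
#' @param probeRadius,nPoints forwarded to \code{\link{computeAsa}}.
#' @return A \linkS4class{ContactPair}.
#' @export
pairFromChains <- function(structure, chainA, chainB, probeRadius = 1.4,
                           nPoints = 960L) {
  a <- structure@atoms
  prot <- !a$hetero & !a$water
  ref <- a[prot & a$chain == chainA, , drop = FALSE]
  prt <- a[prot & a$chain == chainB, , drop = FALSE]
  if (!nrow(ref) || !nrow(prt))
    stop("chains '", chainA, "'/'", chainB, "' not found or empty")
  .buildContactPair(ref, prt, paste0("chain ", chainB),
                    probeRadius = probeRadius, nPoints = nPoints)
}
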