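# In-code fixtures: tiny PDB texts and hand-assembled contact pairs whose
# expected descriptor values can be counted by eye.

tinyPdbLine <- function(serial, name, resname, chain, resseq, x, y, z,
                        element, record = "ATOM") {
  sprintf("%-6s%5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial,
          if (nchar(name) >= 4) substr(name, 1, 4) else sprintf(" %-3s", name),
          resname, chain, resseq, x, y, z, 1, 0, element)
}

cryst1Line <- function(a, b, c, al = 90, be = 90, ga = 90, sg = "P 1") {
  sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f %-11s", a, b, c, al, be, ga, sg)
}

# a 5-residue mixed fixture: 100 protein atoms would be bulky; this keeps a
# small protein core plus ligand + waters for the curation-related counts
mixedPdbText <- function() {
  lines <- cryst1Line(50, 50, 50)
  s <- 0
  for (r in 1:5) {
    for (nm in c("N", "CA", "C", "O")) {
      s <- s + 1
      el <- substr(nm, 1, 1)
      lines <- c(lines, tinyPdbLine(s, nm, "ALA", "A", r,
                                    r * 3.8, (s %% 4) * 1.4, 0, el))
    }
  }
  lines <- c(lines,
             tinyPdbLine(s + 1, "C1", "LIG", "A", 90, 30, 0, 0, "C", "HETATM"),
             tinyPdbLine(s + 2, "O1", "LIG", "A", 90, 31, 0, 0, "O", "HETATM"),
             tinyPdbLine(s + 3, "O", "HOH", "A", 101, 40, 0, 0, "O", "HETATM"),
             tinyPdbLine(s + 4, "O", "HOH", "A", 102, 41, 0, 0, "O", "HETATM"),
             tinyPdbLine(s + 5, "O", "HOH", "A", 103, 42, 0, 0, "O", "HETATM"))
  paste(lines, collapse = "\n")
}

# minimal atom rows for hand-assembled ContactPair objects
mkAtoms <- function(side, ords, chain = "A", resname = "ALA", element = "C",
                    name = "CB", x = 0, y = 0, z = 0, serialStart = 1L) {
  n <- length(ords)
  df <- data.frame(
    serial = seq(serialStart, length.out = n), name = rep_len(name, n),
    element = rep_len(element, n), chain = chain,
    resname = rep_len(resname, n), resseq = ords + 1L, icode = "",
    x = rep_len(x, n), y = rep_len(y, n), z = rep_len(z, n),
    hetero = FALSE, water = FALSE, ordinal = ords)
  df$vdw <- CrystalContacts::vdwRadius(df$element)
  df$polarity <- ifelse(df$element == "C", "nonpolar", "polar")
  df$id <- paste0(side, "|", df$serial)
  df$rid <- paste(side, chain, df$ordinal, sep = "|")
  df
}

# ContactPair with hand-set accessibility maps (geometry irrelevant for the
# accessibility-rule tests)
fakePair <- function(refAtoms, prtAtoms, iso, comp, ia = NULL) {
  if (is.null(ia)) {
    d <- iso - comp[names(iso)]
    ia <- max(0, sum(pmax(d, 0)) / 2)
  }
  new("ContactPair", reference = refAtoms, partner = prtAtoms,
      partnerProvenance = "fixture", asaIsolated = iso, asaComplex = comp,
      interfaceArea = ia)
}

# cached small toy dimer pair shared across tests (quadrature kept light)
toyPair <- local({
  cache <- NULL
  function(nPoints = 240L) {
    if (is.null(cache)) {
      d <- makeToyDimer(nResiduesPerChain = 16L, overlapDepth = 1.5, seed = 42)
      cache <<- pairFromChains(d, "A", "B", nPoints = nPoints)
    }
    cache
  }
})
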