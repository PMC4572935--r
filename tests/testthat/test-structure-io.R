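# PDB parsing, symmetry expansion and packing-contact enumeration.

test_that("readStructure parses atoms, cell and symmetry", {
  txt <- paste(cryst1Line(10, 10, 10),
               tinyPdbLine(1, "CA", "ALA", "A", 1, 0, 0, 0, "C"),
               sep = "\n")
  s <- readStructure(txt)
  expect_equal(nrow(atoms(s)), 1L)
  expect_equal(cellParams(s), c(10, 10, 10, 90, 90, 90))
  expect_equal(spaceGroup(s), "P 1")
  expect_length(symOps(s), 1L)

  # C-alpha-only flag
  ca <- paste(c(cryst1Line(20, 20, 20),
                sapply(1:5, function(r)
                  tinyPdbLine(r, "CA", "GLY", "A", r, r * 3.8, 0, 0, "C"))),
              collapse = "\n")
  expect_true(readStructure(ca)@isCalphaOnly)

  # hetero bookkeeping: 2 ligand atoms, 3 waters (hand count of fixture)
  m <- readStructure(mixedPdbText())
  expect_false(m@isCalphaOnly)
  a <- atoms(m)
  expect_equal(sum(a$hetero & !a$water), 2L)
  expect_equal(sum(a$water), 3L)
  expect_equal(sum(!a$hetero & !a$water), 20L)
  # ordinals are 0-based per chain
  expect_equal(sort(unique(a$ordinal[!a$hetero & !a$water])), 0:4)
})

test_that("readStructure rejects malformed input with useful errors", {
  expect_error(readStructure("HEADER only"), "no ATOM")
  bad <- paste("CRYST1   garbage",
               tinyPdbLine(1, "CA", "ALA", "A", 1, 0, 0, 0, "C"), sep = "\n")
  expect_error(readStructure(bad), "malformed CRYST1")
  unk <- paste(cryst1Line(10, 10, 10, sg = "F 4 3 2"),
               tinyPdbLine(1, "CA", "ALA", "A", 1, 0, 0, 0, "C"), sep = "\n")
  expect_error(readStructure(unk), "supported symbols")
})

test_that("round-trip through PDB text preserves atoms, cell and space group", {
  d <- makeToyDimer(nResiduesPerChain = 9L, overlapDepth = 1, seed = 2)
  cr <- makeToyCrystal(d, cell = c(25, 25, 12, 90, 90, 90), sg = "P 21 21 21")
  # writing truncates to the fixed-column precision; a structure already at
  # PDB precision must survive write -> read exactly
  s1 <- readStructure(cr$text)
  s2 <- readStructure(writeStructure(s1))
  expect_identical(atoms(s2), atoms(s1))
  expect_identical(cellParams(s2), cellParams(s1))
  expect_identical(spaceGroup(s2), spaceGroup(s1))
  # and the text itself agrees with the generator's coordinates to 1e-3
  a1 <- atoms(cr$structure); a2 <- atoms(s1)
  expect_equal(a2$serial, a1$serial)
  expect_equal(a2$name, a1$name)
  expect_equal(a2$resname, a1$resname)
  expect_equal(a2$ordinal, a1$ordinal)
  expect_equal(a2$x, a1$x, tolerance = 1e-3)
  expect_equal(a2$z, a1$z, tolerance = 1e-3)
})

test_that("expandSymmetry produces the triclinic lattice neighbourhood", {
  txt <- paste(cryst1Line(10, 10, 10),
               tinyPdbLine(1, "CA", "ALA", "A", 1, 0, 0, 0, "C"), sep = "\n")
  s <- readStructure(txt)
  mates <- expandSymmetry(s, shell = 1L, contactCutoff = 1000)
  expect_length(mates, 26L)  # 3^3 - 1 pure translations
  # larger shell output is a superset of the smaller shell's images
  mates2 <- expandSymmetry(s, shell = 2L, contactCutoff = 1000)
  key <- function(m) paste(m@opIndex, paste(m@latticeShift, collapse = ","))
  expect_true(all(vapply(mates, key, character(1)) %in%
                    vapply(mates2, key, character(1))))
  # missing cell
  s0 <- makeToyDimer(nResiduesPerChain = 4L, overlapDepth = 0.5, seed = 1)
  s0@cell <- numeric(0); s0@symOps <- list()
  expect_error(expandSymmetry(s0), "CRYST1")
})

test_that("symmetry mates are rigid copies (distance-matrix oracle)", {
  d <- makeToyDimer(nResiduesPerChain = 9L, overlapDepth = 1, seed = 3)
  cr <- makeToyCrystal(d, cell = c(24, 24, 11, 90, 90, 90), sg = "P 21 21 21")
  mates <- expandSymmetry(cr$structure, shell = 2L, contactCutoff = 8)
  expect_gt(length(mates), 0L)
  d0 <- dist(as.matrix(atoms(cr$structure)[, c("x", "y", "z")]))
  for (m in mates) {
    dm <- dist(as.matrix(atoms(m)[, c("x", "y", "z")]))
    expect_lt(max(abs(dm - d0)), 1e-6)
  }
  # isometry on random coordinate pairs for every operator
  M <- cellMatrix(cellParams(cr$structure)); Minv <- solve(M)
  set.seed(7)
  p <- matrix(runif(200 * 3, -30, 30), ncol = 3)
  for (op in symOps(cr$structure)) {
    q <- CrystalContacts:::.applySymOp(p, op, c(0, 0, 0), M, Minv)
    expect_lt(max(abs(dist(q) - dist(p))), 1e-6)
  }
})

test_that("enumeratePackingContacts finds designed contacts and dedups", {
  dimer <- makeToyDimer(nResiduesPerChain = 9L, overlapDepth = 1, seed = 3)
  # isolated molecule in a huge cell: no contacts, empty list not an error
  iso <- makeToyCrystal(dimer, cell = c(100, 100, 100, 90, 90, 90), sg = "P 1")
  expect_identical(enumeratePackingContacts(iso$structure, nPoints = 240L),
                   list())
  # designed counts match (construction oracle, two cells)
  for (cell in list(c(14, 30, 8, 90, 90, 90), c(14, 14, 8, 90, 90, 90))) {
    cr <- makeToyCrystal(dimer, cell = cell, sg = "P 1")
    got <- enumeratePackingContacts(cr$structure, nPoints = 240L)
    expect_equal(length(got), cr$designedContacts)
    for (p in got) expect_gte(interfaceArea(p), 0)
  }
})

test_that("contact enumeration is independent of atom input order", {
  dimer <- makeToyDimer(nResiduesPerChain = 9L, overlapDepth = 1, seed = 5)
  cr <- makeToyCrystal(dimer, cell = c(14, 14, 8, 90, 90, 90), sg = "P 1")
  s <- cr$structure
  perm <- s
  set.seed(1)
  perm@atoms <- perm@atoms[sample(nrow(perm@atoms)), ]
  c1 <- enumeratePackingContacts(s, nPoints = 240L)
  c2 <- enumeratePackingContacts(perm, nPoints = 240L)
  expect_equal(length(c1), length(c2))
  expect_equal(sort(sapply(c1, interfaceArea)),
               sort(sapply(c2, interfaceArea)), tolerance = 1e-9)
})

# all permutations of 1..n (tiny n); avoids pulling in a package
combinat_perms <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- combinat_perms(n - 1L)
  out <- NULL
  for (i in seq_len(n)) {
    rest <- (1:n)[-i]
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub))))
  }
  out
}

test_that("selectLargestContact maximises area with deterministic tie-break", {
  mk <- function(ia, op, shift) {
    a <- mkAtoms("A", 0L); b <- mkAtoms("B", 0L)
    p <- fakePair(a, b, setNames(c(10, 10), c(a$id, b$id)),
                  setNames(c(10, 10), c(a$id, b$id)), ia = ia)
    p@opIndex <- as.integer(op); p@latticeShift <- as.integer(shift)
    p
  }
  contacts <- list(mk(300, 1, c(0, 0, 1)), mk(950, 3, c(1, 0, 0)),
                   mk(950, 2, c(0, 1, 0)), mk(100, 4, c(0, 0, 0)))
  expect_equal(selectLargestContact(contacts)@opIndex, 2L)
  # permuting input never changes the selection (exhaustive on 4 elements)
  perms <- combinat_perms(4)
  for (k in seq_len(nrow(perms))) {
    got <- selectLargestContact(contacts[perms[k, ]])
    expect_equal(got@opIndex, 2L)
  }
  expect_error(selectLargestContact(list()), "no packing contacts")
})

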