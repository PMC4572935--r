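# Interface detection and descriptor computations, mostly against
# hand-countable fabricated contact pairs.

test_that("interface residue rule is strict at 1 square angstrom", {
  a <- mkAtoms("A", 0:1)                       # residue 0: loss 1.00, 1: 1.01
  b <- mkAtoms("B", 0L, chain = "B")
  iso <- setNames(c(5, 5, 10), c(a$id, b$id))
  comp <- setNames(c(4, 3.99, 5), c(a$id, b$id))
  p <- fakePair(a, b, iso, comp)
  iface <- detectInterface(p)
  expect_false(startsWith(iface$residueLabels[["A|A|0"]], "interface"))
  expect_true(startsWith(iface$residueLabels[["A|A|1"]], "interface"))
})

test_that("core/rim classification follows the buried-atom rule", {
  a <- mkAtoms("A", 0:1)
  b <- mkAtoms("B", 0L, chain = "B")
  # residue 0: interface atom fully buried (5 -> 0); residue 1 keeps access
  iso <- setNames(c(5, 5, 10), c(a$id, b$id))
  comp <- setNames(c(0, 2, 5), c(a$id, b$id))
  iface <- detectInterface(fakePair(a, b, iso, comp))
  expect_equal(iface$residueLabels[["A|A|0"]], "interface_core")
  expect_equal(iface$residueLabels[["A|A|1"]], "interface_rim")
  # no atom reaches zero: all rim, and core residues exist only when f_bu > 0
  comp2 <- setNames(c(1, 2, 5), c(a$id, b$id))
  p2 <- fakePair(a, b, iso, comp2)
  iface2 <- detectInterface(p2)
  expect_false(any(iface2$residueLabels == "interface_core"))
  expect_equal(buriedFraction(p2, iface2), 0)
  expect_equal(coreFraction(p2, iface2), 0)
})

test_that("interface area identities and ratio", {
  expect_equal(interfaceAreaFromTotals(1000, 800, 1500), 150)
  expect_equal(interfaceAreaFromTotals(100, 100, 300), 0)   # clamped
  p <- toyPair()
  d <- p@asaIsolated - p@asaComplex[names(p@asaIsolated)]
  expect_equal(interfaceArea(p), sum(d) / 2, tolerance = 1e-6)

  # ratio against a hand-set monomer surface
  a <- mkAtoms("A", 0:2); b <- mkAtoms("B", 0L, chain = "B")
  iso <- setNames(c(1000, 1000, 1000, 500), c(a$id, b$id))
  comp <- iso
  pr <- fakePair(a, b, iso, comp, ia = 150)
  expect_equal(areaRatio(pr), 100 * 150 / 3000)
})

test_that("buried and non-polar fractions are area-weighted hand counts", {
  a <- mkAtoms("A", 0:9)        # ten 1-atom residues
  a$element <- c(rep("C", 5), rep("O", 5)); a$vdw <- vdwRadius(a$element)
  b <- mkAtoms("B", 0L, chain = "B")
  iso <- setNames(c(rep(10, 10), 10), c(a$id, b$id))
  # 3 of 10 interface atoms fully buried; carbon loss 4 each, oxygen loss 6
  comp <- setNames(c(0, 0, 0, 6, 6, 4, 4, 4, 4, 4, 10 - 2), c(a$id, b$id))
  p <- fakePair(a, b, iso, comp)
  iface <- detectInterface(p)
  expect_setequal(iface$interfaceAtoms, c(a$id, b$id))
  expect_equal(buriedFraction(p, iface), 3 / 11)
  # carbon dASA = 10+10+10+4+4 = 38; total = 38 + 6*5 2... hand sum below
  cLoss <- sum(10 - comp[a$id[1:5]])
  oLoss <- sum(10 - comp[a$id[6:10]])
  bLoss <- 10 - comp[[b$id]]
  expect_equal(nonpolarFraction(p, iface),
               (cLoss + bLoss) / (cLoss + oLoss + bLoss))
  # all-carbon and no-carbon edge cases
  allC <- fakePair(mkAtoms("A", 0L), mkAtoms("B", 0L, chain = "B"),
                   setNames(c(10, 10), c("A|1", "B|1")),
                   setNames(c(5, 5), c("A|1", "B|1")))
  expect_equal(nonpolarFraction(allC), 1)
  aO <- mkAtoms("A", 0L, element = "O"); bO <- mkAtoms("B", 0L, chain = "B",
                                                       element = "N")
  noC <- fakePair(aO, bO, setNames(c(10, 10), c(aO$id, bO$id)),
                  setNames(c(5, 5), c(aO$id, bO$id)))
  expect_equal(nonpolarFraction(noC), 0)
})

test_that("core area fraction spans its limits and matches hand sums", {
  a <- mkAtoms("A", 0:1); b <- mkAtoms("B", 0L, chain = "B")
  iso <- setNames(c(10, 10, 10), c(a$id, b$id))
  # residue A0 core (atom buried), A1 rim, B rim
  comp <- setNames(c(0, 5, 6), c(a$id, b$id))
  p <- fakePair(a, b, iso, comp)
  expect_equal(coreFraction(p), 10 / (10 + 5 + 4))
  # every interface residue core -> 1
  compAll <- setNames(c(0, 0, 0), c(a$id, b$id))
  expect_equal(coreFraction(fakePair(a, b, iso, compAll)), 1)
})

test_that("non-bonded contact count is strict at 3.9 angstrom", {
  mk <- function(d) {
    a <- mkAtoms("A", 0L); b <- mkAtoms("B", 0L, chain = "B", x = d)
    fakePair(a, b, setNames(c(10, 10), c(a$id, b$id)),
             setNames(c(5, 5), c(a$id, b$id)))
  }
  expect_equal(nonbondedContacts(mk(3.8)), 1L)
  expect_equal(nonbondedContacts(mk(3.9)), 0L)
  # accelerated search equals brute force on random coordinates
  set.seed(17)
  a <- mkAtoms("A", 0:99, x = 0); b <- mkAtoms("B", 0:99, chain = "B")
  a$x <- runif(100, 0, 20); a$y <- runif(100, 0, 20); a$z <- runif(100, 0, 20)
  b$x <- runif(100, 0, 20); b$y <- runif(100, 0, 20); b$z <- runif(100, 0, 20)
  iso <- setNames(rep(10, 200), c(a$id, b$id))
  p <- fakePair(a, b, iso, iso - 2)
  expect_equal(nonbondedContacts(p, method = "grid"),
               nonbondedContacts(p, method = "brute"))
})

test_that("hydrogen bond criterion needs donor/acceptor chemistry and geometry", {
  mkHB <- function(elA, elB, d, withAnte = FALSE, anteAngle = 120) {
    a <- mkAtoms("A", 0L, element = elA, name = "N")
    if (withAnte) {
      ante <- mkAtoms("A", 0L, element = "C", name = "CA", serialStart = 10L)
      ante$x <- 1.4 * cos(anteAngle * pi / 180)
      ante$y <- 1.4 * sin(anteAngle * pi / 180)
      a <- rbind(a, ante)
    }
    # acceptor carries a carbonyl-like antecedent pointing back at the donor,
    # so the reverse (acceptor-as-donor) orientation fails its angle check
    b <- rbind(mkAtoms("B", 0L, chain = "B", element = elB, x = d),
               mkAtoms("B", 0L, chain = "B", element = "C", name = "CD",
                       x = d - 1.4, serialStart = 20L))
    iso <- setNames(rep(10, nrow(a) + nrow(b)), c(a$id, b$id))
    fakePair(a, b, iso, iso - 2)
  }
  expect_equal(hydrogenBonds(mkHB("N", "O", 2.9, withAnte = TRUE)), 1L)
  expect_equal(hydrogenBonds(mkHB("C", "C", 2.9)), 0L)
  expect_equal(hydrogenBonds(mkHB("N", "O", 3.6)), 0L)     # too long
  expect_equal(hydrogenBonds(mkHB("N", "O", 2.9, withAnte = TRUE,
                                  anteAngle = 45)), 0L)    # bad geometry
  # same-chain polar pairs are never counted: far-apart sides see nothing
  a <- rbind(mkAtoms("A", 0L, element = "N"),
             mkAtoms("A", 1L, element = "O", x = 2.9, serialStart = 2L))
  b <- mkAtoms("B", 0L, chain = "B", element = "C", x = 50)
  iso <- setNames(rep(10, 3), c(a$id, b$id))
  expect_equal(hydrogenBonds(fakePair(a, b, iso, iso - 2)), 0L)
})

test_that("segment count applies the gap rule per chain", {
  mkSeg <- function(ifaceOrds, nres = 8L) {
    a <- mkAtoms("A", seq_len(nres) - 1L)
    b <- mkAtoms("B", 0L, chain = "B")
    iso <- setNames(rep(10, nres + 1), c(a$id, b$id))
    comp <- iso
    comp[paste0("A|", ifaceOrds + 1L)] <- 5       # serial = ordinal + 1
    fakePair(a, b, iso, comp)
  }
  expect_equal(segmentCount(mkSeg(c(0L, 2L))), 1L)   # gap 1 <= 4: one segment
  expect_equal(segmentCount(mkSeg(c(0L, 6L))), 2L)   # gap 5 > 4: two segments
  expect_equal(segmentCount(mkSeg(c(0L, 5L))), 1L)   # gap 4: still one
  expect_equal(segmentCount(mkSeg(0:7)), 1L)         # fully contiguous
})

test_that("local density counts same-subunit neighbours, self excluded", {
  # exactly one interface atom per side -> LD 0
  a <- mkAtoms("A", 0L); b <- mkAtoms("B", 0L, chain = "B", x = 3)
  iso <- setNames(c(10, 10), c(a$id, b$id))
  p <- fakePair(a, b, iso, iso - 5)
  expect_equal(localDensity(p), 0)
  # two same-subunit interface atoms 5 A apart, none elsewhere -> LD 1
  a2 <- mkAtoms("A", 0:1, x = c(0, 5))
  b2 <- mkAtoms("B", 0L, chain = "B", x = 2.5, z = 3)
  iso2 <- setNames(c(10, 10, 10), c(a2$id, b2$id))
  comp2 <- setNames(c(5, 5, 10), c(a2$id, b2$id))  # B atom not interface
  expect_equal(localDensity(fakePair(a2, b2, iso2, comp2)), 1)
  # grid equals brute force on a random interface
  p3 <- toyPair()
  iface <- detectInterface(p3)
  expect_equal(localDensity(p3, iface, method = "grid"),
               localDensity(p3, iface, method = "brute"))
})

test_that("gap volume index: no admissible sphere, growth with separation, grid refinement", {
  # two nearly touching atoms leave room only for a sub-minimal sphere
  a <- mkAtoms("A", 0L); b <- mkAtoms("B", 0L, chain = "B", x = 2 * 1.87 + 1)
  iso <- setNames(c(10, 10), c(a$id, b$id))
  p <- fakePair(a, b, iso, iso - 5, ia = 10)
  expect_equal(gapVolumeIndex(p), 0)
  # two 5x5 rigid slabs: gap volume grows with separation
  slabPair <- function(sep) {
    g <- expand.grid(x = (0:4) * 2.5, y = (0:4) * 2.5)
    a <- mkAtoms("A", seq_len(25) - 1L); a$x <- g$x; a$y <- g$y; a$z <- 0
    b <- mkAtoms("B", seq_len(25) - 1L, chain = "B")
    b$x <- g$x; b$y <- g$y; b$z <- 2 * 1.87 + sep
    iso <- setNames(rep(10, 50), c(a$id, b$id))
    fakePair(a, b, iso, iso - 5, ia = 1)   # index equals raw volume
  }
  vols <- vapply(c(2.2, 2.6, 3.0), function(s) gapVolumeIndex(slabPair(s)),
                 numeric(1))
  expect_true(all(diff(vols) > 0))
  # default 0.5 A voxels agree with a 0.25 A recomputation within 10%
  v1 <- gapVolumeIndex(slabPair(2.6), voxel = 0.5)
  v2 <- gapVolumeIndex(slabPair(2.6), voxel = 0.25)
  expect_lt(abs(v1 - v2) / v2, 0.10)
})

test_that("propensity score follows the log-odds formula", {
  # interface composition identical to surface composition -> 0
  a <- mkAtoms("A", 0:3); b <- mkAtoms("B", 0L, chain = "B")
  iso <- setNames(rep(50, 5), c(a$id, b$id))
  comp <- setNames(c(40, 40, 50, 50, 50), c(a$id, b$id))
  expect_equal(propensityScore(fakePair(a, b, iso, comp)), 0)

  # 5 residues of a type holding 20% of the area vs 10% of the surface
  aT <- mkAtoms("A", 0:4, resname = "THR")
  aU <- mkAtoms("A", 5:19, resname = "ALA", serialStart = 6L)
  aa <- rbind(aT, aU)
  b <- mkAtoms("B", 0L, chain = "B", serialStart = 30L)
  iso <- setNames(c(rep(60, 20), 60), c(aa$id, b$id))
  comp <- iso
  comp[aT$id] <- 60 - 2            # THR loses 2 each: 10 of 50 total = 0.2
  comp[aU$id] <- 60 - 8 / 3        # ALA loses 40 total = 0.8
  p <- fakePair(aa, b, iso, comp)
  ref <- c(THR = 0.1, ALA = 0.8, GLY = 0.1)
  expect_equal(propensityScore(p, surfaceReference = ref), 5 * log(2),
               tolerance = 1e-9)
  # absent type is floored by the pseudocount, never infinite
  refNo <- c(ALA = 0.9, GLY = 0.1)
  nSurfRef <- 20                    # reference floor population
  floorVal <- 0.5 / nSurfRef
  expected <- 5 * log(0.2 / floorVal) + 15 * log(0.8 / 0.9)
  expect_equal(propensityScore(p, surfaceReference = refNo), expected,
               tolerance = 1e-9)
})

test_that("secondary-structure category obeys the 30% rules strictly", {
  a <- mkAtoms("A", 0:9)
  b <- mkAtoms("B", 0L, chain = "B")
  iso <- setNames(rep(10, 11), c(a$id, b$id))
  comp <- setNames(c(rep(5, 10), 10), c(a$id, b$id))
  p <- fakePair(a, b, iso, comp)
  mkSS <- function(nH, nE) {
    ss <- rep("other", 10)
    if (nH) ss[seq_len(nH)] <- "helix"
    if (nE) ss[nH + seq_len(nE)] <- "strand"
    setNames(ss, a$rid)
  }
  iface <- detectInterface(p)
  expect_equal(ssCategory(p, iface, mkSS(4, 1)), "alpha")
  expect_equal(ssCategory(p, iface, mkSS(1, 4)), "beta")
  expect_equal(ssCategory(p, iface, mkSS(4, 4)), "alpha/beta")
  expect_equal(ssCategory(p, iface, mkSS(1, 1)), "coil")
  # exactly 30% counts as "not more than 30%"
  expect_equal(ssCategory(p, iface, mkSS(3, 4)), "beta")
  expect_equal(ssCategory(p, iface, mkSS(3, 3)), "coil")
})

test_that("computeAllDescriptors populates every field deterministically", {
  p <- toyPair()
  d1 <- computeAllDescriptors(p)
  d2 <- computeAllDescriptors(p)
  expect_identical(as.data.frame(d1), as.data.frame(d2))
  df <- as.data.frame(d1)
  expect_equal(ncol(df), 14L)
  expect_true(all(vapply(df[1, -14], is.numeric, logical(1))))
  expect_true(all(is.finite(unlist(df[1, -14]))))
  expect_true(df$f_bu >= 0 && df$f_bu <= 1)
  expect_true(df$f_np >= 0 && df$f_np <= 1)
  expect_true(df$f_core >= 0 && df$f_core <= 1)
  expect_lte(df$Ns, df$n_iface_res)
  # a contact-free pair has no interface and errors out
  far <- makeToyDimer(nResiduesPerChain = 9L, overlapDepth = 0, standoff = 5,
                      seed = 8)
  pf <- pairFromChains(far, "A", "B", nPoints = 92L)
  expect_error(computeAllDescriptors(pf), "no interface")
})

test_that("IA and Nnbc track generator overlap depth across seeds", {
  depths <- seq(0.3, 3, length.out = 20)
  ia <- numeric(20); nb <- numeric(20)
  for (k in seq_along(depths)) {
    d <- makeToyDimer(nResiduesPerChain = 16L, overlapDepth = depths[k],
                      seed = 200L + k)
    p <- pairFromChains(d, "A", "B", nPoints = 92L)
    ia[k] <- interfaceArea(p)
    nb[k] <- nonbondedContacts(p)
  }
  expect_gt(pearsonR(depths, ia), 0.9)
  expect_gt(pearsonR(depths, nb), 0.9)
  expect_gt(pearsonR(ia, nb), 0.5)  # contacts scale with area
})
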