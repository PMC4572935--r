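## Interface detection and the per-interface geometric / physicochemical
## descriptor set for a ContactPair.

#' Detect the interface of a contact pair
#'
#' Applies the standard accessibility rules: a residue is an interface
#' residue when its ASA drops by more than 1 square angstrom upon binding
#' (strict); an interface atom loses ASA and was accessible in isolation.
#' Interface residues with at least one fully buried interface atom
#' (complexed ASA = 0) are core, the others rim. Non-interface residues are
#' split into surface (relative isolated ASA >= 5\% of the residue-type
#' maximum) and interior.
#'
#' @param pair a \linkS4class{ContactPair}.
#' @return list with \code{residueLabels} (named character over residue ids:
#'   interface_core / interface_rim / surface / interior),
#'   \code{interfaceAtoms} (atom ids), \code{atomDelta} and
#'   \code{residueDelta} (named ASA-loss maps).
#' @export
detectInterface <- function(pair) {
  both <- rbind(pair@reference, pair@partner)
  iso <- pair@asaIsolated[both$id]
  comp <- pair@asaComplex[both$id]
  dAtom <- iso - comp
  dAtom[dAtom < 1e-6] <- 0
  names(dAtom) <- both$id
  dRes <- vapply(split(dAtom, both$rid), sum, numeric(1))
  isoRes <- vapply(split(iso, both$rid), sum, numeric(1))

  ifaceAtom <- dAtom > 0 & iso > 0
  ifaceRes <- names(dRes)[dRes > 1.0]

  labels <- setNames(rep("interior", length(dRes)), names(dRes))
  resname1 <- vapply(split(both$resname, both$rid), `[`, character(1), 1)
  relAsa <- isoRes / .maxAsa(resname1[names(isoRes)])
  labels[relAsa >= 0.05] <- "surface"
  for (r in ifaceRes) {
    atomsOfR <- both$id[both$rid == r]
    buried <- any(ifaceAtom[atomsOfR] & comp[atomsOfR] <= 0)
    labels[r] <- if (buried) "interface_core" else "interface_rim"
  }
  list(residueLabels = labels,
       interfaceAtoms = both$id[ifaceAtom],
       atomDelta = dAtom, residueDelta = dRes)
}

#' Interface area from ASA totals
#'
#' Half the total ASA decrease of two molecules upon interaction:
#' IA = (ASA_A + ASA_B - ASA_AB) / 2, clamped at zero.
#'
#' @param asaA,asaB,asaAB total ASA of each molecule alone and of the complex.
#' @return Interface area in square angstrom.
#' @examples
#' interfaceAreaFromTotals(1000, 800, 1500)  # 150
#' @export
interfaceAreaFromTotals <- function(asaA, asaB, asaAB) {
  max(0, (asaA + asaB - asaAB) / 2)
}

#' Fully buried atom fraction
#'
#' Fraction of interface atoms whose ASA is exactly zero in the complex.
#'
#' @param pair a \linkS4class{ContactPair}.
#' @param iface output of \code{\link{detectInterface}} (computed if omitted).
#' @return Fraction in [0, 1].
#' @export
buriedFraction <- function(pair, iface = detectInterface(pair)) {
  ids <- iface$interfaceAtoms
  if (!length(ids)) stop("no interface")
  mean(pair@asaComplex[ids] <= 0)
}

#' Non-polar area fraction
#'
#' Fraction of the interface area (summed per-atom ASA loss over both sides)
#' contributed by carbon atoms.
#'
#' @inheritParams buriedFraction
#' @return Fraction in [0, 1].
#' @export
nonpolarFraction <- function(pair, iface = detectInterface(pair)) {
  ids <- iface$interfaceAtoms
  if (!length(ids)) stop("no interface")
  both <- rbind(pair@reference, pair@partner)
  el <- setNames(both$element, both$id)
  tot <- sum(iface$atomDelta[ids])
  if (tot <= 0) stop("zero total ASA loss over the interface")
  sum(iface$atomDelta[ids][el[ids] == "C"]) / tot
}

#' Core area fraction
#'
#' Fraction of the interface area contributed by atoms of core residues.
#'
#' @inheritParams buriedFraction
#' @return Fraction in [0, 1].
#' @export
coreFraction <- function(pair, iface = detectInterface(pair)) {
  ids <- iface$interfaceAtoms
  if (!length(ids)) stop("no interface")
  both <- rbind(pair@reference, pair@partner)
  rid <- setNames(both$rid, both$id)
  coreRes <- names(iface$residueLabels)[iface$residueLabels == "interface_core"]
  tot <- sum(iface$atomDelta[ids])
  if (tot <= 0) stop("zero total ASA loss over the interface")
  sum(iface$atomDelta[ids][rid[ids] %in% coreRes]) / tot
}

#' Number of non-bonded contacts
#'
#' Cross-interface heavy-atom pairs strictly closer than \code{cutoff}
#' (default 3.9 angstrom, the 2P2I-inspector convention).
#'
#' @param pair a \linkS4class{ContactPair}.
#' @param cutoff distance cutoff in angstrom.
#' @param method \code{"grid"} cell lists or \code{"brute"} distance matrix
#'   (identical counts).
#' @return Integer count.
#' @export
nonbondedContacts <- function(pair, cutoff = 3.9,
                              method = c("grid", "brute")) {
  method <- match.arg(method)
  A <- as.matrix(pair@reference[, c("x", "y", "z")])
  B <- as.matrix(pair@partner[, c("x", "y", "z")])
  sum(.neighborCounts(A, B, cutoff, strict = TRUE, method = method))
}

#' Cross-interface hydrogen bond count
#'
#' Heavy-atom criterion: donor-capable N/O/S on one side and N/O acceptor on
#' the other, donor-acceptor distance <= 3.5 angstrom, and (when the donor
#' has a covalently bonded antecedent within 2 angstrom) at least one
#' antecedent-donor-acceptor angle >= 90 degrees. Each unordered atom pair is
#' counted once.
#'
#' @param pair a \linkS4class{ContactPair}.
#' @param distCutoff donor-acceptor distance cutoff (angstrom).
#' @param minAngle minimal antecedent angle in degrees.
#' @return Integer count.
#' @export
hydrogenBonds <- function(pair, distCutoff = 3.5, minAngle = 90) {
  sides <- list(pair@reference, pair@partner)
  xyz <- lapply(sides, function(s) as.matrix(s[, c("x", "y", "z")]))
  angleOk <- function(side, di, accPos) {
    s <- sides[[side]]
    dPos <- xyz[[side]][di, ]
    dd <- sqrt(colSums((t(xyz[[side]]) - dPos)^2))
    ante <- which(dd > 1e-6 & dd < 2.0 & s$chain == s$chain[di])
    if (!length(ante)) return(TRUE)
    for (ai in ante) {
      v1 <- xyz[[side]][ai, ] - dPos
      v2 <- accPos - dPos
      ang <- acos(max(-1, min(1, sum(v1 * v2) /
                                sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
      if (ang >= minAngle) return(TRUE)
    }
    FALSE
  }
  donor <- lapply(sides, function(s) s$element %in% c("N", "O", "S"))
  accep <- lapply(sides, function(s) s$element %in% c("N", "O"))
  pr <- .pairsWithin(xyz[[1]], xyz[[2]], distCutoff, strict = FALSE)
  n <- 0L
  for (k in seq_len(nrow(pr))) {
    i <- pr$i[k]; j <- pr$j[k]
    ok <- (donor[[1]][i] && accep[[2]][j] && angleOk(1, i, xyz[[2]][j, ])) ||
          (donor[[2]][j] && accep[[1]][i] && angleOk(2, j, xyz[[1]][i, ]))
    if (ok) n <- n + 1L
  }
  n
}

#' Number of interface segments
#'
#' An interface segment is a chain stretch starting and ending with interface
#' residues whose internal non-interface gaps are at most \code{maxGap}
#' residues (default 4). Counts are summed over the chains of both sides.
#'
#' @param pair a \linkS4class{ContactPair}.
#' @param iface output of \code{\link{detectInterface}}.
#' @param maxGap largest allowed internal non-interface stretch.
#' @return Integer segment count.
#' @export
segmentCount <- function(pair, iface = detectInterface(pair), maxGap = 4L) {
  labels <- iface$residueLabels
  ifres <- names(labels)[startsWith(labels, "interface")]
  if (!length(ifres)) return(0L)
  parts <- strsplit(ifres, "|", fixed = TRUE)
  key <- vapply(parts, function(p) paste(p[1], p[2], sep = "|"), character(1))
  ords <- as.integer(vapply(parts, `[`, character(1), 3))
  n <- 0L
  for (ch in unique(key)) {
    o <- sort(ords[key == ch])
    gaps <- diff(o) - 1L
    n <- n + 1L + sum(gaps > maxGap)
  }
  n
}

#' Local density index
#'
#' Mean number of same-side interface atoms within \code{radius} (default
#' 12 angstrom) of each interface atom, the atom itself excluded; averaged
#' over all interface atoms of both sides. High values indicate tight
#' packing.
#'
#' @inheritParams nonbondedContacts
#' @param iface output of \code{\link{detectInterface}}.
#' @param radius neighbourhood radius in angstrom.
#' @return Mean neighbour count (non-negative real).
#' @export
localDensity <- function(pair, iface = detectInterface(pair), radius = 12,
                         method = c("grid", "brute")) {
  method <- match.arg(method)
  ids <- iface$interfaceAtoms
  if (!length(ids)) stop("no interface")
  counts <- integer(0)
  for (side in list(pair@reference, pair@partner)) {
    sel <- side$id %in% ids
    if (!any(sel)) next
    xyz <- as.matrix(side[sel, c("x", "y", "z")])
    counts <- c(counts, .neighborCounts(xyz, NULL, radius, strict = FALSE,
                                        method = method))
  }
  mean(counts)
}

#' Gap volume index
#'
#' Interstitial volume between the two molecular surfaces divided by the
#' interface area (angstrom); lower values mean better shape
#' complementarity. The gap volume follows the classic gap-sphere procedure:
#' for every cross-interface atom pair closer than 10 angstrom a trial
#' sphere is placed midway between the two van der Waals surfaces, shrunk
#' until tangent to the nearest atom sphere, kept when its final radius lies
#' in [1, 5] angstrom; the kept spheres' union volume is integrated on a
#' voxel grid.
#'
#' @param pair a \linkS4class{ContactPair}.
#' @param voxel integration grid spacing in angstrom (default 0.5).
#' @param pairCutoff centre-distance cutoff for generating trial spheres.
#' @param minRadius,maxRadius admissible gap-sphere radii.
#' @return Gap volume index in angstrom.
#' @export
gapVolumeIndex <- function(pair, voxel = 0.5, pairCutoff = 10,
                           minRadius = 1.0, maxRadius = 5.0) {
  if (pair@interfaceArea <= 0) stop("no interface")
  gv <- .gapVolume(pair, voxel, pairCutoff, minRadius, maxRadius)
  gv / pair@interfaceArea
}

.gapVolume <- function(pair, voxel, pairCutoff, minRadius, maxRadius) {
  A <- pair@reference; B <- pair@partner
  xa <- as.matrix(A[, c("x", "y", "z")])
  xb <- as.matrix(B[, c("x", "y", "z")])
  pr <- .pairsWithin(xa, xb, pairCutoff, strict = TRUE)
  if (!nrow(pr)) return(0)
  allXyz <- rbind(xa, xb)
  allR <- c(A$vdw, B$vdw)
  centers <- NULL; radii <- numeric(0)
  for (k in seq_len(nrow(pr))) {
    i <- pr$i[k]; j <- pr$j[k]
    d <- pr$d[k]
    gap <- d - A$vdw[i] - B$vdw[j]
    if (gap <= 0) next
    u <- (xb[j, ] - xa[i, ]) / d
    p <- xa[i, ] + u * (A$vdw[i] + gap / 2)
    r <- min(sqrt(colSums((t(allXyz) - p)^2)) - allR)
    if (r >= minRadius && r <= maxRadius) {
      centers <- rbind(centers, p)
      radii <- c(radii, r)
    }
  }
  if (!length(radii)) return(0)
  lo <- apply(centers - radii, 2, min)
  hi <- apply(centers + radii, 2, max)
  gx <- seq(lo[1], hi[1], by = voxel)
  gy <- seq(lo[2], hi[2], by = voxel)
  gz <- seq(lo[3], hi[3], by = voxel)
  inAny <- array(FALSE, c(length(gx), length(gy), length(gz)))
  for (k in seq_along(radii)) {
    dx2 <- (gx - centers[k, 1])^2
    dy2 <- (gy - centers[k, 2])^2
    dz2 <- (gz - centers[k, 3])^2
    r2 <- radii[k]^2
    ix <- which(dx2 <= r2)
    for (i in ix) {
      iy <- which(dx2[i] + dy2 <= r2)
      if (!length(iy)) next
      for (j in iy) {
        iz <- which(dx2[i] + dy2[j] + dz2 <= r2)
        if (length(iz)) inAny[i, j, iz] <- TRUE
      }
    }
  }
  sum(inAny) * voxel^3
}

#' Residue interface propensity score
#'
#' Per-type propensity ln(f_i / f_i0), where f_i is the area fraction
#' contributed by residue type i to the interface (per-atom ASA loss) and
#' f_i0 the fraction the type contributes to the protein surface. The
#' reference surface is that of the isolated molecules: every residue with
#' relative isolated ASA >= 5\% of its type maximum (interface residues are
#' surface residues in the monomer), weighted by isolated ASA. The score is
#' the sum of the propensities of all interface residues. Surface fractions
#' are floored at 0.5 / (number of surface residues) so types absent from
#' the surface stay finite.
#'
#' @param pair a \linkS4class{ContactPair}.
#' @param iface output of \code{\link{detectInterface}}.
#' @param surfaceReference optional named numeric of surface composition
#'   fractions by residue type; computed from the pair's own surface
#'   residues when omitted.
#' @return The propensity score (dimensionless; 0 when interface and surface
#'   compositions coincide).
#' @export
propensityScore <- function(pair, iface = detectInterface(pair),
                            surfaceReference = NULL) {
  both <- rbind(pair@reference, pair@partner)
  ids <- iface$interfaceAtoms
  if (!length(ids)) stop("no interface")
  labels <- iface$residueLabels
  resType <- vapply(split(both$resname, both$rid), `[`, character(1), 1)

  # interface area fractions by type
  rid <- setNames(both$rid, both$id)
  dIf <- iface$atomDelta[ids]
  typeOfAtom <- resType[rid[ids]]
  fI <- vapply(split(dIf, typeOfAtom), sum, numeric(1))
  fI <- fI / sum(fI)

  iso <- pair@asaIsolated
  isoRes <- vapply(split(iso[both$id], both$rid), sum, numeric(1))
  relIso <- isoRes / .maxAsa(resType[names(isoRes)])
  surfRes <- names(isoRes)[relIso >= 0.05]
  if (is.null(surfaceReference)) {
    if (!length(surfRes)) stop("no surface residues to build the reference")
    sIso <- isoRes[surfRes]
    f0 <- vapply(split(sIso, resType[surfRes]), sum, numeric(1))
    f0 <- f0 / sum(f0)
    nSurf <- length(surfRes)
  } else {
    f0 <- surfaceReference / sum(surfaceReference)
    nSurf <- max(length(surfaceReference), 20L)
  }
  floorVal <- 0.5 / nSurf
  lookup <- function(type) max(floorVal, if (type %in% names(f0)) f0[[type]] else 0)

  ifres <- names(labels)[startsWith(labels, "interface")]
  sum(vapply(ifres, function(r) {
    ty <- resType[[r]]
    log(fI[[ty]] / lookup(ty))
  }, numeric(1)))
}

#' Secondary-structure category of an interface
#'
#' Helix and strand content are the fractions of interface residues
#' annotated helix / strand. Category: alpha (helix > 30\%, strand not),
#' beta (strand > 30\%, helix not), alpha/beta (both > 30\%), coil
#' (neither); "more than 30\%" is strict, exactly 30\% counts as not more.
#'
#' @param pair a \linkS4class{ContactPair}.
#' @param iface output of \code{\link{detectInterface}}.
#' @param ss named character vector over residue ids
#'   (\code{"side|chain|ordinal"}) with values "helix"/"strand"/"other"; when
#'   omitted it is assigned from backbone dihedrals
#'   (\code{\link{assignSecondaryStructure}}).
#' @return One of \code{"alpha"}, \code{"beta"}, \code{"alpha/beta"},
#'   \code{"coil"}.
#' @export
ssCategory <- function(pair, iface = detectInterface(pair), ss = NULL) {
  labels <- iface$residueLabels
  ifres <- names(labels)[startsWith(labels, "interface")]
  if (!length(ifres)) stop("no interface")
  if (is.null(ss)) ss <- assignSecondaryStructure(pair)
  st <- ss[ifres]
  st[is.na(st)] <- "other"
  h <- mean(st == "helix"); e <- mean(st == "strand")
  if (h > 0.3 && e > 0.3) "alpha/beta"
  else if (h > 0.3) "alpha"
  else if (e > 0.3) "beta"
  else "coil"
}

#' Backbone-dihedral secondary structure assignment
#'
#' Fallback used when a structure carries no HELIX/SHEET records: phi/psi
#' windows (helix: -100 < phi < -30 and -80 < psi < -5 over >= 4 consecutive
#' residues; strand: phi < -100 and psi > 90 or psi < -170 over >= 3).
#'
#' @param pair a \linkS4class{ContactPair} (N/CA/C atom names required).
#' @return Named character vector over residue ids with values
#'   "helix"/"strand"/"other".
#' @export
assignSecondaryStructure <- function(pair) {
  both <- rbind(pair@reference, pair@partner)
  both$side <- substr(both$id, 1, 1)
  out <- character(0)
  for (grp in split(both, paste(both$side, both$chain, sep = "|"))) {
    ords <- sort(unique(grp$ordinal))
    getAtom <- function(o, nm) {
      r <- grp[grp$ordinal == o & grp$name == nm, c("x", "y", "z")]
      if (nrow(r) == 1L) as.numeric(r[1, ]) else NULL
    }
    phi <- psi <- setNames(rep(NA_real_, length(ords)), ords)
    for (k in seq_along(ords)) {
      o <- ords[k]
      N <- getAtom(o, "N"); CA <- getAtom(o, "CA"); C <- getAtom(o, "C")
      if (is.null(N) || is.null(CA) || is.null(C)) next
      if (k > 1) {
        Cp <- getAtom(ords[k - 1], "C")
        if (!is.null(Cp)) phi[k] <- .dihedral(Cp, N, CA, C)
      }
      if (k < length(ords)) {
        Nn <- getAtom(ords[k + 1], "N")
        if (!is.null(Nn)) psi[k] <- .dihedral(N, CA, C, Nn)
      }
    }
    isH <- !is.na(phi) & !is.na(psi) & phi > -100 & phi < -30 &
      psi > -80 & psi < -5
    isE <- !is.na(phi) & phi < -100 & !is.na(psi) & (psi > 90 | psi < -170)
    ss <- rep("other", length(ords))
    ss[.runsAtLeast(isH, 4L)] <- "helix"
    ss[.runsAtLeast(isE, 3L)] <- "strand"
    names(ss) <- paste(grp$side[1], grp$chain[1], ords, sep = "|")
    out <- c(out, ss)
  }
  out
}

## logical positions belonging to a TRUE-run of length >= k
.runsAtLeast <- function(flag, k) {
  r <- rle(flag)
  keep <- r$values & r$lengths >= k
  inverse.rle(list(values = keep, lengths = r$lengths))
}

#' Interface area ratio
#'
#' Interface area as a percentage of the reference molecule's total isolated
#' ASA.
#'
#' @param pair a \linkS4class{ContactPair}.
#' @return Percentage (0 when there is no interface).
#' @export
areaRatio <- function(pair) {
  refTotal <- sum(pair@asaIsolated[pair@reference$id])
  if (refTotal <= 0) stop("reference molecule has zero surface")
  100 * pair@interfaceArea / refTotal
}

#' Compute the full descriptor record of an interface
#'
#' Orchestrates interface detection and all descriptor computations for one
#' contact pair and returns them as a single
#' \linkS4class{InterfaceDescriptors} record. Errors from an empty interface
#' propagate.
#'
#' @param pair a \linkS4class{ContactPair}.
#' @param ss optional secondary-structure assignment (see
#'   \code{\link{ssCategory}}).
#' @param nbcCutoff non-bonded contact cutoff (angstrom).
#' @param ldRadius local-density radius (angstrom).
#' @return An \linkS4class{InterfaceDescriptors} object.
#' @export
computeAllDescriptors <- function(pair, ss = NULL, nbcCutoff = 3.9,
                                  ldRadius = 12) {
  iface <- detectInterface(pair)
  ids <- iface$interfaceAtoms
  labels <- iface$residueLabels
  ifres <- names(labels)[startsWith(labels, "interface")]
  if (!length(ids) || !length(ifres)) stop("no interface")
  new("InterfaceDescriptors",
      IA = pair@interfaceArea,
      IAratio = areaRatio(pair),
      Nnbc = as.integer(nonbondedContacts(pair, nbcCutoff)),
      nHB = as.integer(hydrogenBonds(pair)),
      Ns = as.integer(segmentCount(pair, iface)),
      nIfaceRes = length(ifres),
      nIfaceAtoms = length(ids),
      fBu = buriedFraction(pair, iface),
      fNp = nonpolarFraction(pair, iface),
      fCore = coreFraction(pair, iface),
      Rp = propensityScore(pair, iface),
      LD = localDensity(pair, iface, ldRadius),
      Igap = gapVolumeIndex(pair),
      ssCategory = ssCategory(pair, iface, ss))
}
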