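## Solvent-accessible surface area by Shrake-Rupley quadrature with a
## deterministic golden-spiral point set and NACCESS-compatible radii.

.VDW_RADII <- c(C = 1.87, N = 1.65, O = 1.40, S = 1.85)
.DEFAULT_RADIUS <- 1.8

#' Van der Waals radii for heavy atoms
#'
#' NACCESS-compatible radii: C 1.87, N 1.65, O 1.40, S 1.85 angstrom. Other
#' recognised elements (Se, P, metals) fall back to 1.8 angstrom with a
#' warning; an empty element symbol is an error.
#'
#' @param element character vector of element symbols.
#' @param serial optional atom serials used in error/warning messages.
#' @return Numeric vector of radii (angstrom).
#' @examples
#' vdwRadius(c("C", "N", "O", "S"))
#' @export
vdwRadius <- function(element, serial = seq_along(element)) {
  el <- toupper(trimws(element))
  bad <- !grepl("^[A-Z]{1,2}$", el)
  if (any(bad))
    stop("atom(s) with unknown element and no radius override: serial ",
         paste(serial[bad], collapse = ", "))
  r <- unname(.VDW_RADII[el])
  odd <- is.na(r)
  if (any(odd)) {
    warning("no tabulated radius for element(s) ",
            paste(unique(el[odd]), collapse = ", "),
            "; using ", .DEFAULT_RADIUS, " A")
    r[odd] <- .DEFAULT_RADIUS
  }
  r
}

## deterministic, approximately uniform unit-sphere point set (golden spiral)
.goldenSpiral <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent-accessible surface area
#'
#' Shrake-Rupley rolling-probe quadrature: each atom's sphere of radius
#' r_vdw + probe is sampled at \code{nPoints} deterministic golden-spiral
#' points; the accessible fraction (points outside every neighbour's expanded
#' sphere) times the sphere area gives the atom's ASA.
#'
#' @param atoms data.frame with columns \code{x}, \code{y}, \code{z} and
#'   either \code{vdw} (radii) or \code{element}; optional \code{id} (atom
#'   key, default serial or row number) and \code{chain}/\code{ordinal} (or
#'   \code{rid}) for per-residue sums.
#' @param probeRadius probe sphere radius in angstrom (water: 1.4).
#' @param nPoints quadrature points per atom (>= 92; default 960).
#' @param method neighbour search: \code{"grid"} spatial hashing (default) or
#'   \code{"brute"} full distance matrix (identical results).
#' @return An \linkS4class{AsaResult}.
#' @examples
#' a <- data.frame(x = 0, y = 0, z = 0, element = "C")
#' totalAsa(computeAsa(a))          # ~ 4*pi*(1.87+1.4)^2
#' @export
computeAsa <- function(atoms, probeRadius = 1.4, nPoints = 960L,
                       method = c("grid", "brute")) {
  method <- match.arg(method)
  stopifnot(nPoints >= 92L)
  n <- nrow(atoms)
  if (n == 0L) stop("no atoms")
  if (is.null(atoms$vdw)) {
    atoms$vdw <- vdwRadius(atoms$element,
                           if (!is.null(atoms$serial)) atoms$serial
                           else seq_len(n))
  }
  ids <- if (!is.null(atoms$id)) atoms$id
         else if (!is.null(atoms$serial)) as.character(atoms$serial)
         else as.character(seq_len(n))
  if (anyDuplicated(ids)) stop("atom ids must be unique")
  rids <- if (!is.null(atoms$rid)) atoms$rid
          else if (!is.null(atoms$chain)) paste(atoms$chain, atoms$ordinal,
                                                sep = "|")
          else rep("1", n)
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  R <- atoms$vdw + probeRadius
  sphere <- .goldenSpiral(as.integer(nPoints))
  # neighbour candidates: centre distance < R_i + R_j
  maxR <- max(R)
  nb <- .neighborListExpanded(xyz, R, 2 * maxR, method)
  asa <- numeric(n)
  for (i in seq_len(n)) {
    pts <- sphere * R[i]
    pts <- sweep(pts, 2, xyz[i, ], "+")
    js <- nb[[i]]
    acc <- rep(TRUE, nrow(pts))
    if (length(js)) {
      cj <- xyz[js, , drop = FALSE]
      d2 <- outer(rowSums(pts^2), rowSums(cj^2), "+") - 2 * pts %*% t(cj)
      inside <- sweep(d2, 2, R[js]^2, "<")
      acc <- rowSums(inside) == 0L
    }
    asa[i] <- mean(acc) * 4 * pi * R[i]^2
  }
  names(asa) <- ids
  perRes <- vapply(split(asa, rids), sum, numeric(1))
  new("AsaResult", perAtom = asa, perResidue = perRes, total = sum(asa),
      probeRadius = probeRadius, nPoints = as.integer(nPoints))
}

## for each atom, indices of atoms with centre distance < R_i + R_j
.neighborListExpanded <- function(xyz, R, maxCut, method) {
  n <- nrow(xyz)
  if (method == "brute" || n <= 64L) {
    d2 <- outer(rowSums(xyz^2), rowSums(xyz^2), "+") - 2 * tcrossprod(xyz)
    d <- sqrt(pmax(d2, 0))
    lim <- outer(R, R, "+")
    hit <- d < lim
    diag(hit) <- FALSE
    return(lapply(seq_len(n), function(i) which(hit[i, ])))
  }
  cells <- floor(xyz / maxCut)
  key <- paste(cells[, 1], cells[, 2], cells[, 3])
  idx <- split(seq_len(n), key)
  off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  lapply(seq_len(n), function(i) {
    cand <- integer(0)
    for (k in seq_len(nrow(off))) {
      kk <- paste(cells[i, 1] + off[k, 1], cells[i, 2] + off[k, 2],
                  cells[i, 3] + off[k, 3])
      cand <- c(cand, idx[[kk]])
    }
    cand <- cand[cand != i]
    if (!length(cand)) return(integer(0))
    d <- sqrt(colSums((t(xyz[cand, , drop = FALSE]) - xyz[i, ])^2))
    cand[d < R[i] + R[cand]]
  })
}

#' @describeIn computeAsa total ASA of an \linkS4class{AsaResult}.
#' @param x an \linkS4class{AsaResult}.
#' @export
totalAsa <- function(x) x@total

#' @describeIn computeAsa named per-atom ASA map.
#' @export
perAtomAsa <- function(x) x@perAtom

#' @describeIn computeAsa named per-residue ASA map.
#' @export
perResidueAsa <- function(x) x@perResidue

#' ASA loss upon complexation
#'
#' Per-atom and per-residue differences ASA_isolated - ASA_complex for a
#' two-molecule system. Values below the quadrature noise floor (1e-6) are
#' clamped to zero. A residue losing more than 1 square angstrom is an
#' interface residue under the standard definition.
#'
#' @param isolatedA,isolatedB \linkS4class{AsaResult} of each molecule alone.
#' @param complexed \linkS4class{AsaResult} of the union of the same atoms
#'   (same ids).
#' @return list with named numeric \code{perAtom} and \code{perResidue} maps.
#' @export
deltaAsa <- function(isolatedA, isolatedB, complexed) {
  iso <- c(isolatedA@perAtom, isolatedB@perAtom)
  comp <- complexed@perAtom
  miss <- c(setdiff(names(iso), names(comp)), setdiff(names(comp), names(iso)))
  if (length(miss))
    stop("atom ids do not match between isolated and complexed results: ",
         paste(utils::head(miss, 10), collapse = ", "))
  d <- iso - comp[names(iso)]
  d[d < 1e-6] <- 0
  isoR <- c(isolatedA@perResidue, isolatedB@perResidue)
  compR <- complexed@perResidue
  dR <- isoR - compR[names(isoR)]
  dR[dR < 1e-6] <- 0
  list(perAtom = d, perResidue = dR)
}
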