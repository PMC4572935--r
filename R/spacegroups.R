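## Space-group symmetry operators and crystallographic frame conversions.
##
## The built-in table covers triclinic P 1 plus the nine groups that dominate
## monomeric protein crystals (all primitive/C-centred monoclinic,
## orthorhombic, tetragonal 41/43 screw and trigonal 31/32 screw groups).
## Operators are entered as International Tables coordinate triplets;
## C-centred groups additionally get the (1/2,1/2,0) centring copies.

.SG_TRIPLETS <- list(
  "P 1" = c("x,y,z"),
  "P 1 21 1" = c("x,y,z", "-x,y+1/2,-z"),
  "C 1 2 1" = c("x,y,z", "-x,y,-z",
                "x+1/2,y+1/2,z", "-x+1/2,y+1/2,-z"),
  "P 21 21 2" = c("x,y,z", "-x,-y,z",
                  "-x+1/2,y+1/2,-z", "x+1/2,-y+1/2,-z"),
  "P 21 21 21" = c("x,y,z", "-x+1/2,-y,z+1/2",
                   "-x,y+1/2,-z+1/2", "x+1/2,-y+1/2,-z"),
  "C 2 2 21" = c("x,y,z", "-x,-y,z+1/2", "-x,y,-z+1/2", "x,-y,-z",
                 "x+1/2,y+1/2,z", "-x+1/2,-y+1/2,z+1/2",
                 "-x+1/2,y+1/2,-z+1/2", "x+1/2,-y+1/2,-z"),
  "P 41 21 2" = c("x,y,z", "-x,-y,z+1/2",
                  "-y+1/2,x+1/2,z+1/4", "y+1/2,-x+1/2,z+3/4",
                  "-x+1/2,y+1/2,-z+1/4", "x+1/2,-y+1/2,-z+3/4",
                  "y,x,-z", "-y,-x,-z+1/2"),
  "P 43 21 2" = c("x,y,z", "-x,-y,z+1/2",
                  "-y+1/2,x+1/2,z+3/4", "y+1/2,-x+1/2,z+1/4",
                  "-x+1/2,y+1/2,-z+3/4", "x+1/2,-y+1/2,-z+1/4",
                  "y,x,-z", "-y,-x,-z+1/2"),
  "P 31 2 1" = c("x,y,z", "-y,x-y,z+1/3", "-x+y,-x,z+2/3",
                 "y,x,-z", "x-y,-y,-z+2/3", "-x,-x+y,-z+1/3"),
  "P 32 2 1" = c("x,y,z", "-y,x-y,z+2/3", "-x+y,-x,z+1/3",
                 "y,x,-z", "x-y,-y,-z+1/3", "-x,-x+y,-z+2/3")
)

## short Hermann-Mauguin spellings seen in CRYST1 records
.SG_ALIASES <- c("P1" = "P 1", "P 21" = "P 1 21 1", "P 2 21 21" = "P 21 21 2",
                 "C 2" = "C 1 2 1", "C 1 21 1" = "P 1 21 1")

#' Supported space groups
#'
#' Hermann-Mauguin symbols for which built-in symmetry operators are
#' available: triclinic \code{P 1} plus the nine groups most frequently
#' observed in monomeric protein crystals.
#'
#' @return Character vector of space-group symbols.
#' @examples
#' supportedSpaceGroups()
#' @export
supportedSpaceGroups <- function() names(.SG_TRIPLETS)

.normalizeSpaceGroup <- function(symbol) {
  s <- toupper(trimws(gsub("\\s+", " ", symbol)))
  if (s %in% names(.SG_ALIASES)) s <- unname(.SG_ALIASES[s])
  s
}

## parse one coordinate triplet ("-y,x-y,z+1/3") into a 3x3 rotation and a
## fractional translation 3-vector
.parseTriplet <- function(triplet) {
  parts <- strsplit(gsub(" ", "", triplet), ",", fixed = TRUE)[[1]]
  if (length(parts) != 3L)
    stop("malformed symmetry triplet: ", triplet)
  R <- matrix(0, 3, 3)
  t <- numeric(3)
  for (i in 1:3) {
    expr <- parts[i]
    # tokenize signed terms
    expr <- gsub("-", "+-", expr, fixed = TRUE)
    terms <- strsplit(expr, "+", fixed = TRUE)[[1]]
    terms <- terms[nzchar(terms)]
    for (tm in terms) {
      sign <- 1
      if (startsWith(tm, "-")) { sign <- -1; tm <- substring(tm, 2) }
      if (tm %in% c("x", "y", "z")) {
        R[i, match(tm, c("x", "y", "z"))] <- sign
      } else if (grepl("^[0-9]+/[0-9]+$", tm)) {
        f <- as.numeric(strsplit(tm, "/", fixed = TRUE)[[1]])
        t[i] <- t[i] + sign * f[1] / f[2]
      } else if (grepl("^[0-9.]+$", tm)) {
        t[i] <- t[i] + sign * as.numeric(tm)
      } else stop("cannot parse symmetry term '", tm, "' in ", triplet)
    }
  }
  list(R = R, t = t)
}

#' Symmetry operators for a space group
#'
#' Looks up the built-in operator table and returns the symmetry operators of
#' a space group as rotation matrices and fractional translations.
#'
#' @param symbol Hermann-Mauguin space-group symbol (e.g. \code{"P 21 21 21"}).
#'   A few common short spellings (\code{"P 21"}, \code{"C 2"}) are accepted.
#' @return A list of operators, each a list with elements \code{R} (3x3
#'   integer rotation matrix, fractional basis) and \code{t} (length-3
#'   fractional translation).
#' @examples
#' length(spaceGroupOperators("P 21 21 21"))  # 4
#' @export
spaceGroupOperators <- function(symbol) {
  s <- .normalizeSpaceGroup(symbol)
  if (!s %in% names(.SG_TRIPLETS))
    stop("unknown space-group symbol '", symbol, "'; supported symbols: ",
         paste(supportedSpaceGroups(), collapse = ", "))
  lapply(.SG_TRIPLETS[[s]], .parseTriplet)
}

#' Crystal frame matrix
#'
#' Matrix sending fractional coordinates to Cartesian angstroms for a unit
#' cell, using the PDB convention (cell edge a along x, b in the xy plane).
#'
#' @param cell Numeric of length 6: a, b, c in angstroms, then alpha, beta,
#'   gamma in degrees.
#' @return 3x3 orthogonalization matrix; Cartesian = M \%*\% fractional.
#' @examples
#' cellMatrix(c(10, 10, 10, 90, 90, 90))
#' @export
cellMatrix <- function(cell) {
  stopifnot(length(cell) == 6L)
  if (any(cell[1:3] <= 0)) stop("cell edges must be positive")
  if (any(cell[4:6] <= 0 | cell[4:6] >= 180))
    stop("cell angles must lie in (0, 180) degrees")
  a <- cell[1]; b <- cell[2]; c <- cell[3]
  al <- cell[4] * pi / 180; be <- cell[5] * pi / 180; ga <- cell[6] * pi / 180
  v <- sqrt(1 - cos(al)^2 - cos(be)^2 - cos(ga)^2 +
              2 * cos(al) * cos(be) * cos(ga))
  matrix(c(a, b * cos(ga), c * cos(be),
           0, b * sin(ga), c * (cos(al) - cos(be) * cos(ga)) / sin(ga),
           0, 0, c * v / sin(ga)),
         nrow = 3, byrow = TRUE)
}

## apply operator (R,t in fractional basis) + integer lattice shift to an
## n x 3 Cartesian coordinate matrix
.applySymOp <- function(xyz, op, shift, M, Minv) {
  frac <- t(Minv %*% t(xyz))
  frac2 <- t(op$R %*% t(frac)) +
    matrix(op$t + shift, nrow(frac), 3, byrow = TRUE)
  t(M %*% t(frac2))
}

.isIdentityOp <- function(op, tol = 1e-9) {
  all(abs(op$R - diag(3)) < tol) && all(abs(op$t) < tol)
}
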