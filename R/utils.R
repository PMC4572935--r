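## Internal helpers shared across modules.

## run code under a fixed RNG seed without disturbing the caller's stream
.withSeed <- function(seed, code) {
  if (is.null(seed) || length(seed) != 1L || is.na(seed))
    stop("a single integer 'seed' must be supplied")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

.AA3 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
          GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
          MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
          TYR = "Y", VAL = "V")

## theoretical maximum residue ASA (A^2), Gly-X-Gly based; used for the
## relative-accessibility surface/interior split
.MAX_ASA <- c(ALA = 129, ARG = 274, ASN = 195, ASP = 193, CYS = 167,
              GLN = 225, GLU = 223, GLY = 104, HIS = 224, ILE = 197,
              LEU = 201, LYS = 236, MET = 224, PHE = 240, PRO = 159,
              SER = 155, THR = 172, TRP = 285, TYR = 263, VAL = 174)

.maxAsa <- function(resname) {
  out <- unname(.MAX_ASA[resname])
  out[is.na(out)] <- 200
  out
}

## Count, for each row of xyzA, the rows of xyzB strictly/loosely within
## `cutoff`. method "grid" bins atoms into cells of edge `cutoff` and only
## scans the 27 surrounding cells; "brute" uses the full distance matrix.
## Returns an integer vector over rows of xyzA. `strict` selects d < cutoff
## versus d <= cutoff. With self = TRUE (xyzB missing) the atom itself is
## excluded from its own count.
.neighborCounts <- function(xyzA, xyzB = NULL, cutoff, strict = TRUE,
                            method = c("grid", "brute")) {
  method <- match.arg(method)
  self <- is.null(xyzB)
  if (self) xyzB <- xyzA
  nA <- nrow(xyzA); nB <- nrow(xyzB)
  if (nA == 0L || nB == 0L) return(integer(nA))
  cmp <- if (strict) `<` else `<=`
  if (method == "brute") {
    d2 <- outer(rowSums(xyzA^2), rowSums(xyzB^2), "+") -
      2 * xyzA %*% t(xyzB)
    hits <- cmp(sqrt(pmax(d2, 0)), cutoff)
    n <- as.integer(rowSums(hits))
    if (self) n <- n - 1L  # self-distance 0 always counted
    return(n)
  }
  cellsA <- floor(sweep(xyzA, 2, rep(cutoff, 3), "/"))
  cellsB <- floor(sweep(xyzB, 2, rep(cutoff, 3), "/"))
  keyB <- paste(cellsB[, 1], cellsB[, 2], cellsB[, 3])
  idxB <- split(seq_len(nB), keyB)
  n <- integer(nA)
  off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  for (i in seq_len(nA)) {
    cand <- integer(0)
    for (k in seq_len(nrow(off))) {
      key <- paste(cellsA[i, 1] + off[k, 1], cellsA[i, 2] + off[k, 2],
                   cellsA[i, 3] + off[k, 3])
      cand <- c(cand, idxB[[key]])
    }
    if (!length(cand)) next
    d <- sqrt(colSums((t(xyzB[cand, , drop = FALSE]) - xyzA[i, ])^2))
    n[i] <- sum(cmp(d, cutoff)) - if (self) 1L else 0L
  }
  n
}

## index pairs (i in A, j in B) with distance < / <= cutoff
.pairsWithin <- function(xyzA, xyzB, cutoff, strict = TRUE) {
  nA <- nrow(xyzA); nB <- nrow(xyzB)
  if (nA == 0L || nB == 0L)
    return(data.frame(i = integer(0), j = integer(0), d = numeric(0)))
  d2 <- outer(rowSums(xyzA^2), rowSums(xyzB^2), "+") - 2 * xyzA %*% t(xyzB)
  d <- sqrt(pmax(d2, 0))
  hits <- which(if (strict) d < cutoff else d <= cutoff, arr.ind = TRUE)
  data.frame(i = hits[, 1], j = hits[, 2], d = d[hits])
}

## dihedral angle (degrees, in (-180, 180]) defined by four points
.dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2], n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1])
  x <- sum(n1 * n2)
  y <- sum(m1 * n2) / sqrt(sum(b2^2))
  atan2(y, x) * 180 / pi
}

## round half away from zero (base round() rounds half to even)
.roundHalfAway <- function(x) sign(x) * floor(abs(x) + 0.5)
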