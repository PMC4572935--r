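## Seeded generators: toy dimers with tunable contact geometry, toy crystals
## with designed packing contacts, synthetic alignments with controlled
## conservation, and descriptor tables drawn from literature-reported group
## statistics. Every generator is deterministic under its seed.

.HYDROPHOBIC_RES <- c("LEU", "VAL", "ILE", "MET", "PHE", "ALA")
.POLAR_RES <- c("SER", "THR", "ASN", "GLN", "LYS", "ARG", "ASP", "GLU")

#' Synthetic two-chain dimer with tunable interface
#'
#' Builds two pseudo-residue chains (three backbone atoms N/CA/C plus one
#' side-chain sphere CB per residue) laid out as flat square patches whose
#' side chains face each other. \code{overlapDepth} controls how far the two
#' side-chain layers interpenetrate: the centre separation of the facing CB
#' layers is 2 r_vdw + \code{standoff} - \code{overlapDepth}, so deeper
#' overlap buries more surface and increases the interface area
#' monotonically. Side-chain elements are carbon for hydrophobic residues
#' and N/O for polar ones, drawn to match \code{hydrophobicFraction}.
#'
#' @param nResiduesPerChain residues per chain (default 36, a 6 x 6 patch).
#' @param overlapDepth inter-surface penetration in angstrom (>= 0).
#' @param hydrophobicFraction probability that a residue is hydrophobic
#'   (default 0.6, the typical non-polar area fraction of protein-protein
#'   interfaces).
#' @param packingJitter uniform coordinate jitter amplitude in angstrom
#'   (default 0.25).
#' @param standoff extra separation between the side-chain surfaces
#'   (default 0: surfaces touch at zero overlap).
#' @param seed RNG seed (mandatory).
#' @return A two-chain \linkS4class{StructureModel} (chains A and B) in a
#'   large P 1 cell.
#' @export
makeToyDimer <- function(nResiduesPerChain = 36L, overlapDepth = 1.5,
                         hydrophobicFraction = 0.6, packingJitter = 0.25,
                         standoff = 0, seed) {
  stopifnot(overlapDepth >= 0, hydrophobicFraction >= 0,
            hydrophobicFraction <= 1, packingJitter >= 0)
  rCB <- 1.87
  if (overlapDepth > 2 * rCB + standoff)
    stop(sprintf("overlap too deep: %.2f A exceeds the %.2f A side-chain layer depth, atoms would clash",
                 overlapDepth, 2 * rCB + standoff))
  .withSeed(seed, {
    s <- 4.5                       # residue grid spacing, angstrom
    nx <- ceiling(sqrt(nResiduesPerChain))
    zCB_B <- 2.0 + 2 * rCB + standoff - overlapDepth
    rows <- list()
    serial <- 0L
    for (chain in c("A", "B")) {
      for (k in seq_len(nResiduesPerChain) - 1L) {
        i <- k %% nx; j <- k %/% nx
        hydro <- stats::runif(1) < hydrophobicFraction
        resname <- if (hydro) sample(.HYDROPHOBIC_RES, 1)
                   else sample(.POLAR_RES, 1)
        cbElement <- if (hydro) "C" else sample(c("N", "O"), 1)
        if (chain == "A") {
          base <- c(i * s, j * s, 0)
          offs <- list(N = c(-1.2, 0.45, -0.35), CA = c(0, 0, 0),
                       C = c(1.2, 0.45, -0.35), CB = c(0, 0, 2.0))
        } else {
          base <- c(i * s + s / 2, j * s + s / 2, zCB_B + 2.0)
          offs <- list(N = c(-1.2, 0.45, 0.35), CA = c(0, 0, 0),
                       C = c(1.2, 0.45, 0.35), CB = c(0, 0, -2.0))
        }
        el <- c(N = "N", CA = "C", C = "C", CB = cbElement)
        for (nm in names(offs)) {
          serial <- serial + 1L
          p <- base + offs[[nm]] +
            stats::runif(3, -packingJitter, packingJitter)
          rows[[serial]] <- data.frame(
            serial = serial, name = nm, element = unname(el[nm]),
            chain = chain, resname = resname, resseq = k + 1L, icode = "",
            x = p[1], y = p[2], z = p[3], hetero = FALSE, water = FALSE,
            ordinal = k)
        }
      }
    }
    df <- do.call(rbind, rows)
    df$vdw <- vdwRadius(df$element)
    df$polarity <- ifelse(df$element == "C", "nonpolar", "polar")
    xyzA <- as.matrix(df[df$chain == "A", c("x", "y", "z")])
    xyzB <- as.matrix(df[df$chain == "B", c("x", "y", "z")])
    d2 <- outer(rowSums(xyzA^2), rowSums(xyzB^2), "+") - 2 * tcrossprod(xyzA, xyzB)
    if (min(d2) < 1.5^2)
      stop(sprintf("overlap too deep: minimal inter-chain distance %.2f A < 1.5 A",
                   sqrt(max(0, min(d2)))))
    new("StructureModel", atoms = df,
        cell = c(500, 500, 500, 90, 90, 90), spaceGroup = "P 1",
        symOps = spaceGroupOperators("P 1"), resolution = NA_real_,
        ssRecords = data.frame(chain = character(0), ordinal = integer(0),
                               ss = character(0)),
        nModelsInAsu = 1L, isCalphaOnly = FALSE)
  })
}

#' Toy crystal with designed packing contacts
#'
#' Wraps a single chain into a crystal (CRYST1 + coordinates). For P 1
#' crystals the number of distinct packing contacts is known by
#' construction: every non-zero lattice translation within two shells is
#' checked for heavy-atom contact at \code{contactCutoff}, and translation
#' pairs s/-s describe the same interface, so the designed count is half the
#' number of touching translations. For other space groups the designed
#' count is NA (the full enumeration is the only route).
#'
#' @param structure a \linkS4class{StructureModel} whose first chain is used
#'   as the asymmetric unit content.
#' @param cell numeric(6) unit cell.
#' @param sg Hermann-Mauguin space-group symbol (must be supported).
#' @param contactCutoff contact distance used for the design count.
#' @return list with \code{text} (PDB text), \code{structure} (the re-read
#'   \linkS4class{StructureModel}) and \code{designedContacts} (integer or
#'   NA).
#' @export
makeToyCrystal <- function(structure, cell, sg = "P 1", contactCutoff = 5) {
  sgn <- .normalizeSpaceGroup(sg)
  if (!sgn %in% supportedSpaceGroups())
    stop("unsupported space group '", sg, "'; supported: ",
         paste(supportedSpaceGroups(), collapse = ", "))
  a <- structure@atoms
  a <- a[a$chain == a$chain[1] & !a$water, , drop = FALSE]
  ext <- c(diff(range(a$x)), diff(range(a$y)), diff(range(a$z)))
  if (any(ext > cell[1:3]))
    stop("chain does not fit in the cell (extent ",
         paste(sprintf("%.1f", ext), collapse = " x "), " A)")
  model <- new("StructureModel", atoms = a, cell = cell, spaceGroup = sgn,
               symOps = spaceGroupOperators(sgn), resolution = NA_real_,
               ssRecords = data.frame(chain = character(0),
                                      ordinal = integer(0),
                                      ss = character(0)),
               nModelsInAsu = 1L, isCalphaOnly = structure@isCalphaOnly)
  designed <- NA_integer_
  if (sgn == "P 1") {
    M <- cellMatrix(cell)
    xyz <- as.matrix(a[!a$hetero, c("x", "y", "z")])
    shifts <- as.matrix(expand.grid(-2:2, -2:2, -2:2))
    shifts <- shifts[rowSums(abs(shifts)) > 0, , drop = FALSE]
    touching <- 0L
    for (k in seq_len(nrow(shifts))) {
      tvec <- as.numeric(M %*% shifts[k, ])
      moved <- sweep(xyz, 2, tvec, "+")
      if (sum(.neighborCounts(xyz, moved, contactCutoff,
                              strict = FALSE, method = "brute")) > 0L)
        touching <- touching + 1L
    }
    designed <- touching %/% 2L
  }
  list(text = writeStructure(model), structure = model,
       designedContacts = designed)
}

#' Synthetic multiple sequence alignment with controlled conservation
#'
#' Per column, a consensus class (of the ten reduced classes) is chosen and
#' each sequence draws the consensus with probability p (the column's
#' conservation) or one of the other nine classes uniformly; residues are
#' the class representatives, so column entropies are fully determined by
#' the class draws.
#'
#' @param length alignment length.
#' @param nSequences number of sequences.
#' @param conservationProfile per-column consensus probability in [0, 1]
#'   (recycled; default 0.95).
#' @param seed RNG seed (mandatory).
#' @return An \linkS4class{MsaProfile}.
#' @export
makeSyntheticMsa <- function(length, nSequences, conservationProfile = 0.95,
                             seed) {
  stopifnot(all(conservationProfile >= 0), all(conservationProfile <= 1),
            length >= 1L, nSequences >= 2L)
  reps <- c("L", "C", "A", "G", "S", "P", "F", "E", "K", "H")
  p <- rep_len(conservationProfile, length)
  .withSeed(seed, {
    consensus <- sample.int(10L, length, replace = TRUE)
    mat <- matrix("", nSequences, length)
    for (j in seq_len(length)) {
      hit <- stats::runif(nSequences) < p[j]
      other <- sample((1:10)[-consensus[j]], nSequences, replace = TRUE)
      mat[, j] <- reps[ifelse(hit, consensus[j], other)]
    }
    seqs <- apply(mat, 1, paste, collapse = "")
    names(seqs) <- paste0("seq", seq_len(nSequences))
    new("MsaProfile", sequences = seqs, referenceIndex = 1L)
  })
}

#' Literature-reported per-class descriptor statistics
#'
#' Mean and standard deviation of each interface descriptor for the four
#' interaction classes (general and large crystal packing contacts, weak
#' transient complexes, permanent homodimers), with the physical bounds used
#' for truncated sampling. Fractions are on the percent scale.
#'
#' @return data.frame with columns \code{descriptor}, \code{class},
#'   \code{mean}, \code{sd}, \code{lower}, \code{upper}.
#' @export
referenceClassParams <- function() {
  classes <- c("general_cp", "large_cp", "weak_ppi", "strong_ppi")
  spec <- list(
    n_iface_res   = list(m = c(35, 84, 42, 104),  s = c(10, 32, 12, 50),  lo = 0, hi = Inf),
    n_iface_atoms = list(m = c(115, 306, 151, 400), s = c(31, 133, 42, 198), lo = 0, hi = Inf),
    Nnbc          = list(m = c(52, 169, 82, 216), s = c(22, 99, 31, 127), lo = 0, hi = Inf),
    Ns            = list(m = c(7, 12, 7, 12),     s = c(3, 4, 3, 6),      lo = 0, hi = Inf),
    nHB           = list(m = c(2, 7, 4, 10),      s = c(2, 6, 3, 8),      lo = 0, hi = Inf),
    IA            = list(m = c(531, 1472, 718, 1950), s = c(147, 661, 195, 986), lo = 0, hi = Inf),
    IA_ratio      = list(m = c(6, 11, 9, 16),     s = c(3, 6, 4, 7),      lo = 0, hi = 100),
    f_np          = list(m = c(56, 61, 60, 66),   s = c(9, 8, 8, 4),      lo = 0, hi = 100),
    f_core        = list(m = c(56, 67, 69, 77),   s = c(16, 16, 15, 10),  lo = 0, hi = 100),
    f_bu          = list(m = c(20, 29, 29, 37),   s = c(8, 11, 9, 9),     lo = 0, hi = 100),
    R_p           = list(m = c(-1.1, 0.4, 0.8, 4.3), s = c(2.1, 5.0, 2.5, 5.2), lo = -Inf, hi = Inf),
    LD            = list(m = c(29, 39, 35, 45),   s = c(5, 8, 6, 8),      lo = 0, hi = Inf),
    I_gap         = list(m = c(10, 6, 6, 4),      s = c(5, 4, 3, 2),      lo = 0, hi = Inf))
  do.call(rbind, lapply(names(spec), function(d) {
    w <- spec[[d]]
    data.frame(descriptor = d, class = classes, mean = w$m, sd = w$s,
               lower = w$lo, upper = w$hi)
  }))
}

#' Reported group sizes of the four interaction classes
#'
#' @return Named integer vector (general_cp 681, large_cp 92, weak_ppi 103,
#'   strong_ppi 113).
#' @export
referenceClassSizes <- function() {
  c(general_cp = 681L, large_cp = 92L, weak_ppi = 103L, strong_ppi = 113L)
}

#' Sample a synthetic descriptor table
#'
#' Draws per-class descriptor values from truncated normal distributions
#' (inverse-CDF sampling between the physical bounds) parameterised by the
#' literature-reported group means/SDs, or any compatible parameter table.
#'
#' @param nPerClass named integer vector of rows per class (default the
#'   reported group sizes).
#' @param classParams parameter table as from
#'   \code{\link{referenceClassParams}}.
#' @param seed RNG seed (mandatory).
#' @return data.frame with a \code{class} column and one column per
#'   descriptor.
#' @export
sampleDescriptorTable <- function(nPerClass = referenceClassSizes(),
                                  classParams = referenceClassParams(),
                                  seed) {
  stopifnot(all(classParams$sd >= 0))
  .withSeed(seed, {
    descriptors <- unique(classParams$descriptor)
    out <- list()
    for (cl in names(nPerClass)) {
      n <- nPerClass[[cl]]
      df <- data.frame(class = rep(cl, n))
      for (d in descriptors) {
        row <- classParams[classParams$descriptor == d &
                             classParams$class == cl, ]
        if (nrow(row) != 1L)
          stop("no parameters for descriptor '", d, "' in class '", cl, "'")
        df[[d]] <- .rtruncnorm(n, row$mean, row$sd, row$lower, row$upper)
      }
      out[[cl]] <- df
    }
    res <- do.call(rbind, out)
    row.names(res) <- NULL
    res
  })
}

## inverse-CDF truncated normal draws
.rtruncnorm <- function(n, mean, sd, lower, upper) {
  if (sd == 0) return(rep(mean, n))
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}
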