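#' @import methods
NULL

#' StructureModel: a parsed crystal structure
#'
#' Container for a PDB-format crystal structure: atom table, unit cell,
#' space-group operators, crystallographic resolution and secondary-structure
#' annotations. Create with \code{\link{readStructure}} or the synthetic
#' generators.
#'
#' @slot atoms data.frame with one row per heavy atom (columns \code{serial},
#'   \code{name}, \code{element}, \code{chain}, \code{resname}, \code{resseq},
#'   \code{ordinal} (0-based position in the chain's residue list), \code{x},
#'   \code{y}, \code{z}, \code{hetero}, \code{water}, \code{vdw},
#'   \code{polarity}).
#' @slot cell numeric(6): a, b, c (angstrom), alpha, beta, gamma (degrees);
#'   length 0 when the file carries no CRYST1 record.
#' @slot spaceGroup Hermann-Mauguin symbol, or NA when unknown.
#' @slot symOps list of symmetry operators (\code{R} 3x3 rotation and \code{t}
#'   translation, fractional basis).
#' @slot resolution crystallographic resolution in angstrom (NA when absent).
#' @slot ssRecords data.frame (\code{chain}, \code{ordinal}, \code{ss}) of
#'   helix/strand assignments from HELIX/SHEET records.
#' @slot nModelsInAsu number of MODEL blocks (1 for ordinary crystal entries).
#' @slot isCalphaOnly TRUE when every protein atom is a C-alpha.
#' @export
setClass("StructureModel", representation(
  atoms = "data.frame", cell = "numeric", spaceGroup = "character",
  symOps = "list", resolution = "numeric", ssRecords = "data.frame",
  nModelsInAsu = "integer", isCalphaOnly = "logical"),
  prototype(cell = numeric(0), spaceGroup = NA_character_, symOps = list(),
            resolution = NA_real_,
            ssRecords = data.frame(chain = character(), ordinal = integer(),
                                   ss = character()),
            nModelsInAsu = 1L, isCalphaOnly = FALSE))

setValidity("StructureModel", function(object) {
  msgs <- character()
  if (length(object@cell) > 0) {
    if (length(object@cell) != 6L) msgs <- c(msgs, "cell must have 6 values")
    else {
      if (any(object@cell[1:3] <= 0)) msgs <- c(msgs, "cell edges must be > 0")
      if (any(object@cell[4:6] <= 0 | object@cell[4:6] >= 180))
        msgs <- c(msgs, "cell angles must lie in (0, 180)")
      if (length(object@symOps) > 0) {
        M <- cellMatrix(object@cell); Minv <- solve(M)
        for (op in object@symOps) {
          Rc <- M %*% op$R %*% Minv
          if (max(abs(t(Rc) %*% Rc - diag(3))) > 1e-6) {
            msgs <- c(msgs, "symmetry rotation not orthonormal in Cartesian frame")
            break
          }
        }
      }
    }
  }
  needed <- c("serial", "name", "element", "chain", "resname", "resseq",
              "ordinal", "x", "y", "z", "hetero", "water", "vdw", "polarity")
  if (!all(needed %in% names(object@atoms)))
    msgs <- c(msgs, paste("atoms table lacks columns:",
                          paste(setdiff(needed, names(object@atoms)),
                                collapse = ", ")))
  if (length(msgs)) msgs else TRUE
})

#' SymmetryMate: a symmetry-related copy of the reference molecule
#'
#' @slot opIndex index of the generating symmetry operator (1-based, 1 is the
#'   identity).
#' @slot latticeShift integer(3) lattice translation in cell units.
#' @slot atoms transformed atom table (same columns as the reference).
#' @export
setClass("SymmetryMate", representation(
  opIndex = "integer", latticeShift = "integer", atoms = "data.frame"))

#' ContactPair: two molecules in contact with their accessibility bookkeeping
#'
#' Holds the reference and partner atom sets of one protein-protein contact
#' together with per-atom solvent accessibilities computed for each molecule
#' in isolation and for the complex, and the resulting interface area. Atom
#' ids are \code{"A|serial"} (reference) and \code{"B|serial"} (partner);
#' residue ids are \code{"side|chain|ordinal"}.
#'
#' @slot reference,partner atom data.frames carrying \code{id} and \code{rid}
#'   columns in addition to the \code{StructureModel} atom columns.
#' @slot partnerProvenance text describing the partner's origin (symmetry
#'   operator + lattice shift, or a chain identifier).
#' @slot opIndex,latticeShift provenance of a crystal mate (NA for chain pairs).
#' @slot asaIsolated,asaComplex named per-atom ASA maps over both sides.
#' @slot interfaceArea interface area in square angstrom (half the total ASA
#'   loss).
#' @export
setClass("ContactPair", representation(
  reference = "data.frame", partner = "data.frame",
  partnerProvenance = "character", opIndex = "integer",
  latticeShift = "integer", asaIsolated = "numeric", asaComplex = "numeric",
  interfaceArea = "numeric"),
  prototype(opIndex = NA_integer_, latticeShift = c(NA_integer_, NA_integer_,
                                                    NA_integer_)))

setValidity("ContactPair", function(object) {
  msgs <- character()
  if (length(object@interfaceArea) != 1L || object@interfaceArea < 0)
    msgs <- c(msgs, "interfaceArea must be a single non-negative number")
  if (any(object@asaIsolated < 0) || any(object@asaComplex < 0))
    msgs <- c(msgs, "ASA values must be non-negative")
  ids <- c(object@reference$id, object@partner$id)
  if (!setequal(ids, names(object@asaIsolated)) ||
      !setequal(ids, names(object@asaComplex)))
    msgs <- c(msgs, "ASA maps must cover exactly the atoms of both sides")
  if (length(msgs)) msgs else TRUE
})

#' AsaResult: solvent-accessible surface areas
#'
#' @slot perAtom named per-atom ASA (square angstrom).
#' @slot perResidue named per-residue ASA (sums of the residue's atoms).
#' @slot total total ASA.
#' @slot probeRadius probe sphere radius (angstrom).
#' @slot nPoints quadrature points per atom.
#' @export
setClass("AsaResult", representation(
  perAtom = "numeric", perResidue = "numeric", total = "numeric",
  probeRadius = "numeric", nPoints = "integer"))

setValidity("AsaResult", function(object) {
  msgs <- character()
  if (any(object@perAtom < 0)) msgs <- c(msgs, "per-atom ASA must be >= 0")
  if (abs(sum(object@perAtom) - object@total) > 1e-6 * max(1, object@total))
    msgs <- c(msgs, "total must equal the sum of per-atom values")
  if (length(msgs)) msgs else TRUE
})

#' InterfaceDescriptors: the full per-interface descriptor record
#'
#' Geometric and physicochemical descriptors of one protein-protein
#' interface, as produced by \code{\link{computeAllDescriptors}}. Fractions
#' are reported on [0, 1]; \code{IAratio} is a percentage of the reference
#' molecule's isolated surface.
#'
#' @slot IA interface area (square angstrom).
#' @slot IAratio interface area as percent of the reference monomer ASA.
#' @slot Nnbc number of non-bonded cross-interface atom contacts (< 3.9 A).
#' @slot nHB number of cross-interface hydrogen bonds.
#' @slot Ns number of interface segments (both chains).
#' @slot nIfaceRes,nIfaceAtoms interface residue and atom counts.
#' @slot fBu fraction of interface atoms fully buried in the complex.
#' @slot fNp fraction of the interface area contributed by carbon atoms.
#' @slot fCore fraction of the interface area contributed by core residues.
#' @slot Rp residue interface propensity score (sum of log-odds vs surface).
#' @slot LD local density index (mean same-side interface neighbours within
#'   12 A).
#' @slot Igap gap volume index (interstitial volume / IA, angstrom).
#' @slot ssCategory one of "alpha", "beta", "alpha/beta", "coil".
#' @export
setClass("InterfaceDescriptors", representation(
  IA = "numeric", IAratio = "numeric", Nnbc = "integer", nHB = "integer",
  Ns = "integer", nIfaceRes = "integer", nIfaceAtoms = "integer",
  fBu = "numeric", fNp = "numeric", fCore = "numeric", Rp = "numeric",
  LD = "numeric", Igap = "numeric", ssCategory = "character"))

setValidity("InterfaceDescriptors", function(object) {
  msgs <- character()
  fr <- c(object@fBu, object@fNp, object@fCore)
  if (any(fr < 0 | fr > 1)) msgs <- c(msgs, "fractions must lie in [0, 1]")
  if (object@IA < 0 || object@LD < 0 || object@Igap < 0)
    msgs <- c(msgs, "IA, LD and Igap must be non-negative")
  if (object@Ns > object@nIfaceRes)
    msgs <- c(msgs, "segment count cannot exceed interface residue count")
  if (!object@ssCategory %in% c("alpha", "beta", "alpha/beta", "coil"))
    msgs <- c(msgs, "invalid ssCategory")
  if (length(msgs)) msgs else TRUE
})

#' MsaProfile: an aligned protein family with per-column entropies
#'
#' @slot sequences equal-length aligned amino-acid strings (gaps "-").
#' @slot referenceIndex row used to map columns onto a structure's chain.
#' @slot columnEntropies per-column sequence entropies in nats (may be empty
#'   until computed).
#' @export
setClass("MsaProfile", representation(
  sequences = "character", referenceIndex = "integer",
  columnEntropies = "numeric"),
  prototype(referenceIndex = 1L, columnEntropies = numeric(0)))

setValidity("MsaProfile", function(object) {
  msgs <- character()
  if (length(object@sequences) < 1L) msgs <- c(msgs, "no sequences")
  if (length(unique(nchar(object@sequences))) > 1L)
    msgs <- c(msgs, "aligned sequences must all have the same length")
  if (object@referenceIndex < 1L ||
      object@referenceIndex > length(object@sequences))
    msgs <- c(msgs, "referenceIndex out of range")
  if (length(object@columnEntropies) &&
      (any(object@columnEntropies < -1e-9) ||
       any(object@columnEntropies > log(10) + 1e-9)))
    msgs <- c(msgs, "column entropies must lie in [0, ln 10]")
  if (length(msgs)) msgs else TRUE
})

#' CoreSurfaceScore: conservation of the interface core against the surface
#'
#' Background-sampled z-score of the mean core entropy against means of
#' random surface subsets; negative values indicate a core more conserved
#' than the surface.
#'
#' @slot score the z-score.
#' @slot nCore,nSurface residue counts.
#' @slot nSamples background sample count.
#' @slot seed RNG seed used for the background draws.
#' @export
setClass("CoreSurfaceScore", representation(
  score = "numeric", nCore = "integer", nSurface = "integer",
  nSamples = "integer", seed = "integer"))

#' ConfusionCounts: a binary-classification confusion table
#'
#' TP are correctly recognised biological interfaces, TN correctly recognised
#' crystal packing contacts; FP and FN are the corresponding errors. Derived
#' rates come from \code{\link{performanceMetrics}}.
#'
#' @slot TP,TN,FP,FN non-negative integer counts.
#' @export
setClass("ConfusionCounts", representation(
  TP = "integer", TN = "integer", FP = "integer", FN = "integer"))

setValidity("ConfusionCounts", function(object) {
  if (any(c(object@TP, object@TN, object@FP, object@FN) < 0))
    "counts must be non-negative" else TRUE
})

#' GroupComparison: two-group location comparison with significance stars
#'
#' @slot groupMeans,groupSds,n named per-group summaries.
#' @slot pValue two-sided p-value.
#' @slot star "none", "*" (p < 0.05) or "**" (p < 0.001).
#' @slot method test used.
#' @export
setClass("GroupComparison", representation(
  groupMeans = "numeric", groupSds = "numeric", n = "integer",
  pValue = "numeric", star = "character", method = "character"))

setValidity("GroupComparison", function(object) {
  msgs <- character()
  if (any(object@groupSds < 0)) msgs <- c(msgs, "sd must be >= 0")
  p <- object@pValue
  star <- if (p < 0.001) "**" else if (p < 0.05) "*" else "none"
  if (!identical(star, object@star))
    msgs <- c(msgs, "star inconsistent with p-value")
  if (length(msgs)) msgs else TRUE
})
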