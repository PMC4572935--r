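#' @include AllClasses.R
NULL

#' Accessors for structure and contact objects
#'
#' \code{atoms} returns the atom table; \code{cellParams} the unit cell;
#' \code{spaceGroup} the Hermann-Mauguin symbol; \code{symOps} the symmetry
#' operators; \code{interfaceArea} the interface area of a
#' \linkS4class{ContactPair}.
#'
#' @param x an object.
#' @return The slot contents.
#' @name accessors
#' @aliases atoms cellParams spaceGroup symOps interfaceArea
NULL

#' @rdname accessors
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))
#' @rdname accessors
#' @export
setGeneric("cellParams", function(x) standardGeneric("cellParams"))
#' @rdname accessors
#' @export
setGeneric("spaceGroup", function(x) standardGeneric("spaceGroup"))
#' @rdname accessors
#' @export
setGeneric("symOps", function(x) standardGeneric("symOps"))
#' @rdname accessors
#' @export
setGeneric("interfaceArea", function(x) standardGeneric("interfaceArea"))

#' @rdname accessors
#' @export
setMethod("atoms", "StructureModel", function(x) x@atoms)
#' @rdname accessors
#' @export
setMethod("atoms", "SymmetryMate", function(x) x@atoms)
#' @rdname accessors
#' @export
setMethod("cellParams", "StructureModel", function(x) x@cell)
#' @rdname accessors
#' @export
setMethod("spaceGroup", "StructureModel", function(x) x@spaceGroup)
#' @rdname accessors
#' @export
setMethod("symOps", "StructureModel", function(x) x@symOps)
#' @rdname accessors
#' @export
setMethod("interfaceArea", "ContactPair", function(x) x@interfaceArea)

setMethod("show", "StructureModel", function(object) {
  a <- object@atoms
  cat("StructureModel:", sum(!a$hetero & !a$water), "protein atoms,",
      length(unique(a$chain[!a$hetero & !a$water])), "chain(s)\n")
  if (length(object@cell))
    cat("  cell:", paste(format(object@cell, digits = 6), collapse = " "),
        " space group:", object@spaceGroup,
        sprintf("(%d ops)\n", length(object@symOps)))
  if (!is.na(object@resolution))
    cat("  resolution:", object@resolution, "A\n")
})

setMethod("show", "ContactPair", function(object) {
  cat(sprintf("ContactPair: %d vs %d atoms, partner %s, interface area %.1f A^2\n",
              nrow(object@reference), nrow(object@partner),
              object@partnerProvenance, object@interfaceArea))
})

setMethod("show", "InterfaceDescriptors", function(object) {
  cat("InterfaceDescriptors\n")
  print(as.data.frame(object), row.names = FALSE)
})

#' @describeIn computeAllDescriptors one-row data.frame of the 14 descriptors.
#' @param x an \linkS4class{InterfaceDescriptors} object.
#' @param row.names,optional,... ignored (base S3 signature).
#' @export
as.data.frame.InterfaceDescriptors <- function(x, row.names = NULL,
                                               optional = FALSE, ...) {
  data.frame(IA = x@IA, IA_ratio = x@IAratio, Nnbc = x@Nnbc, nHB = x@nHB,
             Ns = x@Ns, n_iface_res = x@nIfaceRes,
             n_iface_atoms = x@nIfaceAtoms, f_bu = x@fBu, f_np = x@fNp,
             f_core = x@fCore, R_p = x@Rp, LD = x@LD, I_gap = x@Igap,
             ss_category = x@ssCategory)
}

setMethod("show", "CoreSurfaceScore", function(object) {
  cat(sprintf("core-surface conservation score: %.3f (%d core vs %d surface, %d samples, seed %d)\n",
              object@score, object@nCore, object@nSurface, object@nSamples,
              object@seed))
})

setMethod("show", "ConfusionCounts", function(object) {
  cat(sprintf("ConfusionCounts: TP=%d TN=%d FP=%d FN=%d\n",
              object@TP, object@TN, object@FP, object@FN))
  m <- performanceMetrics(object)
  cat(sprintf("  Sn=%.1f%% Sp=%.1f%% Acc=%.1f%% MCC=%.3f\n",
              m["Sn"], m["Sp"], m["Acc"], m["MCC"]))
})

setMethod("show", "GroupComparison", function(object) {
  cat(sprintf("GroupComparison (%s): p = %.4g %s\n", object@method,
              object@pValue,
              if (object@star == "none") "" else object@star))
  print(data.frame(group = names(object@groupMeans),
                   mean = object@groupMeans, sd = object@groupSds,
                   n = object@n), row.names = FALSE)
})
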