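## Sequence-entropy conservation on the reduced ten-class amino-acid
## alphabet, and the core-versus-surface conservation z-score.

## ten physicochemical classes: LVIM, C, A, G, ST, P, FYW, EDNQ, KR, H
.MURPHY10 <- local({
  classes <- list(c("L", "V", "I", "M"), "C", "A", "G", c("S", "T"), "P",
                  c("F", "Y", "W"), c("E", "D", "N", "Q"), c("K", "R"), "H")
  m <- integer(0)
  for (k in seq_along(classes)) m[classes[[k]]] <- k
  m
})

#' Read an aligned FASTA file into an MsaProfile
#'
#' @param path path to an aligned (equal-length, gapped) FASTA file.
#' @param referenceIndex row to use as the structure-mapping reference.
#' @return An \linkS4class{MsaProfile}.
#' @export
readMsa <- function(path, referenceIndex = 1L) {
  seqs <- Biostrings::readAAStringSet(path)
  new("MsaProfile", sequences = setNames(as.character(seqs), names(seqs)),
      referenceIndex = as.integer(referenceIndex))
}

#' Per-column sequence entropies (ten-class alphabet)
#'
#' Maps residues onto the ten reduced classes (LVIM, C, A, G, ST, P, FYW,
#' EDNQ, KR, H) and computes the Shannon entropy
#' s(i) = -sum_k p_k ln p_k of the class distribution at each alignment
#' column, in nats. Gaps are excluded from the probabilities; an all-gap
#' column has entropy 0 (with a warning). Any character that is neither a
#' standard amino acid nor a gap is an error naming the column.
#'
#' @param msa an \linkS4class{MsaProfile} or character vector of equal-length
#'   aligned sequences.
#' @return Numeric vector of per-column entropies in [0, ln 10].
#' @examples
#' columnEntropies(c("AL", "AV"))  # c(0, 0): L and V share a class
#' @export
columnEntropies <- function(msa) {
  seqs <- if (is(msa, "MsaProfile")) msa@sequences else msa
  if (length(seqs) < 2L) stop("at least two sequences are required")
  if (length(unique(nchar(seqs))) != 1L)
    stop("aligned sequences must all have the same length")
  mat <- do.call(rbind, strsplit(toupper(seqs), ""))
  ncol <- ncol(mat)
  ent <- numeric(ncol)
  for (j in seq_len(ncol)) {
    col <- mat[, j]
    col <- col[!col %in% c("-", ".")]
    if (!length(col)) {
      warning("column ", j, " contains only gaps; entropy set to 0")
      next
    }
    cls <- .MURPHY10[col]
    if (anyNA(cls))
      stop("non-amino-acid character '", col[is.na(cls)][1],
           "' in column ", j)
    p <- tabulate(cls, 10)
    p <- p[p > 0] / sum(p)
    ent[j] <- -sum(p * log(p))
  }
  ent
}

#' Map alignment columns onto a structure chain
#'
#' Globally aligns the (degapped) reference row of the alignment against a
#' chain sequence and transfers each column's entropy to the matching chain
#' residue ordinal. Residues missing from the chain (unobserved density) are
#' simply skipped.
#'
#' @param msa an \linkS4class{MsaProfile}.
#' @param chainSeq one-letter chain sequence (see
#'   \code{\link{chainSequence}}).
#' @param minIdentity required identity between the reference row and the
#'   chain over the aligned region (default 0.9).
#' @return data.frame with columns \code{ordinal} (0-based chain position),
#'   \code{column} (alignment column) and \code{entropy}.
#' @export
mapMsaToChain <- function(msa, chainSeq, minIdentity = 0.9) {
  stopifnot(is(msa, "MsaProfile"))
  refRow <- msa@sequences[msa@referenceIndex]
  refChars <- strsplit(refRow, "")[[1]]
  notGap <- !refChars %in% c("-", ".")
  refSeq <- paste(refChars[notGap], collapse = "")
  colOfRefPos <- which(notGap)

  letters20 <- names(.MURPHY10)
  mat <- matrix(-1, 21, 21, dimnames = list(c(letters20, "X"),
                                            c(letters20, "X")))
  diag(mat) <- 1
  aln <- Biostrings::pairwiseAlignment(refSeq, chainSeq, type = "overlap",
                                       substitutionMatrix = mat,
                                       gapOpening = 4, gapExtension = 1)
  pat <- strsplit(as.character(Biostrings::pattern(aln)), "")[[1]]
  sub <- strsplit(as.character(Biostrings::subject(aln)), "")[[1]]
  identity <- if (length(pat) == 0L) 0
              else sum(pat == sub & pat != "-") / length(pat)
  if (identity < minIdentity)
    stop(sprintf("reference row and chain share only %.1f%% identity (>= %.0f%% required)",
                 100 * identity, 100 * minIdentity))

  ent <- if (length(msa@columnEntropies)) msa@columnEntropies
         else columnEntropies(msa)
  refPos <- Biostrings::start(Biostrings::pattern(aln)) - 1L
  chainPos <- Biostrings::start(Biostrings::subject(aln)) - 1L
  rows <- list()
  for (k in seq_along(pat)) {
    pGap <- pat[k] == "-"; sGap <- sub[k] == "-"
    if (!pGap) refPos <- refPos + 1L
    if (!sGap) chainPos <- chainPos + 1L
    if (!pGap && !sGap) {
      column <- colOfRefPos[refPos]
      rows[[length(rows) + 1L]] <-
        data.frame(ordinal = chainPos - 1L, column = column,
                   entropy = ent[column])
    }
  }
  do.call(rbind, rows)
}

#' Core-versus-surface conservation score
#'
#' Background-sampled z-score of interface-core conservation: the mean
#' entropy of the core residues is compared with the distribution of mean
#' entropies of \code{nSamples} random draws of the same number of surface
#' residues. Negative scores mean the core is more conserved than the
#' surface.
#'
#' @param entropies named numeric vector of per-residue entropies (names are
#'   residue identifiers, e.g. chain ordinals).
#' @param core,surface names (or indices) of core and surface residues;
#'   requires |surface| > |core| >= 1.
#' @param nSamples number of background draws (default 10000).
#' @param seed RNG seed (mandatory: the score must be reproducible).
#' @return A \linkS4class{CoreSurfaceScore}.
#' @export
coreSurfaceScore <- function(entropies, core, surface, nSamples = 10000L,
                             seed) {
  coreE <- entropies[core]
  surfE <- entropies[surface]
  if (anyNA(coreE) || anyNA(surfE))
    stop("core/surface residues missing from the entropy map")
  nCore <- length(coreE); nSurf <- length(surfE)
  if (nCore < 1L || nSurf <= nCore)
    stop("need |surface| > |core| >= 1")
  bg <- .withSeed(seed, vapply(seq_len(nSamples), function(i)
    mean(sample(surfE, nCore)), numeric(1)))
  s <- stats::sd(bg)
  if (s == 0) {
    warning("background sd is zero; score set to 0")
    score <- 0
  } else score <- (mean(coreE) - mean(bg)) / s
  new("CoreSurfaceScore", score = score, nCore = nCore, nSurface = nSurf,
      nSamples = as.integer(nSamples), seed = as.integer(seed))
}
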