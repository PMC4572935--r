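## Entry-level dataset curation: quality filters, redundancy clustering,
## size classes, matched area controls and space-group tallies.

#' Entry-level quality filters
#'
#' Applies the curation rules for monomeric crystal-structure entries:
#' crystallographic resolution strictly better than 2.5 angstrom, not
#' C-alpha-only, at least 50 residues, at most 5\% non-protein atoms
#' (waters excluded from the count), and exactly one molecule in the
#' asymmetric unit. Every violated rule is reported.
#'
#' @param entries data.frame with columns \code{entry_id}, \code{sequence},
#'   \code{resolution}, \code{n_models_in_asu}, \code{is_calpha_only},
#'   \code{n_protein_atoms}, \code{n_nonprotein_atoms_excl_water}.
#' @param maxResolution resolution threshold (strict; default 2.5).
#' @param minLength minimal sequence length (default 50).
#' @param maxNonproteinFraction maximal non-protein atom fraction (strict;
#'   default 0.05).
#' @return The input with logical \code{pass} and character \code{reasons}
#'   (semicolon-joined violated rules) columns appended.
#' @export
filterEntries <- function(entries, maxResolution = 2.5, minLength = 50L,
                          maxNonproteinFraction = 0.05) {
  n <- nrow(entries)
  reasons <- vector("list", n)
  add <- function(reasons, bad, why) {
    for (i in which(bad)) reasons[[i]] <- c(reasons[[i]], why)
    reasons
  }
  res <- entries$resolution
  reasons <- add(reasons, is.na(res) | res >= maxResolution, "resolution")
  reasons <- add(reasons, entries$is_calpha_only, "calpha_only")
  reasons <- add(reasons, nchar(entries$sequence) < minLength, "length")
  frac <- entries$n_nonprotein_atoms_excl_water /
    (entries$n_protein_atoms + entries$n_nonprotein_atoms_excl_water)
  reasons <- add(reasons, frac > maxNonproteinFraction, "nonprotein")
  reasons <- add(reasons, entries$n_models_in_asu != 1L, "asu")
  entries$pass <- vapply(reasons, function(r) is.null(r), logical(1))
  entries$reasons <- vapply(reasons, function(r)
    if (is.null(r)) "" else paste(r, collapse = ";"), character(1))
  entries
}

#' Greedy sequence-identity clustering
#'
#' CD-HIT-style greedy clustering: sequences are sorted by decreasing length
#' (ties by name), each sequence joins the first existing representative
#' with pairwise identity at or above the threshold, otherwise founds a new
#' cluster. Identity is matches divided by the global alignment length
#' (internal and terminal gaps included).
#'
#' @param sequences named character vector of protein sequences.
#' @param threshold identity threshold in (0, 1] (default 0.5).
#' @return Character vector of representative names; the full cluster
#'   assignment is attached as attribute \code{"clusters"}.
#' @export
clusterByIdentity <- function(sequences, threshold = 0.5) {
  stopifnot(threshold > 0, threshold <= 1)
  if (!length(sequences)) return(character(0))
  if (is.null(names(sequences)))
    names(sequences) <- paste0("seq", seq_along(sequences))
  ord <- order(-nchar(sequences), names(sequences))
  reps <- character(0)
  assign <- setNames(character(length(sequences)), names(sequences))
  for (nm in names(sequences)[ord]) {
    placed <- FALSE
    for (rp in reps) {
      if (.pairIdentity(sequences[[nm]], sequences[[rp]]) >= threshold) {
        assign[nm] <- rp; placed <- TRUE; break
      }
    }
    if (!placed) { reps <- c(reps, nm); assign[nm] <- nm }
  }
  structure(reps, clusters = assign)
}

.pairIdentity <- function(s1, s2) {
  letters20 <- names(.MURPHY10)
  mat <- matrix(-1, 21, 21, dimnames = list(c(letters20, "X"),
                                            c(letters20, "X")))
  diag(mat) <- 1
  aln <- Biostrings::pairwiseAlignment(s1, s2, type = "global",
                                       substitutionMatrix = mat,
                                       gapOpening = 4, gapExtension = 1)
  pat <- strsplit(as.character(Biostrings::pattern(aln)), "")[[1]]
  sub <- strsplit(as.character(Biostrings::subject(aln)), "")[[1]]
  sum(pat == sub & pat != "-") / length(pat)
}

#' Interface-size class of a packing contact
#'
#' Large crystal packing contacts bury strictly more than 900 square
#' angstrom of interface area; everything else is a general packing contact.
#'
#' @param ia numeric vector of interface areas.
#' @param cutoff area cutoff (default 900).
#' @return Character vector: \code{"large_cp"} or \code{"general_cp"}.
#' @examples
#' classifySize(c(196, 900, 900.5))  # general, general, large
#' @export
classifySize <- function(ia, cutoff = 900) {
  stopifnot(all(ia >= 0))
  ifelse(ia > cutoff, "large_cp", "general_cp")
}

#' Matched interface-area control pairs
#'
#' Greedy one-to-one matching between two sets of interface areas: candidate
#' pairs differing by strictly less than \code{tolerance} square angstrom
#' are accepted in increasing order of difference, each entry used at most
#' once. This removes interface-area as a confounder when comparing the
#' other descriptors between groups.
#'
#' @param iaA,iaB numeric vectors of interface areas.
#' @param tolerance maximal allowed area difference (strict; default 10).
#' @return data.frame with columns \code{indexA}, \code{indexB}, \code{iaA},
#'   \code{iaB}, \code{diff} (possibly zero rows).
#' @export
buildMatchedControl <- function(iaA, iaB, tolerance = 10) {
  stopifnot(tolerance > 0)
  cand <- expand.grid(indexA = seq_along(iaA), indexB = seq_along(iaB))
  cand$diff <- abs(iaA[cand$indexA] - iaB[cand$indexB])
  cand <- cand[cand$diff < tolerance, , drop = FALSE]
  cand <- cand[order(cand$diff, cand$indexA, cand$indexB), , drop = FALSE]
  usedA <- logical(length(iaA)); usedB <- logical(length(iaB))
  keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    i <- cand$indexA[k]; j <- cand$indexB[k]
    if (!usedA[i] && !usedB[j]) {
      keep[k] <- TRUE; usedA[i] <- TRUE; usedB[j] <- TRUE
    }
  }
  out <- cand[keep, , drop = FALSE]
  out$iaA <- iaA[out$indexA]; out$iaB <- iaB[out$indexB]
  row.names(out) <- NULL
  out[, c("indexA", "indexB", "iaA", "iaB", "diff")]
}

#' Space-group tally
#'
#' Counts entries per Hermann-Mauguin symbol and lists the symbols observed
#' at least \code{threshold} times.
#'
#' @param symbols character vector of space-group symbols.
#' @param threshold minimal count for the "frequent" list (default 20).
#' @return list with \code{counts} (named integer, decreasing) and
#'   \code{frequent} (symbols with count >= threshold).
#' @export
tallySpaceGroups <- function(symbols, threshold = 20L) {
  if (!length(symbols))
    return(list(counts = integer(0), frequent = character(0)))
  counts <- sort(table(symbols), decreasing = TRUE)
  counts <- setNames(as.integer(counts), names(counts))
  list(counts = counts, frequent = names(counts)[counts >= threshold])
}
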