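## Comparative statistics across interaction classes and classifier
## performance metrics.

#' Per-class summaries and histogram counts
#'
#' Arithmetic mean, sample standard deviation (n - 1 denominator, 0 for a
#' single value) and fixed-width histogram counts per class.
#'
#' @param values numeric vector of descriptor values.
#' @param class factor/character of the same length assigning each value to
#'   an interaction class.
#' @param binwidth histogram bin width (bins anchored at 0); NULL skips
#'   histograms.
#' @return data.frame (class, n, mean, sd); histogram counts, when computed,
#'   attached as attribute \code{"histograms"} (named list of tables).
#' @export
groupSummary <- function(values, class, binwidth = NULL) {
  if (!length(values)) stop("no values: every class must be non-empty")
  groups <- split(values, class)
  empty <- vapply(groups, function(g) length(g) == 0L, logical(1))
  if (any(empty))
    stop("empty class: ", paste(names(groups)[empty], collapse = ", "))
  out <- data.frame(
    class = names(groups),
    n = vapply(groups, length, integer(1)),
    mean = vapply(groups, mean, numeric(1)),
    sd = vapply(groups, function(g) if (length(g) < 2L) 0 else stats::sd(g),
                numeric(1)))
  row.names(out) <- NULL
  if (!is.null(binwidth)) {
    breaks <- seq(binwidth * floor(min(values) / binwidth),
                  binwidth * ceiling(max(values) / binwidth) + binwidth,
                  by = binwidth)
    attr(out, "histograms") <- lapply(groups, function(g)
      table(cut(g, breaks, right = FALSE)))
  }
  out
}

#' Two-group comparison with significance stars
#'
#' Two-sided Mann-Whitney U test (exact when both groups have at most 8
#' values and the pooled sample is tie-free, normal approximation with tie
#' correction otherwise), or Welch's t as an alternative. Stars follow the
#' usual convention: "*" for p < 0.05, "**" for p < 0.001.
#'
#' @param a,b numeric vectors (each length >= 3).
#' @param method \code{"wilcoxon"} (default) or \code{"welch"}.
#' @param exactMax largest per-group size for the exact U distribution.
#' @return A \linkS4class{GroupComparison}.
#' @examples
#' compareGroups(1:5, 101:105)  # exact p = 2/choose(10, 5) * 2
#' @export
compareGroups <- function(a, b, method = c("wilcoxon", "welch"),
                          exactMax = 8L) {
  method <- match.arg(method)
  stopifnot(length(a) >= 3L, length(b) >= 3L)
  pooled <- c(a, b)
  if (length(unique(pooled)) == 1L) {
    p <- 1
  } else if (method == "wilcoxon") {
    exact <- length(a) <= exactMax && length(b) <= exactMax &&
      !anyDuplicated(pooled)
    p <- stats::wilcox.test(a, b, exact = exact,
                            correct = !exact)$p.value
  } else {
    p <- stats::t.test(a, b, var.equal = FALSE)$p.value
  }
  star <- if (p < 0.001) "**" else if (p < 0.05) "*" else "none"
  new("GroupComparison",
      groupMeans = c(a = mean(a), b = mean(b)),
      groupSds = c(a = stats::sd(a), b = stats::sd(b)),
      n = c(a = length(a), b = length(b)),
      pValue = p, star = star, method = method)
}

#' Pearson product-moment correlation
#'
#' @param x,y numeric vectors of equal length (>= 3), neither constant.
#' @return The correlation coefficient.
#' @export
pearsonR <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("constant input")
  stats::cor(x, y)
}

#' Confusion counts from printed sensitivity/specificity
#'
#' Reconstructs an integer confusion table from percentage sensitivity and
#' specificity and the two class sizes: TP = round(Sn/100 * nPos),
#' TN = round(Sp/100 * nNeg) with halves rounded away from zero, FN and FP
#' by complement. Positives are biological interfaces, negatives crystal
#' packing contacts.
#'
#' @param sn,sp sensitivity and specificity in percent.
#' @param nPos,nNeg class sizes.
#' @return A \linkS4class{ConfusionCounts}.
#' @examples
#' confusionFromRates(49.5, 51.1, 103, 92)  # TP=51 TN=47 FP=45 FN=52
#' @export
confusionFromRates <- function(sn, sp, nPos, nNeg) {
  stopifnot(sn >= 0, sn <= 100, sp >= 0, sp <= 100)
  tp <- as.integer(.roundHalfAway(sn / 100 * nPos))
  tn <- as.integer(.roundHalfAway(sp / 100 * nNeg))
  new("ConfusionCounts", TP = tp, TN = tn,
      FP = as.integer(nNeg) - tn, FN = as.integer(nPos) - tp)
}

#' Classifier performance metrics
#'
#' Sensitivity, specificity and accuracy in percent, plus the Matthews
#' correlation coefficient
#' MCC = (TP TN - FP FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)), defined as 0
#' when any factor of the denominator vanishes.
#'
#' @param counts a \linkS4class{ConfusionCounts}.
#' @return Named numeric: \code{Sn}, \code{Sp}, \code{Acc} (percent),
#'   \code{MCC}.
#' @export
performanceMetrics <- function(counts) {
  tp <- as.numeric(counts@TP); tn <- as.numeric(counts@TN)
  fp <- as.numeric(counts@FP); fn <- as.numeric(counts@FN)
  total <- tp + tn + fp + fn
  if (total == 0) stop("empty confusion table")
  if (tp + fn == 0 || tn + fp == 0)
    stop("both classes must be represented (TP+FN > 0 and TN+FP > 0)")
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (den == 0) 0 else (tp * tn - fp * fn) / sqrt(den)
  c(Sn = 100 * tp / (tp + fn),
    Sp = 100 * tn / (tn + fp),
    Acc = 100 * (tp + tn) / total,
    MCC = mcc)
}
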