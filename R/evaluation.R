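#' Pair-counting precision, recall and F1
#'
#' A gene pair is a true pair if the two genes are co-labeled in the truth,
#' and a predicted pair if co-labeled in the prediction (pairs are counted
#' the way the Rand index counts them). Precision = agreeing/predicted
#' pairs, recall = agreeing/true pairs, F1 their harmonic mean. Zero
#' denominators give 0 (no predicted pairs: precision 0; no true pairs:
#' recall 0; both zero: F1 0). Invariant to any renaming of cluster labels
#' on either side.
#'
#' @param truth,pred named vectors of cluster labels over the identical
#'   gene set (any label type).
#' @param exclude genes whose pairs are left out of the count (used for
#'   genes belonging to more than one planted set).
#' @return an \code{\link{EvalScores-class}} object.
#' @examples
#' truth <- c(a = 1, b = 1, c = 1, d = 2, e = 2)
#' pred  <- c(a = 1, b = 1, c = 2, d = 2, e = 2)
#' pairCountingScores(truth, pred)  # precision = recall = 0.5
#' @export
pairCountingScores <- function(truth, pred, exclude = character(0)) {
  if (is.null(names(truth)) || is.null(names(pred)))
    stop("labelings must be named by gene", call. = FALSE)
  sd1 <- setdiff(names(truth), names(pred))
  sd2 <- setdiff(names(pred), names(truth))
  if (length(sd1) || length(sd2))
    stop("gene sets differ; only in truth: {",
         paste(sd1, collapse = ", "), "}, only in prediction: {",
         paste(sd2, collapse = ", "), "}", call. = FALSE)
  keep <- setdiff(names(truth), exclude)
  t <- as.character(truth[keep])
  p <- as.character(pred[keep])
  up <- upper.tri(matrix(0, length(keep), length(keep)))
  coT <- outer(t, t, `==`)[up]
  coP <- outer(p, p, `==`)[up]
  truePairs <- sum(coT)
  predPairs <- sum(coP)
  agree <- sum(coT & coP)
  precision <- if (predPairs > 0) agree / predPairs else 0
  recall <- if (truePairs > 0) agree / truePairs else 0
  f1 <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  new("EvalScores", precision = precision, recall = recall, f1 = f1,
      truePairs = as.integer(truePairs),
      predictedPairs = as.integer(predPairs),
      agreeingPairs = as.integer(agree))
}

#' Random-assignment baseline for pair-counting scores
#'
#' Scores \code{reps} independent uniform random assignments of the genes
#' into k clusters against the truth, and reports the mean and standard
#' error of each metric. This is the control experiment a method must beat.
#'
#' @param truth named vector of true cluster labels.
#' @param k number of clusters to guess into.
#' @param reps number of random assignments.
#' @param seed integer seed (same seed, identical summary).
#' @param exclude genes excluded from pair counting.
#' @return data.frame with columns \code{metric}, \code{mean}, \code{se}.
#' @export
randomBaseline <- function(truth, k, reps = 100L, seed = 0L,
                           exclude = character(0)) {
  stopifnot(reps >= 1L, k >= 1L)
  n <- length(truth)
  scores <- withSeed(seed, {
    vapply(seq_len(reps), function(i) {
      guess <- stats::setNames(sample.int(k, n, replace = TRUE),
                               names(truth))
      s <- pairCountingScores(truth, guess, exclude = exclude)
      c(s@precision, s@recall, s@f1)
    }, numeric(3))
  })
  data.frame(metric = c("precision", "recall", "f1"),
             mean = rowMeans(scores),
             se = apply(scores, 1L, .se))
}

#' Gene-weighted summary of per-cluster coherence p-values
#'
#' Each gene inherits the functional-coherence p-value of its assigned
#' cluster (the p-value provider, e.g. an external graph-theoretic
#' coherence test, is pluggable: any label -> p mapping is accepted);
#' the mean and standard error over genes are returned, i.e. the
#' cluster-size-weighted mean of the cluster p-values.
#'
#' @param assign a \code{GeneClustering}.
#' @param clusterPvalues numeric p-values in [0, 1] named by cluster label,
#'   or a two-column data.frame (label, p).
#' @return list with elements \code{mean} and \code{se}.
#' @export
weightedPvalueSummary <- function(assign, clusterPvalues) {
  stopifnot(is(assign, "GeneClustering"))
  if (is.data.frame(clusterPvalues))
    clusterPvalues <- stats::setNames(clusterPvalues[[2L]],
                                      as.character(clusterPvalues[[1L]]))
  lab <- as.character(assign@labels)
  missing <- setdiff(unique(lab), names(clusterPvalues))
  if (length(missing))
    stop("no p-value supplied for cluster label(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (any(clusterPvalues < 0 | clusterPvalues > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  p <- as.numeric(clusterPvalues[lab])
  list(mean = mean(p), se = .se(p))
}
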