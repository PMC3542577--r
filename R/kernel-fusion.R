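#' Gaussian-kernel affinity matrix from a distance matrix
#'
#' \code{A[i, j] = exp(-d_ij^2 / (2 sigma^2))} for non-missing pairs;
#' missing pairs contribute affinity 0 (maximal dissimilarity in kernel
#' space) and the diagonal is set to 0 before the Laplacian row sums are
#' formed, following the spectral clustering algorithm of Ng, Jordan and
#' Weiss.
#'
#' @param dist a \code{GeneDistanceMatrix}.
#' @param sigma positive bandwidth.
#' @return a \code{\link{GeneAffinityMatrix-class}} object.
#' @examples
#' D <- geneDistanceMatrix(matrix(c(0, 1, 1, 0), 2,
#'                                dimnames = list(c("a", "b"), c("a", "b"))),
#'                         sourceTag = "pubs")
#' gaussianAffinity(D, sigma = 1 / sqrt(2))  # off-diagonal exp(-1)
#' @export
gaussianAffinity <- function(dist, sigma) {
  stopifnot(is(dist, "GeneDistanceMatrix"))
  .assertScalarNumber(sigma, "sigma", positive = TRUE)
  D <- dist@D
  A <- exp(-D^2 / (2 * sigma^2))
  A[is.na(A)] <- 0
  diag(A) <- 0
  A <- (A + t(A)) / 2
  new("GeneAffinityMatrix", genes = dist@genes, A = A,
      fusedFrom = dist@sourceTag,
      sigma = stats::setNames(sigma, dist@sourceTag))
}

#' Fuse affinity matrices by element-wise summation
#'
#' Heterogeneous sources are integrated in kernel space: single-source
#' affinity matrices over the identical gene ordering are summed element
#' by element, without per-source weights or renormalization (per-source
#' bandwidth selection puts sources on comparable scales).
#'
#' @param parts list of \code{GeneAffinityMatrix} objects (>= 1) over
#'   identical gene orderings.
#' @return a fused \code{GeneAffinityMatrix}.
#' @export
fuseAffinities <- function(parts) {
  if (is(parts, "GeneAffinityMatrix")) parts <- list(parts)
  stopifnot(length(parts) >= 1L,
            all(vapply(parts, is, logical(1), "GeneAffinityMatrix")))
  genes <- parts[[1L]]@genes
  for (p in parts[-1L]) {
    if (!identical(p@genes, genes)) {
      bad <- which(p@genes != genes)[1L]
      if (is.na(bad)) bad <- min(length(genes), length(p@genes)) + 1L
      stop("gene orderings disagree at position ", bad, ": '",
           genes[bad], "' vs '", p@genes[bad], "'", call. = FALSE)
    }
  }
  A <- Reduce(`+`, lapply(parts, function(p) p@A))
  new("GeneAffinityMatrix", genes = genes, A = A,
      fusedFrom = unlist(lapply(parts, function(p) p@fusedFrom)),
      sigma = unlist(lapply(parts, function(p) p@sigma)))
}

#' Normalized Laplacian of an affinity matrix
#'
#' \code{L = D^{-1/2} A D^{-1/2}} with \code{D} the diagonal matrix of row
#' sums of \code{A}. Its spectrum lies in [-1, 1] and its top eigenvectors
#' embed the genes. A zero row sum (a gene with no affinity to any other)
#' makes the normalization undefined; such genes must be removed first
#' (see \code{dropIsolated} in \code{\link{partitionGeneList}}).
#'
#' @param aff a \code{GeneAffinityMatrix}.
#' @return a \code{\link{SpectralLaplacian-class}} object.
#' @export
normalizedLaplacian <- function(aff) {
  stopifnot(is(aff, "GeneAffinityMatrix"))
  rs <- rowSums(aff@A)
  if (any(rs <= 0)) {
    bad <- aff@genes[rs <= 0]
    stop("zero affinity row sum for gene(s): ",
         paste(utils::head(bad, 5), collapse = ", "),
         if (length(bad) > 5) ", ..." else "",
         "; remove these isolated genes (dropIsolated = TRUE) or add an ",
         "informative source", call. = FALSE)
  }
  s <- 1 / sqrt(rs)
  L <- aff@A * (s %o% s)
  L <- (L + t(L)) / 2
  new("SpectralLaplacian", L = L, rowSums = rs, genes = aff@genes)
}

#' Spectral embedding from the top eigenvectors of the Laplacian
#'
#' Stacks the eigenvectors of the k largest eigenvalues as columns and
#' scales each row to unit Euclidean length. Deterministic conventions:
#' eigenvalues descending (ties resolved by solver order), and each
#' eigenvector flipped so its largest-magnitude entry is positive (earliest
#' index on ties).
#'
#' @param lap a \code{SpectralLaplacian}.
#' @param k number of eigenvectors, \code{1 <= k <= N}.
#' @param strict if TRUE (default), an all-zero unnormalized row (a gene
#'   untouched by the top-k eigenvectors, possible for disconnected
#'   affinity blocks) is an error naming the gene; if FALSE such rows are
#'   left at zero and flagged in the \code{degenerate} slot.
#' @return a \code{\link{SpectralEmbedding-class}} object.
#' @export
spectralEmbed <- function(lap, k, strict = TRUE) {
  stopifnot(is(lap, "SpectralLaplacian"))
  n <- length(lap@genes)
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k > n)
    stop("k must lie in [1, ", n, "]", call. = FALSE)
  k <- as.integer(k)
  es <- eigen(lap@L, symmetric = TRUE)
  X <- es$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(X[, j]))
    if (X[i, j] < 0) X[, j] <- -X[, j]
  }
  rn <- sqrt(rowSums(X^2))
  degenerate <- rn < 1e-12
  if (any(degenerate) && strict)
    stop("all-zero embedding row for gene(s): ",
         paste(lap@genes[degenerate], collapse = ", "), call. = FALSE)
  Y <- X / pmax(rn, 1e-300)
  Y[degenerate, ] <- 0
  dimnames(Y) <- list(lap@genes, NULL)
  new("SpectralEmbedding", Y = Y, k = k,
      eigenvalues = es$values[seq_len(k)], genes = lap@genes,
      degenerate = lap@genes[degenerate])
}
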