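#' Gene-gene distance matrix from literature co-mentioning
#'
#' For each pair of listed genes the number of shared publications is
#' counted; with \code{M} the maximum shared count over all pairs in the
#' list, the distance is \code{M - shared(i, j)} (pairs attaining the
#' maximum are at distance 0). The maximum is taken within the supplied
#' list, not over the genome, so the matrix is reproducible for a given
#' list. Genes absent from the table have an empty publication set (shared
#' count 0 with every partner, logged); since such a gene carries no
#' co-mention information at all, its pairs are additionally flagged
#' missing rather than assigned the maximal distance. If no pair shares a
#' publication the source carries no ranking information and an
#' all-missing matrix is returned with a warning.
#'
#' @param genes ordered gene identifiers (non-empty).
#' @param pubs named list mapping gene identifier to a character vector of
#'   publication identifiers (e.g. from \code{\link{readGene2Pubmed}}).
#' @return a \code{GeneDistanceMatrix} with \code{sourceTag = "pubs"}.
#' @examples
#' pubs <- list(g1 = c("p1", "p2"), g2 = c("p1", "p2"), g3 = "p9")
#' comentionDistanceMatrix(c("g1", "g2", "g3"), pubs)
#' @export
comentionDistanceMatrix <- function(genes, pubs) {
  genes <- as.character(genes)
  if (!length(genes)) stop("gene list is empty", call. = FALSE)
  sets <- lapply(genes, function(g) unique(as.character(pubs[[g]])))
  absent <- genes[vapply(genes, function(g) is.null(pubs[[g]]), logical(1))]
  if (length(absent))
    message("genes with no publication record (empty set): ",
            paste(utils::head(absent, 5), collapse = ", "),
            if (length(absent) > 5) ", ...")
  n <- length(genes)
  shared <- matrix(0, n, n, dimnames = list(genes, genes))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j > i) shared[i, j] <- length(intersect(sets[[i]], sets[[j]]))
    }
  }
  shared <- shared + t(shared)
  M <- max(shared[upper.tri(shared)], 0)
  if (n > 1L && M == 0) {
    warning("no pair of listed genes shares a publication; ",
            "co-mention source is degenerate (all pairs missing)",
            call. = FALSE)
    D <- matrix(NA_real_, n, n, dimnames = list(genes, genes))
  } else {
    D <- M - shared
    empty <- lengths(sets) == 0L
    D[empty, ] <- NA_real_
    D[, empty] <- NA_real_
  }
  geneDistanceMatrix(D, genes, sourceTag = "pubs")
}

#' Gene-gene distance matrix from expression profiles
#'
#' Pearson correlation mapped to a distance, \code{d = 1 - r}, in
#' \code{[0, 2]}. Genes absent from the matrix or with fewer than two
#' samples or zero profile variance carry no information and have all their
#' pairs flagged missing. Self-pairs are forced to distance 0.
#'
#' @param expr numeric matrix, genes x samples, with gene identifiers as
#'   rownames (e.g. from \code{\link{readExpressionMatrix}}).
#' @param genes ordered gene identifiers to build the matrix over.
#' @return a \code{GeneDistanceMatrix} with \code{sourceTag = "expression"}.
#' @export
expressionDistanceMatrix <- function(expr, genes = rownames(expr)) {
  genes <- as.character(genes)
  if (!length(genes)) stop("gene list is empty", call. = FALSE)
  expr <- as.matrix(expr)
  usable <- genes[genes %in% rownames(expr)]
  if (length(usable)) {
    sub <- expr[usable, , drop = FALSE]
    v <- apply(sub, 1L, stats::var)
    usable <- usable[!is.na(v) & v > 0 & ncol(sub) >= 2L]
  }
  n <- length(genes)
  D <- matrix(NA_real_, n, n, dimnames = list(genes, genes))
  if (length(usable) >= 2L) {
    r <- stats::cor(t(expr[usable, , drop = FALSE]))
    D[usable, usable] <- 1 - r
  }
  dropped <- setdiff(genes, usable)
  if (length(dropped))
    message("genes without usable expression profiles: ",
            paste(utils::head(dropped, 5), collapse = ", "),
            if (length(dropped) > 5) ", ...")
  D[D < 0 & !is.na(D)] <- 0   # guard against -eps from cor rounding
  geneDistanceMatrix(D, genes, sourceTag = "expression")
}
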