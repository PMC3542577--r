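#' @import methods
NULL

## Central S4 containers. Matrices are dense base matrices with gene
## identifiers as dimnames; NA encodes a missing (no-information) pair.

.SOURCE_TAGS <- c("go_bp", "go_mf", "go_cc", "pubs", "expression")

#' Ontology structure
#'
#' Directed acyclic parent-child term structure for one or more ontology
#' aspects (namespaces). Edges carry a relation kind (\code{is_a} or
#' \code{part_of}) and always join two terms of the same aspect.
#'
#' @slot terms character vector of term identifiers.
#' @slot edges data.frame with columns \code{parent}, \code{child},
#'   \code{relation}.
#' @slot aspect named character vector mapping each term to one of
#'   \code{biological_process}, \code{molecular_function},
#'   \code{cellular_component}.
#' @aliases Ontology-class
#' @exportClass Ontology
setClass("Ontology",
  representation(terms = "character", edges = "data.frame",
                 aspect = "character"))

setValidity("Ontology", function(object) {
  msg <- character()
  ed <- object@edges
  if (!all(c("parent", "child", "relation") %in% names(ed)))
    msg <- c(msg, "edges must have columns parent, child, relation")
  else {
    unknown <- setdiff(unique(c(ed$parent, ed$child)), object@terms)
    if (length(unknown))
      msg <- c(msg, paste("edge endpoints not in terms:",
                          paste(utils::head(unknown, 3), collapse = ", ")))
  }
  if (!all(object@terms %in% names(object@aspect)))
    msg <- c(msg, "every term needs an aspect")
  if (length(names(object@aspect)) && nrow(ed) &&
      all(c("parent", "child") %in% names(ed))) {
    same <- object@aspect[ed$parent] == object@aspect[ed$child]
    if (any(!same, na.rm = TRUE))
      msg <- c(msg, "edges must join terms of the same aspect")
    g <- igraph::graph_from_data_frame(ed[, c("parent", "child")],
                                       directed = TRUE)
    if (!igraph::is_dag(g))
      msg <- c(msg, "parent-child relation must be acyclic")
  }
  if (length(msg)) msg else TRUE
})

#' Gene annotation table
#'
#' Records of (gene, term, evidence code) triples; term instance counts are
#' derived from the records (see \code{\link{instanceCounts}}).
#'
#' @slot records data.frame with columns \code{gene}, \code{term},
#'   \code{evidence}.
#' @aliases AnnotationTable-class
#' @exportClass AnnotationTable
setClass("AnnotationTable", representation(records = "data.frame"))

setValidity("AnnotationTable", function(object) {
  if (!all(c("gene", "term", "evidence") %in% names(object@records)))
    "records must have columns gene, term, evidence" else TRUE
})

#' Weighted term graph for one ontology aspect
#'
#' Undirected graph over annotated terms (edge weight = absolute difference
#' in information content of the parent-child pair, in nats) with gene
#' vertices attached to their annotating terms by weight-0 edges.
#'
#' @slot graph an igraph object; term vertices are prefixed \code{t:},
#'   gene vertices \code{g:}.
#' @slot aspect the ontology aspect the graph was built for.
#' @slot genes gene identifiers present as vertices.
#' @slot terms term identifiers present as vertices.
#' @aliases TermGraph-class
#' @exportClass TermGraph
setClass("TermGraph",
  representation(graph = "ANY", aspect = "character", genes = "character",
                 terms = "character"))

#' Per-source gene-gene distance matrix
#'
#' Symmetric nonnegative distances with zero diagonal; \code{NA} marks a
#' pair for which the source carries no information.
#'
#' @slot genes ordered gene identifiers.
#' @slot D numeric matrix, genes x genes.
#' @slot sourceTag one of \code{go_bp}, \code{go_mf}, \code{go_cc},
#'   \code{pubs}, \code{expression}.
#' @aliases GeneDistanceMatrix-class
#' @exportClass GeneDistanceMatrix
setClass("GeneDistanceMatrix",
  representation(genes = "character", D = "matrix", sourceTag = "character"))

setValidity("GeneDistanceMatrix", function(object) {
  msg <- character()
  D <- object@D
  n <- length(object@genes)
  if (!is.numeric(D) || nrow(D) != n || ncol(D) != n)
    return("D must be a numeric genes x genes matrix")
  if (!identical(rownames(D), object@genes) ||
      !identical(colnames(D), object@genes))
    msg <- c(msg, "dimnames of D must equal genes")
  if (!.isSymmetricNA(D)) msg <- c(msg, "D must be symmetric (NA-aware)")
  if (any(diag(D) != 0, na.rm = TRUE) || anyNA(diag(D)))
    msg <- c(msg, "diagonal of D must be 0")
  if (any(D < 0, na.rm = TRUE)) msg <- c(msg, "distances must be >= 0")
  if (any(is.infinite(D))) msg <- c(msg, "non-missing entries must be finite")
  if (length(object@sourceTag) != 1L ||
      !object@sourceTag %in% .SOURCE_TAGS)
    msg <- c(msg, paste("sourceTag must be one of",
                        paste(.SOURCE_TAGS, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Gene-gene affinity matrix
#'
#' Gaussian-kernel transformed similarities, possibly fused over several
#' sources by element-wise summation. Diagonal is zero (Ng-Jordan-Weiss
#' convention); single-source entries lie in [0, 1] and a fusion of m
#' sources in [0, m]. Missing distance pairs contribute affinity 0.
#'
#' @slot genes ordered gene identifiers.
#' @slot A numeric matrix, genes x genes.
#' @slot fusedFrom source tags that contributed to A.
#' @slot sigma named numeric, bandwidth used for each contributing source.
#' @aliases GeneAffinityMatrix-class
#' @exportClass GeneAffinityMatrix
setClass("GeneAffinityMatrix",
  representation(genes = "character", A = "matrix", fusedFrom = "character",
                 sigma = "numeric"))

setValidity("GeneAffinityMatrix", function(object) {
  msg <- character()
  A <- object@A
  n <- length(object@genes)
  if (!is.numeric(A) || nrow(A) != n || ncol(A) != n)
    return("A must be a numeric genes x genes matrix")
  if (anyNA(A)) msg <- c(msg, "affinities must not contain NA")
  if (!.isSymmetricNA(A)) msg <- c(msg, "A must be symmetric")
  if (any(diag(A) != 0)) msg <- c(msg, "diagonal of A must be 0")
  m <- max(1L, length(object@fusedFrom))
  if (any(A < 0) || any(A > m + 1e-9))
    msg <- c(msg, "entries must lie in [0, number of fused sources]")
  if (length(msg)) msg else TRUE
})

#' Normalized Laplacian (as used in spectral clustering)
#'
#' \code{L = D^{-1/2} A D^{-1/2}} where \code{D} is the diagonal matrix of
#' row sums of the affinity matrix. Note this is the similarity-normalized
#' operator whose top eigenvectors embed the genes, not the graph-theoretic
#' Laplacian \code{I - L}.
#'
#' @slot L symmetric numeric matrix with spectrum in [-1, 1].
#' @slot rowSums affinity row sums used in the normalization.
#' @slot genes ordered gene identifiers.
#' @aliases SpectralLaplacian-class
#' @exportClass SpectralLaplacian
setClass("SpectralLaplacian",
  representation(L = "matrix", rowSums = "numeric", genes = "character"))

#' Spectral embedding
#'
#' Rows are genes embedded by the k leading eigenvectors of the normalized
#' Laplacian, each row scaled to unit Euclidean length.
#'
#' @slot Y numeric matrix, genes x k, unit-norm rows (degenerate rows are
#'   all-zero and listed in \code{degenerate}).
#' @slot k number of eigenvectors used.
#' @slot eigenvalues the k largest eigenvalues, descending.
#' @slot genes ordered gene identifiers.
#' @slot degenerate genes whose unnormalized embedding row was all-zero
#'   (possible when fewer than k eigenvectors touch a disconnected block).
#' @aliases SpectralEmbedding-class
#' @exportClass SpectralEmbedding
setClass("SpectralEmbedding",
  representation(Y = "matrix", k = "integer", eigenvalues = "numeric",
                 genes = "character", degenerate = "character"))

setValidity("SpectralEmbedding", function(object) {
  msg <- character()
  if (nrow(object@Y) != length(object@genes))
    msg <- c(msg, "one row per gene required")
  if (ncol(object@Y) != object@k) msg <- c(msg, "Y must have k columns")
  rn <- sqrt(rowSums(object@Y^2))
  isDegen <- object@genes %in% object@degenerate
  if (any(abs(rn[!isDegen] - 1) > 1e-8))
    msg <- c(msg, "every non-degenerate row of Y must have unit norm")
  if (any(rn[isDegen] > 1e-8))
    msg <- c(msg, "degenerate rows must be all-zero")
  if (is.unsorted(rev(object@eigenvalues)))
    msg <- c(msg, "eigenvalues must be in descending order")
  if (length(msg)) msg else TRUE
})

#' Cluster assignment with silhouette annotation
#'
#' @slot genes ordered gene identifiers.
#' @slot labels integer cluster labels in 1..k, one per gene.
#' @slot k number of clusters.
#' @slot silhouette per-gene silhouette value in [-1, 1] (singletons get 0).
#' @slot clusterSilhouette per-cluster mean silhouette, named by label.
#' @slot seed seed used for centroid initialization.
#' @aliases GeneClustering-class
#' @exportClass GeneClustering
setClass("GeneClustering",
  representation(genes = "character", labels = "integer", k = "integer",
                 silhouette = "numeric", clusterSilhouette = "numeric",
                 seed = "integer"))

setValidity("GeneClustering", function(object) {
  msg <- character()
  n <- length(object@genes)
  if (length(object@labels) != n) msg <- c(msg, "one label per gene")
  used <- sort(unique(object@labels))
  if (!identical(used, seq_len(object@k)))
    msg <- c(msg, "labels must use every value in 1..k")
  if (length(object@silhouette) != n)
    msg <- c(msg, "one silhouette value per gene")
  if (length(msg)) msg else TRUE
})

#' Pair-counting evaluation scores
#'
#' @slot precision,recall,f1 pair-counting scores in [0, 1].
#' @slot truePairs,predictedPairs,agreeingPairs pair counts.
#' @aliases EvalScores-class
#' @exportClass EvalScores
setClass("EvalScores",
  representation(precision = "numeric", recall = "numeric", f1 = "numeric",
                 truePairs = "integer", predictedPairs = "integer",
                 agreeingPairs = "integer"))

setValidity("EvalScores", function(object) {
  msg <- character()
  if (object@agreeingPairs > min(object@truePairs, object@predictedPairs))
    msg <- c(msg, "agreeing pairs cannot exceed either pair count")
  pr <- object@precision + object@recall
  f1 <- if (pr > 0) 2 * object@precision * object@recall / pr else 0
  if (abs(f1 - object@f1) > 1e-12)
    msg <- c(msg, "f1 inconsistent with precision and recall")
  if (length(msg)) msg else TRUE
})

#' Collection of reference gene sets
#'
#' GMT-style named gene sets plus an optional genome (superset of all set
#' members) used for noise sampling in simulations.
#'
#' @slot sets named list of character vectors (each of length >= 2).
#' @slot genome character vector; all set members plus extra genes.
#' @aliases GeneSetList-class
#' @exportClass GeneSetList
setClass("GeneSetList",
  representation(sets = "list", genome = "character"))

setValidity("GeneSetList", function(object) {
  msg <- character()
  if (any(lengths(object@sets) < 2L))
    msg <- c(msg, "every gene set needs >= 2 members")
  if (is.null(names(object@sets)) || anyDuplicated(names(object@sets)))
    msg <- c(msg, "sets must have unique names")
  uni <- unique(unlist(object@sets, use.names = FALSE))
  if (length(object@genome) && !all(uni %in% object@genome))
    msg <- c(msg, "set members must be contained in the genome")
  if (length(msg)) msg else TRUE
})

#' One simulated gene-list mixing run
#'
#' @slot genes ordered gene identifiers of the mixed (and noise-injected)
#'   list.
#' @slot labels true source-set label per gene; noise genes are labeled
#'   \code{"noise"}.
#' @slot multiLabel genes belonging to more than one mixed set (excluded
#'   from pair-counting).
#' @slot kPlanted number of mixed sets.
#' @slot nominalNoise requested noise fraction of the final list.
#' @slot realizedNoise noise fraction after information-availability
#'   filtering (NA until a pipeline run computes it).
#' @slot seed seed of the run.
#' @aliases SimulationRun-class
#' @exportClass SimulationRun
setClass("SimulationRun",
  representation(genes = "character", labels = "character",
                 multiLabel = "character", kPlanted = "integer",
                 nominalNoise = "numeric", realizedNoise = "numeric",
                 seed = "integer"))

setValidity("SimulationRun", function(object) {
  msg <- character()
  if (length(object@labels) != length(object@genes))
    msg <- c(msg, "one true label per gene")
  if (anyDuplicated(object@genes)) msg <- c(msg, "genes must be unique")
  if (object@nominalNoise < 0 || object@nominalNoise >= 1)
    msg <- c(msg, "nominal noise fraction must lie in [0, 1)")
  if (length(msg)) msg else TRUE
})
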