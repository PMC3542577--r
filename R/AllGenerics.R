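#' Gene identifiers of an object
#'
#' @param x an object holding an ordered gene list.
#' @return character vector of gene identifiers.
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @describeIn geneIds genes of a distance matrix
setMethod("geneIds", "GeneDistanceMatrix", function(x) x@genes)
#' @describeIn geneIds genes of an affinity matrix
setMethod("geneIds", "GeneAffinityMatrix", function(x) x@genes)
#' @describeIn geneIds genes of a Laplacian
setMethod("geneIds", "SpectralLaplacian", function(x) x@genes)
#' @describeIn geneIds genes of an embedding
setMethod("geneIds", "SpectralEmbedding", function(x) x@genes)
#' @describeIn geneIds genes of a clustering
setMethod("geneIds", "GeneClustering", function(x) x@genes)
#' @describeIn geneIds genes of a term graph
setMethod("geneIds", "TermGraph", function(x) x@genes)
#' @describeIn geneIds genes of a simulation run
setMethod("geneIds", "SimulationRun", function(x) x@genes)

#' Source tag of a per-source matrix
#'
#' @param x a \code{GeneDistanceMatrix} or \code{GeneAffinityMatrix}.
#' @return character tag(s) identifying the information source(s).
#' @export
setGeneric("sourceTag", function(x) standardGeneric("sourceTag"))
#' @describeIn sourceTag tag of a distance matrix
setMethod("sourceTag", "GeneDistanceMatrix", function(x) x@sourceTag)
#' @describeIn sourceTag tags fused into an affinity matrix
setMethod("sourceTag", "GeneAffinityMatrix", function(x) x@fusedFrom)

#' Cluster labels of a clustering
#'
#' @param x a \code{GeneClustering}.
#' @return named integer vector of labels in 1..k.
#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))
#' @describeIn clusterLabels labels named by gene
setMethod("clusterLabels", "GeneClustering", function(x)
  stats::setNames(x@labels, x@genes))

#' Silhouette values
#'
#' @param x a \code{GeneClustering}.
#' @param perCluster if TRUE return per-cluster mean silhouettes instead of
#'   per-gene values.
#' @return named numeric vector.
#' @export
setGeneric("silhouetteValues",
           function(x, perCluster = FALSE) standardGeneric("silhouetteValues"))
#' @describeIn silhouetteValues per-gene (default) or per-cluster values
setMethod("silhouetteValues", "GeneClustering", function(x, perCluster = FALSE) {
  if (perCluster) x@clusterSilhouette
  else stats::setNames(x@silhouette, x@genes)
})

#' True labels of a simulation run
#'
#' @param x a \code{SimulationRun}.
#' @return named character vector of planted labels (noise genes = "noise").
#' @export
setGeneric("trueLabels", function(x) standardGeneric("trueLabels"))
#' @describeIn trueLabels labels named by gene
setMethod("trueLabels", "SimulationRun", function(x)
  stats::setNames(x@labels, x@genes))

#' @export
setMethod("as.matrix", "GeneDistanceMatrix", function(x, ...) x@D)
#' @export
setMethod("as.matrix", "GeneAffinityMatrix", function(x, ...) x@A)
#' @export
setMethod("as.matrix", "SpectralLaplacian", function(x, ...) x@L)
#' @export
setMethod("as.matrix", "SpectralEmbedding", function(x, ...) x@Y)

setMethod("show", "Ontology", function(object) {
  cat("Ontology with", length(object@terms), "terms and",
      nrow(object@edges), "parent-child edges\n")
  tab <- table(object@aspect[object@terms])
  cat("  aspects:", paste(names(tab), tab, sep = ":", collapse = ", "), "\n")
})

setMethod("show", "AnnotationTable", function(object) {
  cat("AnnotationTable with", nrow(object@records), "records:",
      length(unique(object@records$gene)), "genes,",
      length(unique(object@records$term)), "terms\n")
})

setMethod("show", "TermGraph", function(object) {
  cat("TermGraph (", object@aspect, "): ", length(object@terms), " terms, ",
      length(object@genes), " genes, ",
      igraph::ecount(object@graph), " edges\n", sep = "")
})

setMethod("show", "GeneDistanceMatrix", function(object) {
  n <- length(object@genes)
  cat("GeneDistanceMatrix [", object@sourceTag, "] ", n, " x ", n,
      "; missing pairs: ", sum(is.na(object@D[upper.tri(object@D)])),
      "\n", sep = "")
})

setMethod("show", "GeneAffinityMatrix", function(object) {
  n <- length(object@genes)
  cat("GeneAffinityMatrix ", n, " x ", n, " fused from: ",
      paste(object@fusedFrom, collapse = " + "), "\n", sep = "")
})

setMethod("show", "SpectralLaplacian", function(object) {
  cat("SpectralLaplacian over", length(object@genes), "genes\n")
})

setMethod("show", "SpectralEmbedding", function(object) {
  cat("SpectralEmbedding:", length(object@genes), "genes in k =", object@k,
      "dimensions; top eigenvalues:",
      paste(signif(utils::head(object@eigenvalues, 3), 4), collapse = ", "),
      "\n")
})

setMethod("show", "GeneClustering", function(object) {
  cat("GeneClustering of", length(object@genes), "genes into k =",
      object@k, "clusters\n")
  cat("  mean silhouette:", signif(mean(object@silhouette), 4), "\n")
})

setMethod("show", "EvalScores", function(object) {
  cat(sprintf(
    "EvalScores: precision %.4f, recall %.4f, F1 %.4f (%d/%d/%d pairs)\n",
    object@precision, object@recall, object@f1,
    object@agreeingPairs, object@truePairs, object@predictedPairs))
})

setMethod("show", "GeneSetList", function(object) {
  cat("GeneSetList:", length(object@sets), "sets over",
      length(unique(unlist(object@sets))), "genes; genome size",
      length(object@genome), "\n")
})

setMethod("show", "SimulationRun", function(object) {
  cat("SimulationRun:", length(object@genes), "genes,",
      object@kPlanted, "planted sets; nominal noise",
      object@nominalNoise, "\n")
})
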