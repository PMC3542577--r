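#' Construct a GeneDistanceMatrix
#'
#' @param D square numeric matrix (NA = missing pair); the diagonal is
#'   forced to 0.
#' @param genes gene identifiers (defaults to rownames of D).
#' @param sourceTag one of \code{go_bp}, \code{go_mf}, \code{go_cc},
#'   \code{pubs}, \code{expression}.
#' @return a \code{\link{GeneDistanceMatrix-class}} object.
#' @export
geneDistanceMatrix <- function(D, genes = rownames(D), sourceTag) {
  D <- as.matrix(D)
  genes <- as.character(genes)
  dimnames(D) <- list(genes, genes)
  diag(D) <- 0
  D <- .symmetrize(D)
  new("GeneDistanceMatrix", genes = genes, D = D, sourceTag = sourceTag)
}

#' Build the weighted term graph for one ontology aspect
#'
#' Vertices are the annotated terms of the aspect (terms with at least one
#' annotation instance, since information content is undefined otherwise);
#' each ontology parent-child edge whose endpoints both have defined IC gets
#' weight \code{|IC(parent) - IC(child)|}. Every gene annotated in the
#' aspect is attached to each of its annotating terms by a weight-0 edge, so
#' gene-gene shortest paths reduce to minimum term-term distances.
#'
#' @param ont an \code{Ontology}.
#' @param ann a filtered \code{AnnotationTable}.
#' @param aspect one of \code{biological_process},
#'   \code{molecular_function}, \code{cellular_component}.
#' @param propagate counting convention for IC, see
#'   \code{\link{instanceCounts}}.
#' @return a \code{\link{TermGraph-class}} object.
#' @export
buildTermGraph <- function(ont, ann, aspect, propagate = FALSE) {
  stopifnot(is(ont, "Ontology"), is(ann, "AnnotationTable"))
  aspect <- match.arg(aspect, unname(.ASPECTS))
  if (nrow(ann@records) == 0L)
    stop("annotation table is empty", call. = FALSE)
  ic <- informationContent(NULL, ann, propagate = propagate,
                           ont = if (propagate) ont else NULL)
  aspTerms <- .termsOfAspect(ont, aspect)
  terms <- intersect(aspTerms, names(ic))
  if (!length(terms))
    stop("no annotated terms in aspect '", aspect, "'", call. = FALSE)

  ed <- ont@edges
  keep <- ed$parent %in% terms & ed$child %in% terms
  ed <- ed[keep, , drop = FALSE]

  rec <- ann@records[ann@records$term %in% terms, , drop = FALSE]
  genes <- unique(rec$gene)

  termEdges <- if (nrow(ed)) {
    data.frame(from = paste0("t:", ed$parent), to = paste0("t:", ed$child),
               weight = unname(abs(ic[ed$parent] - ic[ed$child])),
               stringsAsFactors = FALSE)
  } else {
    data.frame(from = character(0), to = character(0), weight = numeric(0))
  }
  edges <- rbind(
    termEdges,
    data.frame(from = paste0("g:", rec$gene), to = paste0("t:", rec$term),
               weight = 0, stringsAsFactors = FALSE))
  edges <- unique(edges)
  vertices <- data.frame(name = c(paste0("t:", terms), paste0("g:", genes)),
                         stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = vertices)
  new("TermGraph", graph = g, aspect = aspect, genes = genes, terms = terms)
}

#' Functional distance between two genes on the term graph
#'
#' Weight of the minimum-weight path between the two gene vertices
#' (Dijkstra on the nonnegatively weighted graph). Returns \code{NA} when
#' either gene is absent from the graph or no path exists, so list-level
#' assembly can record the pair as missing.
#'
#' @param graph a \code{TermGraph}.
#' @param geneA,geneB gene identifiers.
#' @return nonnegative numeric, or \code{NA} (missing information).
#' @export
geneDistance <- function(graph, geneA, geneB) {
  stopifnot(is(graph, "TermGraph"))
  if (!(geneA %in% graph@genes) || !(geneB %in% graph@genes))
    return(NA_real_)
  if (geneA == geneB) return(0)
  d <- igraph::distances(graph@graph, v = paste0("g:", geneA),
                         to = paste0("g:", geneB),
                         weights = igraph::E(graph@graph)$weight,
                         algorithm = "dijkstra")[1L, 1L]
  if (is.infinite(d)) NA_real_ else d
}

#' Per-aspect GO distance matrices for a gene list
#'
#' Builds the weighted term graph for each GO aspect and fills a symmetric
#' gene-gene distance matrix with shortest-path distances. Pairs involving a
#' gene with no surviving annotation in the aspect, or genes in disconnected
#' components, are missing (\code{NA}). An aspect in which no listed gene is
#' annotated yields an all-missing matrix with a warning; if that holds for
#' all three aspects an error names the source.
#'
#' @param genes ordered gene identifiers (non-empty).
#' @param ont an \code{Ontology}.
#' @param ann an \code{AnnotationTable}; filtered here with
#'   \code{\link{filterAnnotations}} unless \code{filter = FALSE}.
#' @param filter apply the evidence-code exclusion list first?
#' @param propagate counting convention for IC.
#' @return named list of three \code{GeneDistanceMatrix} objects
#'   (\code{go_bp}, \code{go_mf}, \code{go_cc}).
#' @export
goDistanceMatrices <- function(genes, ont, ann, filter = TRUE,
                               propagate = FALSE) {
  genes <- as.character(genes)
  if (!length(genes)) stop("gene list is empty", call. = FALSE)
  if (filter) ann <- filterAnnotations(ann)
  out <- list()
  anyInfo <- FALSE
  for (tag in names(.ASPECTS)) {
    aspect <- .ASPECTS[[tag]]
    D <- matrix(NA_real_, length(genes), length(genes),
                dimnames = list(genes, genes))
    tg <- tryCatch(buildTermGraph(ont, ann, aspect, propagate = propagate),
                   error = function(e) NULL)
    if (is.null(tg) || !length(intersect(genes, tg@genes))) {
      warning("no gene in the list is annotated in aspect '", aspect,
              "' (source ", tag, "); all pairs missing", call. = FALSE)
    } else {
      present <- intersect(genes, tg@genes)
      dd <- igraph::distances(tg@graph, v = paste0("g:", present),
                              to = paste0("g:", present),
                              weights = igraph::E(tg@graph)$weight,
                              algorithm = "dijkstra")
      dd[is.infinite(dd)] <- NA_real_
      D[present, present] <- dd
      anyInfo <- TRUE
    }
    diag(D) <- 0
    out[[tag]] <- geneDistanceMatrix(D, genes, sourceTag = tag)
  }
  if (!anyInfo)
    stop("no gene in the list is annotated in any GO aspect ",
         "(sources go_bp, go_mf, go_cc)", call. = FALSE)
  out
}
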