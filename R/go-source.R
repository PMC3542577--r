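#' Construct an Ontology
#'
#' @param terms character vector of term identifiers.
#' @param edges data.frame with columns \code{parent}, \code{child} and
#'   optionally \code{relation} (default \code{"is_a"}).
#' @param aspect named character vector mapping terms to aspects, or a
#'   single aspect recycled over all terms.
#' @return an \code{\link{Ontology-class}} object.
#' @examples
#' ont <- ontology(c("R", "A", "B"),
#'                 data.frame(parent = "R", child = c("A", "B")),
#'                 aspect = "biological_process")
#' @export
ontology <- function(terms, edges = data.frame(parent = character(),
                                               child = character()),
                     aspect = "biological_process") {
  if (is.null(edges$relation)) edges$relation <- rep("is_a", nrow(edges))
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (length(aspect) == 1L && is.null(names(aspect)))
    aspect <- stats::setNames(rep(aspect, length(terms)), terms)
  new("Ontology", terms = as.character(terms),
      edges = edges[, c("parent", "child", "relation")],
      aspect = aspect)
}

#' Construct an AnnotationTable
#'
#' @param gene,term,evidence parallel character vectors, or a data.frame in
#'   \code{gene} with those columns.
#' @return an \code{\link{AnnotationTable-class}} object.
#' @export
annotationTable <- function(gene, term = NULL, evidence = "EXP") {
  if (is.data.frame(gene)) {
    rec <- gene
  } else {
    rec <- data.frame(gene = as.character(gene), term = as.character(term),
                      evidence = rep_len(as.character(evidence), length(gene)),
                      stringsAsFactors = FALSE)
  }
  rownames(rec) <- NULL
  new("AnnotationTable", records = rec[, c("gene", "term", "evidence")])
}

#' Evidence codes excluded from the term graph
#'
#' Annotation records carrying electronically inferred or otherwise
#' low-confidence evidence are dropped before distances are computed:
#' IEA (electronic annotation), ISS/ISO/ISA/ISM (sequence similarity,
#' orthology, alignment, model), IGC (genomic context) and RCA (reviewed
#' computational analysis).
#'
#' @return character vector of excluded evidence codes.
#' @export
excludedEvidenceCodes <- function() {
  c("IEA", "ISS", "ISO", "ISA", "ISM", "IGC", "RCA")
}

#' Filter annotation records by evidence code
#'
#' Removes records whose evidence code is in the exclusion list and leaves
#' the order of surviving records unchanged. Instance counts (and hence
#' information content) are always derived from the surviving records.
#'
#' @param ann an \code{AnnotationTable}.
#' @param exclude evidence codes to drop; defaults to
#'   \code{\link{excludedEvidenceCodes}()}.
#' @return a filtered \code{AnnotationTable} (possibly with zero records).
#' @export
filterAnnotations <- function(ann, exclude = excludedEvidenceCodes()) {
  stopifnot(is(ann, "AnnotationTable"))
  keep <- !(ann@records$evidence %in% exclude)
  annotationTable(ann@records[keep, , drop = FALSE])
}

#' Annotation instance counts per term
#'
#' By default each record counts once for the term it names (direct
#' counting). With \code{propagate = TRUE} a record also counts for every
#' ancestor of its term (true-path up-propagation, classic Resnik-style),
#' which requires the ontology. The total number of instances is the number
#' of records in either convention, so the propagated probability of a root
#' term approaches 1.
#'
#' @param ann an \code{AnnotationTable}.
#' @param propagate propagate counts to ancestor terms?
#' @param ont an \code{Ontology}; required when \code{propagate = TRUE}.
#' @return named integer vector of counts (only terms with count >= 1).
#' @export
instanceCounts <- function(ann, propagate = FALSE, ont = NULL) {
  stopifnot(is(ann, "AnnotationTable"))
  rec <- ann@records
  if (!propagate) {
    tab <- table(rec$term)
    return(stats::setNames(as.integer(tab), names(tab)))
  }
  if (is.null(ont))
    stop("propagated counting requires the ontology", call. = FALSE)
  anc <- .ancestorSets(ont)
  counts <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(rec))) {
    for (t in c(rec$term[i], anc[[rec$term[i]]])) {
      counts[[t]] <- (if (is.null(counts[[t]])) 0L else counts[[t]]) + 1L
    }
  }
  out <- unlist(as.list(counts))
  out[order(names(out))]
}

# term -> character vector of all ancestors (via is_a/part_of, child->parent)
.ancestorSets <- function(ont) {
  g <- igraph::graph_from_data_frame(
    ont@edges[, c("child", "parent")], directed = TRUE,
    vertices = data.frame(name = ont@terms))
  reach <- igraph::ego(g, order = igraph::vcount(g), mode = "out")
  stats::setNames(lapply(seq_along(reach), function(i)
    setdiff(names(reach[[i]]), ont@terms[i])), ont@terms)
}

#' Total number of annotation instances
#'
#' @param ann an \code{AnnotationTable}.
#' @return number of annotation records.
#' @export
totalInstances <- function(ann) {
  stopifnot(is(ann, "AnnotationTable"))
  nrow(ann@records)
}

#' Information content of a term
#'
#' \code{IC(t) = -ln P(t)}, where \code{P(t)} is the number of annotation
#' instances for the term divided by the total number of instances in the
#' table. Measured in nats; 0 when the term accounts for every instance,
#' and strictly increasing as the term's share decreases.
#'
#' @param term term identifier (or NULL for all counted terms).
#' @param ann an \code{AnnotationTable} (filter it first; see
#'   \code{\link{filterAnnotations}}).
#' @param propagate,ont counting convention, see
#'   \code{\link{instanceCounts}}.
#' @return nonnegative numeric, named by term.
#' @examples
#' ann <- annotationTable(paste0("g", 1:4), c("A", "R", "R", "R"))
#' informationContent("A", ann)   # -ln(1/4)
#' @export
informationContent <- function(term = NULL, ann, propagate = FALSE,
                               ont = NULL) {
  counts <- instanceCounts(ann, propagate = propagate, ont = ont)
  total <- totalInstances(ann)
  if (total < 1L) stop("annotation table is empty", call. = FALSE)
  if (is.null(term)) return(-log(counts / total))
  missing <- setdiff(term, names(counts))
  if (length(missing))
    stop("information content undefined (no annotation instances) for: ",
         paste(missing, collapse = ", "), call. = FALSE)
  -log(counts[term] / total)
}

#' Semantic distance between a parent-child term pair
#'
#' The absolute difference in information content of the two terms,
#' \code{|IC(parent) - IC(child)|}, defined only on ontology parent-child
#' edges. Symmetric in its arguments; zero exactly when both terms carry
#' the same annotation share.
#'
#' @param parent,child term identifiers forming an ontology edge.
#' @param ann an \code{AnnotationTable}.
#' @param ont the \code{Ontology} (used to verify adjacency).
#' @param propagate counting convention, see \code{\link{instanceCounts}}.
#' @return nonnegative numeric (nats).
#' @export
semanticDistance <- function(parent, child, ann, ont, propagate = FALSE) {
  ed <- ont@edges
  adjacent <- any((ed$parent == parent & ed$child == child) |
                  (ed$parent == child & ed$child == parent))
  if (!adjacent)
    stop("semantic distance is defined only on ontology parent-child edges; ",
         parent, " and ", child, " are not adjacent", call. = FALSE)
  ic <- informationContent(c(parent, child), ann, propagate = propagate,
                           ont = if (propagate) ont else NULL)
  unname(abs(ic[1L] - ic[2L]))
}

#' Aspect of each term, restricted to one namespace
#' @noRd
.termsOfAspect <- function(ont, aspect) {
  names(ont@aspect)[ont@aspect == aspect]
}

.ASPECTS <- c(go_bp = "biological_process", go_mf = "molecular_function",
              go_cc = "cellular_component")
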