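## Readers for the standard external formats (OBO 1.2, GAF 2.x,
## gene2pubmed, GMT, gene lists, expression TSV) and round-trip
## writers/readers for the package's own matrices and manifests.
## Numeric values are serialized at full double precision.

.fmtNum <- function(x) {
  out <- vapply(x, function(v)
    if (is.na(v)) "NA" else sprintf("%.17g", v), character(1))
  out
}

#' Read a plain-text gene list
#'
#' One identifier per line; blank lines and lines starting with '#' are
#' skipped.
#'
#' @param path file path.
#' @return character vector of gene identifiers.
#' @export
readGeneList <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  x[nzchar(x) & !startsWith(x, "#")]
}

#' Read an OBO 1.2 ontology file
#'
#' Parses \code{[Term]} stanzas (fields \code{id}, \code{namespace},
#' \code{is_a}, \code{relationship: part_of}); obsolete terms are skipped
#' and edges are kept only when both endpoints are non-obsolete terms of
#' the same aspect.
#'
#' @param path file path.
#' @return an \code{Ontology}.
#' @export
readOBO <- function(path) {
  lines <- readLines(path, warn = FALSE)
  terms <- character(0)
  aspect <- character(0)
  parents <- list()
  cur <- NULL; curNs <- NA_character_; curObs <- FALSE
  curPar <- character(0); curRel <- character(0)
  inTerm <- FALSE
  flush <- function() {
    if (!is.null(cur) && !curObs && !is.na(curNs)) {
      terms <<- c(terms, cur)
      aspect[cur] <<- curNs
      parents[[cur]] <<- data.frame(parent = curPar, relation = curRel,
                                    stringsAsFactors = FALSE)
    }
  }
  for (ln in lines) {
    ln <- trimws(ln)
    if (startsWith(ln, "[")) {
      flush()
      inTerm <- identical(ln, "[Term]")
      cur <- NULL; curNs <- NA_character_; curObs <- FALSE
      curPar <- character(0); curRel <- character(0)
      next
    }
    if (!inTerm || !nzchar(ln)) next
    ln <- sub("\\s*!.*$", "", ln)    # strip trailing comments
    if (startsWith(ln, "id:")) cur <- trimws(sub("^id:", "", ln))
    else if (startsWith(ln, "namespace:"))
      curNs <- trimws(sub("^namespace:", "", ln))
    else if (startsWith(ln, "is_obsolete:"))
      curObs <- grepl("true", ln, fixed = TRUE)
    else if (startsWith(ln, "is_a:")) {
      curPar <- c(curPar, trimws(sub("^is_a:", "", ln)))
      curRel <- c(curRel, "is_a")
    } else if (grepl("^relationship:\\s*part_of\\b", ln)) {
      curPar <- c(curPar,
                  trimws(sub("^relationship:\\s*part_of", "", ln)))
      curRel <- c(curRel, "part_of")
    }
  }
  flush()
  edges <- do.call(rbind, lapply(names(parents), function(child) {
    p <- parents[[child]]
    if (!nrow(p)) return(NULL)
    data.frame(parent = p$parent, child = child, relation = p$relation,
               stringsAsFactors = FALSE)
  }))
  if (is.null(edges))
    edges <- data.frame(parent = character(), child = character(),
                        relation = character())
  keep <- edges$parent %in% terms & edges$child %in% terms &
    aspect[edges$parent] == aspect[edges$child]
  ontology(terms, edges[keep, , drop = FALSE], aspect = aspect[terms])
}

#' Read a GAF 2.x annotation file
#'
#' Uses column 2 (gene product identifier), column 5 (term identifier) and
#' column 7 (evidence code); comment lines start with '!'. A line with
#' fewer than 9 tab-separated fields raises an error naming the line.
#'
#' @param path file path.
#' @return an unfiltered \code{AnnotationTable} (apply
#'   \code{\link{filterAnnotations}} before computing distances).
#' @export
readGAF <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(lines) & !startsWith(lines, "!"))
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 9L)
  if (length(bad))
    stop("malformed GAF line ", keep[bad[1L]], ": fewer than 9 fields",
         call. = FALSE)
  annotationTable(
    gene = vapply(fields, `[[`, character(1), 2L),
    term = vapply(fields, `[[`, character(1), 5L),
    evidence = vapply(fields, `[[`, character(1), 7L))
}

#' Read an NCBI gene2pubmed mapping
#'
#' Tab-separated columns tax_id, GeneID, PubMed_ID; lines starting with
#' '#' are skipped; optionally filtered to one taxon.
#'
#' @param path file path.
#' @param taxon optional taxon identifier to keep.
#' @return named list mapping gene identifier to unique publication ids.
#' @export
readGene2Pubmed <- function(path, taxon = NULL) {
  df <- utils::read.table(path, sep = "\t", comment.char = "#",
                          colClasses = "character",
                          col.names = c("tax_id", "GeneID", "PubMed_ID"))
  if (!is.null(taxon)) df <- df[df$tax_id == as.character(taxon), ]
  split(df$PubMed_ID, df$GeneID) |> lapply(unique)
}

#' Read an expression matrix TSV
#'
#' First column gene identifier, remaining columns samples, one header row.
#'
#' @param path file path.
#' @return numeric matrix, genes x samples.
#' @export
readExpressionMatrix <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, comment.char = "#")
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- as.character(df[[1L]])
  storage.mode(m) <- "double"
  m
}

#' Read a GMT-style gene-set collection
#'
#' One set per line: name, description, then tab-separated members. Sets
#' with fewer than 2 members are rejected with a warning.
#'
#' @param path file path.
#' @param genome optional genome for noise sampling.
#' @return a \code{GeneSetList}.
#' @export
readGMT <- function(path, genome = character(0)) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  sets <- stats::setNames(
    lapply(fields, function(f) f[-c(1L, 2L)]),
    vapply(fields, `[[`, character(1), 1L))
  geneSetList(sets, genome = genome)
}

#' Write a GMT-style gene-set collection
#'
#' @param x a \code{GeneSetList}.
#' @param path output path.
#' @export
writeGMT <- function(x, path) {
  stopifnot(is(x, "GeneSetList"))
  writeLines(vapply(names(x@sets), function(nm)
    paste(c(nm, "na", x@sets[[nm]]), collapse = "\t"), character(1)), path)
}

# Shared matrix TSV writer: comment header, gene-id header row, one row
# per gene with the gene id in the first field.
.writeMatrixTSV <- function(M, genes, path, comments) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(comments, con)
  writeLines(paste(c("gene", genes), collapse = "\t"), con)
  for (i in seq_along(genes))
    writeLines(paste(c(genes[i], .fmtNum(M[i, ])), collapse = "\t"), con)
  invisible(path)
}

.readMatrixTSV <- function(path) {
  lines <- readLines(path, warn = FALSE)
  comments <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  header <- strsplit(body[1L], "\t", fixed = TRUE)[[1L]][-1L]
  rows <- strsplit(body[-1L], "\t", fixed = TRUE)
  genes <- vapply(rows, `[[`, character(1), 1L)
  M <- do.call(rbind, lapply(rows, function(r)
    suppressWarnings(as.numeric(r[-1L]))))
  dimnames(M) <- list(genes, header)
  meta <- list()
  for (cm in comments) {
    kv <- sub("^#\\s*", "", cm)
    key <- sub(":.*$", "", kv)
    meta[[key]] <- trimws(sub("^[^:]*:", "", kv))
  }
  list(M = M, genes = genes, meta = meta)
}

#' Write / read a GeneDistanceMatrix as TSV
#'
#' Header row of gene identifiers, one data row per gene (gene id first),
#' missing pairs serialized as "NA", source tag and provenance in '#'
#' comment lines. Values round-trip at full double precision.
#'
#' @param x a \code{GeneDistanceMatrix}.
#' @param path file path.
#' @param provenance optional extra comment lines.
#' @return \code{writeDistanceMatrix}: the path, invisibly;
#'   \code{readDistanceMatrix}: a \code{GeneDistanceMatrix}.
#' @export
writeDistanceMatrix <- function(x, path, provenance = character(0)) {
  stopifnot(is(x, "GeneDistanceMatrix"))
  .writeMatrixTSV(x@D, x@genes, path,
                  c(paste0("#source: ", x@sourceTag),
                    if (length(provenance)) paste0("#", provenance)))
}

#' @rdname writeDistanceMatrix
#' @export
readDistanceMatrix <- function(path) {
  p <- .readMatrixTSV(path)
  geneDistanceMatrix(p$M, p$genes, sourceTag = p$meta$source)
}

#' Write / read a GeneAffinityMatrix as TSV
#'
#' @param x a \code{GeneAffinityMatrix}.
#' @param path file path.
#' @return \code{writeAffinityMatrix}: the path, invisibly;
#'   \code{readAffinityMatrix}: a \code{GeneAffinityMatrix}.
#' @export
writeAffinityMatrix <- function(x, path) {
  stopifnot(is(x, "GeneAffinityMatrix"))
  .writeMatrixTSV(x@A, x@genes, path, c(
    paste0("#fused_from: ", paste(x@fusedFrom, collapse = ",")),
    paste0("#sigma: ",
           paste(names(x@sigma), .fmtNum(unname(x@sigma)), sep = "=",
                 collapse = ","))))
}

#' @rdname writeAffinityMatrix
#' @export
readAffinityMatrix <- function(path) {
  p <- .readMatrixTSV(path)
  tags <- strsplit(p$meta$fused_from, ",", fixed = TRUE)[[1L]]
  sig <- strsplit(p$meta$sigma, ",", fixed = TRUE)[[1L]]
  sigma <- stats::setNames(
    as.numeric(sub("^[^=]*=", "", sig)), sub("=.*$", "", sig))
  new("GeneAffinityMatrix", genes = p$genes, A = p$M, fusedFrom = tags,
      sigma = sigma)
}

#' Write / read a SpectralEmbedding as TSV
#'
#' @param x a \code{SpectralEmbedding}.
#' @param path file path.
#' @return \code{writeEmbedding}: the path, invisibly;
#'   \code{readEmbedding}: a \code{SpectralEmbedding}.
#' @export
writeEmbedding <- function(x, path) {
  stopifnot(is(x, "SpectralEmbedding"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#eigenvalues: ",
                    paste(.fmtNum(x@eigenvalues), collapse = ",")), con)
  writeLines(paste(c("gene", paste0("Y", seq_len(x@k))),
                   collapse = "\t"), con)
  for (i in seq_along(x@genes))
    writeLines(paste(c(x@genes[i], .fmtNum(x@Y[i, ])), collapse = "\t"),
               con)
  invisible(path)
}

#' @rdname writeEmbedding
#' @export
readEmbedding <- function(path) {
  p <- .readMatrixTSV(path)
  Y <- p$M
  dimnames(Y) <- list(p$genes, NULL)
  new("SpectralEmbedding", Y = Y, k = ncol(Y),
      eigenvalues = as.numeric(
        strsplit(p$meta$eigenvalues, ",", fixed = TRUE)[[1L]]),
      genes = p$genes,
      degenerate = p$genes[sqrt(rowSums(Y^2)) < 1e-8])
}

#' Write / read a clustering result as TSV
#'
#' Columns: gene, cluster, silhouette, cluster_mean_silhouette, kept_flag
#' (kept = cluster mean silhouette > 0).
#'
#' @param x a \code{GeneClustering}.
#' @param path file path.
#' @return \code{writeClustering}: the path, invisibly;
#'   \code{readClustering}: a \code{GeneClustering}.
#' @export
writeClustering <- function(x, path) {
  stopifnot(is(x, "GeneClustering"))
  cs <- x@clusterSilhouette[as.character(x@labels)]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#seed: ", x@seed), con)
  writeLines("gene\tcluster\tsilhouette\tcluster_mean_silhouette\tkept_flag",
             con)
  for (i in seq_along(x@genes))
    writeLines(paste(c(x@genes[i], x@labels[i], .fmtNum(x@silhouette[i]),
                       .fmtNum(cs[i]), as.integer(cs[i] > 0)),
                     collapse = "\t"), con)
  invisible(path)
}

#' @rdname writeClustering
#' @export
readClustering <- function(path) {
  lines <- readLines(path, warn = FALSE)
  meta <- lines[startsWith(lines, "#")]
  seed <- as.integer(sub("^#seed:\\s*", "",
                         meta[startsWith(meta, "#seed:")][1L]))
  body <- lines[!startsWith(lines, "#")]
  rows <- strsplit(body[-1L], "\t", fixed = TRUE)
  genes <- vapply(rows, `[[`, character(1), 1L)
  labels <- as.integer(vapply(rows, `[[`, character(1), 2L))
  sil <- as.numeric(vapply(rows, `[[`, character(1), 3L))
  clSil <- as.numeric(vapply(rows, `[[`, character(1), 4L))
  cs <- tapply(clSil, labels, `[`, 1L)
  new("GeneClustering", genes = genes, labels = labels,
      k = as.integer(max(labels)), silhouette = sil,
      clusterSilhouette = stats::setNames(as.numeric(cs), names(cs)),
      seed = if (is.na(seed)) 0L else seed)
}

#' Write / read a run manifest (JSON)
#'
#' The manifest attached by \code{\link{partitionGeneList}} records the
#' selected bandwidths, the chosen k, the seed, the restart count and the
#' retained/dropped genes: everything needed for an exact re-run.
#'
#' @param manifest list, e.g. \code{attr(result, "manifest")}.
#' @param path file path.
#' @return \code{writeRunManifest}: the path, invisibly;
#'   \code{readRunManifest}: the manifest list.
#' @export
writeRunManifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' @rdname writeRunManifest
#' @export
readRunManifest <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  m$sigma <- as.list(m$sigma)
  m
}

#' Re-run a partition from its manifest
#'
#' Reproduces a \code{\link{partitionGeneList}} result exactly: bandwidths
#' and k are fixed to the manifest values, and seed/restarts are reused.
#'
#' @param manifest a run manifest (list or path to a manifest JSON).
#' @param sources the same distance sources the original run used.
#' @return a \code{GeneClustering} identical to the original.
#' @export
rerunPartition <- function(manifest, sources) {
  if (is.character(manifest)) manifest <- readRunManifest(manifest)
  partitionGeneList(manifest$inputGenes, sources, config = list(
    sigma = manifest$sigma, k = manifest$k, seed = manifest$seed,
    restarts = manifest$restarts, dropIsolated = manifest$dropIsolated))
}

#' Write / read a simulation score table (TSV)
#'
#' @param df long-format score table from \code{\link{runExperimentGrid}}.
#' @param path file path.
#' @return \code{writeScoreTable}: the path, invisibly;
#'   \code{readScoreTable}: the data.frame.
#' @export
writeScoreTable <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeScoreTable
#' @export
readScoreTable <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}

#' Read per-cluster p-values (two-column TSV: label, p)
#'
#' @param path file path.
#' @return named numeric vector of p-values.
#' @export
readClusterPvalues <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          comment.char = "#",
                          col.names = c("label", "p"),
                          colClasses = c("character", "numeric"))
  stats::setNames(df$p, df$label)
}
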