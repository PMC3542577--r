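# Shared fixtures and independent oracles used across test files.

# Tiny ontology R <- A, R <- B with annotation counts R:4, A:2, B:2
# (total 8): both edges have weight |ln(2/8) - ln(4/8)| = ln 2.
toyOntologyRAB <- function() {
  ontology(c("R", "A", "B"),
           data.frame(parent = "R", child = c("A", "B")),
           aspect = "biological_process")
}

toyAnnotationsRAB <- function() {
  annotationTable(
    gene = c(paste0("r", 1:4), "g1", "a2", "g2", "b2"),
    term = c(rep("R", 4), "A", "A", "B", "B"))
}

# Brute-force shortest gene-gene distance by enumerating all simple paths
# over the term graph's edge list (independent of igraph's Dijkstra).
bruteForceGeneDistance <- function(tg, geneA, geneB) {
  ed <- igraph::as_data_frame(tg@graph, what = "edges")
  adj <- list()
  addE <- function(u, v, w) adj[[u]] <<- rbind(adj[[u]],
                                               data.frame(v = v, w = w))
  for (i in seq_len(nrow(ed))) {
    addE(ed$from[i], ed$to[i], ed$weight[i])
    addE(ed$to[i], ed$from[i], ed$weight[i])
  }
  src <- paste0("g:", geneA); dst <- paste0("g:", geneB)
  if (is.null(adj[[src]]) || is.null(adj[[dst]])) return(NA_real_)
  best <- Inf
  dfs <- function(node, visited, total) {
    if (total >= best) return()
    if (node == dst) { best <<- total; return() }
    nb <- adj[[node]]
    if (is.null(nb)) return()
    for (i in seq_len(nrow(nb))) {
      if (!(nb$v[i] %in% visited))
        dfs(nb$v[i], c(visited, nb$v[i]), total + nb$w[i])
    }
  }
  dfs(src, src, 0)
  if (is.infinite(best)) NA_real_ else best
}

# Brute-force pair counting by explicit double loop over gene pairs.
bruteForcePairScores <- function(truth, pred) {
  genes <- names(truth)
  tp <- 0L; pp <- 0L; ag <- 0L
  n <- length(genes)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ct <- truth[[genes[i]]] == truth[[genes[j]]]
      cp <- pred[[genes[i]]] == pred[[genes[j]]]
      tp <- tp + ct; pp <- pp + cp; ag <- ag + (ct && cp)
    }
  }
  precision <- if (pp > 0) ag / pp else 0
  recall <- if (tp > 0) ag / tp else 0
  f1 <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  list(precision = precision, recall = recall, f1 = f1)
}

# Random small ontology + annotations over nTerms terms (a random tree with
# occasional extra edges) and nGenes genes annotated to random terms.
randomToyGO <- function(nTerms, nGenes, seed) {
  set.seed(seed)
  terms <- paste0("T", seq_len(nTerms))
  edges <- NULL
  if (nTerms > 1) {
    parent <- terms[vapply(2:nTerms, function(i)
      sample.int(i - 1L, 1L), integer(1))]
    edges <- data.frame(parent = parent, child = terms[-1L])
  }
  counts <- sample(1:5, nTerms, replace = TRUE)
  rec <- data.frame(
    gene = paste0("f", seq_len(sum(counts))),
    term = rep(terms, counts), evidence = "EXP")
  genes <- paste0("q", seq_len(nGenes))
  grec <- data.frame(gene = rep(genes, each = 2L),
                     term = sample(terms, 2L * nGenes, replace = TRUE),
                     evidence = "EXP")
  list(ont = ontology(terms, if (is.null(edges))
         data.frame(parent = character(), child = character()) else edges,
       aspect = "biological_process"),
       ann = annotationTable(rbind(rec, grec)),
       genes = genes)
}

# Two well-separated blocks as a distance matrix (within 0, between `gap`).
twoBlockDistance <- function(sizes = c(3, 3), gap = 10) {
  n <- sum(sizes)
  lab <- rep(seq_along(sizes), sizes)
  D <- matrix(gap, n, n)
  D[outer(lab, lab, `==`)] <- 0
  genes <- paste0("g", seq_len(n))
  dimnames(D) <- list(genes, genes)
  geneDistanceMatrix(D, genes, sourceTag = "pubs")
}

makeClustering <- function(labels, clusterSil, genes = NULL) {
  labels <- as.integer(labels)
  if (is.null(genes)) genes <- paste0("g", seq_along(labels))
  new("GeneClustering", genes = genes, labels = labels,
      k = max(labels),
      silhouette = unname(clusterSil[as.character(labels)]),
      clusterSilhouette = clusterSil, seed = 0L)
}
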