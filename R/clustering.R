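#' K-means partition of a spectral embedding
#'
#' Clusters the unit-norm embedding rows into k groups with the best
#' objective (total within-cluster sum of squares) over \code{restarts}
#' random initializations, deterministic for a given seed. Initial centers
#' are drawn from the distinct embedding rows, so clusters are never empty;
#' k may not exceed the number of distinct rows. Per-gene silhouette values
#' (computed on the embedding, singleton clusters scored 0) annotate the
#' result.
#'
#' @param emb a \code{SpectralEmbedding}.
#' @param k number of clusters.
#' @param seed integer seed for initialization.
#' @param restarts number of random restarts (best objective kept).
#' @return a \code{\link{GeneClustering-class}} object; the attained
#'   objective is attached as attribute \code{"objective"}.
#' @export
kmeansPartition <- function(emb, k, seed = 0L, restarts = 10L) {
  stopifnot(is(emb, "SpectralEmbedding"))
  Y <- emb@Y
  k <- as.integer(k)
  uY <- unique(Y)
  if (k > nrow(uY))
    stop("k = ", k, " exceeds the number of distinct embedding rows (",
         nrow(uY), "); K-means cannot form k non-empty clusters",
         call. = FALSE)
  if (k == nrow(uY)) {
    # each distinct position its own cluster: the exact optimum (cost 0)
    key <- apply(Y, 1L, paste, collapse = "\r")
    labels <- .relabelByFirstSeen(match(key, unique(key)))
    sil <- if (k >= 2L) .silhouetteWidths(Y, labels) else rep(0, nrow(Y))
    clSil <- tapply(sil, labels, mean)
    out <- new("GeneClustering", genes = emb@genes, labels = labels,
               k = k, silhouette = unname(sil),
               clusterSilhouette = stats::setNames(as.numeric(clSil),
                                                   names(clSil)),
               seed = as.integer(seed))
    attr(out, "objective") <- 0
    return(out)
  }
  best <- NULL
  withSeed(seed, {
    for (r in seq_len(max(1L, as.integer(restarts)))) {
      centers <- uY[sample.int(nrow(uY), k), , drop = FALSE]
      km <- tryCatch(
        suppressWarnings(stats::kmeans(Y, centers = centers,
                                       iter.max = 100L)),
        error = function(e) NULL)
      if (!is.null(km) &&
          (is.null(best) || km$tot.withinss < best$tot.withinss))
        best <- km
    }
  })
  if (is.null(best))
    stop("K-means failed for every restart", call. = FALSE)
  labels <- .relabelByFirstSeen(best$cluster)
  sil <- .silhouetteWidths(Y, labels)
  clSil <- tapply(sil, labels, mean)
  out <- new("GeneClustering", genes = emb@genes, labels = labels,
             k = k, silhouette = unname(sil),
             clusterSilhouette = stats::setNames(as.numeric(clSil),
                                                 names(clSil)),
             seed = as.integer(seed))
  attr(out, "objective") <- best$tot.withinss
  out
}

# Renumber labels 1..k in order of first appearance (determinism; label
# names are arbitrary and downstream evaluation is permutation-invariant).
.relabelByFirstSeen <- function(labels) {
  map <- stats::setNames(seq_along(unique(labels)), unique(labels))
  as.integer(map[as.character(labels)])
}

# Mean silhouette of a partition against a precomputed distance matrix;
# missing pairs are placed just beyond the largest observed distance.
.distanceSilhouette <- function(D, labels) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L)
    stop("silhouette is undefined for a single cluster", call. = FALSE)
  if (anyNA(D)) {
    mx <- suppressWarnings(max(D, na.rm = TRUE))
    if (!is.finite(mx)) mx <- 1
    D[is.na(D)] <- 1.05 * mx
  }
  sw <- cluster::silhouette(labels, dmatrix = D)
  w <- sw[, "sil_width"]
  w[!is.finite(w)] <- 0
  mean(w)
}

# Per-point silhouette widths on Euclidean distances; singleton clusters
# get width 0 (Rousseeuw's convention), as do points with 0/0 degeneracy.
.silhouetteWidths <- function(points, labels) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L)
    stop("silhouette is undefined for a single cluster", call. = FALSE)
  if (length(unique(labels)) == length(labels))
    return(rep(0, length(labels)))   # all singletons: Rousseeuw convention
  sw <- cluster::silhouette(labels, stats::dist(points))
  w <- sw[, "sil_width"]
  w[!is.finite(w)] <- 0
  w
}

#' Mean silhouette of a labeled point set
#'
#' Per-point silhouette \code{s = (b - a) / max(a, b)} with \code{a} the
#' mean within-cluster distance and \code{b} the smallest mean distance to
#' another cluster (Euclidean); singleton points score 0. Returns the mean
#' over all points.
#'
#' @param points numeric matrix, one row per point.
#' @param labels cluster labels (>= 2 distinct, all clusters non-empty).
#' @return mean silhouette in [-1, 1].
#' @export
meanSilhouette <- function(points, labels) {
  points <- as.matrix(points)
  stopifnot(nrow(points) == length(labels))
  mean(.silhouetteWidths(points, as.integer(factor(labels))))
}

#' Median-distance bandwidth heuristic
#'
#' The median positive non-missing distance of the source, a robust fixed
#' bandwidth that keeps within-module affinities high without collapsing
#' the kernel. Useful when the silhouette scan is unreliable, e.g. for a
#' source that cannot realize the provisional k on its own (see the
#' methods vignette).
#'
#' @param dist a \code{GeneDistanceMatrix}.
#' @return positive numeric bandwidth.
#' @export
medianSigma <- function(dist) {
  d <- dist@D[upper.tri(dist@D)]
  d <- d[!is.na(d) & d > 0]
  if (!length(d)) 1 else stats::median(d)
}

#' Default bandwidth grid for a distance source
#'
#' Log-spaced candidates between 0.01x and 10x the median positive
#' non-missing distance of the source (falling back to 1 when the source
#' has no positive distances).
#'
#' @param dist a \code{GeneDistanceMatrix}.
#' @param n number of grid points.
#' @param lower,upper multipliers of the median distance.
#' @return ascending numeric vector of candidate bandwidths.
#' @export
defaultSigmaGrid <- function(dist, n = 20L, lower = 0.01, upper = 10) {
  d <- dist@D[upper.tri(dist@D)]
  d <- d[!is.na(d) & d > 0]
  med <- if (length(d)) stats::median(d) else 1
  exp(seq(log(lower * med), log(upper * med), length.out = n))
}

#' Select the kernel bandwidth by maximizing the mean silhouette
#'
#' For each candidate bandwidth the full single-source chain is run
#' (Gaussian affinity, normalized Laplacian, k-eigenvector embedding,
#' K-means at the provisional k) and the resulting partition is scored by
#' its mean silhouette. The bandwidth with the highest silhouette wins;
#' ties go to the smallest candidate.
#'
#' With \code{silhouetteOn = "distance"} (the default) the silhouette is
#' computed against the source's own distances (missing pairs treated as
#' slightly beyond the largest observed distance), so a candidate is judged
#' by how well its partition fits the data. With \code{"embedding"} the
#' silhouette is computed on the spectral embedding coordinates; that
#' variant is self-referential (the geometry being scored depends on the
#' candidate itself) and can tie many candidates at a perfect silhouette,
#' including over-narrow kernels whose embedding collapses clusters onto
#' coincident points (see the methods vignette).
#'
#' Candidates whose chain degenerates are skipped: an isolated gene at
#' small bandwidth, or a kernel so narrow that the affinity graph falls
#' apart into more than k effective components (more than k eigenvalues of
#' the normalized Laplacian within 1e-4 of 1; the multiplicity of
#' eigenvalue 1 counts connected components, and eigenvalues within 1e-4
#' of it mark pieces coupled so weakly that the embedding treats them as
#' disconnected).
#'
#' @param dist a \code{GeneDistanceMatrix}.
#' @param k provisional number of clusters used during the scan.
#' @param grid candidate bandwidths (default
#'   \code{\link{defaultSigmaGrid}}).
#' @param seed,restarts passed to \code{\link{kmeansPartition}}.
#' @param dropIsolated during the scan, silently drop genes whose affinity
#'   row sum is zero at a candidate bandwidth (e.g. genes with no
#'   information in this source) instead of failing the candidate.
#' @param silhouetteOn metric space for scoring candidates: the source
#'   distances (default) or the embedding coordinates; see Details.
#' @return the selected bandwidth, with the full (sigma, silhouette) scan
#'   attached as attribute \code{"trace"} (a data.frame).
#' @export
selectSigma <- function(dist, k, grid = defaultSigmaGrid(dist), seed = 0L,
                        restarts = 10L, dropIsolated = FALSE,
                        silhouetteOn = c("embedding", "distance")) {
  stopifnot(is(dist, "GeneDistanceMatrix"), length(grid) >= 1L,
            all(grid > 0))
  silhouetteOn <- match.arg(silhouetteOn)
  grid <- sort(grid)
  sil <- rep(NA_real_, length(grid))
  errs <- rep(NA_character_, length(grid))
  for (i in seq_along(grid)) {
    res <- tryCatch({
      aff <- gaussianAffinity(dist, grid[i])
      if (dropIsolated) {
        keep <- rowSums(aff@A) > 0
        if (sum(keep) <= k)
          stop("fewer than k+1 genes remain after dropping isolated genes")
        aff <- new("GeneAffinityMatrix", genes = aff@genes[keep],
                   A = aff@A[keep, keep, drop = FALSE],
                   fusedFrom = aff@fusedFrom, sigma = aff@sigma)
      }
      lap <- normalizedLaplacian(aff)
      ev <- eigen(lap@L, symmetric = TRUE, only.values = TRUE)$values
      if (sum(ev >= 1 - 1e-4) > k)
        stop("affinity graph splits into more than k (near-)components ",
             "at this bandwidth")
      emb <- spectralEmbed(lap, k)
      cl <- kmeansPartition(emb, k, seed = seed, restarts = restarts)
      if (silhouetteOn == "embedding") meanSilhouette(emb@Y, cl@labels)
      else .distanceSilhouette(dist@D[lap@genes, lap@genes], cl@labels)
    }, error = function(e) e)
    if (inherits(res, "error")) errs[i] <- conditionMessage(res)
    else sil[i] <- res
  }
  trace <- data.frame(sigma = grid, silhouette = sil, error = errs)
  if (all(is.na(sil)))
    stop("every candidate bandwidth degenerated:\n",
         paste(sprintf("  sigma=%g: %s", grid, errs), collapse = "\n"),
         call. = FALSE)
  best <- which.max(sil)   # first (= smallest sigma) on exact ties
  out <- grid[best]
  attr(out, "trace") <- trace
  out
}

#' Select the number of clusters by maximizing the mean silhouette
#'
#' Scans k over a range (default 3-8). Each candidate partition is produced
#' by K-means on the k-eigenvector embedding, but is scored by the mean
#' silhouette of its labels on the row-normalized first-two-eigenvector
#' embedding. Returns the maximizing k and its assignment; ties go to the
#' smallest k.
#'
#' @param lap a \code{SpectralLaplacian}.
#' @param kRange integer candidates within [2, N-1].
#' @param seed,restarts passed to \code{\link{kmeansPartition}}.
#' @return list with elements \code{k}, \code{assignment}
#'   (\code{GeneClustering}) and \code{trace} (data.frame of the scan).
#' @export
selectK <- function(lap, kRange = 3:8, seed = 0L, restarts = 10L) {
  stopifnot(is(lap, "SpectralLaplacian"))
  n <- length(lap@genes)
  kRange <- sort(unique(as.integer(kRange)))
  if (!length(kRange)) stop("empty k range", call. = FALSE)
  if (any(kRange < 2L | kRange > n - 1L)) {
    kRange <- kRange[kRange >= 2L & kRange <= n - 1L]
    if (!length(kRange))
      stop("no candidate k lies in [2, N-1]", call. = FALSE)
  }
  scoreEmb <- spectralEmbed(lap, 2L, strict = FALSE)
  sil <- rep(NA_real_, length(kRange))
  errs <- rep(NA_character_, length(kRange))
  assigns <- vector("list", length(kRange))
  for (i in seq_along(kRange)) {
    res <- tryCatch({
      emb <- spectralEmbed(lap, kRange[i])
      cl <- kmeansPartition(emb, kRange[i], seed = seed,
                            restarts = restarts)
      list(cl = cl, s = meanSilhouette(scoreEmb@Y, cl@labels))
    }, error = function(e) e)
    if (inherits(res, "error")) errs[i] <- conditionMessage(res)
    else {
      assigns[[i]] <- res$cl
      sil[i] <- res$s
    }
  }
  trace <- data.frame(k = kRange, silhouette = sil, error = errs)
  if (all(is.na(sil)))
    stop("every candidate k degenerated:\n",
         paste(sprintf("  k=%d: %s", kRange, errs), collapse = "\n"),
         call. = FALSE)
  best <- which.max(sil)   # first (= smallest k) on exact ties
  list(k = kRange[best], assignment = assigns[[best]], trace = trace)
}

#' Discard poorly clustered subsets
#'
#' Clusters whose mean silhouette is less than or equal to 0 are considered
#' poorly clustered and discarded; membership of kept clusters is
#' unchanged.
#'
#' @param assign a \code{GeneClustering}.
#' @return list with integer vectors \code{kept} and \code{discarded}
#'   (cluster labels; exhaustive and disjoint).
#' @export
filterClusters <- function(assign) {
  stopifnot(is(assign, "GeneClustering"))
  cs <- assign@clusterSilhouette
  lab <- as.integer(names(cs))
  list(kept = lab[cs > 0], discarded = lab[cs <= 0])
}

#' Partition a gene list by fused-kernel spectral clustering
#'
#' End-to-end composition: per-source bandwidth selection, Gaussian
#' affinities, element-wise kernel fusion, normalized Laplacian, selection
#' of the number of clusters (or a fixed k), K-means on the spectral
#' embedding, and silhouette annotation. Fully reproducible from the
#' inputs, the configuration and the seed.
#'
#' Configuration entries (all optional): \code{k} (fixed number of
#' clusters) or \code{kRange} (default 3:8); \code{seed} (default 0);
#' \code{restarts} (default 10); \code{provisionalK} (k used during
#' bandwidth selection; default = fixed k if given, else the rounded-down
#' midpoint of \code{kRange}); \code{sigma} (named numeric of fixed
#' per-source bandwidths, skipping selection); \code{sigmaRule} (how to
#' pick a bandwidth when none is fixed: \code{"select"} for the silhouette
#' scan of \code{\link{selectSigma}}, \code{"median"} for the
#' \code{\link{medianSigma}} heuristic); \code{sigmaGridN} (grid size for
#' \code{\link{defaultSigmaGrid}}, default 20); \code{dropIsolated} (drop
#' genes with zero fused affinity instead of failing; default FALSE).
#'
#' @param genes ordered gene identifiers.
#' @param sources a \code{GeneDistanceMatrix} or list of them; each must
#'   cover every listed gene.
#' @param config list of configuration entries, see Details.
#' @return a \code{GeneClustering}; attribute \code{"manifest"} records
#'   everything needed for an exact re-run (selected bandwidths, chosen k,
#'   seed, restarts, retained and dropped genes).
#' @export
partitionGeneList <- function(genes, sources, config = list()) {
  if (is(sources, "GeneDistanceMatrix")) sources <- list(sources)
  stopifnot(length(sources) >= 1L,
            all(vapply(sources, is, logical(1), "GeneDistanceMatrix")))
  genes <- as.character(genes)
  cfg <- utils::modifyList(
    list(k = NULL, kRange = 3:8, seed = 0L, restarts = 10L,
         provisionalK = NULL, sigma = NULL, sigmaRule = "select",
         sigmaGridN = 20L, dropIsolated = FALSE),
    config)
  cfg$sigmaRule <- match.arg(cfg$sigmaRule, c("select", "median"))
  provisionalK <- cfg$provisionalK
  if (is.null(provisionalK))
    provisionalK <- if (!is.null(cfg$k)) cfg$k
                    else floor(mean(range(cfg$kRange)))

  sigmas <- numeric(0)
  affs <- list()
  for (src in sources) {
    tag <- src@sourceTag
    miss <- setdiff(genes, src@genes)
    if (length(miss))
      stop("source '", tag, "' lacks gene(s): ",
           paste(utils::head(miss, 5), collapse = ", "), call. = FALSE)
    D <- src@D[genes, genes]
    src <- geneDistanceMatrix(D, genes, sourceTag = tag)
    if (all(is.na(D[upper.tri(D)]))) {
      warning("source '", tag, "' carries no information for this list; ",
              "contributing a zero affinity matrix", call. = FALSE)
      affs[[tag]] <- new("GeneAffinityMatrix", genes = genes,
                         A = matrix(0, length(genes), length(genes),
                                    dimnames = list(genes, genes)),
                         fusedFrom = tag,
                         sigma = stats::setNames(NA_real_, tag))
      sigmas[tag] <- NA_real_
      next
    }
    sg <- if (!is.null(cfg$sigma) && !is.null(cfg$sigma[[tag]]) &&
              is.finite(cfg$sigma[[tag]]))
      cfg$sigma[[tag]]
    else if (cfg$sigmaRule == "median") medianSigma(src)
    else as.numeric(selectSigma(src, k = provisionalK,
                                grid = defaultSigmaGrid(src, cfg$sigmaGridN),
                                seed = cfg$seed, restarts = cfg$restarts,
                                dropIsolated = cfg$dropIsolated))
    sigmas[tag] <- sg
    affs[[tag]] <- gaussianAffinity(src, sg)
  }

  fused <- fuseAffinities(unname(affs))
  dropped <- character(0)
  rs <- rowSums(fused@A)
  if (any(rs <= 0)) {
    if (!cfg$dropIsolated)
      stop("gene(s) with zero fused affinity: ",
           paste(utils::head(genes[rs <= 0], 5), collapse = ", "),
           "; set dropIsolated = TRUE to remove them", call. = FALSE)
    dropped <- genes[rs <= 0]
    warning("dropping ", length(dropped),
            " gene(s) with no information in any source: ",
            paste(utils::head(dropped, 5), collapse = ", "), call. = FALSE)
    keep <- genes[rs > 0]
    fused <- new("GeneAffinityMatrix", genes = keep,
                 A = fused@A[keep, keep], fusedFrom = fused@fusedFrom,
                 sigma = fused@sigma)
  }

  lap <- normalizedLaplacian(fused)
  if (!is.null(cfg$k)) {
    emb <- spectralEmbed(lap, as.integer(cfg$k))
    assign <- kmeansPartition(emb, cfg$k, seed = cfg$seed,
                              restarts = cfg$restarts)
    chosenK <- as.integer(cfg$k)
  } else {
    sel <- selectK(lap, cfg$kRange, seed = cfg$seed,
                   restarts = cfg$restarts)
    assign <- sel$assignment
    chosenK <- sel$k
  }
  attr(assign, "manifest") <- list(
    inputGenes = genes, genes = lap@genes, dropped = dropped,
    sigma = as.list(sigmas),
    k = chosenK, seed = as.integer(cfg$seed),
    restarts = as.integer(cfg$restarts),
    dropIsolated = isTRUE(cfg$dropIsolated),
    sources = unname(vapply(sources, sourceTag, character(1))))
  assign
}
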