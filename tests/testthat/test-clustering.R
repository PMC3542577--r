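test_that("K-means partition honors exact structure and determinism", {
  dm <- twoBlockDistance(c(3, 3), gap = 10)
  lap <- normalizedLaplacian(gaussianAffinity(dm, 1))
  emb <- spectralEmbed(lap, 2)
  cl <- kmeansPartition(emb, 2, seed = 1)
  expect_equal(length(unique(cl@labels[1:3])), 1L)
  expect_equal(length(unique(cl@labels[4:6])), 1L)
  expect_false(cl@labels[1] == cl@labels[4])
  # objective equals the brute-force minimum over all 2-partitions
  Y <- as.matrix(emb)
  wss <- function(lab) sum(vapply(unique(lab), function(l) {
    pts <- Y[lab == l, , drop = FALSE]
    sum(sweep(pts, 2, colMeans(pts))^2)
  }, numeric(1)))
  best <- Inf
  for (code in 1:(2^5 - 1)) {
    lab <- c(1L, as.integer(intToBits(code)[1:5]) + 1L)
    if (length(unique(lab)) == 2L) best <- min(best, wss(lab))
  }
  expect_equal(attr(cl, "objective"), best, tolerance = 1e-10)
  # same seed, bit-identical labels
  expect_identical(cl@labels, kmeansPartition(emb, 2, seed = 1)@labels)
  # k = N with distinct rows: singletons at objective 0
  set.seed(2)
  Yr <- matrix(rnorm(8), 4)
  Yr <- Yr / sqrt(rowSums(Yr^2))
  embR <- new("SpectralEmbedding", Y = Yr, k = 2L,
              eigenvalues = c(1, 0.5), genes = paste0("g", 1:4),
              degenerate = character(0))
  clN <- kmeansPartition(embR, 4, seed = 0)
  expect_equal(sort(clN@labels), 1:4)
  expect_equal(attr(clN, "objective"), 0)
  # k beyond the number of distinct rows is an error
  embDup <- new("SpectralEmbedding", Y = Yr[c(1, 1, 2, 2), ], k = 2L,
                eigenvalues = c(1, 0.5), genes = paste0("g", 1:4),
                degenerate = character(0))
  expect_error(kmeansPartition(embDup, 3, seed = 0), "distinct")
  cl2 <- kmeansPartition(embDup, 2, seed = 0)
  expect_equal(cl2@labels, c(1L, 1L, 2L, 2L))
  expect_equal(attr(cl2, "objective"), 0)
})

test_that("mean silhouette matches hand-computed values", {
  pts <- matrix(c(0, 0.1, 10, 10.1), ncol = 1)
  lab <- c(1, 1, 2, 2)
  # point 0: a = 0.1, b = 10.05, s = 9.95/10.05; point 0.1: s = 9.85/9.95
  expected <- mean(c(9.95 / 10.05, 9.85 / 9.95, 9.85 / 9.95,
                     9.95 / 10.05))
  expect_equal(meanSilhouette(pts, lab), expected, tolerance = 1e-12)
  expect_equal(meanSilhouette(pts, lab), 0.9900, tolerance = 1e-4)
  # every point equidistant between the two clusters: a = b, s = 0
  tetra <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  expect_equal(meanSilhouette(tetra, c(1, 1, 2, 2)), 0, tolerance = 1e-12)
  expect_error(meanSilhouette(pts, rep(1, 4)), "single cluster")
  # singleton clusters score 0
  expect_equal(meanSilhouette(matrix(c(0, 0.1, 9), ncol = 1),
                              c(1, 1, 2)),
               mean(c((9 - 0.1) / 9, (8.9 - 0.1) / 8.9, 0)),
               tolerance = 1e-12)
})

test_that("random relabelings of one tight blob score non-positive", {
  set.seed(42)
  pts <- matrix(rnorm(40, sd = 0.3), ncol = 2)
  sils <- vapply(1:200, function(i)
    meanSilhouette(pts, sample(rep(1:2, 10))), numeric(1))
  expect_lt(mean(sils), 0.05)
})

test_that("bandwidth selection maximizes silhouette with smallest-tie rule", {
  dm <- twoBlockDistance(c(4, 4), gap = 10)
  # a single-candidate grid returns that candidate
  expect_equal(as.numeric(selectSigma(dm, 2, grid = 0.7, seed = 1)), 0.7)
  # exactly tied silhouettes (perfectly separated blocks) pick the smaller
  sg <- selectSigma(dm, 2, grid = c(1.5, 1.0), seed = 1)
  trace <- attr(sg, "trace")
  expect_equal(trace$silhouette[1], trace$silhouette[2], tolerance = 1e-12)
  expect_equal(as.numeric(sg), 1.0)
  # the trace covers the grid in ascending order
  expect_equal(trace$sigma, c(1.0, 1.5))
  # on a planted fixture the selected bandwidth recovers the modules
  fx <- generateSyntheticSources(nModules = 3, seed = 5)
  run <- mixGeneSets(fx$collection, 3, seed = 5)
  mats <- syntheticDistanceSources(geneIds(run), fx)
  sg3 <- selectSigma(mats$go_bp, k = 3, seed = 5)
  cl <- partitionGeneList(geneIds(run), mats["go_bp"],
                          config = list(k = 3, seed = 5,
                                        sigma = list(go_bp =
                                                       as.numeric(sg3))))
  sc <- pairCountingScores(scoringLabels(run), clusterLabels(cl))
  expect_equal(sc@f1, 1.0)
  expect_error(selectSigma(dm, 2, grid = c(-1, 0)), "grid")
})

test_that("cluster-number selection maximizes the two-eigenvector
           silhouette", {
  fx <- generateSyntheticSources(nModules = 6, seed = 21)
  run <- mixGeneSets(fx$collection, 4, seed = 21)
  mats <- syntheticDistanceSources(geneIds(run), fx)
  cl <- suppressWarnings(partitionGeneList(
    geneIds(run), mats,
    config = list(seed = 21, provisionalK = 4, dropIsolated = TRUE)))
  expect_equal(cl@k, 4L)
  sc <- pairCountingScores(scoringLabels(run, geneIds(cl)),
                           clusterLabels(cl))
  expect_equal(sc@f1, 1.0)
  # the returned k attains the maximal silhouette in the scan trace
  sig <- attr(cl, "manifest")$sigma
  affs <- lapply(mats, function(m)
    gaussianAffinity(m, sig[[sourceTag(m)]]))
  sel <- selectK(normalizedLaplacian(fuseAffinities(unname(affs))),
                 3:8, seed = 21)
  tr <- sel$trace
  expect_equal(sel$k, tr$k[which.max(tr$silhouette)])
  expect_true(all(tr$silhouette[tr$k == sel$k] >=
                    tr$silhouette[!is.na(tr$silhouette)] - 1e-12))
  expect_error(selectK(normalizedLaplacian(fuseAffinities(unname(affs))),
                       integer(0)), "empty")
})

test_that("poorly clustered subsets (mean silhouette <= 0) are discarded", {
  cl <- makeClustering(c(1, 1, 2, 2, 3, 3),
                       c(`1` = 0.7, `2` = 0, `3` = -0.2))
  flt <- filterClusters(cl)
  expect_equal(flt$kept, 1L)
  expect_setequal(flt$discarded, c(2L, 3L))
  allGood <- makeClustering(c(1, 1, 2, 2),
                            c(`1` = 0.5, `2` = 0.9))
  expect_equal(filterClusters(allGood)$discarded, integer(0))
})

test_that("the end-to-end pipeline composes the stages faithfully", {
  fx <- generateSyntheticSources(nModules = 3, seed = 31)
  run <- mixGeneSets(fx$collection, 3, seed = 31)
  mats <- syntheticDistanceSources(geneIds(run), fx)
  cfg <- list(k = 3, seed = 31, sigma = list(go_bp = 0.9, pubs = 2.5))
  cl <- partitionGeneList(geneIds(run), mats, cfg)
  # manual staging gives the identical assignment
  affs <- list(gaussianAffinity(mats$go_bp, 0.9),
               gaussianAffinity(mats$pubs, 2.5))
  emb <- spectralEmbed(normalizedLaplacian(fuseAffinities(affs)), 3)
  manual <- kmeansPartition(emb, 3, seed = 31)
  expect_identical(cl@labels, manual@labels)
  # same config, bit-identical result (determinism contract)
  expect_identical(clusterLabels(partitionGeneList(geneIds(run), mats,
                                                   cfg)),
                   clusterLabels(cl))
  # downstream evaluation is invariant to relabeling the clusters
  sc1 <- pairCountingScores(scoringLabels(run), clusterLabels(cl))
  perm <- c(2L, 3L, 1L)
  sc2 <- pairCountingScores(scoringLabels(run),
                            stats::setNames(perm[cl@labels], cl@genes))
  expect_equal(sc1@f1, sc2@f1)
  # fixed k = 10 on an expression source yields a 10-cluster assignment
  set.seed(8)
  expr <- matrix(rnorm(40 * 6), nrow = 40,
                 dimnames = list(paste0("e", 1:40), NULL))
  de <- expressionDistanceMatrix(expr)
  cl10 <- partitionGeneList(rownames(expr), de,
                            config = list(k = 10, seed = 8,
                                          sigmaRule = "median"))
  expect_equal(cl10@k, 10L)
  expect_equal(sort(unique(cl10@labels)), 1:10)
})
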