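test_that("Gaussian affinity follows exp(-d^2 / 2 sigma^2)", {
  genes <- c("a", "b", "c")
  D <- matrix(c(0, 1, NA, 1, 0, 2, NA, 2, 0), 3,
              dimnames = list(genes, genes))
  dm <- geneDistanceMatrix(D, genes, sourceTag = "pubs")
  A <- as.matrix(gaussianAffinity(dm, sigma = 1))
  expect_equal(A["a", "b"], exp(-1 / 2), tolerance = 1e-15)
  expect_equal(A["a", "c"], 0)            # missing pair contributes 0
  expect_equal(diag(A), c(a = 0, b = 0, c = 0))
  # d = sigma * sqrt(2) maps to exp(-1)
  dm2 <- geneDistanceMatrix(matrix(c(0, sqrt(2), sqrt(2), 0), 2,
                                   dimnames = list(c("x", "y"),
                                                   c("x", "y"))),
                            sourceTag = "pubs")
  expect_equal(as.matrix(gaussianAffinity(dm2, 1))["x", "y"], exp(-1),
               tolerance = 1e-12)
  # zero distance off-diagonal maps to affinity 1; huge sigma saturates
  dm3 <- geneDistanceMatrix(matrix(c(0, 0, 0, 0), 2,
                                   dimnames = list(c("x", "y"),
                                                   c("x", "y"))),
                            sourceTag = "pubs")
  expect_equal(as.matrix(gaussianAffinity(dm3, 1))["x", "y"], 1)
  expect_equal(as.matrix(gaussianAffinity(dm2, 1e8))["x", "y"], 1,
               tolerance = 1e-12)
  # monotone decreasing in distance
  expect_gt(A["a", "b"], A["b", "c"])
  expect_error(gaussianAffinity(dm, 0), "positive")
  expect_error(gaussianAffinity(dm, -1), "positive")
})

test_that("kernel fusion is element-wise, order-invariant summation", {
  genes <- c("a", "b")
  mk <- function(v, tag) gaussianAffinity(
    geneDistanceMatrix(matrix(c(0, v, v, 0), 2,
                              dimnames = list(genes, genes)),
                       sourceTag = tag), 1)
  p1 <- mk(sqrt(-2 * log(0.3)), "go_bp")   # off-diagonal 0.3
  p2 <- mk(sqrt(-2 * log(0.5)), "pubs")    # off-diagonal 0.5
  fused <- fuseAffinities(list(p1, p2))
  expect_equal(as.matrix(fused)["a", "b"], 0.8, tolerance = 1e-12)
  expect_equal(as.matrix(fuseAffinities(list(p2, p1))),
               as.matrix(fused))
  expect_identical(sort(sourceTag(fused)), c("go_bp", "pubs"))
  # single matrix returned unchanged; adding a zero matrix is identity
  expect_equal(as.matrix(fuseAffinities(list(p1))), as.matrix(p1))
  zero <- new("GeneAffinityMatrix", genes = genes,
              A = matrix(0, 2, 2, dimnames = list(genes, genes)),
              fusedFrom = "expression",
              sigma = c(expression = NA_real_))
  expect_equal(as.matrix(fuseAffinities(list(p1, zero))),
               as.matrix(p1))
  # mismatched orderings are an alignment error naming the position
  p3 <- new("GeneAffinityMatrix", genes = c("b", "a"), A = p2@A,
            fusedFrom = "pubs", sigma = p2@sigma)
  expect_error(fuseAffinities(list(p1, p3)), "position 1")
})

test_that("normalized Laplacian identities hold", {
  genes <- c("a", "b")
  mkAff <- function(A, g = genes) new("GeneAffinityMatrix", genes = g,
    A = `dimnames<-`(A, list(g, g)), fusedFrom = "pubs",
    sigma = c(pubs = 1))
  # A = [[0, a],[a, 0]] gives L = [[0, 1],[1, 0]], eigenvalues +-1
  for (a in c(0.2, 0.6, 1)) {
    L <- as.matrix(normalizedLaplacian(mkAff(matrix(c(0, a, a, 0), 2))))
    expect_equal(unname(L), matrix(c(0, 1, 1, 0), 2), tolerance = 1e-12)
    expect_equal(sort(eigen(L)$values), c(-1, 1), tolerance = 1e-12)
  }
  # positive rescaling of A cancels out
  set.seed(3)
  A <- matrix(runif(16), 4); A <- (A + t(A)) / 2; diag(A) <- 0
  g4 <- paste0("g", 1:4)
  L1 <- as.matrix(normalizedLaplacian(mkAff(A, g4)))
  L2 <- as.matrix(normalizedLaplacian(mkAff(0.25 * A, g4)))
  expect_equal(L1, L2, tolerance = 1e-12)
  # uniform 3-gene affinity: top eigenvalue 1, constant-sign eigenvector
  g3 <- paste0("g", 1:3)
  L3 <- as.matrix(normalizedLaplacian(mkAff(
    matrix(1, 3, 3) - diag(3), g3)))
  es <- eigen(L3, symmetric = TRUE)
  expect_equal(es$values[1], 1, tolerance = 1e-12)
  expect_true(all(es$vectors[, 1] > 0) || all(es$vectors[, 1] < 0))
  # spectrum bounded by [-1, 1]
  expect_true(all(abs(eigen(L1)$values) <= 1 + 1e-12))
  # isolated gene is an actionable error
  A0 <- matrix(0, 3, 3); A0[1, 2] <- A0[2, 1] <- 1
  expect_error(normalizedLaplacian(mkAff(A0, g3)), "g3")
})

test_that("eigen-decomposition matches characteristic-polynomial roots", {
  set.seed(11)
  for (rep in 1:5) {
    A <- matrix(runif(9), 3); A <- (A + t(A)) / 2; diag(A) <- 0
    g <- paste0("g", 1:3)
    aff <- new("GeneAffinityMatrix", genes = g,
               A = `dimnames<-`(A, list(g, g)), fusedFrom = "pubs",
               sigma = c(pubs = 1))
    L <- as.matrix(normalizedLaplacian(aff))
    minors <- (L[1, 1] * L[2, 2] - L[1, 2] * L[2, 1]) +
      (L[1, 1] * L[3, 3] - L[1, 3] * L[3, 1]) +
      (L[2, 2] * L[3, 3] - L[2, 3] * L[3, 2])
    roots <- sort(Re(polyroot(c(det(L), -minors, sum(diag(L)), -1))))
    expect_equal(sort(eigen(L, symmetric = TRUE)$values), roots,
                 tolerance = 1e-8)
  }
})

test_that("spectral embedding has unit rows and deterministic signs", {
  dm <- twoBlockDistance(c(3, 2), gap = 8)
  lap <- normalizedLaplacian(gaussianAffinity(dm, 1))
  emb <- spectralEmbed(lap, 2)
  expect_equal(unname(sqrt(rowSums(as.matrix(emb)^2))), rep(1, 5),
               tolerance = 1e-12)
  expect_true(all(diff(emb@eigenvalues) <= 1e-12))
  # sign convention: largest-magnitude entry of each eigenvector positive
  for (j in 1:2) {
    col <- as.matrix(emb)[, j]
    expect_gt(col[which.max(abs(col))], 0)
  }
  expect_identical(as.matrix(spectralEmbed(lap, 2)), as.matrix(emb))
  expect_error(spectralEmbed(lap, 6), "k must lie")
  # k = 1 on a connected graph: one-signed rows (Perron eigenvector)
  set.seed(5)
  A <- matrix(runif(36, 0.2, 1), 6); A <- (A + t(A)) / 2; diag(A) <- 0
  g6 <- paste0("g", 1:6)
  aff <- new("GeneAffinityMatrix", genes = g6,
             A = `dimnames<-`(A, list(g6, g6)), fusedFrom = "pubs",
             sigma = c(pubs = 1))
  e1 <- as.matrix(spectralEmbed(normalizedLaplacian(aff), 1))
  expect_true(all(e1 == 1) || all(e1 == -1))
})

test_that("block-diagonal affinity collapses blocks to single points", {
  dm <- twoBlockDistance(c(3, 2), gap = 12)
  emb <- spectralEmbed(normalizedLaplacian(gaussianAffinity(dm, 1)), 2)
  Y <- as.matrix(emb)
  blocks <- list(1:3, 4:5)
  for (b in blocks) {
    within <- as.matrix(dist(Y[b, , drop = FALSE]))
    expect_lt(max(within), 1e-6)
  }
  between <- sqrt(sum((Y[1, ] - Y[4, ])^2))
  expect_gt(between, 0.5)
})

test_that("fused affinities stay within [0, number of sources]", {
  set.seed(9)
  fx <- generateSyntheticSources(nModules = 3, seed = 9)
  run <- mixGeneSets(fx$collection, 3, seed = 9)
  mats <- syntheticDistanceSources(geneIds(run), fx)
  affs <- lapply(mats, function(m) gaussianAffinity(m, medianSigma(m)))
  for (a in affs) {
    M <- as.matrix(a)
    expect_true(all(M >= 0 & M <= 1))
    expect_equal(M, t(M))
    expect_true(all(diag(M) == 0))
  }
  fused <- as.matrix(fuseAffinities(unname(affs)))
  expect_true(all(fused >= 0 & fused <= 2))
})
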