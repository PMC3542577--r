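test_that("information content follows -ln of the annotation share", {
  ann <- annotationTable(gene = paste0("g", 1:4),
                         term = c("A", "R", "R", "R"))
  expect_equal(unname(informationContent("A", ann)), -log(1 / 4),
               tolerance = 1e-12)
  expect_equal(unname(informationContent("A", ann)), 1.3863,
               tolerance = 1e-4)
  # a term accounting for every instance carries no information
  allR <- annotationTable(gene = paste0("g", 1:3), term = rep("R", 3))
  expect_equal(unname(informationContent("R", allR)), 0)
  # monotone: smaller share, larger IC
  expect_gt(informationContent("A", ann), informationContent("R", ann))
  # zero-instance term has undefined IC
  expect_error(informationContent("Z", ann), "undefined")
})

test_that("semantic distance is |dIC| on ontology edges only", {
  ont <- toyOntologyRAB()
  ann <- toyAnnotationsRAB()
  # IC(R) = -ln(4/8), IC(A) = -ln(2/8): distance ln 2
  expect_equal(semanticDistance("R", "A", ann, ont), log(2),
               tolerance = 1e-12)
  expect_equal(semanticDistance("R", "A", ann, ont), 0.6931,
               tolerance = 1e-4)
  # symmetric in its arguments
  expect_identical(semanticDistance("R", "A", ann, ont),
                   semanticDistance("A", "R", ann, ont))
  # equal instance counts give zero distance
  expect_equal(semanticDistance("A", "B",
                                annotationTable(c("x", "y"), c("A", "B")),
                                ontology(c("A", "B"),
                                         data.frame(parent = "A",
                                                    child = "B"))),
               0)
  # A and B are not adjacent in the toy ontology
  expect_error(semanticDistance("A", "B", ann, ont), "not adjacent")
})

test_that("evidence-code filtering removes the exclusion list only", {
  raw <- annotationTable(
    gene = c("g1", "g2", "g3", "g4", "g5"),
    term = c("A", "A", "B", "B", "R"),
    evidence = c("EXP", "IEA", "IDA", "ISS", "RCA"))
  flt <- filterAnnotations(raw)
  expect_identical(flt@records$evidence, c("EXP", "IDA"))
  expect_identical(flt@records$gene, c("g1", "g3"))  # order preserved
  expect_equal(totalInstances(flt), 2L)              # counts recomputed
  onlyBad <- annotationTable("g", "A", "IEA")
  expect_equal(totalInstances(filterAnnotations(onlyBad)), 0L)
  expect_setequal(excludedEvidenceCodes(),
                  c("IEA", "ISS", "ISO", "ISA", "ISM", "IGC", "RCA"))
})

test_that("term graph carries |dIC| weights and weight-0 gene edges", {
  ont <- toyOntologyRAB()
  ann <- toyAnnotationsRAB()
  tg <- buildTermGraph(ont, ann, "biological_process")
  ed <- igraph::as_data_frame(tg@graph, what = "edges")
  tt <- ed[startsWith(ed$from, "t:") & startsWith(ed$to, "t:"), ]
  expect_equal(nrow(tt), 2L)
  expect_equal(tt$weight, rep(log(2), 2), tolerance = 1e-12)
  # gene with exactly one annotating term gets one weight-0 edge
  g1e <- ed[ed$from == "g:g1" | ed$to == "g:g1", ]
  expect_equal(nrow(g1e), 1L)
  expect_equal(g1e$weight, 0)
  # never-annotated parent: its incident edges are omitted
  ont2 <- ontology(c("R", "A", "B", "C"),
                   data.frame(parent = c("R", "R", "C"),
                              child = c("A", "B", "R")))
  tg2 <- buildTermGraph(ont2, ann, "biological_process")
  expect_false("C" %in% tg2@terms)
  ed2 <- igraph::as_data_frame(tg2@graph, what = "edges")
  expect_equal(sum(startsWith(ed2$from, "t:") &
                   startsWith(ed2$to, "t:")), 2L)
  expect_error(buildTermGraph(ont, annotationTable(character(0),
                                                   character(0)),
                              "biological_process"), "empty")
})

test_that("gene-gene GO distance is the minimum-weight path", {
  ont <- toyOntologyRAB()
  ann <- toyAnnotationsRAB()
  tg <- buildTermGraph(ont, ann, "biological_process")
  # g1 and a2 share term A
  expect_equal(geneDistance(tg, "g1", "a2"), 0)
  # g1 (A) to g2 (B): path A-R-B sums two ln-2 edges
  expect_equal(geneDistance(tg, "g1", "g2"), 2 * log(2),
               tolerance = 1e-12)
  expect_equal(geneDistance(tg, "g1", "g2"), 1.3863, tolerance = 1e-4)
  expect_identical(geneDistance(tg, "g2", "g1"),
                   geneDistance(tg, "g1", "g2"))
  # disconnected components give a missing flag, not an error
  ontD <- ontology(c("A", "B"),
                   data.frame(parent = character(), child = character()))
  annD <- annotationTable(c("x", "x2", "y", "y2"),
                          c("A", "A", "B", "B"))
  tgD <- buildTermGraph(ontD, annD, "biological_process")
  expect_true(is.na(geneDistance(tgD, "x", "y")))
  expect_true(is.na(geneDistance(tg, "g1", "absent")))
})

test_that("per-aspect distance matrices populate values and missing mask", {
  ont <- toyOntologyRAB()
  ann <- toyAnnotationsRAB()
  mats <- suppressWarnings(
    goDistanceMatrices(c("g1", "a2", "g2"), ont, ann))
  D <- as.matrix(mats$go_bp)
  expect_equal(D["g1", "a2"], 0)
  expect_equal(D["g1", "g2"], 2 * log(2), tolerance = 1e-12)
  expect_equal(diag(D), c(g1 = 0, a2 = 0, g2 = 0))
  # no CC annotation at all: every CC pair is missing
  Dcc <- as.matrix(mats$go_cc)
  expect_true(all(is.na(Dcc[upper.tri(Dcc)])))
  # two genes on one shared BP term give an all-zero matrix
  shared <- suppressWarnings(goDistanceMatrices(
    c("g1", "a2"), ont, ann))$go_bp
  expect_equal(as.vector(as.matrix(shared)), rep(0, 4))
  expect_error(suppressWarnings(
    goDistanceMatrices(c("u1", "u2"), ont, ann)), "no gene")
})

test_that("GO distance agrees with all-paths enumeration and is a metric", {
  for (seed in 1:8) {
    fx <- randomToyGO(nTerms = sample(4:8, 1), nGenes = 4, seed = seed)
    tg <- tryCatch(buildTermGraph(fx$ont, fx$ann, "biological_process"),
                   error = function(e) NULL)
    if (is.null(tg)) next
    gs <- intersect(fx$genes, tg@genes)
    d <- matrix(NA_real_, length(gs), length(gs),
                dimnames = list(gs, gs))
    for (a in gs) for (b in gs) {
      got <- geneDistance(tg, a, b)
      want <- if (a == b) 0 else bruteForceGeneDistance(tg, a, b)
      expect_equal(got, want, tolerance = 1e-10)
      d[a, b] <- got
    }
    # triangle inequality on all defined triples
    for (a in gs) for (b in gs) for (c in gs) {
      if (!anyNA(c(d[a, b], d[a, c], d[c, b])))
        expect_lte(d[a, b], d[a, c] + d[c, b] + 1e-9)
    }
  }
})

test_that("propagated counting makes IC non-increasing toward the root", {
  ont <- ontology(c("R", "M", "L"),
                  data.frame(parent = c("R", "M"), child = c("M", "L")))
  ann <- annotationTable(c("g1", "g2", "g3"), c("L", "M", "R"))
  ic <- informationContent(NULL, ann, propagate = TRUE, ont = ont)
  expect_lte(ic[["R"]], ic[["M"]])
  expect_lte(ic[["M"]], ic[["L"]])
  expect_equal(ic[["R"]], 0)   # root accumulates every instance
  # direct counting asserts no such monotonicity: equal direct counts
  icd <- informationContent(NULL, ann)
  expect_equal(length(unique(round(icd, 12))), 1L)
})

test_that("removing an excluded record off every shortest path never
           shrinks distances", {
  ont <- ontology(c("R", "A", "B", "C"),
                  data.frame(parent = "R", child = c("A", "B", "C")))
  raw <- annotationTable(
    gene = c("r1", "r2", "g1", "g2", "g3"),
    term = c("R", "R", "A", "B", "C"),
    evidence = c("EXP", "EXP", "EXP", "EXP", "IEA"))
  before <- buildTermGraph(ont, raw, "biological_process")
  after <- buildTermGraph(ont, filterAnnotations(raw),
                          "biological_process")
  expect_gte(geneDistance(after, "g1", "g2"),
             geneDistance(before, "g1", "g2") - 1e-12)
})
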