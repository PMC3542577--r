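#' Construct a GeneSetList
#'
#' @param sets named list of character vectors (>= 2 members each); sets
#'   with fewer members are rejected with a warning.
#' @param genome optional superset of gene identifiers used for noise
#'   sampling; defaults to the union of the sets.
#' @return a \code{\link{GeneSetList-class}} object.
#' @export
geneSetList <- function(sets, genome = character(0)) {
  small <- lengths(sets) < 2L
  if (any(small)) {
    warning("rejecting ", sum(small), " gene set(s) with < 2 members: ",
            paste(utils::head(names(sets)[small], 5), collapse = ", "),
            call. = FALSE)
    sets <- sets[!small]
  }
  sets <- lapply(sets, function(s) unique(as.character(s)))
  uni <- unique(unlist(sets, use.names = FALSE))
  if (!length(genome)) genome <- uni
  genome <- unique(c(as.character(genome), uni))
  new("GeneSetList", sets = sets, genome = genome)
}

#' Mix known coherent gene sets into one list
#'
#' Samples k sets without replacement, pools their members into a single
#' gene list and records the true set label of every gene. A gene belonging
#' to more than one sampled set is retained once, labeled with the first
#' sampled set containing it, and recorded in \code{multiLabel} so that its
#' pairs can be excluded from pair-counting evaluation.
#'
#' @param collection a \code{GeneSetList} with at least k sets.
#' @param k number of sets to mix.
#' @param seed integer seed (same seed, identical run).
#' @return a \code{\link{SimulationRun-class}} object.
#' @export
mixGeneSets <- function(collection, k, seed = 0L) {
  stopifnot(is(collection, "GeneSetList"))
  k <- as.integer(k)
  if (k > length(collection@sets))
    stop("k = ", k, " exceeds the ", length(collection@sets),
         " available sets", call. = FALSE)
  chosen <- withSeed(seed, sample(names(collection@sets), k))
  genes <- character(0)
  labels <- character(0)
  seen <- character(0)
  multi <- character(0)
  for (nm in chosen) {
    members <- collection@sets[[nm]]
    dup <- intersect(members, seen)
    multi <- c(multi, dup)
    fresh <- setdiff(members, seen)
    genes <- c(genes, fresh)
    labels <- c(labels, rep(nm, length(fresh)))
    seen <- c(seen, fresh)
  }
  new("SimulationRun", genes = genes, labels = labels,
      multiLabel = unique(multi), kPlanted = k, nominalNoise = 0,
      realizedNoise = NA_real_, seed = as.integer(seed))
}

#' Inject genome-sampled noise genes into a simulation run
#'
#' With requested noise fraction f of the final list, \code{round(f / (1 -
#' f) * n)} genes are sampled uniformly without replacement from the genome
#' excluding the run's genes, appended and labeled \code{"noise"}. The
#' nominal fraction is recorded; the realized fraction (after genes lacking
#' any source information are dropped) is recomputed when a pipeline run
#' scores the list.
#'
#' @param run a \code{SimulationRun}.
#' @param genome gene identifiers to sample noise from (strictly larger
#'   than the run's gene set).
#' @param fraction nominal noise fraction in [0, 1).
#' @param seed integer seed.
#' @return a new \code{SimulationRun} with noise appended.
#' @export
injectNoise <- function(run, genome, fraction, seed = 0L) {
  stopifnot(is(run, "SimulationRun"), fraction >= 0, fraction < 1)
  if (fraction == 0) return(run)
  n <- length(run@genes)
  nNoise <- round(fraction / (1 - fraction) * n)
  pool <- setdiff(genome, run@genes)
  if (length(pool) < nNoise)
    stop("genome pool (", length(pool), ") too small for ", nNoise,
         " noise genes", call. = FALSE)
  noise <- withSeed(seed, sample(pool, nNoise))
  new("SimulationRun", genes = c(run@genes, noise),
      labels = c(run@labels, rep("noise", nNoise)),
      multiLabel = run@multiLabel, kPlanted = run@kPlanted,
      nominalNoise = fraction, realizedNoise = NA_real_,
      seed = run@seed)
}

#' True labels prepared for pair-counting
#'
#' Noise genes are biologically unrelated to every other gene, including
#' each other, so each noise gene receives a unique singleton label (it
#' forms no true pair).
#'
#' @param run a \code{SimulationRun}.
#' @param genes subset/order of genes to return labels for (default all).
#' @return named character vector of scoring labels.
#' @export
scoringLabels <- function(run, genes = run@genes) {
  lab <- trueLabels(run)[genes]
  isNoise <- lab == "noise"
  lab[isNoise] <- paste0("noise_", seq_len(sum(isNoise)))
  lab
}

#' Generate a fully synthetic multi-source fixture with planted modules
#'
#' Builds a rooted toy ontology (one branch of \code{withinDepth} chained
#' terms per module, all in the biological_process aspect), an annotation
#' table in which each module gene is annotated to its own leaf term
#' hanging off a random position of its module's chain, and a publication
#' table in which genes of a module draw from a shared module-specific
#' publication pool plus a large global pool. Background filler genes give
#' every term a stable annotation count, so information-content
#' differences (and hence edge weights) are small and varied within a
#' branch and large through the sparsely annotated root: genes of the same
#' module end up close in GO space (at strictly positive, non-degenerate
#' distances) and far from other modules, while within-module
#' shared-publication counts stochastically dominate between-module
#' counts. Cross-module affinities stay well above machine precision for
#' reasonable bandwidths, so the Laplacian spectrum reflects the module
#' structure without numerically exact disconnection.
#'
#' The genome contains \code{genomeExtra} additional genes for noise
#' sampling; an \code{uninformativeFrac} fraction of them carry no
#' annotation and no publications, so realized noise after
#' information-availability filtering falls below the nominal level. The
#' remaining extras are annotated to one random branch term and draw
#' publications from the global pool only.
#'
#' \code{goMerge}/\code{pubMerge} accept lists of module-index vectors that
#' share one GO branch (resp. one publication pool), producing sources with
#' complementary information: a source cannot separate the modules merged
#' within it.
#'
#' @param nModules number of planted modules (>= 2).
#' @param genesPerModule module size.
#' @param withinDepth number of chained terms per branch.
#' @param seed integer seed; the whole fixture is reproducible.
#' @param pubOverlap numeric of length 2, target mean shared-publication
#'   counts within and between modules.
#' @param goMerge,pubMerge optional lists of module groups sharing a GO
#'   branch / publication pool.
#' @param genomeExtra number of genome-only genes (noise pool).
#' @param uninformativeFrac fraction of genome extras with no information.
#' @return list with elements \code{ontology}, \code{annotations} (already
#'   evidence-filtered record stream plus a few excluded-evidence records
#'   for realism), \code{pubs} (named list gene -> publication ids),
#'   \code{labels} (named true module label per module gene),
#'   \code{collection} (a \code{GeneSetList} of the modules with the full
#'   genome), and \code{genome}.
#' @export
generateSyntheticSources <- function(nModules = 3L, genesPerModule = 8L,
                                     withinDepth = 3L, seed = 0L,
                                     pubOverlap = c(within = 3,
                                                    between = 0.1),
                                     goMerge = NULL, pubMerge = NULL,
                                     genomeExtra = 40L,
                                     uninformativeFrac = 0.25) {
  stopifnot(nModules >= 2L, genesPerModule >= 2L, withinDepth >= 1L)
  if (!is.null(goMerge) && !is.null(pubMerge) &&
      identical(goMerge, pubMerge))
    warning("identical merges in both sources may leave merged modules ",
            "indistinguishable", call. = FALSE)

  groupOf <- function(merge) {
    g <- seq_len(nModules)
    if (!is.null(merge))
      for (grp in merge) g[g %in% grp] <- min(grp)
    match(g, sort(unique(g)))   # contiguous group indices
  }
  goBranch <- groupOf(goMerge)
  pubPool <- groupOf(pubMerge)

  withSeed(seed, {
    modules <- lapply(seq_len(nModules), function(m)
      sprintf("g%d_%02d", m, seq_len(genesPerModule)))
    labels <- stats::setNames(
      rep(paste0("set", seq_len(nModules)), each = genesPerModule),
      unlist(modules))

    ## --- ontology: root plus one chained branch per GO group, plus one
    ## leaf term per module gene hanging off its branch chain ---
    root <- "GO:0000001"
    nBranches <- max(goBranch)
    branchTerms <- lapply(seq_len(nBranches), function(b)
      sprintf("GO:%07d", b * 100L + seq_len(withinDepth)))
    edges <- do.call(rbind, lapply(seq_len(nBranches), function(b) {
      ch <- branchTerms[[b]]
      data.frame(parent = c(root, ch[-length(ch)]), child = ch,
                 relation = "is_a", stringsAsFactors = FALSE)
    }))

    ## --- annotations: fillers pin term counts, genes attach via leaves ---
    recGene <- character(0); recTerm <- character(0); recEv <- character(0)
    addRec <- function(g, t, ev = "EXP") {
      recGene <<- c(recGene, g); recTerm <<- c(recTerm, t)
      recEv <<- c(recEv, ev)
    }
    fillTerm <- function(t, lo = 8L, hi = 12L) {
      # near-equal counts across non-root terms keep |dIC| edge weights
      # small but varied
      for (f in seq_len(sample(lo:hi, 1L)))
        addRec(sprintf("bg_%s_%02d", gsub(":", "", t), f), t)
    }
    for (r in 1:3) addRec(paste0("bg_root", r), root)  # root rarer: big IC
    for (b in seq_len(nBranches))
      for (j in seq_len(withinDepth)) fillTerm(branchTerms[[b]][j])

    leafEdges <- list()
    leafCount <- 0L
    for (m in seq_len(nModules)) {
      ch <- branchTerms[[goBranch[m]]]
      for (g in modules[[m]]) {
        leafCount <- leafCount + 1L
        leaf <- sprintf("GO:%07d", 10000L + leafCount)
        leafEdges[[leafCount]] <- data.frame(
          parent = sample(ch, 1L), child = leaf, relation = "is_a",
          stringsAsFactors = FALSE)
        fillTerm(leaf)
        addRec(g, leaf)
      }
      # one electronically inferred record pointing off-branch; removed by
      # the evidence filter before any distance is computed
      offBranch <- setdiff(seq_len(nBranches), goBranch[m])
      if (length(offBranch))
        addRec(modules[[m]][1L],
               branchTerms[[offBranch[1L]]][1L], ev = "IEA")
    }
    edges <- rbind(edges, do.call(rbind, leafEdges))
    terms <- c(root, unlist(branchTerms),
               vapply(leafEdges, function(e) e$child, character(1)))
    ont <- ontology(terms, edges, aspect = "biological_process")
    ann <- annotationTable(recGene, recTerm, recEv)

    ## --- publications: module pools vs global pool ---
    nDraw <- 4L
    within <- max(pubOverlap[[1L]], 0.25)
    between <- max(pubOverlap[[2L]], 1e-3)
    poolW <- max(nDraw, ceiling(nDraw^2 / within))
    poolG <- min(5000L, max(nDraw, ceiling(nDraw^2 / between)))
    globalPubs <- sprintf("PM_g%05d", seq_len(poolG))
    poolPubs <- lapply(seq_len(max(pubPool)), function(p)
      sprintf("PM_p%d_%03d", p, seq_len(poolW)))
    pubs <- list()
    for (m in seq_len(nModules)) {
      for (g in modules[[m]]) {
        pubs[[g]] <- unique(c(
          sample(poolPubs[[pubPool[m]]], min(nDraw, poolW)),
          sample(globalPubs, min(nDraw, poolG))))
      }
    }

    ## --- genome extras: the noise pool ---
    extras <- sprintf("nz%03d", seq_len(genomeExtra))
    nUninf <- round(uninformativeFrac * genomeExtra)
    uninformative <- if (nUninf > 0) extras[seq_len(nUninf)] else character(0)
    allChain <- unlist(branchTerms)
    extraRecG <- character(0); extraRecT <- character(0)
    for (g in setdiff(extras, uninformative)) {
      extraRecG <- c(extraRecG, g)
      extraRecT <- c(extraRecT, sample(allChain, 1L))
      pubs[[g]] <- sample(globalPubs, min(nDraw, poolG))
    }
    if (length(extraRecG)) {
      ann <- annotationTable(rbind(
        ann@records,
        data.frame(gene = extraRecG, term = extraRecT, evidence = "EXP",
                   stringsAsFactors = FALSE)))
    }

    genome <- c(unlist(modules), extras)
    sets <- stats::setNames(modules, paste0("set", seq_len(nModules)))
    list(ontology = ont, annotations = ann, pubs = pubs, labels = labels,
         collection = geneSetList(sets, genome = genome), genome = genome)
  })
}

#' Distance sources for a simulated gene list
#'
#' Convenience wrapper building the GO biological-process and co-mention
#' distance matrices for the genes of a simulation run from a synthetic
#' fixture.
#'
#' @param genes gene identifiers (e.g. \code{geneIds(run)}).
#' @param fixture list returned by \code{\link{generateSyntheticSources}}.
#' @param use source tags to build (\code{"go_bp"}, \code{"pubs"}).
#' @return named list of \code{GeneDistanceMatrix} objects.
#' @export
syntheticDistanceSources <- function(genes, fixture,
                                     use = c("go_bp", "pubs")) {
  out <- list()
  if ("go_bp" %in% use) {
    gm <- suppressWarnings(
      goDistanceMatrices(genes, fixture$ontology, fixture$annotations))
    out$go_bp <- gm$go_bp
  }
  if ("pubs" %in% use)
    out$pubs <- suppressMessages(
      comentionDistanceMatrix(genes, fixture$pubs))
  out
}

#' Run a grid of mixing simulations and score the recovered partitions
#'
#' For every combination of planted k, replicate and noise level: a fresh
#' synthetic fixture is generated, k sets are mixed, noise is injected,
#' per-source distance matrices are built, each requested source
#' combination is partitioned with \code{\link{partitionGeneList}}, and the
#' result is scored against the planted labels by pair counting. Replicate
#' seeds derive deterministically from the master seed. Individual
#' replicate failures are logged as warning and recorded as NA rows.
#'
#' @param kValues planted numbers of mixed sets.
#' @param reps replicates per cell.
#' @param sourceCombos named list of source-tag vectors to evaluate.
#' @param noiseLevels nominal noise fractions.
#' @param seed master seed.
#' @param fixedK cluster at the planted k (TRUE) or select k by silhouette
#'   over \code{config$kRange} (FALSE).
#' @param fixtureArgs overrides passed to
#'   \code{\link{generateSyntheticSources}} (\code{nModules} defaults to
#'   the planted k plus 2, so mixing samples from a larger collection).
#' @param config overrides for \code{\link{partitionGeneList}};
#'   \code{dropIsolated = TRUE} is forced (uninformative noise genes must
#'   be droppable).
#' @return long-format data.frame with columns \code{condition}, \code{k},
#'   \code{rep}, \code{noise_nominal}, \code{noise_realized},
#'   \code{precision}, \code{recall}, \code{f1}, \code{n_genes}.
#' @export
runExperimentGrid <- function(kValues = 3:8, reps = 20L,
                              sourceCombos = list(go = "go_bp",
                                                  pubs = "pubs",
                                                  fused = c("go_bp", "pubs")),
                              noiseLevels = 0, seed = 0L, fixedK = TRUE,
                              fixtureArgs = list(), config = list()) {
  rows <- list()
  cell <- 0L
  for (k in kValues) {
    for (r in seq_len(reps)) {
      cell <- cell + 1L
      s <- deriveSeed(seed, cell * 17L)
      fx <- do.call(generateSyntheticSources,
                    utils::modifyList(list(nModules = k + 2L, seed = s),
                                      fixtureArgs))
      run0 <- mixGeneSets(fx$collection, k, seed = s + 1L)
      for (f in noiseLevels) {
        run <- injectNoise(run0, fx$genome, f, seed = s + 2L)
        mats <- syntheticDistanceSources(geneIds(run), fx)
        for (combo in names(sourceCombos)) {
          srcs <- mats[sourceCombos[[combo]]]
          cfg <- utils::modifyList(
            list(seed = s + 3L, dropIsolated = TRUE), config)
          if (fixedK) cfg$k <- k
          row <- tryCatch({
            assign <- suppressWarnings(
              partitionGeneList(geneIds(run), srcs, cfg))
            kept <- geneIds(assign)
            truth <- scoringLabels(run, kept)
            sc <- pairCountingScores(truth, clusterLabels(assign),
                                     exclude = intersect(run@multiLabel,
                                                         kept))
            realized <- mean(trueLabels(run)[kept] == "noise")
            data.frame(condition = combo, k = k, rep = r,
                       noise_nominal = f, noise_realized = realized,
                       precision = sc@precision, recall = sc@recall,
                       f1 = sc@f1, n_genes = length(kept))
          }, error = function(e) {
            warning("replicate failed (", combo, ", k=", k, ", rep=", r,
                    ", noise=", f, "): ", conditionMessage(e),
                    call. = FALSE)
            data.frame(condition = combo, k = k, rep = r,
                       noise_nominal = f, noise_realized = NA_real_,
                       precision = NA_real_, recall = NA_real_,
                       f1 = NA_real_, n_genes = NA_integer_)
          })
          rows[[length(rows) + 1L]] <- row
        }
      }
    }
  }
  do.call(rbind, rows)
}
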