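# specFuse

Functional gene module discovery by kernel fusion and spectral clustering.

## The problem

High-throughput experiments end in gene lists, and the genes in them act in
*functional modules* — subsets whose products work together in one or a few
related biological processes. Enrichment tools can match a list against
predefined gene sets, but they cannot find *de novo* modules, and they
rarely combine evidence across heterogeneous sources. specFuse partitions
an arbitrary gene list into functionally coherent subsets by integrating
Gene Ontology annotations, literature co-mentioning and (optionally)
expression profiles, for anyone — bench biologist or bioinformatician — who
needs to turn a flat list into interpretable groups.

## The method

One gene-by-gene distance matrix is built per information source:

* **GO semantic distance** — the information content of a term is
  `IC(t) = -ln P(t)` with `P(t)` the term's share of annotation instances;
  each ontology parent–child edge is weighted `|IC(t_p) - IC(t_c)|`; genes
  attach to their annotating terms with weight-0 edges; the gene–gene
  distance is the shortest path in this weighted term graph (one graph per
  GO aspect). Electronically inferred annotations (IEA, ISS, ISO, ISA,
  ISM, IGC, RCA) are excluded.
* **Co-mentioning** — `M - s_ij`, where `s_ij` counts publications shared
  by genes *i* and *j* and `M` is the largest shared count in the list.
* **Expression** — `1 - r` with `r` the Pearson correlation of profiles.

Each matrix is kernel-transformed, `A_ij = exp(-d_ij² / 2σ²)`, with a
per-source bandwidth σ selected by maximizing the mean silhouette of the
resulting partition (or fixed, or set to the median distance). The affinity
matrices are **fused by element-wise summation**, and the fused graph is cut
by spectral clustering: `L = D^-1/2 A D^-1/2`, rows of the top-*k*
eigenvectors normalized to unit length, K-means on the rows. The number of
clusters is chosen by scanning *k* = 3–8 and scoring each candidate
partition by its silhouette on the first-two-eigenvector embedding;
clusters with mean silhouette ≤ 0 are flagged as poorly clustered.

Partitions are evaluated Rand-index style over gene pairs: precision =
agreeing / predicted co-labeled pairs, recall = agreeing / true co-labeled
pairs, and F1, against a random-assignment baseline. A simulation module
mixes known gene sets, injects genome-sampled noise, and regenerates every
input (toy ontology, annotations, publication table) synthetically, so the
whole pipeline is testable offline.

## Worked example

Mix three known modules, contaminate the list with 20% genome-sampled
noise, and recover the modules from fused GO + literature evidence:

```r
library(specFuse)

fx  <- generateSyntheticSources(nModules = 4, seed = 2024)
run <- mixGeneSets(fx$collection, k = 3, seed = 7)
run <- injectNoise(run, fx$genome, fraction = 0.2, seed = 8)
run
#> SimulationRun: 30 genes, 3 planted sets; nominal noise 0.2

mats <- syntheticDistanceSources(geneIds(run), fx)
mats$go_bp
#> GeneDistanceMatrix [go_bp] 30 x 30; missing pairs: 57

cl <- partitionGeneList(geneIds(run), mats,
        config = list(kRange = 3:8, seed = 7, provisionalK = 3,
                      dropIsolated = TRUE))
cl
#> GeneClustering of 28 genes into k = 3 clusters
#>   mean silhouette: 0.9546

pairCountingScores(scoringLabels(run, geneIds(cl)), clusterLabels(cl))
#> EvalScores: precision 0.7059, recall 1.0000, F1 0.8276 (84/84/119 pairs)

randomBaseline(scoringLabels(run, geneIds(cl)), k = 3, reps = 1000,
               seed = 7)
#>      metric      mean           se
#> 1 precision 0.2207914 0.0009258648
#> 2    recall 0.3314524 0.0015958157
#> 3        f1 0.2647157 0.0011361067
```

Reading the output: two of the 30 genes carried no information in any
source and were dropped (realized noise below the nominal 20%), the scan
over *k* chose 3 clusters, and every true module pair was recovered
(recall 1.0). Precision is 0.71 because informative noise genes were
absorbed into the nearest module — each such gene is a singleton in the
truth, so the pairs it forms in a cluster count against precision. The
random baseline for the same list sits at F1 ≈ 0.26, far below the
method's 0.83.

Per-gene silhouettes, per-cluster means and kept/discarded flags travel
with the result (`silhouetteValues`, `filterClusters`, `writeClustering`),
and `attr(cl, "manifest")` holds everything needed for an exact re-run
(`rerunPartition`).

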