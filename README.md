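# lidcNet

Essential proteins are the proteins whose loss is lethal; in a
protein–protein interaction network (PPIN) they concentrate in densely
connected regions and protein complexes. `lidcNet` identifies candidate
essential proteins from a PPIN in two phases: it first **prunes** the network
of topologically unreliable proteins and interactions, then **ranks** the
surviving proteins with density- and complex-aware centrality scores, and
finally **evaluates** top-ranked sets against a curated gold standard. It is
aimed at computational biologists who work with interactome edge lists
(e.g. DIP-style yeast networks) and complex catalogs (e.g. MIPS/CYC2008
derived collections).

## The method

**Phase 1 — rule-based pruning.** Each protein *v* gets a node weight

> W(v) = (1/|Γ(v)|) Σ<sub>u∈Γ(v)</sub> deg(u),

the average degree of its neighbours, and each interaction u–v gets an edge
weight

> W(u,v) = |Γ(u) ∩ Γ(v)| / |Γ(u) ∪ Γ(v)|,

the Jaccard overlap of the endpoint neighbourhoods (Γ is the open
neighbourhood). Weights below the cut-off

> θ<sub>k</sub> = α + k · σ · (1 − 1/(1+σ²)),  k ∈ {1,2,3} for low/medium/high,

are pruned, where α and σ are the mean and (population) standard deviation
of the weight distribution. Nodes are pruned first, then edges of the
node-reduced network, then stranded degree-0 proteins.

**Phase 2 — centrality scoring.** On the pruned network each protein is
scored by its local interaction density LID(u) = |E(u)|/|V(u)| (edges among
u's neighbours over neighbours that interconnect), its complex in-degree
IDC(u) (interactions with co-members summed over every complex containing
u), and their rank-weighted convex combination

> LIDC(u) = LID(u)·(1 − RANK(u)/N) + IDC(u)·RANK(u)/N,

where RANK(u) is u's position in the descending LID ordering. Proteins are
ranked by LIDC; the top 20 % (or top-k ranges) are predicted essential and
scored with precision, recall, F-score and jackknife curves.

## Worked example

```r
library(lidcNet)

bench <- generateBenchmark(syntheticSpec(seed = 1))
out <- runPipeline(bench$network, bench$catalog, bench$gold,
                   outdir = "demo", level = "high")
out$report
#> PruningReport (high cut-off)
#>   initial:                681 proteins   2368 interactions
#>   after node reduction:    23 proteins     98 interactions (theta = 11.9907)
#>   after edge reduction:    13 proteins     55 interactions (theta = 0.7069)
out$table
#> ScoreTable: 13 proteins (descending LIDC)
#>  protein      lid idc rank     lidc
#>  P000036 3.583333  12    4 6.173077
#>  P000035 3.555556   9    6 6.068376
#>  P000040 2.714286   7   10 6.010989
#>  ...
out$evaluation$topFraction
#> EvaluationResult over 13 proteins (13 gold-essential)
#>   tp 3  fp 0  fn 10  tn 0
#>   precision 1.0000  recall 0.2308  F-score 0.3750
```

The high cut-off strips the 681-protein synthetic interactome down to the
13 proteins sitting in its densest planted modules; all of the top-20 %
predictions are truly essential (precision 1.0), while recall is limited by
how much of the gold standard survives pruning — the behaviour the pruning
strategy trades for precision. The pipeline writes `pruning_report.json`,
`scores.tsv`, `essential.txt`/`nonessential.txt`, `evaluation.json` and
`jackknife.tsv` into `outdir`, and is byte-deterministic for fixed inputs.

A thin command-line wrapper with `simulate`, `prune`, `score`, `evaluate`,
`jackknife` and `run` subcommands ships at
`system.file("scripts", "lidc-pipeline.R", package = "lidcNet")`.

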