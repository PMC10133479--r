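# essMiner

Literature mining and pangenome partitioning for essential-gene discovery
in sulfate-reducing bacteria.

Sulfate-reducing bacteria (SRB) such as *Oleidesulfovibrio alaskensis*
G20 run their energy metabolism on dissimilatory sulfate reduction, and
which of their genes are essential for growth is largely unknown.
essMiner is an R implementation of a semi-automated workflow that turns a
literature corpus plus public-style resources into a ranked essentiality
candidate list, for microbial genomicists who want a computational
baseline before committing to knockout experiments:

1. **Corpus annotation** — dictionary-based gene NER over free text
   (case-folded surface forms, token-boundary matching,
   longest-match-leftmost; windowed *granularization* for long texts with
   exact offset bookkeeping), evaluated mention-level with per-slice mean
   and best F1.
2. **Genome mapping** — mined symbols map onto locus tags through the
   dictionary; non-homologous symbols and redundant entries are funnelled
   out with an audited reason per removal.
3. **PPI enrichment** — 2nd-level breadth-first expansion of the retained
   genes in a scored interaction network, a degree-model Poisson
   enrichment p-value
   (e<sub>exp</sub> = Σ<sub>i&lt;j∈S</sub> min(1, d<sub>i</sub>d<sub>j</sub>/2m),
   p = P(X ≥ e<sub>obs</sub>) for X ~ Poisson(e<sub>exp</sub>)), pathway
   clustering, and *bridging genes* (nodes with edges into the most
   foreign pathway clusters).
4. **Pangenome partitioning** — a K-component multivariate Bernoulli
   mixture P(x<sub>f</sub>) = Σ<sub>k</sub> π<sub>k</sub> Π<sub>g</sub>
   θ<sub>kg</sub><sup>x<sub>fg</sub></sup>(1−θ<sub>kg</sub>)<sup>1−x<sub>fg</sub></sup>
   over the gene-family × genome presence/absence matrix, fitted by EM
   (log-space E-step, clamped M-step) and smoothed by a Potts
   Markov-random-field prior over the family contiguity graph via
   iterated conditional modes; components ranked by mean presence become
   persistent / shell / cloud.
5. **Essentiality report** — pathway × partition segregation table with
   percentages, and deterministic calls: persistent → essential, shell →
   conditionally-essential, cloud → environment-specific.

A first-class synthetic-data module generates every input (dictionary,
corpus with planted gold mentions and decoy tokens, pathway-clustered
scored network, planted-mixture pangenome with contiguity graph) so the
full pipeline runs and is tested offline against known ground truth.

## Worked example

```r
library(essMiner)

fx <- loadFixtures()          # packaged 20-gene dictionary + 116-gene table
fx$dictionary
#> GeneDictionary with 20 genes and 48 surface forms
#>   pathways: energy metabolism=5, nucleotide metabolism=1, ribosome synthesis=1,
#>             sulfur metabolism=8, transporters=3, two-component system=2

# mined-symbol funnel: 91 symbols -> mapped -> deduplicated
deduplicateMapped(mapToGenome(readLines(fx$symbols_path), fx$dictionary))
#> MappingFunnel: 91 symbols -> 42 mapped ( 49 unmapped ) -> 20 retained ( 22 removed )

# segregation of the 116 enriched genes by pangenome partition
seg <- segregatePartitions(fx$partitions)
seg$table
#>                 pathway persistent shell cloud total
#> 1     sulfur metabolism         12     4     2    18
#> 2    ribosome synthesis         27     3     1    31
#> 3 nucleotide metabolism         25     3     2    30
#> 4          transporters          2     6     4    12
#> 5     energy metabolism          8     6     1    15
#> 6  two-component system          7     3     0    10
#> 7                 TOTAL         81    25    10   116
seg$percentages
#> persistent      shell      cloud
#>      69.83      21.55       8.62

# bridging gene of the enriched PPI subnetwork
net <- readInteractionNetwork(fx$network_path,
                              pathway = setNames(fx$partitions$pathway,
                                                 fx$partitions$gene))
clusterByPathway(net, igraph::V(asIgraph(net))$name)$bridging[1:3, ]
#>       node           pathway bridging_degree
#> 1 dde_2265 sulfur metabolism               5
#> 2 dde_0155      transporters               1
#> 3 dde_0526 sulfur metabolism               1
```

Reading: of the 116 enriched genes, 81 (69.83%) sit in the persistent
pangenome partition and are called essential; 25 (21.55%) are shell
(conditionally essential — formate dehydrogenases, hydrogenases and the
like), 10 (8.62%) cloud. The sulfate adenylyltransferase gene *sat*
(dde_2265) bridges all five foreign pathway clusters of the enriched
subnetwork.

An end-to-end synthetic run (simulate → annotate → evaluate → map →
enrich → partition → report, with a byte-stable manifest):

```r
cfg <- pipelineConfig(tempfile(), seed = 3,
                      sim = simulationConfig(seed = 3, n_docs = 8,
                                             n_families = 80, n_genomes = 16))
man <- runPipeline(cfg)
```

A thin command-line front end with the same stages lives at
`inst/scripts/essmine.R`
(`Rscript essmine.R pipeline --seed 3 --out run/`).

## Package layout

* `R/` — S4 classes (`GeneDictionary`, `AnnotatedCorpus`,
  `InteractionNetwork`, `PresenceAbsenceMatrix`, `ContiguityGraph`,
  `BernoulliMixture`, `PartitionResult`, `MappingFunnel`, `EvalResult`)
  with validity methods and accessors, plus one file per pipeline stage.
* `src/` — the Rcpp exhaustive grid-search reference fitter.
* `inst/extdata/` — plain-text fixtures: the curated 20-gene annotation
  table, the 116-gene partition table, and synthetic reconstructions
  (named `*_synthetic.*`) of the mapped-gene funnel and the enriched PPI
  subnetwork.
* `vignettes/essential-gene-mining.Rmd` — the model, its assumptions,
  numerical choices and known limitations.
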