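---
title: "Mining essential genes: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining essential genes: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(essMiner)
```

# The problem

Sulfate-reducing bacteria (SRB) such as *Oleidesulfovibrio alaskensis* G20
(OA G20) are obligate anaerobes whose energy metabolism runs on
dissimilatory sulfate reduction. Which of their genes are *essential* —
indispensable for growth under stated conditions — is largely uncharted,
and knockout screens are expensive. essMiner implements a semi-automated
computational route to a defensible candidate list:

1. **Corpus annotation** — dictionary-based named-entity recognition (NER)
   finds gene mentions in a literature corpus.
2. **Genome mapping** — mined symbols are mapped onto the target genome's
   locus tags; symbols with no homolog and redundant entries are funnelled
   out.
3. **PPI enrichment** — the retained genes seed a breadth-first expansion
   (depth 2 by default) in a scored protein–protein-interaction network; a
   degree-model test asks whether the expanded set is more internally
   connected than chance; pathway clustering exposes *bridging genes* that
   tie several pathway clusters together.
4. **Pangenome partitioning** — each enriched gene's family is classified
   as *persistent* (near-universal in the genus), *shell*
   (condition-dependent) or *cloud* (rare) from a gene-family ×
   genome presence/absence matrix, using a multivariate Bernoulli mixture
   fitted by EM with Markov-random-field (MRF) smoothing over the family
   contiguity graph.
5. **Essentiality calls** — persistent → *essential*, shell →
   *conditionally-essential*, cloud → *environment-specific*, with
   per-gene override notes for documented conditional cases.

A synthetic-data module generates every input — dictionary, corpus with
planted mentions, clustered scored network, planted-mixture pangenome — so
the whole pipeline is testable offline with known ground truth.

# The partition model

Let $x_{fg} \in \{0,1\}$ indicate presence of family $f$ in genome $g$.
The model is a $K$-component multivariate Bernoulli mixture,

$$P(x_f) = \sum_{k=1}^{K} \pi_k \prod_g
  \theta_{kg}^{x_{fg}} (1-\theta_{kg})^{1-x_{fg}},$$

fitted by EM with responsibilities computed in log-space. After
convergence, components are ranked by mean presence probability
$\bar\theta_k$: the highest is labelled persistent, the lowest cloud, and
all middle components shell (so `K > 3` yields several shell components;
`K = 2` with `allow_k2 = TRUE` has no shell). The default `K = 3` matches
the three-class persistent/shell/cloud reading of a genus pangenome.

Assumptions worth stating: presence calls are conditionally independent
across genomes given the component (no phylogenetic correlation), genomes
are exchangeable within a component except through $\theta_{kg}$, and
families are independent except through the MRF prior below.

## Numerical choices

* $\theta$ is clamped to $[10^{-4}, 1-10^{-4}]$ at every M-step: absence
  everywhere would otherwise drive $\log\theta$ to $-\infty$ and freeze a
  component.
* **Initialization**: families are binned by presence frequency into $K$
  equal *intervals* of the observed frequency range; each component starts
  at its bin's column means plus a small per-component uniform jitter
  (seed-controlled). Interval bins rather than equal-count bins matter:
  with a dominant persistent mass (70% of families), equal-count bins seed
  two components inside the persistent block and EM converges to a split
  of persistent rather than to the minority cloud. Per-component (not
  per-cell) jitter keeps the fit exactly equivariant under genome-column
  permutation.
* Convergence: relative log-likelihood change below `tol` (default 1e-6),
  at most `max_iter = 500` iterations; the log-likelihood is asserted
  non-decreasing at every iteration with 1e-9 slack for floating point.
* Degenerate inputs: all-zero families are dropped (with a warning) by
  `readPresenceAbsence()` — they carry no information and their MLE sits
  on the clamp boundary; the in-memory container still allows them because
  degenerate generator settings (a cloud component with $p = 0$)
  legitimately produce them.
* Ties in $\bar\theta_k$ within 1e-9 are broken by component index and
  reported.

## MRF smoothing

The contiguity graph links families that contain neighboring genes on some
genome. Smoothing is *iterated conditional modes* (ICM) on hard labels
after EM: families are swept in input order and each is reassigned to the
component maximizing

$$\log \pi_k + \log P(x_f \mid \theta_k) + \beta \,
  \#\{\text{neighbors currently labelled } k\},$$

until no label changes or `n_sweeps = 10` sweeps. $\beta$ defaults to 2.5;
$\beta = 0$ (or an edgeless graph) reduces exactly to the responsibility
argmax. ICM was chosen over interleaved mean-field updates because it is
deterministic and directly checkable against exhaustive energy
minimization on small instances.

**Limitation.** ICM is a coordinate-wise local optimizer. It provably
never degrades the Potts objective from its initialization, and on the
package's small-instance test family it coincides with exhaustive
enumeration for couplings up to the default $\beta = 2.5$; when $\beta$ is
pushed well beyond the unary log-likelihood margins (e.g. $\beta = 6$ on
near-uninformative rows) single-site updates cannot coordinate a joint
flip and ICM can stop in a local optimum. In the pipeline's operating
regime the unary terms dominate, but very large $\beta$ should be treated
as a deliberate choice, not a safe default.

## Validation against an exhaustive reference

`bmmGridSearch()` is an independent brute-force fitter for 2-component,
2-genome instances: both components' probabilities sweep a 0.01 grid
(clamped like the EM) and the mixing weight is profiled at each grid point
by the EM fixed-point in $\pi$ alone — a concave 1-D subproblem — plus an
endpoint check. The test suite requires the EM log-likelihood to match
this reference within 1e-3 on 4-family × 2-genome instances whose MLE
lands on grid points. It is implemented in C++ because the grid has
$101^4$ points.

# The enrichment test

For a node set $S$ in a background graph with $m$ edges and degrees $d_i$,
the expected number of internal edges under a degree-preserving null is
approximated by $e_{exp} = \sum_{i<j \in S} \min(1, d_i d_j / 2m)$ and the
p-value is the Poisson upper tail $P(X \ge e_{obs})$, $X \sim
\mathrm{Poisson}(e_{exp})$. This degree-product (Chung–Lu) model was
chosen because it is closed-form and testable; the package also ships a
permutation version (uniform same-size node sets, add-one smoothing) as an
internal oracle, and the suite checks the analytic value against full
enumeration of all same-size node sets on small fixture graphs.

Two caveats, both visible in the tests: (i) when the observed set is the
unique most-connected set of its size, the enumeration p-value saturates
at $1/\binom{n}{k}$ while the Poisson tail stays larger — the analytic
value is then conservative; (ii) $e_{exp}$ equals the mean of *its own*
independent-edge null, which differs at order $d_i d_j/2m$ from
degree-preserving rewiring of one small dense graph, so the
self-consistency test resamples from the model's null rather than from
rewired graphs.

Seed expansion is plain BFS over edges with combined score ≥ `min_score`
(default 0.4, the conventional medium-confidence STRING cutoff); a
`max_per_level` cap exists but is unlimited by default. A node's
*bridging degree* is the number of distinct foreign pathway clusters it
has an edge into; bridging genes are the argmax. In the packaged enriched
subnetwork, the sulfate adenylyltransferase gene *sat* (dde_2265) attains
the maximal bridging degree — it touches all five foreign pathway
clusters.

# The annotator and its evaluation

Dictionary NER: surface forms are the case-folded primary symbol, every
synonym, and the locus tag. Matching is case-insensitive at token
boundaries (transitions between word characters — letters, digits,
underscore — and anything else), so `dde_2265` tokenizes intact and `sat`
inside "sulfate" never matches. Overlapping candidates resolve
longest-first, then leftmost; offsets are 0-based half-open. Long texts
can be *granularized* into overlapping windows; with overlap at least the
longest surface form minus one, windowed tagging provably equals
whole-text tagging, and the suite asserts this identity.

This deterministic matcher stands in for a trained statistical recognizer:
it has perfect recall on corpora whose mentions come from the dictionary
(the synthetic generator guarantees this), so the interesting evaluation
cases come from plugging in degraded recognizers. The test suite uses a
naive pattern recognizer that tags every gene-shaped token — the
generator's decoy tokens (symbol-shaped strings absent from the
dictionary) then become false positives.

Evaluation is exact-span (doc, start, end, locus) with one-to-one
matching, 0/0 precision and recall defined as 0, and no partial credit.
`sliceEvaluate()` partitions documents into seed-shuffled slices and
reports per-slice F1 plus its mean ("average F1") and maximum ("best F1");
slicing over documents is our interpretation of mean-vs-best model
scores, since continuous retraining of a statistical model is out of
scope.

# The mapping funnel and its riskiest rule

`deduplicateMapped()` collapses (keeping first occurrence, for
determinism): entries sharing a locus tag (*duplicate-locus*), and entries
sharing a normalized product name **and** symbol family **and** compatible
trailing subunit qualifiers (*duplicate-product*; "compatible" = equal, or
one side has none). Product equality alone deliberately never merges:
curated tables print the identical product string for genuinely distinct
genes — in the packaged 20-gene table, *aprA*, *aprB* and *cysL* all carry
"Cysteine synthase A", and *modA*/*modC* share one product line — and a
product-only (or product-plus-family) rule would silently delete real
genes. The qualifier condition is what keeps subunit pairs (aprA/aprB,
modA/modC) apart while still collapsing same-name paralogs and
bare-family re-mentions. This is the package's riskiest heuristic; the
funnel therefore records every removal with its reason so a reviewer can
audit it.

# The synthetic-data module

The generator defaults describe the study conditions the pipeline was
designed around, and are not tuning knobs:

| parameter | default | why |
|---|---|---|
| `n_genes`, `pathway_quotas` | 20; (8,1,1,3,5,2) | the curated dictionary's size and six-pathway census |
| `n_docs`, `mention_rate` | 50 documents, Poisson(4) | a small literature corpus; rates are unpublished, so chosen once as a realistic density |
| `decoy_rate` | 0.1 | enough gene-shaped non-genes that a pattern-based recognizer scores F1 < 1 |
| `cluster_density`, `background_density` | 0.35 / 0.02 | pathway-clustered PPI structure with sparse cross-talk |
| `n_families`, `n_genomes` | 300 / 63 | a genus-scale pangenome slice |
| mixture weights | 0.70 / 0.21 / 0.09 | the observed persistent/shell/cloud proportions |
| component profiles | 0.98; block 0.9/0.05 (half the genomes); 0.03 | persistent near-universal; an *environment-dependent* shell present in a genome block rather than uniformly at 0.5; rare cloud |
| `contiguity_prob` | 0.05 | same-component families are preferentially contiguous; cross-component pairs use a tenth of it |

One master seed feeds an independent derived stream per generator, so
each artifact is reproducible in isolation and bit-for-bit under a fixed
seed.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: prose is a token soup, not English; mention
ambiguity (one surface, several genes) is excluded by construction;
presence/absence rows ignore phylogenetic correlation between related
genomes; PPI scores are independent uniforms, not calibrated evidence
channels; and the planted mixture is well-separated, so recovery accuracy
on it is an implementation check, not a claim about noisy pangenomes.

# Problem sizes and determinism

The test suite runs EM recovery on three replicates of 300 families × 40
genomes, the grid reference on 4 × 2 instances, ICM enumeration on
3-family paths, and enumeration-based enrichment checks on graphs of 6–12
nodes — sizes chosen so every oracle is exhaustive and the suite completes
in about a minute. The pipeline manifest records the seed and an md5
digest of every artifact; two runs with one seed are byte-identical, which
the suite asserts.

# Known limitations

* Essentiality here *is* pangenome persistence; it inherits that proxy's
  blind spots (a universally conserved but dispensable gene is called
  essential, and vice versa for lineage-specific essentials).
* The dictionary matcher cannot find genes absent from the dictionary;
  recall against an open vocabulary is out of scope by design.
* The degree-model p-value is approximate for small dense backgrounds
  (see above); the permutation version is the fallback when exactness
  matters.
* Table-derived fixtures carry two documented count discrepancies in
  their source material (a transporter row printed as 13 in prose vs 12
  in the table, and a two-component row printed as 12 vs 10); the
  packaged fixtures follow the per-row table counts.

# A worked run

```{r, eval = FALSE}
dir <- tempfile("essmine_")
cfg <- pipelineConfig(dir, seed = 3,
                      sim = simulationConfig(seed = 3, n_docs = 8,
                                             n_families = 80,
                                             n_genomes = 16))
man <- runPipeline(cfg)
list.files(dir, recursive = TRUE)
```

The run directory contains the simulated inputs, the annotated corpus,
the evaluation report, the mapping funnel, the enrichment report with
GraphML export, the partition table with the fitted model, the
segregation report, and `manifest.json` tying them together.
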