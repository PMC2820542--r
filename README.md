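# AlteredNet

Network analysis of recurrently altered genes in tumor cohorts. Cancer
genomes are heterogeneous — individual cases are altered in largely
non-overlapping gene sets — but the altered genes tend to converge on a
small number of interacting processes. AlteredNet makes that convergence
explicit: starting from a curated gene-interaction network and per-case
genomic alteration calls, it

1. applies the altered-gene definition (somatic mutation, homozygous
   deletion or multi-copy amplification) and a recurrence threshold
   (default: altered in ≥ 2 retained cases, hypermutator cases excluded),
2. extracts the subnetwork connecting the altered genes, adding **linker
   genes** — non-altered genes whose number of altered neighbors is
   significantly larger than expected under a hypergeometric null on
   their global degree, Benjamini–Hochberg corrected,
3. partitions the extracted network into **modules** by iterative removal
   of the highest-betweenness edge, keeping the partition that maximizes
   Newman modularity
   *Q = Σ<sub>s</sub> [ l<sub>s</sub>/L − (d<sub>s</sub>/2L)² ]*
   (l<sub>s</sub>: edges within module s, d<sub>s</sub>: its degree sum,
   L: total edges), and
4. assesses significance with a **global null** (random gene sets of the
   same size, re-extracted; empirical p for the largest component's nodes
   and edges) and a **local null** (degree-preserving edge rewiring;
   scaled modularity z = (Q<sub>obs</sub> − mean)/sd over re-detected
   null modularities).

It is aimed at cancer-genomics analysts who have discrete gene-level
alteration calls and an interaction network in the same gene namespace,
and who want Cytoscape-ready module maps with significance attached. A
synthetic-data generator (random networks with planted dense modules and
simulated cohorts) makes every stage testable without any download.

## Worked example

```r
library(AlteredNet)
dir <- tempfile()
fx <- writeFixtures(dir, seed = 1)   # synthetic network + cohort
res <- runPipeline(
  networkFile      = fx$paths$network,
  alterationFile   = fx$paths$alterations,
  hypermutatorFile = fx$paths$hypermutators,
  globalIterations = 200, localIterations = 200, seed = 1)
res
```

prints

```
Altered-gene subnetwork analysis report
=======================================

package: AlteredNet 0.1.0 (R 4.3.3)
parameters: minCases=2, excludeHypermutators=TRUE, spThreshold=2, linkerFdr=0.05, globalIterations=200, localIterations=200, swapMultiplier=10, seed=1, runGlobalNull=TRUE, runLocalNull=TRUE

cases retained: 82
genes passing recurrence threshold (>=2 cases): 30
altered genes present in the global network: 28
network: 24 altered + 0 linker genes, 60 interactions
unplaced altered genes: 4
largest component: 24 nodes / 60 edges
modules: 4; modularity Q = 0.545278
global null (200 iterations): p(nodes) = 0.01, p(edges) = < 0.005
local null (200 iterations): mean Q = 0.19433, sd = 0.0387482, scaled modularity z = 9.05713
```

Reading the report: 30 genes were altered in at least 2 of the 82
retained cases; 24 of them connect into a subnetwork of 60 interactions
whose best partition has 4 modules at Q = 0.545. That component is larger
than ≥ 99% of random same-size gene-set draws (p(nodes) = 0.01), and its
modularity sits 9.1 null standard deviations above degree-preserving
rewirings — the planted modules of the synthetic cohort were found and
are significant. `writeOutputs(res, "out/")` (or `outputDir=`) writes the
network SIF, node/edge attribute files loadable in Cytoscape, module and
linker tables, null distributions, and a report, all byte-reproducible
under a fixed seed.

A thin command-line front end with the same knobs lives at
`inst/scripts/alterednet.R` (subcommands `run`, `fixtures`, `reduce` for
reaction-table pathway reduction, and `null`).

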