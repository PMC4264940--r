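# barcodelim

Species delimitation from single-locus DNA barcode data by multi-method
concordance. `barcodelim` is aimed at taxonomists and molecular ecologists
who have an alignment of COI barcode sequences (typically the 654 bp
barcode region) for a poorly known group and want a fast, repeatable first
partition of specimens into putative species (operational taxonomic units,
OTUs) before any detailed taxonomic work.

## What it does

Three independent delimitation engines are run on the same alignment:

* **ABGD** (Automatic Barcode Gap Discovery). Pairwise distances (p, JC69
  or K2P) are sorted and scanned for the barcode gap — the first gap whose
  width exceeds `X` times the local slope of the ranked distances, at or
  above the largest distance attributable to intraspecific divergence under
  a prior `P`. Specimens are clustered as connected components below the
  gap, recursively within groups, over a geometric grid of priors
  (default 10 values on [0.001, 0.1]).
* **GMYC** (general mixed Yule-coalescent) on an ultrametric tree. The
  model places a threshold height `T` separating a diversification (Yule)
  process with rate `lambda1 * k^p1` from independent within-OTU
  coalescent processes with rate `lambda2 * [n_j(n_j - 1)]^p2`; the
  log-likelihood over inter-event intervals is maximized over all candidate
  thresholds and compared with a single-process null by a likelihood-ratio
  test (chi-square, 3 d.f.). Any ultrametric Newick tree is accepted; a
  UPGMA builder is included for end-to-end runs, with haplotype collapsing.
* **RESL / BIN-style clustering**: single linkage at 2.2% divergence
  followed by Markov-cluster (MCL) refinement of each pre-cluster on the
  similarity transform `s = max(0, 1 - d/t)`.

The three partitions are compared as **comparison units** (connected blocks
across methods) and categorized FULL MATCH / PARTIAL MATCH / DISCORDANT
(all agree / exactly two agree / none agree). Conflicting units are then
resolved by the **sympatry criterion**: sister OTUs (read off a guide tree)
sharing a biogeographic region are kept as distinct species, allopatric
sisters are merged; pure diagnostic nucleotides and monophyly are computed
and logged for every tested pair but are not decision-bearing. A seeded
coalescent-within-Yule simulator generates benchmark datasets with known
true species.

## Worked example

```r
library(barcodelim)

ds  <- generateBarcodeDataset("separated", seed = 1)   # 8 species x 4 specimens
res <- runPipeline(list(alignment = ds$alignment, seed = 1,
                        tree = ds$genealogy,           # any ultrametric tree
                        abgd = list(operatingP = 0.02)),
                   outDir = "demo")
```

The run logs each stage:

```
input: 32 specimens x 654 sites
distances: K2P (primary), p (linkage)
abgd: 8 OTUs at P = 0.0215
gmyc: 8 entities (32 tips), LR = 31.46
resl: 8 OTUs
consensus: FULL 8, PARTIAL 0, DISCORDANT 0
final: 8 OTUs (FULL 8, PARTIAL 0, DISCORDANT 0)
```

and the fitted GMYC model prints as

```r
res$gmyc
#> GmycFit (single threshold)
#>   clusters 8 (8-8)  entities 8 (8-9)
#>   logL null 204.53  logL GMYC 220.26  LR 31.46 (p = 6.81e-07)
#>   threshold(s): 0.0318493
```

Here all 32 specimens fall into 8 comparison units on which all three
methods agree (FULL), so the final count is 8 OTUs — exactly the 8 species
the simulation planted; the GMYC threshold 0.032 sits inside the barcode
gap between the deepest within-species coalescence (~0.003) and the
shallowest species divergence (0.06). `demo/` holds the ABGD scan table,
the GMYC report, the consensus units, the per-pair decision log, the final
per-specimen OTU table and the OTU accumulation curve, all as TSV, plus a
config snapshot; rerunning with the same config and seed reproduces every
file byte for byte. On real data, start from `readBarcodeFasta()` /
`attachMetadata()` and supply your own chronogram via `tree =`.

A thin command-line wrapper is provided in `exec/barcodelim`
(`simulate`, `abgd`, `gmyc`, `resl`, `run` subcommands).

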