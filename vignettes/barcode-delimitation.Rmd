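---
title: "Delimiting putative species from DNA barcodes by multi-method concordance"
author: "barcodelim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Delimiting putative species from DNA barcodes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(barcodelim)
```

## The problem

Single-locus DNA barcodes (the ~654 bp COI fragment) allow a fast first
pass at species discovery in poorly known groups: sequence clusters become
operational taxonomic units (OTUs), putative species pending validation.
No single clustering method is authoritative, so this package runs three
engines with different theoretical bases — a distance-gap method (ABGD), a
tree-based likelihood method (GMYC) and a graph-clustering method
(RESL/BIN-style) — and treats their *concordance* as the measure of
robustness. OTU boundaries supported by all three are accepted; conflicts
are adjudicated by explicit, criterion-based rules rather than ad hoc
judgement. Because mtDNA is a single, maternally inherited locus,
introgression and incomplete lineage sorting can mislead every engine at
once; the output is a scaffold for taxonomy, not a species description.

## The three engines

### ABGD

Let $d_{(1)} \le \dots \le d_{(N)}$ be the sorted pairwise distances under
a model $m \in \{p, \mathrm{JC69}, \mathrm{K2P}\}$, computed with pairwise
deletion of sites containing `N`/`-` (other ambiguity codes are treated as
`N`; transitions are A–G and C–T). The closed forms are
$d_{JC} = -\tfrac34 \log(1 - \tfrac43 p)$ and
$d_{K2P} = -\tfrac12\log(1 - 2P - Q) - \tfrac14\log(1 - 2Q)$, with
saturation reported as an error naming the offending pair.

Given a prior maximum intraspecific divergence $P$ and relative gap width
$X$ (default 1.5), the *prior limit* is the largest observed distance not
exceeding $P$. Scanning up the ranked distances, a gap
$g_i = d_{(i+1)} - d_{(i)}$ qualifies as the barcode gap when
$d_{(i)} \ge$ the prior limit and $g_i > X \cdot s_i$, where $s_i$ is the
local slope — the mean per-rank increment over a sliding window of
$\max(3, \lceil 0.1 N \rceil)$ ranks (exposed as `window`). The initial
partition is the set of connected components of the graph joining pairs
below the gap (operationally, below the gap midpoint: a pair lying exactly
on the lower edge belongs below the gap); the recursive partition re-applies
the procedure within every group of at least 3 specimens until nothing
splits. A scan over a geometric prior grid
$P_k = P_{\min}(P_{\max}/P_{\min})^{k/(n-1)}$ (default 10 steps on
$[0.001, 0.1]$) reports initial and recursive OTU counts per model, with 0
marking priors at which no gap qualifies. These window and prior-limit
choices are this package's documented variant of the gap heuristic;
equivalence with an exhaustive gap search is enforced by test, bit-exact
replication of other implementations is not.

### GMYC

The general mixed Yule-coalescent model takes an ultrametric tree (tips at
height 0) and a threshold height $T$. Branches crossing $T$ define the
OTUs. Branching events deeper than $T$ belong to a generalized Yule
process over species lineages with rate $\lambda_1 k^{p_1}$; events
shallower than $T$ belong to independent per-OTU coalescent processes with
rate $\lambda_2 [n_j(n_j-1)]^{p_2}$. Species lineages persist from their
origin to the present, so the species lineage count $k$ rises from 1 at
the root, flattens at the OTU count below $T$, and equals the full lineage
count when $T$ is at the tips (pure Yule reduction); a single OTU spanning
the tree has $k = 1$ throughout (pure coalescent reduction). Over the
intervals between consecutive event heights (the threshold and the present
are additional, event-free boundaries),

$$\log L = \sum_i \left[ e_i \log b_i - b_i x_i \right], \qquad
  b_i = \lambda_1 k_i^{p_1} + \lambda_2 \sum_j [n_{ij}(n_{ij}-1)]^{p_2},$$

with $x_i$ the waiting time and $e_i$ the number of branching events
closing interval $i$ (tied node heights in constructed trees give
$e_i > 1$). Candidate thresholds are midpoints between consecutive
distinct node heights (plus one below the shallowest node; heights closer
than $10^{-9}$ of the root height are treated as ties); at each candidate
the likelihood is maximized over $(\lambda_1, p_1, \lambda_2, p_2)$ by
multi-start bounded L-BFGS-B in $\log\lambda \in [\log 10^{-8}, \log 10^8]$
and $p \in (0, 10]$, with deterministic event-rate starting points. The
null model is the single coalescent process over the whole tree (2 free
parameters), computed through the same interval machinery, and
$LR = 2(\log L_{GMYC} - \log L_{null})$ is referred to $\chi^2_3$ — the
convention of the original GMYC software, in which the threshold is not
counted as a free parameter ($df$ is configurable since chi-square
mixtures are also in use). Because the one-OTU null is not itself a
candidate threshold, a slightly negative $LR$ can occur numerically; it is
clamped at zero within a tolerance and an error beyond it. Confidence sets
collect all candidates within 2 log-likelihood units of the optimum,
summarized as min–max cluster (multi-member OTU) and entity (total OTU)
counts. The multiple-threshold variant greedily adds per-subtree
thresholds, accepting an addition only when it improves the maximized
log-likelihood by more than `improveTol` (default 2 units, a support-
interval parsimony rule), so it can only refine the single-threshold
partition.

Tree inference is deliberately decoupled: any ultrametric Newick is
accepted (a Bayesian chronogram in practice), and a UPGMA builder is
provided so the pipeline can run end to end. GMYC is fit on
haplotype-collapsed data when the tree is built internally, and the
haplotype partition is expanded back to specimens before consensus. A
caveat observed on simulations: when intraspecific diversity is low, most
species collapse to one or two haplotypes and the coalescent side of the
model has too few events for a stable fit — supplying a chronogram over
all specimens (`tree =` in the pipeline config) is then strongly
preferable to the UPGMA fallback.

### RESL

Single-linkage pre-clustering joins pairs below $t = 0.022$ (the
conventional 2.2% threshold, stored as a proportion; p-distance by
convention). Every pre-cluster of at least 4 members is refined by Markov
clustering of the similarity graph $s = \max(0, 1 - d/t)$: add self-loops,
column-normalize, then alternate expansion (matrix power, default 2) and
inflation (entrywise power, default 2, renormalized) with pruning of
entries below $10^{-12}$ until the largest entry change falls below
$10^{-6}$; clusters are read off the attractor structure. Refinement only
splits within pre-clusters, so RESL always refines single linkage. This is
an approximation of the published two-phase algorithm behind barcode index
numbers, which includes additional server-side steps; reproducing those
identifiers is a non-goal.

## Consensus and resolution

The three partitions are compared on a common specimen universe.
*Comparison units* are the connected components of the join graph in which
each method contributes edges between co-clustered specimens; every OTU of
every method lies wholly inside one unit. A unit is FULL when the three
induced sub-partitions are identical, PARTIAL when exactly two are
("similar results" is implemented as exact identity — anything weaker is
not testable from a definition alone), DISCORDANT when all three differ.
For counting, FULL and DISCORDANT units contribute one OTU each (a
discordant unit is kept as a single OTU precisely because the results
conflict); PARTIAL units contribute their majority sub-partition's count
by default (`partialUse = "finest"` is exposed because published totals do
not always say which convention they use).

PARTIAL and DISCORDANT units are then evaluated against three criteria
drawn from different species concepts: monophyly (phylogenetic), pure
diagnostic characters (diagnosable/phylogenetic) and sympatry of sister
OTUs (biological). Only sympatry decides, matching the empirical finding
that the first two are usually uninformative at this stage — diagnostic
sites are almost always present between any split (especially with few
specimens, where their validity is questionable; singleton comparisons are
flagged low-confidence), and delimitation methods rarely propose
non-monophyletic groups. For each PARTIAL unit the candidate split is the
finest proposed sub-partition; sister pairs are taken innermost-first from
the guide tree (pairs whose union forms a cherry-like split among the
unit's members; a shallowest-MRCA fallback guarantees progress on
paraphyletic tangles). A pair whose region sets intersect is sympatric and
kept as two final OTUs; an allopatric pair is merged — this also folds
single allopatric specimens into their multi-member sister. Merges update
the unit before the next pair is tested; how a unit with both sympatric
and allopatric pairs should behave is not settled by any published rule,
so the pairwise innermost-first procedure is this package's defined
extension, and every decision is logged (unit, pair, region sets,
sympatry, decision, diagnostic-site count, monophyly flags). Two caveats
travel with the output: region labels are coarse, so "sympatric" sisters
may be microallopatric; and incomplete sampling may turn "allopatric"
sisters sympatric later. Monophyly is assessed on a midpoint-rooted NJ
guide tree by default (rooting is the user's choice if they supply a
tree).

## The simulator

`generateBarcodeDataset()` produces benchmark data whose true partition is
known: a Yule species tree conditioned on the species count (waiting times
$\mathrm{Exp}(k\lambda)$, observed at the moment the next speciation would
occur), rescaled to a fixed root depth; independent within-species Kingman
coalescents scaled so the expected intraspecific pairwise divergence is
$\theta$ (deep coalescence beyond a species' stem is compressed below the
stem origin — rare in the regimes used); and two-rate (K80) substitution
with transition/transversion ratio $\kappa$, branch lengths in expected
substitutions per site, so the K2P estimator is exactly matched in
expectation. Sequences are gap-free and 654 bp by default, $\kappa = 4$ (a
typical mitochondrial value). Region labels are assigned per species; each
cherry of the species tree shares a region with probability 0.5,
exercising both arms of the sympatry rule.

Two presets define the simulation regimes used throughout the tests:

* **separated** — 8 species, 4 specimens each, $\theta = 0.0015$ (0.15%
  intraspecific diversity, typical of insect COI), root depth 0.3, and
  species divergences floored at 0.06 substitutions (floors staggered by
  1% so divergence heights stay distinct). The interspecific distance
  floor (~0.12) is then more than fifty times the expected intraspecific
  scale, a textbook barcode gap. The floor makes the guarantee structural
  rather than merely on average; the cost is that the shallowest species
  depths are not Yule-distributed.
* **hard** — 8 species, root depth 0.08, $\theta = 0.02$, uneven sampling
  (geometric, mean 4, singletons common, matching the empirical
  commonness of rarity). Intraspecific and interspecific scales overlap,
  so the engines disagree and the consensus/resolution machinery is
  exercised.

What the simulator does *not* emulate: introgression, incomplete lineage
sorting between species, rate variation among sites or lineages,
alignment gaps and ambiguity codes, and geographic structure within
species. Passing recovery tests on separated data therefore demonstrates
that the machinery is correct, not that the protocol is robust to those
real-data complications.

Benchmarks in the test suite use 50 seeded replicates of the separated
preset (32 sequences each) for recovery, 100 single-population coalescent
trees of 20 tips for the type-I error of the GMYC test, and 100/1000
random instances for the ABGD and consensus oracle-equivalence checks —
sizes chosen so the whole suite completes in a few minutes on one core
while keeping Monte-Carlo noise well inside the asserted margins.

In the recovery experiment ABGD is run with prior $P = 0.02$ (grid value
0.0215). The prior is by definition an upper bound on intraspecific
divergence, and under the separated preset the within-species coalescent
tail reaches ~0.01–0.017 while interspecific distances start at ~0.12, so
0.02 is the informed bound a practitioner with that knowledge would
supply. At a typical real-data operating prior (0.01, the pipeline
default), ABGD occasionally splits off deep intraspecific lineages — the
outlier-splitting behaviour this method family is known for, worth
remembering when interpreting real scans.

## Numerical and degenerate-input choices

* Distances are stored as proportions (2.2% is 0.022); per-pair zero
  comparable sites, JC69 with $p \ge 3/4$, and K2P with
  $1 - 2P - Q \le 0$ or $1 - 2Q \le 0$ are errors naming the pair.
* Partitions are canonical (OTUs numbered by first member in input
  order), making all engine outputs invariant to specimen order and OTU
  relabeling; ties in sorted distances are broken by stable pair order.
* ABGD returns one OTU (not an error) when no gap qualifies; scan tables
  record such priors as 0, retaining the partition.
* Ultrametricity is checked at $10^{-6}$ relative tolerance; MCL
  non-convergence within 200 iterations is an error with diagnostics.
* The pipeline writes no timestamps, so identical config + seed yields
  byte-identical outputs; every stage failure leaves a `FAILED` marker
  naming the stage.

## Limitations

Single-locus evidence only; the GMYC fit inherits all errors of the input
chronogram; the RESL stage approximates, not reproduces, the published
barcode-index clustering; the sympatry rule is only as good as the region
labels supplied; and full-scale replication of published data sets
requires downloading the deposited records, which this package treats as
an optional exercise rather than a test.
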