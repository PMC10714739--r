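---
title: "Microbial food webs: construction, topology and stability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Microbial food webs: construction, topology and stability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(MicroFoodWebs)
```

## The model

MicroFoodWebs analyses genus-level microbial food webs: directed binary
networks whose nodes are protist genera plus aggregate compartments
(algae, bacteria, fungi, detritus, dissolved organic carbon), and whose
links are literature-compiled predator–prey interactions. The adjacency
convention throughout is $a_{ij} = 1$ when node $j$ preys on node $i$:
prey in rows, predators in columns. Cannibalism is not represented (the
diagonal is forced to zero, and interaction catalogs reject self-loops at
parse time), and any web with links must contain at least one basal node —
a node that is eaten but eats nothing.

A seasonal web is built from three inputs: the genera detected in that
season's samples (presence, i.e. summed counts of at least one, unless a
higher threshold is requested), a functional-group annotation mapping each
genus to one or more trophic guilds — algivore (A), bacterivore (B),
mycophagous (M), nonselective omnivore (N), heterotrophic parasite (H-P),
phototroph (P), raptor (R), saprotroph (S), unknown (U) — and the
interaction catalog. Catalog edges whose endpoints are absent are excluded
and counted in the build report rather than raising an error, because
literature catalogs routinely reference taxa missing from a given season.
Aggregate compartments are retained even when isolated (they are standing
compartments of the web), while detected genera that end up with no links
are dropped, so the species count $S$ counts interacting trophic species.
Because it is not self-evident whether published node counts include the
aggregate compartments, the build report carries $S$ both with and without
them.

## Metrics

*Complexity.* $L$ is the number of links, linkage density $LD = L/S$, and
directed connectance $C = L/S^2$. The $L/S^2$ form is used because it
reproduces the published seasonal connectances from the published $(S, L)$
pairs in three of four seasons; the remaining cells (one linkage density,
one connectance) are internally inconsistent with any $L/S$ or $L/S^2$
reading and the package reports the computed values rather than matching
them.

*Topology.* The clustering coefficient is the mean local clustering on the
symmetrized graph, with nodes of degree below two contributing zero; the
characteristic path length is the mean shortest path over unordered
reachable pairs of the symmetrized graph, with unreachable pairs excluded
and counted; modularity is Newman's $Q$ of a greedy agglomerative
(Clauset–Newman–Moore) partition of the symmetrized graph. Trophic
direction is meaningless for neighborhood structure, hence the
symmetrization. Greedy agglomeration was chosen over stochastic Louvain so
repeated runs give identical results; since the agglomeration path ends at
the all-in-one partition, whose $Q$ is exactly zero, the returned partition
is never worse than that. Modularity values depend on the partition
algorithm, which published analyses rarely state, so exact modularity
values are not a meaningful comparison surface across implementations.

*Trophic structure.* Trophic levels are prey-averaged: $TL_i = 1$ for
basal nodes and $TL_i = 1 + \mathrm{mean}_{j \in \mathrm{prey}(i)} TL_j$
otherwise, solved as a linear system so that loops are handled. The system
is nonsingular exactly when every consumer can reach a basal resource
through prey links; a consumer cycle with no basal input raises an error
naming the cycle. Omnivory is the fraction of species feeding at more than
one trophic level (at least two prey whose levels differ by more than
$10^{-9}$), with all $S$ species in the denominator to match the
"percentage of omnivory" convention; a consumers-only denominator is
available behind a flag.

## Quasi sign-stability

Stability is summarized by Monte Carlo sampling of community matrices
constrained to the web's sign pattern. For each link (prey $i$, predator
$j$) one magnitude $u \sim \mathrm{Uniform}(0, 10)$ is drawn; the prey
loses ($-u$ at entry $(i, j)$) and the predator gains a fraction
($+0.1\,u$ at entry $(j, i)$), tying gain to loss through a conversion
efficiency of 0.1. Every diagonal entry is self-limiting,
$-d$ with $d \sim \mathrm{Uniform}(0, 1)$, including the non-living
compartments (a uniform, documented rule). The magnitudes are defaults
exposed as arguments; no distributional choices are inherited from
elsewhere. Two summaries are reported per web: the proportion of draws
whose eigenvalues all have strictly negative real part (a draw exactly at
zero counts unstable, a measure-zero event), and the mean largest real
part, where lower means faster expected recovery. Both are reported
because a proportion in $[0,1]$ cannot reproduce published seasonal
stability values quoted as 4.7 and 3.3 — the scale behind those numbers is
not recoverable — while the *direction* of interpretation (lower mean
largest real part, more stable) is preserved. When a pair of species prey
on each other, the two links' contributions to the shared entries are
summed.

## Null models

The curveball algorithm randomizes a web while preserving every species'
number of prey and number of predators exactly: two predators are chosen
at random and a random subset of the prey found in one diet but not the
other is traded. The two trading predators' own ids are withheld from the
pool so the zero diagonal survives; a trade between identical diets is a
no-op that still counts, bounding runtime. Snapshots are taken every
$5S$ trades as burn-in — there is no canonical trades-per-snapshot value,
and $5S$ decorrelates successive snapshots at these web sizes.

By default, trades are additionally constrained to exchange prey of the
same node kind: genus-level prey against genus-level prey, aggregate
prey against aggregate prey. This preserves each consumer's number of
links to standing compartments. The rationale: compartment attachments
(a bacterivore's link to the bacteria compartment, a saprotroph's to
detritus) are conventions of web construction, not genus-level
interactions sampled from the literature, and an unconstrained trade that
hands a bacterivore's bacteria link to a raptor proposes a web outside
the space the catalog describes — on strongly guild-anchored webs it also
drives null mean trophic levels far above any empirical value and breaks
a fifth of replicates on ungrounded cycles. The unconstrained classic
trade remains available (`withinKind = FALSE`).

"Within the distribution" is operationalized as the empirical value lying
inside the simulated $[\min, \max]$ range, with the 2.5/97.5 percentile
interval reported alongside. Distributions are compared across webs by the
two-sample two-sided Kolmogorov–Smirnov test with asymptotic p values;
comparisons can run ensemble-versus-ensemble (as in the pipeline's season
pairs) or ensemble-versus-empirical — `ksCompare` takes any two vectors.

## Per-sample features

Each sample's sub-network is the subgraph induced by the taxa present in
that sample plus the standing aggregate compartments. Structural metrics
(S, L, LD, C, modularity, mean trophic level, omnivory, average degree
$AD = 2L/S$) are computed on the *topology* sub-network, in which bacteria
are a single compartment. The bacterivore–bacteria interaction proportion
Int is computed on the *phylum-expanded* sub-network, where 16S-derived
bacterial phyla join as prey nodes of the bacterivores — phylum-level
bacteria exist only inside the Int computation. Int's numerator is the
number of links from a guild-B predator to a bacterial node; for the
denominator the per-sample analysis uses the bacterivores' outgoing links
(`interactionProportion(..., denominator = "bacterivore")`), i.e. the
share of bacterivore diet realized on bacteria. The all-links denominator
remains the function's default and matches the plain "proportion of
interaction associations" reading, but it makes Int mechanically
confounded with the size of the protist backbone — richer samples have
quadratically more protist–protist links — which distorts
feature–metric regressions; the diet-share form is invariant to backbone
size. Shannon diversity uses natural logarithms.

Relationships are quantified by ordinary least squares with a two-sided t
test on the slope (Int versus each web metric) and by tie-corrected
Spearman correlations between complexity and stability metric columns,
with Benjamini–Hochberg adjustment within each test family; raw p values
are reported alongside.

## The synthetic-data generator

The generator emulates the processed level of a seasonal subalpine-lake
survey — four seasons of nine samples — so that every stage of the
pipeline runs without downloads. Its defaults are the emulated study
conditions:

* Per-season detected genus richness 64/65/56/54, so built webs with the
  five aggregates have 69/70/61/59 nodes, matching the published seasonal
  node counts (read as totals including aggregates).
* A 90-genus pool with guild composition P 12, B 46, A 6, N 5, R 15,
  H-P 3, M 1, S 1, U 1. Half the bacterivores also carry the saprotroph
  guild (detritivorous bacterivores); a tenth of phototrophs also graze
  bacteria (mixotrophs). This keeps the bacterivore share of predators
  inside the reported 0.45–0.78 band (realized roughly 0.46–0.71 across
  seeds).
* Guild-rule diets with truncated-geometric sizes: bacterivores over the
  17 bacterial phyla plus the bacteria aggregate (lower truncation 8,
  mean 14; the aggregate is always in the diet), algivores over
  phototroph genera plus algae, raptors and nonselective omnivores with
  large generalist diets (lower truncation 45, means 75/80 before
  pool capping). The lower truncation keeps generalist diets from
  degenerating and keeps seasonal connectance in a stable band: realized
  $C$ lies in about $[0.09, 0.21]$ with mean 0.15, against a reported
  range of roughly 0.12–0.19.
* Log-normal abundances (meanlog 3, sdlog 1.2); the analysis uses
  presence and proportions only, so the abundance law is a free choice.
  Within a season every sample holds the same number of genera (80% of
  the season's detected set, drawn without replacement), so per-sample
  richness carries no shared variance; per-sample bacterial phylum counts
  are drawn uniformly between 1 and 17, giving Int strong idiosyncratic
  variation that is independent of the protist backbone.
* Heterotrophic parasites are modeled as predators of their host genera,
  consistent with the prey-to-predator energy convention. Both directions
  of an accidental mutual pair are never kept. A patching step guarantees
  that every detected genus interacts within its season, so built webs
  hit the richness targets exactly.

`plantAssociation` plants a feature–metric association for
parameter-recovery tests: it ranks samples by the baseline value of the
target metric (computed on the topology sub-networks) and shifts each
sample's bacterial phylum incidence up or down that ranking. Phylum
incidence moves Int almost linearly and cannot touch topology-web
metrics, so the planted sign is recovered without mechanical feedback;
strength 0 returns the dataset unchanged, and a phylum is never removed
from its last sample in a season. The default strength of 1 spans the
full incidence range across the ranking.

What the generator does *not* emulate: sequencing noise, compositional
(relative-abundance) effects, OTU-clustering artifacts, environmental
drivers of composition, and any real phylogenetic or trait structure in
guild assignments. Passing tests therefore demonstrate that the pipeline's
operations are correct and that planted effects are recoverable under the
generator's assumptions — not that the same effect sizes or null behavior
hold in field data.

## Numerical and design choices

* Trophic levels: the linear system is solved directly; groundedness is
  checked first so singular systems fail with the offending nodes named.
* Omnivory tie tolerance $10^{-9}$; stability criterion strictly
  $\max \mathrm{Re}(\lambda) < 0$.
* Deterministic tie-breaking throughout: greedy modularity, node ordering
  by sorted id in built webs, seeded RNG in every stochastic stage. The
  pipeline fans one global seed out to per-stage child seeds through a
  counter, so any stage can be re-run in isolation.
* Sub-network QSS defaults to a few hundred draws per sample (200 in the
  pipeline) — the per-sample webs are small and the binomial error of a
  proportion at that depth is below the between-sample spread.
* Problem sizes used by the test suite: null ensembles of 1000 replicates
  on a 70-node web; QSS at 1000–5000 draws; trophic-level oracle
  equivalence enumerated over all $2^{15}$ upper-triangular six-node webs;
  parameter recovery over 100 seeded replicates (plus 100 null
  replicates). These sizes make every Monte Carlo bound in the tests
  comfortably tighter than the assertion it supports.

## Known limitations

* The exact statistic behind published seasonal "QSS" values on a
  0-to-5-ish scale is not recoverable; only direction-of-interpretation
  comparisons are meaningful against those numbers.
* Exact modularity values depend on the (unnamed) partition algorithm and
  are not comparable across implementations.
* The guild-rule generator is not a niche model; degree distributions are
  geometric by construction rather than emerging from a trait axis.
* Cannibalism and parasite-specific energetics are out of scope; H-P
  nodes behave as ordinary predators of their hosts.

## A worked run

```{r, eval = FALSE}
report <- runPipeline(list(seed = 1, nRandom = 1000, nDraws = 1000))
report$metrics      # one row per seasonal web
report$features     # 36 per-sample rows
report$associations # Int regressions and the complexity-stability matrix
```
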