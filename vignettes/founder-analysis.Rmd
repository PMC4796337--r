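---
title: "Dating maternal founder events with mitofounder"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dating maternal founder events with mitofounder}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitofounder)
```

## The problem

Human mitochondrial DNA is maternally inherited and non-recombining, so a
sample of mitogenomes from a population carries a readable genealogy. When
a *sink* population (say, an island) was settled by migrants from a
*source* population (a neighbouring mainland), each immigrant maternal
lineage — a **founder** — seeds a clade in the sink whose internal
diversity has been accumulating since the arrival. Founder analysis turns
that observation into a dating method: identify the founder haplotypes on
a joint mutation tree of source and sink samples, measure the mutational
diversity that each founder's sink descendants have accumulated, convert
it to years with a calibrated molecular clock, and aggregate the
per-founder ages into a picture of when migration happened.

`mitofounder` implements that workflow end to end: variant scoring against
a reference in rCRS coordinates, reduced-median haplotype networks
resolved into a rate-weighted most-parsimonious mutation tree, rho
(&rho;) dating with Saillard standard errors, f-criterion founder
identification, a migration-time scan on a 200-year grid, probabilistic
allocation of founders to stipulated migration events, skyline increment
ratios, and a coalescent simulator that generates datasets with known
demographic truth so every stage can be tested.

## Variant scoring and exclusion filters

Sequences are compared with the reference over their declared region
(whole genome `[1, 16569]` or HVS-I `[16051, 16400]`). Equal-length input
is compared column by column; other input is globally aligned first.
Variants follow mtDNA community conventions: substitutions are written
`T16223C`, insertions `309.1C`, deletions `16166d`, and indels are placed
at their 3'-most equivalent position, matching PhyloTree-style motif
notation. Ambiguity codes never produce variants; they are counted as
missing data, and a sample whose unambiguous coverage falls below a
configurable fraction of the region (default 50&nbsp;%) is rejected
outright.

Two hypermutable features are excluded before any phylogenetic step, as is
standard in the field: the transition at position 16,519 and length
variation in the C-stretches 16,180–16,193 and 309–315. The filter is
idempotent and removes nothing else — a *transversion* at 16,519 or a
*substitution* inside the C-stretches survives.

Functional classes (`synonymous`, `nonsynonymous`, `rRNA`, `tRNA`,
`control_region`, `intergenic`) come from an embedded gene map with the
standard rCRS coordinates. Protein-coding substitutions are classified by
translating the affected codon before and after the change under the
vertebrate mitochondrial genetic code, with light-strand genes (ND6)
handled on the complementary strand. Indels in coding genes are reported
as `nonsynonymous` (frameshift-equivalent); substitutions in an
incomplete terminal codon are treated the same way, since their effect on
the polyadenylation-completed codon cannot be read from the genome alone.
Positions covered by two overlapping genes (ATP8/ATP6, ND4L/ND4) take the
first gene in map order.

### A note on the bundled reference

The package ships a deterministic *synthetic* 16,569-bp reference
(`mito_reference()`) that is coordinate-compatible with rCRS numbering and
has a realistic base composition, but is not the actual revised Cambridge
Reference Sequence. All examples, tests and simulations are internally
consistent because the same reference is both the root state of the
simulator and the scoring baseline. For real data, pass the genuine rCRS
string through the `reference` argument of the scoring functions; nothing
else changes.

## From haplotypes to a mutation tree

Each segregating variant becomes a binary character (absence/presence of
the derived state relative to the reference); positions with more than one
alternate allele are split into one character per allele. The network
stage then proceeds in three steps.

**Latent haplotypes.** The classical reduced-median construction closes
the observed haplotype set under coordinatewise majority (median vectors).
We generate the latent states as the *Buneman vectors*: every 0/1 vector
whose value pair at each pair of characters occurs in some observed
haplotype, found by breadth-first single-character flips from the observed
states. This set contains the median closure — and therefore every
latent node of every most-parsimonious tree — while being computable by
local search; an explicit node cap guards against pathologically
conflicted data.

**Links.** For networks up to 1,200 nodes every pair of states with no
third state geodesically between them is linked (links may carry several
mutations when intermediate haplotypes are unobservable). Beyond that,
links are the single-character flips plus minimal bridges between
flip-connected components, keeping all tied parallel bridges so
reticulations survive.

**Reduction.** A reticulation records a character pair in conflict (all
four gamete combinations observed); resolving it means letting one of the
two characters mutate twice. Each mutation event is costed as
`class_weight / position_rate` — by default transversions weigh 3 times
transitions and indels 5 times, with uniform position rates that can be
replaced from a TSV. When the cost ratio of the two characters reaches the
reduction threshold (conventional default 2), the resolution that makes
the *expensive* character recurrent is removed from the network; of the
two parallel links of that character, the one whose endpoints carry less
sample weight is dropped, with a deterministic state-order tie-break, and
a removal that would disconnect the network is skipped. With uniform costs
nothing is removed and the network retains every most-parsimonious
resolution.

`resolve_to_tree()` extracts one spanning resolution with a lexicographic
objective: minimise the mutation count first, then the total event cost,
so that among equally parsimonious resolutions recurrent mutations land on
the fastest positions; remaining ties break by sorted state order, making
the output deterministic and invariant to input order. Instances with at
most 10 distinct haplotypes (and ≤250 network nodes) are solved *exactly*
with the Dreyfus–Wagner Steiner dynamic programme; larger instances use
the shortest-path terminal-closure heuristic (minimum spanning tree over
the terminal metric closure, expanded into network paths), falling back to
a plain spanning tree with pruning only above 900 nodes. Rooting is by an
explicit outgroup/reference node — never midpoint rooting, which is
misleading under star-like genealogies.

## Rho dating

For a clade root `v`, `rho_statistic()` is the mean number of
scope-eligible mutations on the paths from `v` to each sampled descendant
(samples at internal nodes count with their path), and `saillard_sigma()`
is the standard error derived from the tree's edge structure:
&sigma;&sup2; = &Sigma;<sub>e</sub> m<sub>e</sub>(n<sub>e</sub>/n)&sup2;,
summing over edges below `v` with m<sub>e</sub> eligible mutations and
n<sub>e</sub> samples below. Both are computed in exact integer arithmetic
(numerators and denominators are exposed as attributes) and both respect a
mutation-class scope: all substitutions, transitions only, or synonymous
only. Indels never enter the clocks.

Three calibrated clocks are built in:

| clock | years per mutation | scope |
|---|---|---|
| `transition` | 3,624 | transitions (whole-mtDNA, selection-corrected) |
| `synonymous` | 7,884 | synonymous substitutions |
| `founder` | 2,639 | all substitutions (founder-scan average; the underlying point-estimate rates span 1/2,599–1/2,679) |

`convert_to_age()` returns age = &rho; &times; years-per-mutation with a
95&nbsp;% CI of &rho; &plusmn; 1.96&sigma; converted the same way and
truncated at zero. A purifying-selection correction can be supplied as a
monotone piecewise-linear table from uncorrected to corrected years
(applied by interpolation, linearly extrapolated beyond its last row);
the default is the identity, since the published correction is available
only as constants at the calibration points.

## Founder identification and migration times

With every sample labeled source or sink, each sink sample is walked up
the rooted tree to the most recent ancestor attested in the source —
either source samples of that very haplotype or source-bearing branches
below it — that also satisfies the **f-criterion**: `f0` requires mere
attestation, `f1` at least one derived source branch, `f2` two. The
criterion guards against recurrent mutation and back-migration
masquerading as founders: a haplotype with derived source diversity was
genuinely resident in the source. Stem mutations between the founder node
and the sink sub-clades count toward the sink diversity, following the
convention that a founder is the last haplotype shared with the source.
Clusters therefore partition the sink samples under every criterion, and
tightening f0 &rarr; f1 &rarr; f2 can only merge clusters upward. Clusters
whose source evidence is entangled with sink lineages (no source samples
of the founder haplotype itself and every source-bearing branch also
carrying sink samples) are flagged as possible back-migration.

Each cluster is dated with &rho; over its own sink members only. The
**migration scan** lays a normal kernel per cluster, centred at the
founder age with standard deviation equal to the Saillard error in years,
weighted by the cluster's sink sample count (frequency weighting;
equal-per-founder weighting is a flag, since either convention is
defensible), and integrates the kernels over 200-year cells, normalising
the total to one. A Saillard error of zero degenerates to a point mass in
the age's cell. If the grid is cut below the largest age + 3 SD the
truncation is warned about and the mass renormalised.

**Allocation** to stipulated migration events at times T<sub>j</sub>
(e.g. 6,500 and 11,000 years) treats a cluster's total sink mutation
count m as Poisson with mean n&middot;T<sub>j</sub>/years-per-mutation and
normalises the per-event likelihoods, times an optional prior, per
cluster; computation is in log space, so rescaling the prior by any
constant changes nothing and exact zeros arise only from a zero event
time with a positive mutation count.

### How sharp can the scan be?

The per-cluster age uncertainty is
years-per-mutation &times; &radic;(&lambda;/n) for a star cluster of `n`
tips whose lineages carry &lambda; expected mutations each. With the
founder clock, a 5-tip cluster dating from 6,500 years has an age SD of
roughly 1,850 years, and from 11,000 years roughly 2,400 years — the same
order as the spacing of Holocene migration episodes. Scans built from
many small clusters therefore smear adjacent pulses into broad or merged
modes; resolving pulses a few thousand years apart requires clusters of
dozens of tips (where the SD drops below ~1,000 years) or very many
founders. The scan is an honest visualisation of the likelihood surface,
not a super-resolving estimator, and the stipulated-event allocation is
the more reliable readout at small sample sizes: a cluster's Poisson
count discriminates 6.5 from 11 ka with useful power even when the scan
modes merge.

## Skyline increment ratios

Externally estimated effective-size trajectories (for example the median
curve of a Bayesian skyline plot) are consumed as two-column TSVs; the
estimation itself is out of scope. `increment_ratio()` reports the fold
change Ne(t<sub>young</sub>)/Ne(t<sub>old</sub>) over a stated period,
reading the curve by linear interpolation on the Ne scale (a log-scale
flag exists, as the interpolation convention is not standardised). Ratios
telescope across abutting periods and are invariant to rescaling of the
curve.

## The synthetic-data generator

`scenario_config()` describes a source population and a sink founded by
dated pulses; `simulate_genealogy()` and `evolve_sequences()` realise it.
The design choices:

* **Source genealogy.** A backward-in-time coalescent whose timescale
  shrinks exponentially into the past (present-day pairwise coalescence
  timescale 850,000 years, growth 2&times;10<sup>-4</sup>/year). This
  emulates a source population that expanded strongly through the
  postglacial and Neolithic periods: many distinct lineages persist at
  6,500 and 11,000 years before present — so founder draws at those times
  find ancestors to attach to — while the most recent common ancestor
  stays at a plausible few tens of ka. A constant-size source cannot do
  both: deep enough to keep a dozen lineages at 11 ka, its TMRCA runs to
  hundreds of ka and the resulting homoplasy is absurd for mtDNA.
* **Founder pulses.** At each pulse time the stipulated number of founder
  lineages is drawn *without replacement from the standing source
  genealogy* — the founder node sits exactly at the pulse time on a
  lineage ancestral to sampled source individuals, which is what makes
  f1 identification and unbiased &rho; dating possible in principle.
  Sink samples divide evenly among pulses and, within a pulse, among its
  founders.
* **Sink expansion.** Star-like by default (every sink lineage coalesces
  onto its founder exactly at the pulse time), matching the assumption
  under which &rho; dating is unbiased; a fast within-sink coalescent is
  available as the non-star alternative.
* **Mutation model.** Substitutions only, as a Poisson process with one
  expected event per 2,639 lineage-years (so the founder clock is exact
  by construction), positions drawn by gamma-distributed relative site
  rates (shape 0.4 — strong heterogeneity, as in real mitogenomes) and a
  transition:transversion ratio of 22. Recurrent and back mutations arise
  naturally. Indels and heteroplasmy are not simulated.
* **Reproducibility.** One seed drives the whole scenario: the genealogy
  consumes the seed itself and the sequence evolution the seed + 1, in a
  documented draw order, so fixtures regenerate byte-identically
  (`make_fixture()` registers `two-pulse-taiwan`, `single-founder` and
  `no-migration`).

What passing tests on this generator do **not** show about real data: the
simulator has no sequencing error, no missing data, no sampling bias, no
population structure within source or sink, no back-migration, and its
star-expansion assumption is the best case for &rho;. Reconstruction
noise alone — homoplasy at hot sites and founder nodes occasionally
placed a mutation or two too deep — already inflates founder ages by
a few hundred years at these sample sizes; real data add every other
complication on top.

## Problem sizes and numerical conventions

The shipped test-suite exercises: exact &rho;/&sigma; agreement with a
brute-force path-enumeration oracle on 1,000 random trees (≤20 tips, ≤30
mutations); network/most-parsimonious-tree correctness against exhaustive
topology search on instances of ≤7 haplotypes and ≤10 sites; and the full
pipeline on a simulated two-pulse scenario with 60 source and 100 sink
genomes. These sizes keep the default suite fast while covering every
code path; all simulations are seeded and deterministic.

Degenerate inputs are defined rather than rejected where a convention
exists: a clade with zero mutations has &rho; = &sigma; = 0 and age 0;
identical haplotypes collapse to one node; an empty motif table annotates
nothing; a sink with no samples yields an empty founder set; allocation
with a single event returns probability 1. Iteration over nodes,
characters and edges is always in sorted order, so every output is
reproducible and independent of input permutation.

## Limitations

* The bundled reference is synthetic; real analyses must supply the rCRS.
* Haplogroup annotation honours user-supplied motif tables only; there is
  no built-in nomenclature tree.
* The purifying-selection correction ships as an identity plus the three
  calibrated constants; a full time-dependent correction must be loaded
  as a table.
* Maximum-likelihood branch-length dating and Bayesian skyline estimation
  are consumed as inputs, not reimplemented.
* The migration scan's resolution is limited by per-cluster sampling
  noise, as quantified above.
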