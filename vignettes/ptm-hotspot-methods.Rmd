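---
title: "Methods: family-wide PTM hotspot prioritization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: family-wide PTM hotspot prioritization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ptmhotspots)
```

## The model

A single experimentally observed modification carries weak evidence of
function. The premise of this package is that evidence accumulates at the
level of the *alignment column*: if serines observed as phosphorylated in
several homologs map to the same column of a family alignment, and that
column keeps an acceptor residue across the family, selection is plausibly
maintaining a modification site. The unit of analysis is therefore the
modified alignment position (MAP) — any column harboring at least one
observed PTM — and the analysis proceeds in three stages: conservation
profiling within the focal (query) sub-family, feature computation over
the merged family-wide alignment, and structural projection.

Each MAP gets a multiplicative Integrative Score

$$IS = CPC \times PC \times PRC \times W_1(NKC) \times W_2(PPI)$$

The multiplicative form means the score is driven by the *co-occurrence*
of evidence: a dense cluster (high CPC) of repeatedly observed (high PC)
modifications on a conserved acceptor column (high PRC) scores
multiplicatively higher than any single line of evidence. The two
conditional weights are evidence channels that may simply be absent —
functional annotation of neighbors, and structural coverage. They are
therefore defined as *activation-gated* multipliers: $W_1 = 1$ when no
neighboring MAP has known-functional evidence and $w_1 \cdot NKC$
otherwise; $W_2 = 1$ off-interface and $w_2$ on it. A weight convention
that multiplied by zero when a channel is missing would annihilate the
score of every MAP in a family without crystal structures, which is the
wrong behavior for an integrative prior; gating keeps the score comparable
across families with unequal annotation depth. Whether $NKC$ should enter
as a count or merely as a binary trigger is genuinely underdetermined;
both are supported (`nkc_mode`), and the default is the count, which
rewards MAPs embedded between several functional neighbors.

$IS = 0$ exactly when $PC = 0$ or $PRC = 0$; since a MAP by definition
holds a PTM, in practice the zero case is a column whose dominant-type
acceptor class has been completely lost in the family.

## Features and their conventions

* **Conservation denominators are non-gap rows.** Gap handling is
  isolated in the separate `membership` feature, keeping TRC/PAC/PRC
  orthogonal to alignment coverage. An all-gap column returns zeros with
  a degenerate flag rather than `NaN`.
* **CPC includes the target column; NC/NKC exclude it.** With the default
  half-width $w = 2$ the neighbor count is bounded by 4, which is the
  only reading that makes "cluster count" and "neighbor count"
  consistent. Windows truncate silently at the alignment edges. At
  $w = 0$, $CPC = PC$ and $NC = NKC = 0$ identically (a tested
  invariant).
* **PRC follows the dominant PTM type** of the MAP (ties resolved toward
  phosphorylation, then alphabetically): S/T/Y for phosphorylation, K for
  ubiquitination and acetylation, K/R for methylation, and the observed
  letters themselves for unrecognized types. PRC enters the score as a
  fraction in $[0, 1]$, not a percent — the score is dimensionless and
  ranks are unaffected by the constant factor either way.
* **Conservation scope.** Within-family profiles (e.g. the plant
  sub-family) use `scope = "query"`; features for scoring are computed on
  the merged alignment with `scope = "all"`. Both are exposed because the
  two questions — "is this column conserved among plants?" and "is it
  conserved family-wide?" — are both scientifically relevant.

## Profile-to-profile merge

Sub-family alignments (a curated query alignment; a database-derived PTM
sub-alignment) are merged without disturbing either: columns of each
input are rigid units, and deleting the all-gap columns introduced into
one input recovers it verbatim. The column-pair objective is the expected
substitution score $\sum_x \sum_y f_A(x) f_B(y) S(x, y)$ over non-gap
letter frequencies with BLOSUM62, and gaps are affine (open $-10$, extend
$-0.5$ per column, terminal gaps penalized). A column all-gap in one
profile scores 0 against anything, making padding neutral. Ties in the
dynamic program are broken match > gap-in-second > gap-in-first, which
makes the merge deterministic. These conventions are declared rather than
inherited from any particular aligner so results are reproducible; all of
them are overridable (`submat`, `gap_open`, `gap_extend`). The
implementation is validated against exhaustive enumeration of all
monotone column pairings on small profiles.

## Structure: interfaces and projection

Interface detection is exact, not grid-approximate: residue pairs are in
contact when any two heavy atoms lie within the cutoff, 4.0 Å by default
and *inclusive*, using all-pairs Euclidean distances. Hydrogens are
excluded because crystal structures generally lack them; which atoms the
4 Å convention should include is not standardized, so heavy-atoms and
inclusive-≤ are declared package conventions. Interface sets are
symmetric, monotone in the cutoff, and invariant under rigid motion
(tested to 1e-9).

Mapping a crystallized chain onto the family uses ends-free (overlap)
pairwise alignment with the same matrix and gap parameters as the profile
merge: structures are usually engineered fragments of a full-length
member, and fully-penalized global alignment mispairs the fragment's
termini against the member's distant ends. An identity below 0.95 over
the paired region is an error, not a warning — projecting scores through
a wrong chain assignment is silently catastrophic. Projection writes each
residue's quantile bin into the B-factor field (two decimals; unscored
residues 0.00) so any molecular viewer colors the hotspot landscape
directly.

Binning: zero scores get bin 0; positive scores are split into `n_bins`
rank-quantile bins with ties sharing a bin, so a family whose positive
scores are all equal lands entirely in the top bin rather than being
split arbitrarily.

## Enrichment and conservation comparison

Regional enrichment is the plain observed/expected ratio
$fold = (k/n) / (K/N)$ over candidate acceptor positions (S and T by
default, since observed plant phosphosites are exclusively S/T; Y can be
added). Degenerate denominators ($K = 0$ or $n = 0$) yield a flagged
undefined result instead of an exception, because region sweeps routinely
cross empty regions. No significance testing is attached: at the n of a
single protein's site list, a fold is descriptive, and dressing it in a
p-value would overstate it.

The site-vs-background conservation comparison contrasts mean TRC/PAC of
site columns against all other phospho-capable columns (≥ 1 S/T/Y among
scope rows). Restricting the background to phospho-capable columns is
what makes the comparison fair: a random column is mostly non-acceptor
and would flatter the sites.

## The synthetic generator

`simulate_family()` draws an ancestor uniformly over the 20 amino acids
and descendants that copy each column with probability $c_j$ — a star
phylogeny. This is deliberate: every statistic in this package is a
function of column composition only, so phylogenetic covariance would add
realism without adding test power. Contiguous gap segments (mean length
4) are inserted at a configurable expected fraction (2%). What the
generator does **not** emulate: tree-structured covariance, indel
evolution, biased residue composition, and database ascertainment bias.
Passing recovery tests on this generator therefore demonstrates that the
pipeline's machinery is correct, not that the score is well-calibrated on
real proteome-scale data.

`plant_ptms()` plants ground truth: 5 hotspot columns (spacing
$> 4w$ so clusters cannot interact), forced to ≥ 95% acceptor content,
each receiving $\max(1, \mathrm{Poisson}(6))$ phospho records on distinct
rows; 30 background singleton columns more than $2w$ from any hotspot;
and 2 functional hotspots whose records carry known-function labels and
which are flanked at $\pm w$ by known-functional neighbor MAPs of 4
records each, so a functional cluster totals ~14 PTMs. The flank density
was chosen by simulation before the recovery thresholds were frozen:
functional sites in real families sit inside dense (roughly 6–13 count)
phospho-clusters, and 4-record flanks place the synthetic functional
clusters at that density while leaving non-functional hotspots
competitive enough that the recovery task stays non-trivial. Denser
designs (four flanking MAPs) were rejected because the flanks themselves
crowd non-functional hotspots out of the top ranks, making the benchmark
test the generator rather than the score.

`simulate_structure_pair()` places single-Cα residues on a 6 Å lattice
with planted contacts drawn from $U(2.5, \mathrm{cutoff})$ Å and all
other inter-chain pairs ≥ cutoff + 2 Å, so interface recovery is exact by
construction (which also bounds the feasible cutoff at 4.5 Å on this
lattice).

Problem sizes used throughout the tests and the acceptance script — 40
sequences × 300 columns, 100 simulation replicates for recovery, 500 for
the uniform-planting fold — are the package's chosen study conditions:
large enough that recovery rates are stable to a few percent, small
enough to iterate on.

## Fixtures

The packaged RGS fixtures transcribe the in-text plant and mammalian site
lists (14 plant phosphosites across AtRGS1 and GmRGS2; the named
functional mammalian sites) onto *synthetic stand-in sequences* — no
public accessions were available to ship — engineered so that every
record's residue letter, the region intervals, the AtRGS1 candidate
counts (29 cytoplasmic S/T, 13 in the 288–417 domain window), and the
column coincidence of AtRGS1-S436 with GmRGS2-S437 hold exactly. The
AtRGS1 "S435/436" doublet is recorded at 436; position 435 remains a
serine in the stand-in. The two-chain structure fixture is likewise
synthetic geometry whose contacts touch exactly the interface-annotated
AtRGS1 residues. Conclusions about real RGS biology should of course be
drawn from real sequences and structures; the fixtures exist to make the
pipeline's behavior fully checkable offline.

## Tunable parameters

| parameter | default | units | notes |
|---|---|---|---|
| `window` | 2 | alignment columns | cluster half-width for CPC/NC/NKC |
| `interface_cutoff` | 4.0 | Å | inclusive, heavy atoms |
| `crosstalk_window` | 5 | residues | inclusive phospho–ubiquitin pairing |
| `w1`, `w2` | 2, 2 | — | conditional weights, ≥ 1 |
| `nkc_mode` | "count" | — | count vs binary activation of $W_1$ |
| `n_bins` | 5 | — | projection bins for positive scores |
| `gap_open`, `gap_extend` | −10, −0.5 | score | profile merge, per column |
| acceptor residues | S, T | — | enrichment candidates; add Y if wanted |

## Known limitations

* Star-phylogeny simulation cannot expose errors that only correlated
  evolution would reveal (none of the implemented statistics depend on
  it, but future tree-aware features would need a different generator).
* The Integrative Score is a prioritization heuristic, not a calibrated
  probability; score differences between families are not comparable
  when annotation depth differs.
* Enrichment folds carry no uncertainty; treat them as descriptive.
* PDB parsing handles ATOM records of standard residues; mmCIF and
  modified residues are out of scope.
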