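---
title: "Methods: pan-genome chromatin architecture and SV analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pan-genome chromatin architecture and SV analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panchrom3d)
library(dplyr)
```

`panchrom3d` analyses how 3D-genome features and structural variants are
conserved across many genome assemblies of one species. This vignette
documents the models and procedures, the tunable parameters and their
defaults, the numerical conventions, and what the synthetic-data generator
does and does not emulate.

## Coordinates, interval algebra and liftover

All coordinates are 0-based half-open (`[start, end)`), the BED
convention; GFF input is converted on read. Three primitives carry the
pan-genome machinery:

- `merge_with_gap(iv, max_gap)` merges intervals whose gaps are at most
  `max_gap` (inclusive, matching merge-tool `-d` semantics) into their
  envelope, retaining per-genome membership. It is idempotent and
  order-invariant, which the tests assert as properties.
- `reciprocal_overlap_fraction(a, b)` divides the overlap by the length
  of the **shorter** interval, so a feature nested inside a larger one
  scores 1. The conservation rule for loop anchors uses a strict
  `> 0.5`. The alternative reading — requiring 50% of *both* lengths —
  is stricter and asymmetric in effect; we chose the permissive
  symmetric version and expose the threshold as an argument.
- `coverage_fraction(target, features)` is union coverage. Internally a
  prefix-sum index over the disjoint union answers each query in
  logarithmic time, which is what makes the bootstrap null (tens of
  thousands of coverage evaluations) cheap.

Liftover uses equal-length aligned block maps (genome ↔ backbone). Both
endpoints are mapped independently; if both land on the same target
chromosome in consistent order the envelope is returned, otherwise the
interval is unmapped with a reason code (`chrom_absent`,
`start/end/both_unaligned`, `inconsistent`). An interval fully inside one
block maps with its length preserved, and mapping through a map and its
inverse is the identity on aligned intervals (tested as a property).
Strand is carried as metadata and ignored by all overlap operations.

## Pan-conservation classification

With presence count $c$ over $n$ genomes, categories are mutually
exclusive: core ($c = n$), softcore ($c < n$, $c/n \ge 0.9$), private
($c = 1$), dispensable (otherwise). For $n = 15$, softcore is exactly
$c = 14$; the band is empty for $n < 10$, and the simulator refuses such
configurations rather than silently reassigning classes.

Feature kinds cluster differently:

- **Boundaries and LT-CREs**: pooled backbone-lifted intervals merged
  with `max_gap` 40 kb (boundaries) or 500 bp (LT-CREs); the presence
  count is the number of *distinct* genomes contributing, so duplicated
  features within one genome do not inflate conservation.
- **Loops**: two loops are linked when anchor1–anchor1 and
  anchor2–anchor2 both overlap reciprocally by more than 0.5; clusters
  are connected components (single linkage). Single linkage is the
  minimal closure that makes clusters well-defined from a pairwise rule;
  it can chain distant loops through intermediates, which matters only
  when anchors drift by more than half their width between genomes.
- **SVs**: merged by the SURVIVOR-style rule below; conservation uses
  the supporting-genome count of the merged record.

Accumulation curves re-add genomes in random orders: the pan size at step
$k$ counts clusters present in at least one of the first $k$ genomes, the
core size those present in all $k$. Pan curves are non-decreasing and core
curves non-increasing for every order, and the step-$n$ values are
order-invariant — all asserted in the tests.

Compartment conservation compares per-genome A/B status of orthologous
regions: all-A or all-B is conservative, any disagreement variable, and
regions missing in more than half the genomes are flagged and excluded
from the pan set.

## Chromatin architecture from contact matrices

**Insulation.** For bin $b$ the raw score is the mean contact count in the
off-diagonal diamond $\{(i,j): i \in [b-w, b-1], j \in [b+1, b+w]\}$ — the
center bin is excluded. Scores are normalised as
$\log_2(\mathrm{IS}(b)/\overline{\mathrm{IS}})$ over valid bins, and edge
bins where the window does not fit are masked. The window default is
$w = 2$ bins at 40-kb resolution; the binning is the field's convention
for TAD calling, the window is this package's default and exposed as an
argument. Zero-count windows are floored at $10^{-9}$ of the mean before
the log so strengths stay finite.

**Boundaries.** Candidates are local minima of the normalised track
(plateaus count once and merge into one boundary interval). Strength is
the topographic prominence of the minimum: the drop from the lower of the
two flanking "cols" reached before a deeper point. The retention
threshold is not fixed but computed per chromosome by Li's minimum
cross-entropy method on the candidate strengths — the iteration
$t \leftarrow (\mu_{\le t} - \mu_{> t}) / (\ln \mu_{\le t} - \ln \mu_{> t})$
run on min-shifted values (the reference implementation's convention;
the functional is not shift-invariant), converged at $10^{-8}$. The
frozen test value was computed with scikit-image's `threshold_li` on an
identical sample.

A $w$-bin diamond cannot separate boundaries closer than about $2w + 1$
bins: the shallower minimum degrades into a shoulder of the deeper one and
its prominence collapses. The TAD fixture generator therefore uses a
minimum domain width of 5 bins (200 kb at 40-kb bins) — domains below the
window's resolving scale are not a regime the insulation method is
defined for.

**TADs** are the spans between adjacent passing boundaries; the spans
from the chromosome ends to the first/last boundary are emitted flagged
`partial`. $k$ boundaries always yield $k + 1$ spans.

**Compartments.** At 100-kb bins: mask zero-marginal bins, divide each
entry by its diagonal mean (observed/expected), take the Pearson
correlation matrix, and split bins by the sign of its first eigenvector.
The eigenvector sign is arbitrary, so it is oriented to correlate
positively with a user-supplied track (typically gene density; active
A compartments are gene-dense). Zero eigenvector entries are labelled B —
a deterministic tie-break, flagged per bin. Labels are invariant to global
scaling of the matrix.

**Map resolution** is the smallest bin size at which at least 80% of bins
(inclusive) accumulate at least 1,000 contacts; if none qualifies the
largest candidate is returned with a warning.

**LT-CREs and loop typing.** An ATAC peak is an LT-CRE when its edge is at
least 2,000 bp from every TSS and it overlaps at least one loop anchor.
Anchors are labelled E when they overlap an LT-CRE, else G when they
overlap the 2-kb window upstream of a TSS (strand-aware; a flag disables
strand awareness). E takes precedence — a G anchor is one *only*
overlapping an upstream window. Loop types are the unordered pairs E-E,
E-G, G-G; a loop with an unlabelled anchor is `unannotated`.

**TAD reorganization** labels each query TAD against a reference set:
stable when exactly one reference TAD overlaps reciprocally by ≥ 0.8 of
both lengths; fusion when ≥ 2 reference TADs each cover ≥ 0.2 of the
query and jointly ≥ 0.8; neo when reference coverage is ≤ 0.5. The
thresholds are package defaults exposed as arguments, not literature
constants.

**Boundary activity** z-scores three per-boundary features (ATAC signal
density, mean expression of overlapping genes, gene count) in the
boundary ± 20 kb (half a bin each side beyond the boundary span) and
clusters with k-means, $k = 3$, 50 restarts under a fixed seed; clusters
are relabelled active/neutral/inactive by descending mean ATAC z-score,
making the labels deterministic and order-invariant.

## Structural variants

**Merging** drops records under 50 bp, then links records of the same
type on the same chromosome whose start and end breakpoints are each
within 1,000 bp; merged sets are connected components. These parameters
mirror the common multi-caller merge convention (distance 1000, type
agreement on, strand agreement off, minimum size 50). The representative
record is the medoid — the member minimising summed breakpoint distance
to the others, ties broken by genome id then coordinate — which keeps the
output deterministic and independent of input order (a tested property).

**Mechanism classification** applies the first matching rule in fixed
order: tandem-repeat coverage ≥ 0.8 → VNTR; TE coverage ≥ 0.8 with a
dominant family → TEI; flanking homology ≥ 100 bp → NAHR; templated
switch → FoSTeS/MMBIR; microhomology 3–20 bp → alt-EJ; ≤ 2 bp → NHEJ;
otherwise unassigned. The thresholds follow Meerkat-style conventions and
are arguments, since published decision trees differ in detail.

**Hotspots** count breakpoints (both ends of each record) in 100-kb
tiling windows; a window is a hotspot when its count exceeds the
genome-wide mean by more than 2 population standard deviations. A
top-percentile alternative is provided. Uniform counts produce no calls.

**Genotype filtering** masks calls unless DP > 2 and GQ > 10 (strict),
then drops sites with missing fraction > 0.5 or minor-allele frequency
< 0.05 over the remaining alleles.

## Enrichment and selection

**Bootstrap coverage test.** Observed statistic: fraction of the region
set covered by the features. Null: relocate every region to a uniform
length-preserving position (chromosome sampled proportional to length;
relocated regions may overlap each other — the literal reading of a
"random regions" null), N = 1000 draws by default. Empirical p-values use
$(k+1)/(N+1)$ so they are never zero; a z-score against the null mean/sd
is also reported. Under the null generator the test rejects at the 5%
level in 2–10% of replicates, and planted 0.3× depletion with 10,000 SVs
is detected at $p \le 0.01$ — both run as acceptance checks.

**Fst** is the Weir–Cockerham (1984) two-population estimator from
variance components $a$ (among populations), $b$ (among individuals) and
$c$ (within individuals); the multi-site weighted value is
$\sum a / \sum (a+b+c)$. Sites monomorphic across both populations are
undefined and excluded with a count. The tests compare against an
independent, deliberately literal transcription of the 1984 component
formulas at $10^{-12}$.

**π** per site is $2p(1-p)\,n/(n-1)$ over the $n$ non-missing haplotypes
(equal to exhaustive pairwise difference counting, which the tests verify
exactly), summed over 50-kb windows sliding by 25 kb and divided by
window length.

**Candidate screen.** A marker is a candidate when both its Fst and its
Pi-ratio (π₁/π₂; population 1 is the wild/reference population, so high
ratios flag sweeps in population 2) reach the 95th percentile
(linear-interpolation quantiles; ties at the cutoff included). Ranking
uses the Euclidean distance of min–max scaled Fst and $\log_2$ Pi-ratio —
the scaling makes the two axes commensurate; raw-axis ranking is possible
by pre-scaling the table differently.

**Capture Hi-C.** A score ≥ 3 is high confidence (inclusive); an
MT-specific differential interaction additionally needs the WT score
below 3 and a difference strictly above 3, and symmetrically for WT. One
score per condition is expected; replicate pooling happens upstream.

## The synthetic-data generator

Generation is class-first: each cluster draws its category, then a
membership count consistent with it (core $= n$; softcore uniform on
$[\lceil 0.9n \rceil, n-1]$; private 1; dispensable uniform on
$[2, \lceil 0.9n \rceil - 1]$), then per-genome coordinates. Per-genome
liftover maps carry 1–10 indels of 1–50 kb per chromosome (> 95% of the
backbone stays alignable); cluster positions are laid on a spaced grid
avoiding indel footprints, and member coordinates jitter by at most 45%
of the feature kind's merge tolerance — strictly under the half-gap bound
at which recovery is guaranteed. Cluster spacing exceeds the merge
tolerance, so distinct clusters never coalesce. Consequently pan
classification of generated data is *exact*, which the tests assert at
the 1,000-clusters-per-kind scale on a 250-Mb backbone (a chromosome-1-
scale choice that fits 1,000 boundary clusters at 40-kb merge gaps with
room to spare; the generator default stays a 10-Mb toy chromosome).

Contact matrices are block models (expected `within` inside planted TADs,
`between` elsewhere) with Poisson noise by default (counts), truncated
Gaussian optional, and a `"none"` mode that is exact. SV junction
signatures are planted directly in the rule regions of their mechanism
*and* outside the regions of all higher-priority rules, so classifier
recovery is exact by construction; sequence is never simulated.
Genotypes are Hardy–Weinberg draws at planted per-population frequencies
with Poisson DP and truncated-Gaussian GQ. Capture tables plant an exact
number of MT-specific rows satisfying all three rule conditions, with
background rows violating at least one in either direction.

What this does **not** emulate: distance-decay and compartment structure
in contact matrices beyond blocks, mapping noise or reference bias,
linkage between sites, overlapping or nested SVs, multi-allelic sites,
and loop anchors that drift systematically between genomes. Passing tests
therefore demonstrate the correctness of the rules and estimators under
their stated conditions, not robustness to every artefact of real
sequencing data.

Every generator restores the caller's RNG state and is byte-identical
under a fixed seed.

## Problem sizes and determinism

The test-suite and acceptance runs use: 1,000 clusters per feature kind
across 15 genomes for classification exactness; 20 seeds × 20 planted
TADs (Poisson noise, within/between 5/1, 40-kb bins, $w = 2$) for
boundary recall/precision at ±1-bin tolerance; 200 null replicates and
50 depletion seeds at 500 bootstrap draws each; 100 random sites for the
Fst oracle; and 100 random genome orders for accumulation monotonicity.
These sizes give stable statistics while keeping a full run in the
low minutes on one core.

## Known limitations

- Single-linkage loop clustering can chain across genomes when anchor
  drift approaches half the anchor width.
- The insulation caller cannot separate boundaries closer than ~$2w+1$
  bins (see above); very small domains require finer binning.
- The Li threshold assumes candidate strengths are reasonably bimodal;
  on a chromosome with a single true boundary the threshold degenerates
  and all candidates are kept.
- Mechanism thresholds are conventions, not fitted values; on real data
  they should be calibrated against curated junctions.
- The bootstrap null relocates regions independently; if real regions
  have strong spatial structure (clustering, telomere bias) the null is
  permissive.
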