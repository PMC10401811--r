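---
title: "Building a strain-specific reference genome: methods and models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building a strain-specific reference genome: methods and models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strainref)
```

## The problem

Outbred laboratory stocks segregate millions of variants. When such a stock
is used with a reference genome built from a different, inbred strain, two
distinct problems arise:

* **uniform variants** — sites where every member of the stock carries the
  same allele, which differs from the reference. Reads systematically
  mismatch the reference there, costing mappability and accuracy.
* **non-uniform variants** — sites segregating *within* the stock.
  These are worse than a mappability tax: by chance, all treatment animals
  in an experiment can share one allele while all controls share the
  other, so a purely genetic difference masquerades as a treatment effect.

`strainref` rebuilds the reference for the stock: uniform SNPs and indels
are substituted in, germline transposable-element (TE) insertions and
absences are applied as structural edits, and non-uniform SNPs are masked
with `N`, so that aligners neither reward nor penalise either allele.
Exact chain files relate the two coordinate systems, and liftover
utilities move positions, intervals, VCF and GTF annotation between them.

## Variant classification

Sites are first hard-filtered with the classic GATK germline short-variant
thresholds (SNPs: QD < 2, QUAL < 30, SOR > 3, FS > 60, MQ < 40,
MQRankSum < −12.5, ReadPosRankSum < −8; indels: QD < 2, QUAL < 30,
FS > 200, ReadPosRankSum < −20). Every inequality is strict: a value
exactly at a threshold passes. An absent annotation skips its sub-filter
rather than failing it; GATK omits rank-sum annotations at sites with no
heterozygote, and failing such sites would discard precisely the
homozygous sites a fixed-difference screen is after.

For a cohort of five diploid animals (ten alleles), classification is:

* **uniform**: biallelic, AF > 0.8 and AC > 5 — more than half of the
  alleles observed, and (near-)fixed for the alternate.
* **non-uniform**: biallelic with 0.2 < AF ≤ 0.8 and AC > 2, or
  multiallelic with AN > 5 and the most frequent alternate allele
  exceeding 20% of called alleles.

"Allele frequency" of a multiallelic site means the most-frequent-alternate
fraction of called alleles; ties in the top count give the same fraction,
so no tie-break is needed. The two classes are provably disjoint and
depend only on (AF, AC, AN, allele count), never on sample order.

Uniform indels closer than `min_indel_spacing = 1` bp are removed
*pairwise* (both members are dropped), with the gap measured between
half-open reference footprints after stripping the shared VCF anchor base;
at spacing 1 only touching or overlapping pairs go. Uniform SNPs whose
base falls inside a surviving indel's footprint are then excluded (for
pure insertions the single anchor base counts as the footprint).

Down-sampled reclassification (`downsampleClassify()`) recomputes AF/AC/AN
from a subset's genotypes, drops sites that are non-variant in the subset,
removes unused alternate alleles (re-indexing genotypes), re-runs the hard
filters and applies integer thresholds scaled to the subset: uniform
AC > {2, 3, 4}, non-uniform AC > {0, 1, 1} and multiallelic AN > {2, 3, 4}
for 2, 3 and 4 animals. The scaled rules keep the thresholds as close as
possible to the same *proportions* of the subsampled allele total; note
the non-uniform rule at n = 2 (AC > 0) admits any non-reference allele —
we implement the scaling exactly as stated rather than "repairing" it.

## Germline TE filtering

A germline insertion must occupy at least one of a carrier's two alleles,
so a per-sample call qualifies as a *candidate* when its within-sample
allele frequency is at least 0.495 (half, minus a little sequencing-error
slack) with at least 2 supporting reads. Pooled (population) calls are
retained when their population allele frequency is at least 0.0995 — one
germline allele among ten, again minus slack — *and* they match a
candidate within `match_tolerance_bp` (default 50 bp; TE breakpoint
estimates jitter between runs, and exact-coordinate matching would
silently discard true positives). Reference-TE absences need at least 10
supporting reads and an estimated population frequency of exactly 1
(compared with a 1e-9 tolerance, since the frequency arrives through
floating-point text). All filters are monotone: tightening a threshold
never adds a call.

## Genome building and chains

Edits are intervals on the base genome (0-based, half-open; pure
insertions are zero-length intervals that place their sequence *before*
the position) with a replacement string. Overlaps are resolved by kind
priority — TE removals and insertions above indels above SNP
substitutions above N-masks — mirroring the rule that a SNP overlapping a
retained indel is excluded; losers are dropped and logged, and resolution
is deterministic for any input order. Two same-priority edits with the
same interval but different replacements indicate a contradictory callset
and abort.

The build runs in two stages, because that order fixes the coordinate
frame: structural TE edits first (producing a hybrid genome and its
chain), then nucleotide-level edits, lifted through the stage-1 chain;
masks or substitutions falling inside a removed TE are unmappable and are
dropped with a log entry, not an error. The returned chain composes the
two stages, so a single liftover maps base coordinates to the final
genome.

Chains follow the UCSC dialect: ungapped blocks (`size`) separated by
target/query gaps (`dt`/`dq`). Length-preserving edits (substitutions,
N-masks) stay **inside** blocks — chain blocks are alignments, not
identity runs, which is exactly how UCSC chains represent mismatches —
while each length-changing edit breaks a block with `dt` = reference span
and `dq` = replacement length. Adjacent breaks merge their gaps; edits at
a contig's ends shrink the aligned span instead of emitting zero-size
blocks. Block-sum invariants (`Σ(size+dt) = tEnd − tStart`, likewise for
`dq`) are enforced by the class validity method on construction *and* on
file read, so a malformed chain cannot enter the system. The score field
is the sum of block sizes (liftover does not interpret it) and ids are
sequential.

## Liftover

Positions inside blocks map affinely; positions inside `dt` gaps (or
outside the aligned span) report `deleted`; unknown contigs report
`no_chain`. Interval lifting in `strict` mode requires both endpoints
mappable and at least `min_match = 0.95` of bases mappable — the classic
liftOver default, adopted because no other value is stated — while
`partial` mode trims to the mappable core. GTF conversion lifts exons
strictly and keeps a transcript only when *all* its exons convert
(exclude-partial semantics), recomputing transcript and gene spans from
the surviving exons and exporting the failed exon ids. Lifted VCF records
whose REF no longer matches the target genome are *rejected and written
out* rather than silently dropped: on self-built chains the mapping is
exact, so a non-empty rejection file is a diagnostic, not noise. Chains
read from external sources may carry a `-` strand query; lifting through
them returns forward-strand coordinates counted from the opposite end,
per the UCSC convention. Only `+` strand chains are ever produced by the
builder, and chain composition is restricted to them.

`validateExonSequences()` replays the check used to accept the built
genome: for every converted exon, the base and edited sequences must
agree at every mappable base, except where an edit explains the change
(the substituted allele, or `N` at a mask). The report counts explained
mismatches and lists unexplained ones; the expected count of the latter
is zero.

## The bias probability model

At a balanced biallelic site, alleles `a`/`b` at frequency `f` are drawn
independently for every allele of every animal (Hardy–Weinberg, no
relatedness — the same assumption the synthetic cohort generator uses).
The *biased* event is: every treatment animal shares a **homozygous**
genotype that no control animal carries, or vice versa. A uniformly
heterozygous group does not count — this matters, because a naive reading
of "common genotype" would include the het case and change the number.
Inclusion–exclusion over the four one-sided events, minus the two
double-counted cross configurations (treatment all `aa` *and* control all
`bb`, and its mirror), gives

$$P = f^{2n_t}(1-f^2)^{n_c} + (1-f)^{2n_t}\bigl(1-(1-f)^2\bigr)^{n_c}
    + f^{2n_c}(1-f^2)^{n_t} + (1-f)^{2n_c}\bigl(1-(1-f)^2\bigr)^{n_t}
    - f^{2n_t}(1-f)^{2n_c} - (1-f)^{2n_t}f^{2n_c}.$$

For the 5-vs-5 design at `f = 0.5` this collapses to
`970/4^10 = 0.0009250641`:

```{r}
biasedConfigProbability(biasModelParams(5, 5, 0.5))
```

The closed form is verified against `biasedConfigProbBruteforce()`, which
enumerates all `4^(n_t+n_c)` ordered draws; the two agree to 1e-12
everywhere we test. Two properties worth knowing:

* `P` is symmetric under `f ↔ 1−f`, but it is **not** maximised at
  `f = 0.5`: the profile is bimodal, peaking near `f ≈ 0.29` and `0.71`
  for the 5-vs-5 design, because shared homozygosity is easiest to fix at
  moderately skewed frequencies. The balanced value is the relevant one
  for balanced sites, but it is not a worst case.
* Expected biased-region counts use `round()`; the products involved
  (925.06, 231.27) give the same integers under rounding or truncation.
  The near-gene estimate truncates (`floor`), matching the published
  arithmetic (1156 × 0.674 → 779).

The allele-detection power model is the same independence assumption:
the chance of missing an allele of population frequency `q` entirely in
`n` animals is `(1−q)^{2n}`, e.g. `0.9^24 ≈ 0.08` for 12 animals. For 20
animals the formula gives `0.9^40 ≈ 0.015`; a published figure of 0.01
for that case is inconsistent with the formula at two decimals, and we
implement the formula rather than the figure.

## The saturation curve

Variant discovery as a function of cohort size `x` is modelled as
`N(x) = a − (a−c)·exp(−b·(x−x0))`: asymptote `a`, anchor `N(x0) = c`,
rate `b` per added animal. `fitSaturation()` uses `stats::nls()` with the
port algorithm and `maxiter = 5000`, starting from `c0` = the count at
the smallest `x`, `b0 = 1`, and `a0` solved from the model at the largest
`x`. With three distinct `x` values the three-parameter fit interpolates
the data, so noiseless inputs recover parameters to machine precision;
the suite also checks that 1%-noise fits recover the asymptote to a
median relative error under 5%. Note the curve is falling when `a < c`
(uniform variants: pooling more animals *removes* sites fixed only in
small subsets) and rising when `a > c` (non-uniform variants).

## Region QC

RPKM at merged peaks is the plain ratio
`counts / (kb × library/10^6)`. Irreproducible peaks are those with
minimum RPKM across replicates strictly below a low threshold **and**
maximum strictly above a high one (0.5/2 for the ChIP defaults, 1/2 for
ATAC); values exactly at a threshold are not selected. Shuffled controls
preserve interval lengths, place uniformly (contigs weighted by placeable
positions) and reject placements overlapping an exclusion set by more
than half the interval's own length — the `-f 0.5` semantics measured on
the shuffled interval — with a bounded retry count so impossible
constraints fail loudly. Enrichment uses two-sided Fisher's exact tests
(the conservative default; the sidedness used in comparable analyses is
usually unstated, and a flag allows one-sided tests), annotated with the
star ladder `p < .01 / .001 / 1e-5 / 1e-10`.

The SNP hotspot scan is deliberately a simplification: the genome-wide
SNP density supplies a Poisson rate, each pre-merged region gets an
upper-tail Poisson p-value at its observed count, Benjamini–Hochberg runs
across regions, and significant hotspots additionally need at least 50
SNPs. The ≥50-SNP and FDR < 0.05 filters are the reproducible contract;
the exact scan statistic of specialised hotspot callers is out of scope.
Under uniform scatter the BH-controlled false-positive rate stays at or
below 5% (tested over 200 seeded simulations with the count filter
relaxed to 1, since at realistic background densities the 50-SNP filter
alone already vetoes everything).

## What the synthetic generators do and do not emulate

The generators produce i.i.d.-base genomes, cohort genotypes drawn
allele-by-allele at known population frequencies, TE call tables planted
on either side of every filter threshold, and peak count matrices with
planted irreproducible regions (one replicate enriched at RPKM ≈ 6–12,
one near background; reproducible peaks are correlated negative-binomial
draws at RPKM ≈ 4–10, dispersion 50). Everything is a pure function of
(parameters, seed), and truth labels allow exact recall/precision
computation downstream.

They do **not** model linkage, relatedness, mapping artefacts, GATK's
annotation distributions (passing annotations are drawn uniformly inside
passing ranges; filter behaviour is tested by explicit failing
injections) or sequencing error. A green suite therefore demonstrates
that the *rules* are implemented exactly — boundary behaviour included —
not that the thresholds are optimal for any particular real dataset.

Default test problem sizes, chosen to exercise every code path at desk
scale: 100-kb genomes with 50 random edit plans for build/lift
properties; a 5-animal cohort with 1,000 planted fixed and 1,000 planted
balanced sites for classification recovery; 200 uniform-scatter
simulations for hotspot error control.

## Known limitations

* Per-sample (diploid/phased) genome construction is out of scope; the
  product is a single haploid strain reference with N-masked segregating
  sites.
* Chains are generated only on the `+` strand; `-` strand support exists
  for reading and lifting external chains but not for composition.
* The indel normaliser strips the shared leading anchor only; fully
  left-aligning indels against the reference is the caller's job.
* Repeat soft-masking of the product (case-only, coordinate-neutral) is
  intentionally not reproduced.
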