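# strainref

Build a strain-specific reference genome from cohort variant calls, with
exact chain files and liftover between the old and new coordinate
systems.

Outbred laboratory stocks (the motivating case is an outbred mouse stock
sequenced against an inbred-strain reference) carry two kinds of
confounders. *Uniform* variants — every animal in the stock carries the
same allele, different from the reference — cost mappability at millions
of sites. *Non-uniform* variants segregate within the stock; by chance,
all treatment animals in an experiment can share one allele while all
controls share the other, so a genetic difference masquerades as a
treatment effect. `strainref` substitutes the uniform SNPs/indels and
germline transposable-element (TE) insertions/absences into the
reference, masks non-uniform SNPs with `N` (aligners then neither reward
nor penalise either allele), and emits UCSC chain files that make the
edit exactly invertible.

The package is aimed at genomicists running variant-calling, ChIP-seq,
ATAC-seq or WGBS pipelines on outbred cohorts.

## What it implements

* **Classification** — GATK-style hard filters (QD/QUAL/SOR/FS/MQ/rank
  sums, strict inequalities), then uniform (biallelic, AF > 0.8,
  AC > 5) versus non-uniform (biallelic 0.2 < AF ≤ 0.8 with AC > 2, or
  multiallelic with AN > 5 and top alternate fraction > 0.2) for a
  5-animal cohort, with indel-spacing and SNP-over-indel exclusions and
  scaled thresholds for down-sampled cohorts of 2–4.
* **Germline TE filtering** — per-sample candidates (AF ≥ 0.495,
  ≥ 2 reads), pooled confirmation (population AF ≥ 0.0995 plus a
  candidate witness), and reference-TE absences (≥ 10 reads, population
  frequency 1).
* **Genome building** — a priority-resolved edit plan applied in two
  stages (TEs first, then substitutions and N-masks lifted through the
  stage-1 chain), with per-contig chains whose blocks keep
  length-preserving edits inside ungapped alignments.
* **Liftover** — positions, intervals (strict/partial with the classic
  0.95 min-match), VCF (REF re-validated against the target) and GTF
  (transcripts kept only when every exon converts), plus chain
  composition/inversion and an exon-sequence validation report.
* **Statistics** — the genotype-configuration bias probability

  P = f^(2nt)(1−f²)^(nc) + (1−f)^(2nt)(1−(1−f)²)^(nc)
    + f^(2nc)(1−f²)^(nt) + (1−f)^(2nc)(1−(1−f)²)^(nt)
    − f^(2nt)(1−f)^(2nc) − (1−f)^(2nt)f^(2nc)

  (= 970/4^10 ≈ 0.0009250641 for a balanced site and five animals per
  group), verified in-package against a 4^n enumeration oracle; expected
  biased-region counts; allele-detection power (1−q)^(2n); and the
  asymptotic discovery curve N(x) = a − (a−c)e^(−b(x−x0)) with its
  `nls(port)` fit.
* **Region QC** — RPKM at merged peaks, irreproducible-peak selection
  (min < low AND max > high, strict), seeded shuffled controls with a
  50%-overlap exclusion cap, two-sided Fisher enrichment with the
  `*`/`**`/`***`/`****` ladder, and a Poisson-scan SNP hotspot test with
  Benjamini–Hochberg correction and a ≥ 50-SNP filter.
* **Synthetic fixtures** — seeded generators for genomes, cohort VCFs
  with known population frequencies, TE call tables and peak count
  matrices, all carrying truth labels.

## Worked example

```r
library(strainref)

# a 50-kb synthetic genome and a 5-animal cohort with planted site classes
g      <- simulateGenome(c(chr1 = 50000L), gc = 0.42, seed = 7L)
specs  <- data.frame(kind = "snp", popFreq = c(1.0, 0.5, 0.1),
                     length = 0L, n = c(40L, 40L, 20L))
cohort <- simulateCohortVariants(g, nMice = 5L, specs, seed = 8L)

filt       <- hardFilter(cohort, variantClass = "snp")$pass
uniform    <- classifyUniform(filt)
nonuniform <- classifyNonuniform(filt)
c(nrow(uniform), nrow(nonuniform))
#> [1] 41 37

built <- buildReference(g, uniformVariants = uniform,
                        nonuniformSnps = nonuniform)
built$report$n_masked
#> [1] 37
built$report$applied_by_kind
#> te_remove te_insert     indel   snp_sub    n_mask
#>         0         0         0        41        37

liftPosition(built$chains, "chr1", 12345L)
#> $pos
#> [1] 12345
#> $reason
#> [1] NA

biasedConfigProbability(biasModelParams(5, 5, 0.5))
#> [1] 0.0009250641
```

The 40 planted fixed differences all classify uniform (one balanced site
drew nine alternate alleles and joins them, exactly as the AC rule says);
the 37 non-uniform sites become `N` in the built genome, and with only
length-preserving edits the chain is a single 50-kb block, so position
12345 maps to itself. The bias probability is the chance that a balanced
segregating site splits perfectly between 5 treatment and 5 control
animals — about 1 in 1,080, which is why such sites matter at
genome scale.

## Layout

```
R/                    implementation (S4 classes: Genome, ChainAlignment,
                      EditPlan, SaturationModel)
tests/testthat/       unit, property and acceptance tests
scripts/acceptance.R  headline-quantity reproduction
vignettes/            methods vignette (models, assumptions, design choices)
inst/scripts/         command-line launcher
```
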