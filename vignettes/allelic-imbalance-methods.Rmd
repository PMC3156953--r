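---
title: "Methods: binomial detection of LOH and allele-specific expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: binomial detection of LOH and allele-specific expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alleledrift)
```

## The problem

A tumor genome loses alleles (loss of heterozygosity, LOH) and a tumor
transcriptome can silence alleles (allele-specific expression, ASE);
both mechanisms converge on the same functional outcome — one allele's
product missing — which is the classic signature of tumor-suppressor
inactivation.  Given DNA allele counts for a tumor/normal pair and RNA
allele counts for the same sample, `alleledrift` calls both event types
with one shared statistic and aggregates them to genes.

The package starts from *allele counts*, not reads: mapping,
deduplication and base-calling are upstream concerns, and the TSV/VCF
input contract (`read_allele_counts()`) makes the counts the caller's
responsibility.  Internally every position is 1-based (the
R/Bioconductor convention); BED, the only 0-based format touched, is
converted at the read/write boundary so no other code ever adjusts an
offset.

## The shared statistic

Both tests use the one-sided lower-tail cumulative binomial
\(B(x;n,p_s)=\sum_{y\le x} b(y;n,p_s)\), evaluated via the regularized
incomplete beta (`stats::pbinom`), which is exact to floating point and
stable far beyond \(n = 10^5\).  The test suite cross-checks it against
an independent term-by-term enumeration for every \(x \le n \le 12\).

**Homozygosity (LOH side).**  Under the heterozygous null, reads fall on
the two alleles like fair coin flips, so the minor count \(x\) out of
\(n\) tumor reads has tail probability \(B(x;n,0.5)\).  A locus is
called homozygous when \(n \ge 10\) and \(P < 0.001\).  Ten concordant
reads are the minimal passing configuration (\(0.5^{10}=9.8\times
10^{-4}\)); nine are not callable.  The generalized form tolerates minor
reads while the tail stays under \(\alpha\) (e.g. 20/1 passes at
\(2.1\times10^{-5}\)); a `strict` flag restores the zero-minor-read
rule.  Ties (`ref == alt`) take `minor = alt` by convention and can
never pass for \(n \ge 2\).

**Allelic imbalance (ASE side).**  At an expressed heterozygote,
\(x\) is the rare-allele RNA count and \(n\) the RNA depth.  In a
diploid genome \(p_s = 0.5\); in a copy-number-altered genome the DNA
itself is imbalanced, so \(p_s\) is taken from the exome VAF of the
tested (rare RNA) allele (`adjust_ps(mode = "vaf")`).  This is the
package's central modelling choice: the DNA reads sample the same
allelic copy numbers the RNA null should reflect, so a locus sitting at
3+1 copies is only called ASE if its RNA skew exceeds what the 0.25 DNA
allele fraction already predicts.  Which exome VAF to pair with the rare
RNA allele is not dictated by the arithmetic alone; we use the rare RNA
allele's own exome VAF (the natural completion of the "rare allele"
formulation) and expose `ps_mode = "diploid"` for balanced genomes.
The test is one-sided with no doubling, exactly as the cumulative
formulation states.

Three gates surround the binomial:

* **Coverage**: at least 20 RNA reads (below that the test has no power
  at \(\alpha = 0.05\) after correction); the count of loci passing this
  gate in the current run, \(m\), is also the correction family.
* **Correction**: Bonferroni, \(\min(1, m \cdot P)\).  The procedure
  behind the original analysis is not named in print; Bonferroni is the
  only standard choice that reproduces the published worked value
  (\(0.5^{21} \times 2534 = 0.00121 \rightarrow 0.001\)), so it is the
  default, with Benjamini–Hochberg as an option.  \(m\) is always
  recomputed from the run, never a constant.
* **Drift band**: the allele drift ratio (alt RNA fraction) must fall
  strictly outside (0.2, 0.8).  Strict boundaries follow the "< 0.2 or
  > 0.8" formulation; a locus at exactly 0.8 is not biased.

Reported P-values are rounded to three decimals only at the report
layer; all internal comparisons use full precision.

## Genotype bands and callset comparison

DNA genotyping retains a variant locus when it has at least 3 variant
reads *and* at least 10% VAF (both boundaries inclusive — the source
phrasing says "at least", and the choice is exposed as configuration).
Heterozygotes come in two nested bands: preliminary (10–90%) and
high-confidence (20–80%); only high-confidence heterozygotes seed the
LOH and ASE tests.  Homozygotes are labelled through the same
homozygosity test, so reference-only loci are representable and a
tumor/normal comparison can see both directions.  Whether the 3-read
rule also bounds the preliminary band at low depth was left open
upstream; here the read filter is applied first, then the bands.
`compare_callsets()` cross-tabulates two callsets over shared loci
(het/hom classes, row and overall percentages to the nearest integer),
which is how a sequencing callset is reconciled against array genotypes.

## Gene aggregation and the isolated-LOH filters

LOH events map to genes by CDS containment (exon models via BED12/GFF3;
when a gene has several transcripts the longest exon form is kept, ties
broken lexicographically).  A locus inside two overlapping genes
supports both.  Real LOH concentrates in multi-megabase blocks, so a
lone LOH gene is suspicious: genes with no other LOH gene within 1 Mb
(the clustering distance is not fixed by the source analysis; 1 Mb is
our configurable default) must pass three plausibility criteria —
supporting SNVs known in the variant catalog, no high-confidence tumor
heterozygote within 25 kb in either direction (distance \(\le\) 25,000
bp, not a centered-window assumption), and RNA corroboration
(\(\ge\) 10 RNA reads, zero minor; the RNA threshold is ours, the source
says only that transcriptome support is required).

For ASE genes, a gene is `ase` only when *every* well-covered locus is
biased; a biased/balanced mixture is `ambiguous` (the signature of local
rearrangement or isoform-restricted skew).  We deliberately do **not**
require different loci of one gene to prefer the same ref/alt allele:
without phasing, the orientation of distinct SNVs is arbitrary, and
demanding agreement demotes genuine monoallelic genes whose loci happen
to sit on opposite haplotype assignments.  Allele agreement is instead
evaluated per shared locus in `compare_ase_across_samples()`, where it
is well defined.  Multi-locus genes report their most significant
corrected P.

## The simulator: what it emulates, what it does not

`sim_config()` describes a desk-scale caricature of a paired
exome/transcriptome experiment on a pseudo-tetraploid tumor:

| parameter | default | rationale |
|---|---|---|
| genome | 2 × 10 Mb, 200 genes, ~3,000 het loci | seconds-scale, every filter exercised |
| tumor baseline copies | (2, 2) | pseudo-tetraploid balance |
| LOH | one (2, 0) block over 15% of chr1 | a "large block" plus isolated-call pressure |
| exome depth | Poisson, mean 19.4× | typical captured-exome mean coverage |
| RNA coverage | log-normal across genes, mean 120×, 85% of genes expressed | transcriptome-wide coverage regime |
| ASE | 5% of expressed non-LOH genes, drift ~ U(0.85, 1) | strong, X-inactivation-like skew |
| error | 0.005 symmetric allele flips | post-filter base error |

DNA counts are Binomial(depth, 0.5) in the normal and Binomial(depth,
allelic copy fraction) in the tumor; RNA counts are Binomial(depth,
drift) with drift 0.5 / gene drift / copy fraction for balanced / ASE /
LOH genes.  Phase (which haplotype carries the alt allele) is drawn per
locus, which is exactly why the aggregation rule above must be
phase-blind.  Quality fields are synthesized above the RNA SNV filter
thresholds unless `dirty_quality` injects sub-threshold loci.

The simulator does *not* model mapping bias, reference bias, GC effects,
overdispersion beyond binomial sampling, subclonality, or positional
correlation of errors.  Passing tests therefore demonstrate the
*statistical machinery* — calibration of the binomial tests, the gates,
the aggregation and the filters — not robustness to alignment artifacts
in real data.

## Validation at the default operating point

The acceptance tests run the full pipeline on the default scenario
(seeds 1–3 pooled, a few thousand loci per run — sizes chosen so the
whole suite stays under a minute):

* true LOH genes with \(\ge\) 10 tumor reads at a locus are recovered at
  \(\ge\) 95% (observed: 42/43 pooled; the single miss had one error
  read at depth 12, exactly the failure mode the test tolerance
  anticipates);
* true ASE genes with drift \(\ge 0.95\), all loci at \(\ge\) 30 RNA
  reads, and at least one testable heterozygous genotype are recovered
  at \(\ge\) 99% (observed: 6/6 pooled) — the genotype condition
  restates the caller's input contract, since a gene whose exome
  genotyping misses the heterozygote band never reaches the RNA test;
* on a null genome (no LOH segments, no ASE genes) the number of genes
  falsely called ASE stays within binomial tolerance of the
  \(\alpha = 0.05\) family-wise budget, and on a somatically null tumor
  the per-locus LOH false-call rate stays at or below \(\alpha = 0.001\).

Degenerate inputs are resolved by convention, documented at the function
level: zero-depth loci are uncallable (homozygosity P reported as 1, no
call), empty callsets report a 0 novel fraction, an empty call list
scores precision 1 with a `no_calls` flag, and `p_s` is clamped to
[0.05, 0.95] (unreachable for high-confidence heterozygotes, a guard for
hand-built inputs).

## Known limitations

* The binomial null ignores RNA overdispersion; a beta-binomial would be
  more conservative at very high depth (out of scope by design).
* Copy-number adjustment uses the per-locus exome VAF, which at 19×
  depth is itself noisy; very low-depth exome loci therefore carry
  noisy nulls into the RNA test.  Segment-level smoothing of `p_s` is a
  natural extension.
* LOH block boundaries are not segmented; gene calls are locus-driven.
* Cross-sample ASE comparison assumes comparable gene models and shared
  locus coordinates between the two samples.
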