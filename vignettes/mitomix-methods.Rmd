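---
title: "Methods: simulating and deconvolving mitochondrial sequencing mixtures"
author: "mitomix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and deconvolving mitochondrial sequencing mixtures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Forensic mitochondrial analysis often faces a mixture of two contributors
who share a haplogroup and differ only by a handful of private variants.
Two sequencing chemistries see such a mixture very differently: a deep,
low-error paired short-read platform resolves allele fractions precisely
but cannot link alleles across sites, while a high-error single-molecule
long-read platform spans a whole ~8 kb long-PCR amplicon per molecule and
therefore carries phase information despite per-base error rates an order
of magnitude worse. `mitomix` implements the complete analysis chain for
this setting — variant-allele-frequency (VAF) thresholded SNP calling,
cross-platform concordance grids, long-read phasing, short-read pair
deconvolution by private variants, and reference-guided per-contributor
consensus reconstruction — driven by a synthetic dual-platform read
simulator, so every stage can be validated against a known ground truth
without any sequencing download.

## Simulation model

**Genome and amplicons.** The reference is a random A/C/G/T circle of
16,569 bp by default. Enrichment follows the two-overlapping-amplicon
long-PCR design: amplicon 2 (~8.6 kb) spans the replication origin in
biological coordinates, so the simulator reports everything in rotated
coordinates with the cut placed inside that origin-spanning overlap:
amplicon 2 occupies `[0, 8600)` and amplicon 1 `[8269, 16569)`, leaving a
331 bp interior overlap. On a circle two covering arcs necessarily overlap
twice, and any linear cut falls inside one of them; placing the cut at the
second overlap is the unique choice that keeps both amplicons contiguous so
that no simulated alignment wraps the origin (the package never emits split
alignments). The rotation amount is recorded in the run manifest. For test
genomes smaller than full size the amplicon lengths scale proportionally.

**Homopolymer runs.** `generate_reference()` plants a configurable number
of runs of at least `min_run` (default 6) identical bases at recorded
positions. Only these *annotated* runs drive the homopolymer error mode;
incidental runs in the random background are deliberately not annotated, so
the error mode is a controlled experimental factor rather than a property
scattered over the genome.

**Haplotypes.** Both contributors carry an identical backbone of 31 shared
SNPs (same haplogroup); each adds 6 private SNPs and 1 private insertion,
giving the union 31 shared + 12 private SNPs and 2 private insertions. One
private SNP of contributor A is forced into an annotated homopolymer run so
that the long-read error mode acts on a truth site. Variants avoid primer
intervals, keep a minimum spacing of 15 bp, and avoid a 300 bp margin at
the two linear genome ends: uniform fragment placement within amplicons
tapers coverage to zero at the linear ends — an artefact of linearising
the circle that the real (circular) molecule does not have — and placing
truth variants there would confound the round-trip analyses with a
coverage artefact. Insertions are generated already left-aligned.

**Reads and errors.** Reads are emitted pre-aligned at their true
positions: the haplotype's base-level alignment to the reference (M for
backbone bases, I for haplotype insertions) is composed with injected
per-base errors — substitutions leave the CIGAR untouched, error
insertions add I ops, deletions add D ops, and run-internal deletions are
boosted by `homopolymer_extra_deletion` inside annotated runs of at least
5 bases. No aligner runs anywhere, which removes aligner-specific artefacts
(alternate alignments in repetitive regions, clipping heuristics) from the
study by construction and keeps a contributor-of-origin truth label on
every read. Default profiles, chosen once as order-of-magnitude realistic
for the two chemistries (neither platform's true per-run rates are known
here, so these are free parameters of the study): short reads substitution
2e-3, insertion 1e-4, deletion 1e-4; long reads substitution 0.05,
insertion 0.04, deletion 0.05, homopolymer extra deletion 0.15. Base
qualities are constants (35 short, 10 long): the long-read chemistry's
scores are not phred-scaled, so pretending otherwise would only hide the
caller's behaviour.

The short-read library is 2 x 250 bp with normal fragment lengths
(mean 450 bp, sd 50) drawn uniformly *within* an amplicon — fragments
never span an amplicon end, mirroring tagmentation's requirement of two
integration sites. Long-read molecules are either full-length amplicons
(70% by default) or forward-strand truncated products starting at the
amplicon's forward primer with lengths uniform in 500–4000 bp (failed
extensions / early terminations), which reproduces the multi-modal
long-read coverage profile near primers while short-read coverage stays
unimodal. Depths default to 1000x (short) and 300x (long), an order of
magnitude apart.

## VAF calling

The VAF of an allele at a site is its read count divided by the count of
*all* reads covering the site — including reads carrying other bases or a
deletion there. This denominator convention is what makes printed
count/percentage tables (e.g. `A: 146 (43%)` of A 146 / G 180 / other 14)
reproduce exactly. `call_snps()` emits, per position with at least
`min_depth` covering reads (default 20), every non-reference base at or
above the threshold; insertion and deletion signals are never emitted by
the SNP caller (SNP-only filter). The depth floor replaces an external
caller's `QUAL > 20` filter: with non-phred long-read scores, a
covering-read floor is the transparent analogue. Haploid versus diploid
calling is mapped to alternate retention: single-source mode keeps only the
top alternate per site, mixture mode keeps up to two — the observable
effect of ploidy in a caller without genotype likelihoods.

`left_align_and_decompose()` normalises variant records the standard way:
multi-allelic records split into biallelic ones, same-length block
substitutions decompose into per-position SNPs, and indels shift left while
flanked by repeated sequence; the operation is idempotent and is applied to
both call sets and truth tables before any set comparison.

## Concordance

Sites are matched by (position, alternate allele); a right-position
wrong-allele call counts as one false positive plus one false negative (the
stricter reading of per-site assessment, stated explicitly). Recall is
TP/(TP+FN), precision TP/(TP+FP), F1 their harmonic mean. Metrics with a
zero denominator are reported as `NA` — never silently 0 — while F1 is 0
when TP = 0 with errors present. Reported metrics round to 3 decimals,
half-even. Grids evaluate every (truth VAF, test VAF) threshold pair —
19 x 19 over 0.05..0.95 step 0.05 for single sources; the mixture designs
compare a *single* truth member (the combined 0.90-VAF single-source call
sets, then the 0.25 mixture set) against 19 thresholds over 0.17..0.53
step 0.02. All cells tying for maximal F1 are reported in row-major order,
since optima are typically plateaus, not points. (A printed subset list
elsewhere mentions an `m_0.15` member alongside the stated 0.17–0.53
range; the stated range is used, and yields the 19 members.)

## Phasing

Long reads qualify for phasing when they intersect an interval —
`(1000, 8000)` and `(10000, 15000)` by default, one inside each amplicon —
and their *query length* exceeds 8000 bases, which keeps only fully
extended amplicon molecules. Query length (not aligned span) is used
because a high-deletion-rate molecule can align over more reference than
it has bases; for these contiguous alignments the two differ by at most the
net indel balance. Each read's observed base at every covered het site
(found by a CIGAR walk; sites under a deletion or clip are missing values
excluded from the vote, not mismatches) is compared with the two candidate
allele vectors — the private alleles of each contributor, taken from the
combined truth set rather than re-estimated, matching the study flow where
private variants are known before phasing. A read joins the pool it
matches at strictly more covered sites; ties and zero-coverage reads stay
unassigned. Refinement passes recompute each pool's per-site majority
consensus and re-assign until convergence (default at most 5 passes); the
consensus tie-break keeps the pool's own candidate allele, which makes the
procedure exactly symmetric under swapping the candidate labels. The
algorithm is deterministic given input order.

## Deconvolution

Short read pairs are routed by the private-variant panel. At a private
SNP, a mate is evidence only if the covering CIGAR op is a match (M) and
the base equals one contributor's allele; other bases, deletions and clips
give no evidence. At a private insertion, a *mate* is eligible only when
its span covers both `pos - 10` and `pos + 10`; an eligible mate with an I
op anchored at the site attributes the pair to the carrier, an eligible
mate without one to the other contributor. Eligibility is evaluated per
mate rather than on the union of the two mates' spans: a long fragment can
cover both flanks while the insertion falls in the unsequenced gap between
mates, and such a pair carries no evidence at all — routing it to the
non-carrier would poison the pool even with error-free reads. The
insertion anchor convention is VCF-style everywhere (the reference base
immediately preceding the inserted sequence), for truth tables, pileup
events and the window rule alike. Verdicts from all panel sites a pair
touches are pooled by majority; ties and no-evidence pairs go to the
shared pool — conservative, since the shared pool is added back to both
deconvolved sets. Both mates always travel together.

## Reconstruction and assembly statistics

Each contributor's phased long pool and deconvolved short set merge into
one pileup; every alternate signal — SNP, normalised insertion, or
deletion — reaching VAF 0.75 is applied to the reference. The 0.75
threshold sits far above any residual error signal and far below the
near-1.0 VAF of genuine variants in a correctly separated pool, so the
supporting call set equals the contributor's truth set when phasing and
deconvolution have done their job; this end-to-end identity is the
pipeline's principal acceptance property. Reference positions with zero
coverage are N-filled and reported as gaps. Nx is the length of the
smallest contig in the minimal descending-order prefix whose sum reaches
x% of the total contig length (N50 at x = 50); NGAx thresholds against the
*genome* size and operates on alignment-broken block lengths, undefined
(NA) where the cumulative blocks fall short. Reconstruction here is
reference-guided consensus rather than de-novo assembly: the quantity under
test is a variant-set property, and Nx/NGAx accept any contig list,
including externally assembled ones.

## Numerical and engineering choices

- Threshold grids are enumerated as `lo + k * step` with a rounding guard,
  so 0.17..0.53 step 0.02 gives exactly 19 members despite floating-point
  drift.
- Every stochastic function takes a seed; pipeline stages derive their
  seeds deterministically from one global seed, and re-running a config
  reproduces byte-identical SAM output (digests recorded in the manifest).
- Pileup base counting is delegated to `Biostrings::consensusMatrix` over
  CIGAR-M segments; deletion and coverage accumulation use
  `IRanges::coverage`. The CIGAR walk itself is implemented in the package
  because the base-at-offset rule is part of the method under study.
- Degenerate inputs are contracts, not crashes: VAF at depth 0 is an
  error, an empty pileup yields an empty call set, an empty panel routes
  everything to shared (with a warning), phasing without het sites in the
  interval is a hard error.
- Problem sizes: the bundled analyses and the acceptance script run the
  full study design (16,569 bp, 1000x/300x, 1:1 mixture) — about 200,000
  short reads and 2,300 long reads per run, a few minutes on one CPU.
  Unit tests exercise the same code on 4 kb genomes at 25–80x, plus
  full-size genomes wherever the 8000-base spanning rule matters.

## What the synthetic data does and does not show

The simulator reproduces the *structure* of the real experiment — depth
asymmetry, amplicon geometry, truncated-molecule coverage modes,
homopolymer-concentrated deletions, private/shared variant architecture —
but not every property of real data: errors are context-independent apart
from the annotated-run deletion boost (no k-mer-dependent miscalls, no
strand bias), base qualities are constants, alignment artefacts are absent
by design (reads are emitted at their true positions), and there is no
length-heteroplasmy model for homopolymer stretches (the SNP-only filter is
the only guard, so the real-data behaviour of C-stretch loci is outside
what passing tests demonstrate). Deletion-based *private* variants are not
modelled (the panel supports SNPs and insertions), more than two
contributors are out of scope, and mixture proportions are inputs, not
estimates. Consequently, green tests here certify the analysis logic and
its contracts — not platform-specific error behaviour on real chemistry.
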