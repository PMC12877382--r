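---
title: "Typing MHC genes from mapped reads: models, parameters and design choices"
author: "mhctyper"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Typing MHC genes from mapped reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mhctyper)
```

## The problem

Classical MHC class I loci occur as families of recently duplicated genes
whose typed exons (exons 2 and 3 in class I, exon 2 in class II) differ by
only a few percent — around 8% for the swine class I paralogs. Two
consequences follow for genotyping from whole-genome sequencing:

1. short reads from one paralog routinely map to another, so the pileup over
   a target gene mixes reads from several genes;
2. the alleles of a locus differ at a modest number of exon-concentrated
   SNVs, so distinguishing the two alleles of a diploid requires *phase* —
   which variants co-occur on the same chromosome.

This package types a chosen gene from an already-mapped BAM/SAM by
(i) removing cross-mapped paralog reads, (ii) calling diploid variants,
(iii) phasing the heterozygous calls into haplotype blocks, (iv) building a
consensus sequence per block and haplotype (a *haplotype contig*), and
(v) choosing the allele pair whose reference sequences best explain those
contigs under a total bit-score criterion.

## Local alignment and bit scores

All sequence comparison runs through an affine-gap Smith–Waterman engine
(`alignLocal()`; a gap of length $L$ costs `gap_open` $+ L\,\cdot$
`gap_extend`). Raw scores $S$ are converted to bit scores

$$B = \frac{\lambda S - \ln K}{\ln 2}$$

with Karlin–Altschul constants matching a stock nucleotide BLAST
configuration (match $+2$, mismatch $-3$, gap open 5, gap extend 2,
$\lambda = 0.625$, $K = 0.41$); hits below 50 bits are not reported. All of
these are tunable through `scoringParams()`. N is scored as a mismatch
against everything, including N, and never counts toward identity —
a deliberately conservative treatment of ambiguous reference bases.

Allele references are exon-only sequences, while contigs carry introns, so a
contig is compared to an allele with a chained-HSP score (`hspChain()`): the
best local alignment is extracted, its query and subject spans are masked,
and the process repeats; co-linear non-overlapping hits are kept and their
bit scores summed, identity is alignment-length weighted. A contig spanning
exon 2, an intron and exon 3 therefore scores as two HSPs against an
exon-concatenated allele. A `score_mode = "best_hsp"` switch restricts
scoring to the single best HSP; the chained sum is the default because both
typed exons should inform the call.

Determinism is pinned down everywhere ties can arise: traceback prefers
diagonal over up over left, the best cell is the lowest `(q_end, s_end)`
among equal maxima, and both strands are always tried with the plus strand
preferred on ties.

## Paralog read filtering

For every primary, non-duplicate record overlapping the target's exon
intervals the full read sequence (soft clips included — mapper clipping is
part of the artifact being corrected) is aligned against the target gene's
alleles and the paralog group's alleles. A read is removed when its best
off-target bit score strictly exceeds its best target score, or when it has
an off-target hit but no target hit at or above the reporting floor. Ties
are kept: equal evidence is not evidence of mis-mapping. Reads with no hit
on either side are kept and flagged, and mates are judged independently
(a `drop_pairs` option removes the partner of a removed read).

Reads that do not overlap any target exon interval (±30 bp) are not aligned
at all. The allele references contain only exon sequence, so a pure
intron/flank read cannot reach the 50-bit floor; skipping the alignment is a
screening shortcut with the same outcome, and such reads are kept and
flagged as unscored.

Filtering raises the *precision* of what remains; it does not attempt
recall of every cross-mapped read (intronic paralog reads have no exon
signal and pass through). On simulated families at 8% divergence the removal
precision exceeds 0.9 by a wide margin, which is what protects the
downstream pileup.

## Variant calling

`callVariants()` is a pileup caller over the target region. Bases require
quality ≥ 13 (short mode) and reads MAPQ ≥ 20; candidate alternate alleles
require depth ≥ 2 and allele fraction ≥ 0.2 (0.25 in long mode). The
genotype at a site takes the two highest-count qualifying alleles and calls
heterozygous when the minor fraction is ≥ 0.2, else homozygous for the top
allele; positions whose top allele is the reference with no qualifying
alternate produce no record. Long mode calls SNVs only and applies no
base-quality floor, reflecting the unreliable per-base qualities of noisy
long reads. QUAL is $-10\log_{10}$ of a binomial tail probability of the
minor count under a 1% error rate and is purely informational — nothing
downstream consumes it.

This caller intentionally implements a contract (diploid, variant-only
records with GT:AD:DP) rather than any particular external tool's
likelihood model; an externally produced phased VCF can be supplied to
`runPipeline(external_vcf = ...)` and replaces calling and phasing entirely.

## Phasing by minimum error correction

Fragments (read pairs merged by name) observe an allele at every
heterozygous site they cover; observations matching neither REF nor an ALT,
failing the quality floor, or contradicted by the mate are dropped. Blocks
are connected components of the "some fragment covers both sites" graph.
Within a block the two-haplotype assignment minimizes MEC — the number of
observation flips needed to make every fragment consistent with one of the
two haplotypes. Blocks of up to 15 sites are solved exactly by enumerating
all $2^{k-1}$ orientations (vectorized as a single matrix product); larger
blocks use a greedy linkage sweep refined by single-site and suffix-flip
hill climbing, which matches the exact optimum on all randomized instances
we generate in the test suite. Each block is tagged PS = position of its
leftmost variant. Singleton het sites are kept as their own blocks rather
than dropped — their two alleles still generate two contigs and thus still
carry typing signal.

## Haplotype contigs

For each block the two haplotype sequences are materialized by substituting
the block's phased alleles and all homozygous-alt calls into the reference
over the span `[block_start − flank, block_end + flank]` (flank 200 bp by
default), clipped to the exon envelope ± flank. Substitution proceeds left
to right with coordinates shifted by earlier indels; a REF field that does
not match the genome is a hard error, as are overlapping variants within one
haplotype. One additional consensus contig (block 0) spans the whole
envelope ± flank and carries only the homozygous-alt calls.

The consensus contig is what makes fully homozygous samples typable: with no
heterozygous site there are no blocks, and the genotype must be read off the
homozygous consensus alone. During scoring the consensus is restricted to
the exon intervals that no het block reaches (the "homozygous remainder"),
so an exon is never counted twice when a het block already covers it.

## Two-round allele determination

For each reference allele of the target gene and each block, the Contig List
records the contig (haplotype 1 or 2) scoring higher against that allele,
with its bit score and percent identity; ties go to haplotype 1 and are
flagged. Round 1 sums each allele's recorded bit scores across blocks;
the maximum total (after rounding to 2 decimals, to absorb floating-point
noise) defines Allele 1. Round 2 removes the contigs consumed by Allele 1's
representative and repeats the sum over the remaining contigs —
single-contig blocks and the block-0 consensus stay available to both
rounds, which is exactly why a homozygote calls the same allele twice.

Two kinds of exact ties deserve care. Alleles whose exon sequences are
identical can never be separated by any contig; they tie and are reported
as an ambiguity group joined by `" or "`, exactly as typing tables print
them. But with clean data the two *planted* alleles of a heterozygote also
tie in round 1 — each explains its own haplotype contig perfectly, for equal
totals. These are alternative genotype components, not ambiguous
identities, and the implementation distinguishes the cases by contig
choice: the round-1 group is restricted to the representative's
contig-choice cohort (exon-identical alleles always choose the same
contigs; the complementary allele chooses the other haplotype and is left
for round 2). The lexicographically smallest group member acts as
representative wherever one allele must be singled out, making the
procedure fully deterministic.

Average percent identity is weighted by alignment length across the
winning allele's entries; per-block identities of very different alignment
lengths would otherwise be averaged as if equally informative.

## The simulator

`simulateFamily()` generates the regime described above rather than any
particular genome: an ancestral locus (flank 1000 — exon 270 — intron 800 —
exon 276 — flank 1000) drawn uniformly at random; 3 paralogs derived by
independent per-base substitution at *half* the 8% target divergence each,
so the pairwise divergence between paralogs lands on the target (the
realized exon divergence is recorded and required to be within 25% of the
target); 10 alleles per gene, each placing Poisson(6) SNVs per exon; and a
planted diploid drawn with replacement from the pool (so ~10% of gene
instances are homozygous, exercising the consensus path). Defaults: mean
diploid depth 20 (typical of the short-read WGS this workflow targets), 150
bp proper pairs with 450 ± 50 bp inserts, or 3 kb long reads; per-base
substitution errors at 1%.

Reads are emitted *pre-aligned* at their true coordinates — read mapping is
out of scope — and a `cross_mapped` mode instead places every read from
every paralog onto the target gene's locus, injecting exactly the
paralog-confusion artifact the read filter exists to remove. Every read
carries its origin gene and haplotype, so filter precision and genotype
recovery are measurable without any external truth.

What the simulator does *not* model: realistic error profiles
(quality-by-cycle, homopolymer errors of long-read chemistries), indel
polymorphism in exons (off by default; MHC exon polymorphism is
overwhelmingly SNV), copy-number variation of loci, and recombination.
Passing tests on this generator therefore demonstrate the pipeline's logic
under the stated similarity regime, not performance on any particular real
dataset or platform.

## Problem sizes and numerical choices

The test suite and the acceptance script run the full pipeline on 20 seeded
long-read replicates (depth 15, 1% error) and 5 short-read cross-mapped
replicates per gene (depth 20, error-free) — sizes chosen so a complete
validation run finishes in minutes on one core while leaving the binomial
margins of the asserted properties comfortable. Alignment scores are exact
integers; only bit-score totals are rounded (2 decimals) before comparison.
Seeds fix every random draw, and all outputs are bit-reproducible from
(spec, seed).

## Known limitations

- Exactly two allele calls per gene: duplicated loci (copy-number variation
  within a gene) are out of scope.
- Novel alleles are reported as their best-matching reference with
  identity < 100%, not named.
- Blocks are phased relative to each other only through the genotype logic,
  never sequence-assembled across gaps.
- The internal caller is a contract-level stand-in for production callers;
  for real data an external phased VCF may be preferable and is accepted
  directly.
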