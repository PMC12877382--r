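# mhctyper

Genotyping MHC genes from mapped NGS reads, for species where the
human-specific HLA callers do not apply.

Classical MHC loci come in families of near-identical paralogs — the swine
class I genes SLA-1/-2/-3 differ by only ~8% across the typed exons — so
whole-genome reads cross-map between genes and naive variant calling over a
target locus sees a mixture of paralogs. `mhctyper` types one gene at a time
from a coordinate-sorted BAM/SAM plus a user-supplied allele reference
(IPD-style exon FASTAs), in five stages:

1. **Paralog read filter** — each read over the target region is
   Smith–Waterman-aligned against the target gene's alleles and its paralog
   group's alleles; reads with a strictly higher off-target bit score are
   removed.
2. **Diploid variant calling** over the target region (short- and long-read
   modes).
3. **Read-backed phasing** of heterozygous calls into haplotype blocks by
   minimum error correction (MEC), PS-tagged per block.
4. **Haplotype contig construction**: per block, the two phased consensus
   sequences C\_n^1 / C\_n^2 over the reference span (plus a block-0
   homozygous consensus that keeps fully homozygous samples typable).
5. **Two-round allele determination**: every contig is scored against every
   reference allele of the gene as summed co-linear HSP bit scores,
   B = (λS − ln K)/ln 2; the allele with the highest total across blocks is
   Allele 1, its contigs are removed, and the procedure repeats for
   Allele 2. Alleles identical over the typed exons tie and are reported as
   an ambiguity group joined by `" or "`.

A seeded simulator (`simulateFamily()` / `simulateReads()`) generates
paralogous families with planted diploid genotypes and labeled reads — with
a `cross_mapped` mode that deliberately piles every paralog's reads onto the
target locus — and a concordance module (`compareCalls()`) scores agreement
between two typing call sets at the allele-call level.

## Worked example

Simulate a 3-paralog family at 8% divergence with a planted diploid, emit
~3 kb long reads at depth 15 with 1% error, and type the first gene:

```r
library(mhctyper)

tr  <- simulateFamily(simSpec(seed = 42, mean_depth = 15, error_rate = 0.01))
sim <- simulateReads(tr, mode = "long", depth = 15)

plantedGenotype(tr)[["MHC-1"]]
#> [1] "MHC-1*02:01" "MHC-1*06:01"

call <- runPipeline(sim$reads, simGenome(tr), simAlleleDb(tr),
                    simTargets(tr), "MHC-1", mode = "long")
call
#> GenotypeCall MHC-1
#>   Allele 1: MHC-1*02:01 (987.2 bits, 100.00% id)
#>   Allele 2: MHC-1*06:01 (987.2 bits, 100.00% id)
```

Both planted alleles are recovered with 100% identity; 987.2 bits is the
summed HSP score of the two typed exons (270 + 276 bp of exact match) of one
haplotype contig against the winning allele. With `output_dir=` set,
`runPipeline()` writes the conventional intermediates
(`output_bam/output.filt.bam`, `output_vcf/tmp.output.vcf.gz`,
`output_vcf/output.vcf`, `output.contig.fa`, a report TSV and a JSON-lines
manifest).

Concordance between two typing methods, from the packaged 12-animal SLA
typing table:

```r
tt  <- loadTruthTsv(system.file("extdata", "sla_typing_12pigs.tsv",
                                package = "mhctyper"))
res <- compareCalls(tt[tt$method == "PCR-SBT", ],
                    tt[tt$method == "NGS", ], rule = "exact_group")
res$summary
#>      gene n_allele_calls n_concordant percent
#>     SLA-2             24           14      58
#>     SLA-3             24           21      88
#>  SLA-DRB1             24           22      92
#>  SLA-DQB1             24           24     100
```

The low SLA-2 agreement is the signature of class-I paralog cross-mapping in
short-read data; the long-read route above is how the pipeline resolves it.

A thin command-line front end ships at `inst/cli/mhctyper-cli.R`
(subcommands `pipeline`, `simulate`, `concordance`, `qc`; the `pipeline`
flags `-b/-m/-t/-g` name the BAM, reference directory, target gene and
genome).

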