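# indelsync

Population-scale INDEL synchronization and integrated open-reading-frame
burden testing for association studies in inbred (haploid-equivalent)
lines — *Arabidopsis* accessions, *Drosophila* inbred panels, and similar
sequenced populations.

## The problem

When each sample's variants are called independently against a reference,
the same underlying insertion or deletion is frequently reported in
different but sequence-equivalent forms — shifted within a repeat tract,
split into different SNP/INDEL combinations, or typed as a different event
class. These *alignment isomorphs* masquerade as multi-allelic sites,
burning degrees of freedom on alleles that are in fact identical and
hiding genuine INDEL associations. Loss-of-function alleles compound the
problem: several distinct mutations in one gene can each disrupt the same
protein, so no single variant carries enough carriers to reach genome-wide
significance even when the gene does.

## What the package does

1. **Variant synchronization.** Each chromosome is tiled with overlapping
   windows (default 50,000 bp, overlapping by 1,000 bp). Per window, every
   sample's haplotype is rebuilt from its calls, all distinct haplotypes
   are aligned with the reference (a banded affine-gap pairwise aligner
   merged into an MSA by gap-column union; a MAFFT adapter is available),
   and variants are re-called column by column as atomic 1-bp events. In
   window overlaps, conflicting calls are resolved toward the nearer
   window center; atomic runs are merged back into full INDELs and
   left-aligned to their canonical position.
2. **ORF-state (ORFS) annotation.** Per gene × sample, three annotation
   routes — coordinate lift-over, spliced alignment of the reference CDS,
   and spliced alignment of the reference protein — are each checked
   against four criteria: start/stop codon intact, splice motifs intact
   (reference pair, GT-AG, or GC-AG / GG-AG / GT-TG / GT-CG / CT-AG),
   no premature stop, and spliced CDS length divisible by 3. The gene is
   *interrupted* only if every evaluable route fails a criterion — a
   deliberately conservative burden genotype.
3. **Encoding and filtering.** `{0,1,NA}` matrices per variant class; SNP
   missingness rules (read support < 2, heterozygous, overlapped by an
   INDEL); INDEL identity by (position, length, type); MAF / missing-rate
   / minor-allele-count presets; IBS-based removal of homogeneous lines.
4. **Mixed-model association.** `y = mu + x b + u + e` with
   `Var(u) = sg^2 K` (Balding–Nichols kinship) and `Var(e) = se^2 I`;
   `delta = se^2/sg^2` is fit by REML on the spectral decomposition and
   fixed for per-marker generalized least squares tests, with per-marker
   missing-sample exclusion. Genome-wide thresholds by Bonferroni and by
   permutation (empirical quantile of the genome-wide minimum p over
   phenotype permutations).
5. **Variance decomposition.** Significant SNPs, then INDELs, then ORFS
   markers are offered as fixed covariates under marginal F-test selection
   (p < 1e-4 on nested residual sums of squares);
   `h2 = 1 - RSS/TSS` of the fixed-effect fit after each class gives the
   share explained by SNPs and the extra shares from INDELs and ORFS.
6. **Independent loss-of-function detection.** ORFS-shifting haplotype
   classes of a gene are graph nodes, joined when their variant sets
   overlap in genomic position; a graph at least one edge short of
   complete (with enough carriers) flags independently arisen
   loss-of-function alleles.
7. **Synthetic data.** Generators for reference genomes with planted
   multi-exon genes, populations whose shared alleles are emitted as
   alignment isomorphs (with truth tables), phenotypes with known
   per-class variance shares, and a Wilcoxon-based power simulation for
   burden testing of independent loss-of-function alleles.

## Worked example

Six samples, nine planted isomorph families; carriers of each family get
different but sequence-equivalent call representations:

```r
library(indelsync)
iso  <- sim_isomorph_population(n_samples = 6, n_families = 9, seed = 42)
sync <- synchronize_population(iso$genome, iso$variants,
                               samples = iso$samples,
                               window = 5000, overlap = 500)

subset(iso$variants, pos >= 1500 & pos <= 1515)[, 1:5]   # before
#>   chrom  pos ref alt sample
#> 1  chr1 1500 AAA       s002
#> 2  chr1 1505 AAA       s003      <- same allele, shifted placement
#> 3  chr1 1500 AAA       s004

subset(sync$variants, pos >= 1500 & pos <= 1515)[, 1:5]  # after
#>    chrom  pos ref alt sample
#> 5   chr1 1500 AAA       s002
#> 13  chr1 1500 AAA       s003     <- one shared biallelic deletion
#> 23  chr1 1500 AAA       s004

sync$report
#>   sample n_input_indels n_reassigned n_reassigned_poslen  fraction
#> 1   s001              1            0                   0 0.0000000
#> 2   s002              5            3                   3 0.6000000
#> 3   s003              6            6                   6 1.0000000
#> 4   s004              5            4                   4 0.8000000
#> 5   s005              3            2                   2 0.6666667
#> 6   s006              1            0                   0 0.0000000
```

The report counts, per sample, how many input INDELs changed
representation when re-called from the joint alignment (`n_reassigned`),
and how many changed position or length (`n_reassigned_poslen`).

A full pipeline run (simulation → synchronization → ORFS → encoding →
association) is one call:

```r
run_pipeline(c("simulate", "synchronize", "orfs", "encode", "associate"),
             out_dir = "run1",
             config = pipeline_config(seed = 5, n_samples = 12))
```

or, from a shell, `Rscript inst/cli/indelsync.R simulate synchronize
--out run1 --seed 5`.

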