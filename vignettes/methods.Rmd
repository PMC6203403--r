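---
title: "Synchronized variant re-calling and integrated ORF-state burden testing: models and design choices"
author: "indelsync"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synchronized variant re-calling and integrated ORF-state burden testing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the models implemented in `indelsync`, the
parameters that matter, and the design decisions taken where the design
was genuinely open. It states no empirical number that the test suite and
`scripts/acceptance.R` do not themselves compute.

## 1. Why variants need synchronizing

In an inbred population genotyped sample by sample, an insertion or
deletion has no unique coordinate representation: inside a repeat tract it
can be placed at several positions, and a complex substitution can be
written as one combined event or as several SNPs and INDELs. All of these
*alignment isomorphs* edit the reference to the same haplotype, yet
coordinate-keyed genotype encoding treats them as different alleles. The
consequence for association testing is a spurious multi-allelic site:
carriers of one biological allele are split across several marker columns,
each underpowered.

`indelsync` removes the ambiguity by re-calling all samples from a joint
alignment:

1. **Windows.** Each chromosome is tiled with windows of `window_size`
   (default 50,000 bp) overlapping by `window_overlap` (default 1,000 bp).
   Windowing bounds the alignment problem; the overlap gives every
   interior position two independent calls whose disagreement can be
   arbitrated. A variant straddling a window edge belongs to the window
   containing its leftmost reference base.
2. **Haplotypes.** Within a window each sample's haplotype is rebuilt by
   applying its calls to the reference slice (a sample without calls
   contributes the reference slice itself). All coordinates in the
   package are 0-based half-open; insertions are anchored to the
   reference base they follow.
3. **Alignment.** The builtin engine aligns each *distinct* haplotype to
   the reference with a banded global affine-gap aligner (match +5,
   mismatch −4, gap open 10, gap extension 1, band half-width
   `|Δlength| + 100`, common prefix/suffix trimmed with a 64 bp backoff so
   repeat tracts at the trim edge stay inside the DP core) and merges the
   pairwise alignments into an MSA by taking, at every reference
   position, the union of insertion columns. Identical haplotypes are
   aligned once, so a fully shared allele costs one alignment however
   many samples carry it. `N` never matches anything, itself included.
   An external MAFFT adapter (`engine = "mafft"`) is provided; the
   gap-stripped content of every row is preserved whichever engine runs.
4. **Atomic re-calling.** Variants are read off the MSA column by column:
   sample gap under a reference base → 1 bp deletion; sample base over a
   reference gap → 1 bp insertion anchored to the preceding reference
   base; mismatch → SNP. Decomposing multi-base events into atomic units
   makes overlap arbitration purely positional.
5. **Overlap resolution.** Where the two windows covering a position call
   *different* things for a sample, the call from the window whose center
   is nearer wins (ties: the earlier window). Agreeing calls deduplicate;
   a call seen by only one window (e.g. from an edge-straddling deletion)
   survives.
6. **Merging and canonical placement.** Runs of adjacent atomic deletions
   merge into one deletion, insertions at one anchor into one insertion;
   an insertion anchored inside a deleted span stays an independent
   record. Finally every INDEL is left-aligned to its leftmost
   sequence-equivalent position, never crossing another variant of the
   same sample. Left alignment makes the canonical representation a
   function of the haplotype alone, so any deterministic alignment engine
   yields the same synchronized output.

**Operating condition.** Collapse of isomorph families is guaranteed for
variants that sit at least the window overlap away from window-edge
neighbourhoods; within an overlap, a variant sees different flanking
context in the two windows and its placement is arbitrated, not
normalized. The synthetic generators therefore keep planted variants
1.2 kb clear of window boundaries — the condition under which the
round-trip, collapse and idempotence properties are asserted.

## 2. ORF-state annotation

For gene × sample the package decides whether a protein-coding
interpretation of the gene survives the sample's variants. The haplotype
of the gene span ± 1 kb (configurable `flank`) is rebuilt and expressed on
the coding strand; three candidate annotations are produced:

* **Lift-over** maps every reference CDS boundary through the coordinate
  map; a boundary deleted on the haplotype maps to the left edge of its
  deletion, and intervals emptied by deletions are dropped.
* **Spliced CDS alignment** aligns the reference spliced CDS to the
  haplotype with an est2genome-style dynamic program: exon match +5 /
  mismatch −4, affine gaps (open 10, extend 2), an intron state consuming
  genome only at a flat entry penalty of 10 with minimum length 10, and a
  +4 bonus for a GT donor or AG acceptor so that boundary ties resolve to
  canonical splice sites. Only the best alignment is kept; a score below
  10 makes the route unevaluable.
* **Spliced protein alignment** runs the same DP at codon granularity over
  the translated frames (match +12, mismatch −6, aligned genomic stop
  −20). Introns are placed at codon boundaries; a phase-1/2 intron costs
  one mismatched codon, which the conservative decision rule absorbs.
  The final codon is extended by one so the stop codon participates in
  the criteria.

Each evaluable annotation is checked against four criteria: (i) start
codon `ATG` and a canonical stop (`TAA`/`TAG`/`TGA`) — any canonical stop
is accepted, not only the reference's; (ii) every donor–acceptor pair
equals the reference pair for that intron, or is `GT-AG`, or is one of
`GC-AG, GG-AG, GT-TG, GT-CG, CT-AG`; (iii) no premature stop; (iv)
spliced CDS length divisible by 3. The gene's state is **interrupted only
if every evaluable route fails at least one criterion**; one fully
passing route keeps it conserved; no evaluable route yields missing.
Unevaluable routes are excluded from the conjunction, so evidence can
only rescue, never condemn.

When the reference genome itself carries a non-functional copy of a gene,
a designated replacement sample supplies the query CDS/protein and the
reference splice pairs (`alt_reference`); lift-over still maps the
reference-coordinate model, and all criteria continue to be evaluated on
the target sample's own sequence.

**Trustability.** An ORFS call is trustable when every CDS base has read
coverage ≥ 1 and every CDS INDEL is confirmed by both assembly routes;
with no read-level inputs both checks pass vacuously so the pipeline runs
from variant calls alone. Trustable-ORFS counts per sample double as a
sequencing-quality score when pruning homogeneous lines.

## 3. Genotype encoding and filtering

SNP markers are biallelic sites; a sample is missing at a SNP when its
call has read support below 2, is heterozygous, or lies inside one of the
sample's deletions (absent support/heterozygosity fields pass vacuously).
INDEL marker identity is (position, length, type): two insertions of the
same length at one position are the *same* marker even when the inserted
sequences differ, with the most frequent insert recorded as the allele
descriptor. A sample is missing at an INDEL marker when a different INDEL
of its own occupies part of the marker's span; an insertion conflicts
with another insertion at the same anchor or with a deletion strictly
containing its anchor point. Filters: minor allele frequency, missing
rate, minor allele count, and region exclusion, with presets
(0.1, 0.5, 5) and (0.05, 0.2, 8) for the two population scales the
package targets.

Homogeneous lines are found on the identity-by-state matrix of LD-pruned
SNPs (sliding 2,000 bp windows stepping 1,000 bp, dropping the
later-position SNP of any pair with r² > 0.9). Groups are connected
components of the IBS > 0.9 graph — transitive closure chosen for
determinism — and each group keeps one sample: duplicates-by-identifier
removed first, then highest trustable-ORFS count, ties to the earlier
sample.

## 4. The mixed model

Association uses `y = μ + x β + u + e` with `Var(u) = σg²K`,
`Var(e) = σe²I` on inbred lines (haploid 0/1 coding; the incidence matrix
is the identity). The kinship `K` is the Balding–Nichols style
standardized cross-product `(g−p)(g−p)'/p(1−p)` averaged over markers
non-missing in both samples, made positive semidefinite by adding
`(|min eigenvalue| + 1e-9) I` when needed; IBS and identity flavors are
available. The variance ratio `δ = σe²/σg²` is estimated once under the
null by REML on the spectral decomposition of `S(K+I)S` — a 100-point
grid over `log δ ∈ [−10, 10]` refined by golden-section search — and held
fixed for per-marker generalized least squares t-tests. Samples missing a
marker's genotype are excluded from that marker's test; the Cholesky
whitening factor for each missingness pattern is memoized. With an
identity kinship the test collapses exactly to the ordinary
linear-regression t-test, which is the package's cross-check against
`stats::lm`.

Genome-wide thresholds: Bonferroni `α/n_tests` (pass the combined
SNP+INDEL+ORFS matrices for the integrated threshold), and a permutation
threshold — the empirical `α`-quantile of the genome-wide minimum p over
`n_perm` (default 1,000) phenotype permutations. Raw phenotype values are
permuted against the sample labels, preserving marker LD; `δ` stays at
its null estimate throughout.

## 5. Variance decomposition

Genome-wide significant markers are offered as fixed covariates class by
class (SNPs, then INDELs, then ORFS; within a class by ascending
association p-value). A candidate is kept only when the F-test on the
residual sums of squares of the nested whitened fixed-effect fits gives
p < 1e-4; exact duplicates (|r| = 1 with a selected covariate) are
skipped before testing. After each class all accepted covariates are
jointly refit by GLS (β re-estimated, variance components re-fit) and the
explained share is `h² = 1 − Σ(y−ŷ)²/Σ(y−ȳ)²` with ŷ the fixed part
only. The class increments are the successive differences; a negative
increment (possible because GLS β need not minimize the raw residual sum)
is clamped to zero with a warning, and the reported cumulative values are
rebuilt from the clamped increments so that
`h²_S + h²_I + h²_O = h²_SIO` holds exactly. The unclamped stage values
are also returned. Candidate genotype columns are mean-imputed for this
analysis only; the association scan itself never imputes.

## 6. Independent loss-of-function detection

For a gene, samples sharing an identical set of ORFS-shifting variants
form one haplotype-class node (identical-by-descent alleles must count
once). An edge joins two nodes when any variant of one overlaps any
variant of the other: reference-consuming variants overlap when their
spans share a base; two insertions overlap only at the same anchor — an
insertion shares no reference base with anything else, so an insertion
and a deletion never create an edge. Alleles of shared ancestry all carry
the founding variant and therefore form a complete graph; a graph at
least one edge short of complete, with more than `min_carriers` carriers
(default 130, matching the population scale the default is calibrated to;
synthetic tests scale it down) and at least two nodes, flags
independently arisen loss of function.

## 7. Synthetic data: what it emulates, what it does not

* `sim_reference` plants three-exon genes (ATG start, canonical stop,
  GT..AG introns of 40–90 bp, no internal stop, phase-0 introns, exons of
  at least six codons) on a random background, half on the minus strand.
* `sim_isomorph_population` plants allele families whose carriers share
  one underlying edit but receive different sequence-equivalent
  representations: (a) a deletion inside an 8 bp homopolymer emitted
  left- or right-shifted, (b) a base change emitted as a SNP or as a
  1 bp deletion plus insertion, (c) a complex substitution emitted as two
  SNPs or as a deletion plus insertion. Sequence equivalence of every
  representation pair is asserted during generation.
* `sim_population` plants shared SNP/INDEL alleles (frequencies 0.1–0.9,
  INDELs up to 12 bp) with a single representation each, for round-trip
  and idempotence checks.
* `sim_phenotypes` draws `y = Σ β_c x_c + u + e` with `u ~ MVN(0, h²_poly K)`
  and coefficients scaled so each causal marker's expected share equals
  its target; decomposition checks build `K` from a 400-marker panel so
  that no single causal marker dominates the random effect.
* `simulate_lof_power` draws three 70-sample allele groups (functional
  mean 2; two loss-of-function groups mean 1; variance 1.44 each) and
  compares the single-INDEL Wilcoxon test (one LoF group vs everyone
  else) against the ORFS burden test (both LoF groups vs the functional
  group), recording two-sided p-values per replicate; "70 samples" is
  read as 70 per allele group.

The generators do not emulate linkage disequilibrium decay, demography,
sequencing error, or coverage variation, so passing tests demonstrate the
algorithms' correctness under their stated operating conditions, not
calling accuracy on real reads. Problem sizes in the tests and the
acceptance script — 500 isomorph families at 10 samples, a 20 × 200 kb
round-trip population, 50 idempotence fixtures, 2,000-marker calibration
scans at n = 200, 50 decomposition replicates, 2,000 power replicates —
were chosen as the smallest sizes at which the asserted properties are
statistically meaningful.

## 8. Numerical choices and degenerate inputs

* Ties in the banded aligner's traceback are broken in a fixed order
  (diagonal, then gap-in-haplotype, then gap-in-reference), so identical
  inputs always produce identical alignments; the final left-alignment
  pass makes placement canonical regardless.
* The intron state's maximum length bound (30,000 bp) is vacuous for
  gene-plus-flank extracts shorter than the bound; when an alignment does
  return a longer intron the route is marked unevaluable rather than
  silently accepted.
* Empty haplotypes (a window deleted entirely) become all-gap alignment
  rows; empty variant sets reproduce the reference slice with an identity
  map.
* A phenotype with zero variance, a rank-deficient fixed-effect matrix,
  and a monomorphic marker after missing-sample exclusion are all
  explicit errors or flagged untested results, never silent numbers.
* REML's `δ` grid spans `log δ ∈ [−10, 10]`; boundary optima (pure-noise
  or noise-free phenotypes) land on the grid ends and are returned as
  such.

## 9. Known limitations

* Window-overlap regions arbitrate rather than normalize representations;
  variants inside an overlap can keep window-dependent placement (the
  left-alignment pass still canonicalizes simple shifts).
* The protein route's codon-boundary introns misplace phase-1/2 intron
  boundaries by up to two bases; the three-route conservative rule, not
  the protein route alone, is the unit of correctness.
* The builtin aligner's band assumes near-identical haplotypes; deeply
  divergent sequences (beyond the band's reach after the length-difference
  allowance) would need the MAFFT engine.
* Diploid heterozygous genotypes are out of scope by design; the
  population model is inbred/haploid throughout.
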