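---
title: "Methods: building a multi-tissue expression atlas from a de novo transcriptome"
author: "troutatlas authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: building a multi-tissue expression atlas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(troutatlas)
```

## The problem

A de novo transcriptome assembly of short-read RNA-seq from many tissues of a
single animal — here modelled on a 13-tissue rainbow trout design sequenced
from non-normalized cDNA libraries — produces hundreds of thousands of
contigs, grouped by the assembler into *components* (contigs presumed to
derive from one locus, its splice variants, or close paralogs). Turning that
into a digital gene expression atlas requires a chain of small, rule-based
computations: choosing one representative transcript per gene, measuring
assembly quality, deciding which transcripts are complete cDNAs, normalizing
mapped-read counts, classifying genes as housekeeping or tissue-specific,
summarizing transcriptome complexity per tissue, and comparing predicted gene
loci against a genome annotation. None of these steps is statistically deep,
but each has boundary conventions that change the reported numbers; this
package fixes those conventions explicitly and tests them.

## Models and rules

### RPKM and the two classification rules

Expression of gene $g$ in tissue $t$ is normalized as
$$\mathrm{RPKM}_{gt} = \frac{c_{gt} \cdot 10^9}{L_g \, N_t},$$
with $c_{gt}$ mapped reads, $L_g$ transcript length (nt) and $N_t$ the
tissue's library size. Two rules partition genes (not exhaustively):

* **housekeeping**: $\min_t \mathrm{RPKM}_{gt} \ge 1$ (inclusive);
* **tissue-specific to $t$**: $\mathrm{RPKM}_{gt} \ge 8 \cdot
  \max_{s \ne t} \mathrm{RPKM}_{gs}$ (inclusive), with
  $\mathrm{RPKM}_{gt} > 0$.

Both thresholds are inclusive because the defining phrases are "at least"
phrases. Three edge conventions were genuinely open and are decided here:

* **Zero elsewhere.** If a gene is expressed in exactly one tissue the fold
  ratio is formally infinite; we count it as tissue-specific. Excluding it
  would discard the most extreme specificity, contradicting the intent of
  the rule.
* **Overlap of the classes.** The two rules do not logically exclude each
  other (a row of RPKM 1 everywhere with 10 in brain satisfies both), so
  `atlas_report()` reports the intersection explicitly rather than forcing
  disjointness. Empirically the classes are expected to be disjoint; making
  that an assertion would hide a data problem.
* **Expression floor for fold calls.** Fold rules on near-zero RPKM are
  noise-sensitive; `ts_focal_min_rpkm` exposes a floor but defaults to 0
  because the rule as stated has none.

Since the fold threshold is > 1, a gene's focal tissue is unique, so the
per-tissue sets are pairwise disjoint — this is property-tested rather than
assumed.

### Representative-transcript selection

Within each multi-contig component, the longest contig *among those with a
protein-database hit* is the representative; hit-less components contribute
none. Single-contig components with hits are grouped by best-hit subject
accession (the computable proxy for "annotated as the same gene") and the
longest per group is kept. Length ties break lexicographically by contig id
for determinism. Whether a singleton with a unique annotation should be kept
was an open point; we keep it (`drop_lone_singletons = FALSE`) since
dropping information-bearing transcripts needs a positive reason.

### The interior-ORF full-length rule

`scan_orfs()` is a transparent six-frame scanner: maximal ATG-to-stop ORFs
under the standard code, reported on forward-axis coordinates. A contig is a
putative full-length cDNA iff its (longest) ORF begins after base 1 *and*
its stop codon ends before the last base. We deliberately do not
re-implement hexamer/Markov coding-potential models; the boundary rule is
the computation of interest, and it is pure interval logic — tested as such.
Codons containing N are treated as ordinary sense codons: they can neither
start nor terminate an ORF. ORFs are ATG-anchored; a stop-to-stop reading
frame without ATG never counts. The default minimum protein length is 100
residues (no minimum was stated; 100 aa is the common cutoff for calling a
coding region in assembly QC and is configurable everywhere).

### Assembly statistics

N50 is the largest contig length $L$ such that contigs of length $\ge L$
hold at least half of all assembled bases; it is always the length of an
actual contig. The "long contig" filter is inclusive at 500 nt: the stated
smallest long contig is exactly 500 nt, so the table convention wins over
the "more than 500" prose; a strict mode is provided.

### Complexity and composition metrics

Expressed-gene counts per tissue use inclusive thresholds {5, 1, 0.5, 0.1}
RPKM. Cumulative abundance curves sort genes by RPKM (ties by id) and report
the fraction of a tissue's total RPKM in the top $k$ genes. The
tissue-specific mRNA fraction divides summed RPKM of the tissue's specific
genes by summed RPKM of all genes at or above 0.5 RPKM in that tissue; a
specific gene below 0.5 in its focal tissue leaves both numerator and
denominator (the denominator defines the "expressed universe", and a gene
outside the universe cannot contribute to it). Tissue PCA log2(x+1)
transforms RPKM, centers each gene, and projects tissues onto principal
components; each component's sign is fixed by making its largest-magnitude
loading positive, so coordinates are reproducible.

### Novel loci and splicing

`flag_known_loci()` is a fixed two-stage filter: nucleotide homology to
annotated mRNAs at E ≤ 1e-5 first, then coordinate overlap of locus spans
(strand-agnostic, ≥ 1 bp) on the same sequence. The order matters and is
part of the contract; the three outcome sets partition the predicted ids
exactly. Strandedness and minimum overlap were unstated upstream; both are
exposed (`stranded`, `min_overlap_bp`) with permissive defaults, since an
antisense overlap still indicates the region is annotated. Redundancy
between genome-predicted novel loci and unmatched de novo contigs is
consumed as an explicit pair list (`merge_novel()`) rather than
re-implementing sequence clustering whose criteria were never specified.

## The synthetic-data generator

`simulate_expression()` emulates the stated world of the design rather than
any convenient one: 13 tissues; ~17% housekeeping genes (the atlas
proportion 7,678/44,990); tissue-specific genes at ~9% of genes split
evenly across tissues; planted folds uniform on [8, 40] so the inclusive
8-fold boundary is exercised; log-normal baseline expression (median RPKM
4); log-normal lengths around 1.6 kb clamped to the observed [500, 50000]
nt contig range; 1e7 mapped reads per tissue; Poisson count noise. With no
replicate libraries in the design, overdispersion is not estimable, so
Poisson is the honest noise floor; a negative-binomial extension point is
left to configuration.

Planting is constructive, not statistical: housekeeping rows are clamped to
RPKM ≥ 2 everywhere (margin against Poisson dips below the RPKM 1 line) and
capped below 8-fold max/second-max; tissue-specific rows receive one forced
low tissue (RPKM < 0.3, so they can never be housekeeping) and a focal value
at `fold` times the max of the rest; background rows receive 2–4 forced low
tissues and the same fold cap, so they satisfy neither rule. In `noise =
"none"` mode counts are the rounded expectation; because rounding can move a
value across an inclusive boundary, a deterministic repair pass nudges
single counts until re-derived RPKM is exactly consistent with the planted
labels — this is what makes "100% precision and recall on noise-free data" a
meaningful test rather than a probabilistic one.

The ORF-contig generator builds sequences from a codon alphabet that cannot
produce ATG on either strand (no `ATG` or `CAT` substrings anywhere except
the single planted start codon), so the planted ORF is provably the only
one, and boundary classes are exact by construction. The annotation-pair
generator lays loci with ≥ 1.5 kb spacing, jitters reproduced loci by ≤ 300
bp (overlap preserved), and plants novel loci ≥ 1 kb from any annotated
locus; decoy homology hits above the E-value cutoffs exercise the filters.

What a green test does *not* establish: the generator has no read-level
error, no mapping ambiguity between paralogs (acute in a duplicated salmonid
genome), no length-estimation error, and no overdispersion. Recovery rates
on real data will be lower than the ≥ 95% seen under Poisson noise; the
tests establish correctness of the rules, not field performance of the
pipeline.

## Numerical choices

* Reported fractions use half-up decimal rounding (`round_half_up`),
  declared once and tested, because upstream reports mix rounding and
  truncation; base R's round-half-even would silently differ.
* All interval arithmetic is 1-based inclusive at the GTF boundary and
  stays in that convention internally (spans and overlap are closed
  intervals); nothing in the pipeline needs half-open arithmetic, so no
  conversion layer exists to get wrong.
* E-value comparisons are inclusive (`evalue <= cutoff`).
* Deterministic tie-breaks everywhere: contig id (representatives), gene id
  (abundance curves), `(length desc, strand, start)` (ORFs), largest
  loading positive (PCA signs).
* Degenerate inputs error loudly (`assembly_stats` on empty input,
  zero-RPKM tissue in `cumulative_abundance`, zero denominator fractions)
  rather than returning NA.

## Known limitations

* `simulate_expression()` plants truth block-wise by row index; the row
  order is not shuffled (labels, not positions, carry the truth).
* The proteome-coverage and reciprocal-comparison operations summarize hit
  tables; they do not validate that the tables came from the documented
  search programs or parameter sets.
* PCA coordinates are reported without component scaling; downstream
  plotting decisions (scaling, variance annotation) are left to the caller.
* `screen_novel_orfs()` classifies the single longest ORF per sequence;
  loci whose second-longest ORF is interior while the longest touches a
  boundary are reported `partial_orf`.
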