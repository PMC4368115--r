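# troutatlas

Computational pipeline for building a **multi-tissue digital gene expression
atlas** from a de novo transcriptome assembly, modelled on a 13-tissue
rainbow trout RNA-seq design (brain, white muscle, red muscle, fat, gill,
head kidney, kidney, intestine, skin, spleen, stomach, liver, testis)
sequenced from non-normalized libraries of a single doubled-haploid fish.

It is written for transcriptomics practitioners who have the *tabular
outputs* of an assembly-and-annotation workflow (contigs with component
ids, BLAST hit tables, per-tissue count matrices, GTFs) and need the
downstream atlas computations to be explicit, deterministic and tested:

* **Assembly post-processing** — inclusive 500 nt length filter, N50 and
  length statistics, representative-transcript selection (longest
  hit-bearing contig per component; singletons grouped by hit subject),
  proteome-coverage and reciprocal-comparison summaries, BLAT coverage
  tiers (100% / 90% / 50% of the reference coding sequence).
* **Full-length cDNA calling** — a transparent six-frame ORF scanner plus
  the interior-ORF rule: a contig is full-length iff its ORF starts after
  base 1 and its stop ends before the last base.
* **Expression atlas** — RPKM = count·10⁹/(length·library size);
  housekeeping genes (RPKM ≥ 1 in *every* tissue) and tissue-specific
  genes (RPKM in one tissue ≥ 8 × the maximum across all others, both
  inclusive).
* **Complexity metrics** — expressed-gene counts at RPKM thresholds
  {5, 1, 0.5, 0.1}, cumulative abundance curves, tissue-specific mRNA
  fractions at the 0.5 RPKM expressed universe, tissue PCA coordinates.
* **Genome comparison** — two-stage novel-locus detection (BLASTn at
  E ≤ 1e-5, then coordinate overlap), ORF screening of novel loci, merged
  new-transcript sets with redundancy removal, transcripts/exons-per-locus
  splice statistics.
* **Synthetic data** — `simulate_expression()` and friends generate count
  matrices, components, ORF contigs and GTF pairs with *planted ground
  truth*, so every stage has a parameter-recovery test with no external
  data.

## Worked example

```r
library(troutatlas)

sim <- simulate_expression(sim_config(seed = 1))   # 2000 genes, 13 tissues
rm_ <- compute_rpkm(sim$counts)
atlas_report(rm_)
#> atlas_classification: 334 housekeeping, 179 tissue-specific, 0 overlap
```

Under Poisson noise at 10⁷ reads/tissue, 334 of the 340 planted
housekeeping genes are recovered (98.2% sensitivity, 100% precision), and
the housekeeping and tissue-specific calls are disjoint — matching the
empirical disjointness the atlas design reports.

```r
assembly_stats(sim$counts$lengths)
#> assembly_stats: 2000 contigs, 3882770 bases, N50 2522 nt,
#>                 range [500, 21599] nt, mean 1941.4 nt

head(subset(expressed_counts(rm_), tissue == "brain"), 4)
#>    tissue threshold n_expressed fraction
#> 1   brain       5.0         722     0.36
#> 14  brain       1.0        1521     0.76
#> 27  brain       0.5        1635     0.82
#> 40  brain       0.1        1869     0.93

cumulative_abundance(rm_, "white_muscle")
#> abundance_curve[white_muscle]: top 100 genes contribute 46.1% of mRNA

format_fraction(43824, 44990, 1)   # "n (x%)" reporting helper
#> 43,824 (97.4%)
```

The expressed-gene counts rise monotonically as the RPKM threshold drops
(the Table-4 pattern), and the abundance curve reports how concentrated a
tissue's mRNA pool is in its top genes.

## Command line

A thin CLI wraps the R API (see `exec/troutatlas`):

```sh
troutatlas simulate --outdir sim --seed 1
troutatlas classify --counts sim/counts.tsv --lengths sim/lengths.tsv \
                    --libsizes sim/libsizes.tsv --out atlas.tsv
troutatlas novel-loci --predicted sim/predicted.gtf \
                      --annotated sim/annotated.gtf --out novel.tsv
troutatlas splice-stats --gtf sim/predicted.gtf
```

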