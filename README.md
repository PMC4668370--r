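# hmcdiff

Analysis toolkit for 5-hydroxymethylcytosine (5-hmC) sequencing profiles:
permutation enrichment of pulldown (hMe-Seal) peaks at genomic annotations,
gene-level 5-hmC density quantification, integration with gene expression,
replicate-consensus overlap, tumor/normal differential hydroxymethylation
with expression concordance, and base-resolution TAB-seq quantification.

## Who this is for

Epigenomics analysts working with affinity-enrichment 5-hmC data (peak calls
carrying per-peak tag counts) who need the standard downstream questions
answered reproducibly: *is 5-hmC enriched at CpG islands, shores, promoters,
gene bodies or transcription-factor sites beyond what random placement
explains? Which genes are hydroxymethylated, how strongly, and how does that
relate to their expression? What changes between replicate groups — cell
line vs. tissue, tumor vs. normal — and do expression changes go along?*

## The core statistic

Each peak *i* has tag density *d*<sub>*i*</sub> = *t*<sub>*i*</sub>/*L*<sub>*i*</sub>
(tags over peak length). For a merged annotation *A* the observed tag overlap
is

> Obs(*A*) = Σ<sub>*i*</sub> |*P*<sub>*i*</sub> ∩ *A*| · *d*<sub>*i*</sub>

The null scrambles the peaks across the genome (lengths and tag counts
preserved, chromosome chosen by length, uniform start) 1,000 times; the
enrichment ratio is Obs/Exp where Exp is the null mean, and the empirical
p-value is the add-one estimator (1 + #{null ≥ Obs}) / (1 + B), with floor
1/1001 < 0.001 at B = 1000.

Around it: percentile binning of gene 5-hmC densities (0–25 / 25–75 / 75–98
/ 98–100), chi-squared bin-by-expression-class association, strict
base-intersection replicate consensus, presence/absence gain/loss calls with
Wilcoxon + Bonferroni expression concordance, and three-state TAB-seq
arithmetic (%5hmC = 100·f<sub>tab</sub>, %5mC = 100·max(0, f<sub>bs</sub> −
f<sub>tab</sub>), %C the remainder). A synthetic-data module generates every
input with planted structure. See `vignettes/hmc-analysis.Rmd` for the full
methods account.

## Worked example

```r
library(hmcdiff)

cfg <- sim_config(seed = 1, annotation_fraction_q = 0.5)  # plant half the tag mass in CpG islands
gen <- simulate_genome(cfg)                               # 5 Mb genome, genes + islands
pt  <- simulate_peaks_and_tags(cfg, gen$islands, gen$sizes)

enrichment_test(pt$peaks, gen$islands, gen$sizes, n_shuffles = 1000, seed = 1)
#> Enrichment of peaks at 'CpG islands'
#>   observed 4953.00  expected 332.03 (sd 135.25)
#>   enrichment 14.917  p(enrich) 0.000999  p(deplete) 1  [1000 shuffles]
```

Half the tag mass sits in islands covering ~3% of the genome, so the ratio of
observed to shuffle-expected tag overlap is ≈ 0.5/0.033 ≈ 15, and none of the
1,000 shuffles reaches the observed value, giving the minimal attainable
p of 1/1001.

```r
rec  <- bin_by_percentile(count_tags_per_gene(pt$tags, gen$genes, pt$peaks))
expr <- classify_expression(simulate_expression(rec, cfg))
expression_by_hmc_bin(rec, expr)
#>       bin  n        q1    median        q3
#> 1   P0_25 12  2.339158  3.592904  5.780906
#> 2  P25_75 26  7.897924 10.910727 15.771825
#> 3  P75_98 11 17.184099 26.238780 38.661603
#> 4 P98_100  2 69.392836 84.115006 98.837176
```

Median expression rises monotonically across the four 5-hmC density bins —
the planted density→expression link recovered by the integration module.
`run_pipeline(list(seed = 1))` chains all stages (simulate, annotate, enrich,
gene-quant, integrate, cancer, tabseq) and writes headered TSV/BED outputs
plus a manifest.

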