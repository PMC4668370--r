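---
title: "Methods: permutation enrichment and differential analysis of 5-hmC profiles"
author: "hmcdiff authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: permutation enrichment and differential analysis of 5-hmC profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hmcdiff)
library(GenomicRanges)
library(IRanges)
```

# Background

5-hydroxymethylcytosine (5-hmC) is an oxidized form of 5-methylcytosine
produced by TET enzymes, and its genomic distribution shifts markedly during
epithelial differentiation and in cancer. Affinity-based pulldown sequencing
(hMe-Seal) yields peak calls annotated with sequencing-tag counts; TAB-seq
(TET-assisted bisulfite sequencing) yields base-resolution clone counts that
separate cytosine, 5-mC and 5-hmC. This package implements the downstream
computational layer for such data: a tag-weighted permutation enrichment test
over genomic annotations, gene-level 5-hmC density quantification, integration
with differential expression, replicate-consensus overlap analyses,
tumor/normal differential hydroxymethylation with expression concordance, and
three-state TAB-seq quantification — plus a synthetic-data module that
generates every input with planted structure so the whole pipeline is
testable without external downloads.

# The tag-weighted enrichment statistic

For each peak $i$ with $t_i$ tags over length $L_i$, the tag density is
$d_i = t_i / L_i$. For a merged annotation $A$, the observed statistic is

$$\mathrm{Obs}(A) \;=\; \sum_i |P_i \cap A| \; d_i ,$$

the tag mass falling on annotation bases: a peak fully inside $A$ contributes
all of its tags, a peak half inside contributes half. The null distribution
comes from scrambling peaks across the genome — each peak keeps its length
and tag count, lands on a chromosome with probability proportional to
chromosome length (among chromosomes that can hold it), and gets a uniform
start such that it fits. The expected value is the mean of the statistic over
$B$ shuffles (1,000 by convention), the enrichment ratio is
$\mathrm{Obs}/\mathrm{Exp}$, and the empirical p-value uses the add-one
estimator

$$p \;=\; \frac{1 + \#\{\mathrm{null} \ge \mathrm{Obs}\}}{1 + B},$$

so $p$ is never zero and its floor at $B = 1000$ is $1/1001 < 0.001$, matching
the conventional significance reporting for permutation tests of this kind.
The one-sided enrichment tail is the primary report; the depletion tail is
returned alongside because the direction of interest is not always known in
advance. The standard deviation of the null is also reported to support a
z-score diagnostic, though inference rests on the ratio and the permutation p.

Two numerical choices matter here. First, annotations are merged before
intersection so that a genomic base contributes at most once per annotation;
intersecting per raw feature would double-count bases where features of the
same class overlap. Second, the null loop evaluates the statistic through a
per-chromosome prefix-sum representation of the annotation
(`covered(x) - covered(s-1)` for a placed peak `[s, x]`) rather than building
an interval object per shuffle; the placement stream is shared with
`shuffle_peaks()`, and a test asserts the two routes produce bit-identical
null samples, so the fast path is an implementation detail, not a second
definition.

Replicates are each tested independently and their enrichment ratios averaged,
with the standard deviation across replicates as the error estimate
(`average_replicates()`).

## Coordinates

Internally all intervals are `GRanges` (1-based, closed), the single
convention of the Bioconductor stack this package is built on. BED-family
inputs (0-based, half-open) and MACS-style peak tables are converted on read
and written back in their native convention; GTF (1-based, closed) passes
through unchanged. Keeping exactly one internal convention and converting at
the file boundary is what prevents off-by-one drift.

# Annotations

* **Promoters** — the window from 500 bp upstream to 2 kb downstream of each
  transcription start site. The rule is asymmetric by design (it is the rule
  printed for the data this package targets) and is applied strand-aware, one
  window per distinct transcript TSS, merged afterwards. Because the
  strandedness of the original windows is not documented, a strand-ignorant
  mode (`stranded = FALSE`) is provided; the default is strand-aware since
  the rule references transcription direction. Both `up` and `down` are
  configurable.
* **CpG shores** — the 2-kb flanks adjacent to each CpG island, clamped to
  chromosome bounds, with all island bases subtracted so no base is both
  island and shore (the island/shore contrast is only meaningful if the two
  sets are disjoint), then merged across neighboring islands.
* **Extended genes** — gene bodies grown by 2 kb on both sides, kept per-gene
  so gene-list intersections remain possible. The 2-kb extension is used for
  pathway-style gene lists (`genes_with_peaks()`); gene-level quantification
  (`count_tags_per_gene()`) deliberately uses the *unextended* body, since
  those are the two distinct printed rules.

# Gene-level quantification and binning

Only genes with at least one peak overlapping their body are quantified. Tags
overlapping the body count toward the gene; a tag overlapping more than one
quantified gene is ambiguous and discarded (union-mode counting). Density is
tag count over gene length. Gene densities from pulldown data are unimodal
with a pronounced right tail, which motivates the uneven percentile bins
0–25, 25–75, 75–98 and 98–100: the top 2% isolates the extreme
hydroxymethylation tail. A gene of rank $r$ among $n$ falls in the first bin
whose upper percentile bound is $\ge 100\,r/n$; ties are broken by gene id so
the assignment is deterministic (at $n = 4$ this yields occupancies 1/2/0/1).

Metagene profiles rescale each feature body to a fixed number of bins with
fixed-width flank bins on each side, average per-base coverage per bin over
features, and normalize to tags per million per base so profiles are
sequencing-depth invariant. Minus-strand features have their *binned* profile
reversed (rather than the base-level vector) so that bin 1 is always the 5′
flank and strand-flipping a feature set reverses its profile exactly, even
when a body width is not divisible by the bin count.

# Expression integration

Differential-expression tables are inputs (they come from an external
RNA-seq pipeline); the package classifies genes as up/down/unchanged at
configurable thresholds defaulting to $q \le 0.05$ and $|\log_2 FC| \ge 1$ —
the source analyses relied on an external caller without printing thresholds,
so these defaults are this package's documented convention, not a reproduced
value. Per 5-hmC bin the package reports expression medians and quartiles and
the median $\log_2$ fold change, and tests bin-by-class association with
Pearson's chi-squared (no continuity correction; all-zero rows or columns are
dropped with a warning and the degrees of freedom adjusted).

# Consensus overlap and tumor/normal calls

The consensus of a replicate group is the set of bases with a called peak in
*every* replicate (base-level intersection, merged); a relaxed
$\ge k$-of-$n$ mode exists for larger groups but strict intersection is the
default, matching the "peaks in both replicates" construction. Base-level
overlap between two consensus sets is reported in bases plus the containment
fraction of each set; gene-level overlap partitions genes by whether each
set's consensus hits the unextended gene body.

Genes gaining or losing 5-hmC between matched tumor and normal groups are
called by presence/absence: loss = body hit by the normal consensus and not
the tumor consensus, gain = the reverse, both-or-neither = uncalled. The
underlying criterion is genuinely open (no threshold is printed in the work
this design follows), so a density-ratio alternative
(`mode = "density"`, $|\log_2$ ratio$| \ge 1$ by default) is provided and both
are documented as interpretations. Expression concordance then tests each
called gene tumor-vs-normal with the Wilcoxon rank-sum test, Bonferroni-
corrected across the genes actually tested (not the transcriptome — the
family is the set of hypotheses actually evaluated), with direction taken
from the medians, consistent with a rank test's location interpretation.

The rank-sum test uses the exact null distribution when the combined sample
size is at most 12 and tie-free, and the tie- and continuity-corrected normal
approximation otherwise; identical samples give $p = 1$.

# TAB-seq quantification

Bisulfite leaves both 5-mC and 5-hmC reading as C while TAB treatment
protects only 5-hmC, so with conversion-resistant fractions $f_{bs}$ and
$f_{tab}$:

$$\%\,5hmC = 100 f_{tab}, \qquad
  \%\,5mC = 100\max(0, f_{bs} - f_{tab}), \qquad
  \%\,C = 100 - \%5hmC - \%5mC .$$

When sampling noise makes $f_{tab} > f_{bs}$, the 5-mC estimate is clamped at
zero and unmodified cytosine absorbs the remainder: this keeps the estimate
on the simplex without re-weighting the directly observed 5-hmC fraction,
which is the better-measured quantity. Sites with fewer than 16 clones in
either treatment are flagged and excluded from tests (the printed clone
floor). Condition comparisons pool clone counts across a region's CpGs into
a 2×2 C/T table per condition and apply Pearson's chi-squared with one degree
of freedom; pooling is the default because individual CpGs at ~20 clones are
underpowered, and a per-site mode is provided since the original table
construction is not documented. No continuity correction is applied by
default (pooled totals are ≥ 32 under the clone floor); Yates correction is
available behind a flag.

# The synthetic-data generator

The generator emulates the statistical structure the analysis assumes, not
real genomes:

* **Genome** — a few megabase-scale chromosomes (default 3 + 2 Mb); gene
  bodies (log-normal lengths, median 8 kb) and CpG islands (median 1 kb)
  packed without mutual overlap for interpretability. Real genomes overlap
  these features; nothing downstream depends on disjointness, it just makes
  planted truths unambiguous.
* **Peaks and tags** — log-normal peak lengths (median 500 bp) and
  negative-binomial tag counts (mean 50, dispersion 5; over-dispersed, as
  sequencing counts are). Each peak is placed fully inside the target
  annotation with probability $q$ (the planted tag-mass fraction) and fully
  inside its complement otherwise, so the expected tag-mass fraction inside
  the annotation is exactly $q$ and the enrichment ratio recovers $q/f$ for
  an annotation covering fraction $f$. Tag alignments are placed uniformly
  within their peak.
* **Expression** — FPKM follows a log-linear link on standardized log
  density with configurable slope and noise; the probability of a gene being
  up-regulated rises with density at a configurable strength, so both the
  expression-by-bin gradient and the bin-by-class association are plantable,
  and setting both links to zero gives exact nulls for calibration tests.
* **Cancer cohort** — loss genes carry gene-body peaks in both normal
  samples only, gain genes in both tumors only, half the background in all
  four; a chosen subset of each planted list receives a true expression
  shift (default 8-fold, log-sd 0.2, 12 samples per group), which makes the
  planted concordance counts recoverable.
* **TAB-seq** — clone counts drawn binomially from planted
  (C, 5-mC, 5-hmC) triples per condition.

All generators are deterministic under a seed and emit files the package's
own readers consume (round-trip tested). What passing tests on these data do
**not** show: robustness to mappability artifacts, GC bias, copy-number
distortion of tag counts, overlapping transcript structure, or peak-caller
noise — none of which the generator models.

# Problem sizes and tolerances

The test suite runs the enrichment calibration on 1–5 Mb genomes with
hundreds to thousands of peaks and 200–1,000 shuffles, the association
type-I check over 1,000 simulated expression tables of 2,000 genes, and the
TAB-seq recovery over 1,000 simulated sites at 200 clones; these sizes give
Monte-Carlo error comfortably inside the asserted bands (e.g. the uniform-
placement check uses 2,000 peaks per seed so the statistic's own sampling
coefficient of variation is about 2%, well inside the ±10% band asserted).
Oracle-equivalence checks (per-base accumulation, exhaustive rank-sum
enumeration, textbook chi-squared) assert agreement at $10^{-9}$ tolerance.

# A worked example

```{r example, eval = FALSE}
cfg <- sim_config(seed = 1, annotation_fraction_q = 0.5)
gen <- simulate_genome(cfg)
pt <- simulate_peaks_and_tags(cfg, gen$islands, gen$sizes)
enrichment_test(pt$peaks, gen$islands, gen$sizes,
                n_shuffles = 1000, seed = 1)
```

Half the tag mass planted in islands covering a few percent of the genome
yields an enrichment ratio far above 1 with the minimal attainable p of
1/1001; `run_pipeline(list(seed = 1))` chains all stages and writes every
intermediate as a headered TSV/BED with a manifest.

# Known limitations

* The shuffle null does not exclude assembly gaps or match GC/mappability; a
  configurable exclusion list can be emulated by restricting chromosome
  sizes, but no gap-aware null is offered.
* Gene quantification is interval-based; spliced transcript structure is not
  modeled, and tags are treated as single intervals (fragment-level counting
  is not distinguished).
* Consensus overlap is descriptive; no significance model is attached to
  overlap fractions.
* The differential-expression model itself is an input; the built-in
  generator's convenience fold changes are for synthetic data only.
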