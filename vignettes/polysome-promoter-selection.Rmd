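---
title: "Comparing CAGE-defined 5' ends between translatome and transcriptome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing CAGE-defined 5' ends between translatome and transcriptome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polycage)
```

## The problem

Mammalian genes initiate transcription from many positions: a single gene
commonly drives transcription from several *core promoters*, and within each
core promoter from a distribution of individual transcription start sites
(TSSs). CAGE (Cap Analysis of Gene Expression) maps these 5' ends at
single-nucleotide resolution by sequencing short (27 nt) tags anchored at the
mRNA cap. Because the 5' UTR controls translation initiation — scanning,
upstream AUGs, secondary structure — the choice of TSS is not neutral for
protein output. `polycage` asks the downstream question: when the same cell's
RNA is split into a *translatome* (polysome-associated RNA, i.e. transcripts
being translated) and a *transcriptome* (total RNA), do polysomes engage all
5' isoforms equally, or do they select among TSSs, core promoters and genes?

The package implements the complete comparison as composable stages:

1. **Tag clustering** — overlapping same-strand 27-nt tags are merged
   (single-linkage) into tag clusters (TCs), each a proxy for a core
   promoter.
2. **Promoter annotation** — each TC is placed by its representative TSS
   into 5'UTR / 3'UTR / CDS / intron / intergenic with a fixed priority.
3. **Shape classification and disparity** — TCs are classified into four
   promoter-architecture classes and matched across conditions; matched
   pairs are tested for a change in the 5'-end distribution.
4. **Differential usage** — per-TC abundance changes and per-gene selection
   scores ($S_{fc}$, $S_{du}$).
5. **Sequence features** — GC content, AUG counts and TATA-box enrichment
   in 100-nt windows around representative TSSs of enriched, depleted and
   control TCs.
6. **Synthetic data** — a generator that emulates all of the structure
   above with a truth key, used throughout the test suite.

## Models and statistics

### The Poisson background model behind the four-tag rule

A tag set of $n$ tags spans at most $(n-1)\times 27$ nt. If $T$ mapped tags
were scattered uniformly over a genome of length $N$, the count falling in
such a window would be Poisson with

$$\lambda = \frac{(n-1)\times 27}{N}\, T .$$

`poisson_pvalue()` returns $P(X \ge n)$. With $N$ the human GRCh37 length
(3,095,693,983 nt) and $T \approx 7\times10^6$, $P(X\ge 4) \approx
4\times10^{-5} < 0.001$, which is why clusters are required to hold at least
four tags (`min_tags = 4`): the rule is a global justification, not a
per-cluster filter, and the per-cluster p-value is reported rather than used
to drop anything. On small synthetic genomes the bound can legitimately fail
(with $N \sim 2.5\times10^7$ and $T \sim 10^6$, $\lambda$ is no longer
tiny); `cluster_tags()` then warns instead of failing, because the four-tag
rule remains the operative definition.

### Shape classes

TCs with at least 100 tags are classified, criteria evaluated strictly in
order, first match wins:

* **SP** — 25th–75th percentile distance < 4 nt, *or* 15th–85th < 6 nt;
* **DP** — highest/second-highest single-position peak ratio > 2 and the
  highest peak > 20% of tags;
* **MP** — all consecutive peaks holding > 15% of tags are > 5 nt apart
  (at least two such peaks);
* **BP** — everything else.

Percentiles are *nearest-rank* values on the tag-weighted position multiset
(positions are integers; interpolation would manufacture fractional
coordinates). Ties at the representative TSS (the argmax position) break to
the 5'-most coordinate, which favours the longest 5' UTR and is therefore
conservative for downstream-AUG arguments; the rule is symmetric on the
minus strand.

### Distribution disparity

Matched TC pairs (same-strand span overlap, many-to-many overlaps resolved
greedily by shared-position tag mass) with $\ge 100$ tags on both sides are
compared with a two-sample Kolmogorov–Smirnov test in which each tag is one
sample point. The statistic is computed on weighted ECDFs; the p-value uses
the asymptotic Kolmogorov series
$Q(x) = 2\sum_{k\ge1}(-1)^{k-1}e^{-2k^2x^2}$ at
$x = \sqrt{n_a n_b/(n_a+n_b)}\,D$. Positions are discrete, so ties are
ubiquitous; with heavy ties the asymptotic test is conservative, which the
suite verifies by Monte-Carlo (0 rejections in 2000 null pairs at
$p<0.001$) while retaining sensitivity 1.0 for 6-nt shifts at 500 tags per
side. Both the raw p threshold (0.001, the operative call) and BH-adjusted
q-values are reported.

### Differential abundance and the two scores

Abundance is normalized as RPM (reads per million mapped). Per-TC change is
$FC = \mathrm{RPM}_{translatome}/\mathrm{RPM}_{transcriptome}$, called
significant at $|\log_2 FC|\ge 1$ and $p<0.05$. The p-value is an exact
two-sided binomial test of the translatome count $k_1$ against $k_1+k_2$
with success probability $T_1/(T_1+T_2)$ — the natural exact test for two
libraries without replicates, reproducible and verifiable against direct
tail summation. Replicate-aware dispersion modelling is deliberately out of
scope: the design has one library per condition.

Per gene, with promoter abundances $(p_i, t_i)$:

$$E_p=\sum_i p_i,\quad E_t=\sum_i t_i,\quad S_{fc}=\frac{E_p}{E_t},\quad
S_{du}=\frac12\sum_i\left|\frac{p_i}{E_p}-\frac{t_i}{E_t}\right|.$$

$S_{du}$ is half the $L_1$ distance between usage-proportion vectors:
0 when proportions agree, 1 when the supported promoter sets are disjoint,
and defined only for genes with $\ge 2$ promoters and positive abundance on
both sides. $S_{fc}$ significance is tested on summed raw counts (tests
need counts; the reported ratio uses RPM). A gene's promoter list is its
matched 5'UTR-assigned TC pairs, with unmatched single-sample 5'UTR TCs
entering as zero on the absent side — without those, the disjoint-support
case $S_{du}=1$ would be unreachable.

## The synthetic generator

`simulate_cage()` draws a complete dataset — genome FASTA, GTF, two CTSS
tables — plus a truth key. Design choices, fixed once:

* **Scale.** Defaults: 10,000 genes with 1–3 promoters each
  (probabilities 0.35/0.30/0.35, ≈2×10⁴ TCs) and 10⁶ tags per condition,
  on a ~25-Mb i.i.d. random genome. A full dual-condition run of the
  pipeline on this takes about two minutes on one CPU; the test suite uses
  smaller configurations (120–300 genes) where the question does not
  require scale.
* **Emitters.** SP concentrates 85% of mass on the anchor (spread ≤2 nt);
  DP adds a 30% anchor peak over a ±15-nt floor; MP has two 25% peaks 8 nt
  apart over a broad floor; BP is a discretized normal with sd 8 nt
  truncated at ±16. Each satisfies its own classification criterion in the
  infinite-tag limit, so shape recovery is a real test of the classifier
  under multinomial noise, not a tautology.
* **Effects.** Abundance effects are planted at *gene* level (40% of genes,
  $|\log_2 FC| \in \{1,2,3\}$, random sign); usage effects independently at
  gene level (30% of multi-promoter genes get log-normal promoter-share
  multipliers, renormalized so the gene total is untouched). This
  separation is what makes the near-zero correlation between $S_{du}$ and
  $S_{fc}$ a meaningful check rather than an artifact. 30% of promoters
  additionally have their translatome distribution shifted 6 nt downstream
  (the disparity signal).
* **Sequence context.** Anchor bases follow a planted composition
  (A/C/G/T = 0.30/0.20/0.40/0.10, a CAGE-like purine-skewed initiator);
  TATAAAA is planted 30–24 nt upstream of enriched promoters at rate 0.4
  versus 0.02 elsewhere; downstream 100-nt windows are AT-shifted for
  enriched and GC-shifted for depleted promoters (GC 0.35/0.45/0.55).
  These make the sequence-feature stage recoverable without any external
  genome.
* **Truth key.** Promoters that fail to emit ≥4 tags in both conditions are
  removed from the truth table (their tags remain in the data), so every
  truth entry is testable by construction.

What the generator does **not** emulate: mapping artifacts and
mappability gaps, G-addition bias (the optional `g_correction()` stage is
exercised on constructed inputs instead), overlapping genes on opposite
strands, correlated biological replicates, and realistic promoter sequence
beyond the planted features. Passing recovery tests therefore demonstrates
the pipeline's statistical behaviour under its own model assumptions, not
performance on real libraries.

## Numerical and degenerate-input choices

* Coordinates are 1-based and closed throughout, matching CTSS, GTF and
  IRanges conventions; no conversion layer exists to get wrong.
* On the minus strand a tag body spans the 27 nt *ending* at the 5'-end
  coordinate (CAGE reads run 5'→3' from the cap).
* `poisson_pvalue(1, ...)` is exactly 0 (a single tag spans a zero-length
  window, $\lambda = 0$).
* A TC whose second peak is absent has peak ratio $\infty$ and classifies
  as DP if the single peak clears 20% (it will already have been caught by
  SP in practice).
* In `tc_diff()`, clusters present in only one sample are statuses of their
  own (`translatome_only` / `transcriptome_only`) with undefined FC; pairs
  with zero counts on both sides are excluded.
* `s_du()` returns NA (not 0) for single-promoter genes: the score is
  defined by construction on multi-promoter genes, and reporting 0 would
  conflate "no usage change" with "nothing to compare".
* Fisher odds ratios with an empty off-diagonal are reported as `Inf`
  rather than the conditional-MLE estimate, keeping the "all query genes in
  one family" case legible.
* BH adjustment is delegated to `stats::p.adjust(method = "BH")` behind a
  range-validating wrapper.

## A short worked example

```{r example, eval = FALSE}
cfg <- sim_config(seed = 42, n_genes = 300, library_size = 60000)
sim <- simulate_cage(cfg, out_dir = "sim")
conf <- list(ctss_translatome = sim$files$ctss_translatome,
             ctss_transcriptome = sim$files$ctss_transcriptome,
             annotation = sim$files$annotation,
             genome = sim$files$genome,
             out_dir = "run")
res <- run_all(conf)
summary(res)
truth_compare(res, sim$truth)$shape_confusion
```

## Known limitations

* The KS p-value is asymptotic; for very small clusters near the 100-tag
  threshold it is conservative under ties. The stringent operative
  threshold (p < 0.001) absorbs this; users needing exact small-sample inference
  should raise the tag threshold.
* 5'UTR length is a genomic-coordinate distance from the representative
  TSS to the start codon; introns inside the 5' UTR are not subtracted.
  Length *differences* between conditions, the quantity of interest, are
  unaffected whenever both representative TSSs fall in the same exon.
* Cluster matching is greedy maximum-shared-mass, not a globally optimal
  assignment; with the spacing of real promoters the difference is
  negligible, and the resolution rule is deterministic.
* Gene assignment of a promoter prefers the transcriptome annotation when
  the two samples' 5'UTR assignments disagree.
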