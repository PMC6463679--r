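# polycage

Compare the 5' ends of transcripts between a **translatome**
(polysome-associated RNA — transcripts engaged in translation) and a
**transcriptome** (total RNA) profiled by CAGE. The package is for
transcriptomics researchers who have per-sample CTSS tables (CAGE 5'-end
positions with tag counts) for the two conditions and want to know whether
the translation machinery selects among transcription start sites, core
promoters and genes — and what distinguishes the selected ones.

## What it computes

**Tag clustering.** Same-strand 27-nt tags whose bodies overlap are merged
(single-linkage) into tag clusters (TCs), the unit standing in for a core
promoter. Clusters need at least 4 tags, a threshold justified by a Poisson
background model: a tag set of *n* tags spans at most (*n*−1)×27 nt, so
under uniform background the count in it is Poisson with

&nbsp;&nbsp;&nbsp;&nbsp;λ = (*n*−1)·27/*N* · *T*

(*N* genome length, *T* mapped tags), and P(X ≥ 4) < 0.001 at human-genome
scale.

**Promoter architecture.** Each TC's representative TSS (its modal
position) places it into 5'UTR > 3'UTR > CDS > intron > intergenic
(5'UTRs include 100 nt upstream). TCs with ≥100 tags are classified into
four shape classes — SP (single sharp peak), DP (broad, one dominant peak),
MP (multi-peak), BP (generally broad) — by ordered interquantile-width and
peak criteria.

**Selection tests.** Matched TC pairs are tested for 5'-end distribution
disparity with a tag-weighted two-sample Kolmogorov–Smirnov test
(p < 0.001). Per-TC abundance change is FC = RPM_translatome /
RPM_transcriptome with an exact two-library binomial test (significant at
|log₂FC| ≥ 1, p < 0.05). Per gene, with promoter abundances (pᵢ, tᵢ):

&nbsp;&nbsp;&nbsp;&nbsp;E_p = Σpᵢ, E_t = Σtᵢ, S_fc = E_p/E_t,
S_du = ½ Σ|pᵢ/E_p − tᵢ/E_t|

S_du ∈ [0,1] measures differential core-promoter usage (1 = disjoint
promoter support between conditions), independent of the fold-change score
S_fc. Sequence features (GC, AUG counts, TATA-box enrichment) are compared
across top-enriched, top-depleted and FC≈1 control TCs.

**Synthetic data.** `simulate_cage()` generates a full two-condition
dataset (genome FASTA, GTF, CTSS tables) with a truth key — planted shapes,
fold changes, distribution shifts, usage effects and sequence context — so
every stage is testable end to end.

## Worked example

```r
library(polycage)

cfg <- sim_config(seed = 42, n_genes = 300, library_size = 60000)
sim <- simulate_cage(cfg, out_dir = "sim")
res <- run_all(list(ctss_translatome = sim$files$ctss_translatome,
                    ctss_transcriptome = sim$files$ctss_transcriptome,
                    annotation = sim$files$annotation,
                    genome = sim$files$genome,
                    out_dir = "run", seqfeat_k = 20))
summary(res)
#> Tag clusters: 564 translatome / 589 transcriptome
#> 5'-end distribution disparity: 78 pairs tested, 42.3% changed
#> Differential clusters: 53.1% with significant RPM change
#> Genes: 300 scored, 146 significantly enriched/depleted
#> cor(S_du, S_fc) = -0.116
```

Reading: of the 563 matched cluster pairs, 78 had ≥100 tags on both sides
and qualified for the KS disparity test; 42.3% of those changed their
5'-end distribution (the generator planted shifts in 30% of promoters plus
gene-level effects). 146 of 300 genes changed abundance significantly
(40% of genes carry planted effects). Checking against the truth key:

```r
truth_compare(res, sim$truth)$shape_confusion
#>      predicted
#> truth SP DP MP BP
#>    SP 50  0  0  0
#>    DP  0 40  0  0
#>    MP  0  0 24  1
#>    BP  0  0  0 60
```

Shape recovery is essentially diagonal; fold-change estimates are unbiased
(bias 0.002, RMSE 0.35 log₂ units), disparity sensitivity is 1.00 at
empirical FDR 0.036, and per-gene S_du is recovered with mean absolute
error 0.059.

`run_all()` writes TSV tables (`disparity.tsv`, `utr_lengths.tsv`,
`tc_diff.tsv`, `gene_scores.tsv`, `s_du.tsv`, `seqfeat.tsv`) with `#`
provenance headers. A thin shell front-end with the same stages lives at
`inst/scripts/polycage`.

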