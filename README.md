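# paradoxcna

Integrative discovery of **paradoxical genes** — genes whose consensus
tumor-vs-normal differential expression runs *opposite* to the copy-number
aberration of the region they reside in — and attribution of their
deregulation to consistently deregulated microRNAs.

The package is aimed at cancer genomics analysts integrating heterogeneous
copy-number (aCGH/SNP-array) call sets with multi-cohort expression data.
Amplified genes are expected up and deleted genes down; the reproducible
exceptions are usually discarded as noise, yet when the same inversion
recurs across cohorts — and inside the individual samples that carry the
aberration — it points to an active override of gene dosage, with
miRNA-mediated repression as the prime suspect.

## What it computes

1. **CNA integration** — heterogeneous probe sets are placed on *anchors*
   (the union of all probe boundaries); per-anchor gain/loss recurrence is
   tested by a per-sample permutation null that preserves each sample's
   aberration burden; significant anchors merge into aberrant regions.
2. **Rank meta-analysis** — per-cohort Welch/BH differential rankings are
   combined by robust rank aggregation: for sorted normalized ranks
   `r_(1) <= ... <= r_(n)`,

   `rho = min_k P(at least k of n uniforms <= r_(k))`, `p = min(1, n * rho)`,

   with leave-one-out correction (`p_loo` = mean of the p-values obtained
   excluding each input list in turn).  Genes are called at `p_loo < 0.01`,
   miRNAs (from ranked study lists) at `p_loo < 0.05`.
3. **Paradox classification and validation** — significant genes map to
   regions by overlap; a gene is paradoxical when expression direction ×
   region direction = −1 (association summarized by a 2×2 chi-square).
   Per matched tumor sample, a *paradoxical event* is deregulation beyond
   z = ±1.647 co-occurring with copy number beyond ∓0.2 log2 on the
   opposite side; the excess `T = f_paradox − f_regular` is validated by a
   randomization test (CNA labels permuted against z-scores, p < 1e-4).
4. **miRNA association** — strict-tail hypergeometric target-overlap
   enrichment; per-pair partial correlation controlling for the gene's own
   copy number, `r_xy.z = (r_xy − r_xz r_yz) / sqrt((1−r_xz²)(1−r_yz²))`,
   judged against an empirical null of 10⁴ random pairs, and classified
   *explanatory* when the correlation sign matches the deregulation
   directions; per-gene coefficient of multiple correlation
   `C = sqrt(cᵀ R⁻¹ c)` with empirical background percentiles.
5. **Synthetic cohorts** — a seeded generator plants aberrant regions,
   dosage effects, deregulated miRNAs and paradoxical genes whose
   repression overshoots dosage in aberration-carrying samples, so the
   whole pipeline is testable end to end without any downloads.

## Worked example

```r
library(paradoxcna)

res <- run_pipeline(pipeline_config(seed = 1))
print(res$summary)
#> paradoxcna pipeline summary
#>   anchors: 740 (201 significant), aberrant regions: 10
#>   DE genes: 91 (50 up, 41 down); in aberrant regions: 83
#>   association chi-square = 17.3 (p = 3.24e-05)
#>   paradoxical genes: 60, validated: 56
#>   deregulated miRNAs: 11 (5 up, 6 down)
#>   target overlap: 56/56 targeted (p = 0)
#>   miRNA:gene pairs: 616 tested, 92 significant, 82 explanatory (89.1%)
#>   genes in CMC top 5%: 26 (enrichment p = 3.89e-22)
#>   seeds: simulation=1140350788, anchors=312928385, validation=866248189, pairs=1909893419

evaluate_recovery(res)[c("paradox_sensitivity", "paradox_precision",
                         "mirna_sensitivity")]
#> $paradox_sensitivity
#> [1] 0.9333333
#> $paradox_precision
#> [1] 1
#> $mirna_sensitivity
#> [1] 0.9166667
```

Reading the summary: from three simulated CNA datasets the anchor test
finds all 10 planted aberrant regions; the gene meta-analysis calls 91
genes, 83 of which lie in aberrant regions with a strong
dosage–expression association (chi-square p = 3e-05); 60 of them oppose
their region's direction and 56 survive sample-wise randomization
validation.  The miRNA meta-analysis recovers 11 of the 12 planted
deregulated miRNAs; every validated gene is a target of that set, 89% of
the significant CNA-controlled pair correlations are sign-consistent with
the deregulation directions, and validated genes are massively enriched in
the top 5% of the multiple-correlation background.  Against the planted
truth this is 93% sensitivity at 100% precision.

Individual stages are exposed directly (`simulate_cohort()`,
`build_anchor_table()`, `anchor_frequency_test()`, `rank_differential()`,
`aggregate_ranked_lists()`, `identify_paradoxical()`,
`validate_gene_randomization()`, `empirical_pair_test()`,
`multiple_correlation()`, …), read/write the package's TSV/BED/SEG-like
formats (`read_bed()`, `read_seg_calls()`, `read_ranked_list()`, …), and a
thin command-line wrapper lives in `inst/scripts/paradoxcna.R`
(`simulate` and `run` subcommands over a YAML configuration).

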