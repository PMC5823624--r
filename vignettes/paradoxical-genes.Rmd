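---
title: "Discovering paradoxical genes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering paradoxical genes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paradoxcna)
```

## The problem

Integrating tumor copy-number profiles with tumor-vs-normal expression
usually confirms the expected dosage relationship: amplified regions carry
over-expressed genes, deleted regions under-expressed ones.  A reproducible
minority of genes defies it.  These *paradoxical genes* -- consistently
downregulated genes sitting inside recurrent gains, or consistently
upregulated genes inside recurrent losses -- are easy to dismiss as noise,
but when the same inversion recurs across independent cohorts, and within
individual samples that demonstrably carry the aberration, something must be
actively overriding gene dosage.  microRNA-mediated repression is a natural
candidate: a miRNA deregulated in the tumor, targeting the gene directly or
through mediators, can invert the dosage effect.

`paradoxcna` implements this discovery chain as a reusable, testable
pipeline: (1) integrate heterogeneous CNA call sets and find recurrently
aberrant regions; (2) meta-analyze differential expression across cohorts;
(3) classify deregulated genes in aberrant regions as paradoxical or
regular and validate the paradox per sample; (4) test whether deregulated
miRNAs explain the paradoxical expression.  Because the original patient
cohorts cannot be bundled, the package ships a synthetic-cohort generator
with planted ground truth; every stage is exercised end to end against what
was planted.

## Stage methods

### CNA integration on anchors

Each cohort's copy-number data arrive as probe intervals with per-sample
discrete calls in $\{-1, 0, +1\}$ (pre-called input is the first-class
path; `call_from_log_ratios()` thresholds log2 ratios at $\pm 0.2$ with
*strict* inequalities, so a value exactly at the cutoff is neutral).
Because every platform has its own probe set, probe-level data are not
directly comparable across cohorts.  `build_anchor_table()` therefore takes
as *anchors* the union of all probe starts and ends, assigns to each anchor
and dataset the call vector of the covering probe (half-open containment;
if two probes of one dataset cover an anchor, the shorter -- higher
resolution -- probe wins, ties to the leftmost start), and drops anchors
missing from more than one dataset.

Recurrence is tested by permutation (`anchor_frequency_test()`).  The null
shuffles, independently for every sample, that sample's calls across its
informative anchors.  This preserves each sample's aberration burden -- the
dominant confounder, since genomically unstable tumors inflate every
anchor -- while destroying positional information.  Empirical p-values use
the add-one correction $p = (\#\{T_{perm} \ge T_{obs}\} + 1)/(n_{perm}+1)$,
so $p = 0$ is impossible.  Runs of same-direction significant anchors with
inter-anchor gaps of at most `max_gap` merge into aberrant regions
(`merge_significant_anchors()`); a significant anchor of the opposite
direction interrupts a run.  The merging rule is this package's own choice:
region boundaries are reported at anchor resolution, and the region
frequency is the peak anchor frequency.

The default `n_perm` is $10^4$; large production runs conventionally use
$10^6$.  With the add-one correction the attainable p-value floor is
$1/(n_{perm}+1)$, so $10^4$ comfortably resolves the 0.05 significance
level used for anchors.

### Rank meta-analysis

Within each expression cohort, `rank_differential()` scores every gene with
the Welch two-sample statistic (tumor vs normal), adjusts p-values by
Benjamini-Hochberg, splits genes by the sign of the mean difference, and
ranks each direction by adjusted p (ties by absolute difference, then id).
A moderated-variance statistic would be customary for small microarray
cohorts, but the meta-analysis consumes only *ranks*, which are insensitive
to the exact per-cohort statistic, and the plain Welch form keeps the stage
dependency-free.

`aggregate_ranked_lists()` combines the per-cohort rankings by robust rank
aggregation.  For a feature with normalized ranks $r_{(1)} \le \dots \le
r_{(n)}$ across the $n$ lists where it is measured, the score is

$$\rho = \min_k \; \beta_k, \qquad
  \beta_k = \sum_{j=k}^{n} \binom{n}{j} r_{(k)}^j (1-r_{(k)})^{n-j},$$

the probability that at least $k$ of $n$ independent uniforms fall at or
below $r_{(k)}$; the p-value is the Bonferroni-style $\min(1, n\rho)$.
Features measured in a cohort but absent from a direction's list receive
the worst normalized rank 1 there -- dropping them instead would bias
toward features reported by few studies.  Features not measured in a cohort
(platform dropout) simply reduce $n$.  For full rankings the normalization
denominator is each cohort's own universe; for truncated published lists
(the miRNA meta-analysis) it defaults to the union of all studies'
features, since platform sizes are unknown.

Stability is enforced by leave-one-out correction: the aggregation is
repeated once per input list with that list excluded, and the resulting
p-values are averaged into `p_loo`.  A single dominant study therefore
cannot carry a feature.  Genes are called at `p_loo < 0.01`, miRNAs at
`p_loo < 0.05`.  A feature nominally significant in both directions keeps
the direction with the smaller `p_loo`; exact ties are excluded and logged.

### Paradox classification and sample-wise validation

`assign_genes_to_regions()` maps genes to aberrant regions by interval
overlap ($\ge$ 1 base); a gene overlapping both directions takes the larger
total overlap, with exact ties unassigned.  The association between
aberration direction and expression direction over all significant genes in
regions is summarized by the Pearson chi-square (1 df, no continuity
correction).  A gene is *paradoxical* when its consensus expression
direction times its region direction is $-1$.

Sample-wise validation works on a matched cohort carrying expression,
per-gene log2 copy number and miRNA expression for the same tumor samples.
Expression is standardized against the normal samples,
$z_{gs} = (x_{gs} - \bar{x}_g^{N}) / s_g^{N}$ (`zscore_expression()`); the
all-sample alternative is available but mixes tumor heterogeneity into the
reference.  For each paradoxical gene, a sample shows a *paradoxical event*
when it is deregulated on the gene's consensus side ($|z| > 1.647$; the
threshold is used exactly as conventionally printed, not rounded to the
normal-quantile 1.645) while its copy number lies beyond $\mp 0.2$ on the
*opposite* side, and a *regular event* when the copy number lies on the
same side.

`validate_gene_randomization()` tests the excess
$T = f_{paradox} - f_{regular}$ against the null that the gene's CNA vector
is randomly permuted against its z-scores.  Under such a permutation the
numbers of opposite-side and same-side CNA categories landing on the
deregulated samples follow a multivariate hypergeometric distribution, so
the null is sampled exactly with sequential hypergeometric draws -- the
distributional equivalent of materializing label permutations, verified
against exhaustive enumeration in the test suite.  Validation requires
$p < 10^{-4}$ (add-one-corrected, so `n_rand` defaults to $10^5$) *and*
$f_{paradox} > f_{regular}$.

### miRNA association

Three complementary analyses connect the deregulated miRNA set to the
validated paradoxical genes:

* **Target overlap** (`target_overlap_test()`): hypergeometric enrichment
  of targets of the deregulated miRNAs among the validated genes, against
  the meta-analysis universe as population.  Tails are *strict*,
  $P(X > \text{observed})$: with population 15,323, successes 7,836, draws
  70 and overlap 46 this convention reproduces the conventionally reported
  4.8e-3 (the inclusive tail gives 9.6e-3).
* **Pair correlations** (`empirical_pair_test()`): for each (deregulated
  miRNA, validated gene) pair, the first-order partial correlation
  $r_{xy \cdot z} = (r_{xy} - r_{xz} r_{yz}) /
  \sqrt{(1-r_{xz}^2)(1-r_{yz}^2)}$ across tumor samples, controlling for
  the gene's own copy number $z$ -- the confounder that would otherwise
  produce dosage-driven co-expression.  The continuous log2 value is used
  as the control when available, the discrete call otherwise.  Significance
  is empirical: two-sided comparison against the same measure over $10^4$
  random (gene, miRNA) pairs drawn from the full universes (excluding the
  tested pair), with add-one tails.  A significant pair is *explanatory*
  when the sign of its correlation matches the product of the deregulation
  directions -- positive for same-direction deregulation, negative for
  inverse.
* **Multiple correlation** (`multiple_correlation()`, `cmc_percentile()`):
  per gene, $C = \sqrt{c^\top R^{-1} c}$ with $c$ the gene:miRNA Pearson
  correlations and $R$ the miRNA correlation matrix -- the correlation
  between the gene and its best linear prediction from the deregulated
  miRNAs *en bloc*.  If $R$ is singular or $C^2$ leaves $[0,1]$ beyond
  numerical tolerance ($10^{-8}$), the least-squares pseudo-solution is
  used, clipped, with a condition-number warning.  Each validated gene's
  $C$ is ranked against the all-gene background; genes at or above the 95th
  percentile are reported with a strict-tail hypergeometric enrichment p
  (successes: the floor of 5% of the background).

## The synthetic cohort generator

`simulate_cohort()` emulates the multi-cohort study design with planted,
recoverable truth.  The default configuration -- the package's reference
study conditions -- is: 2,000 genes on 5 chromosomes of 100 Mb; 10 aberrant
regions of 10 Mb (alternating gain/loss) carried by each tumor with
probability 0.4, background call rate 0.01; 3 CNA call datasets of 60
tumors on independent ~2 Mb probe grids with 25% boundary jitter; 4
expression cohorts of 60 tumors / 15 normals with 5% per-cohort gene
dropout; 40 miRNAs of which 12 deregulated (half up, half down, tumor
shift 1.5 log-units); 60 planted paradoxical genes; dosage effect
$\alpha = 0.5$ log-units per call unit, repression scale $\beta = 1$,
expression noise 0.5.

Tumor expression of gene $g$ in sample $s$ is

$$x_{gs} = \mu_g + \alpha \, \mathrm{call}_{gs}
  - \mathrm{repression}_{gs} + \varepsilon_{gs},$$

where the planted repression of a paradoxical gene decomposes into:

* a **programmed mean**: $r_0 = 0.5\,\sigma\beta$ in tumors not carrying
  the aberration and $r_1 = \alpha + r_0 + 4\sigma\beta$ in carrier
  samples, pushing the gene in the direction opposite to its region.  The
  carrier overshoot is the substantive modeling commitment: the phenomenon
  being emulated is precisely that samples carrying the gain still show the
  gene down (and vice versa), which is what the sample-wise randomization
  test measures.  A generator without this clonal coupling would produce
  cohort-level inversion with *no* per-sample co-occurrence excess, and the
  validation stage would (correctly) reject everything.  $r_0$ is raised
  automatically if needed so the cohort-mean inversion is at least
  $2\sigma$, the planted-effect floor the generator guarantees.
* a per-edge **tracking** of each regulator miRNA's expression fluctuation
  around its tumor mean, with coupling SD $0.9\,\sigma\beta$ -- the
  per-sample covariance that the CNA-controlled partial correlation and the
  CMC measure.  Keeping tracking uniform across samples (rather than
  boosting it in carriers) matters: carrier-concentrated *noise* would
  inflate carrier z-score variance and blur the co-occurrence contrast.

Each paradoxical gene receives 1-2 regulator miRNAs deregulated in its
region's direction (an upregulated miRNA represses a gene down inside a
gain, and so on).  Deregulated miRNAs additionally target ~25 background
genes outside aberrant regions with weak coupling (0.1 log-units per
log-unit), and neutral miRNAs target arbitrary non-paradoxical genes --
together these populate the target network realistically so that the
overlap test and the CMC background are non-trivial.

Ranked miRNA study lists emulate 9 published studies: each planted miRNA
is reported by a study with probability 0.8 (the detection rate), ranked by
a latent per-miRNA prominence ($N(2, 0.5)$, drawn once) plus per-study
noise ($N(0, 0.4)$) -- real study rankings are correlated because the
underlying effect sizes are shared -- and padded with a Poisson(2) number
of false-positive miRNAs at unremarkable scores.  The deregulated set size
(12 of a 40-miRNA universe) is the ~20-fold scale-down of the motivating
study design; with per-direction lists of ~6 entries the bottom-ranked
planted miRNA keeps a normalized rank the order-statistic score can
recover from five detections upward, which is what makes the stated
recovery target attainable at all under a 0.8 detection rate.

Matched per-gene log2 CNA values for the validation cohort are drawn
around class means $\{-0.5, 0, +0.58\}$ (the log2 of 1.5 and 3 copies
against 2) with SD 0.1; the same class means drive the generator's
log-ratio mode for exercising the threshold caller.

All randomness flows from a single seed through named per-stage sub-seeds,
so generators can be called independently yet stay mutually consistent,
and identical configurations are byte-identical.

**What the generator does not emulate:** probe-level microarray noise
(expression is simulated directly on the log scale, since the pipeline
consumes summarized matrices), segmentation noise and wavy baselines in
aCGH data, subclonal or allele-specific copy number, miRNA target
competition, and any survival structure.  Passing recovery tests therefore
demonstrates that the pipeline's inference machinery is correct and
calibrated under its stated model -- not that real cohorts satisfy that
model.

## Numerical and design choices

* Coordinates are 0-based half-open everywhere (BED native); SEG-like
  files carry the convention in a header comment.  A single convention
  eliminates off-by-one drift between stages.
* Strict inequalities at every threshold: calls at exactly $\pm 0.2$ are
  neutral, z-scores at exactly $\pm 1.647$ are not deregulated, and
  hypergeometric tails are $P(X > k)$.
* All Monte-Carlo p-values are add-one corrected; reported p-values can
  never be zero and every test's attainable floor is explicit in its
  `n_perm`/`n_rand`/`n_null`.
* Gene-to-region ties (equal overlap in both directions) and
  direction-ties in the meta-analysis are excluded and logged rather than
  broken arbitrarily.
* miRNA identifier normalization is lowercase plus arm-suffix stripping,
  deliberately shallow; full alias resolution is a database concern out of
  scope.
* Degenerate inputs are flagged, not silently patched: constant reference
  genes get missing z-scores, collinear controls give missing partial
  correlations, and an ill-conditioned $R$ in the CMC triggers the
  pseudo-solution path with a warning.

## Problem sizes used by the test suite

The unit suite runs on purpose-built small fixtures (hundreds of genes,
tens of samples).  Calibration checks use 999-permutation /
999-randomization nulls over ~1,000 independent units each, bounding
false-positive rates by the nominal level plus three Monte-Carlo standard
deviations.  End-to-end recovery runs the full reference conditions for
three seeds with `n_perm` $10^4$, `n_rand` $10^5$ and `n_null` $10^4$;
these sizes resolve every significance level the pipeline uses while
keeping a complete run under a minute on one core.  The same conditions
back `scripts/acceptance.R`.

## Known limitations

* The anchor permutation preserves per-sample burden but not local
  correlation along the genome; p-values at neighboring anchors are
  dependent, which region merging absorbs but does not model.
* The per-sample randomization validation conditions on the observed
  deregulation calls; it tests co-occurrence excess, not effect size.
* With ~19 predictors and 60 samples the CMC is substantially inflated by
  fitting noise; the empirical background percentile (not the absolute
  value of $C$) is the meaningful quantity.
* Welch ranking assumes roughly log-scale expression; counts should be
  transformed upstream.
* The union-universe normalization for truncated miRNA lists is one
  defensible reading of an under-specified step; `universe = "per_list"`
  is available when platform sizes are known.
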