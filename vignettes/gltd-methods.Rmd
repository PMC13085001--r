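---
title: "Detecting gene-length-dependent transcriptional decline: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting gene-length-dependent transcriptional decline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gltdseq)
```

## The phenomenon and the statistic

Bulk RNA-seq studies of stressors — early-life stress among them — often find
that *individual* differentially expressed genes replicate poorly across
cohorts while a *global* pattern replicates well: short genes are
preferentially up-regulated and long genes preferentially down-regulated.
This gene-length-dependent transcriptional decline (GLTD) is quantified here
as follows.

1. **Universe.** All abundantly expressed genes: TMM-normalized abundance
   above 1 CPM, averaged over samples (typically > 10,000 genes in a
   12,000-gene expressed universe).
2. **Binning.** Genes are sorted by genomic length (the annotated gene span,
   end − start + 1) and cut into consecutive bins of exactly 500 genes,
   anchored so the *longest*-gene bin is complete; the incomplete bin of
   shortest genes is discarded. Ties in length are broken by gene id so the
   partition is reproducible.
3. **Direction ratio.** In each bin, the up-ratio is
   $n_{up} / (n_{up} + n_{down})$, where direction is the sign of the
   per-gene log2 fold change (ELS vs control). Genes with a fold change of
   exactly zero carry no direction. Bins with an empty denominator are
   dropped, never imputed.
4. **Regression.** Ordinary least squares of the up-ratio on
   $\log_{10}(\text{mean bin length})$. The slope, the Pearson correlation
   $r$, and $t = r\sqrt{df/(1-r^2)}$ with $df = n_{bins} - 2$ are reported.
   A negative slope is the decline signature.
5. **Cohort comparison.** The bin-level model
   `up_ratio ~ log10(length) * cohort` is compared with its no-interaction
   reduction by ANOVA (do slopes differ?), and the reduced model's common
   slope is the pooled cross-cohort estimate. A random-intercept version is
   deliberately not fitted: with two cohorts there is no basis for
   estimating a cohort variance component, so the cohort term enters as a
   fixed effect.

Two single-gene corroborations accompany the bin statistic: a Mann-Whitney
test comparing the lengths of significantly up- versus down-regulated genes
(exact when both groups have at most eight genes and lengths are untied,
normal approximation with tie correction otherwise), and — across cohorts —
the fraction of reference-cohort DEGs whose fold-change sign is preserved,
with an exact binomial test against 0.5.

### Which genes feed the ratio?

The per-bin ratio uses the fold-change sign of **every** binned gene by
default (`mode = "all_genes"`), not only the significant ones. The reason is
arithmetic: a cohort with a few dozen DEGs spread over 20+ bins of 500 genes
would leave nearly every bin without a defined ratio, so a dense
ratio-versus-length profile can only come from nominal directions.
`mode = "deg_only"` is available for the sparse variant, and an unbounded
odds variant `n_up/n_down` is exposed behind `ratio = "odds"`; the bounded
fraction is the default because it degrades gracefully in extreme bins.

### Two normalizations, two jobs

Median-of-ratios feeds differential expression; TMM (trimmed mean of
M-values, 30% M-trim and 5% A-trim per tail, precision weights, factors
rescaled to geometric mean 1, reference chosen by the upper-quartile rule)
feeds only the abundance filter that defines the bin universe. "TMM above 1"
is read as TMM-normalized **CPM** above 1, averaged over samples — the
conventional abundance reading; both the threshold and the aggregation
(`mean` vs `all`) are arguments. The two schemes are kept strictly separate
because they answer different questions (between-sample scaling for testing
vs abundance on a library-independent scale).

## The differential-expression surrogate

The DE caller is a deliberately transparent per-gene NB Wald test: group
means on the normalized scale; a method-of-moments dispersion pooled across
the two groups (floored at $10^{-8}$); `log2fc = log2((m_t + 0.5)/(m_c +
0.5))` with a configurable pseudo-count; a delta-method standard error from
the NB variance $\mu/s + \alpha\mu^2$; a two-sided normal p-value;
Benjamini–Hochberg adjustment. There is no cross-gene dispersion shrinkage,
no outlier replacement and no independent filtering — users who want a
production caller can feed any external DE table through `read_de_table()`
and every downstream stage behaves identically.

Two consequences of this transparency are worth knowing. First, with 4–6
replicates per group the plug-in dispersion makes the statistic behave like
a t on roughly $2(n-1)$ degrees of freedom referred to a normal, so the
gene-level type-I rate at $\alpha = 0.05$ sits near 0.075–0.08 rather than
0.05 (the calibration study in `analysis/06_calibration_study.R` measures
this directly). Second, because this inflation shrinks as $n$ grows, pooled
analyses are *better* calibrated than per-cohort ones; pooling therefore
raises the DEG yield relative to each contributing cohort, but a pooled
count need not exceed the *union* of two small-sample runs, part of which is
miscalibration. The bin-level GLTD statistics are unaffected: their t and F
references are exact at the bin level, and their null rejection rates sit at
5% in the calibration study.

The condition-by-treatment interaction is a contrast of contrasts
($\Delta = \beta_{RU486} - \beta_{vehicle}$, variances added), which keeps
it applicable to externally supplied DE tables; cross-cohort reproducibility
of $\Delta$ uses fixed-effect meta-analysis only (inverse-variance and
equal-weight), since two cohorts cannot support a random-effects variance
estimate.

## Ranking and enrichment

Genes are ranked by the significance-weighted fold change
$\pi = \log_2 FC \times (-\log_{10} p_{adj})$; adjusted p-values of exactly
0, which occur in exported DE tables, are clamped to $10^{-300}$ rather than
rejected. The enrichment score is the signed extremum of the weighted
Kolmogorov–Smirnov running sum (hit weight $|\pi|^w$, $w = 1$ by default;
$w = 0$ recovers the classic KS statistic). The null is **gene-label**
permutation — random same-size subsets of the ranked universe — because the
pipeline may not possess per-sample data when consuming external DE tables.
The permutation p is one-tailed within the observed sign with the plus-one
convention,

$$p = \frac{1 + \#\{|ES_{perm}| \ge |ES|,\ \text{same sign}\}}{1 + \#\{\text{same-sign permutations}\}},$$

so it is never zero, and $NES = ES / \overline{|ES_{perm}|}$ over same-sign
permutations. The leading edge comprises the hits at or before the running-
sum extremum. Defaults follow the cited-practice values: 10,000
permutations, BH correction, set sizes 1–5000 after intersection with the
universe. For universes of at most ten genes the permutation p is verified
against exhaustive enumeration over all same-size subsets in the test suite.

## The synthetic study conditions

Because the underlying cohort data are not public, every stage is validated
against a generator whose defaults *are* the package's reference study
conditions:

| parameter | default | meaning and rationale |
|---|---|---|
| `n_genes` | 12,000 | expressed genes per cohort (post-detection scale of a mouse hippocampus library) |
| `n_per_group` | 6 (4 for the small cohort) | biological replicates per group |
| length distribution | $\log_{10} L \sim N(4.3, 0.6^2)$, clipped to $[10^{2.5}, 10^{6.5}]$ bp | mimics mouse protein-coding genomic spans (20 kb median) |
| `base_mean` | lognormal, meanlog $\log 200$, sdlog 1.5 | deep poly(A) bulk libraries (~7M counted reads/sample) |
| dispersion | Gamma(4, 80), mean 0.05 | isogenic mouse bulk RNA-seq |
| library factors | lognormal, sdlog 0.15 | ±15% library-size variation |
| `de_fraction` | 0.35 | fraction of genes carrying a true effect |
| `effect_scale` | 0.2 | mean of the exponential $|log2FC|$ of affected genes |
| `gltd_slope` ($\beta$) | 1.0 | length bias: $P(\text{up} \mid L) = \text{logistic}(-\beta(\log_{10}L - \overline{\log_{10}L}))$ |

The direction bias enters **only the sign** of affected genes, never the
magnitude, so any length trend in $|log2FC|$ downstream is attributable to
the analysis, not the generator. Length and abundance are generated
independently (the data motivating this package assert nothing about their
correlation).

`de_fraction = 0.35` deserves its own paragraph. The decline signature, as
observed, is a *global* property — per-bin up-ratios move across the 0.5
line over the whole length range — and the mechanistic reading is a broad
constraint on transcriptional capacity rather than a small programmed gene
set. With per-gene effects of mean 0.2 log2 units, an a-priori power
computation fixes how pervasive the response must be for the recovery
benchmark to work at reference scale: the estimated sign of a weakly
affected gene agrees with its true direction with probability
$\approx \Phi(\delta/se)$, which averages $a \approx 0.5$ over
$\delta \sim Exp(0.2)$ at $se \approx 0.2$; the fitted bin-slope is then
$\approx f \cdot a \cdot \beta/4$ against a standard error of
$0.5/\sqrt{N \cdot var(\log_{10}L)} \approx 0.009$, so a fraction
$f \approx 0.35$ is needed for the slope test to detect $\beta = 1$ with
~99% per-seed power (and ≥95/100 seeds overall). Smaller fractions are
scientifically plausible but leave the reference benchmark underpowered;
the fraction is a config field, not a constant.

All randomness flows from one master seed through documented substreams
(`substream_seed()`): universe, effects, counts, gene sets, permutations and
study replicates draw independently, so regenerating one stage never
perturbs another and byte-identical reproduction of a full pipeline bundle
requires only the seed and the configuration.

### What the generator does *not* emulate

Litter structure and other within-group correlation; exon structure,
splicing and reads; correlated (co-regulated) gene modules — counts are
independent across genes given the design; batch effects beyond a scalar
library factor; any RU486 pharmacology (in the synthetic adult cohorts the
two treatment arms are independent draws, so "reversal" is absent by
construction). Passing tests therefore demonstrate that the *statistics*
behave as designed under a faithful NB count model with a known length
bias — not that real hippocampus data satisfy the model's independence
assumptions.

## Numerical choices and degenerate inputs

* Binning requires at least one full bin; the regression requires at least
  three bins with defined ratios and errors (rather than returning `r = 0`)
  when the ratios have zero variance.
* Dispersions below $10^{-12}$ fall back to the Poisson limit in the
  simulator; the Wald test floors its dispersion estimate at $10^{-8}$.
* Size-factor estimation excludes genes with a zero in any sample; if no
  gene survives, the error advises filtering first. TMM trims by the
  published rank rule (`floor(n·trim)+1` from each tail) and short-circuits
  to a factor of 1 when all M-values are numerically zero.
* The expression filter is strictly greater-than: a normalized count of
  exactly 20 does not qualify.
* Gene identifiers are matched exactly and case-sensitively everywhere.
* Ties: ranking ties break by ascending gene id; length ties break by
  ascending gene id; the running-sum extremum takes the first position of
  maximal absolute deviation, preferring the positive candidate on an exact
  tie.

## Problem sizes in the test suite

The heavier checks run at sizes chosen to finish in minutes on one core
while retaining their statistical meaning: parameter recovery at 100 seeds
of the full 12,000-gene reference cohort; null calibration of the slope and
interaction tests at 200 seed pairs of 6,000-gene cohorts (an exact binomial
95% acceptance band around 0.05); the gene-level type-I rate over >20,000
true-null genes in a single large cohort; GSEA oracle equivalence on an
8-gene universe where exhaustive enumeration is feasible; and byte-level
determinism of the full pipeline at 2,000 genes. The calibration driver
(`analysis/06_calibration_study.R`) sweeps $\beta \in \{0, 0.5, 1, 1.5\}$
with 20 replicates each.

## Known limitations

* The DE surrogate's small-sample anticonservativeness (above) is inherent
  to plug-in moment estimation without shrinkage; interpret per-cohort DEG
  *counts* from 4–6 replicates accordingly, or supply external DE tables.
* Gene length is the genomic span; merged-exon length can differ by an
  order of magnitude for long genes. Supply a custom two-column table if
  the exonic definition is wanted.
* The bin regression is unweighted; bins are equally informative by
  construction (equal size), but extreme bins with few direction calls in
  `deg_only` mode would violate that premise — they are dropped instead.
* Gene-label permutation treats genes as exchangeable and ignores
  inter-gene correlation; its p-values are exact for the synthetic
  generator but liberal on strongly co-regulated real data, as for any
  preranked enrichment analysis.
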