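---
title: "Models and methods behind tetherTE"
author: "tetherTE authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind tetherTE}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tetherTE)
```

# Scope

tetherTE quantifies the two complementary experiment families used to study
mRNA-fate regulators such as the yeast Scd6/Dhh1/Dcp2 decapping machinery:

1. **Tethered-function reporter assays** — a candidate repressor fused to
   the MS2 coat protein is recruited to a GFP (or lacZ) reporter mRNA
   carrying MS2 stem-loops; Western densitometry and RT-qPCR then measure
   how reporter protein, reporter mRNA, and their ratio (the translational
   efficiency, TE) respond.
2. **Genome-wide ribosome profiling / RNA-Seq contrasts** — per-CDS counts
   of ribosome-protected fragments (RPF) and mRNA fragments across a panel
   of deletion strains, from which per-gene changes in mRNA abundance,
   ribosome occupancy, and TE are derived, thresholded into gene sets, and
   related to covariates (RIP-seq enrichment, codon optimality).

Everything downstream of counting is implemented here; read trimming,
alignment and CDS counting are out of scope, as are GO enrichment and
heatmap rendering (the clustering *pre-filter* is in scope, the dendrogram
is not). A synthetic-data module generates every input with known ground
truth, so each stage is testable end to end without any external download.

# Reporter calculus

## Relative abundance and normalized protein

qPCR technical triplicates are combined as the ratio of **mean transformed
values**: `mean(2^-Ct_reporter) / mean(2^-Ct_reference)`. Averaging after
the 2^-Ct transform is deliberate and pinned by tests: for triplicates
{10, 11, 12} against {10, 10, 10} it yields 0.583, whereas transforming the
mean Ct difference would yield 0.5. The result is invariant to any common
shift of all Ct values. Protein signals are densitometry ratios against a
loading control, computed per biological replicate.

## Ratio of means with propagated SEM

The repression ratio of two construct means X and Y carries the
first-order (delta-method) propagated standard error expressed through
relative SEMs:

$$\mathrm{SEM}\!\left(\frac{X}{Y}\right) \;=\; \frac{X}{Y}\,
\sqrt{\left(\frac{SE_x}{X}\right)^2 + \left(\frac{SE_y}{Y}\right)^2}.$$

One published description of this formula glosses the lowercase x, y as
"highest values", which is internally inconsistent with the delta method
that the printed expression otherwise is. We implement the standard
reading (x = X, y = Y, i.e. relative SEMs); the alternative is not guessed
at. Monte-Carlo tests confirm the propagated SEM tracks the empirical SD
of the ratio within 10% for coefficient-of-variation levels up to 10%,
which covers the reporter assays this calculus serves.

## Paired delta-TE

TE changes are computed **per replicate pair**: for pair i,
`dTE_i = (protein_treated/protein_control) / (mrna_treated/mrna_control)`,
then averaged. The pairing rule is replicate index in input order; since
no pairing convention is universal, the permutation is exposed as an
argument and the mean dTE depends on it (documented on
`pairedDeltaTE`). Equal repression of protein and mRNA gives dTE = 1 —
the signature of pure mRNA destabilization without translational
repression.

## Significance

Two-sample comparisons use the classical pooled-variance Student t-test
(two-sided), with Welch's form behind a flag; sidedness is not configurable
because every labelled comparison in this calculus is two-sided. Labels
follow the strict cutoffs `**` p < 0.01, `*` p < 0.05, `n.s.` otherwise.
Degenerate zero-variance groups return p = 1 (equal means) or p = 0 by
convention rather than erroring, so zero-noise simulations flow through.

# Decay kinetics

Promoter-shutoff series are normalized to percent remaining (100 at t = 0)
and fitted by ordinary least squares of log percent against time. The
decay rate is minus the slope; the half-life is `0.693 / k`. The constant
0.693 (rather than `log(2)` = 0.6931...) is the convention in which
shutoff half-lives are customarily printed, and using it literally keeps
our half-lives commensurable with published values; `halfLifeConstant =
log(2)` switches to the exact constant. The identity `tHalf * k =
constant` holds exactly for every returned estimate.

"Initial rate" windows are rarely stated explicitly in publications; our
default window is all time points at or below 10 minutes — the first five
post-shift samples of the standard 0/2/4/6/8/10/15/20/30/40/60-minute
schedule — with the t = 0 point included because normalization makes it
exact. The window is user-overridable and r² is always reported, so an
ill-chosen window is visible rather than silent. On noiseless exponentials
the fit recovers k to machine precision regardless of window.

# Polysome gradients

Per-fraction qPCR signals (mean 2^-Ct over technical replicates) are
converted to percentages of the total gradient signal; percentages sum to
100 and are invariant to rescaling. Conditions are compared fraction by
fraction with the same unpaired t-test; raw per-fraction p-values match
the field's reporting convention, and a Benjamini-Hochberg column is
emitted alongside because fifteen fractions are tested. The default
fraction count is 15 (free mRNP through heavy polysomes).

# Genome-wide TE stage

## Filtering and normalization

Genes with fewer than 10 total mRNA reads across the contrast's samples
are excluded (inclusive at 10; the "four samples" of a two-replicate
contrast generalize to however many samples the contrast has). Each
assay's samples are then scaled to equal totals (the mean library size),
the normalization under which the median log2 change across genes is
approximately zero. The wiggle-track factor `q = 1e9 / total reads`
rescales per-position counts for browser display.

## TE and contrasts

TE per genotype pools replicates by **summation** — TE = (sum of RPF) /
(sum of RNA) over the genotype's samples — matching the convention that
the ratio of pooled counts, not the mean of per-replicate ratios, defines
TE; per-replicate averaging is a documented alternative a user can build
from `computeTE` on single replicates. Genes with zero RNA sum get an
undefined TE rather than a silent pseudocount (an optional pseudocount,
default 0, exists because conventions differ). For every gene with defined
values, `log2_dte = log2_drpf - log2_dmrna` holds exactly. Double mutants
carrying the decapping deletion are contrasted against the dcp2d single
mutant rather than WT — the epistasis contrast that asks whether a
factor's effect requires decapping.

## The stand-in significance test

Published analyses of this design use DESeq2; reimplementing DESeq2 is a
non-goal, so the built-in test is a deliberately simple, self-contained
negative-binomial Wald procedure, and externally computed p/FDR columns
can be dropped in via `importExternalStats`. Per gene, dispersion is
estimated by the method of moments on equal-total-normalized counts within
genotypes, a mean-dispersion trend `a0 + a1/mu` is fitted across genes
(moment estimates winsorized at the 98th percentile to tame outliers), and
each gene's dispersion is shrunk toward the trend with weight
`residualDf : priorDf`, floored at 1e-8. The Wald statistic divides the
natural-log ratio of genotype means by its delta-method standard error
`sqrt(sum_groups (1/mu_g + alpha)/n_g)`; the TE test is the interaction —
the difference between RPF and RNA log fold changes with variances added —
rather than a ratio-of-ratios fit, and this choice is deliberate and
documented. `priorDf = 10` dominates the 2 residual degrees of freedom of
a two-replicate design; the heavy shrinkage sacrifices per-gene dispersion
adaptivity for calibration, which label-permutation tests verify (fraction
of null p-values below 0.05 stays near nominal). All-zero genes get p = 1;
Benjamini-Hochberg FDR is computed across retained genes.

A consequence worth stating plainly: with two replicates per genotype and
biological dispersion around 0.1 (NB size 10), the standard error of a
log fold change is roughly 0.32 natural-log units *regardless of
expression level*, so 2-fold changes sit near the detection limit and no
calibrated test — ours or an external one — can recover most of them at a
strict FDR. Sensitivity claims for such designs should be read against
that information limit; 4-fold effects at moderate expression are
comfortably detected.

## Gene sets and set responses

Selections record their provenance (metric, fold, alpha, alpha type,
direction). Fold thresholds are inclusive (>= 1.4-fold keeps 1.4 exactly),
FDR cutoffs are strict (< 0.01) and p cutoffs inclusive (<= 0.01),
mirroring how such selections are customarily printed; `minFold = 1`
together with `alpha = 1` is the identity filter. `setResponse` extracts a
set's log2 changes in any panel of contrasts irrespective of per-contrast
significance, so a cohort's behavior can be compared coherently across
mutants — the epistasis signature (elevated median in mutant-vs-WT,
centered in double-vs-dcp2d) is read directly off these summaries. The
clustering pre-filter drops genes missing anywhere or with |log2 change| >
4 and partitions the rest at the +/-2 boundary into the inner and outer
display sets.

# Set-level statistics

*Hypergeometric overlaps* use the upper tail including the observed
overlap (enrichment), the standard for Venn-diagram p-values; the
implementation is pinned against brute-force enumeration over the full
grid of universes up to N = 25. *Notched box plots* use linear-interpolation
quartiles (`quantile` type 7), whiskers at the most extreme points within
1.5 IQR, and McGill notches `median +/- 1.58 IQR / sqrt(n)` — the formula
behind the common web plotting tools, which publications citing those
tools rarely spell out. *Pentile binning* sorts by the covariate (ties
broken by gene id for determinism) and splits into five nearly equal bins,
remainder to the lowest bins. Published pentile analyses of 3686 genes
describe "five pentiles of 739 genes" although 5 x 739 = 3695; we follow
the nearly-equal-bins rule rather than the printed 739. *sTAI binning*
assigns genes to half-open intervals [e_i, e_{i+1}) and counts out-of-range
genes instead of dropping them silently.

# The synthetic-data module

The generator emulates the study designs: reporter measurements are
lognormal around construct means with a configurable CV, Ct values follow
`Ct = 20 - log2(abundance) + Normal(0, 0.15)` (a noise model chosen so the
2^-Ct arithmetic reproduces workbook-style calculations; published work
specifies no qPCR noise model, and these defaults merely make typical
printed SEMs plausible); decay series are first-order with multiplicative
Gaussian noise; gradients are unimodal Gaussian profiles over 15
fractions; counts are negative binomial with variance `mu + mu^2/size`
(size 10 by default, Poisson at `size = Inf` for exact property tests)
over ~6,000 genes, two replicates per genotype, per-sample library-size
factors lognormal(0, 0.1) so normalization is exercised, 10% of genes
carrying a 2-fold mRNA-abundance effect in the scd6d single mutant and 10%
a 0.5x TE effect in dhh1d, with effects nulled on the dcp2d background by
default (the epistasis structure is a configurable flag, not hard-coded,
so non-epistatic truth can also be tested). RIP-seq enrichment is drawn
with a target Pearson correlation against log2 of the true TE effect, and
sTAI scores are Beta-distributed with mean 0.35, the yeast genome average.

What the generator does **not** emulate: nucleotide-level reads, codon
resolution, alignment artifacts, batch effects, or correlated
gene-gene structure. Passing recovery tests on these simulations therefore
demonstrates that the estimators are correct for the stated stochastic
models, not that real libraries satisfy those models.

# Numerical and reproducibility choices

* All randomness flows from a single integer seed in the configuration;
  identical configurations give byte-identical outputs, including pipeline
  reruns on disk.
* Zero handling: log fold changes are undefined (NA) when a genotype sum
  is zero; inside the Wald test group means are floored at 0.5 only for
  the statistic, never for the reported fold changes.
* Degenerate inputs (zero-variance t-test groups, all-zero genes,
  constant covariates) return conventioned values or flagged NAs with
  warnings, not errors, so simulation sweeps don't abort.
* Test problem sizes: most property tests run at 1,000-3,000 genes;
  full-design recovery and calibration checks run at the study scale of
  6,000 genes and finish in seconds. The Monte-Carlo oracle sizes (1,000
  ratio simulations, 200 decay seeds, full hypergeometric grid to N = 25)
  were chosen so sampling error is several times smaller than the
  tolerances they guard.

# Known limitations

* The NB Wald stand-in is calibrated but less powerful than a
  full-likelihood engine with sophisticated shrinkage; for publication
  analyses, import DESeq2 results via `importExternalStats`.
* Two-replicate designs fundamentally limit dispersion estimation; the
  trend-shrunk estimate is effectively the trend, so genuinely
  outlier-dispersed genes are tested anti-conservatively.
* The reporter error model treats technical triplicates as exchangeable
  and ignores qPCR efficiency deviations from 2 (no standard curves).
* Half-life fitting assumes single-phase exponential decay; lag or
  biphasic kinetics bias k toward the window average (visible as low r²).
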