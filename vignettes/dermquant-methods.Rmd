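---
title: "Models and methods in dermquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in dermquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dermquant)
```

`dermquant` reimplements the analysis stack of a treated-versus-vehicle
atopic-dermatitis time course: negative-binomial differential expression,
a gene-group permutation test, fold-change heatmap clustering, fluorescence
image quantification, bead-calibrated cytometry counts, 4PL ELISA
quantification, and the accompanying behavioral statistics. This vignette
explains each model, its assumptions, the tunable parameters, and the
design decisions taken where more than one reasonable implementation
exists. No empirical claim is made here beyond what the package's test
suite and acceptance script themselves compute.

## The count model and differential expression

Gene-level counts are modeled as negative binomial,
$K_{ij} \sim \mathrm{NB}(\mu_{ij}, \alpha_i)$ with
$\mathrm{Var}(K_{ij}) = \mu_{ij} + \alpha_i \mu_{ij}^2$ and
$\mu_{ij} = s_j\, q_i\, 2^{\beta_i x_j}$, where $s_j$ is a per-sample size
factor, $q_i$ a baseline mean, $x_j$ the treated indicator, and $\beta_i$
the log2 fold change. Each time point is tested as an independent
two-group contrast; there is no longitudinal model, matching how replicate
measurements per time point were analyzed in this study design.

**Size factors** are the median-of-ratios estimator: the median over genes
(restricted to genes with positive counts in every sample) of the ratio of
a sample's count to the gene's geometric mean. When no gene is positive
everywhere the function stops rather than silently switching to a
pseudo-reference; that situation signals data that need filtering first.
Size factors are defined only up to a common scale — the meaningful
quantity is their ratio between samples, which is exactly equivariant to
rescaling one sample's library.

**Dispersions** come from a method-of-moments estimate per gene, pooled
across replicate groups, with the Poisson (shot-noise) part of the
variance removed. Two choices matter:

* the mean-dispersion trend $\alpha(\mu) = a_0 + a_1/\mu$ is fitted by
  ordinary least squares over *all* moment estimates, including negative
  ones. Restricting to positive estimates (the naive choice) selects the
  upper half of the sampling noise and biases the trend upward by an order
  of magnitude on low-dispersion data;
* each gene's final dispersion is a log-scale weighted combination,
  weight 0.75 on the trend, 0.25 on the gene's own estimate. At typical
  replicate numbers (3-5 per arm) the gene-wise estimate has enormous
  sampling variance, so most of the information sits in the trend, but
  genuinely atypical genes retain a quarter of their own signal. Genes
  whose moment estimate is non-positive stay at the floor of `1e-8`.

**The Wald test** fits the two-parameter NB log-linear model per gene by
iteratively reweighted least squares (vectorized across genes, closed-form
2x2 solves), plugs in the shrunk dispersion, and refers
$\beta_i/\mathrm{se}(\beta_i)$ to a standard normal. With trend-stabilized
dispersions the normal reference is calibrated at the study's sample sizes
(null type-I rate around 0.05-0.065 at 4 vs 4 in the package's own
simulations); a t reference with residual degrees of freedom, the other
defensible choice, overcorrects once the dispersion is no longer estimated
per-gene from scratch. Genes with all-zero counts are reported
(`log2fc = 0, p = 1`) rather than dropped, keeping the gene universe
stable for the permutation test downstream. Independent filtering, LFC
shrinkage and outlier replacement from the full DESeq2 pipeline are
deliberately not implemented: the study's selection rule operates on plain
adjusted p-values and raw fold changes.

Multiple testing uses Benjamini-Hochberg (via `stats::p.adjust`); gene
selection is `p_adjusted < alpha` and `|log2fc| > log2(fold_threshold)` at
one or more time points, with `alpha = 0.05` for skin and spinal cord and
`0.1` (conventionally without a fold filter) for trigeminal ganglia.
Degenerate thresholds (`alpha >= 1`, `fold_threshold <= 1`) disable the
corresponding filter so the selection degrades gracefully to "all tested
genes".

## The gene-group permutation test

For a group of $n$ genes the observed statistic is
$z_{\mathrm{true}} = \mathrm{median}_i\, |\mathrm{log2FC}_i|$ over the
members, computed against the universe of *all* genes detected in the
contrast — not only significant ones. Each of $B$ null draws samples $n$
genes uniformly without replacement and recomputes the statistic; the
empirical p-value is

$$p = \frac{1 + \#\{z_{\mathrm{null}} \ge z_{\mathrm{true}}\}}{B + 1},$$

so $p \in [1/(B+1), 1]$ and is never zero. Three decisions:

* **Direction.** Significance means the group changes *more* than random
  sets, i.e. the p-value counts null draws at least as extreme as the
  observation. The complementary proportion (large effects giving large
  p) is available behind `literal = TRUE` for comparison, but it is not a
  significance test and is never the default.
* **Center.** The median is the default statistic; the mean is available
  via `center = "mean"`. With the median, the p-value is invariant under
  any strictly monotone transform of the absolute fold changes (a rank
  property the test suite checks), which makes the test robust to the
  fold-change scale.
* **Ties** count toward the hit set (the `>=` above).

`exact_permutation_test()` enumerates all $\binom{m}{n}$ subsets (bounded
at $10^6$) and is the oracle against which the Monte Carlo path is
validated: on 500 random small universes the Monte Carlo estimate at
B = 10,000 stays within three binomial standard errors of the exact value
in over 99% of instances. `run_group_panel()` applies the test across
groups and tissue/day universes with independent deterministic seed
substreams, reports members missing from a universe rather than silently
dropping them, and emits an NA row (with a warning) for groups that vanish
entirely. Panel-level p-values are reported raw, matching how per-group
empirical p-values are conventionally displayed; BH across groups can be
applied by the caller.

## Clustering and heatmap export

Rows (genes) are clustered with Euclidean distance and complete linkage —
the defaults of the classic `heatmap.2` workflow — columns stay in
chronological order. `stats::hclust` breaks distance ties by original row
index, so leaf order is deterministic. A constant matrix (all distances
zero) returns the input order with a warning instead of an arbitrary tree.
The exported CSV contains the matrix in display order and round-trips
exactly; the PNG uses a diverging magenta-black-green palette centred at
zero (decreased/increased expression in treated skin), odd-length so zero
maps to the middle color.

## Image quantification

The whole-mount pipeline is projection -> binarization -> area fraction:

* `max_z_projection()` is the pixelwise maximum over planes (order-free);
* `binarize(image, min, max)` mirrors batch intensity windowing: clip and
  rescale to the window, threshold at half the rescaled range. Thresholds
  are required inputs — the original batch levels are instrument-specific
  — and `simulate_innervation_image()` records the window that separates
  its intensity classes in the truth object;
* `percent_innervation()` delineates 8-connected regions, optionally
  drops specks below `min_region_px` (4 px is a sensible default under
  noise) and optionally closes enclosed holes, then reports
  `100 * foreground / total`. On noiseless synthetic fibers the full path
  reproduces the generator's mask exactly, and the result is invariant to
  90-degree rotation and plane order.

Cell counting labels 8-connected components (the ImageJ-style "circling"
convention) and keeps regions whose pixel area lies within the size
criteria, inclusive. EBImage's labeller is 4-connected, so labels are
merged across diagonal adjacencies with a small union-find; counts are
monotone non-increasing in the lower size bound. `cd45_prph_ratio()`
guards against zero peripherin counts (NA with a warning) and refuses
region sets from different sections.

Hair-follicle autofluorescence is handled by intensity, not shape: the
generator places follicle blobs at 0.30 of the dynamic range against
fibers at 0.90, and the suggested binarization window (0.45-1.0) excludes
them — mirroring the original analysis where follicles are visible in a
different channel and never enter the neural-channel quantification.

## Assays

**Bead counts.** `absolute_count = cell_events * beads_total /
bead_events`. Under binomial acquisition (both populations recovered with
the same probability) the estimator is a ratio of binomials whose bias is
O(1/bead_events) — negligible at realistic bead counts, and the package
verifies a within-2% mean over 50 simulated acquisitions. Zero bead
events is an acquisition failure and errors; the generator resamples such
draws with a warning.

**4PL ELISA.** The standard curve is
$\mathrm{OD} = d + (a - d)/(1 + (x/c)^b)$ with $a$ the zero-dose
asymptote (blanks enter at $x = 0$, not as a log-zero point), $d$ the
saturation asymptote, $c$ the midpoint (pg/mL) and $b > 0$ the slope.
Fitting is Levenberg-Marquardt (`minpack.lm::nlsLM`) multi-started over a
grid of midpoints (quartiles of the positive standards) and slopes
(0.5, 1, 2), keeping the best residual sum of squares; noiseless standards
are recovered to machine precision. Inversion is closed-form,
$x = c\,((a-d)/(\mathrm{OD}-d) - 1)^{1/b}$, times a combined dilution
factor (default 2, the 1:2 dilution into reagent diluent). ODs outside
the open asymptote interval error naming the violated asymptote;
concentrations outside the standard range are flagged `extrapolated`.
Duplicate sample wells are inverted individually and then averaged — the
default — with the invert-the-mean-OD alternative reported alongside.

## Statistics suite

`t_two_tailed_p(t, df)` is the exact conversion used to check published
figure-legend statistics. `t_test()` defaults to the pooled-variance
Student test (legend degrees of freedom in this literature equal
$n_1+n_2-2$), with Welch available. One-way ANOVA reduces to $F = t^2$
for two balanced groups to machine precision; the all-constant corner
returns $F = 0, p = 1$ by convention. Two-way ANOVA uses Type-III sums of
squares with sum contrasts — the convention of the graphical statistics
software standard in this field — so unbalanced designs are handled;
balanced designs coincide with the textbook decomposition, and a
single-level second factor degrades to the one-way analysis. Post-hoc
families: Tukey-Kramer via the studentized-range distribution on the
one-way mean-square error (exactly matching `TukeyHSD`), Sidak
$1-(1-p)^m$, and Holm-Sidak step-down; all collapse to the raw p for a
single comparison. `pooling_check()` implements the control-pooling rule:
controls are merged when the comparison test does not separate them at
`alpha = 0.05`, and the decision is symmetric in argument order.

## Synthetic data: what it emulates, and what it does not

The generators define the package's test conditions, chosen once:

| generator | defaults | rationale |
|---|---|---|
| counts | baseline means lognormal(log 100, 1.2); size factors U(0.7, 1.4); $\alpha(\mu) = 0.05 + 5/\mu$; 10% DE; effects $\pm(0.5 + \mathrm{Exp}(1))$ log2 units; 4 replicates per arm | moderately deep bulk RNA-seq with a standard mean-dispersion trend; effects bounded away from zero so "differential" is meaningful |
| innervation images | 256 px, 10 fibers as smoothed random walks with 3 px disk cross-section over >= 3 planes, 5 follicle blobs, intensities 0.90/0.30 of range | curvilinear foreground with known mask; any generator satisfying the mask contract would do |
| sections | 12 non-overlapping disk cells, radius 4 px | non-overlap guarantees the true count is well defined |
| flow | 10,000 beads, 30% recovery | typical bead spike and acquisition fraction |
| ELISA | a 0.04, b 1.1, c 250 pg/mL, d 2.6; 7 standards at 2000/2^0..6 pg/mL in duplicate plus blank | a realistic chemokine DuoSet-style layout |

All generators are pure functions of (parameters, seed): a single global
seed fans out to deterministic per-stage substreams, the caller's RNG
state is restored, and every generator returns machine-readable truth.

What the synthetic data does *not* emulate — and therefore what passing
tests do not establish about real data: gene-gene correlation (effects are
independent across genes, so permutation-test calibration on real
co-regulated transcriptomes can be anticonservative, a known property of
gene-set tests); batch and library-preparation artifacts; fiber crossing
density, depth attenuation and clearing artifacts of real BABB-cleared
whole mounts; spectral bleed-through between channels; and matrix effects
or hook effects in immunoassays.

## Numerical choices and degenerate inputs

* IRLS: convergence tolerance `1e-10`, 50 iterations, coefficients
  clamped to avoid divergence on separation (one arm all zero).
* Permutation draws: vectorized rejection sampling (redraw columns with
  duplicates), exact for uniform without-replacement sampling at any
  group/universe size ratio.
* Ties in clustering distances: broken by original row index (the
  `stats::hclust` rule), documented rather than randomized.
* 4PL: `b` bounded below by `1e-6` and `c` by a fraction of the smallest
  positive standard, so the blank at $x = 0$ is always well defined.
* Studentized-range p-values use `stats::ptukey` (numerical integration to
  ~1e-6).
* Monte Carlo p-values are never zero (plus-one correction); exact
  enumeration is refused beyond $10^6$ subsets with a pointer to the
  Monte Carlo path.

## Problem sizes used in the checks

The package's own verification runs at: 5000 genes x 4 vs 4 for null
calibration (3 seeds); 100 simulations of 300 genes for effect recovery;
500 random small universes for Monte-Carlo-vs-exact agreement; 200 panels
at B = 10,000 for permutation calibration; 100 noisy sections for count
recovery; 50 acquisitions for bead-count bias; 500 simulated designs for
two-way interaction calibration. These sizes give the binomial/KS bounds
in the tests enough resolution to be meaningful while keeping a full run
in the minutes range.

## Known limitations

* The DE engine intentionally omits independent filtering, fold-change
  shrinkage and outlier handling; it does not claim numerical identity
  with any specific DESeq release.
* The permutation test assumes exchangeability of genes under the null;
  correlated gene sets violate this.
* Image quantification is 2-D post-projection; no registration,
  deconvolution or 3-D tracing.
* Tukey-Kramer assumes homoscedasticity; an unequal-variance flag is
  refused rather than silently approximated.
* The original study's curated gene groups live in figure source data;
  the bundled GMT is a synthetic example, not the original lists.
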