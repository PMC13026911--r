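---
title: "qPCR standard curves, Poisson detection limits, and varPCR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{qPCR standard curves, Poisson detection limits, and varPCR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(varpcr)
```

## The calibration model

A qPCR standard curve relates the quantification cycle to the starting
amount of target:

$$Cq(N) = k \,\log_{10}(N) + m$$

where $N$ is the expected number of target copies per reaction, $k$ is the
slope in cycles per decade and $m$ is the Cq of a single double-stranded
target molecule.  The slope carries the PCR efficiency $E$, the fraction of
molecules duplicated per cycle:

$$E = 10^{-1/k} - 1, \qquad k = -\frac{1}{\log_{10}(1+E)}$$

Perfect doubling ($E = 1$) gives $k = -3.32$.  `fit_standard_curve()`
estimates $k$ and $m$ by ordinary least squares on the replicate-level
calibration points, and `efficiency_ci()` propagates the slope standard
error to the efficiency by the delta method,
$SE(E) = SE(k)\,(1+E)\ln(10)/k^2$, with a Student-t interval on $n-2$
degrees of freedom.

OLS assumes homoscedastic noise, which low-copy levels violate: their
replicate spread is dominated by molecule sampling (below).  Rather than
weighting, the package follows the practice of excluding levels below the
lower limit of quantification before fitting (`exclude_below`).

## Two sources of replicate variation

The simulator (`simulate_dilution_series()`) and all theoretical results
in the package recognize exactly two variance sources:

1. **Aliquoting (sampling) uncertainty.** The number of targets $x$ in an
   aliquot drawn from a sample averaging $N$ copies per reaction volume is
   Poisson: $P(x) = e^{-N} N^x / x!$.  An aliquot with $x = 0$ is negative;
   a positive aliquot responds as $Cq = m - \log_{10}(x)/\log_{10}(1+E)$.
2. **Technical noise.** Additive Gaussian noise on the measured Cq with
   standard deviation `sigma_tech` (cycles), lumping instrument,
   pipetting-volume and chemistry variability.

Early-cycle amplification stochasticity (branching-process variation in
the first cycles) is deliberately not modeled; at $E$ near 1 its
contribution is small compared to the two terms above, and the methodology
under study attributes replicate variance to aliquoting plus technical
noise.  This is a known limitation: on real data from low-efficiency
assays the simulator will understate low-copy variance.

## Converting Cq spread to linear-scale RSD

Precision criteria for bioanalytical methods are stated on the linear
concentration scale.  The package converts a Cq standard deviation to a
linear-scale relative standard deviation with

$$RSD = \sqrt{(1+E)^{SD(Cq)^2} - 1}$$

implemented in `cq_sd_to_linear_rsd()` with exact inverse
`linear_rsd_to_cq_sd()`.  For small spreads this behaves like
$SD(Cq)\sqrt{\ln(1+E)}$, and composed with the zero-truncated Poisson
model it decays as $1/\sqrt{N \ln(1+E)}$ for large $N$ -- about
$1.2/\sqrt{N}$ at perfect doubling.  This specific form was adopted
because, applied to the truncated-Poisson Cq SD, it reproduces the
reference methodology's published theoretical precision values and its
integer limit of quantification of 26 molecules (the alternative
log-normal CV form, $\sqrt{e^{SD^2 \ln^2(1+E)} - 1}$, reproduces
neither).

## Theoretical detection and quantification limits

`prob_positive(N)` $= 1 - e^{-N}$ gives the probability that an aliquot
contains at least one target.  Requiring 95% positive replicates yields
the theoretical limit of detection `theoretical_lod(0.95)`
$= -\ln(0.05) \approx 3$ molecules per aliquot -- a floor set by sampling,
not by the assay.

For positive aliquots, `truncated_cq_sd(N, E)` computes the SD of Cq over
the zero-truncated Poisson distribution by direct enumeration (terms are
summed until the Poisson tail mass falls below $10^{-12}$ and renormalized
by $1 - e^{-N}$; exact to tolerance, no sampling noise).
`theoretical_rsd()` converts that SD to the linear scale.  The resulting
curve is hump-shaped: rising below a few copies (negatives truncate the
spread), peaking near 3 copies, then decaying.  `theoretical_loq()`
brackets and bisects the decreasing branch (to $|\Delta N| < 10^{-6}$) for
the crossing of the 25% criterion and reports both the real root (about
25.4 at $E = 1$) and the smallest integer copy number meeting the
criterion (26).  The integer is reported as the "smallest $N$ satisfying
the criterion" rather than by rounding the root, since the criterion is
one-sided.

## Empirical limits from data

`precision_profile()` summarizes a replicate table per level: positive
fraction, SD of Cq over positives, and converted RSD.  Where negatives
occur the positives-only SD understates the spread; such levels are
flagged but retained, matching how low-copy calibrators are treated in
practice.

`empirical_lod()` fits positive fraction against $\log_{10} N$ with a
binomial GLM and interpolates the concentration giving 95% detection.
The default link is the complementary log-log, whose inverse
$1 - e^{-e^{\eta}}$ has exactly the Poisson occupancy shape; on data
generated by Poisson sampling it recovers the theoretical limit of 3.0
without bias, whereas a logistic sigmoid fitted to the same exact
fractions interpolates about 3.5 (the logistic is retained as an option
for assays with background interference).  The confidence interval is a
parametric bootstrap: per-level binomial resampling of positive counts,
refit, percentile interval.

`empirical_loq()` applies the 25% RSD criterion.  The dynamic range is
defined as a contiguous interval, so the LLOQ is the bottom of the
contiguous run of quantifiable levels that ends at the highest
quantifiable level; a transient sub-threshold dip at very low copies
(an artifact of negatives shrinking the positives-only SD) does not set
the LLOQ.  When no tested level above the run violates the criterion
there is no ULOQ within the studied range.

## varPCR: copy number from variance

Where aliquoting dominates, the observed replicate Cq SD determines $N$:
`varpcr_estimate()` converts the positives' sample SD to an RSD and
inverts the theoretical curve by bisection.  Since the curve is
hump-shaped, each RSD corresponds to two copy numbers; the estimator uses
the low branch exactly when negative replicates were observed (the
low-side decline of the curve is caused by negatives) and the high branch
otherwise.  An observed RSD above the curve maximum is reported as
inconsistent with Poisson-only variation, and an RSD of zero as above the
quantifiable-by-variance range.  Uncertainty comes from a seeded
nonparametric bootstrap over replicate reactions (negatives included),
percentile interval, 2000 resamples by default.

`varpcr_from_negatives()` is the digital-PCR-style companion:
$\hat N = -\ln(\text{negative fraction})$ with a Wilson-interval-based CI.
`combined_estimate()` routes between the two: any observed negative
selects the occupancy estimator, an all-positive set the variance
estimator.  The routing is deliberately not based on a negative-fraction
window: a single negative among 96 replicates at, say, $N = 5$ would force
the variance path onto its low branch, which is the wrong branch and badly
biased, while the occupancy estimate from that same single negative is
already accurate.  In simulation the combined estimator keeps the median
relative error near or below 10% from 0.5 to 500 copies per reaction at
96 replicates.

Technical noise inflates the observed SD and therefore biases the
variance estimator downward (high branch).  No correction is applied by
default; a known `sigma_tech` can be subtracted in quadrature, flagged as
experimental because in practice the technical variance is rarely known
separately from the data at hand.

## Inverse prediction

A test sample's concentration follows from its (replicate-averaged) Cq by
$\log_{10} N = (Cq - m)/k$, with standard error

$$SE(\log_{10} N) = \frac{SE_{y.x}}{|k|}\sqrt{\frac{1}{b} + \frac{1}{n} +
  \frac{(Cq - \overline{Cq})^2}{k^2\,\sum_i (\log_{10} N_i - \overline{\log_{10} N})^2}}$$

where $b$ is the number of test replicates averaged, $n$ the number of
calibration points, and $SE_{y.x}$ the residual standard error of the
curve.  `predict_samples()` accepts raw replicate Cqs and averages
internally so that the $b$ entering the formula always equals the
averaging actually applied; a warning fires when test replication differs
from the calibration's, since both should be handled identically.  The
Student-t interval (df $= n - 2$) is symmetric in $\log_{10}$ and
asymmetric -- always upward-skewed -- after back-transformation.
Relative errors are reported as $100 \times$ interval width over point
estimate on each scale.  `working_hotelling_band()` provides the
simultaneous confidence band (multiplier $\sqrt{2 F_{1-\alpha;2,n-2}}$)
and the prediction variant with the extra $1/b$ term; a pointwise-t band
is an option.

Run validation uses `qc_check()`: each quality-control sample must
back-calculate within 1 cycle of the curve at its nominal concentration,
and a run passes when all QC samples do.

## Outliers and the linear range

`standardized_residuals()` scales residuals by $SE_{y.x}$ and flags
$|r| > 3$; `grubbs_test()` applies the classical single-outlier,
two-sided Grubbs test once to the pooled residuals (no iterative
removal -- repeated Grubbs on calibration-sized samples inflates the
false-positive rate).  Both views are reported separately.

`linearity_test()` fits quadratic and cubic polynomials in
$\log_{10} N$ and F-tests them against the line; the curve passes when
neither higher-order term is significant at $\alpha = 0.05$ (the
significance level is configurable; 0.05 is the conventional default).
Because the F-test is sensitive enough to flag harmless wiggles in
precise data, the report also carries the maximum deviation from
linearity: each level's concentration is back-calculated through the
cubic and through the linear fit, and the largest relative difference in
linear scale is reported; below 20% a curve would typically still be
accepted.  This operationalization (cubic vs linear back-calculation at
the tested levels) is isolated in one place so it can be revised without
touching the F-tests.

`acceptance_check()` encodes the efficiency rules: hard failure when the
lower confidence bound of $E$ exceeds 100% (points outside the linear
range tilt the slope), warnings when the point estimate exceeds 100% with
an interval spanning it, when $E < 90\%$, or when the interval is wide.

## Simulation defaults and validation problem sizes

The extreme validation preset (`simulate_extreme_series()`) uses two-fold
dilutions 2048 down to 1 copy, replicated 128/64/32 (lowest /
intermediate / two highest levels), $E = 1$, $m = 34$ cycles and
`sigma_tech = 0.15` -- a stand-in for instrument-inclusive repeatability,
exposed in the configuration.  Typical-practice simulations use six
ten-fold levels in triplicate.

The package's own operating-characteristic checks (in the test suite) use
these study sizes, chosen to estimate each property with useful precision
while keeping a full run in minutes: varPCR recovery with 96 replicates
and 500 seeds per copy number; prediction-interval coverage over 500
simulated runs; linearity-test size over 500 null simulations and power
over 100 curvature-injected runs (six ten-fold levels in triplicate with
`sigma_tech = 0.10`, representing instrument-only repeatability, the
regime the linearity test targets); Monte Carlo validation of the
truncated-Poisson SD with $10^6$ draws per copy number.

What passing these simulations does *not* show: robustness to matrix
effects, inhibition, amplification stochasticity at low efficiency, or
instrument-specific Cq-calling artifacts -- none of which the generator
emulates.

## Numerical choices

* Truncated-Poisson moments: exact enumeration to tail mass $10^{-12}$,
  renormalized; no sampling noise anywhere in the theoretical curves.
* Curve inversions (`theoretical_loq()`, `invert_theoretical_rsd()`):
  bracketing plus bisection to $|\Delta N| < 10^{-6}$; the hump maximum is
  located once per efficiency and cached.
* RSD values are fractions internally; percent formatting is a reporting
  concern.
* Exact fits (residual SE at rounding level) report zero standardized
  residuals rather than dividing by a denormal.
* Constant residuals make the Grubbs statistic undefined; reported as "no
  outlier".
* All stochastic steps (simulator, bootstraps) accept integer seeds and
  are reproducible bit-for-bit on one platform.
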