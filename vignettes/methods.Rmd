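---
title: "From paced-breathing heart rhythms to brain change: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From paced-breathing heart rhythms to brain change: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hrvofc)
```

## The analysis chain

Slow paced breathing near the baroreflex resonance (around 0.1 Hz, six
breaths per minute) drives large heart-rate oscillations, and sustained
practice of this kind of breathing has been linked to structural change in
the orbitofrontal cortex (OFC). `hrvofc` implements the full computational
chain needed to study that link on longitudinal data:

1. **HRV reduction** (`clean_ibi`, `segment_session`, `interpolate_hr`,
   `time_domain`, `welch_psd`, `band_power`, `aggregate_subject`): raw
   inter-beat-interval (IBI) recordings from home practice sessions become
   one averaged record of time-domain metrics (RMSSD, SDNN) and spectral
   band powers per subject.
2. **Morphometry change** (`spc`, `change_scores`): three-timepoint volume
   panels become annualized symmetrized-percent-change rates and post
   minus pre change scores.
3. **Associations** (`partial_corr`, `shepherds_pi`, `bh_fdr`,
   `frequency_curve`): residualized partial correlations between training
   HRV power and post-intervention volume controlling for pre-intervention
   volume, with rank-based and outlier-removing robust variants,
   FDR control, and a frequency-resolved correlation curve across breathing
   periods of 4 to 20 s.
4. **Brain-behavior coupling** (`plsc`, `plsc_permutation`,
   `plsc_bootstrap`): partial least squares correlation between a brain
   change block and a behavioral change block, with permutation tests on
   singular values and bootstrap ratios on saliences.
5. **Synthetic ground truth** (`simulate_ibi`, `simulate_volume_panel`,
   `simulate_change_blocks`): every stage above is exercised against
   generated data with known planted structure.

## HRV processing model

A 15-minute practice session is three 5-minute regimes, each paced at a
fixed breathing period (slow condition: 10, 12 or 15 s per breath; random
condition: 4, 5 or 6 s). Because the pace switches at regime boundaries, 15 s
are trimmed from each end of every regime, leaving at most 4 min 30 s of
analyzable data; regimes with less than 3 min 30 s of usable coverage are
excluded. Usable coverage is measured as the length of the union of per-beat
intervals $[t_i - \mathrm{IBI}_i, t_i]$ intersected with the trimmed window,
so a fully covered regime yields exactly 270 s and gaps of any origin reduce
the figure by exactly their length.

Artifact rejection removes beats deviating more than 25% from an 11-beat
running median. The rule and both constants are configurable: consumer
biofeedback hardware applies its own undocumented correction, so the
package's rule is a transparent replacement, and a segment losing more than
20% of beats is flagged unusable rather than silently passed on.

The cleaned (beat time, IBI) pairs are interpolated to a uniform 4 Hz grid
by cubic spline (linear when fewer than 4 beats are available). RMSSD and
SDNN are computed per 60-s window and averaged, with the sample (n-1)
standard deviation for SDNN.

### Spectral estimation

The power spectral density is estimated by Welch's method on the linearly
detrended series: Hann taper, segments of 270 s with 50% overlap, one-sided
density scaling so the integral over frequency recovers the variance. For a
single trimmed regime the default segment length means one full-regime
tapered periodogram, giving a grid spacing of 1/270 Hz (about 0.0037 Hz).
That resolution is deliberate: the custom sub-bands subdivide the baroreflex
range finely — lower LF (0.058–0.068 Hz) spans only 0.01 Hz — and a coarser
grid (e.g. 120-s segments, 1/120 Hz spacing) cannot place even the
first-order taper leakage of a 0.1-Hz oscillation inside the upper-LF band
(0.096–0.130 Hz), let alone resolve the lower band. Users who prefer more
periodogram averaging at the cost of resolution can set `seg_seconds`.

Band powers integrate the PSD over half-open intervals $[f_{lo}, f_{hi})$ by
the rectangle rule, so any partition of a range is exactly additive and
adjacent sub-bands never double-count a bin; the 0.093–0.096 Hz sliver
belongs to the baroreflex band (0.075–0.130 Hz) but to neither the middle
nor the upper sub-band. "Total power" defaults to 0.04–0.40 Hz and is
configurable, since conventions differ on including the very-low-frequency
range.

Metrics are averaged arithmetically over all included regimes of all
sessions, and the natural log is applied **after** averaging (log of the
mean). The alternative mean-of-logs is available by flag
(`log_of_mean = FALSE`); the two differ by Jensen's inequality and the
log-of-mean matches reporting conventions where a "log power" column
summarizes a training period. Mean heart rate is never log-transformed.

## Morphometry change

SPC is $100 \cdot b / \bar v$ where $b$ is the OLS slope of volume on scan
time (years) and $\bar v$ the mean volume over the available timepoints;
with two timepoints this is the two-point difference quotient. Scan times
default to (0, 0.44, 0.85) years, matching protocol weeks 2/7/12, and are
configurable per panel since exact inter-scan intervals vary by subject.
Intracranial volume is carried as a covariate column but never silently
applied.

## Robust associations

`partial_corr` residualizes both variables on the single covariate by least
squares and correlates the residuals; the p-value uses a t reference with
$n-3$ degrees of freedom. The Spearman variant rank-transforms all three
variables first (a Pearson correlation of ranked-then-residualized
variables; rank partial correlations have competing definitions, and this
one matches the residualization description above).

`shepherds_pi` standardizes the two residual axes, computes each point's L1
distance from the coordinate-wise median, and removes points beyond the
99th percentile of the empirical distance distribution before taking the
Spearman correlation of the remainder. The reported p-value is the plain
Spearman p on retained points; the doubled-p convention of the original
Shepherd's pi proposal is available via `double_p = TRUE`. Note that with an
empirical quantile threshold and continuous data, the most extreme point
typically exceeds the threshold; configurations with tied distances are the
case where nothing is removed and pi equals rho exactly.

The univariate 3-IQR prescreen (`iqr_screen`) only reports flags; removal
decisions stay with the analyst. BH-FDR is applied per analysis family (the
17-frequency curve forms one family; the metric-by-ROI table another —
family scope is under the caller's control by correcting subsets).

The frequency curve extracts each subject's PSD at the bin nearest to
1/period for periods 4, 5, ..., 20 s (0.25 down to 0.05 Hz), ties broken
toward the lower frequency, log-transforms the power, and computes the
partial correlation against post-intervention volume controlling
pre-intervention volume at each of the 17 frequencies.

## PLSC

With z-scored change blocks $X$ ($n \times p$, brain) and $Y$ ($n \times q$,
behavior), the cross-block correlation $R = X^\top Y/(n-1)$ is decomposed by
SVD, $R = U \Sigma V^\top$. Column $k$ of $U$ and $V$ are the brain and
behavior saliences of latent variable $k$; latent scores are $Xu_k$ and
$Yv_k$; explained variance uses squared singular values
($\sigma_k^2 / \sum_j \sigma_j^2$ — the share of summed squared covariance).
Signs are fixed by making the largest-magnitude behavioral salience element
positive.

Permutation significance shuffles the rows of $Y$, recomputes singular
values, and reports the plain proportion of permuted $\sigma_k^*$ exceeding
the observed $\sigma_k$, compared per rank without re-alignment (an add-one
smoothed estimator and a projection-based re-alignment variant are available
by flag; per-rank plain proportions are the default because they follow
directly from the test's definition). Bootstrap reliability resamples
subjects with replacement, re-standardizes, refits, sign-aligns each
resampled LV to the original by the combined salience dot product (without
alignment, axis reflections inflate the bootstrap SD), and reports
BSR = salience / bootstrap SD with |BSR| > 1.96 flagged. Resamples in which
some column collapses to zero variance are redrawn and counted. Analyses
without an explicit seed are refused unless `strict = FALSE`.

## The synthetic generator

The generator is the test bed: it emulates the study's signal structure with
known planted parameters.

* **IBI series**: integrate-and-fire on the instantaneous period — the next
  beat falls one current period after the last, with period
  $\mathrm{base} + m \sin(2\pi t / \mathrm{pace}) + \varepsilon$. Defaults
  (base 850 ms, modulation 80 ms, beat noise 15 ms) describe a healthy adult
  breathing at the guided pace with a clearly visible respiratory modulation.
  Regime pace switches are instantaneous; the adaptive per-regime pace
  assignment used by biofeedback software is intentionally not modeled (its
  scoring is proprietary). Parameter combinations that could produce
  non-positive periods are rejected up front.
* **Volume panels**: pre-intervention volumes are Gaussian
  (7000 ± 400 mm³, an OFC-like scale); post = pre + slope × (centered log
  power) + noise, with defaults slope 50 mm³ per log-unit against 100 mm³
  noise — a medium planted effect (partial r ≈ 0.45 at n = 55). The mid
  timepoint is the pre/post average plus noise, present so three-timepoint
  SPC is exercisable.
* **Change blocks**: $X = a\, s u^\top + E$, $Y = a\, s v^\top + F$ with
  standard-normal subject scores $s$, random unit saliences, latent strength
  $a \in [0,1]$ and i.i.d. Gaussian noise (SD 0.25 by default). Because PLSC
  standardizes columns, its estimand is the *standardized-scale* salience
  (the per-column correlation with the latent score, normalized), which the
  generator exposes as `planted_salience_std`; against the raw weights a
  perfect estimator would still appear biased, since standardization
  compresses large weights (in the noise-free limit the estimated salience
  is proportional to the sign pattern of the weights). The default noise SD
  was fixed by a Monte-Carlo calibration so that the planted single latent
  at the study's dimensions (n = 55, 50 brain × 8 behavior variables,
  strength 0.8) is recoverable with salience correlation above 0.9 in ≈97%
  of replicates — a regime in which the inferential machinery, not the
  generator, is what a failing test would indict.

All noise is Gaussian; this keeps the null calibration analytically
checkable (permutation rejection at nominal rate, chi-square Mahalanobis
flags at ≈1%) but means heavy-tailed physiological artifacts, missing-data
mechanisms, scanner drift, and spatial correlation among vertices are *not*
represented. Passing tests therefore demonstrate correctness of the
computations and calibration of the inference under clean conditions, not
robustness to everything real recordings do.

## Numerical choices and degenerate inputs

* Half-open band edges; ties in nearest-bin lookup go to the lower
  frequency.
* Partial correlations with (near-)zero-variance residuals return an
  explicit `degenerate` status instead of a number.
* Welch segments shorter than the configured length fall back to one
  full-length segment; series under 210 s trigger a warning, under 8
  samples an error.
* Empty sessions segment into three excluded regimes with a warning, not an
  error; zero included regimes mark the subject missing.
* SPC requires two distinct scan times; constant volumes give exactly 0.
* `mahalanobis_screen` requires $n > p + 1$ and reports a singular
  covariance as an actionable error.
* Bit-identical reproducibility: the same configuration and seed reproduce
  every simulated dataset and resampling result exactly; `run_pipeline`
  writes byte-identical bundles for identical configs.

## Problem sizes used in the test suite

Monte-Carlo checks run at the study's scale where that scale is part of the
claim (n = 55 subjects, 50 × 8 change blocks, 200 null replicates at n = 40
with 500 permutations each) and at reduced replicate counts where only the
direction of an effect is asserted. The suite completes in well under a
minute on a single core.

## Known limitations

* The spectral estimator is fixed-form (Hann/Welch); Lomb-Scargle for
  unevenly sampled data is not provided, interpolation is always used.
* Shepherd's pi p-values are approximate (t reference on Spearman's rho of
  retained points); the exact permutation distribution is not computed.
* PLSC is the correlation variant only; predictive PLS regression,
  multi-block and mean-centered task-PLS designs are out of scope.
* Vertex cluster definition, surface reconstruction and vertexwise GLMs
  belong to external neuroimaging tools; the package consumes their outputs
  as tables.
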