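---
title: "Multiscale analysis of rest-activity rhythms: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiscale analysis of rest-activity rhythms: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chronossa)
```

# The problem

Wrist actigraphy records movement counts per fixed epoch (here 1 minute)
over many days.  Healthy rest-activity rhythms are dominated by a ~24-h
(circadian) oscillation, but clinically interesting signal often hides in
subtler features: how the circadian parameters fluctuate from day to day,
how fragmented activity is at sub-daily (ultradian) time scales, and
whether the ultradian variance is spread across many scales (1/f-like) or
concentrated near a characteristic period such as the ~90-min basic
rest-activity cycle.  chronossa implements three complementary analyses of
one series $x(n)$, $n = 1..N$:

1. **Cosinor regression** — parametric fit of
   $y(t) = M + A\cos(2\pi t/T + \phi)$.
2. **Intradaily variability** $IV(P)$ — a nonparametric fragmentation
   measure as a function of the resampling interval $P$.
3. **Singular spectrum analysis (SSA)** — a model-free additive
   decomposition $x(n) = \sum_k \sigma_k g_k(n)$ from which day-by-day
   circadian parameters and ultradian scaling laws are read off.

All user-facing functions take a tibble with columns `time_min` (minutes
after the midnight preceding the first sample; strictly increasing,
equidistant) and `counts`, plus `subject_id`/`group` labels for cohorts.

# Cosinor

For a trial period $T$ the model is linear in $(M, a, b)$ after the
reparameterisation $y = M + a\cos(2\pi t/T) + b\sin(2\pi t/T)$, so the
least-squares optimum is closed-form; $A = \sqrt{a^2+b^2}$,
$\phi = \mathrm{atan2}(-b, a)$.  Because each recording can start at an
arbitrary clock time, $\phi$ itself carries no physiology; the reported
quantity is the **acrophase** $\phi_0$, the clock position of the fitted
maximum referenced to midnight, expressed either as an angle (360° = 24 h)
or as hh:mm (232° = 15:28).  The fit quality is
$R^2 = 1 - \mathrm{Var}(x - y)/\mathrm{Var}(x)$.

The per-subject period is chosen by scanning a grid (default 1440 ± 120 min
in 1-min steps) and keeping the period that maximises the fitted amplitude,
with ties broken toward 1440 min (the physiological prior).  Two numerical
caveats are documented deliberately:

* On finite records whose length is not an integer number of cycles,
  spectral leakage can bias the amplitude-maximising period by a few
  minutes even on noise-free data (the fitted amplitude at a slightly
  wrong period can exceed the true amplitude).  This is a property of the
  amplitude-maximisation criterion itself, not of the optimiser; the fit at
  the true period remains exact.
* A period deviation $\Delta T = T - 1440$ accumulates as an acrophase
  drift of $\Delta T / 4$ degrees per day ($+3$ min $\to$ $+0.75$°/day);
  `acrophase_trajectory()` exposes that line, and the reported
  `acrophase_deg` of a fit is the arithmetic mean of the per-day peak
  positions over the recording.

Mean acrophases are computed as arithmetic means of unwrapped values, not
circular statistics: acrophases cluster mid-afternoon, far from the wrap
point, for the populations this package targets.  This is a documented
limitation for populations with peaks near midnight.

# Intradaily variability

The classic measure on an hourly resampled series $X$ is
$$IV = \frac{\sum_{n=2}^{N}(X_n - X_{n-1})^2/(N-1)}
            {\sum_{n=1}^{N}(X_n - \langle X\rangle)^2/N},$$
with the $N-1$ vs $N$ divisor asymmetry kept exactly as written; tests
pin the finite-sample consequences (an alternating series gives exactly 4;
a sampled cosine gives $2(1-\cos(2\pi P/T))\cdot N/(N-1)$).

`iv_curve()` generalises the hourly convention to a function of the
resampling interval $P$.  Resampling uses **bin means**, not sums, so all
$X_P$ stay on the counts/min scale and remain commensurable with the raw
series; trailing samples that do not fill a bin are dropped with a warning
(padding would fabricate a step in the differences).  Two denominator
conventions are exposed: `"original"` divides every numerator by the
constant $\mathrm{Var}(x)$ of the raw series, making $IV(P)$ a simple
function of $P$; `"resampled"` divides by $\mathrm{Var}(X_P)$, the
classic composite form.  The default grid is ~40 log-spaced intervals over
1–600 min plus the canonical 60 min, covering both the circadian maximum
near $P \approx 500$ min and any sub-hour structure.

# Singular spectrum analysis

The series is embedded in a $K \times L$ Hankel trajectory matrix
($K = N - L + 1$, rows are lagged windows), decomposed by SVD into rank-1
elementary matrices $\sigma_k\, u_k v_k^{\!\top}$, and each elementary
matrix is mapped back to a series $g_k(n)$ by averaging its
anti-diagonals, giving the exact identity $x(n) = \sum_k \sigma_k g_k(n)$.
The partial variances $\lambda_k = \sigma_k^2$, ordered decreasingly and
normalised by $\lambda_{tot} = \sum_k \lambda_k$, form the scree diagram:
for week-long actigraphy $\lambda_1$ is the non-oscillating trend (mesor),
$\lambda_2 \approx \lambda_3$ is the nearly degenerate circadian pair, and
the $k \ge 4$ tail is ultradian.

Implementation choices:

* The SVD is obtained from the symmetric $L \times L$ eigenproblem of
  $X^{\!\top}X$, with $u_k = X v_k/\sigma_k$.  This keeps the
  decomposition exact (the reconstruction is a projection identity
  independent of small-singular-value accuracy) and makes $L = 1440$ on
  $N = 10080$ series run in seconds.  A dense-SVD brute-force oracle
  validates the whole path on small series.
* Diagonal averaging of a rank-1 matrix is the linear convolution of
  $u_k$ and $v_k$ divided by the anti-diagonal lengths
  $w_n = \min(n, L, K, N-n+1)$; it is evaluated by FFT.
* Default window `L = 1440` samples (24 h at 1-min epochs), the standard
  choice of one full dominant period: rhythms with period up to about $L$
  resolve into separate components, slower structure joins the trend.
* Default `r_max = 1000` components retained: scaling fits use ranks up to
  $\log_{10} k = 3$; `lambda_tot` is always accumulated over the full rank
  so truncation never distorts scree fractions.
* Component mean periods are estimated from zero crossings of the
  mean-centred component, located with linear interpolation; the period is
  twice the mean crossing spacing.  Components with fewer than two
  crossings are labelled trend.
* The circadian pair defaults to ranks $\{2, 3\}$; `auto_circadian_pair()`
  finds the first nearly degenerate pair whose periods lie within 20% of
  1440 min for cases where a strong ultradian rhythm outranks the
  circadian pair or the trend splits.
* `ssa_wcor()` gives the weighted-correlation separability diagnostic with
  the same weights $w_n$.

# Day-by-day circadian parameters

The source never prescribes a unique way to read daily parameters off the
reconstructed components, so the procedure here is explicit and tested:

* **Acrophase** $\phi_0(d)$: clock position of the $d$-th local maximum of
  the circadian reconstruction, maxima at least 18 h apart (suppresses
  ultradian leakage), unwrapped so consecutive days never jump by ±360°.
* **Period** $T(d)$: spacing between successive maxima ($D-1$ values).
* **Amplitude** $A(d)$: half the peak-to-trough excursion between the
  minima bracketing each maximum.
* **Mesor** $M(d)$: mean of the trend reconstruction over calendar day $d$.
* Maxima within 2 h of the series boundary are flagged `edge = TRUE`
  (diagonal averaging distorts reconstructions there).

Day-to-day summaries use the population ($n$-divisor) variance convention
throughout, and kurtosis is the Pearson moment ratio $m_4/m_2^2$ (Gaussian
= 3, uniform = 1.8).  A classic diagnostic follows: adding a linear trend
to Gaussian noise lowers kurtosis below 3 (a trend spanning 4 SDs gives
$14.2/(7/3)^2 \approx 2.61$ analytically), so platykurtic day-to-day
acrophase distributions are consistent with a drifting circadian period.

**Known attenuation.** The circadian pair acts as a narrowband filter, so
day-to-day *amplitude* modulation that is independent across days loses
part of its energy to higher components: under the generator's default
conditions the recovered day-to-day CV of amplitude is about 60–70% of the
injected value (the count floor also clips high-amplitude troughs, which
destroys amplitude information before any analysis).  Acrophase jitter
passes through with much smaller bias (~10–15%).  The tests assert these
calibrated bands and, more importantly, that recovered variability remains
strictly monotone in the injected variability — the property group
comparisons rely on.

# Ultradian scaling

Power laws $\lambda_k \propto k^{-\gamma}$ are fitted by OLS on
$\log_{10}\lambda_k$ vs $\log_{10}k$ without binning (the rank grid is
already dense in log space).  Ranges follow the published convention:
single law over $0.78 \le \log_{10}k \le 3.0$; crossover exponents
$\gamma_1$ over $[0.8, 1.5]$ and $\gamma_2$ over $[1.6, 2.0]$; and the
summed scree fraction over $[1.4, 1.6]$ — ranks whose components map to
mean periods of roughly 60–90 min at $L = 1440$ — quantifies narrowband
ultradian power.  `band_to_frequency()` translates any rank band into a
physical period range via the component period estimator.  A 1/f-like tail
yields $\gamma_1 \approx \gamma_2 \approx 1$; excess 90-min power flattens
the pre-crossover range and steepens the post-crossover one
($\gamma_2 > \gamma_1$).

# Cohort statistics

Group comparisons use the Kruskal-Wallis rank test (`stats::kruskal.test`)
with a chi-square p-value; the degenerate all-identical case returns
H = 0, p = 1.  `mean_24h_profile()` averages each subject's counts per
minute of day over days (subjects, not days, are the replication unit),
compares groups minute by minute, and reports contiguous significant
intervals as clock-time bands.  No multiplicity correction is applied by
default — matching how minute-wise transition-band significance is usually
presented, a deliberately liberal choice — with an optional
Benjamini-Hochberg mode.  `cosinor_ssa_agreement()` correlates the cosinor
curve with the SSA trend + circadian reconstruction (Pearson and
Spearman).

# The synthetic cohort generator

`cohort_spec()` + `generate_cohort()` emulate the study conditions the
analyses assume: 7 days × 1440 min at 1-min epochs per subject; counts
clipped to 0–3000/min and rounded to integers; between-subject mesor
216 ± 56 counts/min; circadian amplitude 178 counts/min with day-to-day
CV 0.28; acrophase 232° (≈15:28) with 26° day-to-day jitter (a case-like
group shifts the mean to 253° ≈ 16:52); period 1440 min, with other values
injecting an acrophase drift.  Defaults chosen once and documented:

* **Ultradian noise**: Gaussian noise spectrally shaped to power
  $\propto 1/f$, band-limited to periods ≤ 12 h — unbounded 1/f power
  below the circadian frequency would produce multi-day mesor wander that
  real actigraphy does not show — with `noise_scale = 290` counts/min,
  calibrated once so the cosinor fit explains ~0.13 of the variance, the
  scale reported for real young-adult cohorts.  `"brac90"` mode adds a
  narrowband (15% relative width) quasi-periodic oscillation at 90 min
  whose variance is `brac_relative_power` times the 1/f component's.
* **Day-to-day modulation**: amplitude and acrophase values are i.i.d.
  Gaussian per day, anchored at successive nominal peak times and
  interpolated linearly in between — parameters change day to day without
  physically implausible discontinuities at midnight.
* **Clipping before rounding**: the floor at 0 is the dominant
  nonlinearity (rest nights), and is reported per subject as
  `clipped_fraction`.  `integer_counts = FALSE` disables rounding for
  exact parameter-recovery experiments.
* Optional multiplicative burst intermittency (`burst_prob`,
  `burst_scale`) models "spiky" activity; off by default because no
  quantitative parameterisation of it is established.

What the generator does **not** emulate: sleep-stage architecture, nonwear
or artifact segments, device-specific count transduction, autocorrelated
(random-walk) day-to-day parameter drift, or seasonal structure.  Passing
tests therefore demonstrate internal consistency of the pipeline under
these idealised conditions, not validity on any particular clinical data
set.

# Problem sizes and runtime choices

The tests and the acceptance script run full-size single subjects
(N = 10080, L = 1440) where the scientific claim needs them, and scale the
replication counts to what stabilises the checked statistic: 100 random
series for exactness, 100 synthetic cohorts of 20 + 20 subjects for the
acrophase-offset detection rate (cosinor stage only), and 5–6 subjects per
group for the SSA scaling contrasts, whose per-subject cost is a few
seconds.  These sizes are the package's own choice of a stable-but-lean
experiment design.
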