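# chronossa

Multiscale analysis of circadian and ultradian rest-activity rhythms in
epoch-based actigraphy (movement counts per minute), for chronobiology and
sleep researchers who need more than a single cosine fit: day-by-day
variability of the circadian cycle and the scaling structure of ultradian
fluctuations, extracted from one week of continuous 1-min data per
subject.

Three complementary views of a series *x(n)* are implemented:

* **Cosinor regression** — least-squares fit of
  *y(t) = M + A cos(2πt/T + φ)*, with a period scan maximising the
  amplitude *A*, and the acrophase φ₀ (clock position of the daily peak,
  360° = 24 h after midnight) as the physiologically meaningful phase.
* **Intradaily variability** — IV(P) = Var(X′_P)/Var(x), the variance of
  the first differences of the bin-mean resampled series relative to the
  raw-series variance, as a function of the resampling interval *P*.
* **Singular spectrum analysis (SSA)** — Hankel embedding of the series,
  SVD, and diagonal averaging give the exact additive decomposition
  *x(n) = Σ_k σ_k g_k(n)*: a trend (mesor) component, a nearly degenerate
  circadian pair, and an ultradian tail whose ordered partial variances
  λ_k = σ_k² follow a power law λ_k ∝ k^(−γ).  Day-by-day mesor,
  amplitude, acrophase and period are read off the reconstructed
  components; crossover fits (γ₁ before, γ₂ after log₁₀k = 1.5) and the
  scree fraction in the 60–90-min band quantify basic-rest-activity-cycle
  (BRAC)-like ultradian rhythms.

A synthetic cohort generator (`cohort_spec()`, `generate_cohort()`)
produces actigraphy-like series with known injected parameters —
control-like (1/f ultradian tail) or case-like (excess 90-min power,
delayed acrophase) — so every stage of the pipeline is testable without
any clinical data.  Cohort-level functions add Kruskal-Wallis group
comparisons, minute-wise mean 24-h profiles with significance bands, and
cosinor-vs-SSA agreement.

## Worked example

```r
library(chronossa)

spec <- cohort_spec(n_subjects = 1, seed = 42)   # control-like defaults
subj <- generate_subject(spec, 0)

fit <- scan_period(subj, seq(1320, 1560, 4))
fit
#> Cosinor fit (T = 1424.0 min): M = 274.3, A = 113.8,
#>   acrophase = 236.8 deg (15:47), R^2 = 0.103

d <- ssa_decompose(subj, L = 1440)
d
#> SSA decomposition: N = 10080, L = 1440, K = 8641, r = 1000 components
#>   leading lambda/lambda_tot: 0.548, 0.0303, 0.0269, 0.0183

daily <- daily_parameters(circadian_reconstruction(d))
daily
#> Daily circadian parameters over 7 detected cycles (R^2 = 0.141)
#>   parameter         n  mean     sd     cv    skew  kurt
#> 1 mesor             7  274.   5.27 0.0192  0.367   2.24
#> 2 amplitude         7  124.  16.3  0.132   0.621   2.35
#> 3 acrophase_deg     7  234.  25.5  0.109  -0.0302  1.69
#> 4 period            6 1396  122.   0.0875  0.798   2.05

crossover_fit(ssa_scree(d))[, 1:5]
#>   gamma gamma1 gamma2 crossover band_fraction
#> 1 0.976   1.16  0.874    -0.281        0.0247
```

Reading: this subject peaks at 15:47 with a ~24-h period; the single
cosine explains ~10% of the minute-level variance while the SSA
trend + circadian model explains ~14%, because it tracks the day-to-day
fluctuation of acrophase (SD ≈ 26°) and amplitude.  The ultradian scree
tail decays as a single power law with γ ≈ 1 (1/f-like, control-like);
a `brac90` subject instead shows a larger 60–90-min `band_fraction` and
γ₂ > γ₁.  `autoplot(d)` draws the scree diagram, `plot_circadian()` the
reconstruction, and `autoplot()` on `iv_curve()` / `mean_24h_profile()`
the other standard figures.  `tidy()`/`glance()` methods return tibbles
for all fitted objects, so per-subject tables compose with dplyr.

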