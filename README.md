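# superstat

Superstatistical analysis of high-frequency environmental sensor time
series, for researchers studying water-quality dynamics (dissolved oxygen,
electrical conductivity) in monitored rivers — and for anyone whose
detrended sensor fluctuations show heavy tails that a single Gaussian
cannot explain.

## The method

A record `F(t) = Trend(t) + Fluctuations(t)` is detrended either by a
centred moving average with window *f* (default 6 h) or by empirical mode
decomposition, attributing the last *m* (fastest) modes to the
fluctuations (default *m* = 2). The fluctuations are modelled as *locally*
Gaussian: within windows of some long timescale *T* they are Gaussian with
inverse variance β = 1/σ², and β itself fluctuates across windows. *T* is
read off the average-kurtosis curve

    κ̄(Δt) = ⟨ ⟨(u−ū)⁴⟩ / ⟨(u−ū)²⟩² ⟩ over windows of length Δt,

as the first window size where κ̄ crosses the Gaussian value 3. A short
relaxation timescale τ comes from the e⁻¹ crossing of the fluctuation
autocorrelation; the framework requires τ ≪ T. Per-window β values are
then fitted by maximum likelihood under candidate laws — χ² (gamma with
mean β₀), inverse-χ², log-normal, and a two-component χ² mixture
`W·f(β; n₁, β₀) + (1−W)·f(β; n₂, β₀)` sharing one scale β₀, which captures
double-peaked β-histograms — and ranked by AIC. A χ² β-law induces exactly
a q-Gaussian marginal with `q = (n+3)/(n+1)`; the package exposes the
densities, samplers, and MLE fitters for all of these, plus a synthetic
generator with known ground truth.

## Worked example

```r
library(superstat)

gen <- generate_superstat_series(synthetic_config(seed = 1))  # 1 year, 15-min
report <- run_pipeline(gen$series, method = "seasonal", f_hours = 6, seed = 1)
report
#> <superstat_report>
#>   detrending: seasonal (f = 6 h)
#>   long timescale T: 11.1 h
#>   short timescale tau: 0.9531 h
#>   separation tau/T: 0.08588 (pass)
#>   best beta-law by AIC: lognormal
tidy(report)
#> # A tibble: 4 × 5
#>   family       logLik   AIC converged  rank
#>   <chr>         <dbl> <dbl> <lgl>     <int>
#> 1 lognormal    -1389. 2781. TRUE          1
#> 2 chi2_mixture -1429. 2866. TRUE          2
#> 3 chi2         -1434. 2872. TRUE          3
#> 4 inv_chi2     -1458. 2921. TRUE          4
```

The generator drew β log-normally (σ_ln = 1) on epochs of T_true = 16 h
with relaxation time τ_true = 1 h. The pipeline recovers the timescales
(T within a factor of two — kurtosis-crossing estimates of T are
conservative at finite record length — and τ to 5%), confirms the
separation τ ≪ T, and AIC correctly identifies the log-normal β-law
against the other three candidates from 795 extracted windows.
`autoplot(report$kurtosis_curve)`, `autoplot(report$betas, report$fits)`
and `plot_qgaussian_fit()` draw the standard diagnostic figures;
`sweep_detrend_parameter()` tabulates T against the detrending parameter,
including the breakdown regime where κ̄ stays below 3 and no T exists.
Real records enter through `read_series()` + `regularize()`, and
`inst/scripts/superstat-pipeline.R` wraps the pipeline for shell use.

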