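# conflictdyn

Dwell-time and fluctuation analysis of dyadic conflict time series.

When two people argue toward (or away from) consensus, their moment-to-moment
dynamics can be coded once per second: a **behavior stream** of discrete
states — 1 *proself*, 2 *neutral*, 3 *prosocial* — and an **emotion stream**
of continuous valence self-reports recorded as screen pixels in [0, 1123].
`conflictdyn` provides, for researchers in quantitative behavioral science
and conflict research, the statistical machinery to ask whether these
dynamics carry *memory*:

* **Behavior.** If state switching were Markov (constant switching
  probability per second), dwell times t in a state would follow a single
  exponential `PDF(t) = A·exp(−a·t)`. The package estimates the dwell-time
  density with a multi-bin-size histogram method (fine bins for the head,
  coarse bins for the sparse tail), and compares least-squares fits of the
  single exponential, the power law `A·t^(−α)`, and the stretched
  exponential `A·exp(−(a·t)^b)`, ranking them by R² on log–log axes. An
  exponent b < 1 means the effective switching rate
  `k(t) = PDF(t) / ∫ₜ^∞ PDF(u) du` *decreases* with time already spent in
  the state — behavioral memory. `effective_rate_constant()` computes k(t)
  from any fitted law.
* **Emotion.** Hurst rescaled-range (R/S) analysis of the valence
  increments, power spectral density of the raw trace by four estimators
  (FFT, periodogram, Welch, Thomson multitaper), log–log tail slopes, and
  the fBm/fGn identity `|slope| = 2H + 1` linking the two. H ≈ 0.5 and
  slope ≈ −2 together indicate an uncorrelated random walk — no emotional
  memory. Shuffle surrogates and mean-split dichotomization (crossing
  intervals, first-return `t^(−3/2)` diagnostic) complete the toolkit.
* **Groups.** Exact (enumerated) or tie-corrected approximate Mann-Whitney
  U tests between the *intractable* and *tractable* dyad groups, metric
  tables with per-group AVERAGES rows, and an exploratory bootstrap
  interval for a difference in stretching exponents.
* **Synthetic data.** A deterministic generator — semi-Markov behavior
  chains with stretched-exponential dwell times, bounded random-walk or
  fractional-Gaussian-noise emotion traces, the full 11 + 12 dyad study
  shape with occasional missing persons — so every estimator is testable
  against known ground truth.

## A worked example

```r
library(conflictdyn)

cfg <- pipeline_config(gen_config = study_gen_config(master_seed = 11),
                       master_seed = 11)
bundle <- run_pipeline(cfg)

subset(bundle$fits, rank == 1 & state == "123",
       select = c(group, state, form, exponent_b, r_squared))
#>          group state                  form exponent_b r_squared
#> 10 intractable   123 stretched_exponential  0.3870393 0.9591495
#> 22   tractable   123 stretched_exponential  0.3581922 0.9208220

tail(as.data.frame(bundle$metrics), 2)[, c("dyad", "group", "tail_slope", "hurst_H")]
#>        dyad       group tail_slope   hurst_H
#> 42 AVERAGES intractable  -1.767996 0.5740541
#> 43 AVERAGES   tractable  -1.735076 0.5573367

bundle$tests[, c("metric", "u_statistic", "p_two_sided", "method")]
#>         metric u_statistic p_two_sided               method
#> 1      hurst_H         274  0.06589092 normal_approximation
#> 2 rs_r_squared         179  0.51676588 normal_approximation
```

Reading the output: the stretched exponential ranks first for the pooled
("123") dwell times of both groups with exponents near 0.36–0.39 —
state switching slows down the longer a state has been held. The
per-person emotion metrics average to Hurst exponents just above 0.5 and
PSD tail slopes near −1.75: valence fluctuates like a random walk with
uncorrelated steps (the small systematic offsets from 0.5 and −2.0 are
known finite-sample properties of the estimators, documented in the
vignette). The two-sided Mann-Whitney tests find no group difference in
either emotion metric — correct for this generator, which draws both
groups from the same laws.

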