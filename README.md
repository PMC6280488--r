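# pphloss — lognormal analysis of postpartum blood loss

Postpartum haemorrhage (PPH, blood loss ≥ 500 mL within 24 h of birth; severe
PPH ≥ 1000 mL) is the leading direct cause of maternal mortality worldwide.
Prevention trials conventionally dichotomise the measured blood-loss volume
at those cutoffs and compare binomial proportions — throwing away most of
the information in a continuous, right-skewed measurement and forcing trials
of tens of thousands of women.

`pphloss` is for trial statisticians and methodologists who want to analyse
the volume itself. It models blood loss V with the **threshold
(three-parameter) lognormal distribution**

    V = t + exp(m + s·Z),   Z ~ N(0,1),   log(V − t) ~ N(m, s²),

where m is the location (median volume is t + e^m), s the scale of
log-volume, and t a threshold shift that absorbs measurement offsets. Event
probabilities are then survival-function values of the fitted law —
P(V > 1000) is the sPPH probability — estimated far more precisely than raw
proportions, with delta-method intervals, matched-row bootstrap relative
risks, and an order-of-magnitude sample-size reduction for future trials.

The package provides:

* `dlnorm3` / `plnorm3` / `slnorm3` / `qlnorm3` / `rlnorm3` — the threshold
  lognormal distribution functions;
* `fit_mle_2p`, `fit_mle_3p` — closed-form and profile-likelihood maximum
  likelihood, with observed-information standard errors; `fit_from_quantiles`
  recovers parameters from published percentiles; `compare_fits` ranks by
  AIC/BIC;
* `tail_lognormal`, `tail_binomial`, `width_ratio`, `median_ratio` —
  per-arm event-probability estimation by both approaches;
* `rr_binomial` (Katz interval) and `rr_lognormal_bootstrap` (matched-row
  percentile bootstrap) for two-arm relative risks;
* `n_binomial`, `n_lognormal`, `target_location`, `savings_ratio` — trial
  sample sizes by both methods;
* `digit_preference`, `lod_assess`, `probability_plot_data`, `qq_data`,
  `cdf_overlay_data` — measurement diagnostics and goodness-of-fit plot data;
* `trial_scenario` / `generate_blood_loss` — a synthetic trial generator with
  realistic digit heaping and limit-of-detection smearing;
* `read_samples` / `run_full_analysis` — a CSV-driven pipeline, also exposed
  by the `inst/exec/pphloss` command-line script.

## Worked example

Simulate a trial-scale two-arm study with heavy digit preference and a
100 mL limit of detection, then analyse it end to end:

```r
library(pphloss)

trial <- generate_blood_loss(trial_scenario("misoprostol", n_per_arm = 9000, seed = 42))
s1 <- trial$samples$misoprostol

digit_preference(s1)
#>   multiple expected_freq observed_freq     ratio
#> 1       10          0.10     0.8136667  8.136667
#> 2       50          0.02     0.5337778 26.688889
#> 3      100          0.01     0.3847778 38.477778

lod_assess(s1)
#>   candidate_lod uniformity_stat   p_value n_below flag note
#> 1            50      0.05076923 0.1924095     454 TRUE
#> 2           100      0.02078850 0.8072171     948 TRUE

fit <- fit_mle_3p(s1)
fit
#> lognormal3p fit (mle) to 'misoprostol', n = 9000
#>   estimate     se ci95_lower ci95_upper
#> m   5.7590 0.0148     5.7300     5.7880
#> s   0.6311 0.0096     0.6123     0.6498
#> t -58.8318 3.4308   -65.5562   -52.1075
#> logLik -60458.50, AIC 120923.00, BIC 120944.32

tail_lognormal(fit, 1000)
#> P(V > 1000) [lognormal, arm 'misoprostol', n = 9000]: 0.02801 (95% CI 0.02559-0.03065, width 0.00506)
tail_binomial(s1, 1000)
#> P(V > 1000) [binomial, arm 'misoprostol', n = 9000]: 0.03311 (95% CI 0.02961-0.03701, width 0.00741)
width_ratio(tail_lognormal(fit, 1000), tail_binomial(s1, 1000))
#> [1] 68.35962
```

The sample heaps massively on round numbers (38× the expected frequency of
multiples of 100), and both 50 and 100 mL are flagged as plausible detection
limits — the generator smeared values below 100. The binomial sPPH estimate
(0.0331) sits above the lognormal one (0.0280) because rounding to the
nearest 100 pushes mass across the 1000 mL boundary; the generating law's
true tail is 0.0299. The lognormal interval is 68% of the binomial width:
the efficiency gain of using the whole distribution.

Comparing the arms, and sizing a future trial:

```r
rr_lognormal_bootstrap(s1, trial$samples$oxytocin, 1000, n_boot = 1000, seed = 7)
#> RR of blood loss >= 1000 [lognormal]: 1.638 (95% CI 1.416-1.885)
#>   1000 matched-row bootstrap replicates (seed 7, 0 refits fell back to 2p, 0 redraws)

spec <- sample_size_spec(p1 = 0.02, p2 = 0.015)  # sPPH 2% vs 1.5%, one-sided 5%, 80% power
n_binomial(spec)
#> binomial method: 8504 per group, 17008 total
n_lognormal(spec)
#> lognormal method: 914 per group, 1828 total
```

Detecting a 2% → 1.5% sPPH improvement needs 17,008 participants with the
binomial analysis but only 1828 — about 11% — when the comparison is carried
out on the log-volume means.

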