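# capconn

Time-resolved **directed** connectivity for multi-ROI neural time series,
measured as the **water-filling channel capacity** of a fitted
finite-impulse-response (FIR) Gaussian channel.

Functional connectivity tools usually report symmetric correlations;
directed (effective) connectivity tools usually report test statistics
without a physical unit. `capconn` sits between the two: within each
sliding window, the interaction from a sender region to a receiver region
is modelled as

    y_t = a_0 x_t + ... + a_{k-1} x_{t-k+1} + w_t,   w_t ~ N(0, sigma^2),  a_j >= 0,

fitted by nonnegative least squares on standardized signals with
information-criterion selection of the order *k* (the *connection
duration*, in TRs). The fitted channel is summarised by its Shannon
capacity under a unit sender-power constraint,

    C = max over power allocations of  (1/2N) * sum_l log(lambda / S_EIN(f_l)),
    S_EIN(f) = sigma^2 / |H(f)|^2,

computed by discretized water-filling over the equivalent-input-noise
spectrum — a directed, noise-aware information rate (bits per sample by
default). Alongside capacity the package returns the sliding-window
correlation (SWC), the prediction-correlation (SWpC) and the duration
series, plus the validation machinery around the measure: task-sensitivity
testing (CV screen + paired t-tests + FDR), directional-asymmetry
specificity testing (left-tailed Wilcoxon against scan-to-scan
variability), bootstrap cross-modal correspondence, and k-means brain-state
clustering with elbow selection and centroid alignment. Synthetic
generators for every analysis are included and power the test suite.

Audience: researchers analysing fMRI / LFP band-limited power / wide-field
calcium ROI time series who want a directed, time-resolved,
physically-interpretable connectivity measure with its validation
statistics in one place.

## Worked example

```r
library(capconn)

# a synthetic sender -> receiver pair from the generative channel model:
# taps (0.6, 0.3), receiver noise SD 0.7, 600 samples at TR = 1 s
ts <- simulate_pair(taps = c(0.6, 0.3), noise_sd = 0.7, n_timepoints = 600,
                    tr_seconds = 1, seed = 42)

plan <- plan_windows(600, 50, 10)            # 56 windows of 50 s, step 10 s
res <- sliding_capacity(ts$values["sender", ], ts$values["receiver", ], plan,
                        order_config("BIC", k_max = 4), grid_size = 2048)
head(res, 3)
#>   window_index window_start_s capacity pcorr   swc duration_trs
#> 1            1              0    0.549 0.724 0.596            2
#> 2            2             10    0.647 0.771 0.644            2
#> 3            3             20    0.672 0.780 0.670            2

mean(res$capacity)        # 0.469 bits/sample: sustained forward channel
median(res$duration_trs)  # 2 TRs: the fitted channel memory matches the taps
```

The reverse direction, fitted the same way, averages 0.316 bits — lower,
but not zero: with contemporaneous coupling (`a_0 > 0`) the lag-0 column of
the reverse regression still captures shared variance. Purely lagged
couplings separate the directions sharply, and the statistical layer
(`specificity_test`) quantifies when an asymmetry exceeds ordinary
scan-to-scan fluctuation.

A window's capacity of 0.549 bits means: under the fitted taps and noise,
at most 0.549 bits per sample could be transmitted reliably from sender to
receiver — the capacity of the interaction, not just its strength; `pcorr`
is the correlation between observed and model-predicted receiver, and `swc`
the ordinary windowed correlation for comparison.

Higher-level drivers: `connectivity_pairs()` (all directed pairs, long
format), `run_connectivity()` (file outputs + resolved config),
`time_average_matrix()`, `fit_states()` / `align_centroids()`,
`sensitivity_test()` / `specificity_test()` /
`bootstrap_window_correlation()` / `bootstrap_matrix_correlation()`.
A thin command-line front end is installed at
`system.file("cli", "capconn", package = "capconn")` with subcommands
`simulate`, `connectivity` and `validate`.

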