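---
title: "Water-filling channel capacity as a time-resolved directed connectivity measure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Water-filling channel capacity as a time-resolved directed connectivity measure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(capconn)
```

## The model

`capconn` treats the directed interaction from one region of interest (ROI)
to another as a communication channel. Within a short analysis window the
channel is approximated as linear and time-invariant with a finite impulse
response (FIR):

$$y_t = a_0 x_t + a_1 x_{t-1} + \dots + a_{k-1} x_{t-k+1} + w_t,
\qquad w_t \sim \mathcal N(0, \sigma^2),$$

where $x_t$ is the sender signal, $y_t$ the receiver signal, and $w_t$
additive white Gaussian noise independent of the sender. The taps
$a_0,\dots,a_{k-1}$ are constrained to be **nonnegative**: in globally
signal-regressed neuroimaging data, negative couplings are hard to
interpret, so the model class is restricted to nonnegative connectivity and
"no positive channel" is represented by the all-zero tap vector rather than
by an error.

The fitted channel is summarised by its **Shannon capacity under a unit
sender power constraint**. With frequency response
$H(f) = \sum_j a_j e^{-2\pi i j f}$ the equivalent input noise (EIN) has
power spectral density $S_{\mathrm{EIN}}(f) = \sigma^2 / |H(f)|^2$, and

$$C = \int_0^{1/2} \big[\log \lambda / S_{\mathrm{EIN}}(f)\big]^+ df,
\qquad \tfrac12 = \int_0^{1/2} \big[\lambda - S_{\mathrm{EIN}}(f)\big]^+ df,$$

the classical water-filling solution: sender power fills the valleys of the
EIN spectrum up to the water level $\lambda$. Capacity is an interpretable
"maximum reliable information rate" for the fitted interaction, explicitly
incorporating the noise estimate — a property plain correlation measures
lack.

## Fitting one window

1. **Standardization.** The receiver and every lagged sender column are
   centred and divided by their root mean square (population divisor $n$).
   This enforces the unit power constraint exactly and gives the order-1
   fit a closed form: $\hat a_0 = \max(r, 0)$,
   $\hat\sigma^2 = 1 - \hat a_0 (2r - \hat a_0)$, with $r$ the sample
   correlation.
2. **NNLS.** Taps solve $\min_{a \ge 0} \lVert Xa - y\rVert^2$ via
   Lawson–Hanson active-set NNLS (`pracma::lsqnonneg`), a deterministic
   convex program; $\hat\sigma^2$ is the mean squared residual.
3. **Order selection.** Orders $1 \dots k_{\max}$ are fitted and scored by
   an information criterion computed from the Gaussian log-likelihood:
   AIC $= n\ln\hat\sigma^2 + 2k$, BIC $= n\ln\hat\sigma^2 + k\ln n$,
   AICc $=$ AIC $+ 2k(k+1)/(n-k-1)$, with $k$ counting taps only (the
   shared noise parameter cancels from every comparison). Ties break to
   the smaller order. The selected order, in TR units, is the
   **connection duration** — the effective channel memory. The default
   $k_{\max} = \min(8, \lfloor n/10 \rfloor)$ keeps the regression
   comfortably overdetermined; AICc is recommended for very short
   (single-trial) windows, BIC for long resting-state scans.
4. **Lag boundary.** Lagged sender values for rows near the window start
   are taken from the samples immediately preceding the window when the
   caller supplies them (`use_lookback = TRUE`, the default in the sliding
   driver); otherwise the first $k-1$ rows are truncated so only fully
   observed lag vectors are regressed. No data are fabricated either way.
   Both behaviours are exposed because either is a defensible reading of
   the windowed regression; results differ only in the first window of a
   scan and in $O(k/n)$ rows elsewhere.

## Estimating capacity numerically

The frequency response is evaluated by FFT of the tap vector zero-padded to
an $N$-point grid ($N = 4096$ by default — a power of two on which
capacities of channels up to order 8 are converged to better than $10^{-3}$
relative; the grid-refinement check in the test suite quantifies this, and
`grid_size` is configurable). Bins whose squared response falls below
$\max|H|^2 \cdot \varepsilon^{1.5}$ are treated as exact spectral nulls and
carry infinite EIN; they can never enter the active set, so they contribute
no information and no power.

Water-filling sorts the finite EIN values ascending and iterates the
candidate level $\hat\lambda_m = (N + \sum_{l<m} S^{(l)})/m$; the active
set is the largest $m$ with $\hat\lambda_m > S^{(m)}$ (the standard
active-set rule, which coincides with stopping at the first
$\hat\lambda_m \le S^{(m+1)}$ on non-degenerate inputs). By construction
the active bins absorb exactly the unit power budget, which the code
asserts at $10^{-9}$ relative. Capacity is
$(2N)^{-1}\sum_{l<m}\log(\hat\lambda_m/S^{(l)})$; the full-grid sum over
the conjugate-symmetric spectrum equals folded integration over
$[0, \tfrac12]$, also asserted in tests. The numerator $N$ of
$\hat\lambda_m$ is kept even when some bins are infinite: the power budget
is defined over the whole band. Internally the logarithm is natural;
results are reported in **bits** by default with a `{bits, nats}` switch,
since the capacity unit is otherwise ambiguous.

The implementation is cross-checked in the test suite against an
independent oracle — bisection on $\lambda$ in
$\sum(\lambda - S)^+ = N$ — and agrees to ~$10^{-14}$ relative over random
channels.

## The sliding-window framework

Long recordings are divided into $M = \lfloor (T-n)/\text{step}\rfloor + 1$
windows; window length and step are meta-parameters chosen on
neurophysiological grounds (typical settings: 50 s windows with a 1 TR
step). Per window and directed pair the package reports four aligned
series: channel **capacity**, **SWpC** (prediction-correlation,
$\mathrm{corr}(y, X\hat a)$, recorded as 0 for all-zero fits),
**SWC** (plain Pearson correlation of the raw segments, the
non-directional baseline) and **duration** ($\hat k$, in TRs). Degenerate
windows (constant segments) yield missing values in all four series at
their window index rather than being dropped, so windows stay pairable
across measures and across simultaneously recorded modalities. A plan with
one full-length window reproduces trial-level analysis of short task
blocks. The estimation path contains no randomness: reruns are
bit-identical.

## Validation statistics

* **Sensitivity** (`sensitivity_test`): directed pairs are screened for
  stable task-evoked capacity (between-unit CV < 30%), then tested for a
  task > rest increase with within-unit right-tailed paired t-tests,
  Benjamini–Hochberg corrected (default q < 0.02). Pairing is at the
  subject level (subject means over trials); trial-level pairing would
  inflate the degrees of freedom.
* **Specificity** (`specificity_test`): under a resting-state null no
  systematic directional bias is expected between homotopic regions.
  Per scan the *absolute* difference of the two directions' time-averaged
  connectivity is compared against the scan-to-scan standard deviation of
  the (direction-averaged) time-averaged connectivity, with a left-tailed
  Wilcoxon signed-rank test of H0: median asymmetry ≥ variability
  (exact distribution up to 25 scans, normal approximation with continuity
  correction above — and whenever ties or zero differences make the exact
  distribution undefined). Rejection means asymmetry is small relative to
  ordinary between-scan fluctuation. The absolute difference is the
  conservative reading: the null specifies no direction, so a signed test
  would smuggle in one.
* **Cross-modal correspondence** (`bootstrap_window_correlation`,
  `bootstrap_matrix_correlation`): windowed capacity series from two
  concurrent modalities are correlated, with uncertainty from resampling
  windows with replacement within scan (time-resolved) or scans with
  replacement (time-averaged matrices). Both are bit-reproducible given a
  seed.

## Brain states

Window-resolved directed capacity matrices are vectorized over off-diagonal
entries, pooled across scans, and clustered by k-means (Lloyd iterations,
six initializations per candidate $k$, best WCSS kept). Features enter
unscaled: capacity entries already share units. Two deliberate choices:

* **Initialization.** Each run is seeded with k-means++ centers. Plain
  random-row starts miss one of four well-separated planted clusters in a
  large fraction of initializations, turning the subsequent model-order
  choice into a lottery; k-means++ is the de facto standard remedy and
  keeps six initializations sufficient for stability.
* **Elbow rule.** The number of states is the maximizer of the discrete
  second difference of $\log$ WCSS over the candidate range — curvature
  on the ratio scale, so "drop then plateau" beats a large early absolute
  drop (to which the plain normalized second difference is vulnerable when
  planted centroids are unequally spaced). If clustering never removes
  more than 30% of the total variance across the whole range, the curve is
  considered elbow-free and $k = 1$ is returned. On planted 4-state
  features this rule selects $k = 4$ with adjusted Rand index 1 across
  seeds; on single-Gaussian features it returns $k = 1$.

Centroids from two modalities (or two measures) are aligned by exhaustive
search over all $k!$ relabelings, maximizing the summed Pearson correlation
of matched centroids (guarded to $k \le 8$); state time courses are then
compared as numeric label sequences over shared windows.

## What the generators emulate — and what they do not

`simulate_pair` draws data exactly from the FIR/AWGN model class (white
Gaussian sender by default; AR(1) and band-limited senders probe colored
inputs). `simulate_bilateral_null` drives two regions from one shared
filtered latent with independent noise and per-scan lognormal gain jitter
(SD 0.35), making the directions exchangeable while creating genuine
scan-to-scan variability. `simulate_directed_pairs` couples one way only,
through a pure one-TR delay, so the reverse regression finds no channel.
`simulate_task_rest` builds 16-sample single-window trials (coupling in
task trials of planted pairs only) and returns subject-mean capacity
samples. `simulate_state_sessions` emits window features around planted
centroids; `simulate_switching_session` emits full multi-ROI series whose
coupling matrix alternates between planted states.

These generators satisfy every assumption the estimator makes, so
recovery tests are well-posed — and that is also their limit. Real BOLD,
LFP band-limited power and calcium signals are non-Gaussian, autocorrelated,
hemodynamically filtered and confounded by unmodelled third regions; a
passing test suite demonstrates correctness of the estimators under the
model class, not robustness of the scientific conclusions to violations of
it. No hemodynamic convolution is applied by default: the method operates
on whatever signals it is given.

## Problem sizes and numerical conventions

The simulation studies in the test suite and acceptance script use
desk-scale versions of the designs: 22 scans of 300 samples with 50-sample
windows stepped by 25 for the specificity null (100 meta-replicates each
way); 20 pairs × 30 subjects with a 1.5-SD planted shift for sensitivity
(200 planted / 1000 null seeds); 2000 windows × 30 features for the
4-state recovery (20 seeds); mixed-duration windows of 200 samples for the
capacity–p-corr relation. Capacity grids use $N$ = 256–4096 depending on
the check. All seeds are fixed; every generator restores the caller's RNG
state.

One further convention: the dispersion of capacity around
prediction-correlation is quantified per duration as the squared Pearson
correlation between capacity and the order-1 capacity-equivalent of p-corr,
$-\tfrac12\log(1-r^2)$ (`capacity_pcorr_r2`). On this scale duration 1 is
exactly deterministic ($R^2 = 1$), and dispersion grows with duration; a
plain linear $R^2$ would instead be dominated by the curvature of the
duration-1 relation itself.

## Known limitations

* Pairwise model: no conditioning on other regions, so shared drive can
  appear as mutual capacity in both directions (the specificity test's
  contemporaneous null is exactly this regime).
* Nonnegativity discards genuinely inhibitory couplings by design.
* The capacity of a *fitted* channel inherits estimation noise from
  $\hat a$ and $\hat\sigma^2$; at small windows capacity is biased upward
  under the null (a fitted spurious tap always has nonnegative capacity).
  Null-referenced testing, as in the validation procedures, is therefore
  preferred over thresholding raw capacities.
* The elbow rule is a heuristic; it is validated here only on planted-state
  simulations.
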