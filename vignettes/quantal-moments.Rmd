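---
title: "Moment-based quantal analysis of facilitating synapses"
author: "quantalmoments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Moment-based quantal analysis of facilitating synapses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quantalmoments)
```

## The estimation problem

Repetitive stimulation of a chemical synapse under voltage clamp yields a
train of evoked EPSCs whose peak amplitudes fluctuate from sweep to sweep.
Under the quantal hypothesis the amplitude evoked by stimulus $i$ on one
sweep is

$$A_i = q_{\mathrm{sweep}} \, k_i + \eta_i, \qquad
  k_i \sim \mathrm{Binomial}(N, p_i), \qquad
  \eta_i \sim \mathcal N(0, \sigma_\eta^2),$$

where $q_{\mathrm{sweep}}$ is the quantal size (pA) of that sweep, $N$ the
effective number of release sites participating early in the train, $p_i$
the stimulus-dependent release probability, and $\eta_i$ measurement
noise. At facilitating synapses $p_i$ rises across the train through
presynaptic calcium accumulation, so classical stationary-binomial methods
(variance–mean analysis) are poorly matched to the data. The quantal size
is additionally allowed to fluctuate *across* sweeps — receptor state,
access resistance and other slow factors — while staying constant within a
sweep. That sweep-level fluctuation is exactly what produces positive
covariance between EPSC amplitudes at different train positions, and the
package's central idea is to exploit that covariance rather than treat it
as a nuisance.

## Moments and the composite observable

Writing $\mu_i = \mathbb E[A_i]$, the model implies

$$\mu_i = \bar q N p_i, \qquad
  \mathrm{Var}(A_i) = \mathbb E[q^2] N p_i (1 - p_i)
    + \sigma_q^2 N^2 p_i^2 + \sigma_\eta^2, \qquad
  \mathrm{Cov}(A_i, A_j) = \sigma_q^2 N^2 p_i p_j \;(i \ne j),$$

with $\mathbb E[q^2] = \bar q^2 + \sigma_q^2$. The quadratic
$\sigma_q^2 N^2 p_i^2$ term in the variance blocks direct inference, but
it reappears in the covariance, and since
$\mu_i / \mu_j = p_i / p_j$, the fully observable combination

$$F(i,j) = \mathrm{Var}(A_i) - \frac{\mu_i}{\mu_j}\,\mathrm{Cov}(A_i,A_j)
  - \sigma_\eta^2 = \mathbb E[q^2]\, N p_i (1 - p_i)$$

cancels it exactly (`composite_F()`; the identity is asserted to 1e-10
relative in the test suite against the analytic moment oracle). The
noise variance $\sigma_\eta^2$ is an *input*: it is measured from the
pre-stimulus baseline (`estimate_noise_variance()`) or supplied, never
re-estimated from the amplitudes.

The normalized quantal variability $R = \sigma_q^2 / \bar q^2$ is itself
observable, because every covariance-to-mean-product ratio has population
value $R$:

$$\hat R = \mathrm{mean}_{i<j} \frac{\mathrm{Cov}(A_i,A_j)}{\mu_i \mu_j}.$$

`quantal_cv_ratio()` clamps $\hat R$ at zero (it estimates a variance
ratio) and warns when more than a quarter of the pairwise ratios are
negative, a sign the covariance signal is noise-dominated.

## Closed-form estimators

Combining $F$ from two stimulus pairs eliminates $N$, giving the corrected
closed form (for an index tuple $(i,j,k,l)$, all four distinct)

$$\hat q = \frac{\mu_k^2 F(i,j) - \mu_i^2 F(k,l)}
  {\mu_k \mu_i (1 + \hat R)(\mu_k - \mu_i)}, \qquad
  \hat N = \frac{\mu_i^2}{\mu_i \hat q - F(i,j)/(1+\hat R)}, \qquad
  \hat p_i = \frac{\mu_i}{\hat q \hat N}.$$

With $\hat R = 0$ these reduce to the *fast* branch for data whose
sweep-level quantal variability is negligible; the *detailed* branch
(default) estimates $\hat R$ first. On population moments the chain is an
identity — feeding `analytic_moments()` output through
`quantal_estimate_moments()` returns the generative $\bar q$, $N$, $p_i$
to machine precision, for any admissible parameter set. This exactness is
the package's core regression test.

Requiring all four tuple indices to be pairwise distinct is what makes
four stimuli the structural minimum: paired-pulse and three-stimulus
protocols cannot support the estimator (`release_tuples()` is empty for
$K < 4$).

### Aggregation and outlier handling

On finite data every admissible tuple yields a candidate $\hat q$, and
every ordered pair a candidate $\hat N$. Two facts shape the aggregation:

* A candidate whose denominator separation $|\mu_k - \mu_i|$ is not
  resolved by the data is a draw from a reciprocal (Cauchy-like)
  distribution. On a facilitation plateau adjacent means differ by a few
  pA while their sampling SE at 20 sweeps is comparable, so a plain mean
  over candidates is dominated by the blow-up tail. Tuples with
  $|\mu_k - \mu_i| < 4\,\mathrm{SE}(\mu_k - \mu_i)$ (the SE uses the
  sample variances and the pair covariance) are therefore rejected as
  noise-dominated (`sep_se` argument; the screen vanishes on population
  moments, where the SE is zero).
* The surviving candidate set is a tight cluster plus a roughly symmetric
  residual tail. Extremes are removed with a two-sided robust band
  (median ± 3 × scaled MAD — a mean/SD band does not converge on a
  heavy-tailed set), negatives are discarded as non-physical, and the
  survivors are averaged. The same robust band precedes the pool-size
  rule. For $\hat N$ the *maximum* of the surviving candidates is
  reported: covariance-based candidates are expected to underestimate the
  participating pool at real synapses (reserve sites contribute nothing
  to the fluctuations), so the maximal stable value is the conservative
  choice. Candidates with a non-positive denominator are counted as
  rejections, and the rejection fraction is a useful per-cell quality
  signal — it rises with noise and falls with sweep count.

Out-of-range release probabilities ($\hat p_i \notin [0,1]$) are flagged,
never clipped, so downstream calibration sees the raw estimate.

## Tsodyks–Markram calibration of the pool size

$\hat q$ is the stable output of the moment chain; $\hat N$ (and hence
$\hat p_i$) is intrinsically dispersed under strong facilitation. The
calibration step regularizes it with the standard discrete
short-term-plasticity recursion: with utilization $U$ and resources $X$,
state at stimulus 1 is $U_1 = U_0$, $X_1 = 1$, release probability
$p_i = U_i X_i$, and

$$U_{i+1} = U_i e^{-\Delta t/\tau_f} + U_0\!\left(1 - U_i e^{-\Delta t/\tau_f}\right),
\qquad
X_{i+1} = 1 - \left(1 - X_i (1 - U_i)\right) e^{-\Delta t/\tau_d}.$$

Utilization is boosted by each pulse and decays back to $U_0$ with the
facilitation constant $\tau_f$; resources are consumed by the released
fraction and recover toward 1 with $\tau_d$. An alternative
discrete-update form occasionally seen in print — in which the recovery
factor multiplies the post-release resources directly, so that *longer*
intervals produce *less* recovery, and the two exponentials mix $\tau_d$
and $\tau_f$ — is provided behind `recursion = "alternative"` for
comparison only; it inverts the physiology and is never used in fitting.

`calibrate_tm()` minimizes
$\sum_i \left(\mu_i - \hat q\, N_{\mathrm{cal}}\, p_i(U_0, \tau_d, \tau_f)\right)^2$
over $(U_0, \tau_d, \tau_f, N_{\mathrm{cal}})$ with the moment-derived
$\hat q$ held fixed as the scaling constraint. Numerical choices:

* Box bounds $U_0 \in [0.01, 1]$, $\tau_d, \tau_f \in [1, 5000]$ ms,
  $N_{\mathrm{cal}} \in [1, 5000]$; $\tau$ and $N_{\mathrm{cal}}$ are
  optimized on a log10 scale.
* Nelder–Mead on the box-projected objective, restarted from `n_starts`
  Latin-hypercube points (default 10) under a fixed seed. The surface is
  smooth but ill-conditioned along $(\tau_f, N_{\mathrm{cal}})$, where
  finite-difference gradient methods stall measurably above the optimum;
  Nelder–Mead recovers exact noise-free round-trips to SSE ~1e-11.
* Under trajectory noise the objective has a ridge along
  $(U_0, N_{\mathrm{cal}})$: boundary solutions with $U_0$ at its lower
  bound and implausibly large pools can undercut interior fits by less
  than the sampling noise of the SSE. Starts whose SSE is within 25% of
  the best (`tie_tol`) are therefore treated as statistical ties,
  resolved toward the smallest $N_{\mathrm{cal}}$ — the most parsimonious
  pool consistent with the data. Exact fits are unaffected, because the
  band collapses with the SSE.
* A constant trajectory leaves $\tau_f$ unidentifiable; the fit still
  converges (to a no-dynamics solution) and the result carries a
  `flat_trajectory` flag.

## The variance–mean baseline

`vm_estimate()` implements the classical multiple-probability
variance–mean parabola, noise-corrected and fit by unweighted least
squares over stimulus positions:
$\mathrm{Var}(A_i) - \sigma_\eta^2 = q\mu_i - \mu_i^2/N$. It deliberately
ignores cross-stimulus covariance. That is not an implementation
shortcut; it is the baseline's defining assumption, and it is why the
method breaks under facilitation with sweep-level quantal variability:
the covariance term leaks $R\mu_i^2$ into every variance, shifting the
population curvature from $-1/N$ to $R - (1+R)/N$. At $R = 0.04$ and
$N = 20$ the population pool estimate is already $83$ instead of $20$,
and at finite sweep counts the noisy curvature frequently turns
non-negative, in which case the fit is reported as non-physical
($N_{\mathrm{vm}}$ unavailable) rather than silently clipped.

## The generative simulator

Every stage above is testable without recordings because the simulator
produces data from the exact generative model:

* `simulate_sweeps()` — homogeneous mode: one truncated-normal
  $q_{\mathrm{sweep}}$ per sweep (truncation at zero by rejection),
  independent binomial release counts per stimulus given the sweep, and
  additive Gaussian noise. Release counts are *not* coupled across
  stimuli within a sweep: there is no depletion carry-over, which is the
  regime in which the covariance identity
  $\mathrm{Cov} = \sigma_q^2 N^2 p_i p_j$ is exact.
* `simulate_heterogeneous()` — site-level mode: per-site quantal sizes
  $q_m \sim \mathcal N(\bar q, \sigma_{q,\mathrm{site}})$ and
  per-site probability offsets
  $\delta_m \sim \mathcal N(0, \sigma_{p,\mathrm{site}})$ drawn once per
  cell; site $m$ releases on stimulus $i$ with probability
  $\mathrm{clip}(p_i + \delta_m, 0, 1)$. The sweep-level quantal factor
  is disabled by default so the site-level effects are isolated
  (`combine_sweep_variability = TRUE` overlays both).
* `analytic_moments()` — the closed-form population moments, used as the
  independent oracle throughout the tests. It ignores the zero
  truncation of the quantal draw; the induced mean shift is
  $\sigma \varphi(\bar q/\sigma)/\Phi(\bar q/\sigma)$, i.e. at most
  ~2.8% of $\bar q$ at the largest supported CV (0.5) and under 0.1% at
  CV 0.3, so oracle-exactness checks are run at CV ≤ 0.3.

What the simulator does **not** emulate — and hence what green tests do
not certify about real recordings: within-sweep vesicle depletion
(release counts are conditionally independent across stimuli),
stimulus-artifact structure and temporally correlated noise (noise is
white Gaussian), correlated site properties (site $q$ and $p$ offsets
are drawn independently), and any slow drift across the session beyond
the sweep-exchangeable quantal factor.

### Study conditions

The default scenarios mirror the recordings the method targets: trains of
$K = 10$ stimuli at 50 Hz, 20 sweeps per cell, first-EPSC mean
$\bar q N p_1 = 20$ pA (inside the 10–50 pA range), quantal mean 10 pA
with CV 0.2, noise SD 2 pA (10% of the first-EPSC mean). `scenario_stf()`
uses $U_0 = 0.1$, $\tau_f = 200$ ms, $\tau_d = 50$ ms (release
probability rising from 0.1 to ~0.25 across the train);
`scenario_std()` uses $U_0 = 0.5$, $\tau_f = 20$ ms, $\tau_d = 300$ ms
(declining sequence).

The recovery studies run at sizes chosen for the quantity under test:
noise, quantal-CV and heterogeneity sweeps use 200 sweeps per cell
(moment sampling error small enough that the bias claims are about the
estimator, not the Monte Carlo), with 200 replicate cells (100 for
heterogeneity); the sweep-count study spans $T \in \{10, 20, 80, 320\}$;
and the calibration-dispersion study uses 80 sweeps per cell, following
the design rule that pool-size-related quantities need longer recordings
(~80+ sweeps) while $\hat q$ stabilizes by 20–30. Noise levels are
expressed as fractions of the mean first-stimulus EPSC. All sweeps reuse
the same per-replicate seeds across condition values (common random
numbers), so across-condition trends are paired comparisons.

## Preprocessing defaults

`extract_epsc_peaks()` reproduces the standard peak pipeline:
sign-normalization (EPSCs at −70 mV are inward, so traces are negated at
ingestion; configurable), median filtering (default window 5 samples,
zero-padded edges, matching the classic one-dimensional filter routine),
baseline level from the pre-train window, and per-stimulus maximum within
the inter-stimulus interval after a 2 ms artifact-blanking period. The
blanking duration and filter window are defaults of this package —
recordings differ, and both are arguments.

## Known limitations

* $\hat N$ is the method's fragile quantity, by construction: its
  denominator scales with $p_i^2$, so low-probability early stimuli
  dominate its noise. Expect wide dispersion below ~80 sweeps; the
  calibration step, not the raw maximum, is the reportable pool size.
* The $\hat R$ correction assumes the covariance is generated by
  sweep-level quantal fluctuation alone; any other shared sweep-level
  modulation (electrode drift, network state) inflates $\hat R$ and
  deflates $\hat q$.
* Site-level heterogeneity in release probability biases $\hat N$ upward
  and $\hat p_i$ downward; heterogeneity in quantal size biases
  $\hat q$ slightly upward. The heterogeneity sweep quantifies both
  directions under $\sigma_{q,\mathrm{site}} = 2$ pA,
  $\sigma_{p,\mathrm{site}} = 0.05$.
* The variance–mean comparison is directional only: the baseline's
  published variants differ in weighting and pooling, and at 20 sweeps
  its characteristic failure is a non-physical curvature sign rather
  than a finite inflated pool.
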