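# quantalmoments

Moment-based estimation of synaptic quantal parameters from trains of
evoked EPSCs, for electrophysiologists studying short-term facilitating
synapses (e.g. hippocampal CA3–CA1 Schaffer-collateral inputs).

## The problem and the method

A train of K stimuli evokes EPSC peak amplitudes recorded over T repeated
sweeps. Under the quantal model the amplitude at train position *i* is

```
A_i = q_sweep * k_i + eta_i,   k_i ~ Binomial(N, p_i),   eta_i ~ N(0, sigma_eta^2)
```

with quantal size `q_sweep` fluctuating across sweeps (mean `q`, SD
`sigma_q`), effective pool size `N`, and stimulus-dependent release
probability `p_i` that rises across the train at facilitating synapses.
Classical variance–mean analysis assumes stationary `p` and independent
trials, both violated here.

The method works entirely from first- and second-order moments computed
across sweeps. The sweep-level quantal fluctuation produces positive
cross-stimulus covariance `Cov(A_i, A_j) = sigma_q^2 N^2 p_i p_j`, and the
composite observable

```
F(i,j) = Var(A_i) - (mu_i/mu_j) Cov(A_i,A_j) - sigma_eta^2
       = E[q^2] N p_i (1 - p_i)
```

cancels both the measurement-noise floor and the quadratic latent term.
Combining F from two stimulus pairs (any tuple of four distinct indices)
eliminates N and yields a closed form for q, corrected for quantal
variability through the observable ratio `R = sigma_q^2 / q^2 =
Cov/(mu_i mu_j)`:

```
q_hat = (mu_k^2 F(i,j) - mu_i^2 F(k,l)) / (mu_k mu_i (1 + R_hat) (mu_k - mu_i))
N_hat = mu_i^2 / (mu_i q_hat - F(i,j)/(1 + R_hat))
p_hat_i = mu_i / (q_hat N_hat)
```

Candidates are enumerated over all admissible tuples, outliers rejected,
and a Tsodyks–Markram short-term-plasticity fit (utilization U, resources
X, `p_i = U_i X_i`) calibrates the pool size against the mean EPSC
trajectory with `q_hat` as a fixed scaling constraint. A classical
variance–mean baseline, a generative simulator, EPSC peak extraction from
raw traces, and a parameter-recovery harness complete the package.

## Worked example

Estimate from the bundled synthetic facilitating recording (20 sweeps,
10 stimuli at 50 Hz, simulated with q = 10 pA, N = 20, noise SD 2 pA):

```r
library(quantalmoments)

sm <- read_sweep_csv(system.file("extdata", "example_stf_sweeps.csv",
                                 package = "quantalmoments"))
sm
#> <sweep_matrix> 20 sweeps x 10 stimuli @ 50 Hz (ISI 20 ms)

fit <- quantal_estimate(sm, sigma_eta2 = attr(sm, "sigma_eta2"))
fit
#> <quantal_fit> branch = detailed
#>   q_hat = 10.32 pA (SD 4.93, 846/5040 candidates kept)
#>   N_hat = 25.47 (26 candidates rejected)
#>   R_hat = 0.05872
#>   p_hat:  0.0985 0.144 0.162 0.187 0.218 0.212 0.211 0.218 0.206 0.225
```

The quantal size lands within ~3% of the generative 10 pA from just 20
sweeps, and the release-probability sequence tracks the facilitation
profile (0.1 rising to ~0.25). The pool size is the noisy quantity at
this sweep count — its candidates blow up when `mu_i q_hat` and `F(i,j)`
nearly cancel — which is why `q_hat` is trusted directly while N is
refined by calibration:

```r
cal <- calibrate_tm(fit$moments$mu, fit$q_hat, dt = attr(sm, "isi_ms"), seed = 1)
tidy(cal)      # observed vs fitted means, calibrated U, X, p per stimulus
autoplot(cal)  # fit overlay
```

For pool-size work, record (or simulate) ~80+ sweeps;
`run_calibration_study()` quantifies the dispersion reduction calibration
brings at that scale. Simulation, estimation, calibration, comparison and
sensitivity analyses are also scriptable from the shell via the thin
wrapper:

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "quantalmoments.R", package="quantalmoments"))') \
  simulate --config truth.json --out out/
```

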