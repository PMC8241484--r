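# opscr

Open-population spatial capture–recapture (OPSCR) with cause-specific
mortality and bio-logger (GPS collar) effects.

## The problem

Survival inference for instrumented wildlife assumes collared animals are
representative of their population — an assumption that is hard to test
because comparable data from non-instrumented animals are rarely
available. Non-invasive genetic sampling (NGS) breaks the impasse: scat,
hair and urine samples identify individuals without capture, and collared
and non-collared animals appear in the same detection histories. `opscr`
implements the full modelling machinery needed to compare cause-specific
mortality between collared and non-collared individuals from such data,
plus a synthetic-study generator so the whole pipeline is testable by
simulation and parameter recovery.

## The model

Each of `M` (observed + augmented) individuals follows a four-state
categorical Markov chain over `T` monitoring seasons — unborn, alive, dead
from legal culling (fully reported), dead from other causes (mostly
cryptic; absorbing) — with

```
z[i,1] ~ dcat(1 - psi, psi, 0, 0)
logit(h[i,t]) = h0_t + beta_h_gps * GPS[i,t]      # legal culling
logit(w[i,t]) = w0_t + beta_w_gps * GPS[i,t]      # other causes
z[i,t] | z[i,t-1] = 2  ~  dcat(0, 1 - h - w, h, w)
```

Latent activity centres live on a discrete habitat grid (20 km cells, 60 km
buffer by default), placed by an inhomogeneous point process with intensity
`exp(b_dens * X)` and moved between seasons by an isotropic Gaussian random
walk (scale `tau`) re-weighted by the same intensity. Detections are
binomial counts of occupied 2 km subdetectors within 10 km detector cells,
with half-normal distance decay `p = p0 * exp(-d^2 / (2 sigma^2))` and a
logit-linear baseline in search effort, road distance, snow cover,
previous detection, county and collar status. Estimation is
Metropolis-within-Gibbs MCMC with exact forward-filtering
backward-sampling of the latent states, local likelihood evaluation, and
split-chain Gelman–Rubin diagnostics. The headline outputs are the two
logit-scale collar effects and the collared-versus-non-collared mortality
difference in percentage points with 95% credible intervals.

## Worked example

Simulate a reduced single-region study whose generating truth is the
published point estimates (non-collared cause-specific mortality 0.10 and
0.25; logit-scale collar effects −0.37 and −1.08; M = 300, five seasons,
roughly 20% of alive individual-seasons collared), then fit it:

```r
library(opscr)

study <- generate_study(study_config("flagship"), seed = 1)
study
#> OPSCR study: 5 seasons, 132 observed individuals, augmented to 300 in 1 stratum
#>   habitat: 81 cells of 20 km, 42 km buffer
#>   detectors: 100 cells of 10 km, subdetectors of 2 km
#>   positive counts: 526 ; collared individual-seasons: 124

fit <- run_mcmc(study, fit_config(chains = 4, iterations = 4000,
                                  burn = 2000, seed = 2, sigma_max = 7))
round(max(fit$rhat), 3)
#> [1] 1.02

posterior_summary(fit, c("beta_h_gps", "beta_w_gps"))
#>    parameter median lower upper
#> 1 beta_h_gps  -1.26 -2.42 -0.30
#> 2 beta_w_gps  -1.42 -2.59 -0.52

subset(derive_collar_contrasts(fit), measure == "overall",
       c(measure, diff_pp_median, diff_pp_lo, diff_pp_hi))
#>   measure diff_pp_median diff_pp_lo diff_pp_hi
#> 3 overall           24.4       13.1       35.8
```

The 95% credible intervals cover the generating collar effects (−0.37,
−1.08) and the derived overall mortality difference of the generating
truth (17.7 percentage points; 16 when computed from the rounded
cause-specific medians). `cmd_simulate()`, `cmd_fit()` and
`cmd_summarize()` (plus the thin wrapper in `inst/cli/opscr.R`) run the
same pipeline against on-disk CSV/ASCII-grid studies.

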