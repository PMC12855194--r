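# phenoswitch

Quantitative analysis of bistable phenotype heterogeneity in isogenic
multicellular ("snowflake") yeast populations.

Experimentally evolved and engineered multicellular *Saccharomyces
cerevisiae* populations carrying a loss-of-function mutation at the *ACE2*
locus split into two coexisting phenotypes: large multicellular clusters
(> 13 µm diameter) and small ancestral-like propagules (3–13 µm). This
package is for researchers who need to (a) characterise that bimodality
from particle-counter diameter tables and (b) fit a mechanistic switching
model to phenotype-proportion time courses.

## The model

Large clusters *M* grow by fragmentation and shed small clusters *U*
through a stochastic switch that activates around the post-diauxic
transition (~20 h of batch growth):

```
dM/dt = α·log₂(M) + η(t) + γ·U
dU/dt = S(t)·β·M − γ·U
S(t)  = 1 / (1 + exp(−k·(t − t_switch)))
```

with α the growth-rate coefficient of large clusters (per hour, acting on
the doubling-time term log₂ *M*), β the small-cluster production rate, γ
the reversion rate of small clusters back into large ones, η(*t*) additive
growth noise, and *S*(*t*) a logistic switch with steepness *k* and
midpoint `t_switch`. Trajectories are integrated by explicit Euler (with
Euler–Maruyama noise when σ_η > 0), and parameters are fitted to observed
small-cluster fractions at the sampling times by exhaustive grid search,
scored by the RMSE prediction error; R² and residual SDs are reported
alongside.

The size-distribution side implements the accompanying statistics:
two-component Gaussian mixture decomposition by EM, a ΔBIC bimodality
decision, the kernel-density overlap index η between diameter
distributions, Ward-D2 hierarchical clustering of overlap matrices, and
threshold classification into small/large size classes. A synthetic-data
generator emulates Coulter-counter exports (truncated bimodal Gaussian
mixtures) and phenotype-count time courses (model trajectories plus
binomial counting noise) so the whole pipeline is testable without
instrument data.

## Worked example

```r
library(phenoswitch)

# --- size distributions ---------------------------------------------------
particles <- generate_mixture_sample(mixture_spec(), n = 5000, seed = 1)
fit <- fit_two_component_mixture(particles)
fit
#> <mixture_fit> 5000 particles, 11 EM iterations (converged)
#>   small: w = 0.506, mean = 6.068 um, sd = 1.390 um
#>   large: w = 0.494, mean = 24.875 um, sd = 4.914 um
#>   logLik 2-comp = -15300.88 (BIC 30644.3), 1-comp = -18640.32 (BIC 37297.7)
bimodality_decision(fit)
#> [1] "bimodal"
```

The EM decomposition recovers the two subpopulations (generated at 6 and
25 µm) and the two-component model beats the single Gaussian by ~6650 BIC
points, so the distribution is called bimodal. Classification at the 13 µm
boundary puts about half the particles in the small class:

```r
classify_particles(particles)
#> # A tibble: 1 × 6
#>   sample_id time_h count_small count_large fraction_small threshold
#>   <chr>      <dbl>       <int>       <int>          <dbl>     <dbl>
#> 1 synthetic     24        2551        2449          0.510        13
```

```r
# --- switching model ------------------------------------------------------
obs <- generate_timecourse_observations(
  switching_params(alpha = 1, beta = 0.005, gamma = 0, k = 0.001),
  observation_design(seed = 1))   # binomial counts of 10,000 particles
obs
#> # A tibble: 4 × 4
#>   time_h count_small count_large fraction_small
#>    <dbl>       <int>       <int>          <dbl>
#> 1     12         129        9871         0.0129
#> 2     20         208        9792         0.0208
#> 3     24         232        9768         0.0232
#> 4     48         450        9550         0.045

model_fit <- fit_switching_grid(obs,
  alpha_grid = c(0.1, 1), beta_grid = c(0.001, 0.005, 0.02),
  gamma_grid = c(0, 0.02), k_grid = c(0.001, 0.1, 1))
model_fit
#> <switching_fit> 36 grid tuples evaluated
#>   best: alpha = 1, beta = 0.005, gamma = 0, k = 0.001
#>   objective (RMSE of fractions) = 0.002561, R^2 = 0.9537, residual SD = 0.002299
```

The grid search recovers the generating parameters from the noisy counts;
the residual RMSE (~0.0026) is at the binomial counting-noise floor for
10,000 particles per timepoint. `tidy()` and `glance()` return the full
objective surface and the one-row fit summary; `autoplot()` draws the
fitted time course, mixture decomposition, or overlap heatmap.

`run_pipeline(pipeline_config(out_dir = "run1", seed = 1))` executes the
whole chain (generation/reading → mixture fits → overlap matrix and
clustering → size classes → model fit) and writes CSV/JSON outputs, a
plain-text summary, and a manifest with content hashes.

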