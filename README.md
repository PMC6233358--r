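# mallard

Multinomial logistic-normal dynamic linear models for longitudinal
microbiome count data.

## What this solves

Dense microbiome time series — replicate bioreactor vessels sampled daily
and hourly, with technical replicates — mix two kinds of variation.
Biological change accumulates over time; technical noise (extraction, PCR,
library preparation, and the multinomial randomness of sequencing a finite
read depth) hits every sample independently and does not accumulate.
`mallard` separates the two with a state-space model in log-ratio
coordinates and tells you, among other things, how much of the observed
variation is biology and at what sampling interval biological signal
overtakes technical noise.

The model, for sample $k$ with depth $n_k$:

$$
Y_k \sim \mathrm{Multinomial}(\pi_k, n_k), \qquad
\pi_k = \mathrm{ILR}^{-1}(\eta_k),
$$
$$
\eta_k = \theta_k + v_k,\ v_k \sim N(0, V), \qquad
\theta_k = \theta_{k-1} + w_k,\ w_k \sim N(0, W_k),
$$

with $W_k = W$ per advanced base interval and $W_k = 0$ between technical
replicates, $\theta_0 \sim N(m_0, C_0)$, LKJ priors on the correlation
parts of $V$ and $W$ and log-normal priors on their scales.  Inference
marginalizes all states $\theta$ with a Kalman filter and samples
$(\eta, V, W)$ with an in-package No-U-Turn sampler using analytic
gradients; states are recovered afterwards by forward-filtering
backward-sampling.  Zeros in the counts need no pseudo-counts — the
multinomial layer absorbs them.

For whom: microbiome researchers with replicated longitudinal count tables
(TSV or BIOM) who want technical-vs-biological variance decompositions,
principal balances of biological variation, and calibrated uncertainty on
all of it.

## Worked example

Simulate the canonical three-taxon testbed (one vessel, 200 time points,
25 terminal technical replicates, three deleted time points) and fit it:

```r
library(mallard)

toy <- simulate_toy(seed = 1)
model <- mallard_model(toy$counts, toy$schedule, toy$basis)
fit <- mallard_fit(model, fit_config(n_chains = 2, n_warmup = 300,
                                     n_samples = 300, rng_seed = 1001))
print(fit)
#> mallard_fit: 2 chains x 300 samples; 222 samples x 2 ILR coordinates
#> max split-Rhat 1.0090; 0.00% divergent

variance_decomposition(fit)
#>             quantity    median    lower95   upper95
#>                 tr_W 0.1046276 0.06388485 0.1783255
#>                 tr_V 0.3876775 0.30005234 0.5063756
#>  biological_fraction 0.2119353 0.12292937 0.3506289
#>            crossover 3.7184212 1.85203806 7.1347563
```

The generating values were $\mathrm{Tr}(W) = 0.10$ and
$\mathrm{Tr}(V) = 0.40$, i.e. a biological fraction of 0.20 and a
crossover interval $L^* = 4$ base intervals: sampling more often than
every 4 intervals buys you mostly technical noise.  Both are recovered
inside the 95% credible intervals.  Evidence-information units convert to
fold changes with `fold_change_from_balance()`: 1 e.i. of a one-vs-one
balance is a `exp(sqrt(2))` ≈ 4.1-fold change, 2 e.i. ≈ 16.9-fold.

Latent state paths, principal balances and the correlation-structure
permutation test follow the same pattern:

```r
fit <- sample_theta(fit, model, seed = 1)         # exact FFBS state draws
TW <- lapply(mallard:::.as_matrix_list(fit$W), function(m)
  unclass(variation_array(cov_to_clr(m, toy$basis))))
pb <- ward_principal_balances(TW)
pb$bipartition_freq
```

A thin command-line front end over the same functions lives at
`inst/cli/mallard.R` (`simulate`, `filter`, `fit`, `analyze`,
`sensitivity` subcommands).

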