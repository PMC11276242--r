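# espamarkov

Supervised classification of noisy, time-ordered data in the small-data
regime, via entropic learning with a Markov smoothness prior
(**eSPA-Markov**). The package is aimed at segmenting and classifying time
series whose latent regimes are *persistent* and may differ only in their
**variance** — the situation in which centroid-based methods (k-means,
nearest-centroid classifiers) fail at any noise level. The motivating
application is raw nanopore sequencing currents, where each k-mer in the
pore emits a characteristic current distribution for a random dwell time.

## The model

Given a data matrix $X \in \mathbb{R}^{D\times T}$ (columns = time points)
and label probabilities $\Pi \in [0,1]^{M\times T}$, the method minimizes

$$
\frac{\varepsilon_L}{T}\sum_{d,k,t} W_d\,\Gamma_{k,t}\,
  \ell(X_{d,t},\mu_{d,k},\sigma_{d,k})
+ \varepsilon_E \sum_d W_d \log W_d
- \frac{\varepsilon_{CL}}{T}\sum_{m,t}\Pi_{m,t}\sum_k
  \log(\Lambda_{m,k})\,\Gamma_{k,t}
+ \frac{1}{T}\sum_{t<T}\bigl\|\Gamma_{\cdot,t+1}-P\,\Gamma_{\cdot,t}\bigr\|^2
$$

over column-stochastic affiliations $\Gamma$ ($K\times T$), per-cluster
Gaussian parameters $(\mu,\sigma)$, entropy-regularized feature weights
$W$, and a Bayesian cluster-to-label classifier $\Lambda$, where
$\ell$ is the univariate Gaussian negative log-likelihood and $P$ is a
transition prior ($P = I$ enforces persistence / metastability of the
latent regimes). The $\Gamma$-step is a convex quadratic program over a
product of probability simplices, solved with a spectral projected
gradient method; the other three steps are closed forms. A direct
*one-shot* variant fits the whole model without iteration when clusters
and labels are in bijection. See the methods vignette
(`vignettes/espa-markov-methods.Rmd`) for the full account.

## Worked example

Variance-switching regimes (both states have mean 0; state 2 has a four
times smaller standard deviation), fitted and evaluated on chronological
splits:

```r
library(espamarkov)

sim   <- sim_variance_switch(Tn = 1500, sigma_ratio = 4, D = 1, seed = 42)
split <- triple_split(ncol(sim$X))
fit   <- espa_markov(sim$X[, split$train], sim$Pi[, split$train],
                     K = 2, eps_L = 1, eps_E = 1e-2, eps_CL = 1e-2,
                     n_starts = 5, seed = 1)
fit
#> eSPA-Markov model (iterative fit)
#>   D = 1 features, T = 500 time points, K = 2 clusters, M = 2 labels
#>   eps_L = 1, eps_E = 0.01, eps_CL = 0.01
#>   total loss = 0.830512 nats (9 outer iterations, converged)

coef(fit)$sigma           # per-cluster emission SDs (truth: 0.25 and 1)
#>           [,1]     [,2]
#> [1,] 0.2518589 1.074613

pred <- predict(fit, sim$X[, split$test], seed = 2)
auc_score(pred$Pi[2, ], sim$states[split$test] == 2)
#> [1] 0.9932921
```

The fitted SDs recover the two emission scales, and ranking test points by
the predicted probability of state 2 separates the regimes almost
perfectly (AUC 0.99; 0.5 would be chance). The same data with
`sigma_ratio = 1` has identical state laws and the pipeline lands at
chance, which is the calibration the acceptance script recomputes.

One-shot learning on the nanopore toy — train on one simulated molecule,
decode a different one:

```r
train <- sim_nanopore_toy(n_bases = 30, seed = 5)
test  <- sim_nanopore_toy(n_bases = 30, seed = 6)   # different sequence
os    <- espa_oneshot(train$X, train$Pi)
p     <- predict(os, test$X, seed = 3)
mean(apply(p$Pi, 2, which.max) == test$states)
#> [1] 0.9851852
```

A command-line interface over the same functions lives in
`inst/cli/espa-markov.R` (subcommands `simulate`, `fit`, `oneshot`,
`predict`, `evaluate`, `gridsearch`), writing a manifest with the resolved
configuration and seed alongside every run.

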