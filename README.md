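# warpmpt

Bayesian model comparison for **hierarchical multinomial processing tree
(MPT) models** by **Warp-III bridge sampling**.

MPT models explain categorical responses (e.g., free-recall outcomes,
true/false judgments) as mixtures of latent cognitive processes arranged
in a rooted tree: each branch probability is a product of process
probabilities `θ_p` or their complements, each response category sums
the branches that end in it, and the observed frequencies follow a
product-multinomial distribution across the independent subtrees. The
hierarchical *latent-trait* formulation places a multivariate normal
group distribution on the probit scale,

```
θ'_i = μ + ξ ⊙ ω_i,   ω_i ~ N_P(0, Q),   θ_i = Φ(θ'_i),
```

with a scaled inverse-Wishart prior on the covariance
`Σ = Diag(ξ) Q Diag(ξ)` (`Q ~ InvWishart(P + 1, I_P)`, `ξ_p ~
Uniform(0, 10)`), standard normal priors on `μ`, and — for two-condition
designs — zero-centered normal priors on the condition differences `δ`
that enter as `μ ∓ δ/2`.

Comparing such models (nested or non-nested) needs each model's
**marginal likelihood**, a `P(I + 2)`-dimensional integral after the
closed-form elimination of `Q`. The package estimates its log by
**bridge sampling** with a *warped* posterior: the draws are shifted by
the posterior mean, rotated/scaled by a Cholesky factor of the posterior
covariance, and given a random sign, so that their first three moments
match the standard normal proposal (Warp-III). The optimal bridge is
found by a fixed-point iteration run entirely in log space, which keeps
Bayes factors of order 10^42 representable. Simpler Warp-0/Warp-II
variants are included; marginal likelihoods feed Bayes factors,
posterior model probabilities, Bayesian-model-averaged inclusion
probabilities, and a Savage–Dickey density-ratio cross-check for nested
families.

## Worked example

Simulate a two-trial pair-clustering experiment (storage parameter `c`,
retrieval `r`, singleton/unclustered recall `u = a`; the generating
truth shifts `r` and `u` between trials but not `c`), fit the full
latent-trait model, and bridge it:

```r
library(warpmpt)

fx  <- pair_clustering_fixture()            # spec, model, truth
gen <- generate_dataset(fx$model, fx$truth, I = 15, J = c(20, 10),
                        seed = 42)

ch <- sample_posterior(fx$model, gen$data, n_chains = 3, n_iter = 2000,
                       burnin = 2000, thin = 3, seed = 1)
max(rhat(ch))
#> [1] 1.037675
br <- estimate_log_ml(fx$model, gen$data, ch, method = "warp3",
                      n_repetitions = 5, seed = 2)
br
#> Bridge sampling estimate (warp3): log ML = -259.711
#>   5 repetition(s), range [-259.885, -259.421]
#>   D1 = 3000 , D2 = 3000 , ESS used = 589.5
```

All chains converged (R-hat < 1.05) and the five bridge repetitions
agree to about 0.1 on the log scale. Enumerating all `2^3 = 8`
combinations of free/fixed trial differences and repeating the
fit-and-bridge step for each gives posterior model probabilities and
model-averaged inclusion probabilities:

```r
set  <- enumerate_nested_models(fx$model, c("c", "r", "u"))
cmp  <- compare_nested_models(set, gen$data, seed = 1,
                              n_repetitions = 5, n_chains = 3,
                              n_iter = 2000, burnin = 2000, thin = 3)
round(cmp$pmp, 3)
#> c-r-u   r-u   c-u     u   c-r     r     c  none
#> 0.208 0.775 0.009 0.008 0.000 0.001 0.000 0.000
round(cmp$posterior_inclusion, 3)
#>     c     r     u
#> 0.217 0.983 0.999
```

The model freeing `r` and `u` dominates (posterior probability ≈ 0.78
against a prior of 0.125), the inclusion probabilities for `r` and `u`
rise far above their prior value of 0.5, and the inclusion probability
of `c` falls below it — evidence *for* the invariance of `c`, exactly
the pattern planted by the generator. (Exact values vary slightly with
the seed and chain settings.)

A command-line front end wrapping the same functions is installed at
`inst/cli/warpmpt` (subcommands `simulate`, `fit`, `logml`, `compare`;
YAML config in, JSON/CSV out).

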