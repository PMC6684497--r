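---
title: "Marginal likelihoods for hierarchical MPT models: model, sampler, and warp bridge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Marginal likelihoods for hierarchical MPT models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(warpmpt)
```

This vignette is the package's account of the statistical machinery it
implements: the hierarchical latent-trait MPT model and its priors, the
MCMC sampler, the Warp-III bridge estimator of the log marginal
likelihood, the model-comparison layer built on top of it, and the
numerical and design choices a maintainer should know about.

## The model

An MPT model reparametrizes the category probabilities of `K`
independent multinomials ("subtrees") through a rooted tree of latent
processing stages. A branch that passes `v_p` nodes governed by process
probability `θ_p` and `w_p` nodes governed by its complement has
probability `∏_p θ_p^{v_p} (1 − θ_p)^{w_p}`; a category's probability
sums its branches; a participant's counts follow the product-multinomial
over subtrees with fixed item totals `J_k`. `parse_eqn()` reads the
standard EQN text convention for these trees, and equality constraints
such as `a = u` in the pair-clustering model are folded into the
exponent matrices before the free parameter count `P` is fixed, so
constrained parameters contribute no dimensions anywhere downstream.

Participant heterogeneity is modeled on the probit scale:
`θ'_i = μ + ξ ⊙ ω_i` with `ω_i ~ N_P(0, Q)`. The prior block is the
standard latent-trait choice:

* `μ_p ~ N(0, 1)` — uniform on the probability scale for the group
  means;
* `Q ~ InvWishart(ν = P + 1, I_P)` — uniform priors on random-effect
  correlations;
* `ξ_p ~ Uniform(0, ξ_max)`, `ξ_max = 10` by default — the scaling
  half of the scaled inverse-Wishart covariance
  `Σ = Diag(ξ) Q Diag(ξ)`, a parameter expansion that frees the
  standard deviations from the Wishart's constraints. `ξ_max` is a
  tuning constant with prior-sensitivity consequences for marginal
  likelihoods; it is exposed in `latent_trait_model()`.

For two-condition designs a difference vector `δ` shifts the group mean
to `μ − δ/2` (condition 1) and `μ + δ/2` (condition 2) with one shared
`ω_i` per participant; each free `δ_p` gets a `N(0, σ_δ²)` prior with
presets `σ_δ ∈ {0.52, 0.84, 1.28}` ("narrow"/"medium"/"wide",
corresponding to small/medium/large effects on the probability scale
around 0.5). The two-condition design is the v1 scope; the condition
signs ∓1/2 are fixed.

Two integrals are handled analytically rather than sampled:

* `Q` is integrated out of the posterior in closed form, leaving the
  group-level factor
  `Γ_P((ν+I)/2) / Γ_P(ν/2) · π^{−IP/2} · |ΩᵀΩ + I_P|^{−(ν+I)/2}`
  (`log_group_level_factor()`), so the bridge operates on the
  `d = P(I+2) + F` dimensional state `ψ = (μ, ξ_trans, δ, ω_1, …, ω_I)`;
* the bounded `ξ` is mapped to `ξ_trans = Φ⁻¹(ξ/ξ_max)`; the uniform
  prior times the Jacobian of this map is exactly a standard normal
  density in `ξ_trans`, which is how it appears in the unnormalized
  posterior (`log_unnormalized_posterior()`, compiled twin
  `lt_log_posterior()`).

All density evaluation is in log space end to end; impossible data
(zero category probability with a positive count) yields `−∞`, never
`NaN`.

## The sampler

`sample_posterior()` is a blocked adaptive random-walk Metropolis
sampler with a conjugate Gibbs step, targeting the joint posterior of
`(ψ, Q)`; because the retained `ψ` margin coincides with the
Q-marginalized posterior that the bridge evaluates, `Q` is kept only
for mixing and dropped afterwards. Each sweep:

1. updates the shared block `(μ, ξ_trans, δ)` by a multivariate
   random-walk proposal shaped by the empirical covariance of the
   burn-in history (refreshed every 100 sweeps, frozen after burn-in),
   repeated four times per sweep because this block limits mixing and
   one evaluation is cheap;
2. proposes all `ω_i` blocks at once and accepts per participant — the
   likelihood factorizes over `i` and, given `Q`, so does the prior;
3. draws `Q | Ω ~ InvWishart(ν + I, ΩᵀΩ + I_P)`;
4. recenters `μ` by an exact Gibbs draw along the unidentified ridge
   `μ + ξ ⊙ ω_i = const`: conditional on those sums, `μ` is Gaussian
   and the map has a `μ`-free Jacobian;
5. proposes a joint scale move `ξ → ξe^a`, `ω → ωe^{−a}`,
   `Q → D⁻¹QD⁻¹` along the second unidentified ridge. The `ω`
   normalizing constant cancels the `ω` Jacobian, so the acceptance
   ratio involves only the `ξ_trans` prior (with its probit Jacobian)
   and the inverse-Wishart prior — it does not degrade as `I` grows.

Moves 4–5 exist because the scaled inverse-Wishart expansion leaves
`(μ, ξ, Q)` only jointly identified with `Ω`; plain blocked updates
random-walk along these ridges and can stall badly (we observed
R-hat > 4 at `I = 200` without them). Proposal scales adapt toward
0.23 acceptance (0.3 for the scale move) by Robbins–Monro during
burn-in only, so retained draws are Markov. Start values are
overdispersed in the identified parameters (`μ`, `δ`); the
random-effect scale starts moderate with small `ω` because chains
initialized inside the `ξ ≈ 0` funnel — tiny scale, unaligned random
effects — are metastable there: the likelihood locally rejects `ξ`
growth until `ω` aligns, and `ω` cannot align while `ξ ≈ 0`.

Diagnostics follow the usual conventions: `rhat()` is the classic
potential scale reduction across chains with the 1.05 threshold helper
`rhat_flags()`; `effective_sample_size()` estimates the spectral
density at frequency zero by AR-model fitting and sums chains.
Defaults mirror common practice for these models: 3 chains, 4000
burn-in, thinning configurable.

## The warp bridge

Bridge sampling estimates a normalizing constant from two draw sets —
`D_1` posterior draws and `D_2` draws from a proposal `g` — tied
together by the optimal bridge function, whose fixed point is found by
iterating

```
Z ← mean_r[ l_2r / (s1 l_2r + s2 Z) ] / mean_j[ 1 / (s1 l_1j + s2 Z) ]
```

(`iterative_bridge()`), where `l = p̃/g` evaluated at proposal and
posterior draws respectively. The implementation iterates on `log Z`
with log-sum-exp everywhere: the package exists to compare models whose
Bayes factors reach 10^40 and beyond, so no intermediate quantity may
leave log space. Convergence is declared when the log estimate changes
by less than `tol = 1e-10` (default), capped at 1000 iterations with a
flag rather than an error; the starting value is the median of the
`log l_2` values.

Warp-III fixes `g` to a standard normal and instead *warps* the
posterior: `η = b·R⁻¹(ψ − v)` with `v` the posterior mean, `R` the
lower Cholesky factor of the posterior covariance, and `b` a random
sign. The sign makes the warped density an even mixture of the two
mirror images, which zeroes the third moment; the mixture is evaluated
by log-sum-exp of the two mirror terms (`warped_log_density_terms()`,
`proposal_log_terms()`). `warp2` omits the mirror term (a plain
moment-matched normal proposal, half the density evaluations), `warp0`
omits warping entirely; all three share the same iterative core, so the
variance ordering between them is a pure property of the warp.

Operationally (`estimate_log_ml()`, generic core `bridge_sampler()`):
the retained iterations are split per chain into a first half (moment
estimation) and second half (`D_1` bridge draws); `D_2 = D_1` fresh
proposal draws are generated per repetition from the recorded seed.
Because MCMC draws are autocorrelated, the weight `s_1` replaces `D_1`
by an effective sample size — the median across dimensions of the
bridge-half ESS, a deliberate interpretation since no canonical
reduction exists. Repetitions by default share the fixed half-split and
differ only in proposal draws; `resplit = TRUE` re-randomizes the split
per repetition. Summaries report the median and min–max range across
repetitions, and the median is what feeds model comparison.

## Model comparison

`posterior_model_probabilities()` is a max-shifted softmax of
`log ML + log prior`; `enumerate_nested_models()` builds the `2^q`
lattice of free/fixed difference parameters with uniform prior model
probabilities by default; `inclusion_probabilities()` sums model
probabilities over the models containing each difference. For nested
families the Savage–Dickey density ratio offers an independent route:
the Bayes factor of a restriction against the full model is the
posterior density of the restricted subset at zero over its prior
density at zero. `savage_dickey()` (one parameter) and
`savage_dickey_model_probs()` (joint subsets) estimate the posterior
density by Gaussian (product-)kernel estimates with Silverman's
bandwidth. Kernel estimates of joint densities at a point are
approximate — bandwidth bias grows with subset dimension — so this
route is documented and used as a cross-check on the bridge results,
not as the primary estimator.

## The synthetic generator

`generate_dataset()` simulates the generative chain exactly as the
model states it: `ω_i` from the multivariate normal with a configurable
correlation matrix, `θ_i` per condition through the probit link with
the `∓δ/2` shifts, counts from per-subtree multinomials. The two
fixtures mirror the package's two canonical applications: a
pair-clustering memory experiment (`pair_clustering_fixture()`: 4
categories for word pairs, 2 for singletons, `a = u`, two trials, 21
participants and 20 word pairs by default) and a truth-judgment
experiment with competing knowledge-conditional vs fluency-conditional
trees (`truth_effect_fixture()`: 2×2×2 design, eight subtrees, five
shared parameters, 39 participants, 22 items per cell). Defaults chosen
as configuration, not estimates: probability-scale group means in the
0.3–0.7 band, probit scales 0.4–1.0, a singleton item total of 10
(the pairs literature fixes 20 word pairs; the singleton count is
exposed as configuration), and a generating truth for the two-trial
fixture that shifts `r` and `u` but not `c`. The guessing parameter in
the truth-effect fixture carries a full latent-trait random effect like
every other parameter — an assumption, since conditional-tree
formulations sometimes fix it.

What the generator does *not* emulate: item-level effects (counts are
aggregated over items within a subtree, as the model assumes),
response times, order effects, and any misspecification of the probit
link or group-level normality. Passing tests therefore demonstrate
correctness of the machinery under the model's own assumptions, not
robustness to their violation.

The conditional trees in the truth-effect fixture coincide exactly when
fluency never drives the response (`f = 0`), and their true-statement
subtrees coincide under certain knowledge retrieval (`k = 1`); the
false-statement subtrees differ at `k = 1` (the fluency-conditional
tree still answers "true" with probability `f`). The fixture tests pin
both identities.

## Numerical choices and problem sizes

* Multinomial coefficients via log-gamma; determinants via Cholesky /
  `log_det`; the group-level factor's multivariate gamma functions are
  precomputed once per dataset.
* The compiled evaluator (`lt_log_posterior()`) is checked against an
  independent plain-R implementation to 1e-9 in the test suite, and
  the marginalized posterior is checked against a Monte Carlo average
  of the unmarginalized chain on a small toy by quadrature.
* Test and acceptance runs use desk-scale problem sizes chosen so each
  oracle's own error is far below the assertion tolerance: 15
  participants and shortened chains (3 × 2000 retained) for the nested
  model-averaging run, 20,000 + 20,000 draws for the known-constant
  oracle, 64-node Gauss–Legendre tensor quadrature (exact for the
  polynomial likelihood) for the single-participant oracle, and 10^6
  draws for the inverse-Wishart Monte Carlo identity.
* The warp-ladder moment checks (mean ≈ 0, covariance ≈ identity,
  third moments ≈ 0 after warping) are asserted on a skewed,
  light-tailed 2-D fixture target. They cannot be asserted at tight
  tolerances on full latent-trait posteriors: conditional on small
  `ξ_p`, the unidentified `ω` margins have t-like tails (degrees of
  freedom of order `ν`), so their sample covariances fluctuate heavily
  no matter how long the chains run. This is the same irregularity of
  the `ω`/`ξ` margins that users are advised to monitor before
  bridging — it degrades warp efficiency but not correctness.

## Known limitations

* Warp-III assumes a unimodal posterior; multimodal posteriors (or the
  funnel-shaped `ω`/`ξ` geometries above) reduce proposal–posterior
  overlap and inflate repetition variability. The repetition range in
  every `bridge_result` is the intended diagnostic: when it is wide
  enough to flip a model ranking, increase the draw budget or treat
  the comparison as undecided.
* One- and two-condition designs only; no beta-MPT or crossed
  item/participant random effects; no order constraints on parameters;
  no Reversible Jump over model space.
* The Savage–Dickey route shares none of the bridge's machinery but
  inherits kernel-density bias at zero, particularly for 2–3
  dimensional restrictions.
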