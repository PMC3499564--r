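---
title: "SpikeSlabGWAS: model, samplers and numerical design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SpikeSlabGWAS: model, samplers and numerical design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Model

For a continuous trait $y \in \mathbb{R}^n$ and centered dosage columns
$x_j$, the sparse linear model is

$$ y = \alpha 1 + \sum_{j:\gamma_j = 1} x_j \beta_j + \varepsilon,\qquad
\varepsilon \sim N(0, \sigma^2 I), $$

with binary inclusion indicators $\gamma$. The effect prior is parameter
expanded: $\beta_j = \xi b_j$ with $b_j \sim N(0, \sigma^2 s_j^2)$,
$s_j^2 \sim \text{Scale-inv-}\chi^2(\nu_s, s^2_s)$ and
$\xi \sim N(\mu_\xi, \sigma^2_\xi)$, so the effective per-variant slab
variance is $\tau_j^2 = \xi^2 s_j^2$ (a heavy-tailed, noncentral-F-type
marginal). The residual variance has a scaled-inverse-$\chi^2$ prior and
the model-size prior is beta-binomial,

$$ p(\gamma) = \frac{B(a_\pi + q,\; b_\pi + m - q)}{B(a_\pi, b_\pi)},
\qquad q = \textstyle\sum_j \gamma_j, $$

obtained by integrating a Beta-distributed inclusion probability out of
independent Bernoulli indicators; `priorSpec(expectedAssociations = E)`
sets $b_\pi = a_\pi (m/E - 1)$.

Conditional on $(\gamma, \tau^2)$, the intercept (flat prior, handled by
centering $y$ and $X$, which removes one degree of freedom), the effects
and $\sigma^2$ integrate out in closed form:

$$ \log p(y \mid \gamma, \tau^2) = C
 - \tfrac12 \sum_{j \in \gamma} \log \tau_j^2 - \log |R|
 - \tfrac{\nu_\sigma + n - 1}{2}
   \log\!\Big(1 + \tfrac{S}{\nu_\sigma s^2_\sigma}\Big), $$

where $A = X_\gamma' X_\gamma + \mathrm{diag}(1/\tau_j^2) = R'R$,
$w = R^{-T} X_\gamma' y$ and $S = y'y - w'w$. The package maintains $R$ and
$w$ incrementally: adding a variant is one forward substitution plus a
scalar pivot ($O(nq + q^2)$), removing one is a Givens-rotation column
deletion ($O(q^2)$), and a full LAPACK refactorization runs every
`refactorInterval` modifications to reset floating-point drift. The pivot
guard refuses an addition whose Schur complement falls below
$10^{-12}(\lVert x_j\rVert^2 + 1/\tau_j^2)$ (a numerically collinear
column), which the samplers treat as a rejection; models with
$q > n - 2$ are likewise never entered. The test suite asserts agreement
between this incremental path and dense refactorization over long random
walks, and `enumeratePosterior` (for $m \le 20$) is computed from scratch
per model, independent of the incremental engine.

## Gibbs scheme

`runChain` cycles: (1) variance components $s_j^2$, (2) $\xi$ followed by
a sign-flip Metropolis move that leaves $\beta = \xi b$ invariant, (3) the
indicator Metropolis–Hastings update, (4) $\sigma^2$, (5) the included
coefficients. Step 3 runs every iteration; the hyperparameter steps every
`hyperUpdateInterval`-th iteration (default 10 for the sequential kernels,
100 for the block comparison kernels). Excluded-variant $s_j^2$ are
refreshed from their prior each sweep so the full vector
$\tau^2$ is always current. With `fixedTau2` set, steps 1–2 freeze and the
indicator chain targets the enumerable fixed-variance posterior used by
the exactness tests.

Each sub-kernel draws from its own named RNG stream derived from the master
seed, so enabling one kernel never perturbs another's draws and runs are
reproducible byte-for-byte given `seed`.

## Indicator kernels

**Single-step (ss)** toggles one variant. **Multistep (ms)** draws a move
size $k$ from a truncated geometric (mode at 1, cap `kMax`), then builds a
sequence of add/remove operations: each step picks a direction (probability
1/2, or forced when only one is legal) and a variant from the renormalized
adaptive weights over still-untouched variants; no variant is touched
twice. The acceptance ratio uses the exact sequence probability of the
deterministic reverse (operations inverted, order reversed). When a
sequence exhausts every legal step before reaching $k$, the size factor
becomes the tail probability $P(K \ge \text{len})$, since every larger
drawn size realizes the same sequence.

**Delayed rejection (msdr).** When a multistep proposal with
$k \le$ `drCutoff` is rejected, a second stage selects among all $2^k$
"trimmed" candidates $m$ obtainable by keeping a subset of the proposed
variable set $V$: candidate $m$ is weighted by
$\pi(m)\, q(z_m \mid m)\, (1 - a_1(m \to m \oplus V))$, where $z_m$ visits
the same variables in the same realized order with operation directions
determined by $m$'s inclusion states. This map is an involution (applying
it twice recovers the original sequence), which makes the per-order flow
between any two candidates symmetric, so the second-stage acceptance
probability is exactly 1 — the property the delayed-rejection audit
(`drAudit = TRUE`) verifies by recomputing every factor densely and
independently of the sampler's caches. The $2^k$ candidates are scanned in
Gray-code order so each differs from the previous by one rank-one update;
a numerically refused pivot during the scan abandons the second stage and
returns to the original state. Trimming is the mechanism that lets an
oversized exploratory move succeed as its useful sub-move, which is what
solves the cancelling-pair fixture (`makePairTrap`) that defeats
single-step sampling.

**Locus moves**, mixed by `kernelWeights = c(main, swap, toggle)`: the
swap exchanges an included anchor with an excluded neighbor within
`neighborhoodCutoff` positions in genomic order (a geometric number of
such swaps per proposal), and the toggle flips a neighbor of an included
anchor, with delayed rejection available under msdr. Both use exact
reverse-probability accounting of their (anchor, neighbor) selection laws.

**Comparison kernels**: Kohn–Smith–Chan draws `blockK` variants and
proposes each flip from the conditional prior odds (the normalizer
cancels in the ratio); Nott–Kohn proposes from a product of clamped
estimated inclusion probabilities frozen at the end of burn-in.

## Adaptation (finite)

During burn-in only: per-variant add weights track the Rao-Blackwellized
inclusion estimates $\hat p_j$ (add $\max(\hat p_j, \epsilon)$, remove
$\max(1 - \hat p_j, \epsilon)$, floor $\epsilon = 1/m$ by default for
irreducibility), and the move-size parameter is re-selected on a grid by
maximizing estimated expected jump distance with multiple importance
sampling (balance heuristic) over the history. The per-record jump
contribution is $k$ times the Rao-Blackwellized first-stage acceptance for
ss/ms, but the *realized* jump for msdr — delayed-rejection rescues move
fewer than $k$ indicators yet more than zero, and crediting only the first
stage would drive the move size to 1 and disable the mechanism. At the end
of burn-in all proposal parameters freeze; the trace stores a fingerprint
(`psHash`) of every parameter the kernels read, asserted constant
thereafter, so the sampling phase is a fixed-kernel Markov chain and
ergodicity is unaffected by adaptation. The reported Rao-Blackwellized
estimator restarts at the freeze so it averages the fixed-kernel phase
only.

## Synthetic data

`simulateGenotypes` draws, per LD block, two latent Gaussian AR($\rho$)
haplotypes per individual and thresholds them at $\Phi^{-1}(\text{maf}_j)$,
summing to Hardy–Weinberg dosages; monomorphic columns are resampled.
`simulatePhenotype` picks causal variants uniformly, double-exponential
effect sizes, and Gaussian noise orthogonalized against the realized
signal and scaled so the in-sample proportion of variance explained equals
`pve` exactly. `makePairTrap` manufactures two tightly correlated variants
with opposite effects whose marginals nearly cancel: the noise scale is
set from $\sqrt{n}\,\mathrm{cov}(x_j, d)/\mathrm{sd}(x_j)$ so the expected
marginal $|t|$ stays near 1 at any $n$, and generation retries (redrawing
the disagreement pattern) until both marginal $|t| <$ `tMax` and the joint
F-test p-value $<$ `fMax` hold, asserting the trap property rather than
hoping for it.

## Diagnostics

`geyerEss` implements the initial monotone sequence estimator (FFT
autocovariances, paired sums, first-nonpositive truncation, monotone
envelope); it is calibrated on AR(1) closed forms in the tests. `psrf` is
the Gelman–Rubin factor. `moveStatistics` reports realized and proposed
jump distance and move rate; for indicator vectors the squared jump
distance equals the Hamming distance, linking expected jump distance to
lag-one autocorrelation. `modelGof` tests sampled model frequencies
against enumeration with counts rescaled to an effective sample size,
because a plain multinomial test on autocorrelated draws is
anti-conservative.

## Scale and limitations

The package targets desk-scale problems: enumeration up to $m = 20$,
exactness benchmarks at $n = 40, m = 6$, and adversarial fixtures at
$n = 2000, m = 200$; the compiled engine handles these at roughly
10–60 µs per indicator update. It supports a single continuous phenotype,
additive dosage coding and one chain per call (`psrf` accepts multiple
traces run with different seeds). Binary traits, covariates, dosage
uncertainty and VCF input are out of scope.
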