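---
title: "Clustering coefficients for correlation networks: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clustering coefficients for correlation networks: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(corrclust)
```

## The problem

Functional brain networks — and correlation networks generally — are usually
summarized by graph statistics designed for networks whose edges exist or do
not. The clustering coefficient, the abundance of connected triangles around a
node, is the canonical example. Applying it to a correlation matrix runs into
three linked difficulties:

1. **Indirect paths.** If node $i$ correlates with both $j$ and $\ell$, then
   $j$ and $\ell$ correlate by about $\rho_{ij}\rho_{i\ell}$ even with no
   direct relationship. Correlation networks are therefore full of
   "triangles" that carry no information about genuine triadic structure, and
   a node's local clustering is mechanically confounded with its
   connectivity.
2. **Thresholding.** Dichotomizing at a threshold $\theta$ (or a target edge
   density) is arbitrary, and clustering values depend strongly on the
   choice.
3. **Negative edges.** Weighted-network clustering coefficients assume
   nonnegative weights, so negative correlations are usually discarded.

## The two correlation-matrix coefficients

The package's central statistics avoid all three issues by measuring, for
every pair of neighbors $(j, \ell)$ of a focal node $i$, how far their
observed correlation sits from the indirect-path expectation — using the
**three-way partial correlation**

$$\rho^{\mathrm{partial}}(j,\ell \mid i) =
  \frac{\rho_{j\ell} - \rho_{ij}\rho_{i\ell}}
       {\sqrt{1-\rho_{ij}^2}\sqrt{1-\rho_{i\ell}^2}},$$

which conditions on the single node $i$ only (keeping the statistic local and
avoiding the ill-posed estimation of a full partial correlation matrix), or
the **Gaussian partial mutual information**

$$I(X_j, X_\ell \mid X_i) = \tfrac12\left[\ln(1-\rho_{ij}^2) +
  \ln(1-\rho_{i\ell}^2) - \ln \det R_3\right]
  = -\tfrac12\ln\!\big(1-\rho^{\mathrm{partial}}(j,\ell\mid i)^2\big),$$

with $R_3$ the $3\times3$ correlation matrix of the triple (natural
logarithms throughout; the closed-form identity on the right is an exact
property of Gaussians and is exercised as a test invariant).

The local coefficients weight each pair by $|\rho_{ij}\rho_{i\ell}|$ — a
strong triangle should involve strong attachment to the focal node — giving

$$C_i^{\mathrm{cor},A} = \frac{\sum_{j<\ell}|\rho_{ij}\rho_{i\ell}\,
  \rho^{\mathrm{partial}}(j,\ell\mid i)|}{\sum_{j<\ell}|\rho_{ij}\rho_{i\ell}|},
\qquad
C_i^{\mathrm{cor},M} = \frac{\sum_{j<\ell}|\rho_{ij}\rho_{i\ell}|\,
  I(X_j,X_\ell\mid X_i)}{\frac{1+\ln 2\pi}{2}\sum_{j<\ell}|\rho_{ij}\rho_{i\ell}|}.$$

Global coefficients are means over nodes where the local value is defined.
No thresholding, no discarded negatives: a deviation of $\rho_{j\ell}$ from
the indirect-path product counts whether positive or negative. Sign-filtered
variants (`sign_filter = "positive"` / `"negative"`) restrict both sums to
triples whose three correlations are all strictly positive (all strictly
negative); zero correlations belong to neither restricted variant.

### Conventions and edge cases

- **Undefined, not zero.** A node with no admissible triple (zero weight
  sum; degree $\le 1$ for the comparators) is flagged undefined and
  *excluded* from the global mean. Zero-filling would bias the global value
  downward. If no node is defined, the global coefficient is an error
  (`global_clustering()`) or `NA` (`corrclust()`), and the batch tables
  report undefined-node counts.
- **The $[0,1]$ bound of $C^{\mathrm{cor},M}$ is not exact.** Since
  $-\tfrac12\ln(1-\rho_p^2) > \frac{1+\ln 2\pi}{2}$ once $|\rho_p| \gtrsim
  0.97$, near-singular matrices can push a local value above 1. The package
  computes the statistic as written, never clips, and warns; treat values
  above 1 as a symptom of near-degenerate input.
- **Degeneracy guard.** Conditioning on a node that is a perfect copy of a
  neighbor ($|\rho| = 1$ within `eps = 1e-12`, configurable) or a singular
  correlation triple raises an error naming the focal node rather than
  emitting `NaN`.
- **Full partial correlation** (the benchmark connectivity measure) is
  computed as $-\Omega_{ij}/\sqrt{\Omega_{ii}\Omega_{jj}}$ from the matrix
  inverse $\Omega$; the square root in the denominator is required for the
  output to be a correlation. Inputs with condition number above `1e10` are
  refused — shrinkage estimation is deliberately out of scope.

## Comparator coefficients

For context the package carries the standard alternatives: the unweighted
coefficient on a thresholded graph (edge iff $\rho \ge \theta$, or exactly
$\lfloor d\,N(N-1)/2\rfloor$ top edges for a target density $d$, with
deterministic lexicographic tie-breaking), and the Barrat, Onnela and
Zhang–Horvath weighted coefficients on the positive-weight network
$w_{ij} = \max(\rho_{ij}, 0)$. Inside the weighted formulas the adjacency
indicator is weight positivity, not any $\theta$. The Onnela and
Zhang–Horvath max-weight normalizers are recomputed per matrix (the formulas
are written per network). All four reduce to familiar identities used as
tests: binary weights recover the unweighted coefficient exactly, and
uniform rescaling leaves Onnela and Zhang–Horvath unchanged.

## Null models

**White noise.** `white_noise_correlation(n_nodes, n_time)` draws independent
standard-normal series and correlates them. Two analytic anchors make this
null useful: off-diagonal correlations fluctuate with standard deviation
$\approx 1/\sqrt{T-1}$, and the mean absolute three-way partial correlation
is $\approx \sqrt{2/(\pi(T-3))}$ — about $0.0568$ at $T = 200$ — which is
why the white-noise baseline of $C^{\mathrm{cor},A}$ sits near $0.057$ at 30
nodes and 200 time points, with $C^{\mathrm{cor},M}$ near
$0.057^2/(1+\ln2\pi) \approx 0.002$.

**H-Q-S random covariances.** `hqs_generate()` implements the
Hirschberger–Qu–Steuer construction: given the mean diagonal element
$\mu_{\mathrm{on}}$, mean off-diagonal element $\mu_{\mathrm{off}} > 0$ and
off-diagonal variance $\sigma^2_{\mathrm{off}} > 0$ of a reference
covariance matrix, it draws
$\bar t_{\max} = \max(2, \lfloor(\mu_{\mathrm{on}}^2 -
\mu_{\mathrm{off}}^2)/\sigma^2_{\mathrm{off}}\rfloor)$ latent white-noise
samples per node with mean $\sqrt{\mu_{\mathrm{off}}/\bar t_{\max}}$ and
variance $-\mu_{\mathrm{off}}/\bar t_{\max} +
\sqrt{\mu_{\mathrm{off}}^2/\bar t_{\max}^2 +
\sigma^2_{\mathrm{off}}/\bar t_{\max}}$ and returns the Gram matrix (PSD by
construction), normalized to a correlation matrix by default. This
parameterization provably recovers all three moments in expectation
($E[\mathrm{cov}_{ij}] = \mu_{\mathrm{off}}$,
$\mathrm{Var}[\mathrm{cov}_{ij}] = \sigma^2_{\mathrm{off}}$,
$E[\mathrm{cov}_{ii}] = \sqrt{\mu_{\mathrm{off}}^2 + \bar t_{\max}
\sigma^2_{\mathrm{off}}}$, which equals $\mu_{\mathrm{on}}$ at the exact
ratio); a radical-free `"literal"` variant is kept behind an option for
auditability, but it preserves no moment and typically has a negative latent
variance, so it is not the default. A negative or zero $\mu_{\mathrm{off}}$
violates the algorithm's precondition and is an error. Numerical notes: the
floor in $\bar t_{\max}$ is taken with a $10^{-9}$ guard so exact-integer
ratios are not truncated by binary round-off, and moments use the
population (denominator-$n$) variance; both choices are invisible at
realistic sizes. Only the base algorithm is implemented — no fine-tuned
heuristic variants.

### Choice of null moments for the strength-confound experiment

The contrast the local coefficients are designed for — conventional weighted
clustering correlates positively with node strength on null data while
$C_i^{\mathrm{cor},A}$ and $C_i^{\mathrm{cor},M}$ stay near-orthogonal — is
tested on H-Q-S matrices with moments $\mu_{\mathrm{on}} = 1$,
$\mu_{\mathrm{off}} = 0.03$, $\sigma^2_{\mathrm{off}} = 0.03$ at $N = 30$.
These emulate covariance matrices of globally signal-regressed resting-state
recordings, whose mean off-diagonal covariance is small (occasionally
negative) and whose variances are unit-scale. The weak mean matters
scientifically, not just numerically: the H-Q-S construction plants a common
positive latent mean in every node, so with a *large* $\mu_{\mathrm{off}}$
it approaches a one-factor model in which conditioning on a
high-loading node genuinely removes more shared variance — there
$C_i^{\mathrm{cor},A}$ legitimately *anti*-correlates with strength. The
near-orthogonality property holds in the weak-mean regime that
functional-connectivity data occupy, and that is the regime the test pins
down.

## Synthetic fixtures

`generate_structured_series()` builds Gaussian series whose population
correlations are known exactly, via latent factors
($x = \sqrt{c}\,f + \sqrt{1-c}\,\varepsilon$):

- `common_driver` — a hub emits the factor itself; peripherals load on it.
  Then $\rho_{j\ell} = \rho_{\mathrm{hub},j}\rho_{\mathrm{hub},\ell}$
  *exactly* in the population, so the hub's three-way partial correlations
  vanish: conventional weighted clustering scores the hub high,
  $C^{\mathrm{cor},A}$ sends it to zero as $T$ grows. This is the
  discriminative-validity fixture.
- `direct_triad` — a designated triple shares a mutual factor; its
  population partial correlation is $c/(1+c) > 0$, so the correlation
  coefficients reward it.
- `block` — disjoint groups with group factors.

What these fixtures do *not* emulate: temporal autocorrelation, hemodynamic
smoothing, motion artifacts, or non-Gaussian tails of real recordings. The
clustering statistics consume only the correlation matrix, so passing tests
demonstrate correctness of the statistics given a correlation matrix and the
claimed population-level contrasts — not robustness to fMRI preprocessing
choices, which are out of scope.

## Problem sizes in the test suite

The reference conditions are 30-node networks, length-200 series and 138
replicate matrices (white-noise baselines), 2,000 replicates per moment
setting for the H-Q-S moment-recovery contract, 100 null matrices for the
strength-confound contrast, and 20 seeds at $T = 10{,}000$ for the
discriminative-validity ordering. Property-style invariants (bounds,
permutation equivariance, oracle agreement) run over a few hundred to a few
thousand random matrices at $N \le 10$ — enough for the properties asserted,
chosen to keep the default suite fast.

## A worked example

```{r example}
rho <- white_noise_correlation(n_nodes = 30, n_time = 200, seed = 1)
fit <- corrclust(rho, edge_density = 0.1)
summary(fit)
```

The `cor_A` value sits near the analytic white-noise baseline
`sqrt(2/(pi * 197))` $\approx 0.057$, while the comparators are dominated by
the sampling fluctuations they cannot distinguish from structure. On real
functional-connectivity matrices the same call reports substantially higher
correlation-clustering values; the gap to the white-noise baseline is the
signal.

## Known limitations

- $C^{\mathrm{cor},M}$ exceeding 1 on near-singular input (above).
- The H-Q-S null requires $\mu_{\mathrm{off}} > 0$; reference matrices with
  a negative mean off-diagonal covariance must be excluded, exactly as
  cohort analyses drop such participants.
- No shrinkage estimation of partial correlations, no frequency-domain
  connectivity, no preprocessing, no NIfTI ingestion, and no path-length or
  small-worldness indices.
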