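---
title: "A degree-block SIRS model of disturbance spread on food webs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A degree-block SIRS model of disturbance spread on food webs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sirsnet)
```

## The model

An ecological disturbance — a toxin, a population crash, an invasive shock —
rarely stays confined to the species it first hits. Because species depend on
one another through predator–prey links, instability travels along the food
web much like an infection travels along a contact network. `sirsnet`
implements this analogy quantitatively: species are nodes, trophic links are
undirected transmission pathways, and each species is at any time
undisturbed (S), disturbed (I), or recovered (R), with migration in and out
of the system.

Species are grouped by their number of trophic links `k` (the degree-block,
or annealed mean-field, approximation). Writing `S_k, I_k, R_k` for the
densities in class `k = 1..kmax` and `P(k)` for the degree distribution, the
dynamics are

$$
\begin{aligned}
S_k' &= b\,(1 - N_k) - \beta k \theta S_k - \mu S_k + \delta R_k,\\
I_k' &= \beta k \theta S_k - (\mu + \gamma + \sigma) I_k,\\
R_k' &= \sigma I_k - (\mu + \delta) R_k,
\end{aligned}
\qquad
\theta = \frac{\alpha}{\langle k\rangle}\sum_k k P(k) I_k,
$$

with `N_k = S_k + I_k + R_k`. The edge pressure `θ` is the probability that
a random link points at a disturbed species; classes interact only through
it. The rates, all dimensionless per-unit-time proportions strictly in
(0,1):

| rate | meaning | default regime |
|------|---------|----------------|
| `b` | immigration into empty sites | 0.1 |
| `mu` | emigration (all compartments) | 0.1 |
| `gamma` | loss caused by the disturbance itself | 0.1 |
| `sigma` | recovery of disturbed species | 0.5 |
| `delta` | loss of disturbance memory (R back to S) | 0.5 |
| `beta` | per-contact transmission probability | regime-dependent |
| `alpha` | transmissibility coefficient in `φ(k) = αk` | 1 |

Emigrated and lost species leave *empty sites* that immigrants re-occupy, so
the topology — and hence `P(k)` — never changes. Without disturbance each
class settles at the occupancy `b/(b+μ)` (0.5 in the default regime). With
`γ > 0` a circulating disturbance can only push the occupancy below that
carrying value, never above.

`alpha` generalizes the assumption that transmissibility is proportional to
degree. It enters `θ`, and therefore all reproduction numbers, as a single
multiplicative factor; the default `alpha = 1` is the standard choice and
nothing qualitative depends on it.

## Thresholds and equilibria

Everything about the long-run behaviour reduces to one number,

$$
\rho = \frac{\alpha b \beta}{(b+\mu)(\mu+\gamma+\sigma)}
       \frac{\langle k^2\rangle}{\langle k\rangle},
$$

the product of the transmission probability, the disturbance-free occupancy,
the mean disturbed lifetime, and the effective connectivity
`<k²>/<k>`. Heterogeneous webs (heavy-tailed `P(k)`) have large `<k²>/<k>`
and are therefore fragile even when the average connectivity is modest.

* `ρ < 1`: the disturbance-free state `E0` (`S_k = b/(b+μ)`) is globally
  stable; any initial disturbance dies out.
* `ρ > 1`: `E0` loses stability and a unique endemic state `E+` appears and
  attracts every trajectory that starts with some disturbance. Stationary
  per-class densities follow closed forms in a single scalar `θ∞`, which
  solves the self-consistency equation `θ = f(θ)` (`f` is increasing and
  concave with `f'(0) = ρ`, so the positive root exists exactly when
  `ρ > 1`). `sirsnet` solves it by bisection on `[1e-12, 1]` (robust under
  concavity; the bracket is guaranteed); damped fixed-point iteration is
  kept in the test suite as an independent oracle, and the k-regular case,
  where the root is available in closed form, as a second one.

Equivalently, the outbreak condition is `β > β_c` with
`β_c = (b+μ)(μ+γ+σ)⟨k⟩ / (α b ⟨k²⟩)`; the stationary burden rises
continuously from zero as `β` crosses `β_c` (transcritical bifurcation).

```{r thresholds}
p <- sirs_params(b = 0.1, mu = 0.1, gamma = 0.1, sigma = 0.5, delta = 0.5, beta = 0.8)
otago <- degree_moments(5.36, 62.66)  # published moments of an 85-species web
basic_reproduction_number(p, otago)
critical_beta(p, otago)

d <- inverse_degree_dist(a = 0.26, kmax = 31)  # fitted inverse-degree law
endemic_equilibrium(p, d)
```

## What the synthetic generator emulates

The package's reference topology is the truncated inverse-degree law
`P(k) = a/k` on `k = 1..31` with `a = 0.26`, the curve fitted to an
85-species pine-forest food web; the raw masses sum to about 1.047, so the
law is renormalized before use (the published coefficient describes the
unnormalized fit — `fit_inverse_degree()` on the renormalized law returns
`a = 0.2483` with `R² = 1`, the same shape). The configuration-model
generator (`generate_configuration_network()`) draws degrees i.i.d. from the
law, fixes parity by resampling the last degree, and wires stubs into a
simple graph. It reproduces the degree statistics of such webs — and that is
all the mean-field theory depends on — but not their ecological micro-
structure: no trophic levels, no degree correlations, no clustering beyond
what random wiring produces. Tests passing on these graphs therefore
validate the degree-driven predictions, not any claim about a particular
real web's wiring.

Reference parameter regimes are available as named fixtures: `fixture("fig5")`
(outbreak, `β = 0.8`), `fixture("fig6")` (extinction, `β = 0.05`), sweep
regimes `"fig7"`–`"fig9"` (grids over `β`, `σ`, `δ`), `"otago-moments"`,
and the degenerate `"regular-k"` / `"star-n"` topologies.

## Protection strategies

Conservation effort is modeled as immunization with a node budget
`φ̄` = fraction of species protected:

* **uniform** — a random fraction `φ` is protected; transmission scales by
  `1-φ`, so `ρ1 = (1-φ)ρ`.
* **targeted** — the budget is spent top-down by degree: everything above a
  cutoff `κ`, a fraction `c` of class `κ` (`targeted_schedule()` solves for
  `κ` and `c` exactly). Then
  `ρ2 = ρ (1 - ⟨k²φ_k⟩/⟨k²⟩)`; the protected share of the `k²` mass is what
  matters, and for heavy-tailed webs it is much larger than the node share.
* **active** — trophic neighbors of disturbed species are protected as the
  disturbance is detected. In the mean field this adds the link-weighted
  budget `φ̄_k = Σ k P(k) φ_k / ⟨k⟩` to the removal of disturbed species, so
  `ρ3 = ρ (μ+γ+σ)/(μ+γ+σ+φ̄_k)`. The per-class profile reuses the top-down
  schedule; only `φ̄_k` enters the dynamics.

```{r strategies}
cmp <- compare_strategies(p, d, phi_bar = 0.2, check_ordering = FALSE)
cmp
```

Two of the orderings here are structural: targeted never loses to uniform at
equal budget (its covariance with `k²` is non-negative), and every strategy
lowers both `ρ` and the endemic burden. The relative ranking of *targeted
versus active* is not structural, and the run above shows the targeted
strategy winning (`ρ2 = 1.83` against `ρ3 = 5.07`; stationary burden 0.044
against 0.076). The reason is arithmetic: at budget 0.2 the top-down
schedule removes about 80% of the `k²` mass of the inverse-degree web,
while the active mechanism merely divides `ρ` by
`1 + φ̄_k/(μ+γ+σ) ≈ 1.8`. Active protection dominates only where the
disturbed lifetime is long (`μ+γ+σ` small relative to `φ̄_k`) or the web is
nearly homogeneous — a finding the strategy-comparison test suite records
quantitatively rather than assuming either ranking. `compare_strategies()`
flags, but does not enforce, the textbook ordering.

## Stochastic simulator on explicit networks

`quenched_run()` abandons the mean-field closure: it runs the four-state
process (empty / undisturbed / disturbed / recovered) synchronously on a
fixed graph, reading the rates as per-step probabilities. A susceptible
node with `m` disturbed neighbors flips with probability `1-(1-β)^m`;
competing events are resolved in a fixed order (infection before
emigration; recovery before loss; return before emigration), and empty
sites keep their position in the graph.

Two structural gaps separate this process from the ODEs, and both are
deliberate objects of study rather than defects. First, discrete time: a
per-step probability of 0.8 is a poor stand-in for a continuous rate of
0.8. Because `ρ` and all equilibrium *fractions* are invariant under a
uniform rescaling of the six rates, the quantitative cross-check runs at
rates scaled by 0.1, where the chain is a faithful discretization. Second,
the annealed closure itself: on a fixed graph, neighbor states correlate,
and the mean field overestimates prevalence by roughly 10% on
configuration-model graphs of the reference law (n ≈ 1200). The test suite
asserts 20% relative agreement at scaled rates; tighter agreement should
not be expected and is not claimed. On small webs (tens of species) the
gap widens further — documented, not asserted.

`bifurcation_scan()` sweeps `β` and estimates the critical value as the
smallest grid point whose stationary density exceeds an extinction
tolerance (default `1e-3`) with its lower confidence bound above zero. On
finite graphs stochastic extinction pushes the apparent threshold above the
annealed `β_c`; the scan therefore reports both numbers side by side and
the one-grid-step agreement check is run against the annealed stationary
branch, not the stochastic scan.

## Numerical choices

* Integration: `deSolve::lsoda`, `rtol = 1e-9`, `atol = 1e-11` by default;
  trajectories store 401 grid points plus `t_end - 50` so convergence
  (sup-norm change below `1e-10` over 50 time units) can be reported.
* Degree classes with `P(k) = 0` evolve like any other class (their ODEs
  are well defined; they simply do not feed `θ`). This keeps the per-class
  closed-form comparison meaningful for every `k` and costs nothing, since
  such classes carry zero weight in all aggregates.
* The endemic root is found by bisection to residual `1e-12`; parameter
  validation rejects boundary values (`0` or `1`) because the stability
  theory requires strict positivity.
* The inverse-degree fit is linear in its one coefficient, so "nonlinear"
  least squares on `(k, P(k))` reduces exactly to regression through the
  origin on `1/k`; classes with zero observed mass are excluded, and the
  95% CI uses the linearized standard error.
* Property tests draw migration and loss rates from (0.05, 0.3) and
  recovery/memory rates from (0.1, 0.7) — regimes comparable to the
  reference fixtures — and condition asymptotic checks on `ρ < 0.9` or
  `ρ > 1.2`: at the transcritical point relaxation is arbitrarily slow, so
  finite-horizon assertions about `t → ∞` behaviour are only meaningful
  with a margin. Stochastic cross-checks use graphs of 400–2000 nodes and a
  few thousand steps, sizes at which sampling error is well below the
  tolerances being asserted.

## Limitations

The model inherits the limits of its assumptions: links are unweighted and
undirected (no distinction between bottom-up and top-down cascades), the
topology is static (no secondary extinctions), transmission is uniform
across links, and the mean field ignores degree correlations. The active
strategy is represented only through its mean-field rate `φ̄_k`; an explicit
neighbor-sampling implementation on the quenched simulator would be the
natural next refinement.
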