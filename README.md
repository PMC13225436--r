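# sirsnet

Disturbance propagation on food webs, modeled as an SIRS epidemic with
migration on a heterogeneous network.

Ecologists and modelers who want to ask *"will a local shock die out or
become a persistent, ecosystem-wide state — and which species should we
protect to prevent that?"* can use this package to get quantitative answers
from nothing more than a food web's degree distribution and six rates.
Species are nodes, trophic links are undirected transmission pathways, and
each species is undisturbed (S), disturbed (I), or recovered (R), with
proportional immigration `b`, emigration `μ`, disturbance-induced loss `γ`,
recovery `σ`, memory loss `δ`, and per-contact transmission `β`. Grouping
species by degree `k` (the degree-block mean-field approximation) gives,
for `k = 1..kmax`:

    S_k' = b (1 − N_k) − β k θ S_k − μ S_k + δ R_k
    I_k' = β k θ S_k − (μ + γ + σ) I_k
    R_k' = σ I_k − (μ + δ) R_k        θ = Σ_k k P(k) I_k / ⟨k⟩

The basic reproduction number

    ρ = b β ⟨k²⟩ / ((b+μ)(μ+γ+σ) ⟨k⟩)

decides everything: below 1 the disturbance-free state `S_k = b/(b+μ)` is
globally stable; above 1 a unique endemic state exists (closed forms in the
root `θ∞` of a scalar self-consistency equation) and attracts every
trajectory with initial disturbance. Equivalently the outbreak threshold in
transmission is `β_c = (b+μ)(μ+γ+σ)⟨k⟩/(b⟨k²⟩)`.

The package provides:

- **degree tools** — edge-list ingestion (`load_edge_list`), empirical
  degree distributions and moments, inverse-degree (`P(k) = a/k`) fitting
  with CI and R², and a seeded configuration-model generator;
- **mean-field engine** — `basic_reproduction_number`, `critical_beta`,
  `simulate_sirs` (stiff-capable `lsoda`), `endemic_equilibrium`
  (bisection on the self-consistency map), `dfe_stability` (Jacobian
  spectrum at the disturbance-free state);
- **protection strategies** — uniform, degree-targeted and active
  ("protect the disturbed species' best-connected neighbors")
  immunization, with modified reproduction numbers `ρ1, ρ2, ρ3` and a
  matched-budget comparison (`compare_strategies`);
- **stochastic simulator** — the four-state process (including empty sites
  left by migration) on an explicit graph (`quenched_run`), plus a
  bifurcation scan over `β` (`bifurcation_scan`);
- a thin command-line front end at `inst/cli/sirsnet`
  (`stats | fit | generate | rho | simulate | endemic | stability |
  immunize | compare | qsim | scan-beta`).

## Worked example

An 85-species pine-forest food web has published degree statistics
`⟨k⟩ = 5.36`, `⟨k²⟩ = 62.66`, and its degree distribution is well described
by the truncated inverse-degree law `P(k) = 0.26/k`, `k ≤ 31`:

```r
library(sirsnet)

p <- sirs_params(b = 0.1, mu = 0.1, gamma = 0.1,
                 sigma = 0.5, delta = 0.5, beta = 0.8)
otago <- degree_moments(5.36, 62.66)

basic_reproduction_number(p, otago)
#> [1] 6.680171
critical_beta(p, otago)
#> [1] 0.1197574
```

`ρ ≈ 6.68 > 1`: at `β = 0.8` the disturbance becomes endemic; it would take
`β < 0.12` for it to die out. On the fitted law itself, the endemic state
and the long-run burden:

```r
d <- inverse_degree_dist(a = 0.26, kmax = 31)
endemic_equilibrium(p, d)
#> Endemic equilibrium: theta_inf = 0.176990, aggregates S = 0.1838, I = 0.1355, R = 0.1129
```

About 13.5% of sites end up occupied by disturbed species (of the 50%
occupancy that migration sustains). Protecting 20% of species, three ways:

```r
compare_strategies(p, d, phi_bar = 0.2, check_ordering = FALSE)
#> Protection strategies at budget phi_bar = 0.200
#>  strategy   rho  I_star
#>      none 9.143 0.13550
#>   uniform 7.314 0.12485
#>  targeted 1.828 0.04421
#>    active 5.072 0.07559
```

Degree-targeted protection is by far the strongest here: spending the 20%
budget top-down removes ~80% of the `⟨k²⟩` mass that drives transmission
on this heavy-tailed web. See the vignette
(`vignettes/disturbance-model.Rmd`) for when the active strategy wins
instead, and for the stochastic simulator that checks these mean-field
predictions on explicit graphs.

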