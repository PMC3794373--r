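# netevolve

Growing networks rarely grow by node arrival alone: links form between
existing nodes, nodes disappear, edges are pruned. netevolve implements a
minimal evolution model in which these four elementary processes act
simultaneously and independently, for anyone studying how each mechanism
shapes a network's degree distribution — the setting where citation webs,
social networks, protein-interaction maps and the web graph are usually
modelled.

In each unit of time:

* a node arrives with `c` edges, attaching to a degree-`k` node with
  probability ∝ `a + b·k` (random + preferential external attachment);
* `m` internal edges are added, each endpoint drawn with weight `s + t·k`;
* with probability `r` a uniformly random node is deleted with its edges;
* with probability `q`, `m` uniformly random edges are deleted.

For the stationary degree distribution `p_k`, the package provides three
mutually checking routes, plus the phase structure:

* **Simulation** — a compiled stochastic engine (`evolve()`), seeds fully
  reproducible, ~1e5 nodes per second-or-few.
* **Rate equation** — `stationary_distribution()` solves the master
  equation for `p_k` under the uncorrelated-network factorization.
* **Closed forms** — mean degree `⟨k⟩ = 2(c + m(1−q))/(1+r)`; with
  `Φ = cAb + 2mBt`, `Ψ = cAa + 2mBs`, `D = r + 2qm/⟨k⟩` (where
  `A = 1/(a+b⟨k⟩)`, `B = 1/(s+t⟨k⟩)`), the tail exponent
  `γ = 1 + 1/(Φ − D)`, the pure-growth shift `k₀ = Ψ/Φ`, the exact
  pure-growth recurrence, and the exponential-correction factor
  `Ω = Φ/D` (clipped at 1).
* **Phase diagram** — `Ω < 1` marks an exponential phase; the critical
  boundaries `a_c = (c+2m)/D − ⟨k⟩` (power law ↔ exponential) and
  `ã_c = (c+2m)/(D+1/2) − ⟨k⟩` (finite ↔ infinite variance, closing at
  `r_c = m(1−q)/c`) drive `classify_phase()` and `phase_grid()`.
* **Tail fitting** — discrete maximum-likelihood fits of shifted power
  laws `(k+k₀)^−γ`, exponentially corrected power laws `k^−γ Ω^k` and
  geometric tails, with KS-based `k_min` selection and bootstrap CIs
  (`fit_tail()`), plus logarithmic binning (`log_bin()`).

## Worked example

All four processes on, at the standard benchmark parameters:

```r
library(netevolve)
p <- evo_params(c = 3, m = 2, r = 0.2, q = 0.1, a = 0.5, b = 1, s = 0.5, t = 1)

aggregate_rates(p)
#> Rate-equation coefficients: <k> = 8.0000, Phi = 0.8235, Psi = 0.4118, D = 0.2500
predict_exponent(p)
#> [1] 2.74359
phase_boundaries(p)
#> $a_c 20    $a_tilde_c 1.333    $r_c 0.6
classify_phase(p)
#> [1] "powerlaw_infinite_variance"
```

The deletion rates `r = 0.2`, `q = 0.1` push the mean degree down from 10
to 8 and steepen the tail from γ = 2.5 to γ ≈ 2.744 — still in the
infinite-variance phase (`a = 0.5` is below `ã_c = 1.33`; the exponential
phase would need `a > a_c = 20`). Simulation, rate equation and tail fit
agree:

```r
g <- evolve(p, n_target = 1e5, seed = 42)
g
#> Evolving network: n = 100000 nodes, e = 401988 edges, <k> = 8.0398
#>   run: 125065 steps, 25069 nodes deleted, 24896 edges deleted, ...

sol <- stationary_distribution(p, k_max = 20000)
compare_distributions(empirical_degree_distribution(g), sol)$ks_stat
#> [1] 0.002147235

d <- pooled_degree_distribution(p, 1e5, seeds = 1:5)
fit_tail(d, "shifted_powerlaw", k_min = 10, n_boot = 200, seed = 42)
#> Tail fit (shifted_powerlaw), k_min = 10, n_tail = 88828
#>   gamma_hat = 2.7107  [2.6814, 2.7393]
#>   k0_hat = 1.8883
#>   omega_hat = 1.000000, KS = 0.00179
```

The KS distance of 0.002 between a single 1e5-node run and the
master-equation solution, and a fitted exponent within 0.04 of the
closed-form 2.744, are the model's internal consistency in action.

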