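---
title: "Degree distributions of growing networks with internal links and deletion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Degree distributions of growing networks with internal links and deletion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netevolve)
```

## The model

netevolve implements a minimal model of network evolution in which, in each
unit of time, four elementary processes act on a simple undirected graph:

1. **Node addition.** A new node arrives with `c` edges. Each edge attaches
   to a pre-existing node of degree $k$ with probability proportional to
   $a + bk$: the preferential part $bk$ reproduces rich-get-richer growth,
   while the constant $a$ (an *initial attractiveness*) lets degree-0 nodes
   acquire links at all.
2. **Internal links.** `m` edges are added between nodes already present,
   each endpoint drawn independently with weight $s + tk$, so the joint
   kernel factorizes as $(s + tk)(s + tk')$.
3. **Node deletion.** With probability `r` a uniformly random node is
   removed with all its edges. We require $r < 1$ (net growth); $r \ge 1$
   produces steady-state or shrinking networks, which the package refuses.
4. **Edge deletion.** With probability `q`, `m` uniformly random edges are
   removed.

Each mechanism has its own independent dial, which is the point: the effect
of every process on the degree distribution $p_k$ can be switched on and off
separately.

## Mean degree

Per unit time the node count grows by $1 - r$ and the edge count by
$c + m - r\langle k\rangle - qm$ (a deleted node takes $\langle k\rangle$
edges with it on average). With $\langle k\rangle = 2e/n$ asymptotically
constant,

$$\langle k \rangle = \frac{2\,\big(c + m(1 - q)\big)}{1 + r}.$$

`mean_degree()` evaluates this; both the simulator and the solver recover it
independently, which the test suite uses as a cross-check rather than an
input.

## The stationary rate equation

Let $A = (a + b\langle k\rangle)^{-1}$ and $B = (s + t\langle
k\rangle)^{-1}$ be the kernel normalizations. Assuming no degree–degree
correlations (so the joint degree distribution factorizes and the degree of
a random edge endpoint is distributed as $kp_k/\langle k\rangle$), the
stationary distribution obeys

$$p_k = \delta_{kc}
 + cA\big[(a + b(k\!-\!1))p_{k-1} - (a + bk)p_k\big]
 + 2mB\big[(s + t(k\!-\!1))p_{k-1} - (s + tk)p_k\big]
 + D\big[(k\!+\!1)p_{k+1} - kp_k\big],$$

where $D = r + 2qm/\langle k\rangle$ collects every way a node loses a
degree: a deleted neighbour ($r$) or a deleted incident edge
($2qm/\langle k\rangle$). The self-removal term $-rp_k$ cancels against the
dilution from net node growth $(1-r)$, which is why it does not appear.

Three aggregates organise all closed forms: the preferential inflow
$\Phi = cAb + 2mBt$, the random inflow $\Psi = cAa + 2mBs$, and $D$.
`aggregate_rates()` computes them at the analytic mean.

## Closed forms

**Pure growth** ($r = q = 0$). The equation closes into a two-term
recurrence solved exactly by `exact_pure_growth_pk()`:
$p_c = 1/(1 + \Phi c + \Psi)$ and
$p_k = \big(\Phi(k-1) + \Psi\big)p_{k-1}\big/\big(1 + \Phi k + \Psi\big)$.
Its large-$k$ ratio equals that of a shifted power law
$p_k \sim (k + k_0)^{-\gamma}$ with

$$\gamma = 1 + \frac{1}{\Phi}, \qquad k_0 = \frac{\Psi}{\Phi}.$$

**Growth with deletion.** Substituting the tail ansatz
$p_k = Ck^{-\gamma}\Omega^k$ and expanding the successive ratios
$p_{k\pm1}/p_k$ in $1/k$ (telescoping products), the terms of order $k$
give either $\Omega = 1$ or $\Omega = \Phi/D$; the order-one terms then give

$$\gamma = 1 + \frac{1}{\Phi - D}.$$

When $\Phi/D < 1$ the exponential correction is normalizable and the tail
decays exponentially; when $\Phi/D \ge 1$ only $\Omega = 1$ is admissible
and the tail is a pure power law. `omega_factor()` returns the clipped value
with the raw ratio attached, and `predict_exponent()` refuses the
exponential phase rather than returning a meaningless number.

All of these expressions were re-derived from the balance arguments above
and are validated in two independent ways in the test suite: against the
numerical solver's tail, and against the known limiting cases — $\gamma = 3$
for pure preferential attachment, $\gamma = 1 + 2/(1-r)$ with node deletion
only (divergent as $r \to 1$), $\gamma \in (2,3)$ for double preferential
attachment, $\gamma = 3 + a/(bc)$ for external random + preferential
attachment, and $\gamma \to 3$ as $q \to 1$, where edge deletion exactly
cancels internal addition.

**Phase boundaries.** With $b = t = 1$ and $a = s$, $\Omega(a) = 1$ at
$a_c = (c + 2m)/D - \langle k\rangle$ and $\gamma(a) = 3$ at
$\tilde a_c = (c + 2m)/(D + 1/2) - \langle k\rangle$. The infinite-variance
phase disappears ($\tilde a_c \le 0$) once deleted links outnumber the
internal links added, $r\langle k\rangle + 2mq \ge 2m$, i.e. at
$r_c = m(1-q)/c$. `classify_phase()` and `phase_grid()` expose the
resulting three-phase diagram; a distribution exactly at $a_c$ is labelled
`critical_stretched` (the stretched-exponential form at criticality is
labelled, not computed — its prefactor is outside the package's scope).

## Numerical solution of the rate equation

`stationary_distribution()` treats the stationary equation, at fixed
$\langle k\rangle$, as the tridiagonal linear system it is on the truncated
grid $k = 0, \dots, k_{\max}$ (with $p_{-1} = p_{k_{\max}+1} = 0$) and
solves it exactly with a sparse LU factorisation. The mean is then
recomputed from the solution and the solve repeated — a damped
self-consistency iteration. Design notes:

* A naive fixed-point sweep of the time-dependent update map converges like
  $1/n$ per sweep and cannot reach tight tolerances; the exact solve per
  sweep removes that bottleneck while keeping the self-consistency loop, so
  the analytic mean remains a *test output* of the solver, not an input.
* The undamped mean map has derivative $-1$ at the pure-growth fixed point
  (it oscillates forever); damping by $1/2$ makes it locally
  superconvergent. Convergence is declared when the L1 change of $p$ plus
  the mean change drops below `tol` (default $10^{-10}$), typically within
  6–30 sweeps.
* Truncation is absorbing and $p$ is renormalized; when the boundary mass
  $p_{k_{\max}}$ exceeds $100\,\mathrm{tol}$, $k_{\max}$ (default $10^4$) is
  doubled automatically. For heavy tails ($\gamma \le 3$) truncation biases
  the self-consistent mean by $O(k_{\max}^{2-\gamma})$; quantitative
  mean/entry comparisons in the tests therefore use light-tailed parameter
  sets or tolerances matched to the tail weight, and tail *slopes* (which
  truncation barely affects) for the heavy-tailed benchmarks.
* Negative round-off entries are clipped to zero before renormalizing.

## The simulator

`evolve()` runs the process in compiled code with R's RNG, so a run is
reproducible from `set.seed`-style integer seeds alone. Degree-biased draws
never materialize a weight vector: a draw is a two-component mixture of a
uniform node (weight $\text{rand}\cdot n$) and a uniform endpoint of a
uniform edge (weight $\text{pref}\cdot 2e$). Choices that the rate equation
does not pin down, fixed once:

* **Sub-step order** is addition, internal links, node deletion, edge
  deletion. The rate equation treats processes as independent per unit
  time; order affects only $O(1/n)$ terms, and adding first guarantees the
  new node cannot be its own target. The just-added node *is* eligible for
  same-step internal edges and deletion.
* **"Remove the edge between `m` selected pairs"** is implemented as
  deleting `m` uniformly random existing edges, the reading consistent with
  the degree-proportional loss term in the rate equation; the literal
  alternative (sample vertex pairs, delete when an edge exists) would make
  the deletion rate depend on density.
* The graph is kept **simple**: the `c` external targets are distinct and
  exclude the new node; internal draws rejecting self-pairs and existing
  edges are redrawn (cap $10^6$ consecutive rejections, then an error with
  graph statistics). When the graph is momentarily complete, fewer than `m`
  internal edges are added — relevant only in the first few steps from a
  small seed.
* **Isolated nodes are retained** and can re-attach through the random
  components $a$, $s$; with $a = s = 0$ they never do, matching a kernel
  that vanishes at degree 0.
* The **seed graph** is a clique (or ring) on $\max(c,2)+1$ nodes, so `c`
  distinct targets exist at step one; the stationary distribution is
  insensitive to this (tested by comparing both styles at KS $\le 0.02$).
* `burn_in_fraction` (default 0.1) only affects optional distribution
  summaries, never the graph itself.

## What the synthetic benchmarks emulate

The quantitative benchmarks run the two standard parameter sets
$c = 3$, $m = 2$, $a = s = 0.5$, $b = t = 1$ — pure growth, and with
deletion $r = 0.2$, $q = 0.1$ — to $n = 10^5$ nodes, pooled over 10 seeds,
and require KS $\le 0.02$ against the solver. These sizes keep every
stochastic check inside a few minutes on one CPU while leaving Monte Carlo
error well below the tolerances; they are also the sizes at which the
stationary regime is comfortably reached for these parameter sets.
Estimator calibration draws $10^5$ degrees directly from known tail
families ($\gamma = 3$ shifted power law; $\gamma = 2.5$, $\Omega = 0.9$
exponentially corrected) and requires 95% bootstrap intervals to cover the
truth in at least 17 of 20 replicates.

Passing these tests shows that simulator, solver and closed forms agree
*with each other* under the model's assumptions. It does not show that real
networks follow the model: real systems have degree correlations (the
factorization is an approximation), non-linear kernels, aging, fitness
heterogeneity, and rarely stationary parameters. Within the model, the
uncorrelated closure is exact only asymptotically; at $n = 10^5$ residual
finite-size deviations are visible mainly beyond the natural degree cutoff.

## Tail fitting

`fit_tail()` fits the model's three tail families by *discrete* maximum
likelihood (degrees are integers): shifted power law
$(k + k_0)^{-\gamma}$ normalized by a Hurwitz zeta (computed via
Euler–Maclaurin), exponentially corrected power law
$k^{-\gamma}\Omega^k$ normalized by direct summation, and geometric.
`k_min = "auto"` minimizes the KS distance over candidate cut-offs, ties
toward smaller `k_min` (more data). Bootstrap intervals resample the degree
multiset at fixed `k_min`, seeded from the run seed plus a fixed offset;
the percentile interval is widened, if needed, to contain the point
estimate. Degree-0 mass is reported separately and never fitted. Under
deletion the small-degree shift is exposed *only* as a fitted quantity —
the closed-form $k_0 = \Psi/\Phi$ is defined for pure growth, and the
package does not extrapolate it.

## Known limitations

* The exponent and phase formulas hold in the regimes stated above
  ($\Phi > D$ for $\gamma$; $b = t = 1$, $a = s$ for the boundaries); the
  package enforces the regimes instead of extrapolating.
* The stretched-exponential law exactly at $a = a_c$ is classified but not
  evaluated.
* Directed or weighted networks, rewiring, nonlinear kernels, fitness
  distributions and shrinking networks ($r \ge 1$) are out of scope.
* The solver's truncated grid cannot represent the extreme tail of
  heavy-tailed solutions; for $\gamma$ near 2 prefer the closed forms or
  tail slopes over truncated means.
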