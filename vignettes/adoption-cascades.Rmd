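---
title: "Threshold-driven adoption cascades: model, equations and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Threshold-driven adoption cascades: model, equations and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model and its assumptions

adoptnet implements a binary-state contagion on a static network. A node
of degree $k$ is susceptible (0) or an adopter (1); adoption is
absorbing. Susceptible non-immune nodes adopt

* **socially**, as soon as the fraction of adopting neighbours reaches
  their behavioural threshold: $m/k \ge \varphi$, with $\varphi \in (0,1]$
  drawn once per node from a lognormal law truncated to the unit interval
  (thresholds are fractions, so we truncate rather than censor); or
* **spontaneously**, at rate $p_r = p_n/(1-r)$ per non-immune node, so
  that the flux of innovators per *network* node is $p_n$ — the
  convention under which $p_n$ is directly comparable to an empirically
  fitted per-user innovator rate.

A fraction $r$ of nodes is immune and never adopts; the frozen state
therefore has $\rho(\infty) = 1 - r$. The substrate is a
configuration-model graph: degree heterogeneity is retained, and all
degree–degree and degree–threshold correlations are deliberately ignored.
Treating the network as static presumes that adoption is much faster than
the evolution of the social graph (time-scale separation).

Assumptions worth keeping in mind: linear threshold response (the
fraction of adopting neighbours is what matters, not their identity or
tie strength), thresholds independent of degree, homogeneous $p_n$, and
no un-adoption.

## Parameters

| parameter | meaning | unit | default |
|---|---|---|---|
| $\mu_D$, $\sigma_D$ | location/width of $\log k$ | — | 1.09, 1.39 |
| $k_\min$ | smallest degree | — | 1 |
| $k_\max$ | degree cutoff | — | structural, $Q(1-1/n)$ |
| $\mu_T$, $\sigma_T$ | location/width of $\log \varphi$ | — | −2, 1 |
| $r$ | immune fraction | — | 0.73 (reference fit) |
| $p_n$ | spontaneous rate | per node per month | 0.00019 |
| $T$ | observation window | months | 89 |
| $M$ | threshold types in the AME | — | 25 |
| supra-threshold rate | adoption rate once $m \ge k\varphi$ | per month | 1 |

One Monte Carlo iteration = one AME time unit = one month; the
calibration is inherited from fitting $p_n$ to a monthly innovator rate.
The threshold law $(\mu_T, \sigma_T) = (-2, 1)$ reproduces the average
threshold $w = 0.19$ (truncated mean, `threshold_moments()`); inverting
the untruncated moment map at (mean 0.19, sd 0.233) with
`fit_lognormal_moments()` returns $(-2.12, 0.96)$, i.e. the integer
parameterisation at rounding.

### Degree discretisation

The continuous lognormal must be mapped to integer degrees. The default
places mass proportional to the continuous density at each integer
$k \in [k_\min, k_\max]$ and renormalises; an interval-mass convention is
available (`convention = "interval"`). Neither convention (nor the
continuous mean, 8.72) reproduces a mean degree of exactly 8.56 from
$\mu_D = 1.2$; with the model-side $\mu_D = 1.09$ and the structural
cutoff for $n = 10^4$ the discretised mean is 8.61. We therefore use
$\mu_D = 1.09$ as the package default everywhere, which is also the value
the model literature uses for finite simulations so that $z$ matches its
empirical target. The exact finite-size correction procedure behind that
adjustment is not published; we do not attempt to reconstruct it.

## The approximate master equations

Writing $s_{(k,c),m}(t)$ for the fraction of nodes of degree $k$ and
threshold type $c$ ($c = 0$ immune, $c = 1..M$ at threshold $\varphi_c$)
that are susceptible with $m$ adopting neighbours, the AME for monotone
dynamics is

$$\dot s_{(k,c),m} = -F_{(k,c),m}\, s_{(k,c),m}
  - \beta_s (k-m)\, s_{(k,c),m} + \beta_s (k-m+1)\, s_{(k,c),m-1},$$

with the response function $F$ equal to 0 for immune nodes, $p_r$ below
threshold ($m < k\varphi_c$, and for isolated non-immune nodes), and the
supra-threshold rate (default 1) otherwise; $\beta_s$ is the rate at
which a susceptible neighbour of a susceptible node adopts, computed over
the degree-biased class masses. `integrate_full_ame()` integrates this
system directly (dimension $\sum_k (k+1)(M+1)$, capped; intended for
toys and verification).

For threshold dynamics this system reduces *exactly* to two ODEs. With
the ansatz $s_{(k,c),m} = B_{k,m}(\nu)\, e^{-p_r t}$ for sub-threshold
$m$ (binomial $B_{k,m}$, and no decay factor for immune classes), the
consistency condition collapses every class equation onto

$$\dot\rho = \lambda\,[h_t(\nu) - \rho], \qquad
  \dot\nu = \lambda\,[g_t(\nu) - \nu],$$

$$h_t(\nu) = (1-r)\Big[1 - \big(1 - \tfrac{p_r}{\lambda}\big) e^{-p_r t}
  \sum_k P(k) \sum_c P(c) \sum_{m < k\varphi_c} B_{k,m}(\nu)\Big],$$

and $g_t$ identical with $P(k)$ replaced by the neighbour distribution
$kP(k)/z$ and $B_{k,m}$ by $B_{k-1,m}$; $\lambda$ is the supra-threshold
rate and $\rho(0) = \nu(0) = 0$. Checks built into the test suite: the
reduction agrees with the full AME to $10^{-3}$ (in practice $10^{-8}$)
on single-type regular substrates, where the ansatz is exact; trivial
limits ($p_n = 0$; thresholds out of reach giving
$\rho = (1-r)(1-e^{-p_r t})$) hold in closed form; and the solution
tracks the Monte Carlo mean within 0.02 at the reference
parameterisation.

Two bookkeeping ODEs run alongside:

* `rho0` — **innovators by exposure**: spontaneous adopters with no
  adopting neighbour at adoption time
  ($\dot\rho_0 = p_r(1-r)e^{-p_r t}\sum_k P(k)(1-\nu)^k$). This matches
  the empirical categorisation $\Phi_k = 0$, and it is the definition
  under which the final innovator fraction and the half-adoption time
  $t_c$ peak at the *same* immune fraction, the crossover
  $r_c \approx 0.8$ at the reference setting.
* `rho0_spont` — **all spontaneous adopters**
  ($\dot\rho_0 = p_r(1-r-\rho)$), whose maximum sits lower
  ($r \approx 0.73$). Both are exposed; `crossover_point()` uses the
  exposure definition by default.

### Degree support

`integrate_reduced()` uses the full integer degree range by default. The
25 geometric degree classes on $[3, 150]$ (mass outside folded to the
boundary classes) are retained as an option — they are the standard
economical setting for the *full* AME — but folding the ~30% of mass at
$k \in \{1, 2\}$ upward makes low-degree nodes adopt socially too fast
and costs an order of magnitude in MC agreement (max
$|\Delta\rho| \approx 0.09$ vs $0.014$ at $r = 0.5$). The crossover scan
is insensitive to this choice.

## Monte Carlo engine

Per iteration: (1) spontaneous draws among susceptible non-immune nodes
with probability $p_r$; (2) **one synchronous threshold sweep** against
the states frozen at the start of the iteration. All adopters of an
iteration share a timestamp and are mutually invisible to the threshold
rule — consistent with the analysis-side exclusion of same-time links.
One sweep per iteration gives cascades a finite speed (so the
1-iteration-=-1-month calibration is meaningful). The alternative —
iterating the sweep to exhaustion within a timestamp
(`update = "exhaustive"`) — collapses entire cascades onto a single
timestamp, which empties the adoption network of edges and is kept only
for sensitivity analysis; it cannot reproduce the observed giant adoption
components.

## Cascade analytics

$\Phi_k$ counts neighbours adopting **strictly earlier** than the ego;
ties carry no direction of influence and are excluded everywhere
(classification, adoption network, stable subgraph, vulnerable forest).
Vulnerable nodes ($\Phi_k = 1$) have exactly one strictly-earlier
neighbour, which becomes their parent; parent chains end at a
non-vulnerable root. Tie-breaking (earliest neighbour, then smallest id)
is stated for completeness — for true vulnerable nodes the parent is
unique. A tree's size counts its vulnerable members only, and a single
vulnerable node below its root has depth 1. Trees rooted at stable
adopters exist and are reported, but only innovator-rooted trees enter
$\langle s_v\rangle(k)$. Relative component sizes are reported against
the substrate size by default, with the graph's own node count always
available.

## Estimators

* `estimate_pn()` is the least-squares constant fit (the mean) of the
  innovator rate $R_i(t)$ beyond a burn-in. The plateau assumption holds
  only while cumulative adoption is small: susceptible depletion scales
  the flux by $1 - \rho/(1-r)$, and spontaneous adopters with an
  already-adopting neighbour are not counted as $\Phi_k = 0$ innovators
  (an undercount of order $\langle k\rangle \bar\rho$). Fit guidance:
  restrict the window to months where cumulative adoption is below ~2%
  of the non-immune pool; on transient-free synthetic logs use burn-in 0
  (the burn-in exists to discard launch transients in empirical series).
  Under that rule the mean over ten fixtures recovers $p_n$ within a few
  percent at the reference setting.
* `estimate_r()` matches the mean relative largest component of the
  adoption network at time $T$ against an observed value over a grid of
  $r$, averaging over configuration-model realisations (runs
  configurable; dispersion is the only uncertainty quantified). The
  matching curve is steep and monotone through the crossover, which is
  what makes $r$ identifiable to ±0.05 with a handful of runs.

## Synthetic data generator

`generate_fixture()` wraps `build_population()` + `simulate_adoption()`
and returns the event log with full ground truth (parameters, per-node
adoption channel and exposure at adoption). Optionally a configured
fraction of adopters is reassigned the timestamp of a random
earlier-adopting neighbour, emulating instantaneous group adoptions not
driven by influence; at collision rate 0 the analysis-side classification
recovers the generator classes exactly, which is the round-trip oracle
used throughout the tests. The generator emulates what the model
emulates — it shares the configuration-model independence assumptions,
integer (monthly) timestamps and stationary $p_n$ — so passing tests
demonstrate internal consistency and correct algorithmics, not that real
adoption data satisfies those assumptions (real networks have clustering,
homophily, degree–threshold correlation and non-stationary exogenous
pressure).

## Numerical choices

* ODEs: `deSolve::lsoda`, atol $10^{-10}$, rtol $10^{-8}$; frozen state
  detected by integrating to $t = 20/p_r$ (susceptible mass down to
  $e^{-20}$).
* $t_c$ is linearly interpolated at the first crossing of $(1-r)/2$; a
  never-crossing series returns `NA` with a warning.
* `phase_surface()` re-derives $\mu_T$ and $\mu_D$ per grid point by
  root-finding on the truncated-threshold mean and the discretised degree
  mean; infeasible cells (no lognormal location attains the requested
  $w$ or $z$) are masked. Monotonicity in $w$ is rigorous; monotonicity
  in $z$ holds only inside the cascading region — outside it adoption is
  spontaneous-dominated and *sparser* networks adopt slightly faster via
  single-neighbour triggering, so no global $z$-ordering is asserted.
* Configuration model: stub matching, then erasure of self-loops and
  multi-edges (<2% of edges at the reference sizes); an odd stub sum adds
  one stub to the first node. Immune placement is by exact count
  `round(r n)`, making $\rho(\infty) = 1-r$ exact per realisation.
* Isolated nodes never reach the social branch; their response is
  $p_r$ regardless of the threshold.

## Problem sizes

Reference desk scale, chosen to keep the full suite in minutes while
leaving stochastic margins well clear of the tolerances: unit tests run
populations of $10^2$–$10^4$ nodes; the acceptance suite uses $10^5$
nodes × 10 seeds for the Monte Carlo reproducibles, $10^4$ × 10 seeds ×
6 grid points for the fragmentation scan, 19 grid points for the AME
crossover scan, and ten $5\times10^4$-node fixtures for parameter
recovery. The AME–MC comparison averages 10 runs at $10^5$ nodes; at
that size single-run fluctuations of $\rho(t)$ are ~$3\times10^{-3}$, an
order below the 0.02 agreement band.

## Known limitations

* The reduced pair is exact only on regular single-type substrates; for
  heterogeneous degrees/types it is an (excellent) approximation whose
  residual error is largest at the cascade explosion, where discrete
  sweeps and continuous rates also differ most — deep in the rapid
  regime ($r \lesssim 0.3$) the explosion is near-vertical and a
  one-iteration timing offset dominates pointwise comparisons even
  though the final state matches.
* Deep in the rapid-cascade regime roughly 40% of adopters end up in the
  percolating stable cluster under the strictly-earlier classification;
  the ~10% share quoted in the empirical literature emerges here only
  near the crossover ($r \approx 0.73$–0.75), as the acceptance report
  and the README example show.
* No temporal networks, no recovery, no degree–threshold correlation, no
  likelihood-based inference; estimation uncertainty is grid + run
  dispersion only.
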