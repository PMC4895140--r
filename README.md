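# adoptnet

Modelling and analysis of threshold-driven adoption cascades on social
networks, for researchers studying how products and online services spread
through a population of interconnected individuals.

## The model

Each node of a static social network is either susceptible (0) or an
adopter (1), and adoption is absorbing. A node of degree *k* carries a
behavioural threshold *φ* ∈ (0, 1]: it adopts through social influence as
soon as a fraction *m/k ≥ φ* of its neighbours have adopted. Two features
turn this classic linear-threshold rule into a realistic model of service
adoption:

- a fraction *r* of **immune** nodes that never adopt (individuals with no
  interest in the service), and
- **spontaneous adoption**: every susceptible non-immune node adopts
  exogenously at constant rate *p_n* per network node per unit time
  (*p_r = p_n / (1 − r)* per non-immune node), so innovators keep arriving
  throughout the process instead of only seeding it.

The substrate is a configuration-model graph with lognormal degrees
(*μ_D*, *σ_D*, *k*<sub>min</sub>) and i.i.d. lognormal thresholds
truncated to (0, 1] (*μ_T*, *σ_T*), independent of degree. The reference
parameterisation (`default_config()`) uses *μ_D* = 1.09, *σ_D* = 1.39,
*μ_T* = −2, *σ_T* = 1 (average threshold *w* = 0.19), *p_n* = 0.00019 per
month, and an 89-month observation window.

Three layers are provided:

1. **Monte Carlo** (`simulate_adoption()`): discrete-time synchronous
   dynamics emitting an adoption event log `(node, t)`.
2. **Approximate master equations** (`integrate_reduced()`,
   `integrate_full_ame()`): the per-(degree, type, exposure) master
   equations for monotone binary dynamics, reduced exactly to a pair of
   ODEs for the adopter fraction ρ(t) and the neighbour-adopter
   probability ν(t). `crossover_point()` scans the immune fraction and
   locates the crossover *r_c* between rapid cascades and quenched slow
   adoption (maximal final innovator fraction and half-adoption time
   *t_c*).
3. **Cascade structure** (`classify_adopters()`,
   `build_adoption_network()`, `stable_subnetwork()`,
   `vulnerable_forest()`): adopters are classed by their integer threshold
   Φ_k — the number of neighbours adopting strictly earlier — as
   innovators (Φ_k = 0), vulnerable (Φ_k = 1) or stable (Φ_k > 1); links
   between same-time adopters are excluded as carrying no evidence of
   influence. `estimate_r()` recovers the immune fraction from an event
   log by matching largest-component sizes, and `estimate_pn()` fits the
   innovator-rate plateau.

## Worked example

```r
library(adoptnet)
set.seed(42)

deg <- degree_model(1.09, 1.39)        # lognormal degrees, z ~ 8.6
thr <- threshold_model(-2, 1)          # lognormal thresholds, w = 0.19
threshold_moments(thr)
#>    mean    sd
#> 1 0.192 0.180

pop <- build_population(deg, thr, n = 10000, r = 0.73)
sim <- simulate_adoption(pop, p_n = 0.00019, steps = 89)
sim
#> <adoption_sim> 89 iterations, 578/10000 adopters (rho = 0.058, 1 - r = 0.270)

cls <- classify_adopters(pop, sim$events)
table(cls$class)
#>  innovator     stable vulnerable
#>        151         75        352

stable <- component_stats(stable_subnetwork(pop, sim$events),
                          n_total = pop$n)
glance(stable)
#>      lc   lc2 n.nodes lc.frac
#> 1    56     2      75  0.0056

max_relative_growth_rate(sim$events)
#> [1] 0.2301038

pars <- ame_params(deg, thr, r = 0.73, p_n = 0.00019, n = 10000)
sol <- integrate_reduced(pars, t_grid = 0:89)
c(rho_mc = nrow(sim$events) / pop$n, rho_ame = tail(sol$rho, 1))
#>     rho_mc    rho_ame
#> 0.05780000 0.06041712
```

At *r* = 0.73 the process sits in the crossover regime: after 89 months
only 5.8% of the network has adopted (out of an eventual 27%), adoption
is dominated by innovators and the small vulnerable trees they trigger,
the largest stable cluster holds about 10% of adopters, and the maximum
relative growth rate (largest yearly adoption count over the final total,
0.23 here) indicates gradual rather than instantaneous spreading. The
reduced AME tracks the simulated adoption curve closely (0.060 vs 0.058
at *t* = 89).

`autoplot()` methods exist for simulations, AME solutions, crossover
scans, `(w, z)` phase surfaces and regime reports; `tidy()`/`glance()`
return tibbles for all fitted or scanned objects. A thin command-line
front end over the same functions lives in `inst/cli/adoptnet.R`
(subcommands `simulate`, `fixtures`, `analyze`, `crossover`, configured
by YAML).

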