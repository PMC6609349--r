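---
title: "The producibility metric: probabilistic biosynthetic capability of metabolic networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The producibility metric: probabilistic biosynthetic capability of metabolic networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pmnet)
```

## The model

A stoichiometric metabolic network is a matrix $S$ (metabolites $\times$
reactions) with flux bounds $lb \le v \le ub$.  Whether a target metabolite
can be synthesized from a given set of available input metabolites is a
linear-programming question: open an importing exchange ($\emptyset \to$
metabolite, bounds $[0,1000]$) for each available input, maximize the
target's exporting exchange flux subject to $S v = 0$ and the bounds, and
call the target *producible* when the optimum exceeds a small threshold
(0.001 flux units).  Under **inequality mass balance** — the default here —
every metabolite additionally receives a free exporting exchange, so the
network may leave byproducts behind; only the *production* of the target is
constrained, not global steady state.  This treatment matters for
cofactors: a reaction consuming NADH can run as long as some other reaction
regenerates NADH from NAD$^+$, with zero net cofactor consumption, which a
purely graph-topological expansion would miss.

The environment is rarely known.  The producibility metric embraces that:
every candidate input metabolite is drawn independently as a
Bernoulli($P_{in}$) variable, and the **producibility curve**
$P_{out}(P_{in})$ is the probability that a random environment supports
production of the target.  By monotonicity of LP feasibility in the input
set, the curve is non-decreasing.  The **producibility metric** is

$$\mathrm{PM} = 1 - P_{in,0.5},$$

where $P_{in,0.5}$ is the input probability at which $P_{out} = 0.5$
(analogous to the half-saturation constant of a Michaelis–Menten curve).
Targets that are synthesized from many alternative precursors cross early
(PM near 1); targets needing a rare conjunction of inputs cross late (PM
near 0); a target with no producing route never crosses (PM = 0 by
convention), and one producible with no random inputs at all never falls
below it (PM = 1).

The candidate input pool defaults to all intracellular metabolites except
the target itself, which sidesteps unreliable transporter annotations in
draft reconstructions.

## Exact counterpart: minimal precursor sets

For a candidate pool of size $m \le 20$, `enumerate_structure()` decides
feasibility of all $2^m$ input subsets (with monotone pruning) and records
the antichain of **minimal precursor sets**.  With $c_k$ the number of
feasible subsets of size $k$,

$$P_{out}(p) = \sum_{k=0}^{m} c_k\, p^k (1-p)^{m-k}$$

is exact, and `analytic_pm()` finds its half-crossing by bisection to
1e-10.  Closed forms follow for the elementary motifs: a linear chain of
$n$ intermediates (any one suffices) has $P_{out} = 1-(1-p)^n$ and
$\mathrm{PM} = 0.5^{1/n}$; $k$ jointly required substrates give
$\mathrm{PM} = 1 - 0.5^{1/k}$.  These closed forms, the enumeration
oracle, and the sampling estimator are three independent routes that the
test suite plays against each other.

## The sampling estimator

`calc_pm()` estimates the crossing adaptively, as exhaustive sampling of
the whole curve would waste almost all of its LP solves far from the
crossing:

1. Boundary shortcuts: if the target is unproducible even with every
   candidate present, PM = 0; if producible with only the fixed-on
   metabolites, PM = 1.  Flat curves have no half-crossing, so they are
   decided before any fitting.
2. Otherwise each of `runs` independent runs starts at $P_{in} = 0.5$,
   estimates $P_{out}$ there from `samp` Bernoulli environments, refits a
   sigmoid to all points sampled so far, takes the fitted half-crossing as
   the current PM estimate, and places the next point at the estimate plus
   uniform jitter of half-width `noise`.  A run converges when the last
   `n_conv` estimates span at most `thresh` (on the PM scale).
3. The reported PM is the arithmetic mean of the per-run final estimates;
   per-run values are kept for dispersion diagnostics (`tidy()`).

Defaults (`pm_params()`): `samp = 50`, `noise = 0.3`, `n_conv = 7`,
`thresh = 0.01`, `runs = 10`, a `max_points = 100` cap per run (hitting the
cap reports the last estimate with `converged = FALSE`).  These are the
reference analysis conditions and were not re-tuned here.

### Numerical choices in the curve fit

The fitted sigmoid is the two-parameter logistic
$P_{out} = 1/(1+\exp(-(p-m)/s))$ with the crossing read off as $m$.  Two
refinements control bias, both motivated by comparison against the exact
enumeration oracle:

* **Crossing-information weighting.**  Residuals are weighted by
  $q(1-q) + 0.01$.  True producibility curves are asymmetric (e.g.
  $1-(1-p)^n$ saturates slowly on one side); an unweighted symmetric
  logistic is dragged by the saturated tail and systematically
  misplaces the crossing by up to ~0.03 on steep chain-like curves.
  Near the crossing every smooth monotone curve is locally logistic, so
  points there carry the information; the floor keeps early, saturated
  fits identifiable.
* **Local polynomial polish.**  After the logistic fit, the crossing is
  refined by a Gaussian-kernel-weighted quadratic fit around the current
  estimate (bandwidth $\max(1.5 s, 0.025)$, up to four iterations), whose
  second-order term absorbs the local curvature that biases any symmetric
  first-order fit.  When the window holds too few points the step falls
  back to a local linear fit, then to the logistic value.

With both refinements the estimator agrees with the exact PM to within
about 0.01–0.02 (mean bias $\lesssim$ 0.01) across chains, fan-ins,
conjunctions and random enumerable networks at default parameters.  A
known limitation remains at extreme crossings ($P_{in,0.5} \lesssim
0.04$, PM $\gtrsim 0.96$): the jitter window is large relative to the
crossing, most samples saturate, and a residual downward bias of about
0.01 persists.

The jitter is $\mathrm{Uniform}(-\mathrm{noise}, +\mathrm{noise})$,
clamped to $[0,1]$.  Convergence is measured as the max–min span of the
last `n_conv` estimates.  LP feasibility calls inside one `calc_pm()` are
served through a monotone witness cache: a sampled environment containing
a known-feasible set is feasible without a solve, and one contained in a
known-infeasible set is infeasible; correctness rests on the same
monotonicity property that the test suite checks directly.

### The linear programming core

No LP solver is required as a dependency: the package carries a
bounded-variable two-phase revised simplex (C++/Armadillo, dense basis
inverse with periodic refactorisation, sparse pricing, Bland's-rule
anti-cycling fallback, early exit for threshold queries, tolerance 1e-9).
All programs it faces are homogeneous ($Sv = 0$) with the environment in
the bounds.  It is validated against an independent pure-R simplex on
random programs and against hand-solved cases, including forced-flux
bounds that exercise phase 1.

## Pairwise organism metrics

From a PM matrix (organisms $\times$ metabolites) the package derives the
inter-organism measures used in co-occurrence analyses: the L1 **PM
distance**; the directional **PM complementarity**
$\sum_i(\max(PM_i^A, PM_i^B) - PM_i^B) / \sum_i PM_i^A$ (how much A could
supplement B); NetSeed-style **seed sets** (source strongly connected
components of the directed metabolite graph; seed score $1/|$component$|$;
no minimum component size, isolated metabolites retained) with seed
distance/competition/complementarity; and reaction-content L1 and Jaccard
distances.  Missing PM entries are dropped pairwise.  `collapse_to_genus()`
averages a metric over ordered organism pairs between genera, excluding
self-pairs; a within-genus entry for a single-member genus is therefore
missing rather than 0 — forcing the conventional zero diagonal would
discard the within-genus dispersion the average is meant to carry.

## Permutation statistics

`mantel()` correlates the off-diagonal cells of two aligned square
matrices (Spearman by default) and permutes the organism labels of the
first matrix — one relabelling applied simultaneously to rows and columns —
with the two-sided p-value $(n+1)/(N+1)$, where $n$ counts permutations
with $|\rho|$ exceeding the observed.  `partial_mantel()` controls for a
third matrix via the standard partial-correlation formula and permutes
only the first matrix.  Directional metrics use both triangles by default;
`triangle = "upper"` matches analyses of symmetric growth matrices.  Ties
in Spearman ranks take average ranks.

## Robustness experiment

`perturbation_study()` removes $n$ random reactions (biomass and
maintenance protected; reactions are deleted, not bounded to zero) at each
level, with fresh replicates, and scores each perturbed network against
the original: FBA quantitative accuracy $1 - |flux - flux_0|/flux_0$ in a
minimal and a complete medium, PM quantitative accuracy $1 - \sum_i |PM_i
- PM_i^0| / \sum_i PM_i^0$ over biomass components, both floored at 0
(the normalized L1 can exceed 1 when perturbation inflates a metric), and
qualitative biomass calls (FBA flux $>1\%$ of original; all component PMs
above 0.1 or 0.6).  Components with baseline PM 0 are dropped — they carry
no signal, like metal ions in a genome-scale model.

## What the synthetic generators emulate — and what they do not

The fixture generators produce 1:1 mass-consistent networks, so nothing is
producible from an empty environment and PM = 1 arises only via fixed-on
metabolites.  `make_chain()`, `make_fan_in()` and `make_conjunctive()`
realize the closed-form motifs.  `make_cofactor_loop()` couples target
synthesis to an NADH/NAD pair regenerated by 6 independent reactions
(default): with several recycling routes the exact PM of the target sits
within 0.01 of the cofactor-free chain, reproducing the observation that
readily recycled cofactors barely affect producibility; removing the
recycling strictly lowers it to the conjunctive value $1-\sqrt{0.5}$.

`make_perturbation_network()` (default 300 reactions: per-metabolite
secretion exchanges, layered single-product internal reactions with one or
two substrates, a 20-component biomass) emulates the *draft-reconstruction
regime*: producer redundancy is deliberately low, so minimal-medium FBA is
fragile to reaction loss while producibility — which credits any remaining
upstream route — degrades gradually.  Real genome-scale networks differ in
ways these fixtures do not capture: non-unit stoichiometry, compartments
and transporters, promiscuous enzymes, and thermodynamically constrained
reversibility.  Passing tests on these fixtures validate the machinery and
its scaling behaviour, not the biology of any particular organism.

## Problem sizes used by the test suite

The suite exercises the estimator at the scale a reviewer can re-run on one
CPU: enumerable networks up to 12 candidates ($2^{12}$ subsets with
pruning), the agreement battery at default estimator parameters, the
robustness experiment on the 300-reaction synthetic network with 20
replicates at removal levels 4–30 using reduced sampling
(`samp = 12, runs = 2, n_conv = 5, thresh = 0.02`), and Mantel calibration
with 200 simulations of 15 organisms at 999 permutations.  The reduced
perturbation sampling parameters are a deliberate precision/runtime
trade-off for the experiment's aggregate accuracy means, which average over
20 components $\times$ 20 replicates and therefore tolerate per-PM noise;
single-target analyses should keep the defaults.

## Known limitations

* PM values above ~0.96 are estimated with a residual downward bias of
  about 0.01 (see above); exact enumeration is preferable when the
  candidate pool permits it.
* The inequality-balance relaxation credits production routes that leave
  byproducts behind; under strict steady-state assumptions use
  `balance = "equality"`, which is the more conservative call.
* Reaction reversibility is taken from model bounds as given; misannotated
  directionality propagates into the PM, as it does into any
  stoichiometric method.
* `seed_set()` follows the published source-component definition with no
  currency-metabolite filtering; hub cofactors can therefore join large
  components and dilute seed scores.

## A worked example

```{r, eval = FALSE}
net <- make_cofactor_loop()
prep <- prepare_model(net)

# exact: minimal precursor sets and PM
st <- enumerate_structure(prep, "T")
st$minimal_sets
analytic_pm(st)

# sampled: default estimator, reproducible under a seed
est <- calc_pm(prep, "T", seed = 1)
glance(est)
autoplot(est)
```
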