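# pmnet — producibility metrics for stoichiometric metabolic networks

Draft metabolic networks reconstructed straight from genomes are full of
gaps, and the chemical environment of most microbes — above all the
uncultivated ones — is unknown. Flux balance analysis needs both a curated
network and a defined medium, so it stumbles on exactly the organisms for
which biosynthetic predictions would be most valuable: community members
suspected of depending on metabolites made by their neighbours.

`pmnet` implements a percolation-inspired, probabilistic alternative. Every
candidate input metabolite is present in the environment independently with
probability *P*<sub>in</sub>; for each sampled environment a linear program
decides whether the network can produce a target metabolite (maximize the
target's export subject to *S v* = 0, bounds, and — under the default
*inequality mass balance* — free export of all byproducts, so that
recyclable cofactors need not be supplied). Scanning *P*<sub>in</sub> yields
the producibility curve *P*<sub>out</sub>(*P*<sub>in</sub>), and the

**producibility metric PM = 1 − *P*<sub>in,0.5</sub>**,

one minus the input probability at which the target is producible in half
of the sampled environments. PM ≈ 1: robustly synthesized from many
alternative precursors. PM ≈ 0: needs a rare conjunction of inputs, or has
no route at all. For small candidate pools the package also computes the PM
*exactly* from the antichain of minimal precursor sets
(*P*<sub>out</sub>(p) = Σ<sub>k</sub> c<sub>k</sub> p<sup>k</sup>(1−p)<sup>m−k</sup>),
giving closed forms such as PM = 0.5<sup>1/n</sup> for a linear chain of
*n* intermediates and 1 − 0.5<sup>1/k</sup> for *k* jointly required
substrates.

On top of the estimator the package provides the surrounding toolkit:
SBML (Level 3 + FBC) and COBRA JSON readers/writers, model standardisation,
FBA, gene knockouts, random reaction-removal robustness experiments
(PM versus FBA accuracy), pairwise inter-organism metrics (PM distance and
complementarity, NetSeed-style seed sets, reaction distances, genus
collapsing) and Mantel / partial Mantel permutation tests — everything
needed to go from a directory of draft models to a producibility atlas and
its ecological correlates. A self-contained LP solver (bounded-variable
revised simplex in C++) is built in; no external solver is required.

## A worked example

```r
library(pmnet)

net  <- make_cofactor_loop()   # A + NADH -> T + NAD, six NAD->NADH recycling routes
prep <- prepare_model(net)     # silence native exchanges, add import/export handles

st <- enumerate_structure(prep, "T")   # exact: all input subsets
st
#> <precursor_structure> 15 candidates, 7 minimal precursor set(s)
st$minimal_sets[1:2]
#> [[1]]
#> [1] "A"    "NADH"
#> [[2]]
#> [1] "A"  "B_1"
analytic_pm(st)
#> [1] 0.496266

est <- calc_pm(prep, "T", seed = 1)    # sampled: adaptive curve estimator
est
#> <pm_estimate> target: T  PM = 0.4908
glance(est)
#>          pm    p_half      pm_sd runs n_points converged boundary
#> 1 0.4908055 0.5091945 0.02160739   10      224      TRUE     none
```

What the numbers mean: production of `T` needs `A` plus *any one* of
{NADH, B_1, …, B_6} — the cofactor can cycle at steady state, so each
recycling substrate is as good as NADH itself. The exact PM (0.4963) is
within 0.01 of the cofactor-free chain `A -> T` (PM = 0.5): readily
recycled cofactors barely affect producibility. The sampled estimate
(0.491 ± 0.022 across 10 runs) agrees with the exact value. Deleting the
recycling reactions collapses the minimal sets to {A, NADH} and the PM to
1 − √0.5 ≈ 0.293.

`autoplot(est)` draws the sampled producibility curve; `pm_matrix()` scales
the calculation to many models × targets; `perturbation_study()` reproduces
the reaction-removal robustness comparison against FBA; `mantel()` links
pairwise metric matrices to co-occurrence data. A command-line wrapper with
the same capabilities ships at `inst/cli/pmnet.R`
(`Rscript inst/cli/pmnet.R pm --model model.xml --target T --seed 1`).

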