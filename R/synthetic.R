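# Deterministic generators of toy and random metabolic networks with known
# precursor structure.  All fixtures are 1:1 mass-consistent, so nothing can
# be produced from an empty input set and PM = 1 can only arise through
# fixed-on metabolites.

rxn_tbl <- function(id, stoich, lb = 0, ub = 1000, name = id) {
  tibble::tibble(id = id, name = name, stoich = stoich, lb = lb, ub = ub)
}

#' Linear-chain fixture
#'
#' Metabolites `M_1 ... M_n` feed the target `T` through irreversible
#' reactions `M_i -> M_(i+1)` and `M_n -> T`.  Any intermediate alone
#' suffices to make `T`, so the exact producibility curve is
#' `1 - (1 - p)^n` and the analytic PM equals `0.5^(1/n)`.  Each reaction
#' carries a gene `g1 ... gn` so knockout experiments can target single
#' steps.
#'
#' @param n chain length (number of intermediates).
#' @return a [metabolic_network()].
#' @export
make_chain <- function(n) {
  stopifnot(n >= 1)
  mets <- c(paste0("M_", seq_len(n)), "T")
  stoich <- lapply(seq_len(n), function(i) {
    out <- c(-1, 1)
    names(out) <- c(mets[i], mets[i + 1])
    out
  })
  ids <- paste0("R", seq_len(n))
  genes <- stats::setNames(as.list(ids), paste0("g", seq_len(n)))
  metabolic_network(
    metabolites = tibble::tibble(id = mets),
    reactions = rxn_tbl(ids, stoich),
    genes = genes,
    id = paste0("chain", n)
  )
}

#' Fan-in fixture: k alternative single-step routes to the target
#'
#' Each precursor `P_i` converts directly to `T`, so the minimal precursor
#' sets are the k singletons and the analytic PM is `0.5^(1/k)`.
#'
#' @param k number of independent precursors.
#' @export
make_fan_in <- function(k) {
  stopifnot(k >= 1)
  mets <- c(paste0("P_", seq_len(k)), "T")
  stoich <- lapply(seq_len(k), function(i) {
    out <- c(-1, 1); names(out) <- c(mets[i], "T"); out
  })
  metabolic_network(
    metabolites = tibble::tibble(id = mets),
    reactions = rxn_tbl(paste0("R", seq_len(k)), stoich),
    id = paste0("fanin", k)
  )
}

#' Conjunctive fixture: one reaction consuming k distinct substrates
#'
#' All k precursors are required simultaneously, so the single minimal
#' precursor set is the full set and the analytic PM is `1 - 0.5^(1/k)`.
#'
#' @param k number of jointly required substrates.
#' @export
make_conjunctive <- function(k) {
  stopifnot(k >= 1)
  mets <- c(paste0("P_", seq_len(k)), "T")
  st <- c(rep(-1, k), 1)
  names(st) <- mets
  metabolic_network(
    metabolites = tibble::tibble(id = mets),
    reactions = rxn_tbl("R1", list(st)),
    id = paste0("conj", k)
  )
}

#' Cofactor-recycling fixture
#'
#' The target is made by `A + NADH -> T + NAD`, and the cofactor is
#' regenerated by `n_recycle` independent reactions `B_j + NAD -> NADH + C_j`.
#' Because the NADH/NAD pair can cycle at steady state, production of `T`
#' requires `A` plus any one of `{NADH, B_1, ..., B_r}` -- so with several
#' recycling routes the PM of `T` approaches that of the cofactor-free chain
#' `A -> T`, reproducing the observation that readily recycled cofactors
#' barely affect a target's producibility.  Dropping the recycling reactions
#' (see `recycle = FALSE`) leaves `{A, NADH}` as the only minimal precursor
#' set and strictly lowers the PM.
#'
#' @param n_recycle number of cofactor-regenerating reactions.
#' @param recycle include the recycling reactions?
#' @export
make_cofactor_loop <- function(n_recycle = 6, recycle = TRUE) {
  stopifnot(n_recycle >= 1)
  r <- if (recycle) n_recycle else 0
  mets <- c("A", "T", "NADH", "NAD",
            if (r) c(paste0("B_", seq_len(r)), paste0("C_", seq_len(r))))
  stoich <- list(c(A = -1, NADH = -1, T = 1, NAD = 1))
  ids <- "R_main"
  for (j in seq_len(r)) {
    st <- c(-1, -1, 1, 1)
    names(st) <- c(paste0("B_", j), "NAD", "NADH", paste0("C_", j))
    stoich <- c(stoich, list(st))
    ids <- c(ids, paste0("R_rec", j))
  }
  metabolic_network(
    metabolites = tibble::tibble(id = mets),
    reactions = rxn_tbl(ids, stoich),
    id = if (recycle) "cofactor_loop" else "cofactor_noloop"
  )
}

#' Random enumerable network
#'
#' A chain backbone `M_1 -> ... -> M_n -> T` guarantees that the target is
#' reachable from every intermediate; extra random reactions (one or two
#' substrates, one product) add disjunctive and conjunctive structure on
#' top.  With `n_met <= 12` the candidate pool stays small enough for exact
#' enumeration by [enumerate_structure()].
#'
#' @param n_met number of candidate intermediates (excluding the target).
#' @param n_rxn total reaction count (at least `n_met`).
#' @param reversibility probability that an extra reaction is reversible.
#' @param seed integer seed (the generator calls `set.seed`).
#' @export
make_random <- function(n_met = 10, n_rxn = 20, reversibility = 0, seed = 1) {
  stopifnot(n_met >= 1, n_rxn >= n_met, reversibility >= 0, reversibility <= 1)
  set.seed(seed)
  mets <- c(paste0("M_", seq_len(n_met)), "T")
  stoich <- lapply(seq_len(n_met), function(i) {
    out <- c(-1, 1); names(out) <- c(mets[i], mets[i + 1]); out
  })
  lb <- rep(0, n_met)
  for (j in seq_len(n_rxn - n_met)) {
    ns <- sample(1:2, 1)
    subs <- sample(mets[seq_len(n_met)], ns)
    prod <- sample(setdiff(mets, subs), 1)
    st <- c(rep(-1, ns), 1)
    names(st) <- c(subs, prod)
    stoich <- c(stoich, list(st))
    lb <- c(lb, if (stats::runif(1) < reversibility) -1000 else 0)
  }
  metabolic_network(
    metabolites = tibble::tibble(id = mets),
    reactions = rxn_tbl(paste0("R", seq_along(stoich)), stoich, lb = lb),
    id = paste0("random_", seed)
  )
}

#' Random genome-scale-like network for perturbation experiments
#'
#' A layered network emulating a draft reconstruction: a handful of nutrient
#' metabolites with native uptake/secretion exchanges, internal metabolites
#' each made by one (sometimes two) biosynthetic reactions from lower
#' layers, per-metabolite secretion exchanges, and a biomass reaction
#' consuming `biomass_size` late-layer components into a `BIOMASS`
#' metabolite.  Producer redundancy is deliberately low, as in non-gap-filled
#' draft networks, so minimal-medium FBA is fragile to reaction removal
#' while producibility degrades gradually.
#'
#' The returned network carries the experiment configuration in fields
#' `nutrients`, `biomass_components`, and `objective_reaction`.
#'
#' @param n_rxn total reaction count (exchanges + internal + biomass).
#' @param n_met number of metabolites excluding `BIOMASS`.
#' @param n_nutrients number of base nutrients (the minimal medium).
#' @param biomass_size number of biomass components.
#' @param seed integer seed.
#' @export
make_perturbation_network <- function(n_rxn = 300, n_met = 120,
                                      n_nutrients = 8, biomass_size = 20,
                                      seed = 1) {
  set.seed(seed)
  n_internal_rxn <- n_rxn - n_met - 2 # minus exchanges, EX_BIOMASS, biomass rxn
  stopifnot(n_internal_rxn >= n_met - n_nutrients, biomass_size < n_met / 2)
  mets <- c(paste0("N_", seq_len(n_nutrients)),
            paste0("M_", seq_len(n_met - n_nutrients)))
  all_mets <- c(mets, "BIOMASS")

  stoich <- list(); ids <- character(0)
  # secretion exchanges for every metabolite (uptake is opened by fba media)
  for (i in seq_along(all_mets)) {
    st <- c(-1); names(st) <- all_mets[i]
    stoich <- c(stoich, list(st))
    ids <- c(ids, paste0("EX_", all_mets[i]))
  }
  # one producer per internal metabolite, from strictly lower layers
  internal <- seq(n_nutrients + 1, length(mets))
  for (i in internal) {
    ns <- if (stats::runif(1) < 0.6 || i <= n_nutrients + 1) 1 else 2
    subs <- sample(seq_len(i - 1), min(ns, i - 1))
    st <- c(rep(-1, length(subs)), 1)
    names(st) <- c(mets[subs], mets[i])
    stoich <- c(stoich, list(st))
    ids <- c(ids, paste0("R_", length(ids)))
  }
  # surplus reactions: occasional second producers
  n_extra <- n_internal_rxn - length(internal)
  for (j in seq_len(max(n_extra, 0))) {
    i <- sample(internal, 1)
    ns <- sample(1:2, 1)
    subs <- sample(seq_len(i - 1), min(ns, i - 1))
    st <- c(rep(-1, length(subs)), 1)
    names(st) <- c(mets[subs], mets[i])
    stoich <- c(stoich, list(st))
    ids <- c(ids, paste0("R_", length(ids)))
  }
  # biomass: late-layer components -> BIOMASS
  pool <- mets[seq(floor(length(mets) / 2), length(mets))]
  comps <- sample(pool, biomass_size)
  st <- c(rep(-1, biomass_size), 1)
  names(st) <- c(comps, "BIOMASS")
  stoich <- c(stoich, list(st))
  ids <- c(ids, "BIOMASS_RXN")

  net <- metabolic_network(
    metabolites = tibble::tibble(id = all_mets),
    reactions = rxn_tbl(ids, stoich),
    id = paste0("perturbnet_", seed)
  )
  net$nutrients <- mets[seq_len(n_nutrients)]
  net$biomass_components <- comps
  net$objective_reaction <- "BIOMASS_RXN"
  net
}
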