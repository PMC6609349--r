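# Exact producibility on small candidate pools: exhaustive enumeration of
# feasible input subsets, the minimal-precursor-set antichain, and the exact
# producibility polynomial P_out(p) = sum_k c_k p^k (1-p)^(m-k).

#' Enumerate the precursor structure of a target
#'
#' Decides feasibility for every subset of the candidate pool (with monotone
#' pruning: a superset of a feasible set is feasible without solving an LP)
#' and returns the antichain of minimal precursor sets together with the
#' subset-count coefficients `c_k` = number of feasible subsets of size `k`.
#' This is the brute-force exact counterpart of the sampling estimator, and
#' the oracle used to validate it.
#'
#' @inheritParams feas
#' @param target target metabolite id (or set).
#' @param candidates candidate input metabolites; defaults to all
#'   intracellular metabolites except the target.
#' @param cap refuse pools larger than this (default 20; enumeration is
#'   exponential -- use [calc_pm()] beyond the cap).
#' @return object of class `precursor_structure` with elements `candidates`,
#'   `minimal_sets` (list of character vectors), `poly` (c_0 ... c_m), and
#'   `empty_feasible`.
#' @export
enumerate_structure <- function(prep, target, candidates = NULL, cap = 20,
                                balance = "inequality", threshold = 0.001) {
  stopifnot(inherits(prep, "prepared_metnet"))
  if (is.null(candidates)) candidates <- setdiff(prep$intracellular, target)
  candidates <- setdiff(unique(as.character(candidates)), target)
  m <- length(candidates)
  if (m > cap) {
    stop("candidate pool of size ", m, " exceeds the enumeration cap (", cap,
         "); use the sampling estimator calc_pm() instead")
  }
  nmask <- bitwShiftL(1L, m)
  popcount <- integer(nmask)
  if (m > 0) {
    for (mask in seq_len(nmask - 1L)) {
      popcount[mask + 1L] <- popcount[bitwShiftR(mask, 1L) + 1L] + bitwAnd(mask, 1L)
    }
  }
  feas_mask <- logical(nmask)
  bits <- bitwShiftL(1L, seq_len(m) - 1L)
  mask_set <- function(mask) candidates[bitwAnd(mask, bits) != 0L]

  ord <- order(popcount)
  for (mask in ord - 1L) {
    if (mask > 0L) {
      sub_ok <- FALSE
      for (b in bits) {
        if (bitwAnd(mask, b) && feas_mask[mask - b + 1L]) { sub_ok <- TRUE; break }
      }
      if (sub_ok) { feas_mask[mask + 1L] <- TRUE; next }
    }
    feas_mask[mask + 1L] <- feas(prep, mask_set(mask), target, balance, threshold)
  }

  minimal <- list()
  for (mask in which(feas_mask) - 1L) {
    if (mask == 0L) { minimal <- c(minimal, list(character(0))); next }
    is_min <- TRUE
    for (b in bits) {
      if (bitwAnd(mask, b) && feas_mask[mask - b + 1L]) { is_min <- FALSE; break }
    }
    if (is_min) minimal <- c(minimal, list(mask_set(mask)))
  }
  poly <- vapply(0:m, function(k) sum(feas_mask & popcount == k), numeric(1))
  structure(list(candidates = candidates, minimal_sets = minimal,
                 poly = poly, m = m, empty_feasible = feas_mask[1L]),
            class = "precursor_structure")
}

#' @export
print.precursor_structure <- function(x, ...) {
  cat("<precursor_structure> ", x$m, " candidates, ",
      length(x$minimal_sets), " minimal precursor set(s)\n", sep = "")
  invisible(x)
}

#' Exact producibility at input probability p
#'
#' Evaluates `P_out(p) = sum_k c_k p^k (1-p)^(m-k)` -- the probability that
#' an independent Bernoulli(p) draw over the candidates yields a feasible
#' input set.
#'
#' @param structure an [enumerate_structure()] result.
#' @param p input probability (vectorised).
#' @export
exact_pout <- function(structure, p) {
  stopifnot(inherits(structure, "precursor_structure"))
  if (any(p < 0 | p > 1)) stop("p must lie in [0, 1]")
  m <- structure$m
  ks <- 0:m
  vapply(p, function(pp) sum(structure$poly * pp^ks * (1 - pp)^(m - ks)),
         numeric(1))
}

#' Exact producibility metric
#'
#' PM = `1 - P_in,0.5` where `P_in,0.5` is the unique root of
#' `P_out(p) = 0.5` (unique by monotonicity of `P_out`).  By convention the
#' PM is 0 when no subset is feasible and 1 when the empty set is feasible.
#'
#' @param structure an [enumerate_structure()] result.
#' @param tol root-finding tolerance.
#' @export
analytic_pm <- function(structure, tol = 1e-12) {
  stopifnot(inherits(structure, "precursor_structure"))
  if (length(structure$minimal_sets) == 0) return(0)
  if (structure$empty_feasible) return(1)
  root <- stats::uniroot(function(p) exact_pout(structure, p) - 0.5,
                         c(0, 1), tol = tol, maxiter = 2000)$root
  1 - root
}

#' Pathway completeness scores
#'
#' Given the reactions of a linear biosynthetic pathway ordered from the
#' target backwards, `pathway_sum` counts how many are present in the model
#' and `pathway_length` counts the unbroken run of present reactions
#' starting at the target end (stopping at the first missing one).  A
#' reaction is present when it exists in the model with a nonzero flux
#' range; knockouts (both bounds zero) count as missing.
#'
#' @param net a [metabolic_network()].
#' @param pathway_reactions character vector of reaction ids, ordered from
#'   the reaction adjacent to the target backwards.
#' @return one-row tibble with `pathway_sum` and `pathway_length`.
#' @export
pathway_scores <- function(net, pathway_reactions) {
  stopifnot(inherits(net, "metnet"))
  j <- match(pathway_reactions, net$reactions$id)
  present <- !is.na(j) & !(net$reactions$lb[pmax(j, 1)] == 0 &
                             net$reactions$ub[pmax(j, 1)] == 0)
  present[is.na(j)] <- FALSE
  run <- 0L
  for (ok in present) {
    if (!ok) break
    run <- run + 1L
  }
  tibble::tibble(pathway_sum = sum(present), pathway_length = run)
}
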