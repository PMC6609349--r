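# LP feasibility of target production, and plain FBA.

#' Is a target metabolite (set) producible from a given input set?
#'
#' Builds the flux program `maximize c'v  s.t.  S v = 0, lb <= v <= ub` on the
#' prepared network: import exchanges of `inputs` are opened to `[0, 1000]`,
#' all other imports stay closed.  Under inequality mass balance every export
#' exchange is free (`[0, 1000]`), so intermediates may accumulate or be
#' secreted; under equality balance only the targets' exports are open.  For
#' a single target the export flux is maximized and production is feasible
#' when the optimum exceeds `threshold`; for a target set, production is
#' joint: every target's export must simultaneously reach `threshold`
#' (implemented by splitting each target export into a threshold-capped
#' objective column plus a free relief column, so the optimum equals
#' `length(targets) * threshold` exactly when all targets are co-producible).
#'
#' @param prep a [prepare_model()] result.
#' @param inputs character vector of metabolite ids available as inputs.
#' @param targets character vector of target metabolite ids (usually one).
#' @param balance `"inequality"` (default; production may leave byproducts
#'   behind) or `"equality"` (strict steady state).
#' @param threshold minimum export flux counted as production (default 0.001).
#' @return `TRUE` if the target set is producible, else `FALSE`.
#' @export
feas <- function(prep, inputs, targets,
                 balance = c("inequality", "equality"), threshold = 0.001) {
  stopifnot(inherits(prep, "prepared_metnet"), threshold > 0)
  balance <- match.arg(balance)
  mets <- prep$net$metabolites$id
  unknown <- setdiff(c(inputs, targets), mets)
  if (length(unknown)) stop("unknown metabolite(s): ", paste(unknown, collapse = ", "))
  if (length(targets) == 0) stop("at least one target is required")

  lb <- prep$net$reactions$lb
  ub <- prep$net$reactions$ub
  if (length(inputs)) ub[prep$import_idx[inputs]] <- 1000
  if (balance == "inequality") {
    ub[prep$export_idx] <- 1000
  } else {
    ub[prep$export_idx[targets]] <- 1000
  }

  S <- prep$net$S
  n <- ncol(S)
  tgt_exp <- prep$export_idx[targets]

  if (length(targets) == 1L) {
    obj <- numeric(n)
    obj[tgt_exp] <- 1
    res <- lp_max(S, lb, ub, obj, early_stop = threshold)
    return(res$objval > threshold)
  }

  # joint production: capped objective exports plus free relief exports
  k <- length(targets)
  ub[tgt_exp] <- threshold
  m <- nrow(S)
  rows <- match(targets, mets)
  relief <- Matrix::sparseMatrix(i = rows, j = seq_len(k), x = -1, dims = c(m, k))
  S2 <- cbind(S, relief)
  lb2 <- c(lb, rep(0, k))
  ub2 <- c(ub, rep(1000, k))
  obj <- c(numeric(n), numeric(k))
  obj[tgt_exp] <- 1
  res <- lp_max(S2, lb2, ub2, obj, early_stop = k * threshold - 1e-7 * k)
  res$objval > k * threshold - 1e-6 * k
}

#' Maximal biomass flux by flux balance analysis
#'
#' Standard equality-balance FBA on the raw (unprepared) network: uptake is
#' closed on every native boundary reaction, re-opened (bound 1000) for the
#' `medium` metabolites, and the objective reaction flux is maximized.
#'
#' @param net a [metabolic_network()].
#' @param medium character vector of metabolite ids available for uptake;
#'   each must have a native boundary reaction (a reaction touching only that
#'   metabolite).
#' @param objective_reaction reaction id to maximize (e.g. the biomass
#'   reaction).
#' @return the maximal flux; 0 if the program is infeasible (no growth).
#' @export
fba_biomass <- function(net, medium, objective_reaction) {
  net <- validate_metnet(net)
  j_obj <- match(objective_reaction, net$reactions$id)
  if (is.na(j_obj)) stop("unknown objective reaction: ", objective_reaction)

  nz <- Matrix::colSums(net$S != 0)
  is_exch <- nz == 1
  lb <- net$reactions$lb
  ub <- net$reactions$ub

  # direction of each boundary reaction: sign of its single coefficient
  exch_cols <- which(is_exch)
  exch_met <- character(length(exch_cols))
  exch_sign <- numeric(length(exch_cols))
  for (k in seq_along(exch_cols)) {
    col <- net$S[, exch_cols[k]]
    i <- which(col != 0)
    exch_met[k] <- net$metabolites$id[i]
    exch_sign[k] <- sign(col[i])
  }
  # close all uptake, keep secretion as modelled
  for (k in seq_along(exch_cols)) {
    j <- exch_cols[k]
    if (exch_sign[k] < 0) lb[j] <- max(lb[j], 0) else ub[j] <- min(ub[j], 0)
  }
  # open uptake for the medium
  medium <- unique(medium)
  for (metab in medium) {
    ks <- which(exch_met == metab)
    if (!length(ks)) stop("medium metabolite '", metab, "' has no native boundary reaction")
    for (k in ks) {
      j <- exch_cols[k]
      if (exch_sign[k] < 0) lb[j] <- -1000 else ub[j] <- 1000
    }
  }

  obj <- numeric(ncol(net$S))
  obj[j_obj] <- 1
  res <- tryCatch(lp_max(net$S, lb, ub, obj), error = function(e) NULL)
  if (is.null(res) || res$status == 1) return(0)
  max(res$objval, 0)
}
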