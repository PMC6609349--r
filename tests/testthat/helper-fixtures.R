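# Shared fixtures and independent oracles for the test suite.

# Small literal network: build from a named list of stoichiometries.
net_from_list <- function(stoich, lb = NULL, ub = NULL, genes = list(), id = "toy") {
  mets <- unique(unlist(lapply(stoich, names)))
  n <- length(stoich)
  metabolic_network(
    metabolites = tibble::tibble(id = mets),
    reactions = tibble::tibble(
      id = names(stoich) %||% paste0("R", seq_len(n)),
      stoich = unname(stoich),
      lb = lb %||% rep(0, n),
      ub = ub %||% rep(1000, n)),
    genes = genes, id = id)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# The two-reaction cofactor motif used in the feasibility examples:
# R1: A + NADH -> T + NAD ; R2: P + NAD -> NADH + Q
cofactor_motif <- function() {
  net_from_list(list(
    R1 = c(A = -1, NADH = -1, T = 1, NAD = 1),
    R2 = c(P = -1, NAD = -1, NADH = 1, Q = 1)
  ), id = "cofactor_motif")
}

# Independent LP oracle built on boot::simplex (pure-R, three-phase
# simplex).  Maximizes obj'v subject to S v = 0, lb <= v <= ub, after
# splitting reversible variables so everything is >= 0.
boot_lp_max <- function(S, lb, ub, obj) {
  S <- as.matrix(S)
  neg <- which(lb < 0)
  A <- cbind(S, if (length(neg)) -S[, neg, drop = FALSE])
  ubx <- c(ub, if (length(neg)) -lb[neg])
  a <- c(obj, if (length(neg)) -obj[neg])
  nn <- length(a)
  fit <- tryCatch(
    boot::simplex(a = a,
                  A1 = diag(nn), b1 = ubx,
                  A3 = A, b3 = rep(0, nrow(A)),
                  maxi = TRUE, n.iter = 50 * (nn + nrow(A))),
    error = function(e) NULL)  # boot::simplex can fail on degenerate cases
  if (is.null(fit)) return(NULL)
  list(solved = fit$solved, value = unname(fit$value))
}

# Oracle feasibility decision for a prepared model via boot_lp_max,
# mirroring the single-target LP that feas() builds.
oracle_feas <- function(prep, inputs, target, balance = "inequality",
                        threshold = 0.001) {
  lb <- prep$net$reactions$lb
  ub <- prep$net$reactions$ub
  if (length(inputs)) ub[prep$import_idx[inputs]] <- 1000
  if (balance == "inequality") ub[prep$export_idx] <- 1000
  else ub[prep$export_idx[target]] <- 1000
  obj <- numeric(ncol(prep$net$S))
  obj[prep$export_idx[target]] <- 1
  res <- boot_lp_max(prep$net$S, lb, ub, obj)
  if (is.null(res)) return(NA)
  res$solved == 1 && res$value > threshold
}

# Inclusion-exclusion evaluation of the producibility polynomial from the
# minimal-set antichain: P(feasible at p) = P(union of "contains M_i").
pout_inclusion_exclusion <- function(structure, p) {
  ms <- structure$minimal_sets
  k <- length(ms)
  if (k == 0) return(rep(0, length(p)))
  if (any(lengths(ms) == 0)) return(rep(1, length(p)))
  out <- rep(0, length(p))
  for (mask in 1:(2^k - 1)) {
    sel <- which(bitwAnd(mask, bitwShiftL(1L, seq_len(k) - 1L)) != 0L)
    u <- length(unique(unlist(ms[sel])))
    out <- out + (-1)^(length(sel) + 1) * p^u
  }
  out
}
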