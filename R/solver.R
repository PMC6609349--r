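# Internal interface to the bounded-variable simplex in src/simplex.cpp.

#' Solve a homogeneous linear program
#'
#' Maximizes `obj' v` subject to `S v = 0` and `lb <= v <= ub`.  This is the
#' canonical flux-balance shape: mass balance is homogeneous and the
#' environment (which imports are open, which exchanges are free) enters only
#' through the bounds.
#'
#' @param S constraint matrix (metabolites x reactions), dense or
#'   `Matrix::dgCMatrix`.
#' @param lb,ub,obj numeric vectors, one entry per column of `S`.
#' @param early_stop if finite, return as soon as a feasible point with
#'   objective above this value is found (the simplex is primal feasible
#'   throughout, so the early answer is exact for threshold queries).
#' @return list with `status` (0 optimal/early-stopped, 1 infeasible,
#'   2 unbounded, 3 iteration limit, 4 numerical failure), `objval`, `x`.
#' @keywords internal
#' @noRd
lp_max <- function(S, lb, ub, obj, early_stop = NA_real_) {
  S <- methods::as(methods::as(methods::as(S, "dMatrix"), "generalMatrix"), "CsparseMatrix")
  m <- nrow(S)
  n <- ncol(S)
  stopifnot(length(lb) == n, length(ub) == n, length(obj) == n)
  res <- .simplex_lp_cpp(m, n, S@p, S@i, S@x, as.double(lb), as.double(ub),
                         as.double(obj), early_stop = early_stop)
  if (res$status >= 3) {
    # retry once from scratch with a larger budget before giving up
    res <- .simplex_lp_cpp(m, n, S@p, S@i, S@x, as.double(lb), as.double(ub),
                           as.double(obj), early_stop = early_stop,
                           max_iter = 2000L * (m + n) + 20000L)
    if (res$status >= 3) {
      stop("linear programming failed (status ", res$status, ")")
    }
  }
  res
}
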