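# Estimation of the producibility metric (PM) by Bernoulli sampling of input
# environments and adaptive logistic fitting of the producibility curve.

#' Parameters for the PM sampling estimator
#'
#' Defaults follow the reference analysis conditions: 50 feasibility samples
#' per curve point, next-point jitter of half-width 0.3, convergence when the
#' last 7 PM estimates span at most 0.01, and 10 independent runs.
#'
#' @param samp feasibility samples per producibility-curve point.
#' @param noise half-width of the uniform jitter applied when choosing the
#'   next `P_in` sampling point.
#' @param n_conv number of consecutive PM estimates inspected for
#'   convergence.
#' @param thresh convergence window: the last `n_conv` estimates must span at
#'   most this value (on the PM scale).
#' @param runs number of independent estimator runs averaged into the PM.
#' @param max_points per-run cap on sampled curve points.
#' @return a list of class `pm_params`.
#' @export
pm_params <- function(samp = 50, noise = 0.3, n_conv = 7, thresh = 0.01,
                      runs = 10, max_points = 100) {
  stopifnot(samp >= 1, noise > 0, n_conv >= 1, thresh > 0, thresh < 1,
            runs >= 1, max_points >= n_conv)
  structure(list(samp = as.integer(samp), noise = noise,
                 n_conv = as.integer(n_conv), thresh = thresh,
                 runs = as.integer(runs), max_points = as.integer(max_points)),
            class = "pm_params")
}

#' Specify the random input environment
#'
#' @param candidates metabolite ids eligible to be drawn as inputs.
#' @param p_in Bernoulli input probability: a scalar applied to every
#'   candidate, or a named vector over (a subset of) the candidates.
#' @param fixed_on metabolite ids always present (`P_in = 1`).
#' @param fixed_off metabolite ids never present (`P_in = 0`).
#' @return a list of class `environment_spec`.
#' @export
environment_spec <- function(candidates, p_in = 0.5,
                             fixed_on = character(), fixed_off = character()) {
  stopifnot(all(p_in >= 0), all(p_in <= 1))
  if (length(intersect(fixed_on, fixed_off))) {
    stop("fixed_on and fixed_off overlap: ",
         paste(intersect(fixed_on, fixed_off), collapse = ", "))
  }
  structure(list(candidates = unique(as.character(candidates)), p_in = p_in,
                 fixed_on = unique(as.character(fixed_on)),
                 fixed_off = unique(as.character(fixed_off))),
            class = "environment_spec")
}

#' Draw one random input-metabolite set
#'
#' Each candidate is included by an independent Bernoulli draw; `fixed_on`
#' metabolites are always included and `fixed_off` never.
#'
#' @param env an [environment_spec()].
#' @param p_in optional probability overriding `env$p_in`.
#' @return character vector of input metabolite ids.
#' @export
sample_inputs <- function(env, p_in = NULL) {
  stopifnot(inherits(env, "environment_spec"))
  cands <- setdiff(env$candidates, c(env$fixed_on, env$fixed_off))
  p <- if (is.null(p_in)) env$p_in else p_in
  if (!is.null(names(p))) {
    p <- ifelse(cands %in% names(p), p[cands], 0)
  } else if (length(p) == 1L) {
    p <- rep(p, length(cands))
  }
  stopifnot(length(p) == length(cands))
  union(env$fixed_on, cands[stats::runif(length(cands)) < p])
}

#' Estimate one producibility-curve point
#'
#' Draws `samp` random environments at input probability `p_in` and returns
#' the fraction in which the target is producible.
#'
#' @inheritParams sample_inputs
#' @inheritParams feas
#' @param target target metabolite id (or set, produced jointly).
#' @param p_in input probability for this curve point.
#' @param samp number of sampled environments.
#' @param .feas optional feasibility function `(inputs) -> logical`
#'   (internal; used for witness caching inside [calc_pm()]).
#' @return one-row tibble with `p_in`, `p_out`, `n_samples`, `n_feasible`.
#' @export
estimate_pout <- function(prep, target, env, p_in, samp = 50,
                          balance = "inequality", threshold = 0.001,
                          .feas = NULL) {
  if (is.null(.feas)) {
    .feas <- function(inputs) feas(prep, inputs, target, balance, threshold)
  }
  n_ok <- 0L
  for (s in seq_len(samp)) {
    if (.feas(sample_inputs(env, p_in))) n_ok <- n_ok + 1L
  }
  tibble::tibble(p_in = p_in, p_out = n_ok / samp,
                 n_samples = as.integer(samp), n_feasible = n_ok)
}

# Estimate the half-crossing of the producibility curve from sampled
# points.  Stage 1: weighted least-squares logistic fit
# q ~ 1/(1 + exp(-(p - m)/s)), residuals weighted by q(1-q) (floored) so
# points near the crossing -- where any monotone curve is locally logistic --
# dominate and the saturated tails of asymmetric curves do not drag the
# estimate.  Grid-seeded then refined with Nelder-Mead, which copes with the
# few-point, flat-residual fits early in a run.  Stage 2: the crossing is
# polished by a kernel-local quadratic fit around the current estimate
# (falling back to local linear, then to the logistic value, when the
# window is data-poor); the quadratic term absorbs the curvature of the true
# curve that would otherwise bias a symmetric fit.
fit_logistic_half <- function(p, q) {
  w0 <- q * (1 - q) + 0.01
  sse <- function(m, s) sum(w0 * (q - stats::plogis((p - m) / s))^2)
  m_grid <- seq(-0.05, 1.05, by = 0.02)
  s_grid <- c(0.002, 0.005, 0.01, 0.02, 0.05, 0.1, 0.2, 0.4)
  best <- Inf; m0 <- 0.5; s0 <- 0.1
  for (s in s_grid) {
    v <- vapply(m_grid, sse, numeric(1), s = s)
    i <- which.min(v)
    if (v[i] < best) { best <- v[i]; m0 <- m_grid[i]; s0 <- s }
  }
  fit <- stats::optim(c(m0, log(s0)),
                      function(par) sse(par[1], exp(par[2])),
                      method = "Nelder-Mead",
                      control = list(maxit = 200, reltol = 1e-10))
  m <- min(max(fit$par[1], 0), 1)
  s <- exp(fit$par[2])

  for (it in 1:4) {
    h <- max(1.5 * s, 0.025)
    wk <- w0 * exp(-0.5 * ((p - m) / h)^2)
    use <- wk > 0.05 * max(wk)
    if (sum(use) >= 5 && length(unique(p[use])) >= 4) {
      X <- cbind(1, p - m, (p - m)^2)
      co <- tryCatch(stats::lm.wfit(X, q, wk)$coefficients, error = function(e) NULL)
      if (!is.null(co) && !anyNA(co) && is.finite(co[2]) && co[2] > 0) {
        disc <- co[2]^2 - 4 * co[3] * (co[1] - 0.5)
        dm <- if (is.finite(disc) && disc >= 0 && abs(co[3]) > 1e-8) {
          r1 <- (-co[2] + sqrt(disc)) / (2 * co[3])
          r2 <- (-co[2] - sqrt(disc)) / (2 * co[3])
          if (abs(r1) < abs(r2)) r1 else r2
        } else {
          (0.5 - co[1]) / co[2]
        }
        if (is.finite(dm) && abs(dm) <= 2 * h) {
          m <- min(max(m + dm, 0), 1)
          next
        }
      }
    }
    if (sum(use) >= 3 && length(unique(p[use])) >= 2) {
      W <- sum(wk); pbar <- sum(wk * p) / W; qbar <- sum(wk * q) / W
      vv <- sum(wk * (p - pbar)^2)
      if (vv >= 1e-8) {
        b <- sum(wk * (p - pbar) * (q - qbar)) / vv
        if (is.finite(b) && b > 0) {
          m_new <- pbar + (0.5 - qbar) / b
          if (abs(m_new - m) <= 2 * h) {
            m <- min(max(m_new, 0), 1)
            next
          }
        }
      }
    }
    break
  }
  m
}

# Monotone witness cache around a feasibility predicate: a sampled set that
# contains a known-feasible set is feasible; one contained in a known
# infeasible set is infeasible (feasibility is monotone in the input set).
make_cached_feas <- function(universe, feas_fun, max_witness = 512L) {
  feas_w <- matrix(FALSE, nrow = length(universe), ncol = 0)
  infeas_w <- matrix(FALSE, nrow = length(universe), ncol = 0)
  function(inputs) {
    a <- universe %in% inputs
    if (ncol(feas_w) && any(colSums(feas_w & !a) == 0)) return(TRUE)
    if (ncol(infeas_w) && any(colSums(a & !infeas_w) == 0)) return(FALSE)
    ok <- feas_fun(inputs)
    if (ok) {
      feas_w <<- cbind(feas_w, a)
      if (ncol(feas_w) > max_witness) feas_w <<- feas_w[, -1, drop = FALSE]
    } else {
      infeas_w <<- cbind(infeas_w, a)
      if (ncol(infeas_w) > max_witness) infeas_w <<- infeas_w[, -1, drop = FALSE]
    }
    ok
  }
}

#' Estimate the producibility metric of a target metabolite
#'
#' The PM is `1 - P_in,0.5`, where `P_in,0.5` is the input probability at
#' which the target is producible in half of the sampled environments.  Two
#' boundary shortcuts are evaluated first: if the target is not producible
#' even with every candidate present the PM is 0, and if it is producible
#' with only the `fixed_on` metabolites (no random inputs) the PM is 1; in
#' either case the producibility curve is flat and has no half-crossing.
#' Otherwise each run samples the curve adaptively: starting at
#' `P_in = 0.5`, a logistic curve is refit to all sampled points after each
#' new point, the fitted half-crossing is the current estimate, and the next
#' point is placed at the estimate plus uniform jitter.  A run converges when
#' the last `n_conv` estimates span at most `thresh`; the PM is the mean of
#' the per-run final estimates.
#'
#' @inheritParams feas
#' @param target metabolite id (or a set, produced jointly).
#' @param env an [environment_spec()]; default: all intracellular metabolites
#'   except the target as candidates, none fixed.  The target is always
#'   removed from the candidates and from `fixed_on`.
#' @param params a [pm_params()].
#' @param seed optional integer seed for reproducibility.
#' @return object of class `pm_estimate` with elements `pm`, `p_half`,
#'   `run_values`, `converged`, and `curve` (a tibble of sampled points).
#' @examples
#' net <- make_chain(2)
#' prep <- prepare_model(net)
#' est <- calc_pm(prep, "T", params = pm_params(samp = 20, runs = 2), seed = 1)
#' est$pm   # close to 0.5^(1/2)
#' @export
calc_pm <- function(prep, target, env = NULL, params = pm_params(),
                    balance = "inequality", threshold = 0.001, seed = NULL) {
  stopifnot(inherits(prep, "prepared_metnet"), inherits(params, "pm_params"))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(env)) env <- environment_spec(setdiff(prep$intracellular, target))
  env$candidates <- setdiff(env$candidates, target)
  env$fixed_on <- setdiff(env$fixed_on, target)
  env$fixed_off <- setdiff(env$fixed_off, target)

  cands <- setdiff(env$candidates, env$fixed_off)
  universe <- union(cands, env$fixed_on)
  feas_c <- make_cached_feas(universe, function(inputs) {
    feas(prep, inputs, target, balance, threshold)
  })

  empty_curve <- tibble::tibble(p_in = numeric(), p_out = numeric(),
                                n_samples = integer(), n_feasible = integer(),
                                run = integer())
  finish <- function(pm, p_half, run_values, converged, curve, boundary) {
    structure(list(pm = pm, p_half = p_half, run_values = run_values,
                   converged = converged, curve = curve, target = target,
                   params = params, balance = balance, boundary = boundary),
              class = "pm_estimate")
  }

  if (!feas_c(universe)) {
    return(finish(0, 1, rep(0, params$runs), TRUE, empty_curve, "unproducible"))
  }
  if (feas_c(env$fixed_on)) {
    return(finish(1, 0, rep(1, params$runs), TRUE, empty_curve, "always_producible"))
  }

  curves <- vector("list", params$runs)
  run_values <- numeric(params$runs)
  conv <- logical(params$runs)
  for (r in seq_len(params$runs)) {
    p_pts <- numeric(0); q_pts <- numeric(0); nf <- integer(0)
    ests <- numeric(0)
    p_cur <- 0.5
    repeat {
      pt <- estimate_pout(prep, target, env, p_cur, params$samp,
                          balance, threshold, .feas = feas_c)
      p_pts <- c(p_pts, pt$p_in); q_pts <- c(q_pts, pt$p_out)
      nf <- c(nf, pt$n_feasible)
      p_hat <- fit_logistic_half(p_pts, q_pts)
      ests <- c(ests, 1 - p_hat)
      if (length(ests) >= params$n_conv) {
        win <- tail(ests, params$n_conv)
        if (max(win) - min(win) <= params$thresh) { conv[r] <- TRUE; break }
      }
      if (length(ests) >= params$max_points) {
        warning("PM run did not converge within max_points; reporting last estimate")
        break
      }
      p_cur <- min(max(p_hat + stats::runif(1, -params$noise, params$noise), 0), 1)
    }
    run_values[r] <- ests[length(ests)]
    curves[[r]] <- tibble::tibble(p_in = p_pts, p_out = q_pts,
                                  n_samples = params$samp, n_feasible = nf,
                                  run = r)
  }
  finish(mean(run_values), 1 - mean(run_values), run_values, all(conv),
         dplyr::bind_rows(curves), "none")
}

#' @export
print.pm_estimate <- function(x, ...) {
  cat("<pm_estimate> target:", paste(x$target, collapse = "+"),
      " PM =", format(x$pm, digits = 4),
      if (!x$converged) "(not converged)" else "", "\n")
  invisible(x)
}

#' PM values for a set of models and targets
#'
#' Runs [calc_pm()] for every (model, target) pair.  Each job draws its own
#' seed deterministically from the master seed, so results are reproducible
#' and independent of evaluation order.  Targets absent from a model, and
#' jobs that error, are recorded as `NA`.
#'
#' @param models list of [prepare_model()] results (or `metnet` objects,
#'   prepared on the fly); names become organism ids.
#' @param targets character vector of target metabolite ids.
#' @param env optional [environment_spec()] applied to every job.
#' @param params a [pm_params()].
#' @param seed master seed.
#' @return numeric matrix (organisms x metabolites) of PM values, class
#'   `pm_matrix`.
#' @export
pm_matrix <- function(models, targets, env = NULL, params = pm_params(),
                      seed = 1L) {
  models <- lapply(models, function(mdl) {
    if (inherits(mdl, "metnet")) prepare_model(mdl) else mdl
  })
  ids <- names(models)
  if (is.null(ids)) ids <- vapply(models, function(p) p$net$id, character(1))
  out <- matrix(NA_real_, nrow = length(models), ncol = length(targets),
                dimnames = list(ids, targets))
  job <- 0L
  for (i in seq_along(models)) {
    mets <- models[[i]]$net$metabolites$id
    for (j in seq_along(targets)) {
      job <- job + 1L
      if (!(targets[j] %in% mets)) next
      job_seed <- as.integer((as.double(seed) + 1009 * job) %% 2147483647)
      out[i, j] <- tryCatch(
        calc_pm(models[[i]], targets[j], env = env, params = params,
                seed = job_seed)$pm,
        error = function(e) NA_real_)
    }
  }
  class(out) <- c("pm_matrix", class(out))
  out
}

#' PM gain in an enriched environment
#'
#' Recomputes the PM of each target with a set of metabolites fixed always
#' present (`P_in = 1`) and reports the change against the baseline random
#' environment.  A target is never fixed on for its own computation.
#'
#' @inheritParams calc_pm
#' @param targets character vector of targets to evaluate.
#' @param fixed_on metabolites fixed present in the enriched environment.
#' @return tibble with `target`, `pm_baseline`, `pm_enriched`, `delta_pm`.
#' @export
enriched_delta <- function(prep, targets, fixed_on, env = NULL,
                           params = pm_params(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(env)) env <- environment_spec(prep$intracellular)
  rows <- lapply(targets, function(tg) {
    base_env <- env
    enr_env <- env
    enr_env$fixed_on <- setdiff(union(enr_env$fixed_on, fixed_on), tg)
    b <- calc_pm(prep, tg, env = base_env, params = params)
    e <- calc_pm(prep, tg, env = enr_env, params = params)
    tibble::tibble(target = tg, pm_baseline = b$pm, pm_enriched = e$pm,
                   delta_pm = e$pm - b$pm)
  })
  dplyr::bind_rows(rows)
}
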