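# The sampling PM estimator: environment sampling, curve points, boundary
# shortcuts, agreement with exact values, and reproducibility.

test_that("sample_inputs draws Bernoulli environments honouring fixed sets", {
  env <- environment_spec(paste0("m", 1:5), fixed_on = "on1", fixed_off = "m5")
  expect_setequal(sample_inputs(env, p_in = 1), c("on1", paste0("m", 1:4)))
  expect_equal(sample_inputs(env, p_in = 0), "on1")
  env2 <- environment_spec(paste0("m", 1:10))
  set.seed(1)
  sizes <- replicate(10000, length(sample_inputs(env2, p_in = 0.5)))
  # mean within 3 binomial sigma of np
  expect_lt(abs(mean(sizes) - 5), 3 * sqrt(10 * 0.25) / sqrt(10000))
  expect_error(environment_spec("a", fixed_on = "x", fixed_off = "x"), "overlap")
})

test_that("estimate_pout returns exact Bernoulli frequencies", {
  prep <- prepare_model(make_chain(1))
  env <- environment_spec("M_1")
  set.seed(2)
  pt <- estimate_pout(prep, "T", env, p_in = 1, samp = 10)
  expect_equal(pt$p_out, 1)
  pt0 <- estimate_pout(prep, "M_1", environment_spec(character(0)), p_in = 0.5, samp = 5)
  expect_equal(pt0$p_out, 0)  # nothing produces M_1
  # single precursor: p_out is Binomial(samp, 0.5)/samp; check 99% interval
  pt5 <- estimate_pout(prep, "T", env, p_in = 0.5, samp = 50)
  expect_gte(pt5$p_out, qbinom(0.005, 50, 0.5) / 50)
  expect_lte(pt5$p_out, qbinom(0.995, 50, 0.5) / 50)
  expect_equal(pt5$n_feasible / pt5$n_samples, pt5$p_out)
})

test_that("calc_pm boundary shortcuts classify degenerate targets", {
  prep <- prepare_model(make_fan_in(2))
  z <- calc_pm(prep, "P_1", seed = 3)  # no reaction produces P_1
  expect_equal(z$pm, 0)
  expect_true(z$converged)
  expect_equal(z$boundary, "unproducible")
  expect_equal(length(z$run_values), pm_params()$runs)

  o <- calc_pm(prep, "T",
               env = environment_spec(c("P_1", "P_2"), fixed_on = "P_1"),
               seed = 3)
  expect_equal(o$pm, 1)
  expect_equal(o$boundary, "always_producible")
})

test_that("calc_pm matches closed-form PMs on elementary motifs", {
  est1 <- calc_pm(prepare_model(make_chain(1)), "T", seed = 11)
  expect_lt(abs(est1$pm - 0.5), 0.03)
  est2 <- calc_pm(prepare_model(make_fan_in(2)), "T", seed = 12)
  expect_lt(abs(est2$pm - 0.5^(1 / 2)), 0.03)
  estc <- calc_pm(prepare_model(make_conjunctive(2)), "T", seed = 13)
  expect_lt(abs(estc$pm - (1 - 0.5^(1 / 2))), 0.03)
  expect_true(all(est2$run_values >= 0 & est2$run_values <= 1))
  expect_equal(est2$pm, mean(est2$run_values))
  expect_equal(est2$p_half, 1 - est2$pm)
})

test_that("run-to-run dispersion shrinks with more samples per point", {
  prep <- prepare_model(make_chain(2))
  sds <- vapply(c(10, 200), function(samp) {
    est <- calc_pm(prep, "T", params = pm_params(samp = samp, runs = 6), seed = 21)
    sd(est$run_values)
  }, numeric(1))
  expect_lt(sds[2], sds[1])
})

test_that("pm_matrix is deterministic, shaped, and NA-safe", {
  models <- list(org_a = prepare_model(make_chain(2)),
                 org_b = prepare_model(make_fan_in(3)))
  pars <- pm_params(samp = 10, runs = 2, n_conv = 3)
  m1 <- pm_matrix(models, c("T", "M_1", "ghost"), params = pars, seed = 5)
  m2 <- pm_matrix(models, c("T", "M_1", "ghost"), params = pars, seed = 5)
  expect_identical(m1, m2)
  expect_equal(dim(m1), c(2, 3))
  expect_equal(rownames(m1), c("org_a", "org_b"))
  expect_true(all(is.na(m1[, "ghost"])))
  expect_true(is.na(m1["org_b", "M_1"]))   # fan-in has no M_1
  expect_true(all(m1[, "T"] > 0))
  m3 <- pm_matrix(models, c("T", "M_1", "ghost"), params = pars, seed = 6)
  expect_false(identical(m1, m3))
})

test_that("enriched environments raise the PM only through reachable precursors", {
  prep <- prepare_model(make_chain(1))
  pars <- pm_params(samp = 30, runs = 4)
  d <- enriched_delta(prep, "T", fixed_on = "M_1", params = pars, seed = 8)
  expect_equal(d$pm_enriched, 1)  # the sole precursor is always present
  expect_lt(abs(d$delta_pm - 0.5), 0.03)

  # fixing a metabolite outside the precursor cone leaves the PM unchanged
  net <- net_from_list(list(R1 = c(A = -1, T = 1), R2 = c(U = -1, V = 1)))
  prep2 <- prepare_model(net)
  d2 <- enriched_delta(prep2, "T", fixed_on = "V", params = pars, seed = 9)
  expect_lt(abs(d2$delta_pm), 0.05)
  # and the target itself is never fixed on
  d3 <- enriched_delta(prep2, "T", fixed_on = "T", params = pars, seed = 10)
  expect_lt(d3$pm_enriched, 1)
})

test_that("estimated producibility curves are monotone within noise", {
  prep <- prepare_model(make_chain(3))
  env <- environment_spec(paste0("M_", 1:3))
  set.seed(42)
  ps <- seq(0.1, 0.9, by = 0.2)
  qs <- vapply(ps, function(p) estimate_pout(prep, "T", env, p, samp = 200)$p_out,
               numeric(1))
  expect_true(all(diff(qs) > -0.1))
  exact <- 1 - (1 - ps)^3
  expect_lt(max(abs(qs - exact)), 0.1)
})
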