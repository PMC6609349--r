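# LP feasibility of target production: worked motifs, balance modes,
# monotonicity, and agreement with an independent LP implementation.

test_that("a linear chain is producible exactly from its upstream intermediates", {
  prep <- prepare_model(make_chain(2))
  expect_true(feas(prep, "M_1", "T"))
  expect_true(feas(prep, "M_2", "T"))
  expect_false(feas(prep, character(0), "T"))
  expect_false(feas(prep, "T", "M_1"))  # chain is irreversible
  expect_error(feas(prep, "nope", "T"), "unknown metabolite")
})

test_that("cofactors can be recycled at steady state instead of supplied", {
  prep <- prepare_model(cofactor_motif())
  expect_true(feas(prep, c("A", "P"), "T"))     # NADH/NAD cycles via R2
  expect_false(feas(prep, "A", "T"))
  expect_true(feas(prep, c("A", "NADH"), "T"))  # one-shot reduction
  expect_false(feas(prep, c("A", "NAD"), "T"))
})

test_that("joint multi-target production requires every target", {
  net <- net_from_list(list(
    R1 = c(A = -1, X = 1),
    R2 = c(B = -1, Y = 1)
  ))
  prep <- prepare_model(net)
  expect_true(feas(prep, c("A", "B"), c("X", "Y")))
  expect_false(feas(prep, "A", c("X", "Y")))  # Y not producible from A alone
  expect_true(feas(prep, "A", "X"))
})

test_that("equality-balance feasibility implies inequality-balance feasibility", {
  for (s in 1:5) {
    net <- make_random(n_met = 8, n_rxn = 16, reversibility = 0.2, seed = 30 + s)
    prep <- prepare_model(net)
    set.seed(s)
    for (q in 1:10) {
      inputs <- sample(paste0("M_", 1:8), sample(0:6, 1))
      eq <- feas(prep, inputs, "T", balance = "equality")
      ineq <- feas(prep, inputs, "T", balance = "inequality")
      if (eq) expect_true(ineq)
    }
  }
})

test_that("feasibility is monotone in the input set", {
  set.seed(55)
  checks <- 0
  for (s in 1:5) {
    prep <- prepare_model(make_random(n_met = 10, n_rxn = 22, seed = 60 + s))
    cands <- paste0("M_", 1:10)
    for (q in 1:20) {
      a <- sample(cands, sample(0:8, 1))
      b <- union(a, sample(cands, sample(0:8, 1)))
      if (feas(prep, a, "T")) {
        expect_true(feas(prep, b, "T"))
        checks <- checks + 1
      }
    }
  }
  expect_gt(checks, 10)
})

test_that("feas decisions match an independent simplex implementation", {
  set.seed(77)
  for (s in 1:4) {
    net <- make_random(n_met = 7, n_rxn = 14, reversibility = 0.2, seed = 80 + s)
    prep <- prepare_model(net)
    for (q in 1:8) {
      inputs <- sample(paste0("M_", 1:7), sample(0:5, 1))
      ref <- oracle_feas(prep, inputs, "T")
      if (is.na(ref)) next  # independent solver choked on this instance
      expect_equal(feas(prep, inputs, "T"), ref,
                   info = paste("seed", s, "query", q))
    }
  }
})

test_that("FBA biomass flux responds to the medium", {
  net <- net_from_list(list(
    EX_A = c(A = -1),
    EX_B = c(B = -1),
    EX_BIO = c(BIO = -1),
    R1 = c(A = -1, P = 1),
    R2 = c(B = -1, Q = 1),
    BIOMASS = c(P = -1, Q = -1, BIO = 1)
  ), id = "fba_toy")
  expect_gt(fba_biomass(net, c("A", "B"), "BIOMASS"), 0)
  expect_equal(fba_biomass(net, character(0), "BIOMASS"), 0)
  expect_equal(fba_biomass(net, "A", "BIOMASS"), 0)  # Q missing
  expect_error(fba_biomass(net, "P", "BIOMASS"), "no native boundary")
  expect_error(fba_biomass(net, "A", "nope"), "unknown objective")
})

test_that("relaxing the medium never lowers the FBA optimum", {
  net <- make_perturbation_network(n_rxn = 150, n_met = 60, seed = 9)
  f_min <- fba_biomass(net, net$nutrients, "BIOMASS_RXN")
  f_com <- fba_biomass(net, pmnet:::native_exchange_metabolites(net), "BIOMASS_RXN")
  expect_gt(f_min, 0)
  expect_gte(f_com, f_min - 1e-6)
})
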