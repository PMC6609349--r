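# Reaction-removal robustness and gene knockouts.

test_that("remove_random_reactions removes exactly n non-protected reactions", {
  net <- make_random(8, 20, seed = 1)
  expect_identical(remove_random_reactions(net, 0), net)
  set.seed(1)
  r <- remove_random_reactions(net, 5, protected = "R1")
  expect_equal(nrow(r$reactions), 15)
  expect_true("R1" %in% r$reactions$id)
  expect_equal(ncol(r$S), 15)
  # all removable removed -> only protected remain
  r2 <- remove_random_reactions(net, 19, protected = "R1")
  expect_equal(r2$reactions$id, "R1")
  expect_error(remove_random_reactions(net, 20, protected = "R1"), "only")
  # reproducible under a fixed seed
  set.seed(9); a <- remove_random_reactions(net, 7)
  set.seed(9); b <- remove_random_reactions(net, 7)
  expect_identical(a$reactions$id, b$reactions$id)
})

test_that("gene knockouts zero bounds of all associated reactions only", {
  net <- net_from_list(
    list(R1 = c(A = -1, B = 1), R2 = c(A = -1, C = 1), R3 = c(B = -1, C = 1)),
    genes = list(g1 = "R1", g2 = c("R2", "R3")))
  k1 <- knockout_genes(net, "g1")
  expect_equal(k1$reactions$ub[k1$reactions$id == "R1"], 0)
  expect_equal(k1$reactions$ub[k1$reactions$id == "R2"], 1000)
  # a gene spanning two reactions (isoenzyme context) silences both
  k2 <- knockout_genes(net, "g2")
  expect_true(all(k2$reactions$ub[k2$reactions$id %in% c("R2", "R3")] == 0))
  expect_identical(knockout_genes(net, character(0)), net)
  expect_error(knockout_genes(net, "ghost"), "unknown gene")
  # stoichiometry and reaction count untouched
  expect_equal(as.matrix(k2$S), as.matrix(net$S))
  expect_equal(nrow(k2$reactions), 3)
})

test_that("losing the final biomass-assembly step kills FBA but not producibility", {
  net <- net_from_list(list(
    EX_A = c(A = -1),
    EX_BIO = c(BIO = -1),
    R1 = c(A = -1, B = 1),
    R2 = c(B = -1, C = 1),
    ASSEMBLE = c(C = -1, BIO = 1)
  ), id = "assembly_toy")
  expect_gt(fba_biomass(net, "A", "ASSEMBLE"), 0)
  crippled <- net
  j <- match("ASSEMBLE", crippled$reactions$id)
  crippled$reactions$lb[j] <- 0; crippled$reactions$ub[j] <- 0
  expect_equal(fba_biomass(crippled, "A", "ASSEMBLE"), 0)
  # upstream producibility of the components persists
  prep <- prepare_model(crippled)
  est <- calc_pm(prep, "C", params = pm_params(samp = 20, runs = 3), seed = 2)
  expect_gt(est$pm, 0)
})

test_that("perturbation study reports sane per-replicate accuracies", {
  net <- make_perturbation_network(n_rxn = 120, n_met = 48, n_nutrients = 5,
                                   biomass_size = 8, seed = 21)
  pars <- pm_params(samp = 8, runs = 2, n_conv = 3, thresh = 0.05)
  res <- suppressMessages(
    perturbation_study(net, levels = c(0, 3), reps = 2, params = pars, seed = 31))
  expect_s3_class(res, "perturbation_study")
  expect_equal(nrow(res), 4)
  num <- c("fba_accuracy_minimal", "fba_accuracy_complete", "pm_accuracy")
  for (cn in num) {
    expect_true(all(res[[cn]] >= 0 & res[[cn]] <= 1))
  }
  lvl0 <- res[res$level == 0, ]
  expect_true(all(lvl0$fba_accuracy_minimal == 1))
  expect_true(all(lvl0$fba_accuracy_complete == 1))
  expect_true(all(lvl0$fba_biomass_ok_minimal))
  expect_true(all(lvl0$pm_accuracy > 0.5))  # only PM sampling noise at level 0
  s <- summarize_perturbation(res)
  expect_equal(s$level, c(0, 3))
  expect_equal(s$n, c(2L, 2L))
  # oversized levels are dropped with a message
  expect_message(
    perturbation_study(net, levels = c(2, 10000), reps = 1, params = pars, seed = 7),
    "dropping removal level")
})
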