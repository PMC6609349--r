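# Network container, format round trips, compartment classification, and
# model preparation.

test_that("network validation rejects malformed inputs", {
  expect_error(metabolic_network(
    tibble::tibble(id = c("A", "A")),
    tibble::tibble(id = "R1", stoich = list(c(A = -1)))),
    "duplicate metabolite")
  expect_error(net_from_list(list(R1 = c(A = -1, B = 1), R1 = c(B = -1, A = 1))),
               "duplicate reaction")
  expect_error(net_from_list(list(R1 = c(A = -1, Z = 1))), NA) # Z declared implicitly
  expect_error(metabolic_network(
    tibble::tibble(id = "A"),
    tibble::tibble(id = "R1", stoich = list(c(B = 1)))),
    "undeclared")
  expect_error(net_from_list(list(R1 = c(A = -1, B = 1)), lb = 5, ub = 1), "lb > ub")
})

test_that("SBML and COBRA JSON round trips preserve the network", {
  net <- make_chain(3)
  for (fmt in c("sbml", "cobra_json")) {
    path <- tempfile(fileext = if (fmt == "sbml") ".xml" else ".json")
    write_network(net, path, fmt)
    back <- read_network(path, fmt)
    expect_equal(back$metabolites$id, net$metabolites$id)
    expect_equal(back$reactions$id, net$reactions$id)
    expect_equal(back$reactions$lb, net$reactions$lb)
    expect_equal(back$reactions$ub, net$reactions$ub)
    expect_equal(as.matrix(back$S), as.matrix(net$S))
    expect_equal(back$genes[order(names(back$genes))],
                 net$genes[order(names(net$genes))])
  }
})

test_that("the same model read from SBML and JSON is identical", {
  net <- make_random(n_met = 6, n_rxn = 12, reversibility = 0.3, seed = 4)
  p1 <- tempfile(fileext = ".xml"); p2 <- tempfile(fileext = ".json")
  write_network(net, p1); write_network(net, p2)
  a <- read_network(p1); b <- read_network(p2)
  expect_equal(as.matrix(a$S), as.matrix(b$S))
  expect_equal(a$reactions$lb, b$reactions$lb)
  expect_equal(a$metabolites, b$metabolites)
})

test_that("format errors are reported with context", {
  bad <- tempfile(fileext = ".xml")
  writeLines("<sbml><model></model></sbml>", bad)
  expect_error(read_network(bad, "sbml"), "no species")
  bad2 <- tempfile(fileext = ".json")
  jsonlite::write_json(list(foo = 1), bad2)
  expect_error(read_network(bad2, "cobra_json"), "COBRA JSON")
  expect_error(read_network(tempfile(), "sbml"), "not found")
})

test_that("compartment classification follows naming conventions", {
  net <- metabolic_network(
    tibble::tibble(id = c("glc__D_c", "glc__D_e"), compartment = c("", "")),
    tibble::tibble(id = "R1", stoich = list(c(glc__D_e = -1, glc__D_c = 1))))
  cc <- classify_compartments(net)
  expect_equal(cc$intracellular, "glc__D_c")
  expect_equal(cc$extracellular, "glc__D_e")

  kb <- metabolic_network(
    tibble::tibble(id = c("cpd00027_c0", "cpd00027_e0"), compartment = c("c0", "e0")),
    tibble::tibble(id = "R1", stoich = list(c(cpd00027_e0 = -1, cpd00027_c0 = 1))))
  cc <- classify_compartments(kb)
  expect_equal(cc$intracellular, "cpd00027_c0")
  expect_equal(cc$extracellular, "cpd00027_e0")

  toy <- make_chain(2)
  cc <- classify_compartments(toy)
  expect_equal(length(cc$extracellular), 0)
  expect_setequal(cc$intracellular, toy$metabolites$id)
})

test_that("prepare_model silences native boundary/maintenance and adds 2m exchanges", {
  net <- net_from_list(list(
    EX_A = c(A = -1),
    R1 = c(A = -1, B = 1),
    ATPM_like = c(B = -1, A = 1)
  ), id = "boundary_toy")
  net$reactions$name[3] <- "ATP maintenance"
  prep <- prepare_model(net)
  expect_setequal(prep$disabled_native, c("EX_A", "ATPM_like"))
  j <- match(c("EX_A", "ATPM_like"), prep$net$reactions$id)
  expect_true(all(prep$net$reactions$lb[j] == 0 & prep$net$reactions$ub[j] == 0))
  m <- nrow(net$metabolites)
  expect_equal(nrow(prep$net$reactions), nrow(net$reactions) + 2 * m)
  # each metabolite has one +1 import and one -1 export
  for (metab in net$metabolites$id) {
    imp <- reaction_stoich(prep$net, prep$import[[metab]])
    expp <- reaction_stoich(prep$net, prep$export[[metab]])
    expect_equal(imp, stats::setNames(1, metab))
    expect_equal(expp, stats::setNames(-1, metab))
  }
  # base stoichiometry untouched
  expect_equal(as.matrix(prep$net$S[, seq_len(prep$n_base)]), as.matrix(net$S))
})

test_that("PM matrix TSV round trips exactly", {
  m <- matrix(c(0, 1, 1 / 3, 0.7071067811865476), 2, 2,
              dimnames = list(c("org1", "org2"), c("met1", "met2")))
  class(m) <- c("pm_matrix", class(m))
  path <- tempfile(fileext = ".tsv")
  write_pm_matrix(m, path)
  expect_equal(length(readLines(path)), 3) # header + 2 organisms
  back <- read_pm_matrix(path)
  expect_identical(unclass(back), unclass(m))

  ragged <- tempfile(fileext = ".tsv")
  writeLines(c("organism\ta\tb", "o1\t1\t2", "o2\t3"), ragged)
  expect_error(read_pm_matrix(ragged), "malformed")
})
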