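# Inter-organism metrics: PM distance/complementarity, seed sets, reaction
# distances, genus collapsing.

test_that("pm_distance is an L1 metric on aligned vectors", {
  expect_equal(pm_distance(c(1, 0, 0.5), c(1, 0, 0.5)), 0)
  expect_equal(pm_distance(c(1, 0, 0.5), c(0, 0, 0.5)), 1)
  set.seed(1)
  a <- runif(10); b <- runif(10)
  expect_equal(pm_distance(a, b), pm_distance(b, a))
  expect_error(pm_distance(1:3, 1:4), "length")
  # missing entries are dropped pairwise
  expect_equal(pm_distance(c(1, NA, 0.5), c(0, 1, 0.5)), 1)
})

test_that("pm_complementarity follows its defining formula and bounds", {
  expect_equal(pm_complementarity(c(1, 1), c(0, 1)), 0.5)
  expect_equal(pm_complementarity(c(0.3, 0.8), c(0.3, 0.8)), 0)
  expect_equal(pm_complementarity(c(0.4, 0.6), c(0, 0)), 1)
  expect_true(is.na(pm_complementarity(c(0, 0), c(1, 1))))
  set.seed(2)
  for (i in 1:20) {
    a <- runif(6); b <- runif(6)
    v <- pm_complementarity(a, b)
    expect_gte(v, 0); expect_lte(v, 1)
    # raising b elementwise can never increase how much a supplements it
    b2 <- pmin(b + runif(6, 0, 0.5), 1)
    expect_lte(pm_complementarity(a, b2), v + 1e-12)
  }
})

test_that("seed sets are the source components of the metabolite graph", {
  chain <- net_from_list(list(R1 = c(A = -1, B = 1), R2 = c(B = -1, C = 1)))
  s <- seed_set(chain)
  expect_equal(s$seed_score, c(A = 1))

  # reversible 2-cycle feeding C: the source SCC {A, B} scores 1/2 each
  cyc <- net_from_list(list(R1 = c(A = -1, B = 1), R2 = c(B = -1, C = 1)),
                       lb = c(-1000, 0))
  s2 <- seed_set(cyc)
  expect_equal(s2$seed_score[order(names(s2$seed_score))], c(A = 0.5, B = 0.5))

  # isolated metabolite keeps its own source component (score 1)
  iso <- metabolic_network(
    tibble::tibble(id = c("A", "B", "LONER")),
    tibble::tibble(id = "R1", stoich = list(c(A = -1, B = 1)), lb = 0, ub = 1000))
  s3 <- seed_set(iso)
  expect_equal(s3$seed_score[["LONER"]], 1)
  expect_equal(s3$seed_score[["A"]], 1)
  expect_false("B" %in% names(s3$seed_score))

  # every zero-in-degree metabolite is a seed with score 1
  fan <- net_from_list(list(R1 = c(A = -1, B = 1), R2 = c(C = -1, B = 1)))
  sf <- seed_set(fan)
  expect_equal(sf$seed_score[order(names(sf$seed_score))], c(A = 1, C = 1))
})

test_that("seed distance, competition and complementarity match their definitions", {
  mk <- function(seeds, mets, id) {
    structure(list(organism = id,
                   seed_score = seeds,
                   network_metabolites = mets), class = "seed_set")
  }
  a <- mk(c(x = 1, y = 1), c("x", "y", "z"), "a")
  b <- mk(c(y = 1), c("x", "y"), "b")
  expect_equal(seed_distance(a, a), 0)
  expect_equal(seed_distance(mk(c(x = 1), "x", "s1"), mk(c(w = 1), "w", "s2")), 2)
  expect_equal(seed_distance(a, b), seed_distance(b, a))

  expect_equal(seed_competition(a, b), 0.5)          # of {x, y} only y is b's seed
  expect_equal(seed_competition(a, a), 1)
  expect_equal(seed_competition(mk(c(x = 1), "x", "s"), mk(c(w = 1), "w", "t")), 0)
  expect_true(is.na(seed_competition(mk(stats::setNames(numeric(0), character(0)), "x", "e"), a)))

  # x is interior to b's network? x is in b's network and not b's seed -> counts
  expect_equal(seed_complementarity(a, b), 0.5)
  b2 <- mk(c(q = 1), c("q"), "b2")                   # lacks all of a's seeds
  expect_equal(seed_complementarity(a, b2), 0)
  b3 <- mk(c(q = 1), c("q", "x", "y"), "b3")         # all of a's seeds interior
  expect_equal(seed_complementarity(a, b3), 1)
})

test_that("reaction distance and Jaccard agree with set arithmetic", {
  expect_equal(reaction_distance(c("r1", "r2"), c("r1", "r2")), 0)
  expect_equal(reaction_jaccard(c("r1", "r2"), c("r1", "r2")), 0)
  expect_equal(reaction_distance(c("a", "b"), c("c", "d", "e")), 5)
  expect_equal(reaction_jaccard(c("a", "b"), c("c", "d", "e")), 1)
  expect_equal(reaction_distance("a", c("a", "b")), 1)
  expect_equal(reaction_jaccard("a", c("a", "b")), 0.5)
  expect_true(is.na(reaction_jaccard(logical(0), logical(0))))
})

test_that("genus collapsing averages over distinct-organism pairs", {
  m <- matrix(c(0, 1, 2, 3,
                1, 0, 4, 5,
                2, 4, 0, 6,
                3, 5, 6, 0), 4, 4, byrow = TRUE,
              dimnames = list(paste0("o", 1:4), paste0("o", 1:4)))
  gen <- c(o1 = "G1", o2 = "G1", o3 = "G2", o4 = "G2")
  g <- collapse_to_genus(m, gen)
  expect_equal(g["G1", "G2"], mean(c(2, 3, 4, 5)))
  expect_equal(g["G1", "G1"], 1)   # the single distinct pair within G1
  expect_equal(g["G2", "G2"], 6)

  # singleton genera: matrix unchanged up to relabeling; self-pairs missing
  gs <- collapse_to_genus(m, c(o1 = "A", o2 = "B", o3 = "C", o4 = "D"))
  expect_true(all(is.na(diag(gs))))
  expect_equal(gs["A", "B"], m["o1", "o2"])

  # invariant under organism permutation
  perm <- c(3, 1, 4, 2)
  g2 <- collapse_to_genus(m[perm, perm], gen)
  expect_equal(g2, g)
  expect_error(collapse_to_genus(m, gen[1:3]), "no genus")
})

test_that("pm_pairwise builds full metric matrices from a PM matrix", {
  pm <- matrix(c(1, 0.5, 0, 1, 0.2, 0.4), nrow = 2, byrow = TRUE,
               dimnames = list(c("a", "b"), c("m1", "m2", "m3")))
  d <- pm_pairwise(pm, "distance")
  expect_equal(diag(d), c(a = 0, b = 0))
  expect_equal(d["a", "b"], sum(abs(pm["a", ] - pm["b", ])))
  cmpl <- pm_pairwise(pm, "complementarity")
  expect_equal(cmpl["a", "b"], pm_complementarity(pm["a", ], pm["b", ]))
  expect_equal(cmpl["a", "a"], 0)
})
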