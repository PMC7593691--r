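# Unrooted contribution functions, pairwise cost identities, and the
# top-split dynamic program.

TOP_ABC <- list("a", c("b", "c"))

test_that("star contribution functions on the worked stars", {
  s_abc <- classifyStar(list("a", "b", "c"), TOP_ABC)        # S2, |A| = 1
  s_dup <- classifyStar(list(c("b", "c"), "a", "a"), TOP_ABC) # S2 degenerate
  s4 <- classifyStar(list(c("a", "d"), c("b", "e"), c("c", "f")),
                     list(c("a", "b", "c"), c("d", "e", "f")))

  # lambda-hat
  expect_equal(hatLambda("D", s_dup, "a"), 1)
  expect_equal(hatLambda("D", s_abc, "a"), 0)
  expect_equal(hatLambda("DC", s_abc, "b"), 1)
  expect_equal(hatLambda("DC", s_dup, "a"), 0)    # degenerate branch
  expect_equal(hatLambda("DL", s_dup, "a"), 3)    # 0 + omega_DL * 1

  # gamma-hat
  expect_equal(hatGamma("DC", s_abc, list("b", "c")), 1)
  expect_equal(hatGamma("DC", s_dup, list("b", "c")), 0)
  expect_equal(hatGamma("D", s4, list("a", c("b", "c"))), 0)
  expect_equal(hatGamma("D", s_abc, list("b", "c")), 0)

  # sigma
  expect_equal(sigmaContrib("D", s_abc), -1)
  expect_equal(sigmaContrib("D", s_dup), 0)
  expect_equal(sigmaContrib("D", s4), 1)
  expect_equal(sigmaContrib("DC", s_abc), 0)
  expect_equal(sigmaContrib("DL", s_abc), -3)

  # B/C swap invariance under re-classification
  s_abc2 <- classifyStar(list("a", "c", "b"), TOP_ABC)
  expect_equal(hatGamma("DC", s_abc2, list("b", "c")),
               hatGamma("DC", s_abc, list("b", "c")))
})

test_that("per-tree epsilon constants", {
  U <- "(a,b,c);"
  expect_equal(epsilonConst("D", U), 1)
  expect_equal(epsilonConst("DC", U), 0)
  expect_equal(epsilonConst("L", U), 1 - 5 + 2)    # rooted |V_G| = 5
  expect_equal(epsilonConst("DL", U), 1 - 5 + 3)
  expect_equal(epsilonConst("DL", "((a,a),b,c);"), 1 - 7 + 3)
})

test_that("pairwise unrooted costs on the worked examples", {
  S <- "(a,(b,c));"
  expect_equal(unrootedCost("(a,b,c);", S, ALL_COSTS),
               c(D = 0, DC = 4, L = 0, DL = 0))
  expect_equal(unname(unrootedCost("((a,a),b,c);", S, "D")), 1)
})

test_that("the contribution identity equals the rooting minimum on random pairs", {
  set.seed(71)
  for (i in 1:120) {
    n <- pick1(3:8)
    taxa <- paste0("t", seq_len(n))
    G <- rand_unrooted_gene(taxa, extra = pick1(0:3))
    S <- rand_species(taxa)
    expect_equal(unrootedCost(G, S, ALL_COSTS),
                 bruteUnrootedCost(G, S, ALL_COSTS))
  }
})

test_that("rooting splits and the general/minus pairwise costs", {
  S4 <- parseNewick("((a,(b,c)),d);", "species")
  expect_equal(rootingSplit(c("a", "b", "c"), S4),
               list("a", c("b", "c")))
  # complete gene tree: rooting split is the top-split, general == plateau
  expect_equal(rootingSplit(c("a", "b", "c", "d"), S4),
               list(c("a", "b", "c"), "d"))
  G <- "(a,b,c);"
  expect_equal(unrootedCost(G, S4, ALL_COSTS, method = "general"),
               bruteUnrootedCost(G, S4, ALL_COSTS))
  expect_equal(unrootedCost("(a,b,(c,d));", S4, ALL_COSTS, method = "general"),
               unrootedCost("(a,b,(c,d));", S4, ALL_COSTS))
  # minus method restricts the species tree first
  expect_equal(unname(unrootedCost(G, S4, "D", method = "minus")), 0)
  expect_equal(writeNewick(restrictSpeciesTree("((a,b),(c,d));",
                                               c("a", "c", "d"))),
               "((c,d),a);")

  set.seed(81)
  for (i in 1:40) {
    ns <- pick1(4:7)
    staxa <- paste0("t", seq_len(ns))
    S <- rand_species(staxa)
    gtaxa <- sample(staxa, pick1(3:(ns - 1L)))
    G <- rand_unrooted_gene(gtaxa, extra = pick1(0:2))
    expect_equal(unrootedCost(G, S, ALL_COSTS, method = "general"),
                 bruteUnrootedCost(G, S, ALL_COSTS))
    expect_equal(unrootedCost(G, S, ALL_COSTS, method = "minus"),
                 bruteUnrootedCost(G, restrictSpeciesTree(S, G$labels),
                                   ALL_COSTS))
  }
})

test_that("the unrooted solver on the 3-taxon star and additivity", {
  sol <- solveUnrooted("(a,b,c);", cost = "D", want = "all_trees")
  expect_equal(sol$cost, 0)
  expect_equal(sol$optima_count, 3L)     # all three species trees optimal
  expect_true("((b,c),a);" %in% sol$trees)
  expect_equal(solveUnrooted("(a,b,c);", cost = "DC")$cost, 4)

  set.seed(91)
  ds <- makeDataset(5, 2, 7)
  one <- solveUnrooted(ds$trees, "DL", want = "one_tree")
  two <- solveUnrooted(c(ds$trees, ds$trees), "DL", want = "one_tree")
  expect_equal(two$cost, 2 * one$cost)
  expect_equal(two$tree, one$tree)
  # the collection objective is additive
  S <- parseNewick(one$tree, "species")
  expect_equal(collectionCost(c(ds$trees, ds$trees), S, "DL"),
               2 * collectionCost(ds$trees, S, "DL"))
})

test_that("the solver matches the species-tree/rooting double brute force", {
  set.seed(92)
  for (i in 1:10) {
    n <- pick1(3:5)
    k <- pick1(1:3)
    ds <- makeDataset(n, k, seed = 1000L + i)
    brute <- double_brute_median(ds$trees, ds$labels)
    for (m in ALL_COSTS) {
      sol <- solveUnrooted(ds$trees, m, want = "all_trees")
      expect_equal(sol$cost, unname(brute[[m]]))
      # every reported optimum re-evaluates to the reported cost
      for (tr in sol$trees) {
        expect_equal(collectionCost(ds$trees, parseNewick(tr, "species"), m),
                     sol$cost)
      }
    }
  }
})

test_that("DC conventions, table occupancy and validation errors", {
  ds <- makeDataset(4, 3, 5)
  paper <- solveUnrooted(ds$trees, "DC")$cost
  std <- solveUnrooted(ds$trees, "DC", dc_convention = "standard")$cost
  expect_equal(std, paper + sum(vapply(ds$trees, function(G)
    1 - (2 * G$n_leaves - 1), numeric(1))))

  for (n in 4:5) {
    ds <- makeDataset(n, 2, n)
    k <- seq_len(n - 1L)
    expect_equal(solveUnrooted(ds$trees, "D")$upsilon_entries,
                 sum(choose(n, k) * (2^k - 1)))
  }

  expect_error(solveUnrooted(list(parseNewick("(a,b,c);", "unrooted"),
                                  parseNewick("(a,b,d);", "unrooted")),
                             "D"), "incomplete")
  expect_error(solveUnrooted(makeDataset(6, 1, 1)$trees, "D", max_taxa = 5L),
               "max_taxa")
})
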