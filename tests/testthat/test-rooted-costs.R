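# Rooted reconciliation costs, the lca-mapping, and the per-split
# contribution identity.

test_that("worked examples: all four costs via the lca-mapping", {
  S <- "(a,(b,c));"
  expect_equal(rootedCost("((a,b),c);", S, ALL_COSTS),
               c(D = 1, DC = 5, L = 3, DL = 4))
  expect_equal(rootedCost("(a,(b,c));", S, ALL_COSTS),
               c(D = 0, DC = 4, L = 0, DL = 0))
  expect_equal(rootedCost("((a,b),(a,c));", S, ALL_COSTS),
               c(D = 1, DC = 6, L = 2, DL = 3))
  # standard deep-coalescence convention differs by 1 - |V_G|
  expect_equal(unname(rootedCost("(a,(b,c));", S, "DC",
                                 dc_convention = "standard")), 0)
  expect_equal(unname(rootedCost("((a,b),c);", S, "DC",
                                 dc_convention = "standard")), 1)
})

test_that("lca-mapping satisfies both defining clauses", {
  S <- parseNewick("(a,(b,c));", "species")
  M <- lcaMapping("((a,b),c);", S)
  gi <- attr(M, "gene_index")
  # the (a,b) gene node and the gene root both map to the species root
  expect_equal(M[1L], 1L)
  expect_equal(M[gi$kid1[1L]], 1L)
  # congruent trees: the mapping preserves clusters
  M2 <- lcaMapping("(a,(b,c));", S)
  g2 <- attr(M2, "gene_index")
  Sx <- urmedian:::species_index(S)
  expect_equal(Sx$idx$clus[M2], g2$clus)
  expect_error(lcaMapping("((a,b),z);", S), "absent")
  # duplication nodes: only the root of ((a,b),(a,c)) vs (a,(b,c))... all
  # three internal nodes map to the root but only the root is a duplication
  expect_equal(duplicationNodes("((a,b),(a,c));", S), 1L)
})

test_that("leaf and split contribution indicators", {
  expect_equal(lambdaContrib("DC", list("a", "b"), "a"), 1)
  expect_equal(lambdaContrib("DC", list("a", "b"), "c",
                             taxa = c("a", "b", "c")), 0)
  expect_equal(lambdaContrib("D", list("a", "b"), "a"), 0)
  # duplicate-label split: both sides are the set {a}
  expect_equal(lambdaContrib("D", list("a", "a"), "a"), 1)
  expect_equal(lambdaContrib("DC", list("a", "a"), "a"), 0)

  expect_equal(gammaContrib("D", list(c("a", "b"), "c"), list("a", c("b", "c"))), 1)
  expect_equal(gammaContrib("D", list("a", "b"), list("a", c("b", "c"))), 0)
  expect_equal(gammaContrib("DC", list(c("a", "b"), "c"), list("b", "c"),
                            taxa = c("a", "b", "c")), 1)
  expect_equal(gammaContrib("DC", list("a", c("b", "c")), list("b", "c"),
                            taxa = c("a", "b", "c")), 1)
  # linear combinations for loss / duplication-loss
  expect_equal(lambdaContrib("L", list("a", "a"), "a"), 2)
  expect_equal(lambdaContrib("DL", list("a", "a"), "a"), 3)
})

test_that("contribution identity equals the direct cost (worked examples)", {
  S <- parseNewick("(a,(b,c));", "species")
  expect_equal(costViaContrib("((a,b),c);", S, "D"), 1)
  expect_equal(costViaContrib("((a,b),c);", S, "DC"), 5)
  expect_equal(costViaContrib("(a,(b,c));", S, "D"), 0)
  expect_error(costViaContrib("((a,b),c);",
                              parseNewick("((a,(b,c)),d);", "species"), "D"),
               "incomplete")
})

test_that("contribution identity, cost identities and invariances hold on random pairs", {
  set.seed(101)
  for (i in 1:120) {
    n <- pick1(3:8)
    taxa <- paste0("t", seq_len(n))
    extra <- pick1(0:3)
    labs <- c(taxa, taxa[sample.int(n, extra, replace = TRUE)])
    G <- yuleTree(length(labs), labs)
    S <- rand_species(taxa)
    cc <- rootedCost(G, S, ALL_COSTS)
    # exact integer identities
    expect_equal(cc[["L"]], cc[["DC"]] + 2 * cc[["D"]] - G$n_nodes + 1)
    expect_equal(cc[["DL"]], cc[["D"]] + cc[["L"]])
    expect_true(all(cc >= 0))
    # per-split identity against the direct costs, all four models
    for (m in ALL_COSTS) {
      expect_equal(costViaContrib(G, S, m), unname(cc[[m]]))
    }
    # child-order invariance: costs are unchanged under re-parsing the
    # canonically sorted form
    expect_equal(rootedCost(parseNewick(writeNewick(G), "rooted"),
                            parseNewick(writeNewick(S), "species"),
                            ALL_COSTS), cc)
  }
  # congruent trees cost zero under every model (standard DC convention)
  set.seed(102)
  for (i in 1:10) {
    S <- rand_species(paste0("t", seq_len(pick1(3:7))))
    G <- parseNewick(writeNewick(S), "rooted")
    expect_equal(unname(rootedCost(G, S, c("D", "L", "DL"))), c(0, 0, 0))
    expect_equal(unname(rootedCost(G, S, "DC", dc_convention = "standard")), 0)
  }
})
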