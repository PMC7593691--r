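# Star types, symmetric edges, plateau, and the plateau/forest
# decomposition of unrooted gene trees.

TOP_ABC <- list("a", c("b", "c"))

test_that("simple-set predicate", {
  expect_true(isSimple(c("b", "c"), TOP_ABC))
  expect_false(isSimple(c("a", "c"), TOP_ABC))
  expect_true(isSimple("a", TOP_ABC))
  expect_true(isSimple(character(0), TOP_ABC))
  expect_error(isSimple("z", TOP_ABC), "universe")
})

test_that("star classification: the five types and the forced S2 role", {
  s <- classifyStar(list("a", "b", "c"), TOP_ABC)
  expect_equal(s$type, "S2")
  expect_equal(s$A, "a")
  expect_false(s$degenerate)

  s2 <- classifyStar(list(c("b", "c"), "a", "a"), TOP_ABC)
  expect_equal(s2$type, "S2")
  expect_equal(s2$A, c("b", "c"))
  expect_true(s2$degenerate)

  s4 <- classifyStar(list(c("a", "d"), c("b", "e"), c("c", "f")),
                     list(c("a", "b", "c"), c("d", "e", "f")))
  expect_equal(s4$type, "S4")

  # component order never matters
  s2b <- classifyStar(list("a", c("b", "c"), "a"), TOP_ABC)
  expect_equal(s2b$type, "S2")
  expect_equal(s2b$A, c("b", "c"))
})

test_that("star census counts", {
  expect_length(allStars("(a,b,c);"), 1L)
  expect_length(allStars("((a,b),c,d);"), 2L)
  set.seed(41)
  for (i in 1:5) {
    n <- pick1(4:9)
    U <- rand_unrooted_gene(paste0("t", seq_len(n)), extra = pick1(0:2))
    expect_length(allStars(U), U$n_leaves - 2L)
  }
})

test_that("symmetric edges and plateau on the worked examples", {
  U3 <- parseNewick("(a,b,c);", "unrooted")
  ea <- U3$edges[U3$node_labels[U3$edges[, 1]] %in% "a" |
                   U3$node_labels[U3$edges[, 2]] %in% "a", , drop = FALSE]
  eb <- U3$edges[U3$node_labels[U3$edges[, 1]] %in% "b" |
                   U3$node_labels[U3$edges[, 2]] %in% "b", , drop = FALSE]
  expect_true(isSymmetricEdge(U3, ea[1, ], TOP_ABC))
  expect_false(isSymmetricEdge(U3, eb[1, ], TOP_ABC))
  expect_equal(plateauEdges(U3, TOP_ABC), ea)

  # 4-leaf tree with cherries (a,c) and (b,d): only the middle edge is
  # symmetric under top ab|cd
  U4 <- parseNewick("((a,c),b,d);", "unrooted")
  top4 <- list(c("a", "b"), c("c", "d"))
  pe4 <- plateauEdges(U4, top4)
  expect_equal(nrow(pe4), 1L)
  expect_true(all(is.na(U4$node_labels[pe4])))  # both endpoints internal

  # three cherries (a,d) (b,e) (c,f) joined at one node, top abc|def:
  # exactly the 3 internal edges
  U6 <- parseNewick("((a,d),(b,e),(c,f));", "unrooted")
  pe6 <- plateauEdges(U6, list(c("a", "b", "c"), c("d", "e", "f")))
  expect_equal(nrow(pe6), 3L)
  expect_true(all(is.na(U6$node_labels[pe6])))
})

test_that("decomposition types and forests on the worked examples", {
  # plateau is the single edge toward a; removing it leaves the leaf a and
  # the (b,c) subtree rooted at the star center
  d1 <- decomposeTree("(a,b,c);", TOP_ABC)
  expect_equal(d1$utype, "U1")
  expect_setequal(unlist(d1$forest), c("a;", "(b,c);"))

  d2 <- decomposeTree("((a,a),b,c);", TOP_ABC)
  expect_equal(d2$utype, "U2")
  expect_equal(sort(d2$star_types), c("S2", "S2"))

  d3 <- decomposeTree("((a,c),b,d);", list(c("a", "b"), c("c", "d")))
  expect_equal(d3$utype, "U3")
  expect_equal(sort(d3$star_types), c("S3", "S3"))

  d4 <- decomposeTree("((a,d),(b,e),(c,f));",
                      list(c("a", "b", "c"), c("d", "e", "f")))
  expect_equal(d4$utype, "U4")
  expect_true("S4" %in% d4$star_types)
})

test_that("plateau theory holds exhaustively at small scale", {
  set.seed(51)
  for (i in 1:40) {
    n <- pick1(3:6)
    taxa <- paste0("t", seq_len(n))
    G <- rand_unrooted_gene(taxa, extra = pick1(0:2))
    S <- rand_species(taxa)
    top <- top_split_of(S)
    pe <- optimalRootingEdges(G, S)
    pk <- edge_keys(pe)
    expect_gt(nrow(pe), 0L)
    # plateau is connected: every edge within BFS distance 0
    expect_true(all(edge_distance_to(G, pe)[edge_keys(G$edges) %in% pk] == 0L))
    costs <- per_edge_costs(G, S)
    for (m in ALL_COSTS) {
      mn <- min(costs[, m])
      # every plateau rooting attains the minimum...
      expect_true(all(costs[edge_keys(G$edges) %in% pk, m] == mn))
      # ...and cost is non-decreasing along every path leaving the plateau
      dist <- edge_distance_to(G, pe)
      for (r in seq_len(nrow(G$edges))) {
        if (dist[r] == 0L) next
        touch <- which(G$edges[, 1L] %in% G$edges[r, ] |
                         G$edges[, 2L] %in% G$edges[r, ])
        nearer <- touch[dist[touch] == dist[r] - 1L]
        expect_true(all(costs[r, m] >= costs[nearer, m]))
      }
    }
    # the plateau equals the DL argmin edge set exactly
    am <- attr(bruteUnrootedCost(G, S, "DL"), "argmin_edges")
    expect_setequal(edge_keys(am), pk)
    # top-split sufficiency: any species tree sharing the top-split yields
    # the same plateau
    expect_equal(optimalRootingEdges(G, rand_species_with_top(top)), pe)
  }
})

test_that("forest subtrees map below the species root or to it without duplication", {
  set.seed(61)
  for (i in 1:25) {
    n <- pick1(3:6)
    taxa <- paste0("t", seq_len(n))
    G <- rand_unrooted_gene(taxa, extra = pick1(0:2))
    S <- rand_species(taxa)
    dec <- decomposeTree(G, top_split_of(S))
    for (f in dec$forest) {
      if (!grepl("(", f, fixed = TRUE)) next      # single-leaf subtree
      phy <- ape::read.tree(text = f)
      Mt <- map_of_labels(S, phy$tip.label)
      kids <- phy$edge[phy$edge[, 1] == length(phy$tip.label) + 1L, 2]
      Mk <- vapply(kids, function(k) map_of_labels(S, tips_under(phy, k)),
                   integer(1))
      if (Mt == 1L) {
        expect_false(any(Mk == Mt))    # at the root only as a non-duplication
      } else {
        expect_gt(Mt, 1L)
      }
    }
  }
})
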