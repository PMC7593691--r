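# Seeded random-instance generators and small cross-checking utilities used
# across the suite.  All fixtures are built in code; seeds are set inside
# each test block.

pick1 <- function(v) v[sample.int(length(v), 1L)]

# random unrooted gene tree on `taxa` plus `extra` duplicated labels
rand_unrooted_gene <- function(taxa, extra = 0L) {
  labs <- c(taxa, taxa[sample.int(length(taxa), extra, replace = TRUE)])
  unrootTree(yuleTree(length(labs), labs))
}

# random species tree on `taxa` (Yule topology, unique labels)
rand_species <- function(taxa) {
  parseNewick(writeNewick(yuleTree(length(taxa), taxa)), "species")
}

ALL_COSTS <- c("D", "DC", "L", "DL")

edge_keys <- function(m) paste(m[, 1L], m[, 2L])

# minimum total unrooted cost over every rooted species tree, per cost:
# the full double brute force (species-tree enumeration x rooting
# enumeration per gene tree)
double_brute_median <- function(trees, labels) {
  cands <- enumerateSpeciesTrees(labels)
  totals <- vapply(cands, function(S) {
    Reduce(`+`, lapply(trees, function(G) bruteUnrootedCost(G, S, ALL_COSTS)))
  }, numeric(4))
  apply(totals, 1L, min)
}

# per-edge rooted costs of every rooting of G against S, one row per edge of
# G$edges, columns D/DC/L/DL
per_edge_costs <- function(G, S) {
  t(vapply(enumerateRootings(G), function(r)
    rootedCost(r$tree, S, ALL_COSTS), numeric(4)))
}

# random rooted topology on an arbitrary label multiset, as a bare Newick
# fragment without the trailing semicolon (sizes below the package's 3-label
# floor are allowed here)
rand_newick_fragment <- function(labels) {
  labels <- sample(labels)
  while (length(labels) > 1L) {
    i <- sample.int(length(labels), 2L)
    merged <- paste0("(", labels[i[1L]], ",", labels[i[2L]], ")")
    labels <- c(labels[-i], merged)
  }
  labels
}

# random species tree sharing a given top-split
rand_species_with_top <- function(top) {
  parseNewick(paste0("(", rand_newick_fragment(top[[1]]), ",",
                     rand_newick_fragment(top[[2]]), ");"), "species")
}

top_split_of <- function(S) rootingSplit(S$labels, S)

# image under the lca-mapping of a set of leaf labels (node id in S)
map_of_labels <- function(S, labs) {
  labs <- unique(labs)
  cur <- lca(S, labs[1L], labs[1L])
  for (x in labs[-1L]) cur <- lca(S, cur, x)
  cur
}

tips_under <- function(phy, node) {
  nt <- length(phy$tip.label)
  if (node <= nt) return(phy$tip.label[node])
  ape::extract.clade(phy, node)$tip.label
}

# breadth-first distance of every edge of G to the plateau edge set, in the
# line graph (adjacent edges share a node)
edge_distance_to <- function(G, plateau) {
  ek <- edge_keys(G$edges)
  dist <- ifelse(ek %in% edge_keys(plateau), 0L, NA_integer_)
  repeat {
    changed <- FALSE
    for (i in seq_along(ek)) {
      if (!is.na(dist[i])) next
      touch <- G$edges[, 1L] %in% G$edges[i, ] | G$edges[, 2L] %in% G$edges[i, ]
      d <- dist[touch]
      if (any(!is.na(d))) {
        dist[i] <- min(d, na.rm = TRUE) + 1L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  dist
}
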