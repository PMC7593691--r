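# Rooted reconciliation costs via the lca-mapping, and the per-split
# contribution functions that re-express each cost as a sum over species-tree
# nodes (the identity driving the rooted dynamic program).
#
# Cost conventions.  DC here is the "path" convention: the sum over gene-tree
# sibling pairs of (number of nodes on the species path between their images
# minus one).  The standard deep-coalescence cost differs by the constant
# 1 - |V_G|.  Loss and duplication-loss are the exact integer identities
# L = DC + 2 D - |V_G| + 1 and DL = D + L, with |V_G| the rooted node count.

COSTS <- c("D", "DC", "L", "DL")
cost_omega <- c(D = NA_real_, DC = NA_real_, L = 2, DL = 3)

check_cost <- function(cost) {
  cost <- match.arg(cost, COSTS)
  cost
}

#' Least common ancestor mapping of a gene tree into a species tree
#'
#' Maps every gene-tree node to the most recent species-tree node that could
#' have contained it: leaves map to the species leaf with the same label,
#' internal nodes to the lca of their children's images.
#'
#' @param G a `rooted_gene_tree` (or Newick string); `L(G)` must be a subset
#'   of `L(S)`.
#' @param S a `species_tree` (or Newick string).
#' @return integer vector over the preorder node ids of `G` giving the
#'   preorder node id in `S` of each image, with the gene-tree node table in
#'   attribute `"gene_index"`.
#' @export
lcaMapping <- function(G, S) {
  G <- as_rooted(G)
  S <- species_index(S)
  if (!all(G$labels %in% S$labels)) {
    stop("gene leaf labels absent from the species tree: ",
         paste(setdiff(G$labels, S$labels), collapse = ", "))
  }
  gi <- index_nested(G$root, S$labels)
  leafmap <- integer(S$idx$n)
  leafmap[S$idx$leaves] <- S$idx$leaves
  names_leaf <- S$idx$label
  M <- integer(gi$n)
  for (v in rev(seq_len(gi$n))) {            # reverse preorder: children first
    if (gi$kid1[v] == 0L) {
      M[v] <- which(!is.na(names_leaf) & names_leaf == gi$label[v])
    } else {
      M[v] <- lca_ids(S$idx, M[gi$kid1[v]], M[gi$kid2[v]])
    }
  }
  attr(M, "gene_index") <- gi
  M
}

# all four costs in one pass; returns c(D, DC, L, DL) with paper-convention DC
rc_costs <- function(G, S) {
  G <- as_rooted(G)
  S <- species_index(S)
  M <- lcaMapping(G, S)
  gi <- attr(M, "gene_index")
  idx <- S$idx
  internal <- which(gi$kid1 != 0L)
  D <- 0L
  DC <- 0L
  for (v in internal) {
    a <- M[gi$kid1[v]]
    b <- M[gi$kid2[v]]
    m <- M[v]
    if (m == a || m == b) D <- D + 1L
    DC <- DC + idx$depth[a] + idx$depth[b] - 2L * idx$depth[m]
  }
  VG <- gi$n
  L <- DC + 2L * D - VG + 1L
  c(D = D, DC = DC, L = L, DL = D + L)
}

#' Rooted reconciliation cost between a gene tree and a species tree
#'
#' @param G a `rooted_gene_tree` (duplicate labels permitted).
#' @param S a `species_tree` with `L(G)` contained in `L(S)`.
#' @param cost one of `"D"` (duplication), `"DC"` (deep coalescence), `"L"`
#'   (loss), `"DL"` (duplication-loss); may be a vector to get several at
#'   once.
#' @param dc_convention `"paper"` (path-count convention, the solver's
#'   internal currency) or `"standard"` (differs by `1 - |V_G|`); applies to
#'   `"DC"` only.
#' @return named numeric vector of the requested costs.
#' @examples
#' rootedCost("((a,b),c);", "(a,(b,c));", c("D", "DC", "L", "DL"))
#' @export
rootedCost <- function(G, S, cost = "DL",
                       dc_convention = c("paper", "standard")) {
  dc_convention <- match.arg(dc_convention)
  cost <- vapply(cost, check_cost, character(1), USE.NAMES = FALSE)
  all4 <- rc_costs(G, S)
  out <- all4[cost]
  if (dc_convention == "standard" && "DC" %in% cost) {
    G <- as_rooted(G)
    out["DC"] <- out["DC"] + 1 - G$n_nodes
  }
  out
}

#' Duplication nodes of a reconciliation (debug accessor)
#'
#' @inheritParams lcaMapping
#' @return preorder node ids in `G` of the gene duplications.
#' @export
duplicationNodes <- function(G, S) {
  M <- lcaMapping(G, S)
  gi <- attr(M, "gene_index")
  internal <- which(gi$kid1 != 0L)
  internal[vapply(internal, function(v)
    M[v] == M[gi$kid1[v]] || M[v] == M[gi$kid2[v]], logical(1))]
}

## ------------------------------------------- per-split contribution terms ---

# vectorized indicators on split masks; s is a singleton species mask
lam_D_vec <- function(A, B, s) as.numeric(bitwOr(A, B) == s)
lam_DC_vec <- function(A, B, s) as.numeric((A == s) + (B == s) == 1L)

gam_D_vec <- function(A1, A2, X, Y) {
  U <- bitwOr(X, Y)
  inU <- mask_subset(bitwOr(A1, A2), U)
  fits <- function(P) mask_subset(P, X) | mask_subset(P, Y)
  as.numeric(inU & !(fits(A1) & fits(A2)))
}

gam_DC_vec <- function(A1, A2, X, Y) {
  U <- bitwOr(X, Y)
  in1 <- mask_subset(A1, U)
  in2 <- mask_subset(A2, U)
  # the side-avoidance clause (some X_j not containing A_i) holds for any
  # nonempty A_i since X and Y are disjoint
  as.numeric((in1 & !in2) | (in2 & !in1))
}

lam_vec <- function(cost, A, B, s) {
  switch(cost,
         D = lam_D_vec(A, B, s),
         DC = lam_DC_vec(A, B, s),
         lam_DC_vec(A, B, s) + cost_omega[[cost]] * lam_D_vec(A, B, s))
}

gam_vec <- function(cost, A, B, X, Y) {
  switch(cost,
         D = gam_D_vec(A, B, X, Y),
         DC = gam_DC_vec(A, B, X, Y),
         gam_DC_vec(A, B, X, Y) + cost_omega[[cost]] * gam_D_vec(A, B, X, Y))
}

split_masks <- function(split, taxa) {
  vapply(split, function(side) mask_of(side, taxa), integer(1))
}

#' Cost contribution of a gene split to a species leaf
#'
#' The leaf-level indicator behind the rooted dynamic program: for D (and its
#' DL component) the split contributes iff both sides carry only species `s`;
#' for DC iff exactly one side equals `{s}`.  L and DL are the linear
#' combinations `DC + 2 D` and `DC + 3 D`.
#'
#' @param cost cost model.
#' @param split a gene split: list of two character vectors of labels.
#' @param s a single species label.
#' @param taxa taxon universe (defaults to the labels present).
#' @return numeric contribution.
#' @export
lambdaContrib <- function(cost, split, s, taxa = NULL) {
  cost <- check_cost(cost)
  if (is.null(taxa)) taxa <- taxonUniverse(c(unlist(split), s))
  m <- split_masks(split, taxa)
  lam_vec(cost, m[1L], m[2L], mask_of(s, taxa))
}

#' Cost contribution of a gene split to an internal species split
#'
#' @inheritParams lambdaContrib
#' @param x a species split: list of two character vectors of labels.
#' @return numeric contribution.
#' @export
gammaContrib <- function(cost, split, x, taxa = NULL) {
  cost <- check_cost(cost)
  if (is.null(taxa)) taxa <- taxonUniverse(c(unlist(split), unlist(x)))
  q <- split_masks(split, taxa)
  s <- split_masks(x, taxa)
  gam_vec(cost, q[1L], q[2L], s[1L], s[2L])
}

species_splits <- function(S) {
  idx <- S$idx
  internal <- which(idx$kid1 != 0L)
  list(X = idx$clus[idx$kid1[internal]],
       Y = idx$clus[idx$kid2[internal]],
       is_top = internal == 1L)
}

#' Total rooted cost via per-split contribution sums
#'
#' Computes `c(Q, S)` as the sum over species of leaf contributions plus the
#' sum over the species tree's internal splits of split contributions (plus,
#' for L/DL, the per-tree constant `1 - |V_G|`).  Exactly equals the direct
#' lca-mapping cost; used as the identity behind the rooted DP and verified
#' against it in the test-suite.
#'
#' @param Q a rooted gene tree or list of them; every tree must be complete
#'   (`L(G) = L(S)`).
#' @param S a `species_tree`.
#' @param cost cost model.
#' @return total cost (numeric scalar).
#' @export
costViaContrib <- function(Q, S, cost = "DL") {
  cost <- check_cost(cost)
  Q <- as_collection(Q, as_rooted)
  S <- species_index(S)
  for (G in Q) {
    if (!setequal(G$labels, S$labels)) {
      stop("incomplete gene tree (L(G) != L(S)); use unrootedCost(..., ",
           "method = \"general\") for incomplete trees")
    }
  }
  r <- rootedSplits(Q, taxa = S$labels)
  total <- 0
  for (i in seq_along(S$labels)) {
    total <- total + sum(lam_vec(cost, r$A, r$B, bitwShiftL(1L, i - 1L)))
  }
  sp <- species_splits(S)
  for (j in seq_along(sp$X)) {
    total <- total + sum(gam_vec(cost, r$A, r$B, sp$X[j], sp$Y[j]))
  }
  if (cost %in% c("L", "DL")) {
    total <- total + sum(vapply(Q, function(G) 1 - G$n_nodes, numeric(1)))
  }
  total
}
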