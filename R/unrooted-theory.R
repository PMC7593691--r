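# Structural theory of unrooted reconciliation.  Relative to the top-split
# of a species tree, a species set is "simple" if it fits inside one side of
# the split.  Every internal node of an unrooted gene tree determines a star
# (the label sets of its three neighbor subtrees); the pattern of simplicity
# over a star's components and their complements yields five disjoint star
# types.  Symmetric edges (both sides simple, or both non-simple) plus the
# asymmetric edge of every S5 star form the plateau: exactly the edges whose
# rootings minimize every reconciliation cost.

top_masks <- function(top, taxa = NULL) {
  if (is.null(taxa)) taxa <- taxonUniverse(unlist(top))
  Tm <- mask_of(top[[1L]], taxa)
  Tp <- mask_of(top[[2L]], taxa)
  if (bitwAnd(Tm, Tp) != 0L) stop("top-split sides must be disjoint")
  if (Tm == 0L || Tp == 0L) stop("top-split sides must be nonempty")
  list(taxa = taxa, T = Tm, Tp = Tp)
}

top_of_species_tree <- function(S) {
  S <- species_index(S)
  idx <- S$idx
  list(labels_of(idx$clus[idx$kid1[1L]], S$labels),
       labels_of(idx$clus[idx$kid2[1L]], S$labels))
}

#' Is a species set simple relative to a top-split?
#'
#' @param Z character vector of species labels (may be empty).
#' @param top a top-split: list of two disjoint character vectors of labels.
#' @return `TRUE` iff `Z` is contained in one side of the split.
#' @export
isSimple <- function(Z, top) {
  tm <- top_masks(top)
  z <- mask_of(Z, tm$taxa)
  mask_subset(z, tm$T) || mask_subset(z, tm$Tp)
}

# Vectorized star classification over component masks.  Returns the role
# assignment (A, B, C with B <= C), the star type 1..5, the complement
# Ab = B|C, and the degenerate flag (S2 with B = C a singleton).
classify_masks <- function(c1, c2, c3, Tm, Tp) {
  m <- length(c1)
  sT1 <- mask_subset(c1, Tm); sP1 <- mask_subset(c1, Tp)
  sT2 <- mask_subset(c2, Tm); sP2 <- mask_subset(c2, Tp)
  sT3 <- mask_subset(c3, Tm); sP3 <- mask_subset(c3, Tp)
  s1 <- sT1 | sP1; s2 <- sT2 | sP2; s3 <- sT3 | sP3
  ns <- s1 + s2 + s3
  Aidx <- rep(1L, m)
  i2 <- ns == 2L                      # the unique non-simple component
  Aidx[i2] <- ((!s1) * 1L + (!s2) * 2L + (!s3) * 3L)[i2]
  i1 <- ns == 1L                      # the unique simple component
  Aidx[i1] <- (s1 * 1L + s2 * 2L + s3 * 3L)[i1]
  i3 <- ns == 3L                      # the component alone on its side
  cnt <- sT1 + sT2 + sT3
  pickT <- (sT1 * 1L + sT2 * 2L + sT3 * 3L)
  pickP <- ((!sT1) * 1L + (!sT2) * 2L + (!sT3) * 3L)
  Aidx[i3 & cnt == 1L] <- pickT[i3 & cnt == 1L]
  Aidx[i3 & cnt == 2L] <- pickP[i3 & cnt == 2L]
  comp <- cbind(c1, c2, c3)
  rows <- seq_len(m)
  A <- comp[cbind(rows, Aidx)]
  o1 <- c(2L, 1L, 1L)[Aidx]
  o2 <- c(3L, 3L, 2L)[Aidx]
  b0 <- comp[cbind(rows, o1)]
  c0 <- comp[cbind(rows, o2)]
  B <- pmin(b0, c0)
  C <- pmax(b0, c0)
  Ab <- bitwOr(B, C)
  type <- integer(m)
  type[ns == 0L] <- 4L
  type[i1] <- 5L
  type[i3] <- 2L
  simpAb <- mask_subset(Ab, Tm) | mask_subset(Ab, Tp)
  type[i2] <- ifelse(simpAb[i2], 1L, 3L)
  # canonical all-sorted roles for S4 (role choice is immaterial there)
  s4 <- type == 4L
  if (any(s4)) {
    m4 <- cbind(c1[s4], c2[s4], c3[s4])
    srt <- t(apply(m4, 1L, sort))
    A[s4] <- srt[, 1L]
    B[s4] <- srt[, 2L]
    C[s4] <- srt[, 3L]
    Ab[s4] <- bitwOr(B[s4], C[s4])
  }
  deg <- type == 2L & B == C & popcount(B) == 1L
  list(type = type, A = A, B = B, C = C, Ab = Ab, deg = deg,
       popA = popcount(A))
}

#' Classify a star relative to a top-split
#'
#' A star is the unordered triple of neighbor-subtree label sets at an
#' internal node of an unrooted gene tree.  Exactly one of the five disjoint
#' types S1-S5 matches after canonical role reordering; for S2 the A role is
#' the component equal to one entire side of the top-split (this choice is
#' forced).  A star is degenerate when B = C is a single species, which
#' happens only with duplicate gene labels.
#'
#' @param components list of three character vectors (the label sets).
#' @param top a top-split: list of two character vectors; the union of both
#'   sides must cover the components.
#' @return object of class `recon_star` with fields `type` (`"S1"`..`"S5"`),
#'   `A`, `B`, `C` (label vectors), `degenerate`, and the mask encoding used
#'   by the contribution functions.
#' @export
classifyStar <- function(components, top) {
  tm <- top_masks(top)
  cm <- vapply(components, function(x) mask_of(x, tm$taxa), integer(1))
  cls <- classify_masks(cm[1L], cm[2L], cm[3L], tm$T, tm$Tp)
  structure(list(type = paste0("S", cls$type),
                 A = labels_of(cls$A, tm$taxa),
                 B = labels_of(cls$B, tm$taxa),
                 C = labels_of(cls$C, tm$taxa),
                 degenerate = cls$deg,
                 masks = cls, taxa = tm$taxa, top = tm),
            class = "recon_star")
}

#' @export
print.recon_star <- function(x, ...) {
  cat(x$type, if (x$degenerate) "(degenerate)" else "", "star ",
      paste(x$A, collapse = ""), "|", paste(x$B, collapse = ""), "|",
      paste(x$C, collapse = ""), "\n", sep = "")
  invisible(x)
}

# component mask triples of every star of G (one per internal node),
# in internal-node order; each row sorted ascending
star_components <- function(G, taxa, side = NULL) {
  if (is.null(side)) side <- unrooted_side_masks(G, taxa)
  t(vapply(G$internal, function(v) {
    sort(vapply(G$adj[[v]], function(w) side[v, w], integer(1)))
  }, integer(3)))
}

#' All stars of an unrooted gene tree
#'
#' One star per internal node; a tree with `l` leaves has `l - 2` stars.
#'
#' @param G an `unrooted_gene_tree` (or Newick string).
#' @return list of component triples (each a list of three label vectors),
#'   in internal-node order.
#' @export
allStars <- function(G) {
  G <- as_unrooted(G)
  sc <- star_components(G, G$labels)
  lapply(seq_len(nrow(sc)), function(i)
    lapply(sc[i, ], labels_of, taxa = G$labels))
}

#' Is an edge symmetric relative to a top-split?
#'
#' An edge is symmetric when the two leaf-label sets it separates are either
#' both simple or both non-simple.
#'
#' @param G an `unrooted_gene_tree`.
#' @param e an edge, as a length-2 vector of adjacent node ids (see
#'   `G$edges`).
#' @param top a top-split over `L(G)`.
#' @return logical flag.
#' @export
isSymmetricEdge <- function(G, e, top) {
  G <- as_unrooted(G)
  tm <- top_masks(top, G$labels)
  side <- unrooted_side_masks(G, G$labels)
  simp <- function(z) mask_subset(z, tm$T) || mask_subset(z, tm$Tp)
  simp(side[e[1L], e[2L]]) == simp(side[e[2L], e[1L]])
}

plateau_rows <- function(G, tm, side) {
  simp <- function(z) mask_subset(z, tm$T) | mask_subset(z, tm$Tp)
  a <- vapply(seq_len(nrow(G$edges)), function(r)
    side[G$edges[r, 1L], G$edges[r, 2L]], integer(1))
  b <- vapply(seq_len(nrow(G$edges)), function(r)
    side[G$edges[r, 2L], G$edges[r, 1L]], integer(1))
  keep <- simp(a) == simp(b)
  # add the asymmetric edge of every S5 star: the edge toward its simple
  # component
  for (v in G$internal) {
    comps <- vapply(G$adj[[v]], function(w) side[v, w], integer(1))
    cs <- simp(comps)
    if (sum(cs) == 1L) {               # S5 star: one simple component
      w <- G$adj[[v]][which(cs)]
      keep <- keep | (G$edges[, 1L] == min(v, w) & G$edges[, 2L] == max(v, w))
    }
  }
  which(keep)
}

#' Plateau edges of an unrooted gene tree
#'
#' The plateau is the set of edges whose rootings attain the minimal
#' reconciliation cost; it consists of all symmetric edges plus the
#' asymmetric edge of every S5 star, is nonempty, connected, and identical
#' for D, DC, L and DL.  It depends on the species tree only through its
#' top-split.
#'
#' @param G an `unrooted_gene_tree` (or Newick string).
#' @param top a top-split over `L(G)`.
#' @return integer matrix of edges (rows of `G$edges`).
#' @export
plateauEdges <- function(G, top) {
  G <- as_unrooted(G)
  tm <- top_masks(top, G$labels)
  side <- unrooted_side_masks(G, G$labels)
  G$edges[plateau_rows(G, tm, side), , drop = FALSE]
}

#' Optimal rooting edges of a gene tree against a species tree
#'
#' By the plateau theory these are exactly the plateau edges under the
#' species tree's top-split, for every cost in D, DC, L, DL.
#'
#' @param G an `unrooted_gene_tree`.
#' @param S a `species_tree` over `L(G)`.
#' @return integer matrix of edges.
#' @export
optimalRootingEdges <- function(G, S) {
  plateauEdges(G, top_of_species_tree(S))
}

#' Plateau/forest decomposition of an unrooted gene tree
#'
#' Splits the tree into the plateau (the subtree of optimal rooting edges)
#' and the rooted forest hanging below its border nodes; every forest
#' subtree appears intact in every plateau rooting.  The tree is typed by
#' its star census: U1/U2 carry one/two S2 stars, U3 has a single-edge
#' plateau between S3 borders, U4 has S4/S5 interior stars.
#'
#' @inheritParams plateauEdges
#' @return list with `plateau_edges` (matrix), `plateau_nodes`,
#'   `border_nodes`, `forest` (list of canonical Newick strings of the
#'   rooted subtrees, rooted at border nodes), `utype`, and `star_types`
#'   (per internal node).
#' @export
decomposeTree <- function(G, top) {
  G <- as_unrooted(G)
  tm <- top_masks(top, G$labels)
  side <- unrooted_side_masks(G, G$labels)
  rows <- plateau_rows(G, tm, side)
  pe <- G$edges[rows, , drop = FALSE]
  pnodes <- sort(unique(as.integer(pe)))
  pdeg <- tabulate(as.integer(pe), nbins = length(G$adj))
  border <- pnodes[pdeg[pnodes] == 1L]
  if (length(pnodes) == 0L) stop("empty plateau: internal inconsistency")
  in_plateau <- matrix(FALSE, length(G$adj), length(G$adj))
  for (r in seq_len(nrow(pe))) {
    in_plateau[pe[r, 1L], pe[r, 2L]] <- TRUE
    in_plateau[pe[r, 2L], pe[r, 1L]] <- TRUE
  }
  forest <- lapply(border, function(b) {
    dn <- G$adj[[b]][!in_plateau[b, G$adj[[b]]]]
    nested <- if (length(dn) == 0L) {
      G$node_labels[b]                       # border node is a leaf of G
    } else if (length(dn) == 2L) {
      list(unrooted_subtree(G, b, dn[1L]), unrooted_subtree(G, b, dn[2L]))
    } else {
      stop("border node with unexpected off-plateau degree")
    }
    paste0(nested_newick(nested), ";")
  })
  sc <- star_components(G, G$labels, side)
  cls <- classify_masks(sc[, 1L], sc[, 2L], sc[, 3L], tm$T, tm$Tp)
  n_s2 <- sum(cls$type == 2L)
  utype <- if (n_s2 == 1L) "U1" else if (n_s2 == 2L) "U2" else
    if (any(cls$type %in% c(4L, 5L))) "U4" else "U3"
  list(plateau_edges = pe, plateau_nodes = pnodes, border_nodes = border,
       forest = forest, utype = utype,
       star_types = paste0("S", cls$type))
}
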