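# Tree containers and Newick I/O.
#
# Internally a rooted tree is a plain recursive structure: a leaf is a
# character scalar (its species label), an internal node is an unnamed list
# of its two children.  Unrooted trees are stored natively as undirected
# graphs whose internal nodes have degree 3, so that no privileged
# pseudo-root leaks into the star/edge machinery.

## ---------------------------------------------------------------- rooted ---

new_rooted_nested <- function(phy) {
  nt <- length(phy$tip.label)
  kids <- vector("list", nt + phy$Nnode)
  for (r in seq_len(nrow(phy$edge))) {
    p <- phy$edge[r, 1L]
    kids[[p]] <- c(kids[[p]], phy$edge[r, 2L])
  }
  build <- function(v) {
    if (v <= nt) return(phy$tip.label[v])
    k <- kids[[v]]
    if (length(k) != 2L) {
      stop("polytomy at internal node: rooted trees must be binary")
    }
    list(build(k[1L]), build(k[2L]))
  }
  build(nt + 1L)
}

nested_leaves <- function(t) {
  if (is.character(t)) t else c(nested_leaves(t[[1L]]), nested_leaves(t[[2L]]))
}

nested_n_leaves <- function(t) {
  if (is.character(t)) 1L else nested_n_leaves(t[[1L]]) + nested_n_leaves(t[[2L]])
}

quote_label <- function(x) {
  bad <- grepl("[ ,():;'\\[\\]]", x)
  x[bad] <- paste0("'", gsub("'", "''", x[bad]), "'")
  x
}

nested_newick <- function(t) {
  if (is.character(t)) return(quote_label(t))
  a <- nested_newick(t[[1L]])
  b <- nested_newick(t[[2L]])
  if (a <= b) paste0("(", a, ",", b, ")") else paste0("(", b, ",", a, ")")
}

# Node table in preorder: parent/children/depth/cluster-mask/label.
# Clusters are label SETS: duplicate gene labels collapse in the mask.
index_nested <- function(root, taxa) {
  env <- new.env(parent = emptyenv())
  env$parent <- integer(0)
  env$kid1 <- integer(0)
  env$kid2 <- integer(0)
  env$depth <- integer(0)
  env$clus <- integer(0)
  env$label <- character(0)
  rec <- function(t, p, d) {
    id <- length(env$parent) + 1L
    env$parent[id] <- p
    env$depth[id] <- d
    env$kid1[id] <- 0L
    env$kid2[id] <- 0L
    env$clus[id] <- 0L
    env$label[id] <- NA_character_
    if (is.character(t)) {
      env$label[id] <- t
      env$clus[id] <- mask_of(t, taxa)
    } else {
      a <- rec(t[[1L]], id, d + 1L)
      b <- rec(t[[2L]], id, d + 1L)
      env$kid1[id] <- a
      env$kid2[id] <- b
      env$clus[id] <- bitwOr(env$clus[a], env$clus[b])
    }
    id
  }
  rec(root, 0L, 0L)
  leaves <- which(!is.na(env$label))
  list(parent = env$parent, kid1 = env$kid1, kid2 = env$kid2,
       depth = env$depth, clus = env$clus, label = env$label,
       n = length(env$parent), leaves = leaves)
}

#' @export
print.rooted_gene_tree <- function(x, ...) {
  cat("Rooted gene tree:", writeNewick(x), "\n")
  cat("  ", x$n_leaves, "leaves,", length(x$labels), "distinct species\n")
  invisible(x)
}

#' @export
print.species_tree <- function(x, ...) {
  cat("Species tree:", writeNewick(x), "\n")
  invisible(x)
}

#' @export
print.unrooted_gene_tree <- function(x, ...) {
  cat("Unrooted gene tree:", writeNewick(x), "\n")
  cat("  ", x$n_leaves, "leaves,", length(x$labels), "distinct species,",
      nrow(x$edges), "edges\n")
  invisible(x)
}

make_rooted_tree <- function(nested, class) {
  lv <- nested_leaves(nested)
  labs <- taxonUniverse(lv)
  if (class == "species_tree" && anyDuplicated(lv)) {
    stop("species tree has duplicate leaf labels: ",
         paste(unique(lv[duplicated(lv)]), collapse = ", "))
  }
  if (length(labs) < 3L) {
    stop("tree must carry at least 3 distinct species labels")
  }
  structure(list(root = nested, labels = labs, n_leaves = length(lv),
                 n_nodes = 2L * length(lv) - 1L),
            class = class)
}

## -------------------------------------------------------------- unrooted ---

# adj: adjacency list over node ids; node_labels: NA for internal nodes;
# edges: E x 2 matrix, each row sorted, rows in lexicographic order.
make_unrooted_from_adj <- function(adj, node_labels) {
  deg <- lengths(adj)
  active <- which(deg > 0L)
  leaves <- active[deg[active] == 1L]
  internal <- active[deg[active] >= 2L]
  if (any(deg[internal] != 3L)) {
    stop("unrooted gene tree must have internal nodes of degree 3")
  }
  if (any(is.na(node_labels[leaves]))) stop("unlabeled leaf in unrooted tree")
  lv <- node_labels[leaves]
  labs <- taxonUniverse(lv)
  if (length(labs) < 3L) {
    stop("tree must carry at least 3 distinct species labels")
  }
  e <- do.call(rbind, lapply(active, function(u) {
    w <- adj[[u]]
    w <- w[w > u]
    if (length(w)) cbind(u, w) else NULL
  }))
  e <- e[order(e[, 1L], e[, 2L]), , drop = FALSE]
  dimnames(e) <- list(NULL, c("u", "v"))
  structure(list(adj = adj, node_labels = node_labels, leaves = leaves,
                 internal = internal, edges = e, labels = labs,
                 n_leaves = length(leaves)),
            class = "unrooted_gene_tree")
}

unrooted_from_phylo <- function(phy) {
  nt <- length(phy$tip.label)
  N <- nt + phy$Nnode
  adj <- rep(list(integer(0)), N)
  for (r in seq_len(nrow(phy$edge))) {
    u <- phy$edge[r, 1L]
    v <- phy$edge[r, 2L]
    adj[[u]] <- c(adj[[u]], v)
    adj[[v]] <- c(adj[[v]], u)
  }
  root <- nt + 1L
  if (length(adj[[root]]) == 2L) {           # suppress the degree-2 root
    ab <- adj[[root]]
    a <- ab[1L]; b <- ab[2L]
    adj[[a]] <- c(setdiff(adj[[a]], root), b)
    adj[[b]] <- c(setdiff(adj[[b]], root), a)
    adj[[root]] <- integer(0)
  }
  labs <- rep(NA_character_, N)
  labs[seq_len(nt)] <- phy$tip.label
  make_unrooted_from_adj(adj, labs)
}

# label mask of the component on the far side of directed edge (from -> to)
unrooted_side_masks <- function(U, taxa) {
  N <- length(U$adj)
  memo <- matrix(NA_integer_, N, N)
  down <- function(from, to) {
    if (!is.na(memo[from, to])) return(memo[from, to])
    m <- if (!is.na(U$node_labels[to])) {
      mask_of(U$node_labels[to], taxa)
    } else {
      acc <- 0L
      for (w in U$adj[[to]]) if (w != from) acc <- bitwOr(acc, down(to, w))
      acc
    }
    memo[from, to] <<- m
    m
  }
  for (r in seq_len(nrow(U$edges))) {
    down(U$edges[r, 1L], U$edges[r, 2L])
    down(U$edges[r, 2L], U$edges[r, 1L])
  }
  memo
}

# nested rooted subtree hanging from `to`, entered from `from`
unrooted_subtree <- function(U, from, to) {
  if (!is.na(U$node_labels[to])) return(U$node_labels[to])
  w <- U$adj[[to]]
  w <- w[w != from]
  list(unrooted_subtree(U, to, w[1L]), unrooted_subtree(U, to, w[2L]))
}

## ---------------------------------------------------------------- parser ---

#' Parse a Newick string into a tree object
#'
#' Branch lengths and internal node labels are accepted and discarded: all
#' costs in this package depend on topology and leaf labels only.  An
#' unrooted tree may be written either with a top-level trifurcation or as an
#' arbitrary binary rooting; in the latter case the degree-2 root is
#' suppressed.
#'
#' @param text a Newick string (terminating semicolon required).
#' @param type `"rooted"` for a rooted gene tree (duplicate leaf labels
#'   permitted), `"species"` for a species tree (unique labels enforced), or
#'   `"unrooted"` for an unrooted gene tree.
#' @return an object of class `rooted_gene_tree`, `species_tree` or
#'   `unrooted_gene_tree`.
#' @examples
#' parseNewick("(a,(b,c));", "rooted")
#' parseNewick("(a,b,c);", "unrooted")
#' @export
parseNewick <- function(text, type = c("rooted", "species", "unrooted")) {
  type <- match.arg(type)
  phy <- tryCatch(ape::read.tree(text = text),
                  error = function(e) stop("malformed Newick: ",
                                           conditionMessage(e), call. = FALSE))
  if (is.null(phy)) stop("malformed Newick: ", text, call. = FALSE)
  if (type == "unrooted") return(unrooted_from_phylo(phy))
  nested <- new_rooted_nested(phy)
  make_rooted_tree(nested,
                   if (type == "species") "species_tree" else "rooted_gene_tree")
}

#' Write a tree in canonical Newick form
#'
#' The canonical writer emits lexicographically sorted children, no branch
#' lengths and a terminating semicolon; unrooted trees are written with a
#' trifurcation at a deterministically chosen internal node.  Two trees are
#' topologically equal iff their canonical Newick strings are equal.
#'
#' @param x a tree object from [parseNewick()] or a bare nested structure.
#' @return a single Newick string.
#' @export
writeNewick <- function(x) {
  if (inherits(x, "unrooted_gene_tree")) {
    # canonical: the lexicographically smallest trifurcation writing over
    # all internal centers, so equal topologies get equal strings
    cand <- vapply(x$internal, function(ctr) {
      parts <- sort(vapply(x$adj[[ctr]], function(w)
        nested_newick(unrooted_subtree(x, ctr, w)), character(1)))
      paste0("(", paste(parts, collapse = ","), ");")
    }, character(1))
    return(min(cand))
  }
  nested <- if (is.list(x) && !is.null(x$root)) x$root else x
  paste0(nested_newick(nested), ";")
}

#' Read a collection of gene trees, one Newick per line
#'
#' @param file path to a text file with one Newick tree per line.
#' @param type tree type passed to [parseNewick()].
#' @return list of tree objects.
#' @export
readTrees <- function(file, type = c("unrooted", "rooted", "species")) {
  type <- match.arg(type)
  lines <- readLines(file)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  lapply(lines, parseNewick, type = type)
}

## ------------------------------------------------- rootings and rootedness ---

#' Enumerate all rootings of an unrooted gene tree
#'
#' Placing the root on each of the 2n-3 edges of an unrooted binary tree
#' (subdividing the edge with a new root node) gives every rooted version of
#' the tree.
#'
#' @param G an `unrooted_gene_tree` (or Newick string).
#' @return a list with one element per edge: `list(edge = c(u, v),
#'   tree = <rooted_gene_tree>)`, in the deterministic edge order of `G`.
#' @export
enumerateRootings <- function(G) {
  G <- as_unrooted(G)
  lapply(seq_len(nrow(G$edges)), function(r) {
    u <- G$edges[r, 1L]
    v <- G$edges[r, 2L]
    nested <- list(unrooted_subtree(G, v, u), unrooted_subtree(G, u, v))
    list(edge = c(u, v), tree = make_rooted_tree(nested, "rooted_gene_tree"))
  })
}

#' Suppress the root of a rooted gene tree
#'
#' Inverse of rooting: the degree-2 root is removed, producing the unrooted
#' tree all of whose rootings include `G`.
#'
#' @param G a `rooted_gene_tree` (or Newick string).
#' @return an `unrooted_gene_tree`.
#' @export
unrootTree <- function(G) {
  G <- as_rooted(G)
  parseNewick(writeNewick(G), "unrooted")
}

as_rooted <- function(x) {
  if (inherits(x, "rooted_gene_tree")) return(x)
  if (inherits(x, "species_tree")) {
    return(make_rooted_tree(x$root, "rooted_gene_tree"))
  }
  if (is.character(x)) return(parseNewick(x, "rooted"))
  stop("cannot interpret object as a rooted gene tree")
}

as_species <- function(x) {
  if (inherits(x, "species_tree")) return(x)
  if (is.character(x)) return(parseNewick(x, "species"))
  if (inherits(x, "rooted_gene_tree")) {
    return(make_rooted_tree(x$root, "species_tree"))
  }
  stop("cannot interpret object as a species tree")
}

as_unrooted <- function(x) {
  if (inherits(x, "unrooted_gene_tree")) return(x)
  if (is.character(x)) return(parseNewick(x, "unrooted"))
  if (inherits(x, "rooted_gene_tree")) return(unrootTree(x))
  stop("cannot interpret object as an unrooted gene tree")
}

as_collection <- function(Q, coerce) {
  if (inherits(Q, c("rooted_gene_tree", "species_tree", "unrooted_gene_tree")) ||
      is.character(Q)) {
    Q <- if (is.character(Q)) as.list(Q) else list(Q)
  }
  lapply(Q, coerce)
}

species_index <- function(S) {
  S <- as_species(S)
  if (is.null(S$idx)) S$idx <- index_nested(S$root, S$labels)
  S
}

## -------------------------------------------------------- splits and lca ---

#' Multiset of rooted splits of a gene tree collection
#'
#' Every internal node of every tree contributes the unordered pair of its
#' children's clusters (as label sets; duplicate gene labels collapse).
#' Multiplicities are preserved.
#'
#' @param Q a rooted tree, a Newick string, or a list of them.
#' @param taxa optional taxon universe; defaults to the union over `Q`.
#' @return an object of class `split_multiset` with integer mask vectors
#'   `A`, `B` (canonically `A <= B`) and the `taxa` ordering.
#' @export
rootedSplits <- function(Q, taxa = NULL) {
  Q <- as_collection(Q, as_rooted)
  if (is.null(taxa)) taxa <- taxonUniverse(unlist(lapply(Q, `[[`, "labels")))
  A <- integer(0)
  B <- integer(0)
  collect <- function(t) {
    if (is.character(t)) return(mask_of(t, taxa))
    a <- collect(t[[1L]])
    b <- collect(t[[2L]])
    A[length(A) + 1L] <<- min(a, b)
    B[length(B) + 1L] <<- max(a, b)
    bitwOr(a, b)
  }
  for (G in Q) collect(G$root)
  structure(list(A = A, B = B, taxa = taxa), class = "split_multiset")
}

#' @export
print.split_multiset <- function(x, ...) {
  cat(length(x$A), "rooted splits over {",
      paste(x$taxa, collapse = ","), "}\n")
  for (i in seq_along(x$A)) {
    cat("  ", paste(labels_of(x$A[i], x$taxa), collapse = ""), "|",
        paste(labels_of(x$B[i], x$taxa), collapse = ""), "\n", sep = "")
  }
  invisible(x)
}

resolve_node <- function(S, x) {
  if (is.character(x)) {
    id <- which(!is.na(S$idx$label) & S$idx$label == x)
    if (length(id) != 1L) stop("no unique leaf labeled '", x, "'")
    return(id)
  }
  x <- as.integer(x)
  if (x < 1L || x > S$idx$n) stop("node id out of range: ", x)
  x
}

lca_ids <- function(idx, a, b) {
  while (idx$depth[a] > idx$depth[b]) a <- idx$parent[a]
  while (idx$depth[b] > idx$depth[a]) b <- idx$parent[b]
  while (a != b) {
    a <- idx$parent[a]
    b <- idx$parent[b]
  }
  a
}

#' Least common ancestor of two species-tree nodes
#'
#' Nodes may be given as preorder node ids or as leaf labels.
#'
#' @param S a `species_tree`.
#' @param a,b nodes of `S`.
#' @return the preorder node id of the lca.
#' @export
lca <- function(S, a, b) {
  S <- species_index(S)
  lca_ids(S$idx, resolve_node(S, a), resolve_node(S, b))
}

#' Number of nodes on the path between two species-tree nodes
#'
#' Counts all nodes inclusive of the endpoints; `pathSize(S, x, x)` is 1.
#'
#' @inheritParams lca
#' @param x,y nodes of `S`.
#' @return integer node count.
#' @export
pathSize <- function(S, x, y) {
  S <- species_index(S)
  x <- resolve_node(S, x)
  y <- resolve_node(S, y)
  l <- lca_ids(S$idx, x, y)
  S$idx$depth[x] + S$idx$depth[y] - 2L * S$idx$depth[l] + 1L
}
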