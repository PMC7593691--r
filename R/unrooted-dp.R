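# Unrooted cost contribution functions and the median-tree dynamic program.
#
# For a fixed top-split, the unrooted reconciliation cost of a gene tree
# against any species tree with that top-split decomposes into per-star
# contributions: lambda-hat to each species leaf, gamma-hat to each non-root
# species split, sigma to the root split, plus a per-tree constant epsilon.
# The solver then minimizes, over every top-split T|T', a subset recurrence
# Upsilon restricted to subsets of one side, and takes the best top-split.
#
# Fractional arithmetic: the S2 terms of gamma-hat^DC and sigma^D produce
# exact halves; they are accumulated in doubles (dyadic, hence exact) and
# every final cost is integral.

## ------------------------------------------- per-star contribution terms ---

star_lam_D <- function(cls, s) {
  as.numeric(cls$type <= 2L & cls$B == s & cls$C == s)
}

star_lam_DC <- function(cls, s) {
  v <- numeric(length(cls$type))
  i <- cls$type == 1L | cls$type == 3L
  if (any(i)) v[i] <- lam_DC_vec(cls$B[i], cls$C[i], s)
  i <- cls$type == 5L
  if (any(i)) v[i] <- lam_DC_vec(cls$A[i], cls$Ab[i], s)
  i <- cls$type == 2L & !cls$deg
  if (any(i)) {
    v[i] <- pmax(lam_DC_vec(cls$B[i], cls$C[i], s),
                 lam_DC_vec(cls$A[i], cls$Ab[i], s))
  }
  v
}

star_lam <- function(cost, cls, s) {
  switch(cost,
         D = star_lam_D(cls, s),
         DC = star_lam_DC(cls, s),
         star_lam_DC(cls, s) + cost_omega[[cost]] * star_lam_D(cls, s))
}

star_gam_D <- function(cls, X, Y) gam_D_vec(cls$B, cls$C, X, Y)

star_gam_DC <- function(cls, X, Y) {
  v <- numeric(length(cls$type))
  i <- cls$type == 1L | cls$type == 3L
  if (any(i)) v[i] <- gam_DC_vec(cls$B[i], cls$C[i], X, Y)
  i <- cls$type == 5L
  if (any(i)) v[i] <- gam_DC_vec(cls$A[i], cls$Ab[i], X, Y)
  i <- cls$type == 2L & !cls$deg
  if (any(i)) {
    v[i] <- gam_DC_vec(cls$B[i], cls$C[i], X, Y) +
      (1 + (cls$popA[i] == 1L)) / 2 * gam_DC_vec(cls$A[i], cls$Ab[i], X, Y)
  }
  v
}

star_gam <- function(cost, cls, X, Y) {
  switch(cost,
         D = star_gam_D(cls, X, Y),
         DC = star_gam_DC(cls, X, Y),
         star_gam_DC(cls, X, Y) + cost_omega[[cost]] * star_gam_D(cls, X, Y))
}

# Per-star root correction.  The D form is: +1 for every S4/S5 star (each
# forces a duplication at the species root, as does the root of the rooting
# itself, balanced by epsilon); for S2 stars the epsilon over-count is paid
# back, -1 from a singleton-A star, -1/2 from each of a non-degenerate pair,
# 0 from a degenerate star, so the total correction is -1 whenever an S2
# star is present.  The DC form is identically zero.
star_sigma_D <- function(cls) {
  v <- as.numeric(cls$type >= 4L)
  i <- cls$type == 2L & !cls$deg
  v[i] <- v[i] - (1 + (cls$popA[i] == 1L)) / 2
  v
}

star_sigma <- function(cost, cls) {
  switch(cost,
         D = star_sigma_D(cls),
         DC = numeric(length(cls$type)),
         cost_omega[[cost]] * star_sigma_D(cls))
}

#' Star contribution to a species leaf (lambda-hat)
#'
#' @param cost cost model (`"D"`, `"DC"`, `"L"`, `"DL"`).
#' @param star a classified star from [classifyStar()].
#' @param s a single species label.
#' @return numeric contribution.
#' @export
hatLambda <- function(cost, star, s) {
  cost <- check_cost(cost)
  star_lam(cost, star$masks, mask_of(s, star$taxa))
}

#' Star contribution to a non-root species split (gamma-hat)
#'
#' @inheritParams hatLambda
#' @param x a species split: list of two character vectors of labels.
#' @return numeric contribution.
#' @export
hatGamma <- function(cost, star, x) {
  cost <- check_cost(cost)
  m <- split_masks(x, star$taxa)
  star_gam(cost, star$masks, m[1L], m[2L])
}

#' Star contribution to the species root (sigma)
#'
#' @inheritParams hatLambda
#' @return numeric contribution (may be a negative half-integer).
#' @export
sigmaContrib <- function(cost, star) {
  cost <- check_cost(cost)
  star_sigma(cost, star$masks)
}

#' Per-gene-tree cost correction (epsilon)
#'
#' `1` for D, `0` for DC, and `1 - |V_G| + omega_c` for L/DL where `|V_G|`
#' is the node count of a rooting of `G` (unrooted node count plus one).
#'
#' @param cost cost model.
#' @param G an `unrooted_gene_tree` (or Newick string).
#' @return numeric constant.
#' @export
epsilonConst <- function(cost, G) {
  cost <- check_cost(cost)
  G <- as_unrooted(G)
  VG <- 2L * G$n_leaves - 1L
  switch(cost, D = 1, DC = 0, 1 - VG + cost_omega[[cost]])
}

## --------------------------------------------------------- pairwise costs ---

# shared evaluation of the contribution identity for a classified star set
# against the splits of S, with sigma applied at the designated rooting split
pair_cost_eval <- function(cost, cls, S, root_row, eps) {
  total <- eps
  n <- length(S$labels)
  for (i in seq_len(n)) {
    total <- total + sum(star_lam(cost, cls, bitwShiftL(1L, i - 1L)))
  }
  sp <- species_splits(S)
  for (j in seq_along(sp$X)) {
    total <- total + if (j == root_row) {
      sum(star_sigma(cost, cls))
    } else {
      sum(star_gam(cost, cls, sp$X[j], sp$Y[j]))
    }
  }
  total
}

#' Unrooted reconciliation cost of a gene tree against a species tree
#'
#' Computes `min` over all `2n-3` rootings of the rooted cost -- without
#' enumerating rootings, via the star contribution identity.  Three methods:
#' `"plateau"` requires a complete gene tree (`L(G) = L(S)`) and uses the
#' top-split of `S`; `"general"` allows `L(G)` to be a proper subset of
#' `L(S)` and uses the rooting split (the unique split of `S` separating
#' `L(G)`) in the top-split's role; `"minus"` restricts `S` to `L(G)` first
#' and then applies the plateau method, which is a different cost.
#'
#' @param G an `unrooted_gene_tree` (or Newick string) with at least 3
#'   distinct labels.
#' @param S a `species_tree`.
#' @param cost cost model; may be a vector.
#' @param method see above.
#' @return named numeric vector of costs.
#' @examples
#' unrootedCost("(a,b,c);", "(a,(b,c));", c("D", "DC", "L", "DL"))
#' @export
unrootedCost <- function(G, S, cost = "DL",
                         method = c("plateau", "general", "minus")) {
  method <- match.arg(method)
  cost <- vapply(cost, check_cost, character(1), USE.NAMES = FALSE)
  G <- as_unrooted(G)
  S <- species_index(S)
  if (method == "minus") {
    S <- species_index(restrictSpeciesTree(S, G$labels))
    method <- "plateau"
  }
  if (method == "plateau") {
    if (!setequal(G$labels, S$labels)) {
      stop("L(G) != L(S); use method = \"general\" for incomplete trees")
    }
    root_row <- 1L
    tm <- list(taxa = S$labels,
               T = S$idx$clus[S$idx$kid1[1L]],
               Tp = S$idx$clus[S$idx$kid2[1L]])
  } else {
    if (!all(G$labels %in% S$labels)) {
      stop("gene labels absent from the species tree")
    }
    rs <- rooting_split_row(S, mask_of(G$labels, S$labels))
    root_row <- rs$row
    tm <- list(taxa = S$labels, T = rs$X, Tp = rs$Y)
  }
  sc <- star_components(G, tm$taxa)
  cls <- classify_masks(sc[, 1L], sc[, 2L], sc[, 3L], tm$T, tm$Tp)
  VG <- 2L * G$n_leaves - 1L
  vapply(cost, function(cc) {
    eps <- switch(cc, D = 1, DC = 0, 1 - VG + cost_omega[[cc]])
    pair_cost_eval(cc, cls, S, root_row, eps)
  }, numeric(1))
}

# the unique split X|Y of S with L <= X|Y union, L meeting both sides:
# the child split of the lca of the leaves in L
rooting_split_row <- function(S, Lmask) {
  idx <- S$idx
  if (popcount(Lmask) < 2L) stop("rooting split undefined for |L| < 2")
  v <- 1L
  repeat {
    if (idx$kid1[v] == 0L) stop("no rooting split: internal inconsistency")
    x <- idx$clus[idx$kid1[v]]
    if (mask_subset(Lmask, x)) { v <- idx$kid1[v]; next }
    y <- idx$clus[idx$kid2[v]]
    if (mask_subset(Lmask, y)) { v <- idx$kid2[v]; next }
    break
  }
  internal <- which(idx$kid1 != 0L)
  list(row = match(v, internal),
       X = idx$clus[idx$kid1[v]], Y = idx$clus[idx$kid2[v]], node = v)
}

#' Rooting split of a species tree for a label subset
#'
#' The unique split `X|Y` of `S` whose union covers `L` with `L` meeting
#' both sides; it plays the top-split's role for incomplete gene trees.
#'
#' @param L character vector of at least 2 species labels.
#' @param S a `species_tree` containing them.
#' @return list of two character vectors `(X, Y)`.
#' @export
rootingSplit <- function(L, S) {
  S <- species_index(S)
  rs <- rooting_split_row(S, mask_of(L, S$labels))
  list(labels_of(rs$X, S$labels), labels_of(rs$Y, S$labels))
}

#' Restrict a species tree to a label subset
#'
#' Prunes the leaves outside `keep` and suppresses the resulting degree-1/2
#' nodes.
#'
#' @param S a `species_tree`.
#' @param keep character vector of at least 3 labels to retain.
#' @return a `species_tree` on `keep`.
#' @export
restrictSpeciesTree <- function(S, keep) {
  S <- as_species(S)
  rec <- function(t) {
    if (is.character(t)) return(if (t %in% keep) t else NULL)
    a <- rec(t[[1L]])
    b <- rec(t[[2L]])
    if (is.null(a)) return(b)
    if (is.null(b)) return(a)
    list(a, b)
  }
  r <- rec(S$root)
  if (is.null(r)) stop("restriction removed every leaf")
  make_rooted_tree(r, "species_tree")
}

## ----------------------------------------------------------------- solver ---

# star components of a whole collection, concatenated, plus per-tree sizes
prep_collection <- function(Q, taxa = NULL) {
  Q <- as_collection(Q, as_unrooted)
  if (is.null(taxa)) taxa <- taxonUniverse(unlist(lapply(Q, `[[`, "labels")))
  sc <- do.call(rbind, lapply(Q, function(G) {
    if (!setequal(G$labels, taxa)) {
      stop("incomplete gene tree over {",
           paste(G$labels, collapse = ","), "}: every tree must carry the ",
           "full species set {", paste(taxa, collapse = ","), "}")
    }
    star_components(G, taxa)
  }))
  list(taxa = taxa, c1 = sc[, 1L], c2 = sc[, 2L], c3 = sc[, 3L],
       leaf_counts = vapply(Q, `[[`, integer(1), "n_leaves"), k = length(Q))
}

collection_epsilon <- function(cost, prep) {
  switch(cost,
         D = prep$k,
         DC = 0,
         sum(1 - (2 * prep$leaf_counts - 1) + cost_omega[[cost]]))
}

# DC-type gamma-hat depends on the split only through its union, via a list
# of weighted mask pairs; D-type gamma-hat needs the split itself
dc_pairs <- function(cls) {
  P <- integer(0); Qm <- integer(0); W <- numeric(0)
  add <- function(p, q, w) {
    P <<- c(P, p); Qm <<- c(Qm, q); W <<- c(W, w)
  }
  i <- cls$type == 1L | cls$type == 3L
  if (any(i)) add(cls$B[i], cls$C[i], rep(1, sum(i)))
  i <- cls$type == 5L
  if (any(i)) add(cls$A[i], cls$Ab[i], rep(1, sum(i)))
  i <- cls$type == 2L & !cls$deg
  if (any(i)) {
    add(cls$B[i], cls$C[i], rep(1, sum(i)))
    add(cls$A[i], cls$Ab[i], (1 + (cls$popA[i] == 1L)) / 2)
  }
  list(P = P, Q = Qm, W = W)
}

# Upsilon table for one side of a top-split; delta/argmin over submasks of W
upsilon_side <- function(W, cls, cost, lam_cache, record = FALSE) {
  omega <- if (cost == "D") 1 else if (cost == "DC") 0 else
    cost_omega[[cost]]
  use_D <- cost != "DC"
  use_DC <- cost != "D"
  pr <- if (use_DC) dc_pairs(cls) else NULL
  BCu <- if (use_D) cls$Ab else NULL
  subset_dp_side(W, cls, cost, lam_cache, pr, BCu, omega, use_D, use_DC,
                 record)
}

subset_dp_side <- function(W, cls, cost, lam_cache, pr, BCu, omega,
                           use_D, use_DC, record) {
  up <- new.env(parent = emptyenv())
  delta <- rep(NA_real_, bitwShiftL(1L, length(lam_cache)))
  argmin <- if (record) vector("list", length(delta)) else NULL
  subs <- submasks(W)[-1L]
  for (Z in subs) {
    if (popcount(Z) == 1L) {
      delta[Z + 1L] <- lam_cache[round(log2(Z)) + 1L]
      next
    }
    base <- 0
    if (use_DC) {
      inP <- mask_subset(pr$P, Z)
      inQ <- mask_subset(pr$Q, Z)
      base <- sum(pr$W * ((inP & !inQ) + (inQ & !inP)))
    }
    if (use_D) {
      idx <- which(mask_subset(BCu, Z))
      Bv <- cls$B[idx]
      Cv <- cls$C[idx]
    }
    best <- Inf
    args <- integer(0)
    for (X in canonical_subsplits(Z)) {
      Y <- bitwXor(Z, X)
      v <- delta[X + 1L] + delta[Y + 1L]
      if (use_D && length(idx)) {
        fB <- mask_subset(Bv, X) | mask_subset(Bv, Y)
        fC <- mask_subset(Cv, X) | mask_subset(Cv, Y)
        v <- v + omega * sum(!(fB & fC))
      }
      if (v < best - 1e-9) {
        best <- v
        args <- X
      } else if (record && v < best + 1e-9) {
        args <- c(args, X)
      }
    }
    delta[Z + 1L] <- best + base
    if (record) argmin[[Z + 1L]] <- sort(args)
  }
  list(delta = delta, argmin = argmin, entries = length(subs))
}

#' Exact median species tree for unrooted gene trees
#'
#' Solves the unrooted median tree problem: the species tree minimizing the
#' total unrooted reconciliation cost (each gene tree charged its best
#' rooting) over all rooted species trees on `L(Q)`.  For every candidate
#' top-split the per-star contributions are tabulated and a subset
#' recurrence is run over each side; the root split receives the sigma
#' correction and the per-tree epsilon constants are added once.
#'
#' @param Q an unrooted gene tree or list of them; every tree must be
#'   complete (carry all of `L(Q)`), with `|L(Q)| >= 3`.
#' @param cost cost model.
#' @param want `"cost"`, `"one_tree"` (deterministic traceback) or
#'   `"all_trees"` (every optimal species tree).
#' @param max_taxa resource cap (default 14; the work grows as `4^n`).
#' @param dc_convention for `cost = "DC"`, report the paper/path convention
#'   (solver currency) or the standard one (shifted by `sum(1 - |V_G|)`).
#' @return list with `cost`, `model`, `n`, `k`, `top_split` (canonical
#'   string), and per `want` a `tree` / `trees` of canonical Newick strings
#'   plus `optima_count`.
#' @examples
#' solveUnrooted("(a,b,c);", cost = "D", want = "all_trees")
#' @export
solveUnrooted <- function(Q, cost = "DL",
                          want = c("cost", "one_tree", "all_trees"),
                          max_taxa = 14L,
                          dc_convention = c("paper", "standard")) {
  cost <- check_cost(cost)
  want <- match.arg(want)
  dc_convention <- match.arg(dc_convention)
  prep <- prep_collection(Q)
  taxa <- prep$taxa
  n <- length(taxa)
  if (n < 3L) stop("need at least 3 species")
  if (n > max_taxa) {
    stop("species set of size ", n, " exceeds max_taxa = ", max_taxa,
         "; raise max_taxa deliberately (work grows as 4^n)")
  }
  full <- bitwShiftL(1L, n) - 1L
  tops <- seq.int(1L, full - 1L, by = 2L)     # sides containing taxon 1
  eps <- collection_epsilon(cost, prep)

  eval_top <- function(Tm, record = FALSE) {
    Tp <- bitwXor(full, Tm)
    cls <- classify_masks(prep$c1, prep$c2, prep$c3, Tm, Tp)
    lam_cache <- vapply(seq_len(n), function(i)
      sum(star_lam(cost, cls, bitwShiftL(1L, i - 1L))), numeric(1))
    a <- upsilon_side(Tm, cls, cost, lam_cache, record)
    b <- upsilon_side(Tp, cls, cost, lam_cache, record)
    val <- a$delta[Tm + 1L] + b$delta[Tp + 1L] + sum(star_sigma(cost, cls))
    list(value = val, a = a, b = b, entries = a$entries + b$entries)
  }

  entries <- 0L
  vals <- vapply(tops, function(Tm) {
    et <- eval_top(Tm)
    entries <<- entries + et$entries
    et$value
  }, numeric(1))
  best <- min(vals)
  out <- list(cost = best + eps, model = cost, n = n, k = prep$k,
              upsilon_entries = entries)
  if (cost == "DC" && dc_convention == "standard") {
    out$cost <- out$cost + sum(1 - (2 * prep$leaf_counts - 1))
    out$dc_convention <- "standard"
  }
  win <- tops[vals < best + 1e-9]
  out$top_split <- paste0(paste(labels_of(win[1L], taxa), collapse = ","),
                          " | ",
                          paste(labels_of(bitwXor(full, win[1L]), taxa),
                                collapse = ","))
  if (want == "cost") return(out)
  if (want == "one_tree") win <- win[1L]
  trees <- list()
  for (Tm in win) {
    et <- eval_top(Tm, record = TRUE)
    merged <- et$a$argmin
    bi <- which(!vapply(et$b$argmin, is.null, logical(1)))
    merged[bi] <- et$b$argmin[bi]
    lt <- expand_trees(Tm, merged, taxa, all = want == "all_trees")
    rt <- expand_trees(bitwXor(full, Tm), merged, taxa,
                       all = want == "all_trees")
    for (x in lt) for (y in rt) {
      trees[[length(trees) + 1L]] <- paste0(nested_newick(list(x, y)), ";")
    }
  }
  nwk <- sort(unlist(trees))
  if (want == "one_tree") {
    out$tree <- nwk[1L]
  } else {
    out$trees <- nwk
    out$optima_count <- length(nwk)
  }
  out
}

#' Total collection cost of a candidate species tree
#'
#' The objective the solvers minimize: the sum over the collection of the
#' unrooted pairwise cost of each gene tree against `S`.
#'
#' @param Q unrooted gene tree(s), complete over `L(S)`.
#' @param S a `species_tree`.
#' @param cost cost model.
#' @return numeric total.
#' @export
collectionCost <- function(Q, S, cost = "DL") {
  cost <- check_cost(cost)
  S <- species_index(S)
  prep <- if (is.list(Q) && !is.null(Q$taxa) && !is.null(Q$c1)) Q else
    prep_collection(Q, taxa = S$labels)
  cls <- classify_masks(prep$c1, prep$c2, prep$c3,
                        S$idx$clus[S$idx$kid1[1L]],
                        S$idx$clus[S$idx$kid2[1L]])
  pair_cost_eval(cost, cls, S, 1L, collection_epsilon(cost, prep))
}
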