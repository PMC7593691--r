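# Exact rooted median-tree dynamic program: minimize the total reconciliation
# cost over all rooted species trees on L(Q) by a recurrence over species
# subsets.  Delta(Z) is the minimal contribution of a clade with cluster Z;
# singletons take the leaf contribution, larger Z minimize over their
# 2-partitions, adding the split contribution of the partition.

#' Enumerate the 2-partitions of a species set
#'
#' @param Z character vector of at least two distinct species labels.
#' @return list of splits, each a list of two character vectors; there are
#'   `2^(|Z|-1) - 1` of them.
#' @export
enumerateSubsplits <- function(Z) {
  Z <- taxonUniverse(Z)
  if (length(Z) < 2L) stop("need at least 2 species to split")
  full <- bitwShiftL(1L, length(Z)) - 1L
  lapply(canonical_subsplits(full), function(X)
    list(labels_of(X, Z), labels_of(bitwXor(full, X), Z)))
}

# Shared inner DP over subsets.  Contributions are supplied as closures:
#   lam_fun(smask)        -> leaf contribution
#   gamDC_fun(Z)          -> split-free (union-only) part for Z
#   gamD_prepare(Z)       -> state for the per-split part within Z
#   gamD_fun(state, X, Y) -> per-split part
# The DC-type contribution depends on the split only through its union, so it
# is hoisted out of the split minimization; the D-type part cannot be.
subset_dp <- function(full, lam_fun, gamDC_fun, gamD_prepare, gamD_fun,
                      record = FALSE) {
  delta <- rep(NA_real_, full + 1L)
  argmin <- if (record) vector("list", full + 1L) else NULL
  subs <- submasks(full)[-1L]
  for (Z in subs) {
    if (popcount(Z) == 1L) {
      delta[Z + 1L] <- lam_fun(Z)
      next
    }
    base <- gamDC_fun(Z)
    st <- gamD_prepare(Z)
    best <- Inf
    args <- integer(0)
    for (X in canonical_subsplits(Z)) {
      Y <- bitwXor(Z, X)
      v <- delta[X + 1L] + delta[Y + 1L] + gamD_fun(st, X, Y)
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
  list(delta = delta, argmin = argmin)
}

expand_trees <- function(Z, argmin, taxa, all = FALSE) {
  if (popcount(Z) == 1L) return(list(labels_of(Z, taxa)))
  Xs <- argmin[[Z + 1L]]
  if (!all) Xs <- Xs[1L]
  out <- list()
  for (X in Xs) {
    lt <- expand_trees(X, argmin, taxa, all)
    rt <- expand_trees(bitwXor(Z, X), argmin, taxa, all)
    for (a in lt) for (b in rt) out[[length(out) + 1L]] <- list(a, b)
  }
  out
}

#' Exact median species tree for rooted gene trees
#'
#' Minimizes the total reconciliation cost over all `(2n-3)!!` rooted species
#' trees on `L(Q)` by dynamic programming over species subsets (never by
#' enumeration).  For L/DL the per-tree constant `sum(1 - |V_G|)` is added to
#' the table optimum.
#'
#' @param Q a rooted gene tree or list of them; all trees must be complete
#'   over the same species set of size at least 3.
#' @param cost cost model, one of `"D"`, `"DC"`, `"L"`, `"DL"`.
#' @param want `"cost"` for the optimal value only, `"one_tree"` to add a
#'   deterministic traceback tree (lexicographically smallest argmin split at
#'   every node), `"all_trees"` for every optimal tree.
#' @param max_taxa resource cap on `|L(Q)|` (the table has `2^n` entries).
#' @return list with elements `cost`, `model`, `n`, `k`, and (per `want`)
#'   `tree` / `trees` as canonical Newick strings plus `optima_count`.
#' @examples
#' solveRooted("((a,b),c);", cost = "DL", want = "one_tree")
#' @export
solveRooted <- function(Q, cost = "DL",
                        want = c("cost", "one_tree", "all_trees"),
                        max_taxa = 16L) {
  cost <- check_cost(cost)
  want <- match.arg(want)
  Q <- as_collection(Q, as_rooted)
  taxa <- taxonUniverse(unlist(lapply(Q, `[[`, "labels")))
  n <- length(taxa)
  if (n < 3L) stop("need at least 3 species")
  if (n > max_taxa) {
    stop("species set of size ", n, " exceeds max_taxa = ", max_taxa,
         " (the subset table has 2^n entries); raise max_taxa deliberately")
  }
  for (G in Q) {
    if (!setequal(G$labels, taxa)) {
      stop("incomplete gene tree (missing ",
           paste(setdiff(taxa, G$labels), collapse = ","), ")")
    }
  }
  r <- rootedSplits(Q, taxa = taxa)
  full <- bitwShiftL(1L, n) - 1L
  uni <- bitwOr(r$A, r$B)
  omega <- if (cost %in% c("L", "DL")) cost_omega[[cost]] else
    if (cost == "D") 1 else 0
  use_D <- cost != "DC"
  use_DC <- cost != "D"

  lam_fun <- function(s) {
    v <- 0
    if (use_DC) v <- v + sum(lam_DC_vec(r$A, r$B, s))
    if (use_D) v <- v + omega * sum(lam_D_vec(r$A, r$B, s))
    v
  }
  gamDC_fun <- function(Z) {
    if (!use_DC) return(0)
    inA <- mask_subset(r$A, Z)
    inB <- mask_subset(r$B, Z)
    sum((inA & !inB) | (inB & !inA))
  }
  gamD_prepare <- function(Z) {
    if (!use_D) return(NULL)
    idx <- which(mask_subset(uni, Z))
    list(A = r$A[idx], B = r$B[idx])
  }
  gamD_fun <- function(st, X, Y) {
    if (!use_D || length(st$A) == 0L) return(0)
    fits <- function(P) mask_subset(P, X) | mask_subset(P, Y)
    omega * sum(!(fits(st$A) & fits(st$B)))
  }

  dp <- subset_dp(full, lam_fun, gamDC_fun, gamD_prepare, gamD_fun,
                  record = want != "cost")
  const <- if (cost %in% c("L", "DL")) {
    sum(vapply(Q, function(G) 1 - G$n_nodes, numeric(1)))
  } else 0
  out <- list(cost = dp$delta[full + 1L] + const, model = cost, n = n,
              k = length(Q))
  if (want != "cost") {
    trees <- expand_trees(full, dp$argmin, taxa, all = want == "all_trees")
    nwk <- sort(vapply(trees, function(t) paste0(nested_newick(t), ";"),
                       character(1)))
    if (want == "one_tree") {
      out$tree <- nwk[1L]
    } else {
      out$trees <- nwk
      out$optima_count <- length(nwk)
    }
  }
  out
}
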