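# Brute-force references.  These exist to certify the dynamic programs on
# small instances and to reproduce the naive rooting-enumeration baseline;
# none of them is ever used on the solver's hot path.

#' Enumerate all rooted binary species trees on a label set
#'
#' Stepwise leaf insertion on every node position, in deterministic label
#' order; yields exactly `(2n-3)!!` distinct topologies.
#'
#' @param labels character vector of 3 to 8 distinct species labels.
#' @return list of `species_tree` objects.
#' @export
enumerateSpeciesTrees <- function(labels) {
  labels <- taxonUniverse(labels)
  n <- length(labels)
  if (n < 3L) stop("need at least 3 labels")
  if (n > 8L) {
    stop("enumeration capped at 8 labels ((2n-3)!! trees); this is an ",
         "oracle, not a solver")
  }
  insert_everywhere <- function(t, leaf) {
    out <- list(list(t, leaf))                       # above the root
    if (!is.character(t)) {
      for (x in insert_everywhere(t[[1L]], leaf)) {
        out[[length(out) + 1L]] <- list(x, t[[2L]])
      }
      for (x in insert_everywhere(t[[2L]], leaf)) {
        out[[length(out) + 1L]] <- list(t[[1L]], x)
      }
    }
    out
  }
  trees <- list(list(labels[1L], labels[2L]))
  for (i in seq.int(3L, n)) {
    trees <- unlist(lapply(trees, insert_everywhere, leaf = labels[i]),
                    recursive = FALSE)
  }
  lapply(trees, make_rooted_tree, class = "species_tree")
}

#' Brute-force unrooted cost by rooting enumeration
#'
#' Minimum of the rooted cost over all `2n-3` rootings of `G`; the argmin
#' edge set (available when a single cost is requested) equals the plateau.
#'
#' @param G an `unrooted_gene_tree`.
#' @param S a `species_tree` with `L(G)` contained in `L(S)`.
#' @param cost cost model(s).
#' @return named numeric vector of minima; for a single cost the attribute
#'   `"argmin_edges"` holds the optimal edges as a matrix.
#' @export
bruteUnrootedCost <- function(G, S, cost = "DL") {
  cost <- vapply(cost, check_cost, character(1), USE.NAMES = FALSE)
  G <- as_unrooted(G)
  S <- species_index(S)
  per <- vapply(enumerateRootings(G), function(r) rc_costs(r$tree, S),
                numeric(4))
  out <- apply(per[cost, , drop = FALSE], 1L, min)
  names(out) <- cost
  if (length(cost) == 1L) {
    rows <- which(per[cost, ] <= out + 1e-9)
    attr(out, "argmin_edges") <- G$edges[rows, , drop = FALSE]
  }
  out
}

#' Naive median tree by rooting-combination enumeration
#'
#' The baseline the dynamic program replaces: enumerate every combination of
#' rootings of the input trees, solve the rooted median problem for each,
#' and keep the best.  The number of combinations is the product of
#' `2n_i - 3` over the trees and explodes quickly; the cap fails fast.
#'
#' @param Q unrooted gene tree(s), complete over a shared species set.
#' @param cost cost model.
#' @param max_combinations resource cap on the rooting-combination count.
#' @return list with `cost`, `tree` (a Newick string from the best rooted
#'   solve), `combinations`, `model`.
#' @export
naiveMedian <- function(Q, cost = "DL", max_combinations = 100000L) {
  cost <- check_cost(cost)
  Q <- as_collection(Q, as_unrooted)
  rootings <- lapply(Q, enumerateRootings)
  combos <- prod(vapply(rootings, length, integer(1)))
  if (combos > max_combinations) {
    stop(combos, " rooting combinations exceed max_combinations = ",
         max_combinations)
  }
  idx <- rep(1L, length(Q))
  sizes <- vapply(rootings, length, integer(1))
  best <- Inf
  best_tree <- NULL
  repeat {
    rooted <- lapply(seq_along(Q), function(i) rootings[[i]][[idx[i]]]$tree)
    sol <- solveRooted(rooted, cost = cost, want = "one_tree")
    if (sol$cost < best) {
      best <- sol$cost
      best_tree <- sol$tree
    }
    j <- 1L
    while (j <= length(idx)) {
      idx[j] <- idx[j] + 1L
      if (idx[j] <= sizes[j]) break
      idx[j] <- 1L
      j <- j + 1L
    }
    if (j > length(idx)) break
  }
  list(cost = best, tree = best_tree, combinations = combos, model = cost)
}
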