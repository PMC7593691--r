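# Random-start NNI local search over rooted species trees, and the
# accuracy-versus-exact experiment harness.  The search is steepest-descent
# with random tie-breaking among the best strictly improving neighbors; the
# objective is the total unrooted reconciliation cost of the collection.

#' Rooted NNI neighborhood of a species tree
#'
#' All trees reachable by one rooted nearest-neighbor-interchange move: for
#' each internal edge, the sibling subtree above it is swapped with either
#' child subtree below it.  Neighbors are deduplicated and returned in
#' canonical Newick order; the relation is symmetric.
#'
#' @param S a `species_tree` (or Newick string) on at least 3 leaves.
#' @return list of `species_tree` objects.
#' @export
nniNeighbors <- function(S) {
  S <- as_species(S)
  moves <- function(t) {
    out <- list()
    if (is.character(t)) return(out)
    l <- t[[1L]]
    r <- t[[2L]]
    if (!is.character(l)) {
      out <- c(out, list(list(list(r, l[[2L]]), l[[1L]]),
                         list(list(l[[1L]], r), l[[2L]])))
    }
    if (!is.character(r)) {
      out <- c(out, list(list(r[[1L]], list(l, r[[2L]])),
                         list(r[[2L]], list(r[[1L]], l))))
    }
    for (m in moves(l)) out <- c(out, list(list(m, r)))
    for (m in moves(r)) out <- c(out, list(list(l, m)))
    out
  }
  cand <- moves(S$root)
  nwk <- vapply(cand, function(t) paste0(nested_newick(t), ";"), character(1))
  keep <- !duplicated(nwk)
  nwk <- nwk[keep]
  cand <- cand[keep]
  o <- order(nwk)
  lapply(cand[o], make_rooted_tree, class = "species_tree")
}

#' Steepest-descent NNI local search for a median species tree
#'
#' From `start`, repeatedly moves to a minimum-cost NNI neighbor while that
#' strictly improves the total collection cost, breaking ties uniformly at
#' random (session RNG), and stops at a local optimum.
#'
#' @param Q unrooted gene tree(s), complete over the species set.
#' @param cost cost model.
#' @param start a `species_tree` over `L(Q)`.
#' @return list of class `nni_search_run` with `start`, `final` (Newick
#'   strings), `cost`, `trajectory` (cost after each step, starting with the
#'   start tree's), and `steps`.
#' @export
localSearch <- function(Q, cost = "DL", start) {
  cost <- check_cost(cost)
  prep <- if (is.list(Q) && !is.null(Q$c1)) Q else prep_collection(Q)
  cur <- as_species(start)
  if (!setequal(cur$labels, prep$taxa)) {
    stop("start tree must be over the collection's species set")
  }
  cur_cost <- collectionCost(prep, cur, cost)
  traj <- cur_cost
  steps <- 0L
  repeat {
    nb <- nniNeighbors(cur)
    costs <- vapply(nb, function(s) collectionCost(prep, s, cost), numeric(1))
    if (min(costs) >= cur_cost - 1e-9) break
    pick <- which(costs < min(costs) + 1e-9)
    j <- if (length(pick) == 1L) pick else pick[sample.int(length(pick), 1L)]
    cur <- nb[[j]]
    cur_cost <- costs[j]
    steps <- steps + 1L
    traj <- c(traj, cur_cost)
  }
  structure(list(start = writeNewick(as_species(start)),
                 final = writeNewick(cur), cost = cur_cost,
                 trajectory = traj, steps = steps, model = cost),
            class = "nni_search_run")
}

#' @export
print.nni_search_run <- function(x, ...) {
  cat("NNI local search (", x$model, "): ", x$steps, " steps, final cost ",
      x$cost, "\n  final: ", x$final, "\n", sep = "")
  invisible(x)
}

#' Heuristic accuracy against the exact solver
#'
#' For each dataset the exact optimum is computed with [solveUnrooted()];
#' then `runs_per_dataset` local searches are started from independent
#' random Yule trees, and the accuracy is the fraction of runs whose final
#' cost attains the optimum.  Mirrors the published protocol at a
#' configurable (desk) scale.
#'
#' @param datasets list of `gene_tree_dataset` objects (see
#'   [makeDataset()]).
#' @param cost cost model.
#' @param runs_per_dataset random starts per dataset.
#' @param seed integer seed for the whole experiment.
#' @param max_taxa passed to [solveUnrooted()]; infeasible datasets are
#'   skipped with a warning.
#' @return data.frame with one row per dataset: `n`, `k`, `model`,
#'   `dataset_seed`, `runs`, `exact_cost`, `accuracy` (in `[0, 1]`), and
#'   `min_heuristic_cost`.
#' @export
accuracyExperiment <- function(datasets, cost = "D", runs_per_dataset = 200L,
                               seed = 1L, max_taxa = 14L) {
  cost <- check_cost(cost)
  rows <- list()
  with_seed(seed, {
    for (ds in datasets) {
      if (ds$n > max_taxa) {
        warning("dataset with n = ", ds$n, " skipped (exceeds max_taxa)")
        next
      }
      prep <- prep_collection(ds$trees)
      exact <- solveUnrooted(ds$trees, cost = cost, want = "cost",
                             max_taxa = max_taxa)$cost
      finals <- vapply(seq_len(runs_per_dataset), function(i) {
        start <- yuleTree(ds$n, ds$labels)
        localSearch(prep, cost, make_rooted_tree(start$root, "species_tree"))$cost
      }, numeric(1))
      rows[[length(rows) + 1L]] <- data.frame(
        n = ds$n, k = ds$k, model = cost, dataset_seed = ds$seed,
        runs = runs_per_dataset, exact_cost = exact,
        accuracy = mean(finals <= exact + 1e-9),
        min_heuristic_cost = min(finals))
    }
  })
  do.call(rbind, rows)
}
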