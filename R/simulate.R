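# Seeded pure-birth (Yule) tree generation.  Costs in this package are
# topology-only, so the generator is the topology-level Yule process:
# starting from a cherry, an extant leaf is chosen uniformly at random and
# split, until n leaves; labels are a random permutation of the taxon set.

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

grow_yule_nested <- function(n) {
  t <- list(1L, 2L)
  for (k in seq.int(3L, n)) {
    target <- sample.int(k - 1L, 1L)
    split_kth <- function(x) {
      # replaces the target-th leaf (in-order) by a cherry
      if (is.integer(x) && length(x) == 1L && !is.list(x)) {
        target <<- target - 1L
        if (target == 0L) return(list(x, k))
        return(x)
      }
      list(split_kth(x[[1L]]), split_kth(x[[2L]]))
    }
    t <- split_kth(t)
  }
  t
}

relabel_nested <- function(t, labels) {
  if (!is.list(t)) return(labels[t])
  list(relabel_nested(t[[1L]], labels), relabel_nested(t[[2L]], labels))
}

#' Random rooted tree under the pure-birth (Yule) model
#'
#' Uses the session RNG; seed with [set.seed()] or use [makeDataset()] for
#' reproducible collections.
#'
#' @param n number of leaves (at least 3).
#' @param labels taxon set to permute onto the leaves; defaults to
#'   `s1..sn`.
#' @return a `rooted_gene_tree`.
#' @export
yuleTree <- function(n, labels = paste0("s", seq_len(n))) {
  n <- as.integer(n)
  if (n < 3L) stop("need n >= 3")
  if (length(labels) != n) stop("need exactly n labels")
  nested <- relabel_nested(grow_yule_nested(n), sample(labels))
  make_rooted_tree(nested, "rooted_gene_tree")
}

#' Simulated dataset of unrooted gene trees
#'
#' `k` independent Yule trees on `n` shared taxa, unrooted by root
#' suppression -- the generating conditions of the scalability and accuracy
#' experiments.  Byte-identical output under a fixed seed.
#'
#' @param n taxon count.
#' @param k tree count.
#' @param seed integer seed.
#' @return object of class `gene_tree_dataset`: list with `n`, `k`, `seed`,
#'   `labels` and `trees` (list of `unrooted_gene_tree`).
#' @export
makeDataset <- function(n, k, seed) {
  labels <- paste0("s", seq_len(n))
  trees <- with_seed(seed, lapply(seq_len(k), function(i)
    unrootTree(yuleTree(n, labels))))
  structure(list(n = as.integer(n), k = as.integer(k),
                 seed = as.integer(seed), labels = taxonUniverse(labels),
                 trees = trees),
            class = "gene_tree_dataset")
}

#' @export
print.gene_tree_dataset <- function(x, ...) {
  cat("Gene tree dataset: k =", x$k, "unrooted trees on n =", x$n,
      "taxa (seed", paste0(x$seed, ")"), "\n")
  invisible(x)
}

#' Grid of simulated datasets mirroring the experimental setup
#'
#' Five datasets for each combination of `n` and `k`; defaults reproduce
#' the published grid (`n` in 5..11, `k` in 20 and 100) and are meant to be
#' scaled down for desk-size runs.
#'
#' @param seed integer base seed; each dataset gets a distinct derived seed.
#' @param n_values taxon counts.
#' @param k_values tree counts.
#' @param datasets_per datasets per combination.
#' @return list of `gene_tree_dataset` objects.
#' @export
makePaperGrid <- function(seed, n_values = 5:11, k_values = c(20L, 100L),
                          datasets_per = 5L) {
  out <- list()
  i <- 0L
  for (n in n_values) for (k in k_values) for (d in seq_len(datasets_per)) {
    i <- i + 1L
    out[[i]] <- makeDataset(n, k, seed = (seed + 7919L * i) %% .Machine$integer.max)
  }
  out
}

#' Write a dataset to a Newick file with a JSON sidecar
#'
#' @param ds a `gene_tree_dataset`.
#' @param file output path; the sidecar is written to `paste0(file, ".json")`.
#' @return `file`, invisibly.
#' @export
writeDataset <- function(ds, file) {
  writeLines(vapply(ds$trees, writeNewick, character(1)), file)
  jsonlite::write_json(list(n = ds$n, k = ds$k, seed = ds$seed),
                       paste0(file, ".json"), auto_unbox = TRUE)
  invisible(file)
}
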