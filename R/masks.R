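# Bitmask encoding of species sets against a fixed, lexicographically sorted
# taxon universe.  Masks are plain R integers; all solvers cap the taxon count
# well below the 31-bit limit.

#' Fixed taxon ordering for a set of labels
#'
#' Returns the sorted unique labels; every bitmask in the package is relative
#' to such an ordering, fixed once per analysis.
#'
#' @param labels character vector of species labels (repeats allowed).
#' @return sorted character vector of unique labels.
#' @export
taxonUniverse <- function(labels) sort(unique(as.character(labels)))

mask_of <- function(labels, taxa) {
  if (length(labels) == 0L) return(0L)
  i <- match(labels, taxa)
  if (anyNA(i)) {
    stop("labels not in taxon universe: ",
         paste(unique(labels[is.na(i)]), collapse = ", "))
  }
  m <- 0L
  for (b in unique(i)) m <- bitwOr(m, bitwShiftL(1L, b - 1L))
  m
}

labels_of <- function(mask, taxa) {
  taxa[bitwAnd(bitwShiftR(mask, seq_along(taxa) - 1L), 1L) == 1L]
}

# vectorized population count
popcount <- function(x) {
  n <- integer(length(x))
  while (any(x != 0L)) {
    n <- n + bitwAnd(x, 1L)
    x <- bitwShiftR(x, 1L)
  }
  n
}

# vectorized: bits of a outside b are empty
mask_subset <- function(a, b) bitwAnd(a, bitwNot(b)) == 0L

mask_lowbit <- function(x) bitwAnd(x, bitwNot(x - 1L))

# all submasks of m (including 0 and m), in increasing order
submasks <- function(m) {
  out <- integer(bitwShiftL(1L, popcount(m)))
  i <- 1L
  s <- m
  repeat {
    out[i] <- s
    if (s == 0L) break
    i <- i + 1L
    s <- bitwAnd(s - 1L, m)
  }
  rev(out)
}

# canonical unordered 2-partitions of Z: the side containing the lowest bit
# of Z is returned; there are 2^(|Z|-1) - 1 of them
canonical_subsplits <- function(Z) {
  lb <- mask_lowbit(Z)
  rest <- bitwXor(Z, lb)
  s <- submasks(rest)
  bitwOr(lb, s[-length(s)])
}
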