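Package: urmedian
Title: Exact Median Species Trees from Unrooted Gene Trees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Exact inference of median (supertree) species trees from
    collections of unrooted gene trees under the gene duplication, deep
    coalescence, loss, and duplication-loss reconciliation costs.  Implements
    the rooted subset dynamic program over species clades, the unrooted
    star/plateau decomposition with per-star cost contribution functions, and
    a dynamic program over species subsets parameterized by top-splits that
    solves the unrooted median tree problem without enumerating rootings.
    Includes brute-force reference solvers, a seeded pure-birth (Yule) tree
    simulator, and a random-start NNI local-search heuristic with an
    accuracy-versus-exact experiment harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    jsonlite,
    optparse,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
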