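# urmedian

Exact median (supertree) species-tree inference from collections of
**unrooted** gene trees under the classic gene tree reconciliation costs:
gene duplication (D), deep coalescence (DC), gene loss (L) and
duplication–loss (DL).

## The problem

Standard phylogenetic inference yields *unrooted* gene trees whose topologies
disagree with each other because of gene duplication, loss and deep
coalescence. The median tree problem asks for the rooted species tree `S`
minimizing the total reconciliation cost

```
c(Q, S) = Σ_{G ∈ Q}  min_{e ∈ E(G)}  c(G_e, S)
```

where each unrooted gene tree `G` is charged its best rooting `G_e` (the
root placed on edge `e`), and `c` is one of D, DC, L, DL computed through
the lca-mapping. The problem is NP-hard; the naive exact route enumerates
every combination of rootings (`Π (2n_i − 3)` of them) and solves a rooted
median problem for each.

`urmedian` implements an exact solver that avoids rooting enumeration
entirely. Relative to the top-split `T|T′` of a candidate species tree
(the bipartition at its root), every internal node of an unrooted gene tree
determines a *star* of one of five types (S1–S5), and the optimal rooting
edges form a connected *plateau* determined by the top-split alone. Each
cost then decomposes exactly into per-star contributions — `λ̂` to each
species leaf, `γ̂` to each non-root species split, a root correction `σ`,
and a per-tree constant `ε` — and a dynamic program over species subsets,
run once per top-split, minimizes the total in `O(mn·4ⁿ)` elementary steps
for `n` species and `m` gene-tree leaves. Runtime grows linearly with the
number of input trees.

The package also provides the rooted-input median solver (subset DP over
clades), brute-force oracles (species-tree enumeration, rooting
enumeration, the naive baseline), a seeded pure-birth (Yule) simulator, and
a random-start NNI local-search heuristic with an accuracy harness — the
apparatus needed to certify the solver and to measure how often local
search misses the true median tree.

Intended users: phylogeneticists running gene-tree parsimony analyses on
small taxon sets (the exact solver is practical to roughly a dozen taxa)
and methods developers needing a certified reference implementation.

## Worked example

```r
library(urmedian)

# 10 simulated unrooted gene trees on 6 taxa (pure-birth, seeded)
ds  <- makeDataset(n = 6, k = 10, seed = 42)
sol <- solveUnrooted(ds$trees, cost = "DL", want = "all_trees")
str(sol[c("cost", "trees", "optima_count", "top_split")])
#> $ cost        : num 59
#> $ trees       : chr [1:2] "(((((s1,s4),s6),s3),s2),s5);" "(((((s1,s4),s6),s3),s5),s2);"
#> $ optima_count: int 2
#> $ top_split   : chr "s1,s2,s3,s4,s6 | s5"
```

The minimal total duplication–loss cost over all 945 rooted species trees on
6 taxa is 59, attained by exactly two trees; `top_split` is a root
bipartition attaining the optimum. Pairwise costs come from the same
identity, without enumerating rootings:

```r
unrootedCost("((a,b),c,d);", "((a,(b,c)),d);", c("D", "DC", "L", "DL"))
#>  D DC  L DL
#>  1  7  3  4
```

(DC uses the path-count convention throughout; `dc_convention = "standard"`
shifts by `1 − |V_G|`.) The local-search heuristic the exact solver is
meant to replace can stall above the optimum:

```r
localSearch(ds$trees, "DL", parseNewick("((((s1,s2),s3),(s4,s5)),s6);", "species"))
#> NNI local search (DL): 5 steps, final cost 64
#>   final: ((((s2,s5),s3),(s1,s4)),s6);
```

A command line mirrors the library (`solve`, `naive`, `cost`, `inspect`,
`simulate`, `heuristic`, `accuracy`):

```sh
Rscript exec/urmedian solve --cost dl trees.nwk
Rscript exec/urmedian cost --cost dc --species "(a,(b,c));" --gene "(a,b,c);"
```

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the package's main pipeline from scratch: it simulates a seeded
20-tree dataset on 7 taxa, infers exact median trees under D and DL,
re-evaluates each reported optimum against the collection objective, and
cross-checks the solver against the naive rooting-enumeration baseline on a
small instance before writing the JSON report.
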