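---
title: "Exact median species trees from unrooted gene trees: models and methods"
author: "urmedian"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exact median species trees from unrooted gene trees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

A *rooted gene tree* `G` is a binary tree whose leaves carry species labels,
possibly with repeats; a *species tree* `S` is a rooted binary tree with
unique labels. The *lca-mapping* `M` sends each gene leaf to the species
leaf with the same label and each internal gene node to the lca of its
children's images. Four costs measure the discordance this embedding
implies:

* **D** (duplication): the number of internal gene nodes mapping to the
  same species node as one of their children.
* **DC** (deep coalescence, *path convention*): the sum over gene sibling
  pairs `(a, b)` of the number of species nodes on the path between `M(a)`
  and `M(b)`, minus one. The conventional deep-coalescence count differs
  from this by the constant `1 − |V_G|`; `dc_convention = "standard"`
  applies the shift. The path convention is the solver's internal currency
  because it makes the per-split decomposition below exact.
* **L** (loss): `L = DC + 2·D − |V_G| + 1`, an exact integer identity.
* **DL**: `DL = D + L`.

For an *unrooted* gene tree, each cost is the minimum of the rooted cost
over all `2n − 3` rootings. The *median tree problem* asks for the species
tree over the union label set minimizing the summed unrooted cost of a
collection; `solveUnrooted()` solves it exactly, `solveRooted()` solves the
rooted-input variant.

## Per-split decomposition and the rooted DP

For rooted inputs, each cost is a sum of independent contributions: a
leaf term `λ(A|B, s)` for every gene split and species, and a split term
`γ(A|B, X|Y)` for every gene split and internal species split. For D, `λ`
fires when both sides of the gene split reduce to the single species `s`,
and `γ` when the gene split's union fits in the species node's cluster but
some side fits in neither child cluster. For DC, `λ` fires when exactly one
side equals `{s}`, and `γ` when one side fits the cluster while the other
does not. L and DL are the linear combinations `DC + ω·D` with `ω_L = 2`,
`ω_DL = 3`, plus the per-tree constant `Σ (1 − |V_G|)`. These four cases
are validated in the suite against the direct lca-mapping costs on hundreds
of random pairs, including duplicate-label gene trees.

Because the total cost is additive over species-tree nodes, the optimal
tree follows from a recurrence over species subsets: `Δ(Z)` is the leaf
contribution for singletons and otherwise the minimum over 2-partitions
`X|Y` of `Z` of `Δ(X) + Δ(Y) + Γ(X|Y)`. `solveRooted()` implements it with
bitmask submask enumeration; clusters are label *sets* (an `(a,a)` cherry
has cluster `{a}`), so masks are well defined under duplicate labels.

## Stars, the plateau, and the unrooted DP

Fix a candidate top-split `T|T′` (the root bipartition of a species tree).
A species set is *simple* if it fits inside `T` or inside `T′`. Each
internal node of an unrooted gene tree yields a *star*, the triple
`A|B|C` of its neighbor-subtree label sets, and the simplicity pattern of
the components and their complements sorts every star into exactly one of
five types:

* **S1**: `A` non-simple, `B ∪ C` simple;
* **S2**: `A` and `B ∪ C` both simple (then `A` is forced to be one entire
  top cluster — the package asserts this uniqueness);
* **S3**: `A` and `B ∪ C` non-simple, `B`, `C` simple;
* **S4**: all three components non-simple;
* **S5**: `A` simple, `B`, `C` non-simple.

An edge is *symmetric* if the two label sets it separates are both simple
or both non-simple. The symmetric edges plus the `A`-side edge of every S5
star form the *plateau*: a nonempty connected subtree whose rootings all
attain the minimal cost, for all four costs at once, and which depends on
`S` only through its top-split. Off the plateau, cost is non-decreasing
along every path toward a leaf. The suite verifies all of this against
rooting enumeration; it also confirms that the plateau coincides exactly
with the DL argmin edge set, while for D and DC the argmin set can be a
strict superset (cost-specific ties), which is why the package defines
`optimalRootingEdges()` through the plateau rather than per-cost argmins.

Removing the plateau edges decomposes the gene tree into the plateau and a
*rooted forest* hanging below the plateau's border nodes; each forest
subtree appears intact in every optimal rooting. On the 3-leaf star with
top-split `a|bc`, the plateau is the single edge toward `a` and the forest
is `{a, (b,c)}` — the star center is itself a border node rooting the
`(b,c)` cherry.

The unrooted cost then decomposes per star: `λ̂` (leaf terms), `γ̂`
(non-root split terms), `σ` (root-split correction) and the per-tree
constant `ε` (`1` for D, `0` for DC, `1 − |V_G| + ω` for L/DL, with
`|V_G|` the node count of a *rooting* of `G`). `solveUnrooted()` runs, for
every one of the `2^{n−1} − 1` top-splits, a subset recurrence `Υ`
restricted to subsets of one side (singletons take `λ̂` sums; larger sets
minimize over sub-splits adding `γ̂` sums), joins the two sides with the
`σ` correction at the root, and takes the best top-split plus `ε`.

### The σ reconstruction

The per-star root correction for D is: `+1` for every S4/S5 star; for a
non-degenerate S2 star, `−(1 + [|A| = 1])/2`; `0` otherwise, where an S2
star is *degenerate* when `B = C` is a single species (a configuration that
requires duplicate gene labels). This is the unique per-star form that pays
back the `ε = 1` over-count in each of the three S2 configurations (one
singleton-`A` star: `−1`; a singleton-`A` star paired with a degenerate
partner: `−1 + 0`; a non-degenerate pair: `−1/2 − 1/2`) while charging one
root duplication per plateau-interior star. Because this form is a
reconstruction, the package treats the brute-force rooting oracle as the
gate: the identity `pairwise cost = min over rootings` is asserted on 500
seeded random pairs per run, duplicate-label trees included, for all four
costs.

### Numerical choices

* The S2 terms of `γ̂`(DC) and `σ`(D) are exact halves; they are accumulated
  in doubles, which represent dyadic rationals exactly, and every final
  cost is integral.
* Comparisons in the DP use an `1e-9` slack purely to collect ties; all
  quantities are exact multiples of `1/2`, so the slack can never merge
  distinct values.
* Tie-breaking is deterministic: `want = "one_tree"` follows the
  lexicographically smallest argmin sub-split at every node and the
  smallest optimal top-split; `want = "all_trees"` expands every argmin.
* The DC-type `γ̂` depends on a split only through its union, so it is
  hoisted out of the sub-split minimization; only the D-type term is
  evaluated per sub-split, after filtering stars whose `B ∪ C` fits the
  current subset. This is what makes `n = 8, k = 100` solve in about a
  second.
* Resource caps fail fast with explicit errors: `max_taxa = 16` for the
  rooted solver (a `2^n` table), `max_taxa = 14` for the unrooted solver
  (work grows as `4^n`), 8 labels for species-tree enumeration,
  `max_combinations` for the naive baseline.
* Degenerate inputs are rejected with messages, not silently repaired:
  polytomies in rooted trees, duplicate species-tree labels, incomplete
  gene trees in the complete-input solvers, fewer than 3 distinct labels.

## Incomplete gene trees

When `L(G) ⊂ L(S)`, two pairwise costs are provided. The *general* method
replaces the top-split by the *rooting split* — the unique split of `S`
whose union covers `L(G)` with both sides met — and evaluates the same
contribution sums; splits of `S` disjoint from or above the rooting split
contribute zero, which the oracle tests confirm. The *minus* method instead
restricts `S` to `L(G)` (suppressing degree-1/2 nodes) and applies the
complete-tree identity; it is a genuinely different cost. Median inference
itself is implemented for complete collections only; the τ-parameterized DP
for incomplete collections is out of scope.

## The simulator: what it emulates and what it does not

`makeDataset(n, k, seed)` draws `k` independent topology-level pure-birth
(Yule) trees — start from a cherry, repeatedly split a uniformly chosen
extant leaf, permute the labels — and suppresses the roots, matching the
generating conditions of the scalability and accuracy experiments (which
used `n` up to 11 with `k = 20` and `k = 100`). Branch lengths are never
generated because every cost is topology-only. The simulated trees are
*species-tree-free*: they are not generated by duplication/loss or
coalescent processes inside a true species tree, carry no duplicate labels,
and have no missing taxa. A green test on this world therefore certifies
algorithmic correctness and scaling claims, not biological calibration;
duplicate-label and incomplete-tree behavior is exercised by separate
randomized tests that relabel and subsample.

## The heuristic

`localSearch()` is a steepest-descent rooted-NNI search: all neighbors are
scored with the exact collection objective, the best strictly improving
neighbor is taken (ties broken uniformly at random), and the search stops
at a local optimum, so trajectories are strictly decreasing and final costs
never undercut the exact optimum. The descent rule (steepest vs first
improvement) is not dictated by the published description of the reference
heuristic; steepest descent with seeded tie-breaking was chosen for
determinism, and accuracy claims are therefore qualitative. Starting trees
are drawn from the same Yule generator (*random mode*); the cluster-based
starting mode is out of scope. `accuracyExperiment()` reports, per dataset,
the fraction of runs attaining the exact optimum; at desk scale (200 runs,
3 datasets per condition) mean accuracy drops from roughly 0.5–0.7 at
`n = 5` to below 0.1 at `n = 8` for both D and DL — the deterioration the
exact solver exists to expose — with run-to-run variability that makes the
individual percentages, unlike the trend, not a stable quantity.

## Known limitations

* The unrooted solver enumerates all top-splits; beyond ~14 taxa the `4^n`
  work is prohibitive. Cluster-constrained search and bit-parallel DP
  encodings are deliberately not implemented.
* Only binary trees are supported; polytomous gene trees must be resolved
  upstream.
* The minus method is provided as a pairwise cost only, not as a median
  objective.
* `Inf` never appears in results: infeasible requests fail fast instead.

```{r example}
library(urmedian)
ds <- makeDataset(n = 6, k = 10, seed = 42)
solveUnrooted(ds$trees, cost = "DL", want = "all_trees")
```
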