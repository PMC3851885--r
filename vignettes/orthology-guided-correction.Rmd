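---
title: "Orthology-guided correction of reconciled gene trees: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Orthology-guided correction of reconciled gene trees: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orthofix)
```

## The problem

A reconciled gene tree implies, for every pair of genes, whether they are
orthologs (their last common ancestor is a speciation) or paralogs (a
duplication).  Independent evidence — above all conserved gene order — often
contradicts those implications: a pair the tree shows as paralogous sits in
regions whose neighbouring genes are clearly orthologous, or a duplication
node is "dubious" because no living species witnesses it.  `orthofix` edits
the gene tree as little as possible, under the rooted Robinson–Foulds (RF)
distance, so that such external orthology evidence is respected.

Two constraint languages are supported:

* **Pair constraints** (`correct_goc()`): a set *P* of gene pairs that must
  be orthologous in the corrected tree.  A correction always exists.
* **Clade constraints** (`correct_coc()`): a set *C* of clades of the input
  tree whose root must become a speciation node.  A correction exists iff
  every constrained clade maps to an internal species and no two
  overlapping constrained clades map to the same species
  (`coc_feasible()`).

The two problems genuinely differ: on the packaged `fig1` fixture the pair
optimum is at RF 2 from the input while the clade optimum is at RF 4.

## Model and conventions

All trees are rooted; the species tree and all top-level gene-tree inputs
must be binary (a trifurcating root is taken as a sign of an unrooted tree
and rejected).  Reconciliation is by lowest common ancestors: every
gene-tree node is assigned the species-tree node `s(g)` spanning the
species of its descendant genes, and an internal node is a *duplication*
exactly when it shares its species with one of its children, a *speciation*
otherwise.  The rooted RF distance between two trees on the same leaves is
the size of the symmetric difference of their clade sets — twice the number
of clades of one tree missing from the other, hence always even.

Branch lengths are read and ignored, and never written: the corrections
move subtrees, which makes input lengths meaningless.  Internal node labels
are kept on inputs (they are convenient handles for nodes) but dropped from
corrected trees for the same reason.  All outputs are canonicalised —
children ordered by their smallest descendant leaf label in the C locale —
so equal topologies serialise to byte-identical Newick.

Nodes are addressed throughout by their *clade key*, the sorted
comma-joined leaf labels below them; in a tree without unary nodes this is
a unique, serialisation-stable identifier, which is why constraint files
survive re-parsing.

## The pair correction

For an ordered pair (a, b) required to be orthologous, with `r = lca(a,b)`
and `s_ab = lca_S(s(a), s(b))`, the *movable apex* `h_(a,b)` is the highest
node on the path from `a` towards `r` whose species maps **strictly** below
`s_ab`.  The strict reading matters: with the non-strict one the apex of the
packaged `fig2` example would land one node higher (on a node mapping to
`s_ab` itself) and the RF = 2·|H| accounting below would break.
Nodes strictly between an apex and its `r`, over all ordered false-paralog
pairs, form the *forbidden set* H: no tree satisfying the constraints can
keep their clades.  Every other node is *preservable* and provably keeps
its clade, so the optimal correction is at RF exactly `2·|H|`.

The construction recursively re-assembles, at each preservable node, its
highest preservable descendants into a *maximum orthology tree*: each
subtree is grafted immediately above the node carrying its species in a
skeleton copy of the species tree, the skeleton leaves are then removed and
the tree standardized (prune non-extant nodes, contract unary nodes).  Two
subtrees whose root species are unrelated in the species tree always meet
at a speciation in the result.  Design points the construction leaves open,
fixed here once:

* Grafting order: ascending order of each subtree's smallest leaf label.
  The order only moves the output within the RF-equivalent optima; fixing
  it makes runs byte-reproducible.
* Several subtrees with the same species graft successively immediately
  above the same skeleton node, forming a caterpillar.
* The skeleton is always a full copy of the species tree (the construction
  also works from partial skeletons, but the full copy is simpler to reason
  about); the extra leaves are removed by standardization.  Corrected
  subtrees returned by the recursion are scrubbed of any skeleton
  bookkeeping before being grafted again one level up.
* Pairs of *P* that are already orthologous are accepted and re-checked on
  the output; their contribution to H is provably empty, so they never
  cost anything.

## The clade correction

Pushing a constrained duplication `x` (species `s`, species-tree children
`A`, `B`) *by multifurcation* replaces its clade by a speciation joining
two multifurcations: the maximal subtrees of `x` purely below `A`, and
those purely below `B`.  The binary resolutions of the fully pushed tree
are exactly the RF-optimal corrections; `binary_resolutions()` materialises
them for the oracle (refusing, rather than truncating, beyond a
configurable limit).  Pushing *by tree duplication* instead keeps two
pruned copies of the whole subtree — one per side, each standardized — and
is the specific optimal resolution that also shares the maximum number of
rooted triplets with the input; this is what `correct_coc()` applies, in a
canonical (but provably irrelevant) order, re-reconciling after every push
rather than patching annotations incrementally.

For infeasible constraint sets, `mode = "force"` applies the best-effort
heuristic: constraints are processed from the highest nodes down
(decreasing node height, ties broken lexicographically), each pushed if its
clade still exists and is still a duplication, and the outcome of every
constraint is reported.  No optimality is claimed in this mode, and
constraints whose clade was destroyed by an earlier push are reported as
lost rather than silently dropped.  We deliberately do not push
unconstrained ancestor duplications that block a constraint.

A clade constraint whose root is already a speciation is skipped with a
warning rather than rejected: tolerating satisfied constraints keeps
pipelines that regenerate constraint files idempotent.

## Constraints from gene order

`infer_orthology_constraints()` implements the synteny rule used to build
pair constraints: the region of a gene is the 3-gene window of the gene and
its two adjacencies, and two regions are syntenic when their flanks pair up
as homologs position by position.  Flank homology is read off companion
family trees: two flanking genes are orthologous when they are leaves of
one companion tree whose lca there is a speciation.  Windows in reversed
order count as syntenic by default (inversions conserve gene order up to
orientation); `strict = TRUE` disables this.  Both flanks must match — a
single matching adjacency is not accepted — and a gene at a contig end has
no region at all (`status = "incomplete"`), a deliberate conservative
choice.  Genes in syntenic regions are expected to be either all pairwise
orthologous or all pairwise paralogous; the package uses this only to
justify emitting the central pair as a constraint, never as a hard filter.

`flag_non_apparent_duplications()` marks duplication nodes with no extant
same-species witness across their children — the classic "dubious" label —
as natural candidates for clade constraints.

## The simulator and what it does (not) emulate

The duplication–loss generator is deliberately discrete: a lineage entering
a species-tree branch is lost with probability `loss_prob`, duplicates with
probability `dup_prob` (both daughters re-entering the branch), and
otherwise traverses it.  Defaults used by the verification suites are
`dup_prob = 0.2`, `loss_prob = 0.1` on 5–6 species — enough duplication to
make false paralogies common (more than half of the sampled instances have
a non-empty forbidden set) while keeping families small.  Clade-constraint
suites use a slightly duplication-richer regime (`dup_prob = 0.3–0.4`)
because they need duplication nodes to constrain.  The generator produces
exactly the discrete structures the algorithms consume: it does not model
branch lengths, sequence evolution, rate heterogeneity, transfer, or
incomplete lineage sorting.  Consequently the passing suites certify the
combinatorial guarantees of the corrections — cost identity, optimality,
triplet maximality — not that corrected trees are better estimates for any
particular real data set, which is a statistical question outside this
package's scope.

Pair-constraint instances are sampled biased towards duplication-lca pairs
so the constraint sets are usually non-trivial; clade-constraint instances
are rejection-sampled against the feasibility conditions when a feasible
set is required.

## Verification sizes and numerical choices

The test suite and `scripts/acceptance.R` re-derive the guarantees at these
problem sizes, chosen so the exhaustive oracle stays desk-scale (the oracle
enumerates (2n−3)!! topologies — 945 at n = 6 — and reconciles each):

* RF = 2·|H| identity, constraint satisfaction, clade preservation: 200
  simulated instances with 5–20 gene leaves.
* Pair-correction optimality against the oracle: 50 instances with ≤ 6
  leaves.
* Feasibility ↔ exhaustive existence: 50 mixed instances with ≤ 6 leaves.
* Clade-correction optimality, the characterisation of *all* optima as
  binary resolutions of the pushed tree, and triplet maximality: 30
  feasible instances with ≤ 6 leaves.
* Order independence: 20 instances with two feasible clades, five shuffled
  push orders each.

Other fixed numerical choices: the enumeration cap defaults to 8 leaves and
`binary_resolutions()` to 10^6 trees, both erroring rather than truncating;
all seeds derive from a single integer; ties anywhere are broken by the
radix (C-locale) order of labels or clade keys, never by hash or insertion
order.  Degenerate inputs: single-leaf trees parse (flagged) but are
rejected as correction inputs; an empty constraint set returns the input at
RF 0.

## Known limitations

* Only rooted binary species trees and gene trees are corrected;
  multifurcations arise only as internal intermediates of the clade
  correction.
* Minimality is with respect to the rooted clade RF distance; a correction
  minimal here can be large under edit distances such as NNI.
* Paralogy constraints, and mixed orthology/paralogy constraint sets, are
  not supported.
* The corrected tree's duplication count is reported but not optimised;
  duplication/loss-minimal binary resolutions of the pushed tree are a
  known alternative to the triplet-maximal one and are out of scope.

## A worked run

```{r example}
fx <- load_fixture("fig2")
res <- correct_goc(fx$recon, fx$P)
res
res$n_forbidden        # three clades are provably unkeepable ...
res$rf                 # ... and the correction costs exactly twice that
```
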