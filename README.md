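# orthofix

Orthology-guided correction of reconciled gene trees.

A gene tree reconciled with a species tree labels every internal node as a
speciation or a duplication, and thereby declares every pair of genes
orthologous or paralogous. Independent evidence — conserved gene order
above all — frequently contradicts those declarations: a pair shown as
paralogs sits in syntenic regions whose flanking genes are orthologs, or a
duplication node has no extant witness. `orthofix` repairs the tree
instead of discarding it: it computes a corrected tree satisfying the
external orthology evidence that is **as close as possible to the input
under the rooted Robinson–Foulds (RF) distance**, in polynomial time.

It is aimed at people who curate or consume gene-tree databases and
phylogenomic pipelines: the input is ordinary rooted Newick plus a
tab-separated gene–species map, the constraints are small text files, and
the output is again Newick plus a JSON report.

## The two corrections

Write `s(g)` for the species-tree node a gene-tree node maps to under LCA
reconciliation, and `E(g) = duplication` iff `s(g)` equals the species of
one of its children. The rooted RF distance between two trees on the same
leaves is the size of the symmetric difference of their clade sets.

**Pair constraints** (`correct_goc`). Given pairs *P* that must be
orthologous: for each ordered pair (a, b) with `r = lca(a, b)` and
`s_ab = lca_S(s(a), s(b))`, the highest node on the path from `a` to `r`
whose species lies strictly below `s_ab` is the pair's *movable apex*
`h_(a,b)`. The nodes strictly between apexes and their `r`, over all
ordered false-paralog pairs, form the forbidden set *H*: no satisfying
tree can keep their clades, every other clade can be kept, and the
correction built by recursive maximum-orthology-tree assembly achieves

```
RF(G, G_P) = 2 |H|
```

which is therefore optimal. A correction always exists.

**Clade constraints** (`correct_coc`). Given clades *C* of the input that
must be rooted by speciations: a solution exists iff every constrained
clade maps to an internal species and no two overlapping constrained
clades share a species. All optima are exactly the binary resolutions of
the tree obtained by *pushing* each constrained duplication by
multifurcation; pushing by *tree duplication* selects, among those optima,
the one sharing the maximum number of rooted triplets with the input. An
infeasible set can still be processed best-effort with `mode = "force"`.

Around the two corrections the package provides LCA reconciliation
(`reconcile`), rooted RF and shared-triplet comparison, non-apparent
("dubious") duplication flagging, synteny-based constraint inference from
gene orders (`infer_orthology_constraints`), exhaustive brute-force
oracles that certify the optimality claims on small instances, and seeded
duplication–loss simulators.

## A worked example

The packaged `fig2` fixture is a six-gene family over three species with
three required-ortholog pairs, two of which the input tree contradicts:

```r
library(orthofix)
fx  <- load_fixture("fig2")      # species tree ((A,B)D,C)E, six genes
res <- correct_goc(fx$recon, fx$P)
res
#> GOC correction: RF to input = 6 (3 clades lost)
#>   constraints: 3 pairs, 2 false paralogs, |H| = 3
#>   duplications: 2 -> 3
#>   corrected:  (((a1,(b1,b2)),b3),(c1,c2));
```

Reading the report: of the three constrained pairs, two are false
paralogs (their lca in the input is a duplication). Exactly three nodes of
the input — the forbidden set H, here the nodes labelled `e1`, `e2`, `d1`
— cannot survive in any satisfying tree, and the corrected tree loses
exactly those three clades: its RF distance to the input is 2·|H| = 6, the
proven minimum. Every other clade of the input reappears in the corrected
tree, and all three pairs are orthologous in it.

The same instance from the shell:

```sh
inst/scripts/orthofix goc \
  -g inst/extdata/fig2/gene.nwk  -s inst/extdata/fig2/species.nwk \
  -m inst/extdata/fig2/map.tsv   -p inst/extdata/fig2/pairs.tsv \
  -o corrected.nwk --report report.json
#> goc: |P|=3 |P_f|=2 |H|=3 RF=6 -> corrected.nwk
```

Subcommands: `goc`, `coc`, `infer-constraints`, `simulate`, `compare`,
`verify` (run `inst/scripts/orthofix help` for the flags).

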