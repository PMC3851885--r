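# Shared helpers: compact tree builders and seeded instance batches.

nwk <- function(text, ...) parse_newick(text, ...)

# a reconciled toy instance in one call; species read from the first letter
# of each gene label
toy_recon <- function(gene_newick, species_newick) {
  g <- nwk(gene_newick)
  s <- nwk(species_newick)
  map <- map_from_regex(tree_leaves(g), "^([a-z]+)[0-9]*$")
  map[] <- toupper(map)
  reconcile(g, s, map)
}

goc_batch <- function(n, min_l, max_l, seed, ...) {
  orthofix:::collect_goc_instances(n, min_l, max_l, seed = seed, ...)
}

coc_batch <- function(n, min_l, max_l, seed, ...) {
  orthofix:::collect_coc_instances(n, min_l, max_l, seed = seed, ...)
}

canon <- function(tree) write_newick(rt_canonical(tree))
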