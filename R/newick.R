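# Newick I/O, delegated to ape for the grammar.

#' Parse a rooted Newick string
#'
#' Branch lengths are accepted and discarded (topology corrections invalidate
#' them); internal node labels are kept.  Trees must be rooted: a
#' trifurcating root is accepted by the grammar but rejected when
#' `check_binary = TRUE`, which is what every top-level algorithm input uses.
#'
#' @param text a Newick string (single tree).
#' @param check_binary require every internal node, root included, to have
#'   exactly two children.  A trifurcating root usually denotes an unrooted
#'   tree, which this package does not handle.
#' @return an [rt_leaf()]/[rt_node()] tree of class `rtree`.  A single-leaf
#'   tree is allowed but carries `attr(, "degenerate") = TRUE`; if branch
#'   lengths were present, `attr(, "had_branch_lengths") = TRUE` records that
#'   they were read and dropped.
#' @export
parse_newick <- function(text, check_binary = FALSE) {
  stopifnot(is.character(text), length(text) == 1L)
  txt <- trimws(text)
  if (!nzchar(txt)) stop("empty Newick string")
  # locate unbalanced parentheses before handing to ape, to report an offset
  depth <- 0L
  chars <- strsplit(txt, "", fixed = TRUE)[[1]]
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) stop("malformed Newick: unmatched ')' at character ", i)
    }
  }
  if (depth != 0L) {
    stop("malformed Newick: ", depth, " unclosed '(' at end of string")
  }

  # a bare label is a degenerate single-leaf tree ape cannot represent
  if (grepl("^[^(),;:[:space:]]+(:[0-9.eE+-]+)?;?$", txt)) {
    lab <- sub(":.*$", "", sub(";$", "", txt))
    out <- rt_leaf(lab)
    attr(out, "degenerate") <- TRUE
    return(out)
  }

  ph <- tryCatch(ape::read.tree(text = txt),
                 error = function(e) NULL, warning = function(w) NULL)
  if (is.null(ph)) stop("malformed Newick string: ", txt)
  if (any(is.na(ph$tip.label)) || any(!nzchar(ph$tip.label))) {
    stop("malformed Newick string (empty or missing leaf label): ", txt)
  }
  tree <- phylo_to_rtree(ph)
  validate_rtree(tree)
  if (!is.null(ph$edge.length)) attr(tree, "had_branch_lengths") <- TRUE
  if (is_leaf(tree)) attr(tree, "degenerate") <- TRUE
  if (check_binary && !is_binary_tree(tree)) {
    k <- length(tree$children)
    if (k > 2L) {
      stop("tree root has ", k, " children; the input looks unrooted. ",
           "Root the tree: all inputs must be rooted and binary.")
    }
    stop("tree is not binary: a multifurcating internal node was found")
  }
  tree
}

# ape phylo -> rtree
#' @noRd
phylo_to_rtree <- function(ph) {
  ntip <- length(ph$tip.label)
  nlab <- ph$node.label
  kids <- split(ph$edge[, 2L], ph$edge[, 1L])
  build <- function(id) {
    if (id <= ntip) return(rt_leaf(ph$tip.label[id]))
    lab <- if (!is.null(nlab)) {
      l <- nlab[id - ntip]
      if (is.na(l) || !nzchar(l)) NULL else l
    } else NULL
    ch <- lapply(kids[[as.character(id)]], build)
    if (length(ch) == 1L) return(ch[[1L]])  # contract a degree-1 (root) node
    rt_node(ch, label = lab)
  }
  build(ntip + 1L)
}

#' Serialise a tree to canonical Newick
#'
#' Children are ordered by smallest descendant leaf label, so output is
#' deterministic: equal topologies give byte-identical strings.  Branch
#' lengths are never written.
#'
#' @param tree an `rtree`.
#' @param internal_labels write internal node labels when present.
#' @return a Newick string ending in ";".
#' @export
write_newick <- function(tree, internal_labels = TRUE) {
  tree <- rt_canonical(tree)
  ser <- function(node) {
    if (is_leaf(node)) return(node$label)
    inner <- paste(vapply(node$children, ser, character(1)), collapse = ",")
    lab <- if (internal_labels && !is.null(node$label)) node$label else ""
    paste0("(", inner, ")", lab)
  }
  paste0(ser(tree), ";")
}
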