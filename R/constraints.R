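# Building orthology constraints from external evidence: non-apparent
# duplication flags and synteny (conserved gene order).

#' Flag non-apparent duplications
#'
#' A duplication node is "non-apparent" (dubious, in database parlance) when
#' no extant species is represented on both sides of it: nothing in the
#' living data witnesses the duplication, only the incongruence with the
#' species tree does.  Such nodes are natural candidates for clade
#' constraints.
#'
#' @param recon a `recon` object.
#' @return character vector of clade keys of the flagged nodes.
#' @export
flag_non_apparent_duplications <- function(recon) {
  out <- character(0)
  rec <- function(node) {
    if (is_leaf(node)) return(invisible())
    k <- clade_key(tree_leaves(node))
    if (identical(recon$event[[k]], "duplication")) {
      sp_sets <- lapply(node$children, function(ch)
        unique(unname(recon$map[tree_leaves(ch)])))
      witnessed <- FALSE
      for (i in seq_along(sp_sets)[-1L]) for (j in seq_len(i - 1L)) {
        if (length(intersect(sp_sets[[i]], sp_sets[[j]])) > 0L) {
          witnessed <- TRUE
        }
      }
      if (!witnessed) out <<- c(out, k)
    }
    for (ch in node$children) rec(ch)
  }
  rec(recon$tree)
  lsort(out)
}

#' Read gene orders
#'
#' Tab-separated columns `genome`, `seq`, `position`, `gene`: one row per
#' gene, positions defining the order along each sequence
#' (chromosome/scaffold).  Gene labels must be unique within a genome.
#'
#' @param path file path, or a data.frame with those four columns.
#' @return an object of class `gene_orders`.
#' @export
read_gene_orders <- function(path) {
  tab <- if (is.data.frame(path)) path else
    utils::read.table(path, header = FALSE, sep = "\t", comment.char = "#",
                      col.names = c("genome", "seq", "position", "gene"),
                      colClasses = c("character", "character", "numeric",
                                     "character"))
  stopifnot(all(c("genome", "seq", "position", "gene") %in% names(tab)))
  for (g in unique(tab$genome)) {
    genes <- tab$gene[tab$genome == g]
    if (anyDuplicated(genes)) {
      stop("duplicate gene labels in genome ", g, ": ",
           paste(unique(genes[duplicated(genes)]), collapse = ", "))
    }
  }
  tab <- tab[order(tab$genome, tab$seq, tab$position, method = "radix"), ]
  structure(list(table = tab), class = "gene_orders")
}

# genome of a gene, and its left/right adjacencies (NA at a contig end)
#' @noRd
gene_window <- function(orders, gene) {
  tab <- orders$table
  i <- which(tab$gene == gene)
  if (length(i) == 0L) return(NULL)
  i <- i[1L]
  same <- tab$genome == tab$genome[i] & tab$seq == tab$seq[i]
  block <- which(same)
  pos <- match(i, block)
  list(genome = tab$genome[i],
       left = if (pos > 1L) tab$gene[block[pos - 1L]] else NA_character_,
       right = if (pos < length(block)) tab$gene[block[pos + 1L]] else
         NA_character_)
}

#' Synteny test between the regions of two genes
#'
#' The region around a gene is the 3-gene window of the gene and its left
#' and right adjacencies.  Two regions are syntenic when the flanking genes
#' pair up as homologs position by position; by default a reversed window
#' also counts (an inversion conserves synteny), `strict = TRUE` demands the
#' same orientation.
#'
#' @param orders a `gene_orders` object covering both genomes.
#' @param g1,g2 gene labels in different genomes.
#' @param homology a predicate `function(a, b)` returning `TRUE` when genes
#'   `a` and `b` are homologous (typically: orthologous in their family's
#'   tree, see [infer_orthology_constraints()]).
#' @param strict require the flanks to match in the same order.
#' @return logical; `attr(, "status")` is `"syntenic"`, `"no_match"`, or
#'   `"incomplete"` when either gene lacks an adjacency (region undefined).
#' @export
syntenic_regions <- function(orders, g1, g2, homology, strict = FALSE) {
  w1 <- gene_window(orders, g1); w2 <- gene_window(orders, g2)
  if (is.null(w1) || is.null(w2)) {
    stop("gene absent from the gene orders: ",
         if (is.null(w1)) g1 else g2)
  }
  if (identical(w1$genome, w2$genome)) {
    stop("genes ", g1, " and ", g2, " are in the same genome")
  }
  res <- function(value, status) structure(value, status = status)
  if (anyNA(c(w1$left, w1$right, w2$left, w2$right))) {
    return(res(FALSE, "incomplete"))
  }
  same <- homology(w1$left, w2$left) && homology(w1$right, w2$right)
  rev <- !strict && homology(w1$left, w2$right) && homology(w1$right, w2$left)
  if (same || rev) res(TRUE, "syntenic") else res(FALSE, "no_match")
}

#' Infer orthology constraints from conserved gene order
#'
#' Emits the pairs of target-family genes whose surrounding regions are
#' syntenic, flank homology being read off the companion families' trees: two
#' flanking genes are treated as orthologous when they are leaves of the
#' same companion tree and their lca there is a speciation.  Genes in two
#' syntenic regions are expected to be orthologous, so each such central
#' pair becomes a constraint; with `only_false_paralogs = TRUE` the pairs
#' the target tree already shows as orthologous are dropped, leaving only
#' the contradictions.
#'
#' @param orders a `gene_orders` object.
#' @param trees list of `recon` objects for the companion (flanking) gene
#'   families.
#' @param target `recon` of the family to be corrected.
#' @param only_false_paralogs drop pairs already orthologous in `target`.
#' @param strict passed to [syntenic_regions()].
#' @return a 2-column matrix of gene pairs, valid as a constraint set for
#'   `target` (possibly empty).  Target genes absent from `orders` are
#'   skipped with a warning.
#' @export
infer_orthology_constraints <- function(orders, trees, target,
                                        only_false_paralogs = FALSE,
                                        strict = FALSE) {
  hom <- function(a, b) {
    for (r in trees) {
      lv <- tree_leaves(r$tree)
      if (a %in% lv && b %in% lv) return(is_orthologous(r, a, b))
    }
    FALSE
  }
  lv <- lsort(tree_leaves(target$tree))
  placed <- vapply(lv, function(g) !is.null(gene_window(orders, g)),
                   logical(1))
  if (any(!placed)) {
    warning("target genes absent from the gene orders, skipped: ",
            paste(lv[!placed], collapse = ", "))
    lv <- lv[placed]
  }
  out <- NULL
  if (length(lv) >= 2L) {
    prs <- utils::combn(lv, 2L)
    for (i in seq_len(ncol(prs))) {
      g1 <- prs[1L, i]; g2 <- prs[2L, i]
      if (target$map[[g1]] == target$map[[g2]]) next
      if (!identical(gene_window(orders, g1)$genome,
                     gene_window(orders, g2)$genome)) {
        if (isTRUE(as.logical(syntenic_regions(orders, g1, g2, hom,
                                               strict = strict)))) {
          if (only_false_paralogs && is_orthologous(target, g1, g2)) next
          out <- rbind(out, c(g1, g2))
        }
      }
    }
  }
  if (is.null(out)) {
    return(matrix(character(0), ncol = 2L,
                  dimnames = list(NULL, c("g1", "g2"))))
  }
  colnames(out) <- c("g1", "g2")
  as_pairs(out)
}
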