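# Readers and writers for the plain-text exchange formats.

#' Read a gene-species map
#'
#' Two tab-separated columns `gene<TAB>species`; `#` starts a comment.
#'
#' @param path file path.
#' @return named character vector: gene label -> species label.
#' @export
read_gene_species_map <- function(path) {
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
                           comment.char = "#",
                           col.names = c("gene", "species"),
                           colClasses = "character")
  if (anyDuplicated(tab$gene)) {
    stop("duplicate genes in map: ",
         paste(unique(tab$gene[duplicated(tab$gene)]), collapse = ", "))
  }
  stats::setNames(tab$species, tab$gene)
}

#' Derive a gene-species map from leaf names
#'
#' Applies a regular expression with one capturing group to each gene label;
#' the captured text is the species label.
#'
#' @param genes character vector of gene labels.
#' @param regex a regex with exactly one capturing group, e.g.
#'   `"^([a-z]+)[0-9]+$"`.
#' @return named character vector.
#' @export
map_from_regex <- function(genes, regex) {
  m <- regmatches(genes, regexec(regex, genes))
  bad <- lengths(m) < 2L
  if (any(bad)) {
    stop("regex did not capture a species for: ",
         paste(genes[bad], collapse = ", "))
  }
  stats::setNames(vapply(m, `[`, character(1), 2L), genes)
}

#' Read / write orthology pair constraints
#'
#' Two tab-separated gene labels per line; `#` starts a comment.
#'
#' @param path file path.
#' @return a 2-column character matrix.
#' @export
read_orthology_pairs <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) {
    return(matrix(character(0), ncol = 2L,
                  dimnames = list(NULL, c("g1", "g2"))))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) != 2L)) {
    stop("each line must have exactly two tab-separated gene labels")
  }
  as_pairs(do.call(rbind, parts))
}

#' @rdname read_orthology_pairs
#' @param P a 2-column matrix of pairs.
#' @export
write_orthology_pairs <- function(P, path) {
  P <- as_pairs(P)
  writeLines(paste(P[, 1L], P[, 2L], sep = "\t"), path)
  invisible(path)
}

#' Read clade constraints
#'
#' One clade per line as comma-separated gene labels; `#` starts a comment.
#'
#' @param path file path.
#' @return a list of character vectors.
#' @export
read_clade_constraints <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  lapply(lines, function(l) lsort(trimws(strsplit(l, ",", fixed = TRUE)[[1]])))
}

#' @rdname read_clade_constraints
#' @param C a list of leaf-label vectors.
#' @export
write_clade_constraints <- function(C, path) {
  writeLines(vapply(as_clades(C), paste, character(1), collapse = ","), path)
  invisible(path)
}
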