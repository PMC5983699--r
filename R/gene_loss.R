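# Gene presence/absence accounting across species and monophyly of losses.
#
# A gene is "present" in a species iff a non-pseudo feature with that
# normalized name exists; pseudogenes count as losses (non-functional copies
# are treated as absent, as in gene-loss tables for IRLC legumes).

#' Build a species x gene presence/absence matrix
#'
#' @param records list of [plastome_record()]s
#' @param gene_panel optional character vector of gene names (defaults to
#'   the union of observed non-pseudo genes across records, in order of
#'   first appearance)
#' @return logical matrix (TRUE = present) with species rows, gene columns
#' @export
build_presence_matrix <- function(records, gene_panel = NULL) {
  ids <- vapply(records, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("duplicate species ids: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  observed <- lapply(records, function(r) {
    feats <- Filter(function(f) !f$pseudo, r$features)
    unique(normalize_gene_name(vapply(feats, `[[`, character(1), "name")))
  })
  if (is.null(gene_panel)) gene_panel <- unique(unlist(observed))
  gene_panel <- as.character(normalize_gene_name(gene_panel))
  m <- matrix(FALSE, nrow = length(records), ncol = length(gene_panel),
              dimnames = list(unname(ids), unname(gene_panel)))
  for (i in seq_along(observed)) m[i, ] <- gene_panel %in% observed[[i]]
  m
}

#' Count species lacking each gene
#'
#' Column-wise count of absences in a presence matrix.
#'
#' @param matrix logical presence matrix from [build_presence_matrix()] or
#'   [read_presence_matrix()]
#' @return named integer vector of loss counts per gene
#' @export
loss_counts <- function(matrix) {
  counts <- colSums(!matrix)
  storage.mode(counts) <- "integer"
  counts
}

#' Read a presence/absence matrix from TSV ("+" present, "-" absent)
#'
#' First column: species names; remaining columns: genes. Both an ASCII
#' hyphen and a Unicode minus are accepted for absence.
#'
#' @param path TSV path
#' @return logical presence matrix
#' @export
read_presence_matrix <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                   fileEncoding = "UTF-8")
  species <- df[[1]]
  m <- as.matrix(df[, -1, drop = FALSE])
  pres <- m == "+"
  abs_ <- m == "-" | m == "−"
  if (any(!pres & !abs_)) stop("presence matrix cells must be '+' or '-'")
  dimnames(pres) <- list(species, colnames(m))
  pres
}

#' Write a presence/absence matrix as TSV ("+"/"-")
#'
#' @param matrix logical presence matrix
#' @param path output path
#' @return invisibly, the path
#' @export
write_presence_matrix <- function(matrix, path) {
  df <- data.frame(species = rownames(matrix),
                   ifelse(matrix, "+", "-"), check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# All non-trivial bipartitions of an unrooted tree: for each internal edge,
# the tip labels on the child side.
tree_bipartition_sides <- function(tree) {
  nt <- length(tree$tip.label)
  sides <- list()
  for (e in seq_len(nrow(tree$edge))) {
    child <- tree$edge[e, 2]
    tips <- tips_below(tree, child)
    sides[[length(sides) + 1]] <- tree$tip.label[tips]
  }
  sides
}

tips_below <- function(tree, node) {
  nt <- length(tree$tip.label)
  if (node <= nt) return(node)
  out <- integer(0)
  stack <- node
  while (length(stack)) {
    nd <- stack[length(stack)]
    stack <- stack[-length(stack)]
    kids <- tree$edge[tree$edge[, 1] == nd, 2]
    tips <- kids[kids <= nt]
    out <- c(out, tips)
    stack <- c(stack, kids[kids > nt])
  }
  out
}

setequal_strict <- function(a, b) length(a) == length(b) && setequal(a, b)

#' Is a gene's loss pattern monophyletic on a tree?
#'
#' A loss set is monophyletic iff the absent species form exactly one side of
#' one edge of the unrooted tree (the result is invariant to re-rooting).
#' Losses in no species or in all species are trivially monophyletic and
#' flagged. Otherwise, when not monophyletic, the minimal exception set is
#' reported: the smallest symmetric difference between the absent set and any
#' edge side.
#'
#' @param tree an `ape::phylo` tree whose leaf set covers the matrix species
#' @param matrix logical presence matrix
#' @param gene gene name (must be a matrix column)
#' @return list with `monophyletic`, `exceptions` (species names), `trivial`
#' @export
loss_monophyly <- function(tree, matrix, gene) {
  if (!(gene %in% colnames(matrix))) stop("gene not in matrix: ", gene)
  species <- rownames(matrix)
  if (!all(species %in% tree$tip.label)) {
    stop("tree leaf set does not cover matrix species")
  }
  if (length(setdiff(tree$tip.label, species))) {
    tree <- ape::keep.tip(tree, species)
  }
  absent <- species[!matrix[, gene]]
  if (length(absent) == 0 || length(absent) == length(species)) {
    return(list(monophyletic = TRUE, exceptions = character(0), trivial = TRUE))
  }
  sides <- tree_bipartition_sides(tree)
  best <- NULL
  best_size <- Inf
  for (s in sides) {
    for (cand in list(s, setdiff(species, s))) {
      if (setequal_strict(cand, absent)) {
        return(list(monophyletic = TRUE, exceptions = character(0),
                    trivial = FALSE))
      }
      exc <- union(setdiff(cand, absent), setdiff(absent, cand))
      if (length(exc) < best_size) {
        best <- exc
        best_size <- length(exc)
      }
    }
  }
  list(monophyletic = FALSE, exceptions = sort(best), trivial = FALSE)
}
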