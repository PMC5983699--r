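# Distance-based phylogeny: p-distances on concatenated alignments,
# neighbor-joining (ape backend, negative branch lengths clamped), column
# bootstrap, and bipartition-based monophyly checks.

#' p-distance matrix on concatenated locus alignments
#'
#' Concatenates the per-locus alignments (each a named character vector of
#' equal-length gapped sequences over the same taxa) and returns the pairwise
#' proportion of differing columns among columns where both taxa have an
#' unambiguous base (pairwise deletion).
#'
#' @param alignments_by_locus list of named character vectors
#' @return symmetric numeric matrix with zero diagonal
#' @export
concat_distance_matrix <- function(alignments_by_locus) {
  stopifnot(length(alignments_by_locus) >= 1)
  taxa <- sort(names(alignments_by_locus[[1]]))
  for (loc in alignments_by_locus) {
    if (!setequal(names(loc), taxa)) {
      stop("taxon missing from a locus: all loci must cover the same taxa")
    }
    stopifnot(length(unique(nchar(loc))) == 1)
  }
  concat <- vapply(taxa, function(tx) {
    collapse0(vapply(alignments_by_locus, function(loc) loc[[tx]], character(1)))
  }, character(1))
  n <- length(taxa)
  d <- matrix(0, n, n, dimnames = list(taxa, taxa))
  mats <- lapply(concat, function(s) chars(toupper(s)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      a <- mats[[i]]; b <- mats[[j]]
      ok <- a %in% DNA_BASES & b %in% DNA_BASES
      d[i, j] <- d[j, i] <- if (any(ok)) sum(a[ok] != b[ok]) / sum(ok) else NA_real_
    }
  }
  d
}

#' Neighbor-joining tree
#'
#' Standard NJ agglomeration (ape backend) on a symmetric distance matrix.
#' Negative branch lengths are clamped to zero with the deficit transferred
#' to the sibling edge, a common reporting convention.
#'
#' @param d symmetric distance matrix with zero diagonal, n >= 3 taxa
#' @return an unrooted `ape::phylo` tree
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  stopifnot(nrow(d) == ncol(d))
  if (nrow(d) < 3) stop("need at least 3 taxa")
  stopifnot(max(abs(d - t(d))) < 1e-12, all(diag(d) == 0))
  tr <- ape::nj(d)
  # clamp negative branch lengths, moving the deficit to the sibling edge
  repeat {
    neg <- which(tr$edge.length < -1e-12)
    if (!length(neg)) break
    e <- neg[1]
    parent <- tr$edge[e, 1]
    sibs <- setdiff(which(tr$edge[, 1] == parent), e)
    if (length(sibs)) {
      tr$edge.length[sibs[1]] <- tr$edge.length[sibs[1]] + tr$edge.length[e]
    }
    tr$edge.length[e] <- 0
  }
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Bootstrap support for a reference tree
#'
#' Resamples alignment columns with replacement, rebuilds an NJ tree per
#' replicate from p-distances, and maps bipartition frequencies (percent)
#' onto the internal edges of the reference tree. Reproducible under a fixed
#' seed.
#'
#' @param alignments_by_locus list of named character vectors (as for
#'   [concat_distance_matrix()])
#' @param tree reference `phylo` tree (e.g. from [nj_tree()])
#' @param n_reps number of bootstrap replicates
#' @param seed integer seed
#' @return `tree` with `node.label` set to support percentages (internal
#'   nodes; the root label is NA)
#' @export
bootstrap_support <- function(alignments_by_locus, tree, n_reps = 100,
                              seed = 1) {
  if (n_reps < 1) stop("n_reps must be >= 1")
  set.seed(seed)
  taxa <- sort(names(alignments_by_locus[[1]]))
  concat <- vapply(taxa, function(tx) {
    collapse0(vapply(alignments_by_locus, function(loc) loc[[tx]], character(1)))
  }, character(1))
  cm <- do.call(rbind, lapply(concat, function(s) chars(toupper(s))))
  rownames(cm) <- taxa
  ncol_ <- ncol(cm)
  n <- nrow(cm)

  ref_keys <- bipartition_keys(tree)
  counts <- setNames(numeric(length(ref_keys)), ref_keys)
  for (rep_i in seq_len(n_reps)) {
    idx <- sample.int(ncol_, ncol_, replace = TRUE)
    sub <- cm[, idx, drop = FALSE]
    d <- matrix(0, n, n, dimnames = list(taxa, taxa))
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        a <- sub[i, ]; b <- sub[j, ]
        ok <- a %in% DNA_BASES & b %in% DNA_BASES
        d[i, j] <- d[j, i] <- if (any(ok)) sum(a[ok] != b[ok]) / sum(ok) else 0
      }
    }
    bt <- nj_tree(d)
    for (key in bipartition_keys(bt)) {
      if (key %in% names(counts)) counts[key] <- counts[key] + 1
    }
  }
  support <- round(100 * counts / n_reps)
  # map supports onto internal nodes
  nt <- length(tree$tip.label)
  n_nodes <- tree$Nnode
  labels <- rep(NA_character_, n_nodes)
  for (e in seq_len(nrow(tree$edge))) {
    child <- tree$edge[e, 2]
    if (child <= nt) next
    key <- edge_key(tree, e)
    if (key %in% names(support)) {
      labels[child - nt] <- as.character(support[[key]])
    }
  }
  tree$node.label <- labels
  tree
}

# Canonical key of the bipartition induced by edge e: the sorted side not
# containing the alphabetically first taxon.
edge_key <- function(tree, e) {
  all_tips <- sort(tree$tip.label)
  side <- tree$tip.label[tips_below(tree, tree$edge[e, 2])]
  if (all_tips[1] %in% side) side <- setdiff(all_tips, side)
  paste(sort(side), collapse = "|")
}

bipartition_keys <- function(tree) {
  nt <- length(tree$tip.label)
  keys <- character(0)
  for (e in seq_len(nrow(tree$edge))) {
    child <- tree$edge[e, 2]
    if (child <= nt) next  # trivial bipartition
    keys <- c(keys, edge_key(tree, e))
  }
  unique(keys)
}

#' Test monophyly of a taxon set on an unrooted tree
#'
#' TRUE iff some edge of the tree separates exactly `taxa` from the rest
#' (equivalently, the set or its complement is one side of one bipartition;
#' the complement of a clade is itself monophyletic on an unrooted tree).
#'
#' @param tree `ape::phylo`
#' @param taxa character vector of tip labels
#' @return logical
#' @export
is_monophyletic <- function(tree, taxa) {
  if (!all(taxa %in% tree$tip.label)) {
    stop("unknown taxon: ", paste(setdiff(taxa, tree$tip.label), collapse = ", "))
  }
  all_tips <- tree$tip.label
  if (length(taxa) %in% c(0, 1, length(all_tips) - 1, length(all_tips))) {
    return(TRUE)  # trivial splits always exist
  }
  for (e in seq_len(nrow(tree$edge))) {
    side <- all_tips[tips_below(tree, tree$edge[e, 2])]
    if (setequal_strict(side, taxa) ||
        setequal_strict(setdiff(all_tips, side), taxa)) {
      return(TRUE)
    }
  }
  FALSE
}
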