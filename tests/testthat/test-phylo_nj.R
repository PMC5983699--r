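test_that("p-distances on concatenations behave like length-weighted locus means", {
  ident <- list(l1 = c(A = "ACGT", B = "ACGT", C = "ACGT"))
  expect_true(all(concat_distance_matrix(ident) == 0))

  two <- list(l1 = c(A = "AAAAAAAAAA", B = "AAACCCAAAT"))
  expect_equal(concat_distance_matrix(two)["A", "B"], 0.4)

  set.seed(90)
  loci <- list(
    l1 = c(A = rnd_dna(60), B = rnd_dna(60), C = rnd_dna(60)),
    l2 = c(A = rnd_dna(140), B = rnd_dna(140), C = rnd_dna(140))
  )
  d_all <- concat_distance_matrix(loci)
  d1 <- concat_distance_matrix(loci["l1"])
  d2 <- concat_distance_matrix(loci["l2"])
  expect_equal(d_all["A", "B"],
               (60 * d1["A", "B"] + 140 * d2["A", "B"]) / 200,
               tolerance = 1e-12)

  bad <- list(l1 = c(A = "ACGT", B = "ACGT"), l2 = c(A = "ACGT", C = "ACGT"))
  expect_error(concat_distance_matrix(bad), "taxon")
})

test_that("NJ recovers the exact topology and branch lengths from an additive matrix", {
  # tree ((A:1,B:2):1,(C:3,D:1)); pairwise path lengths written by hand
  lab <- c("A", "B", "C", "D")
  d <- matrix(0, 4, 4, dimnames = list(lab, lab))
  d["A", "B"] <- 3; d["A", "C"] <- 5; d["A", "D"] <- 3
  d["B", "C"] <- 6; d["B", "D"] <- 4; d["C", "D"] <- 4
  d[lower.tri(d)] <- t(d)[lower.tri(d)]
  tr <- nj_tree(d)
  expect_true(is_monophyletic(tr, c("A", "B")))
  expect_true(is_monophyletic(tr, c("C", "D")))
  tip_edge_len <- function(tree, tip) {
    tree$edge.length[tree$edge[, 2] == match(tip, tree$tip.label)]
  }
  expect_equal(tip_edge_len(tr, "A"), 1)
  expect_equal(tip_edge_len(tr, "B"), 2)
  expect_equal(tip_edge_len(tr, "C"), 3)
  expect_equal(tip_edge_len(tr, "D"), 1)
  internal <- tr$edge.length[tr$edge[, 2] > 4]
  expect_equal(sum(internal), 1)
})

test_that("three taxa resolve to the closed-form star lengths", {
  lab <- c("x", "y", "z")
  d <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, dimnames = list(lab, lab))
  tr <- nj_tree(d)
  lens <- setNames(tr$edge.length[match(1:3, tr$edge[, 2])], lab)
  expect_equal(unname(lens["x"]), (3 + 4 - 5) / 2)
  expect_equal(unname(lens["y"]), (3 + 5 - 4) / 2)
  expect_equal(unname(lens["z"]), (4 + 5 - 3) / 2)
  expect_error(nj_tree(matrix(0, 2, 2)), "at least 3")
})

test_that("NJ recovers the generating topology from random additive matrices", {
  set.seed(71)
  for (rep_i in 1:12) {
    n <- sample(5:8, 1)
    gen <- ape::rtree(n, br = function(k) runif(k, 0.2, 1.5))
    d <- ape::cophenetic.phylo(gen)
    d <- d[sort(rownames(d)), sort(colnames(d))]
    rec <- nj_tree(d)
    expect_equal(ape::dist.topo(ape::unroot(gen), ape::unroot(rec)), 0,
                 ignore_attr = TRUE,
                 info = sprintf("replicate %d (n=%d)", rep_i, n))
  }
})

test_that("an ultrametric six-taxon matrix yields the generating topology", {
  gen <- ape::read.tree(text = "(((a:1,b:1):1,(c:1.5,d:1.5):0.5):1,(e:2,f:2):1);")
  d <- ape::cophenetic.phylo(gen)
  rec <- nj_tree(d)
  expect_true(is_monophyletic(rec, c("a", "b")))
  expect_true(is_monophyletic(rec, c("c", "d")))
  expect_true(is_monophyletic(rec, c("e", "f")))
  expect_true(is_monophyletic(rec, c("a", "b", "c", "d")))
})

test_that("bootstrap gives full support for perfectly congruent signal and is reproducible", {
  # 4 taxa, one internal split AB|CD supported by every column
  cols_ab <- strrep("A", 60)
  cols_cd <- strrep("G", 60)
  noise_a <- rnd_dna(0)
  aln <- list(l1 = c(A = paste0(cols_ab, "ACGTAC"),
                     B = paste0(cols_ab, "ACGTAG"),
                     C = paste0(cols_cd, "ACCTAC"),
                     D = paste0(cols_cd, "ATGTAC")))
  d <- concat_distance_matrix(aln)
  tr <- nj_tree(d)
  bs <- bootstrap_support(aln, tr, n_reps = 50, seed = 4)
  sup <- suppressWarnings(as.numeric(bs$node.label))
  sup <- sup[!is.na(sup)]
  expect_true(all(sup >= 0 & sup <= 100))
  expect_true(any(sup == 100))

  bs2 <- bootstrap_support(aln, tr, n_reps = 50, seed = 4)
  expect_identical(bs$node.label, bs2$node.label)
  bs3 <- bootstrap_support(aln, tr, n_reps = 50, seed = 5)
  expect_true(is.character(bs3$node.label))
  expect_error(bootstrap_support(aln, tr, n_reps = 0), "n_reps")
})

test_that("monophyly checks agree with exhaustive bipartition enumeration", {
  tree <- ape::read.tree(text = "((a:1,b:1):1,((c:1,d:1):1,(e:1,f:1):1):1);")
  expect_true(is_monophyletic(tree, c("a", "b")))
  expect_true(is_monophyletic(tree, c("c", "d", "e", "f")))  # complement
  expect_false(is_monophyletic(tree, c("a", "c")))
  expect_error(is_monophyletic(tree, c("a", "zz")), "unknown taxon")

  set.seed(73)
  for (rep_i in 1:8) {
    tr <- ape::rtree(8, tip.label = letters[1:8])
    taxa <- sample(letters[1:8], sample(2:6, 1))
    got <- is_monophyletic(tr, taxa)
    ut <- ape::unroot(tr)
    want <- FALSE
    for (e in seq_len(nrow(ut$edge))) {
      side <- ut$tip.label[plastcomp:::tips_below(ut, ut$edge[e, 2])]
      if (setequal(side, taxa) || setequal(setdiff(letters[1:8], side), taxa)) {
        want <- TRUE
      }
    }
    expect_identical(got, want)
  }
})

test_that("a planted four-taxon clade is recovered with high bootstrap support", {
  cfg <- sim_config(
    seed = 19, n_genes = 8,
    tree = "(((P1:0.01,P2:0.01):0.002,(P3:0.01,P4:0.01):0.002):0.03,(O1:0.01,O2:0.04):0.001);",
    gene_losses = data.frame(taxon = character(), gene = character(),
                             stringsAsFactors = FALSE)
  )
  sim <- evolve_on_tree(generate_root(cfg), cfg)
  aln <- list(genome = sim$truth$leaf_alignment)
  tr <- nj_tree(concat_distance_matrix(aln))
  clade <- c("P1", "P2", "P3", "P4")
  expect_true(is_monophyletic(tr, clade))
  bs <- bootstrap_support(aln, tr, n_reps = 100, seed = 2)
  # support of the clade edge
  nt <- length(bs$tip.label)
  sup <- NA_real_
  for (e in seq_len(nrow(bs$edge))) {
    child <- bs$edge[e, 2]
    if (child <= nt) next
    side <- bs$tip.label[plastcomp:::tips_below(bs, child)]
    if (setequal(side, clade) || setequal(setdiff(bs$tip.label, side), clade)) {
      sup <- as.numeric(bs$node.label[child - nt])
    }
  }
  expect_gte(sup, 95)
})
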