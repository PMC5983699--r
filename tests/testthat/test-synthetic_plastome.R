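test_that("generation is structurally correct and byte-deterministic", {
  no_plants <- list(
    planted_ssrs = data.frame(motif = character(), n_units = integer(),
                              igs = integer(), stringsAsFactors = FALSE),
    planted_repeats = data.frame(kind = character(), length = integer(),
                                 igs1 = integer(), igs2 = integer(),
                                 stringsAsFactors = FALSE)
  )
  cfg <- sim_config(seed = 2, n_genes = 10,
                    planted_ssrs = no_plants$planted_ssrs,
                    planted_repeats = no_plants$planted_repeats,
                    hotspot_igs = 3)
  root <- generate_root(cfg)
  expect_equal(length(root$record$features), 10)
  expect_equal(nrow(extract_igs(root$record)), 10)
  expect_true(root$record$circular)

  root2 <- generate_root(cfg)
  expect_identical(root$record$sequence, root2$record$sequence)
  sim1 <- evolve_on_tree(root, cfg)
  sim2 <- evolve_on_tree(root2, cfg)
  expect_identical(lapply(sim1$records, `[[`, "sequence"),
                   lapply(sim2$records, `[[`, "sequence"))
})

test_that("every planted SSR is recovered at its exact coordinates", {
  cfg <- sim_config(seed = 6)
  root <- generate_root(cfg)
  loci <- find_ssrs(root$record$sequence, circular = TRUE)
  tr <- root$truth$planted_ssrs
  hits <- merge(loci, tr, by = c("motif", "n_units", "start", "end"))
  expect_equal(nrow(hits), nrow(tr))
})

test_that("a zero-length branch leaves the child identical to the parent", {
  cfg <- sim_config(seed = 7, n_genes = 6, tree = "(Z1:0,Z2:0.1);",
                    gene_losses = data.frame(taxon = character(),
                                             gene = character(),
                                             stringsAsFactors = FALSE))
  root <- generate_root(cfg)
  sim <- evolve_on_tree(root, cfg)
  expect_identical(sim$records[["Z1"]]$sequence, root$record$sequence)
  expect_false(identical(sim$records[["Z2"]]$sequence, root$record$sequence))
})

test_that("realized substitution counts reproduce K2p inputs exactly on a two-taxon truth alignment", {
  cfg <- sim_config(seed = 8, n_genes = 8, tree = "(U:0.03,V:0.03);",
                    gene_losses = data.frame(taxon = character(),
                                             gene = character(),
                                             stringsAsFactors = FALSE))
  sim <- evolve_on_tree(generate_root(cfg), cfg)
  pc <- sim$truth$pair_region_counts
  regs <- lapply(sim$records, extract_igs)
  tab <- region_distance_table(regs, prealigned = TRUE, categories = "IGS")
  m <- merge(tab, pc[pc$category == "IGS", ],
             by = c("region", "species_a", "species_b"))
  expect_equal(nrow(m), nrow(tab))
  expect_equal(m$P, m$ts / m$sites, tolerance = 1e-12)
  expect_equal(m$Q, m$tv / m$sites, tolerance = 1e-12)
})

test_that("hotspot spacers carry the top divergence in most seeds", {
  top2 <- vapply(1:20, function(seed) {
    cfg <- sim_config(seed = seed, n_genes = 12,
                      gene_losses = data.frame(taxon = character(),
                                               gene = character(),
                                               stringsAsFactors = FALSE))
    sim <- evolve_on_tree(generate_root(cfg), cfg)
    tab <- region_distance_table(lapply(sim$records, extract_igs),
                                 prealigned = TRUE, categories = "IGS")
    means <- aggregate(d ~ region, data = tab[!is.na(tab$d), ], FUN = mean)
    top <- means$region[order(-means$d)][1:2]
    setequal(top, sim$truth$hotspot_regions)
  }, logical(1))
  expect_gte(mean(top2), 0.95)
})

test_that("gene loss removes the feature and sequence, fusing the flanking spacers", {
  cfg <- sim_config(seed = 10)
  root <- generate_root(cfg)
  sim <- evolve_on_tree(root, cfg)
  lost <- cfg$gene_losses[1, ]
  rec <- sim$records[[lost$taxon]]
  names_ <- vapply(rec$features, `[[`, character(1), "name")
  expect_false(lost$gene %in% names_)
  # genome shrinks by the gene extent
  f <- Filter(function(x) x$name == lost$gene, root$record$features)[[1]]
  ext <- plastcomp:::feature_extent(f)
  expect_equal(nchar(rec$sequence),
               nchar(root$record$sequence) - (ext[2] - ext[1]))
  # the fused spacer joins the genome-order neighbors of the lost gene
  ext_all <- t(vapply(root$record$features, plastcomp:::feature_extent,
                      numeric(2)))
  ord <- order(ext_all[, 1])
  on <- vapply(root$record$features[ord], `[[`, character(1), "name")
  i <- match(lost$gene, on)
  fused <- paste0(on[i - 1], "-", on[i + 1])
  expect_true(fused %in% extract_igs(rec)$name)
})

test_that("emitted files round-trip and regenerate identically", {
  cfg <- sim_config(seed = 3, n_genes = 8)
  sim <- evolve_on_tree(generate_root(cfg), cfg)
  d1 <- file.path(tempdir(), "emit1")
  d2 <- file.path(tempdir(), "emit2")
  emit_synthetic(sim, cfg, d1)
  emit_synthetic(evolve_on_tree(generate_root(cfg), cfg), cfg, d2)
  files <- list.files(d1)
  expect_true(all(c("T1.gb", "T1.fasta", "truth_planted_ssrs.tsv",
                    "truth_presence.tsv", "tree.nwk", "config.txt") %in% files))
  for (f in files) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
  back <- read_genbank(file.path(d1, "T3.gb"))
  orig <- sim$records[["T3"]]
  expect_identical(back$sequence, orig$sequence)
  expect_equal(length(back$features), length(orig$features))
  tr <- read_presence_matrix(file.path(d1, "truth_presence.tsv"))
  expect_equal(sum(!tr), nrow(cfg$gene_losses))
})

test_that("planted elements that cannot fit their spacer raise a generation error", {
  cfg <- sim_config(seed = 4, n_genes = 6,
                    igs_length = c(mean = 70, sd = 0),
                    planted_ssrs = data.frame(motif = "ACGTAC", n_units = 40,
                                              igs = 2, stringsAsFactors = FALSE))
  expect_error(generate_root(cfg), "does not fit")
})

test_that("the codon-pair simulator hits its dN/dS target directionally", {
  set.seed(123)
  r_high <- ng86_many(3, 200, 0.25, 5)
  r_low <- ng86_many(3, 200, 0.25, 0.1)
  expect_gt(median(r_high, na.rm = TRUE), 1)
  expect_lt(median(r_low, na.rm = TRUE), 0.5)
})
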