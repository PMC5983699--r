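test_that("global alignment handles identity, single gaps, and matches the exhaustive optimum", {
  a <- align_pair("ACGT", "ACGT")
  expect_identical(a$gapped_a, "ACGT")
  expect_identical(a$gapped_b, "ACGT")
  expect_equal(a$score, 4)

  b <- align_pair("ACGT", "AGT")
  expect_equal(nchar(b$gapped_a), 4)
  expect_equal(sum(str_chars(b$gapped_b) == "-"), 1)
  expect_equal(b$score, 3 - 12)  # 3 matches, one length-1 gap (10 + 2)

  set.seed(71)
  for (i in 1:15) {
    x <- rnd_dna(sample(3:8, 1))
    y <- rnd_dna(sample(3:8, 1))
    got <- align_pair(x, y)$score
    want <- brute_align_score(x, y)
    expect_equal(got, want, info = sprintf("%s vs %s", x, y))
  }
})

test_that("K2p matches closed-form hand evaluations", {
  ident <- k2p(c("ACGTACGT", "ACGTACGT"))
  expect_equal(ident$P, 0)
  expect_equal(ident$Q, 0)
  expect_equal(ident$d, 0)

  one_ts <- k2p(c("AAAA", "GAAA"))
  expect_equal(one_ts$P, 0.25)
  expect_equal(one_ts$Q, 0)
  expect_equal(one_ts$d, -0.5 * log(0.5), tolerance = 1e-12)
  expect_equal(one_ts$d, 0.3466, tolerance = 1e-4)

  # 20 sites, 2 transitions (A/G), 1 transversion (C/G): P = 0.1, Q = 0.05
  a <- "AAAAAAAAAACCCCCCCCCC"
  b <- "GGAAAAAAAAGCCCCCCCCC"
  res <- k2p(c(a, b))
  expect_equal(res$P, 0.1)
  expect_equal(res$Q, 0.05)
  expect_equal(res$d, -0.5 * log(0.75 * sqrt(0.9)), tolerance = 1e-12)
  expect_equal(round(res$d, 4), 0.1702)

  # saturation: 1 - 2P - Q <= 0
  sat <- k2p(c("AAAAAAAAAA", "GGGGGGGAAC"))
  expect_false(sat$defined)
  expect_true(is.na(sat$d))
})

test_that("gap and N columns are excluded by pairwise deletion", {
  res <- k2p(c("A-GTNA", "AAGTCG"))
  expect_equal(res$n_sites, 4)
  expect_equal(res$P, 0.25)  # A/G at the last comparable site
})

test_that("K2p agrees with an independent reference implementation", {
  set.seed(13)
  for (i in 1:5) {
    pair <- simulate_k2p_pair(2000, d = 0.1, kappa = 2)
    ours <- k2p(pair)
    bin <- ape::as.DNAbin(list(a = tolower(str_chars(pair[1])),
                               b = tolower(str_chars(pair[2]))))
    ref <- as.matrix(ape::dist.dna(bin, model = "K80"))["a", "b"]
    expect_equal(ours$d, unname(ref), tolerance = 1e-10)
  }
})

test_that("the K2p estimator recovers the true distance on simulated pairs", {
  set.seed(29)
  for (d_true in c(0.05, 0.1, 0.2)) {
    ds <- replicate(60, k2p(simulate_k2p_pair(10000, d_true, kappa = 2))$d)
    mc_se <- sd(ds) / sqrt(length(ds))
    expect_lt(abs(mean(ds) - d_true), 3 * mc_se + 1e-4)
  }
})

test_that("d is monotone in P at fixed Q and in Q at fixed P", {
  dd <- function(P, Q) -0.5 * log((1 - 2 * P - Q) * sqrt(1 - 2 * Q))
  Ps <- seq(0, 0.3, by = 0.05)
  Qs <- seq(0, 0.2, by = 0.05)
  for (Q in Qs) {
    vals <- vapply(Ps, dd, numeric(1), Q = Q)
    expect_true(all(diff(vals) > 0))
  }
  for (P in Ps) {
    vals <- vapply(Qs, dd, numeric(1), P = P)
    expect_true(all(diff(vals) > 0))
  }
})

test_that("the distance table is zero for identical genomes and exact for logged truth", {
  cfg <- sim_config(seed = 47, n_genes = 8)
  root <- generate_root(cfg)
  recs <- list(A = root$record, B = root$record)
  recs$A$id <- "A"; recs$B$id <- "B"
  tab <- region_distance_table(lapply(recs, extract_igs))
  expect_true(all(tab$d == 0))

  sim <- evolve_on_tree(root, cfg)
  regs <- lapply(sim$records, extract_igs)
  # prealigned truth route: P and Q equal realized counts / sites exactly
  tab2 <- region_distance_table(regs, prealigned = TRUE, categories = "IGS")
  pc <- sim$truth$pair_region_counts
  m <- merge(tab2, pc, by = c("region", "species_a", "species_b"))
  # losses fuse spacers in some taxa; compare the regions shared verbatim
  m <- m[m$n_sites == m$sites, ]
  expect_gt(nrow(m), 10)
  expect_equal(m$P, m$ts / m$sites, tolerance = 1e-12)
  expect_equal(m$Q, m$tv / m$sites, tolerance = 1e-12)
})

test_that("hotspot threshold is mean + 2 sample SD with the documented edge cases", {
  expect_equal(hotspot_threshold(c(0.1, 0.2, 0.3)), 0.2 + 2 * 0.1)
  expect_equal(hotspot_threshold(rep(0.07, 5)), 0.07)
  expect_error(hotspot_threshold(c(0.1)), "at least 2")
  expect_error(hotspot_threshold(c(0.1, NA)), "at least 2")

  # permutation invariance and affine equivariance
  set.seed(5)
  v <- runif(20)
  expect_equal(hotspot_threshold(v), hotspot_threshold(sample(v)))
  expect_equal(hotspot_threshold(2 * v + 1), 2 * hotspot_threshold(v) + 1)
})

test_that("hotspot identification flags planted fast spacers and honors boundaries", {
  empty_tab <- data.frame(region = c("r1", "r2"), category = "IGS",
                          species_a = "A", species_b = "B",
                          P = 0, Q = 0, d = 0, n_sites = 100L, defined = TRUE,
                          stringsAsFactors = FALSE)
  expect_equal(nrow(identify_hotspots(empty_tab, 0)), 0)

  cfg <- sim_config(seed = 42)
  root <- generate_root(cfg)
  sim <- evolve_on_tree(root, cfg)
  tab <- region_distance_table(lapply(sim$records, extract_igs),
                               prealigned = TRUE, categories = "IGS")
  thr <- hotspot_threshold(tab$d)
  hs <- identify_hotspots(tab, thr)
  expect_setequal(hs$region, root$truth$hotspot_regions)
  # threshold 0 flags everything with any divergence
  all_hot <- identify_hotspots(tab, 0)
  expect_true(all(tab$region[tab$d > 0 & !is.na(tab$d)] %in% all_hot$region))
})
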