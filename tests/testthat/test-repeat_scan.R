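test_that("a planted exact forward copy is reported with identity 100 and exact coordinates", {
  set.seed(31)
  block <- rnd_dna(40)
  # flanks chosen so the copies cannot extend without a mismatch
  s <- paste0(rnd_dna(80), "C", block, "A", rnd_dna(120),
              "G", block, "T", rnd_dna(60))
  start1 <- 82
  start2 <- 82 + 40 + 1 + 120 + 1
  res <- find_dispersed_repeats(s)
  exact <- res[res$mismatches == 0 & res$kind == "forward", ]
  hit <- exact[exact$start1 == start1 & exact$length == 40, ]
  expect_equal(nrow(hit), 1)
  expect_equal(hit$start2, start2)
  expect_equal(hit$identity, 100)
})

test_that("a planted reverse-complement copy is reported as palindromic", {
  set.seed(32)
  block <- rnd_dna(35)
  s <- paste0(rnd_dna(50), "A", block, "A", rnd_dna(90),
              "A", rc_(block), "A", rnd_dna(40))
  res <- find_dispersed_repeats(s)
  pal <- res[res$kind == "palindromic" & res$mismatches == 0 & res$length >= 35, ]
  expect_gte(nrow(pal), 1)
  expect_true(any(pal$start1 == 52 & pal$length == 35))
})

test_that("detector equals the exhaustive all-diagonals oracle on random sequences", {
  set.seed(202)
  for (rep_i in 1:6) {
    n <- sample(150:400, 1)
    s <- rnd_dna(n)
    # embed one degraded copy to exercise the mismatch paths
    if (rep_i %% 2 == 0) {
      blk <- substr(s, 10, 50)
      ch <- str_chars(blk)
      ch[c(5, 20)] <- vapply(ch[c(5, 20)], function(x) {
        setdiff(c("A", "C", "G", "T"), x)[1]
      }, character(1))
      s <- paste0(s, paste(ch, collapse = ""), rnd_dna(20))
    }
    got <- find_dispersed_repeats(s, min_len = 20, max_mismatch = 3)
    want <- brute_dispersed(s, min_len = 20, max_mm = 3)
    expect_equal(got[, repeat_cols], want[, repeat_cols],
                 info = sprintf("replicate %d (n=%d)", rep_i, nchar(s)))
  }
})

test_that("oracle equivalence holds for every mismatch budget 0..3", {
  set.seed(203)
  s <- paste0(rnd_dna(120), substr(rnd_dna(0), 0, 0), rnd_dna(0))
  base <- rnd_dna(200)
  blk <- substr(base, 50, 95)
  s <- paste0(base, blk, rnd_dna(30))
  for (mm in 0:3) {
    got <- find_dispersed_repeats(s, min_len = 25, max_mismatch = mm)
    want <- brute_dispersed(s, min_len = 25, max_mm = mm)
    expect_equal(got[, repeat_cols], want[, repeat_cols],
                 info = sprintf("budget %d", mm))
  }
})

test_that("a sequence aligned to itself at identical coordinates is never reported", {
  s <- rnd_dna(300)
  res <- find_dispersed_repeats(s, min_len = 20)
  expect_false(any(res$start1 == res$start2 & res$end1 == res$end2))
})

test_that("reverse-complementing the genome preserves the repeat structure", {
  set.seed(33)
  block <- rnd_dna(40)
  s <- paste0(rnd_dna(60), "C", block, "A", rnd_dna(80), "G", block, "T",
              rnd_dna(50), "A", rc_(substr(block, 1, 35)), "C", rnd_dna(30))
  a <- find_dispersed_repeats(s)
  b <- find_dispersed_repeats(rc_(s))
  expect_equal(nrow(a), nrow(b))
  expect_equal(sort(table(a$kind)), sort(table(b$kind)))
  expect_setequal(a$length, b$length)
})

test_that("containment-based dedupe keeps outermost same-identity pairs", {
  mk <- function(kind, s1, e1, s2, e2, mm) {
    data.frame(kind = kind, length = e1 - s1 + 1L, start1 = s1, end1 = e1,
               start2 = s2, end2 = e2, mismatches = mm,
               identity = 100 * (e1 - s1 + 1 - mm) / (e1 - s1 + 1),
               stringsAsFactors = FALSE)
  }
  nested <- rbind(mk("forward", 10, 69, 210, 269, 0),
                  mk("forward", 20, 49, 220, 249, 0))
  expect_equal(nrow(dedupe_repeats(nested)), 1)
  expect_equal(dedupe_repeats(nested)$start1, 10)

  disjoint <- rbind(mk("forward", 10, 49, 210, 249, 0),
                    mk("forward", 60, 99, 310, 349, 0))
  expect_equal(nrow(dedupe_repeats(disjoint)), 2)

  chain <- rbind(mk("forward", 10, 99, 210, 299, 1),
                 mk("forward", 20, 79, 220, 279, 1),
                 mk("forward", 30, 59, 230, 259, 1))
  expect_equal(nrow(dedupe_repeats(chain)), 1)
  expect_equal(dedupe_repeats(chain)$length, 90)

  # a tighter higher-identity core inside a wider degraded window is kept
  core_kept <- rbind(mk("forward", 10, 69, 210, 269, 3),
                     mk("forward", 20, 59, 220, 259, 0))
  expect_equal(nrow(dedupe_repeats(core_kept)), 2)
})

test_that("tandem scoring reproduces hand-counted scores and boundary cases", {
  acgt <- find_tandem_repeats(strrep("ACGT", 10))
  expect_equal(nrow(acgt), 1)
  expect_equal(acgt$period, 4)
  expect_equal(acgt$copies, 10)
  expect_equal(acgt$score, 72)   # 36 matching offset positions x 2
  expect_identical(acgt$consensus, "ACGT")

  at_boundary <- find_tandem_repeats(strrep("A", 26))
  expect_equal(nrow(at_boundary), 1)
  expect_equal(at_boundary$period, 1)
  expect_equal(at_boundary$score, 50)  # 25 x 2, exactly at the cutoff

  expect_equal(nrow(find_tandem_repeats(strrep("A", 25))), 0)
})

test_that("overlapping tandem calls resolve to the highest-scoring period", {
  s <- paste0(rnd_dna(40), strrep("ACGTA", 12), rnd_dna(40))
  res <- find_tandem_repeats(s)
  expect_equal(nrow(res), 1)
  expect_equal(res$period, 5)
  # a mismatch inside the array lowers the score by match+mismatch loss
  v <- str_chars(s)
  v[63] <- setdiff(c("A", "C", "G", "T"), v[63])[1]
  res2 <- find_tandem_repeats(paste(v, collapse = ""))
  expect_lt(res2$score[1], res$score[1])
})
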