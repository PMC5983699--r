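# Brute-force oracles and fixture builders shared across the suite.
# Each oracle is an independent re-derivation of the operation it checks:
# per-position loops instead of run-length encodings, exhaustive enumeration
# instead of seed-and-extend, recursion instead of dynamic programming.

rnd_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                             collapse = "")

str_chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

rc_ <- function(s) paste(rev(str_chars(chartr("ACGT", "TGCA", s))), collapse = "")

# --- SSR oracle: per-start scan over all periods -----------------------------

primitive_ <- function(motif) {
  u <- nchar(motif)
  if (u == 1) return(TRUE)
  for (p in seq_len(u - 1)) {
    if (u %% p == 0 &&
        motif == paste(rep(substr(motif, 1, p), u / p), collapse = "")) {
      return(FALSE)
    }
  }
  TRUE
}

brute_ssrs <- function(sequence, thresholds = c(`1` = 8, `2` = 4, `3` = 4,
                                                `4` = 3, `5` = 3, `6` = 3)) {
  v <- str_chars(sequence)
  n <- length(v)
  rows <- list()
  for (u in 1:6) {
    thr <- thresholds[[as.character(u)]]
    i <- 1
    while (i + u - 1 <= n) {
      # maximal left boundary: no period-u continuation into position i-1
      if (i > 1 && i - 1 + u <= n && v[i - 1] == v[i - 1 + u]) {
        i <- i + 1
        next
      }
      # extend the period-u tract from i
      j <- i + u
      while (j <= n && v[j] == v[j - u]) j <- j + 1
      tract_len <- j - i
      if (tract_len >= u * thr) {
        motif <- paste(v[i:(i + u - 1)], collapse = "")
        if (primitive_(motif)) {
          k <- tract_len %/% u
          rows[[length(rows) + 1]] <- data.frame(
            motif = motif, unit_len = u, n_units = k,
            start = i, end = i + k * u - 1, remainder = tract_len %% u,
            stringsAsFactors = FALSE
          )
        }
      }
      i <- i + 1
    }
  }
  if (!length(rows)) {
    return(data.frame(motif = character(), unit_len = integer(),
                      n_units = integer(), start = integer(), end = integer(),
                      remainder = integer(), stringsAsFactors = FALSE))
  }
  out <- unique(do.call(rbind, rows))
  out <- out[order(out$start, out$unit_len), ]
  rownames(out) <- NULL
  out
}

# --- dispersed repeat oracle: every diagonal, no seeding ---------------------

# maximal exactly-k-mismatch windows >= min_len from a logical mismatch vector
windows_from_mismatches <- function(mism, len, min_len, max_mm) {
  p <- c(0L, which(mism), len + 1L)
  nm <- length(p) - 2L
  out <- list()
  for (k in 0:max_mm) {
    for (j in 0:nm) {
      if (j + k + 2L > length(p)) next
      lo <- p[j + 1L] + 1L
      hi <- p[j + k + 2L] - 1L
      if (hi - lo + 1L < min_len) next
      realmm <- sum(mism[lo:hi])
      if (realmm != k) next
      out[[length(out) + 1]] <- c(lo, hi, k)
    }
  }
  if (!length(out)) return(NULL)
  unique(do.call(rbind, out))
}

brute_dispersed <- function(sequence, min_len = 30, max_mm = 3) {
  v <- str_chars(sequence)
  n <- length(v)
  rows <- list()
  add <- function(kind, a1, a2, b1, b2, k) {
    if (a1 == b1 && a2 == b2) return()
    if (a1 > b1 || (a1 == b1 && a2 > b2)) {
      t1 <- a1; t2 <- a2; a1 <- b1; a2 <- b2; b1 <- t1; b2 <- t2
    }
    rows[[length(rows) + 1]] <<- data.frame(
      kind = kind, length = a2 - a1 + 1L, start1 = a1, end1 = a2,
      start2 = b1, end2 = b2, mismatches = k, stringsAsFactors = FALSE
    )
  }
  # forward: offset d
  for (d in seq_len(n - min_len)) {
    len <- n - d
    mism <- v[1:len] != v[(d + 1):(d + len)]
    w <- windows_from_mismatches(mism, len, min_len, max_mm)
    if (is.null(w)) next
    for (r in seq_len(nrow(w))) {
      add("forward", w[r, 1], w[r, 2], w[r, 1] + d, w[r, 2] + d, w[r, 3])
    }
  }
  # palindromic: compare v with reverse complement on every diagonal
  t <- str_chars(rc_(sequence))
  for (off in (-(n - min_len)):(n - min_len)) {
    i0 <- max(1, 1 - off)            # position in v; partner t[i + off]
    i1 <- min(n, n - off)
    len <- i1 - i0 + 1
    if (len < min_len) next
    mism <- v[i0:i1] != t[(i0 + off):(i1 + off)]
    w <- windows_from_mismatches(mism, len, min_len, max_mm)
    if (is.null(w)) next
    for (r in seq_len(nrow(w))) {
      a1 <- i0 + w[r, 1] - 1L; a2 <- i0 + w[r, 2] - 1L
      tb1 <- a1 + off; tb2 <- a2 + off          # interval on rc
      b1 <- n - tb2 + 1L; b2 <- n - tb1 + 1L    # back to + coordinates
      add("palindromic", a1, a2, b1, b2, w[r, 3])
    }
  }
  if (!length(rows)) {
    return(data.frame(kind = character(), length = integer(),
                      start1 = integer(), end1 = integer(),
                      start2 = integer(), end2 = integer(),
                      mismatches = integer(), stringsAsFactors = FALSE))
  }
  out <- unique(do.call(rbind, rows))
  out <- out[100 * (out$length - out$mismatches) / out$length >= 90, ,
             drop = FALSE]
  # independent containment filter (same-kind, no-better-identity nesting)
  keep <- rep(TRUE, nrow(out))
  for (i in seq_len(nrow(out))) {
    for (j in seq_len(nrow(out))) {
      if (i == j) next
      if (out$kind[i] == out$kind[j] &&
          out$start1[i] >= out$start1[j] && out$end1[i] <= out$end1[j] &&
          out$start2[i] >= out$start2[j] && out$end2[i] <= out$end2[j] &&
          out$length[i] < out$length[j] &&
          out$mismatches[i] >= out$mismatches[j]) {
        keep[i] <- FALSE
        break
      }
    }
  }
  out <- out[keep, , drop = FALSE]
  out <- out[order(out$start1, -out$length, out$start2, out$kind), ]
  rownames(out) <- NULL
  out
}

repeat_cols <- c("kind", "length", "start1", "end1", "start2", "end2", "mismatches")

# --- exhaustive global alignment score (affine gaps) -------------------------

# best global score by enumerating all alignments recursively; gap of length
# L costs open + L * ext, matching the aligner's convention
brute_align_score <- function(a, b, match = 1, mismatch = -1,
                              open = 10, ext = 2) {
  av <- str_chars(a); bv <- str_chars(b)
  rec <- function(i, j, state) {
    # state: 0 none, 1 gap-in-b open, 2 gap-in-a open
    if (i > length(av) && j > length(bv)) return(0)
    best <- -Inf
    if (i <= length(av) && j <= length(bv)) {
      s <- if (av[i] == bv[j]) match else mismatch
      best <- max(best, s + rec(i + 1, j + 1, 0))
    }
    if (i <= length(av)) {
      cost <- ext + if (state == 1) 0 else open
      best <- max(best, -cost + rec(i + 1, j, 1))
    }
    if (j <= length(bv)) {
      cost <- ext + if (state == 2) 0 else open
      best <- max(best, -cost + rec(i, j + 1, 2))
    }
    best
  }
  rec(1, 1, 0)
}

# --- NG86 per-codon site counts (independent enumeration) --------------------

brute_syn_sites <- function(codon, code = Biostrings::GENETIC_CODE) {
  bases <- c("A", "C", "G", "T")
  v <- str_chars(codon)
  syn <- 0
  for (pos in 1:3) {
    for (b in bases[bases != v[pos]]) {
      w <- v; w[pos] <- b
      mut <- paste(w, collapse = "")
      if (code[[mut]] != "*" && code[[mut]] == code[[codon]]) syn <- syn + 1
    }
  }
  syn / 3
}

ng86_many <- function(k, n_codons, t, omega) {
  vapply(seq_len(k), function(i) {
    p <- simulate_codon_pair(n_codons, t, omega)
    ng86(p[1], p[2])$ratio
  }, numeric(1))
}

# --- small record fixtures ---------------------------------------------------

# linear toy record: two genes and a spacer with known layout
toy_record <- function() {
  # layout: [0,30) gene gA (+, CDS, 30 bp), [30,80) spacer, [80,140) gene gB
  # (-, CDS, two exons 80-110 / 119-140 with a 9 bp intron; spliced 51 bp)
  set.seed(99)
  seqv <- rnd_dna(140)
  plastome_record(
    "TOY", seqv,
    list(
      gene_feature("gA", "CDS", matrix(c(0, 30), 1), "+"),
      gene_feature("gB", "CDS", matrix(c(80, 110, 119, 140), 2, byrow = TRUE), "-")
    ),
    circular = FALSE
  )
}

write_tmp_genbank <- function(record) {
  path <- tempfile(fileext = ".gb")
  write_genbank(record, path)
  path
}
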