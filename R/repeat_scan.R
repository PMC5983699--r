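# Dispersed repeat pairs (forward and palindromic) and tandem repeats.
#
# Dispersed repeats follow the classic maximal k-mismatch definition: for
# each mismatch count k = 0..max_mismatch, a pair of equal-length segments
# aligned without gaps ("Hamming distance" = mismatches only) is reported
# when it has exactly k mismatches and cannot be extended in either
# direction without adding one. With min_len = 30 and max_mismatch = 3 every
# reported pair has identity >= 90%.
#
# The detector is seed-and-extend (exact 7-mers; any >= 30 bp segment with
# <= 3 mismatches contains an exact 7-mer by pigeonhole) and is checked in
# the test suite against an exhaustive all-offsets oracle.

empty_repeat_df <- function() {
  data.frame(kind = character(), length = integer(),
             start1 = integer(), end1 = integer(),
             start2 = integer(), end2 = integer(),
             mismatches = integer(), identity = numeric(),
             stringsAsFactors = FALSE)
}

# Collect mismatch offsets around a seed on the diagonal (va[i + off] vs
# vb[j + off]) walking outward until max_mm + 1 mismatches or the boundary.
# Returns candidate windows in va/vb coordinates.
extend_seed <- function(va, vb, i, j, seed_len, min_len, max_mm) {
  la <- length(va); lb <- length(vb)
  left_room <- min(i, j) - 1L
  right_room <- min(la - i, lb - j) - seed_len + 1L
  # offsets relative to seed start (seed occupies offsets 0..seed_len-1)
  lmm <- integer(0); step <- -1L
  while (length(lmm) <= max_mm && -step <= left_room) {
    if (va[i + step] != vb[j + step]) lmm <- c(lmm, step)
    step <- step - 1L
  }
  rmm <- integer(0); step <- seed_len
  while (length(rmm) <= max_mm && step < seed_len + right_room) {
    if (va[i + step] != vb[j + step]) rmm <- c(rmm, step)
    step <- step + 1L
  }
  lbound <- -left_room - 1L              # one past the furthest legal offset
  rbound <- seed_len + right_room        # one past the furthest legal offset
  lp <- c(lmm, lbound)                   # nearest-first
  rp <- c(rmm, rbound)
  rows <- list()
  for (k in 0:max_mm) {
    for (a in 0:k) {
      b <- k - a
      if (a + 1 > length(lp) || b + 1 > length(rp)) next
      lo <- lp[a + 1] + 1L
      hi <- rp[b + 1] - 1L
      # real mismatch count inside (boundary sentinels don't count)
      realmm <- sum(lmm >= lo) + sum(rmm <= hi)
      if (realmm != k) next              # window maximal only for its own k
      if (hi - lo + 1L < min_len) next
      rows[[length(rows) + 1]] <- c(i + lo, i + hi, j + lo, j + hi, k)
    }
  }
  if (!length(rows)) return(NULL)
  do.call(rbind, rows)
}

kmer_positions <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(list())
  kmers <- substring(s, 1:(n - k + 1), k:n)
  split(seq_len(n - k + 1), kmers)
}

#' Detect dispersed (forward and palindromic) repeat pairs
#'
#' Finds all maximal gapless repeat pairs of length >= `min_len` with at most
#' `max_mismatch` mismatches. Forward pairs have both copies on the + strand;
#' for palindromic pairs the second copy is the reverse complement of the
#' first. A segment paired with itself at identical coordinates is never
#' reported. Output is deduplicated with [dedupe_repeats()] and ordered by
#' first-copy position, then length descending.
#'
#' @param sequence uppercase DNA string
#' @param min_len minimum repeat length (default 30)
#' @param max_mismatch maximum Hamming distance (default 3; no indels)
#' @param seed_len exact seed length used by the scan (default 7, which is
#'   exhaustive for the default min_len/max_mismatch)
#' @return data frame: kind, length, start1, end1, start2, end2 (1-based
#'   inclusive), mismatches, identity (percent)
#' @export
find_dispersed_repeats <- function(sequence, min_len = 30, max_mismatch = 3,
                                   seed_len = 7) {
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  if (n < min_len) return(empty_repeat_df())
  v <- chars(sequence)
  rc <- revcomp(sequence)
  vrc <- chars(rc)
  pos_s <- kmer_positions(sequence, seed_len)
  pos_rc <- kmer_positions(rc, seed_len)

  cand <- list()
  add_rows <- function(rows, kind, map_b = FALSE) {
    if (is.null(rows)) return()
    for (r in seq_len(nrow(rows))) {
      a1 <- rows[r, 1]; a2 <- rows[r, 2]
      b1 <- rows[r, 3]; b2 <- rows[r, 4]
      if (map_b) {
        # map interval on the reverse complement back to + coordinates
        nb1 <- n - b2 + 1L; nb2 <- n - b1 + 1L
        b1 <- nb1; b2 <- nb2
      }
      if (a1 == b1 && a2 == b2) next      # self match
      if (a1 > b1 || (a1 == b1 && a2 > b2)) {
        tmp <- c(a1, a2); a1 <- b1; a2 <- b2; b1 <- tmp[1]; b2 <- tmp[2]
      }
      cand[[length(cand) + 1]] <<- c(a1, a2, b1, b2, rows[r, 5],
                                     if (kind == "forward") 0L else 1L)
    }
  }

  # forward: seeds within the sequence itself
  for (p in pos_s) {
    if (length(p) < 2) next
    prs <- combn(p, 2)
    for (c_i in seq_len(ncol(prs))) {
      i <- prs[1, c_i]; j <- prs[2, c_i]
      if (i == j) next
      add_rows(extend_seed(v, v, i, j, seed_len, min_len, max_mismatch),
               "forward")
    }
  }
  # palindromic: seeds shared between the sequence and its reverse complement
  shared <- intersect(names(pos_s), names(pos_rc))
  for (km in shared) {
    for (i in pos_s[[km]]) {
      for (j in pos_rc[[km]]) {
        add_rows(extend_seed(v, vrc, i, j, seed_len, min_len, max_mismatch),
                 "palindromic", map_b = TRUE)
      }
    }
  }
  if (!length(cand)) return(empty_repeat_df())
  m <- unique(do.call(rbind, cand))
  df <- data.frame(
    kind = ifelse(m[, 6] == 0, "forward", "palindromic"),
    length = m[, 2] - m[, 1] + 1L,
    start1 = m[, 1], end1 = m[, 2], start2 = m[, 3], end2 = m[, 4],
    mismatches = m[, 5], stringsAsFactors = FALSE
  )
  df$identity <- round_half_up(100 * (df$length - df$mismatches) / df$length)
  df <- df[df$identity >= 90, , drop = FALSE]
  dedupe_repeats(df)
}

#' Remove nested/redundant repeat pairs
#'
#' A pair is removed when both of its copies are contained within the
#' corresponding copies of another reported pair of the same kind that has
#' at most as many mismatches (a higher-identity core inside a wider window
#' is kept). Output is ordered deterministically by first-copy start, then
#' length descending.
#'
#' @param pairs data frame as returned by [find_dispersed_repeats()]
#' @return filtered, ordered data frame
#' @export
dedupe_repeats <- function(pairs) {
  if (!nrow(pairs)) return(pairs)
  pairs <- unique(pairs)
  keep <- rep(TRUE, nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    for (j in seq_len(nrow(pairs))) {
      if (i == j || !keep[i]) next
      same <- pairs$kind[i] == pairs$kind[j]
      contained <- pairs$start1[i] >= pairs$start1[j] &&
        pairs$end1[i] <= pairs$end1[j] &&
        pairs$start2[i] >= pairs$start2[j] &&
        pairs$end2[i] <= pairs$end2[j]
      strictly_smaller <- pairs$length[i] < pairs$length[j] ||
        (pairs$length[i] == pairs$length[j] &&
           (pairs$start1[i] != pairs$start1[j] || pairs$start2[i] != pairs$start2[j]))
      if (same && contained && strictly_smaller &&
          pairs$mismatches[i] >= pairs$mismatches[j]) {
        keep[i] <- FALSE
      }
    }
  }
  out <- pairs[keep, , drop = FALSE]
  out <- out[order(out$start1, -out$length, out$start2, out$kind), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# ---------------------------------------------------------------------------
# Tandem repeats

#' Detect tandem repeats by deterministic offset scoring
#'
#' For every period p up to `max_period` the sequence is compared against
#' itself offset by p; maximal positively scoring segments under
#' +`match`/-`mismatch` scoring are collected, and a segment scoring at least
#' `min_score` is reported as a tandem tract covering both copies
#' (`[segment_start, segment_end + p]`). Overlapping calls from different
#' periods are resolved to the highest-scoring one (ties to the smaller
#' period). Scores are exact and reproducible by hand; no indels are modelled
#' (`indel` is part of the parameter surface for compatibility).
#'
#' @param sequence uppercase DNA string
#' @param match match bonus (default 2)
#' @param mismatch mismatch penalty (default 7)
#' @param indel indel penalty (accepted for interface compatibility;
#'   the gapless scan never applies it)
#' @param min_score minimum alignment score (default 50)
#' @param max_period maximum period size (default 500)
#' @return data frame: period, copies, score, start, end (1-based
#'   inclusive), consensus
#' @export
find_tandem_repeats <- function(sequence, match = 2, mismatch = 7, indel = 7,
                                min_score = 50, max_period = 500) {
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  v <- chars(sequence)
  cand <- list()
  for (p in seq_len(min(max_period, n - 1))) {
    if (n - p < ceiling(min_score / match)) break
    eq <- v[seq_len(n - p)] == v[(p + 1):n]
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    scores <- ifelse(r$values, match, -mismatch) * r$lengths
    # Kadane-style scan over runs: collect disjoint maximal positive segments
    cur <- 0; cur_start <- NA_integer_; best <- 0; best_end <- NA_integer_
    flush <- function() {
      if (!is.na(cur_start) && best >= min_score) {
        cand[[length(cand) + 1]] <<- c(p, cur_start, best_end, best)
      }
    }
    for (k in seq_along(scores)) {
      if (cur <= 0) {
        if (scores[k] <= 0) next
        flush()
        cur <- 0; best <- 0; cur_start <- starts[k]; best_end <- NA_integer_
      }
      cur <- cur + scores[k]
      if (cur > best) { best <- cur; best_end <- ends[k] }
      if (cur <= 0) { flush(); cur <- 0; cur_start <- NA_integer_; best <- 0 }
    }
    flush()
  }
  if (!length(cand)) {
    return(data.frame(period = integer(), copies = numeric(), score = integer(),
                      start = integer(), end = integer(), consensus = character(),
                      stringsAsFactors = FALSE))
  }
  m <- do.call(rbind, cand)
  df <- data.frame(period = m[, 1], seg_start = m[, 2], seg_end = m[, 3],
                   score = m[, 4])
  df$start <- df$seg_start
  df$end <- df$seg_end + df$period
  # resolve overlaps to the highest score, ties to the smaller period
  df <- df[order(-df$score, df$period, df$start), ]
  acc <- list()
  for (i in seq_len(nrow(df))) {
    s <- df$start[i]; e <- df$end[i]
    overlaps <- any(vapply(acc, function(a) s <= a[2] && a[1] <= e, logical(1)))
    if (!overlaps) acc[[length(acc) + 1]] <- c(s, e, df$period[i], df$score[i])
  }
  out <- do.call(rbind, acc)
  res <- data.frame(period = out[, 3],
                    copies = round((out[, 2] - out[, 1] + 1) / out[, 3], 2),
                    score = out[, 4], start = out[, 1], end = out[, 2],
                    stringsAsFactors = FALSE)
  res$consensus <- vapply(seq_len(nrow(res)), function(i) {
    tandem_consensus(v[res$start[i]:res$end[i]], res$period[i])
  }, character(1))
  res <- res[order(res$start), ]
  rownames(res) <- NULL
  res
}

# Majority vote across copies at each of the p positions.
tandem_consensus <- function(tract_chars, p) {
  cons <- vapply(seq_len(p), function(off) {
    col <- tract_chars[seq(off, length(tract_chars), by = p)]
    names(sort(table(col), decreasing = TRUE))[1]
  }, character(1))
  collapse0(cons)
}
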