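# Microsatellite (SSR) detection.
#
# Perfect repeats only, with MISA-style minimum unit counts per motif length
# (mono 8, di 4, tri 4, tetra/penta/hexa 3). A tract is reported under its
# primitive period only ("ATATATAT" is a di-AT x4 tract, never a tetra-ATAT
# tract); the motif is the tract's leading unit, not canonicalized across
# rotations or strands.

DEFAULT_SSR_THRESHOLDS <- c(`1` = 8L, `2` = 4L, `3` = 4L, `4` = 3L, `5` = 3L, `6` = 3L)

is_primitive_motif <- function(motif) {
  u <- nchar(motif)
  if (u == 1) return(TRUE)
  divs <- which(u %% seq_len(u - 1) == 0)
  for (p in divs) {
    if (motif == collapse0(rep(substring(motif, 1, p), u / p))) return(FALSE)
  }
  TRUE
}

empty_ssr_df <- function() {
  data.frame(motif = character(), unit_len = integer(), n_units = integer(),
             start = integer(), end = integer(), remainder = integer(),
             stringsAsFactors = FALSE)
}

#' Detect simple sequence repeats
#'
#' All maximal perfect tandem tracts of 1-6 nt motifs meeting the unit-count
#' thresholds, reported left to right under their primitive period. The
#' reported interval covers the complete units (`unit_len * n_units`); a
#' trailing partial unit is recorded in `remainder`. On circular sequences
#' the origin-spanning tract is detected and reported with its start inside
#' the genome (end positions may be given modulo the length downstream).
#'
#' @param sequence uppercase DNA string
#' @param thresholds named integer vector: minimum unit count per motif
#'   length 1-6
#' @param circular treat the sequence as circular
#' @return data frame: motif, unit_len, n_units, start, end (1-based
#'   inclusive, complete units), remainder
#' @export
find_ssrs <- function(sequence, thresholds = DEFAULT_SSR_THRESHOLDS,
                      circular = FALSE) {
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  if (n < 3) return(empty_ssr_df())
  scan_seq <- if (circular) paste0(sequence, sequence) else sequence
  v <- chars(scan_seq)
  L <- length(v)
  out <- list()
  for (u in 1:6) {
    thr <- thresholds[[as.character(u)]]
    if (L <= u) next
    m <- v[seq_len(L - u)] == v[(u + 1):L]
    r <- rle(m)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    hit <- which(r$values & r$lengths + u >= u * thr)
    for (h in hit) {
      i <- starts[h]                      # 1-based tract start
      tract_len <- r$lengths[h] + u
      if (circular) {
        if (i > n) next                   # duplicate copy
        # a run at position 1 that continues across the origin is a fragment
        # of a wrap-around tract reported at its true start (unless the tract
        # covers the whole circle)
        if (i == 1 && n <= length(m) && m[n] && tract_len < 2 * n) next
        tract_len <- min(tract_len, n)    # whole-genome tract cap
      }
      motif <- collapse0(v[i:(i + u - 1)])
      if (!is_primitive_motif(motif)) next
      n_units <- tract_len %/% u
      if (n_units < thr) next
      out[[length(out) + 1]] <- data.frame(
        motif = motif, unit_len = u, n_units = n_units,
        start = i, end = i + n_units * u - 1L,
        remainder = tract_len %% u, stringsAsFactors = FALSE
      )
    }
  }
  if (!length(out)) return(empty_ssr_df())
  res <- do.call(rbind, out)
  res <- res[order(res$start, res$unit_len), ]
  rownames(res) <- NULL
  res
}

#' Assign SSR loci to genomic region classes
#'
#' Each locus is labeled by the region class (CDS, intron, IGS, other)
#' containing its midpoint; a midpoint falling exactly on a region boundary
#' is assigned to the upstream region. "CDS" here means inside a
#' protein-coding exon; tRNA/rRNA genes and unannotated positions fall under
#' "other".
#'
#' @param loci data frame from [find_ssrs()]
#' @param record the [plastome_record()] the loci came from
#' @return `loci` with `region_category` and `region_name` columns appended
#' @export
classify_ssrs <- function(loci, record) {
  n <- nchar(record$sequence)
  if (nrow(loci) && any(loci$start < 1 | loci$start > n)) {
    stop("locus outside genome bounds")
  }
  regions <- list()
  for (f in record$features) {
    if (f$kind == "CDS") {
      for (i in seq_len(nrow(f$exons))) {
        regions[[length(regions) + 1]] <- list(
          s = f$exons[i, 1], e = f$exons[i, 2], cat = "CDS", name = f$name)
      }
    }
  }
  intr <- extract_introns(record)
  for (i in seq_len(nrow(intr))) {
    regions[[length(regions) + 1]] <- list(
      s = intr$start[i] - 1L, e = intr$end[i], cat = "intron", name = intr$name[i])
  }
  igs <- extract_igs(record)
  for (i in seq_len(nrow(igs))) {
    e <- igs$end[i]
    if (e < igs$start[i]) e <- e + n  # wrap spacer
    regions[[length(regions) + 1]] <- list(
      s = igs$start[i] - 1L, e = e, cat = "IGS", name = igs$name[i])
  }
  cat_out <- character(nrow(loci))
  name_out <- character(nrow(loci))
  for (k in seq_len(nrow(loci))) {
    # 0-based midpoint of the full tract (complete units + remainder)
    m <- ((loci$start[k] - 1) + (loci$end[k] + loci$remainder[k])) / 2
    hit <- NA_integer_
    for (ri in seq_along(regions)) {
      r <- regions[[ri]]
      inside <- (r$s < m && m <= r$e) ||
        (record$circular && r$e > n && (r$s < m + n && m + n <= r$e))
      if (inside) { hit <- ri; break }
    }
    if (is.na(hit)) {
      cat_out[k] <- "other"; name_out[k] <- NA_character_
    } else {
      cat_out[k] <- regions[[hit]]$cat
      name_out[k] <- regions[[hit]]$name
    }
  }
  loci$region_category <- cat_out
  loci$region_name <- name_out
  loci
}

#' Summarize classified SSR loci
#'
#' Tallies mirroring the usual SSR report panels: counts per motif length,
#' per region class, and per motif.
#'
#' @param loci output of [classify_ssrs()]
#' @return list of three tables: `by_unit_len`, `by_region`, `by_motif`
#' @export
ssr_summary <- function(loci) {
  list(
    by_unit_len = table(factor(loci$unit_len, levels = 1:6)),
    by_region = if ("region_category" %in% names(loci)) {
      table(factor(loci$region_category,
                   levels = c("CDS", "IGS", "intron", "other")))
    } else NULL,
    by_motif = sort(table(loci$motif), decreasing = TRUE)
  )
}
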