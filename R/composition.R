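# Composition accounting: GC content (overall, per partition, per codon
# position), codon usage under the plastid (bacterial) genetic code, and the
# per-genome summary table.

#' GC content of a sequence
#'
#' (G+C) / (A+C+G+T); N is excluded from the denominator. An all-N (or empty
#' after N removal) sequence yields NA with a warning.
#'
#' @param sequence DNA string(s)
#' @return GC fraction in `[0, 1]` (vectorized)
#' @export
gc_content <- function(sequence) {
  vapply(sequence, function(s) {
    stopifnot(nchar(s) > 0)
    v <- chars(toupper(s))
    den <- sum(v %in% DNA_BASES)
    if (den == 0) {
      warning("GC content undefined: no unambiguous bases")
      return(NA_real_)
    }
    sum(v %in% c("G", "C")) / den
  }, numeric(1), USE.NAMES = FALSE)
}

#' GC content by codon position
#'
#' Pools all supplied coding regions and returns the GC fraction at each of
#' the three codon offsets. Regions whose length is not divisible by 3 are
#' excluded with a warning.
#'
#' @param coding_regions character vector of spliced CDS sequences
#' @return numeric vector c(p1, p2, p3) of GC fractions
#' @export
gc_by_codon_position <- function(coding_regions) {
  ok <- nchar(coding_regions) %% 3 == 0
  if (any(!ok)) {
    warning(sprintf("%d region(s) not divisible by 3 excluded", sum(!ok)))
    coding_regions <- coding_regions[ok]
  }
  counts <- matrix(0, nrow = 3, ncol = 2,
                   dimnames = list(NULL, c("gc", "acgt")))
  for (s in coding_regions) {
    v <- chars(toupper(s))
    pos <- ((seq_along(v) - 1) %% 3) + 1
    for (p in 1:3) {
      vp <- v[pos == p]
      counts[p, "gc"] <- counts[p, "gc"] + sum(vp %in% c("G", "C"))
      counts[p, "acgt"] <- counts[p, "acgt"] + sum(vp %in% DNA_BASES)
    }
  }
  as.numeric(counts[, "gc"] / counts[, "acgt"])
}

split_codons <- function(s) {
  len <- nchar(s)
  stopifnot(len %% 3 == 0)
  if (len == 0) return(character())
  substring(s, seq(1, len - 2, 3), seq(3, len, 3))
}

#' Codon usage table
#'
#' Counts per codon and per amino acid (plastid/bacterial code; stops counted
#' under "*"). Codons containing an ambiguous base go to a separate
#' `ambiguous` bin. Amino-acid percentages use the total codon count
#' (including stops) as denominator.
#'
#' @param coding_regions character vector of spliced CDS sequences with
#'   lengths divisible by 3
#' @return list with `codon_counts` (named, 64 entries), `aa_counts`,
#'   `aa_percent`, `total_codons`, `ambiguous`
#' @export
codon_usage <- function(coding_regions) {
  codons <- unlist(lapply(toupper(coding_regions), split_codons))
  ambig <- grepl("[^ACGT]", codons)
  clean <- codons[!ambig]
  codon_counts <- setNames(integer(length(ALL_CODONS)), ALL_CODONS)
  if (length(clean)) {
    tab <- table(factor(clean, levels = ALL_CODONS))
    codon_counts[] <- as.integer(tab)
  }
  aas <- GENETIC_CODE_PLASTID[ALL_CODONS]
  aa_counts <- tapply(codon_counts, aas, sum)
  total <- length(codons)
  list(
    codon_counts = codon_counts,
    aa_counts = aa_counts,
    aa_percent = if (total > 0) percent_of(aa_counts, total) else aa_counts * NA_real_,
    total_codons = total,
    ambiguous = sum(ambig)
  )
}

#' Genome summary statistics
#'
#' The per-genome characteristics table: length, gene counts by kind,
#' partition sizes (summed exon lengths) with percent of genome, GC content
#' overall and per partition, and GC by codon position over all CDS.
#' Partitions with no genes report size 0 and NA GC.
#'
#' @param record a [plastome_record()]
#' @return a one-row data frame
#' @export
genome_summary <- function(record) {
  n <- nchar(record$sequence)
  kinds <- vapply(record$features, `[[`, character(1), "kind")
  lens <- vapply(record$features, feature_length, numeric(1))
  size_of <- function(k) as.integer(sum(lens[kinds == k]))
  gc_of <- function(k) {
    feats <- record$features[kinds == k]
    if (!length(feats)) return(NA_real_)
    seqs <- vapply(feats, function(f) feature_sequence(record, f), character(1))
    gc_content(collapse0(seqs))
  }
  coding <- extract_coding(record)
  cds_ok <- coding$sequence[coding$length %% 3 == 0]
  gc_pos <- if (length(cds_ok)) gc_by_codon_position(cds_ok) else rep(NA_real_, 3)

  data.frame(
    id = record$id,
    length = n,
    n_genes = length(record$features),
    n_cds = sum(kinds == "CDS"),
    n_trna = sum(kinds == "tRNA"),
    n_rrna = sum(kinds == "rRNA"),
    size_cds = size_of("CDS"),
    size_trna = size_of("tRNA"),
    size_rrna = size_of("rRNA"),
    pct_cds = percent_of(size_of("CDS"), n),
    pct_trna = percent_of(size_of("tRNA"), n),
    pct_rrna = percent_of(size_of("rRNA"), n),
    gc_overall = round_half_up(100 * gc_content(record$sequence)),
    gc_cds = if (is.na(gc_of("CDS"))) NA_real_ else round_half_up(100 * gc_of("CDS")),
    gc_trna = if (is.na(gc_of("tRNA"))) NA_real_ else round_half_up(100 * gc_of("tRNA")),
    gc_rrna = if (is.na(gc_of("rRNA"))) NA_real_ else round_half_up(100 * gc_of("rRNA")),
    gc_pos1 = round_half_up(100 * gc_pos[1]),
    gc_pos2 = round_half_up(100 * gc_pos[2]),
    gc_pos3 = round_half_up(100 * gc_pos[3]),
    stringsAsFactors = FALSE
  )
}
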