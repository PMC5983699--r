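# Divergence-hotspot screening: pairwise global alignment of homologous
# regions, Kimura 2-parameter distances, and the mean + 2 SD threshold rule.

#' Global pairwise alignment with affine gap penalties
#'
#' Deterministic Needleman-Wunsch alignment (Biostrings backend) with unit
#' match/mismatch scores and the gap penalties used for plastome region
#' alignment (open 10, extend 2; a gap of length L costs open + L * extend).
#'
#' @param seq_a,seq_b DNA strings
#' @param match match score (default 1)
#' @param mismatch mismatch score (default -1)
#' @param gap_open gap opening penalty, applied as a cost (default 10)
#' @param gap_extend gap extension penalty per gapped position (default 2)
#' @param id_a,id_b optional sequence labels
#' @return list with `id_a`, `id_b`, `gapped_a`, `gapped_b`, `score`
#' @export
align_pair <- function(seq_a, seq_b, match = 1, mismatch = -1,
                       gap_open = 10, gap_extend = 2,
                       id_a = "a", id_b = "b") {
  stopifnot(nchar(seq_a) > 0, nchar(seq_b) > 0)
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = match, mismatch = mismatch, baseOnly = FALSE, type = "DNA")
  aln <- Biostrings::pairwiseAlignment(
    toupper(seq_a), toupper(seq_b), type = "global",
    substitutionMatrix = mat,
    gapOpening = gap_open, gapExtension = gap_extend)
  ga <- as.character(Biostrings::alignedPattern(aln))
  gb <- as.character(Biostrings::alignedSubject(aln))
  list(id_a = id_a, id_b = id_b, gapped_a = unname(ga), gapped_b = unname(gb),
       score = Biostrings::score(aln))
}

#' Kimura 2-parameter distance of an aligned pair
#'
#' Over columns where both symbols are unambiguous bases (gap and N columns
#' excluded; pairwise deletion), computes the transition proportion P, the
#' transversion proportion Q and the corrected distance
#' d = -1/2 * ln((1 - 2P - Q) * sqrt(1 - 2Q)). The distance is undefined
#' (saturated) when 1 - 2P - Q <= 0 or 1 - 2Q <= 0, and when no comparable
#' sites remain.
#'
#' @param alignment list with `gapped_a`/`gapped_b` (from [align_pair()]), or
#'   a character vector of two equal-length gapped sequences
#' @return list with `P`, `Q`, `d`, `n_sites`, `defined`
#' @export
k2p <- function(alignment) {
  if (is.character(alignment) && length(alignment) == 2) {
    ga <- alignment[1]; gb <- alignment[2]
  } else {
    ga <- alignment$gapped_a; gb <- alignment$gapped_b
  }
  stopifnot(nchar(ga) == nchar(gb))
  a <- chars(toupper(ga)); b <- chars(toupper(gb))
  ok <- a %in% DNA_BASES & b %in% DNA_BASES
  n <- sum(ok)
  if (n == 0) {
    warning("no comparable sites; K2p undefined")
    return(list(P = NA_real_, Q = NA_real_, d = NA_real_,
                n_sites = 0L, defined = FALSE))
  }
  a <- a[ok]; b <- b[ok]
  diff <- a != b
  both_pur <- a %in% PURINES & b %in% PURINES
  both_pyr <- a %in% PYRIMIDINES & b %in% PYRIMIDINES
  ts <- sum(diff & (both_pur | both_pyr))
  tv <- sum(diff & !(both_pur | both_pyr))
  P <- ts / n
  Q <- tv / n
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) {
    return(list(P = P, Q = Q, d = NA_real_, n_sites = as.integer(n),
                defined = FALSE))
  }
  d <- -0.5 * log(w1 * sqrt(w2))
  list(P = P, Q = Q, d = d, n_sites = as.integer(n), defined = TRUE)
}

#' Per-region, per-species-pair K2p distance table
#'
#' Aligns each homologous region (matched across species by name) for every
#' species pair and computes the K2p distance. Regions present in fewer than
#' two species are skipped. When `prealigned = TRUE` the sequences are used
#' as-is (they must be equal length per region), bypassing the aligner —
#' useful for simulator truth alignments or externally aligned input.
#'
#' @param region_list named list (per species) of region data frames, as
#'   produced by [extract_igs()] etc.
#' @param prealigned logical; skip the internal aligner
#' @param categories optional filter, e.g. "IGS"
#' @return data frame: region, category, species_a, species_b, P, Q, d,
#'   n_sites, defined
#' @export
region_distance_table <- function(region_list, prealigned = FALSE,
                                  categories = NULL) {
  if (!is.null(categories)) {
    region_list <- lapply(region_list, function(df) {
      df[df$category %in% categories, , drop = FALSE]
    })
  }
  matched <- match_regions(region_list)
  rows <- list()
  for (nm in names(matched)) {
    df <- matched[[nm]]
    sp <- sort(unique(df$species))
    for (i in seq_len(length(sp) - 1)) {
      for (j in (i + 1):length(sp)) {
        sa <- df$sequence[df$species == sp[i]][1]
        sb <- df$sequence[df$species == sp[j]][1]
        if (prealigned) {
          stopifnot(nchar(sa) == nchar(sb))
          res <- k2p(c(sa, sb))
        } else {
          res <- suppressWarnings(k2p(align_pair(sa, sb)))
        }
        rows[[length(rows) + 1]] <- data.frame(
          region = nm, category = df$category[1],
          species_a = sp[i], species_b = sp[j],
          P = res$P, Q = res$Q, d = res$d, n_sites = res$n_sites,
          defined = res$defined, stringsAsFactors = FALSE
        )
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(region = character(), category = character(),
                      species_a = character(), species_b = character(),
                      P = numeric(), Q = numeric(), d = numeric(),
                      n_sites = integer(), defined = logical(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Divergence-hotspot threshold: mean + 2 standard deviations
#'
#' The screening threshold over a pool of K2p values: arithmetic mean plus
#' `k` sample standard deviations (n - 1 denominator). NA (undefined)
#' values are dropped.
#'
#' @param values numeric vector of K2p distances
#' @param k SD multiplier (default 2)
#' @return the threshold
#' @export
hotspot_threshold <- function(values, k = 2) {
  values <- values[!is.na(values)]
  if (length(values) < 2) stop("need at least 2 defined values")
  mean(values) + k * sd(values)
}

#' Identify divergence hotspot regions
#'
#' Regions whose maximum pairwise K2p distance reaches the threshold, sorted
#' by that maximum, descending.
#'
#' @param table distance table from [region_distance_table()]
#' @param threshold numeric threshold (e.g. from [hotspot_threshold()])
#' @return data frame: region, max_d, ordered by max_d descending
#' @export
identify_hotspots <- function(table, threshold) {
  def <- table[table$defined & !is.na(table$d), , drop = FALSE]
  if (!nrow(def)) {
    return(data.frame(region = character(), max_d = numeric(),
                      stringsAsFactors = FALSE))
  }
  mx <- aggregate(d ~ region, data = def, FUN = max)
  names(mx) <- c("region", "max_d")
  mx <- mx[mx$max_d >= threshold & mx$max_d > 0, , drop = FALSE]
  mx <- mx[order(-mx$max_d, mx$region), , drop = FALSE]
  rownames(mx) <- NULL
  mx
}
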