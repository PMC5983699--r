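# Homologous region classes compared across species: spliced coding
# sequences (exons), introns, and intergenic spacers (IGS).
#
# Regions are returned as a data frame with 1-based inclusive coordinates
# (`start`, `end`); multi-part coding regions report the extent of the gene
# and carry the spliced sequence. IGS are unoriented (+ strand slices) and
# named "upstream-downstream" in genome order, matching the rps12-clpP style
# of label used throughout plastome comparative work.

region_df <- function(name, category, start0, end0, strand, sequence, source_id,
                      flag = NA_character_) {
  data.frame(
    name = name, category = category,
    start = start0 + 1L, end = as.integer(end0),
    strand = strand, length = nchar(sequence),
    sequence = sequence, source_id = source_id,
    flag = flag, stringsAsFactors = FALSE
  )
}

empty_regions <- function() {
  region_df(character(), character(), integer(), integer(),
            character(), character(), character(), character())
}

#' Extract spliced protein-coding regions
#'
#' One region per CDS feature, exons spliced in transcript order and
#' strand-corrected (minus-strand genes are reverse-complemented). Non-pseudo
#' genes whose spliced length is not divisible by 3 are kept with a
#' `length_not_multiple_of_3` flag and a warning.
#'
#' @param record a [plastome_record()]
#' @return data frame of regions (category "exon")
#' @export
extract_coding <- function(record) {
  cds <- Filter(function(f) f$kind == "CDS", record$features)
  if (!length(cds)) return(empty_regions())
  rows <- lapply(cds, function(f) {
    s <- feature_sequence(record, f)
    flag <- NA_character_
    if (!f$pseudo && nchar(s) %% 3 != 0) {
      warning(sprintf("CDS '%s' length %d not divisible by 3", f$name, nchar(s)))
      flag <- "length_not_multiple_of_3"
    }
    ext <- feature_extent(f)
    region_df(f$name, "exon", ext[1], ext[2], f$strand, s, record$id, flag)
  })
  do.call(rbind, rows)
}

#' Extract introns
#'
#' For each gene with k exons, the k-1 gaps between consecutive exons in
#' genome orientation, named `gene.intron1` ... in genome order. Sequences
#' are + strand slices (introns are only consumed by unoriented distance
#' comparisons).
#'
#' @param record a [plastome_record()]
#' @return data frame of regions (category "intron")
#' @export
extract_introns <- function(record) {
  rows <- list()
  for (f in record$features) {
    k <- nrow(f$exons)
    if (k < 2) next
    for (i in seq_len(k - 1)) {
      s0 <- f$exons[i, 2]
      e0 <- f$exons[i + 1, 1]
      if (e0 <= s0) stop(sprintf("gene '%s': overlapping exons", f$name))
      rows[[length(rows) + 1]] <- region_df(
        sprintf("%s.intron%d", f$name, i), "intron",
        s0, e0, "+", subseq0(record$sequence, s0, e0), record$id
      )
    }
  }
  if (!length(rows)) return(empty_regions())
  do.call(rbind, rows)
}

#' Extract intergenic spacers (IGS)
#'
#' Gene extents (min exon start to max exon end, introns included) are sorted
#' by start; a spacer is emitted between each adjacent pair and named
#' `"upstream-downstream"` in genome order. On circular records the
#' wrap-around spacer between the last and first gene is included. Spacers of
#' length < 1 (overlapping or abutting genes) are omitted.
#'
#' @param record a [plastome_record()]
#' @return data frame of regions (category "IGS")
#' @export
extract_igs <- function(record) {
  feats <- record$features
  if (length(feats) < 2) {
    warning("fewer than 2 genes: no intergenic spacers")
    return(empty_regions())
  }
  ext <- t(vapply(feats, feature_extent, numeric(2)))
  o <- order(ext[, 1])
  feats <- feats[o]
  ext <- ext[o, , drop = FALSE]
  n <- nchar(record$sequence)
  k <- length(feats)
  rows <- list()
  last <- if (record$circular) k else k - 1
  for (i in seq_len(last)) {
    j <- if (i == k) 1 else i + 1
    s0 <- ext[i, 2]
    e0 <- if (i == k) ext[j, 1] + n else ext[j, 1]
    if (e0 - s0 < 1) next
    rows[[length(rows) + 1]] <- region_df(
      sprintf("%s-%s", feats[[i]]$name, feats[[j]]$name), "IGS",
      s0, e0, "+", subseq0(record$sequence, s0, e0), record$id
    )
  }
  if (!length(rows)) return(empty_regions())
  out <- do.call(rbind, rows)
  out$end <- ifelse(out$end > n, out$end - n, out$end)  # wrap spacer reporting
  out
}

#' Extract all region classes of a record
#'
#' @param record a [plastome_record()]
#' @return data frame with categories exon, intron and IGS
#' @export
extract_regions <- function(record) {
  rbind(extract_coding(record), extract_introns(record), extract_igs(record))
}

#' Group regions of several records by region name
#'
#' Regions are matched across species by normalized name equality. Regions
#' present in fewer than two species are dropped with a note.
#'
#' @param region_list named list (one entry per record id) of region data
#'   frames as returned by [extract_regions()] and friends
#' @param quiet suppress notes about skipped regions
#' @return named list of data frames, one per shared region name
#' @export
match_regions <- function(region_list, quiet = TRUE) {
  stopifnot(is.list(region_list), !is.null(names(region_list)))
  all_rows <- do.call(rbind, Map(function(df, id) {
    df$species <- id
    df
  }, region_list, names(region_list)))
  split_by <- split(all_rows, all_rows$name)
  shared <- Filter(function(df) length(unique(df$species)) >= 2, split_by)
  skipped <- setdiff(names(split_by), names(shared))
  if (length(skipped) && !quiet) {
    message("skipped regions present in < 2 species: ",
            paste(head(skipped, 10), collapse = ", "),
            if (length(skipped) > 10) " ..." else "")
  }
  shared
}
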