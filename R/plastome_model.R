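# Domain model: annotated plastome records.
#
# Coordinates are 0-based half-open internally; every user-facing table emits
# 1-based inclusive positions to match the GenBank convention. Sequences are
# uppercased on ingest; N is allowed but excluded from GC and distance
# denominators downstream.

#' Construct a gene feature
#'
#' A single annotated gene: a name, a kind (CDS/tRNA/rRNA), a strand and an
#' ordered set of exons. Exons are stored in ascending genome order as a
#' two-column matrix of 0-based half-open intervals; for minus-strand genes
#' the transcript order is the reverse.
#'
#' @param name gene symbol (normalized with [normalize_gene_name()])
#' @param kind one of "CDS", "tRNA", "rRNA"
#' @param exons two-column matrix (start, end), 0-based half-open, ascending
#' @param strand "+" or "-"
#' @param pseudo logical; pseudogenes are treated as absent by the gene-loss
#'   module and exempt from the length-divisible-by-3 check
#' @return an object of class `gene_feature`
#' @export
gene_feature <- function(name, kind = c("CDS", "tRNA", "rRNA"),
                         exons, strand = "+", pseudo = FALSE) {
  kind <- match.arg(kind)
  exons <- matrix(as.integer(exons), ncol = 2,
                  dimnames = list(NULL, c("start", "end")))
  if (any(exons[, 2] <= exons[, 1])) {
    stop(sprintf("feature '%s': empty or inverted exon interval", name))
  }
  if (nrow(exons) > 1) {
    o <- order(exons[, 1])
    exons <- exons[o, , drop = FALSE]
    if (any(exons[-1, 1] < exons[-nrow(exons), 2])) {
      stop(sprintf("feature '%s': overlapping exons", name))
    }
  }
  structure(
    list(name = name, kind = kind, exons = exons,
         strand = strand, pseudo = isTRUE(pseudo)),
    class = "gene_feature"
  )
}

feature_extent <- function(f) c(min(f$exons[, 1]), max(f$exons[, 2]))

feature_length <- function(f) sum(f$exons[, 2] - f$exons[, 1])

#' Construct an annotated plastome record
#'
#' @param id accession or identifier string
#' @param sequence DNA string over A,C,G,T,N (uppercased on ingest)
#' @param features list of [gene_feature()] objects
#' @param organism organism name
#' @param circular logical; plastomes are circular molecules
#' @return an object of class `plastome_record`
#' @export
plastome_record <- function(id, sequence, features = list(),
                            organism = "", circular = TRUE) {
  stopifnot(nchar(sequence) > 0)
  stop_if_not_dna(sequence)
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  for (f in features) {
    ext <- feature_extent(f)
    if (ext[1] < 0 || ext[2] > n) {
      stop(sprintf("feature '%s' lies outside [0, %d)", f$name, n))
    }
  }
  structure(
    list(id = id, organism = organism, sequence = sequence,
         circular = isTRUE(circular), features = features),
    class = "plastome_record"
  )
}

#' @export
print.plastome_record <- function(x, ...) {
  kinds <- vapply(x$features, function(f) f$kind, character(1))
  cat(sprintf("<plastome_record> %s (%s)\n", x$id,
              if (x$circular) "circular" else "linear"))
  cat(sprintf("  %d bp; %d features (%d CDS, %d tRNA, %d rRNA)\n",
              nchar(x$sequence), length(x$features),
              sum(kinds == "CDS"), sum(kinds == "tRNA"), sum(kinds == "rRNA")))
  invisible(x)
}

# Spliced transcript sequence of a feature (reverse-complemented for "-").
feature_sequence <- function(record, f) {
  parts <- apply(f$exons, 1, function(e) subseq0(record$sequence, e[1], e[2]))
  s <- collapse0(parts)
  if (f$strand == "-") revcomp(s) else s
}

# ---------------------------------------------------------------------------
# Gene-name normalization

# Canonical plastid gene symbols (community capitalization).
PLASTID_GENE_NAMES <- c(
  "accD", "atpA", "atpB", "atpE", "atpF", "atpH", "atpI",
  "ccsA", "cemA", "clpP", "infA", "matK",
  paste0("ndh", LETTERS[1:11]),
  "petA", "petB", "petD", "petG", "petL", "petN",
  "psaA", "psaB", "psaC", "psaI", "psaJ",
  "psbA", "psbB", "psbC", "psbD", "psbE", "psbF", "psbH", "psbI",
  "psbJ", "psbK", "psbL", "psbM", "psbN", "psbT", "psbZ",
  "rbcL",
  "rpl2", "rpl14", "rpl16", "rpl20", "rpl22", "rpl23", "rpl32", "rpl33", "rpl36",
  "rpoA", "rpoB", "rpoC1", "rpoC2",
  "rps2", "rps3", "rps4", "rps7", "rps8", "rps11", "rps12", "rps14",
  "rps15", "rps16", "rps18", "rps19",
  "rrn16", "rrn23", "rrn4.5", "rrn5",
  "ycf1", "ycf2", "ycf3", "ycf4", "ycf15"
)

#' Normalize a gene name to its community-standard capitalization
#'
#' Case-insensitive match against the canonical plastid gene set (e.g.
#' `"Rps12"` to `"rps12"`, `"PSBA"` to `"psbA"`). tRNA names are rebuilt as
#' `trnX-ANT` with the amino-acid letter and anticodon uppercased (`"TRNI-CAU"`
#' to `"trnI-CAU"`; the initiator `trnfM-CAU` keeps its `fM`). Unknown names
#' are trimmed and passed through verbatim with attribute `unknown = TRUE`.
#'
#' @param raw raw gene name(s)
#' @return normalized name(s); unknown names carry attribute `unknown`
#' @export
normalize_gene_name <- function(raw) {
  out <- vapply(raw, function(x) {
    x <- trimws(x)
    if (grepl("^trn", x, ignore.case = TRUE)) {
      body <- sub("^trn", "", x, ignore.case = TRUE)
      m <- regmatches(body, regexec("^(f?[A-Za-z])[-_]?([A-Za-z]{3})?", body))[[1]]
      aa <- m[2]
      aa <- if (tolower(aa) == "fm" || grepl("^f", aa)) "fM" else toupper(aa)
      ac <- m[3]
      if (!is.na(ac) && nzchar(ac)) paste0("trn", aa, "-", toupper(ac))
      else paste0("trn", aa)
    } else {
      hit <- match(tolower(x), tolower(PLASTID_GENE_NAMES))
      if (!is.na(hit)) PLASTID_GENE_NAMES[hit] else x
    }
  }, character(1), USE.NAMES = FALSE)
  known <- tolower(out) %in% tolower(PLASTID_GENE_NAMES) |
    grepl("^trn", out)
  if (any(!known)) attr(out, "unknown") <- !known
  out
}

# ---------------------------------------------------------------------------
# GenBank flat-file I/O

parse_gb_location <- function(loc, feature_name = "?") {
  loc <- gsub("[[:space:]<>]", "", loc)
  strand <- "+"
  if (grepl("^complement\\(", loc)) {
    if (!grepl("\\)$", loc)) stop(sprintf("malformed location for '%s': %s", feature_name, loc))
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
    strand <- "-"
  }
  if (grepl("^(join|order)\\(", loc)) {
    if (!grepl("\\)$", loc)) stop(sprintf("malformed location for '%s': %s", feature_name, loc))
    loc <- sub("^(join|order)\\((.*)\\)$", "\\2", loc)
  }
  if (grepl("complement|join|order", loc)) {
    stop(sprintf("malformed or unsupported location for '%s': %s", feature_name, loc))
  }
  parts <- strsplit(loc, ",", fixed = TRUE)[[1]]
  exons <- t(vapply(parts, function(p) {
    if (grepl("^[0-9]+\\.\\.[0-9]+$", p)) {
      se <- as.integer(strsplit(p, "..", fixed = TRUE)[[1]])
    } else if (grepl("^[0-9]+$", p)) {
      se <- c(as.integer(p), as.integer(p))
    } else {
      stop(sprintf("malformed location for '%s': %s", feature_name, p))
    }
    c(se[1] - 1L, se[2])  # 1-based inclusive -> 0-based half-open
  }, integer(2)))
  list(exons = exons, strand = strand)
}

infer_kind_from_name <- function(name) {
  ifelse(grepl("^trn", name), "tRNA",
         ifelse(grepl("^rrn", name), "rRNA", "CDS"))
}

#' Read a single-record GenBank flat file
#'
#' Parses LOCUS, FEATURES and ORIGIN of a one-record GenBank file.
#' `join()`/`complement()` locations become multi-exon features with strand;
#' 1-based inclusive coordinates are converted to the internal 0-based
#' half-open convention. `gene` features and their `CDS`/`tRNA`/`rRNA`
#' children are reconciled by gene name, the typed child winning; a bare
#' `gene` with no typed child is kept with its kind inferred from the name
#' prefix (trn = tRNA, rrn = rRNA, otherwise CDS).
#'
#' @param path path to a GenBank flat file
#' @return a [plastome_record()]
#' @export
read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  locus_i <- grep("^LOCUS", lines)
  if (length(locus_i) != 1) stop("expected exactly one LOCUS line")
  locus <- strsplit(trimws(lines[locus_i]), "[[:space:]]+")[[1]]
  id <- locus[2]
  circular <- any(tolower(locus) == "circular")
  org_i <- grep("^  ORGANISM", lines)
  organism <- if (length(org_i)) trimws(sub("^  ORGANISM", "", lines[org_i[1]])) else ""

  feat_i <- grep("^FEATURES", lines)
  orig_i <- grep("^ORIGIN", lines)
  if (length(orig_i) != 1) stop("missing ORIGIN/sequence section")
  seq_lines <- lines[(orig_i + 1):length(lines)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  sequence <- toupper(gsub("[0-9[:space:]/]", "", collapse0(seq_lines)))
  if (!nzchar(sequence)) stop("missing sequence under ORIGIN")
  stop_if_not_dna(sequence, "GenBank sequence")

  raw_feats <- list()
  if (length(feat_i) == 1) {
    block <- lines[(feat_i + 1):(orig_i - 1)]
    cur <- NULL
    for (ln in block) {
      key <- substr(ln, 6, 20)
      rest <- trimws(substr(ln, 21, nchar(ln)))
      if (nzchar(trimws(key))) {
        if (!is.null(cur)) raw_feats[[length(raw_feats) + 1]] <- cur
        cur <- list(key = trimws(key), loc = rest, quals = character())
      } else if (!is.null(cur)) {
        if (startsWith(rest, "/")) {
          cur$quals <- c(cur$quals, rest)
        } else {
          cur$loc <- paste0(cur$loc, rest)  # continued location
        }
      }
    }
    if (!is.null(cur)) raw_feats[[length(raw_feats) + 1]] <- cur
  }

  get_qual <- function(f, name) {
    pat <- paste0("^/", name, "=")
    hit <- grep(pat, f$quals, value = TRUE)
    if (!length(hit)) return(NA_character_)
    gsub('^"|"$', "", sub(pat, "", hit[1]))
  }

  keep <- c("gene", "CDS", "tRNA", "rRNA")
  feats <- list()
  for (f in raw_feats) {
    if (!(f$key %in% keep)) next
    name <- get_qual(f, "gene")
    if (is.na(name)) name <- get_qual(f, "locus_tag")
    if (is.na(name)) next
    name <- normalize_gene_name(name)
    loc <- parse_gb_location(f$loc, name)
    pseudo <- any(grepl("^/pseudo", f$quals))
    feats[[length(feats) + 1]] <- list(
      key = f$key, name = as.character(name), exons = loc$exons,
      strand = loc$strand, pseudo = pseudo
    )
  }

  # Reconcile: typed child (CDS/tRNA/rRNA) wins over bare gene with same name.
  keys <- vapply(feats, `[[`, character(1), "key")
  names_ <- vapply(feats, `[[`, character(1), "name")
  out <- list()
  for (nm in unique(names_)) {
    mine <- feats[names_ == nm]
    typed <- mine[vapply(mine, function(x) x$key != "gene", logical(1))]
    chosen <- if (length(typed)) typed else mine
    for (x in chosen) {
      kind <- if (x$key == "gene") infer_kind_from_name(nm) else x$key
      out[[length(out) + 1]] <- gene_feature(
        nm, kind = kind, exons = x$exons, strand = x$strand, pseudo = x$pseudo
      )
    }
  }
  plastome_record(id, sequence, out, organism = organism, circular = circular)
}

format_gb_location <- function(f) {
  parts <- apply(f$exons, 1, function(e) sprintf("%d..%d", e[1] + 1, e[2]))
  loc <- if (length(parts) > 1) sprintf("join(%s)", paste(parts, collapse = ",")) else parts
  if (f$strand == "-") sprintf("complement(%s)", loc) else loc
}

#' Write a plastome record as a GenBank flat file
#'
#' Emits LOCUS, minimal source/gene/CDS/tRNA/rRNA features (1-based inclusive
#' coordinates) and the ORIGIN block. Round-trips through [read_genbank()].
#'
#' @param record a [plastome_record()]
#' @param path output path
#' @return invisibly, the path
#' @export
write_genbank <- function(record, path) {
  n <- nchar(record$sequence)
  lines <- c(
    sprintf("LOCUS       %-16s %d bp    DNA     %s PLN 01-JAN-2026",
            record$id, n, if (record$circular) "circular" else "linear"),
    sprintf("DEFINITION  %s plastome.", record$id),
    sprintf("ACCESSION   %s", record$id),
    "  ORGANISM  " , "FEATURES             Location/Qualifiers",
    sprintf("     source          1..%d", n)
  )
  lines[4] <- sprintf("  ORGANISM  %s", record$organism)
  for (f in record$features) {
    loc <- format_gb_location(f)
    lines <- c(lines,
               sprintf("     gene            %s", loc),
               sprintf("                     /gene=\"%s\"", f$name),
               sprintf("     %-15s %s", f$kind, loc),
               sprintf("                     /gene=\"%s\"", f$name))
    if (f$pseudo) lines <- c(lines, "                     /pseudo")
  }
  lines <- c(lines, "ORIGIN")
  s <- tolower(record$sequence)
  for (i in seq(1, n, by = 60)) {
    starts <- seq(i, min(i + 59, n), by = 10)
    block <- substring(s, starts, pmin(starts + 9, n))
    lines <- c(lines, sprintf("%9d %s", i, paste(block, collapse = " ")))
  }
  lines <- c(lines, "//")
  writeLines(lines, path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# FASTA I/O (Biostrings-backed)

#' Read a FASTA file
#'
#' @param path FASTA path
#' @return named character vector of uppercased sequences
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (!length(set)) stop("empty FASTA file: ", path)
  seqs <- toupper(as.character(set))
  names(seqs) <- sub("[[:space:]].*$", "", names(set))
  stop_if_not_dna(seqs, "FASTA sequence")
  seqs
}

#' Write sequences as FASTA (60-column wrapping)
#'
#' @param records named character vector of sequences
#' @param path output path
#' @return invisibly, the path
#' @export
write_fasta <- function(records, path) {
  stop_if_not_dna(records, "FASTA sequence")
  set <- Biostrings::DNAStringSet(toupper(records))
  Biostrings::writeXStringSet(set, path, width = 60)
  invisible(path)
}
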