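# Pairwise Ka/Ks screen, Nei-Gojobori (1986) counting with Jukes-Cantor
# correction.
#
# Per codon, the synonymous site count is the expected fraction of the three
# possible single-nucleotide changes at each position that preserve the
# amino acid; changes creating a stop codon count as nonsynonymous, which
# keeps N_sites + S_sites = 3 per codon. Codon pairs differing at several
# positions are averaged over all minimal mutational pathways; pathways
# passing through a stop codon are excluded (falling back to all pathways if
# every ordering is blocked). Proportions are Jukes-Cantor corrected:
# k = -3/4 * ln(1 - 4p/3).

codon_neighbors <- function(codon) {
  v <- chars(codon)
  out <- character(0)
  for (pos in 1:3) {
    for (b in setdiff(DNA_BASES, v[pos])) {
      w <- v
      w[pos] <- b
      out <- c(out, collapse0(w))
    }
  }
  out
}

is_stop_codon <- function(codon) GENETIC_CODE_PLASTID[[codon]] == "*"

# Fractional synonymous site count of one codon (0..3).
ng86_syn_sites <- function(codon) {
  aa <- GENETIC_CODE_PLASTID[[codon]]
  nb <- codon_neighbors(codon)
  sum(vapply(nb, function(x) {
    !is_stop_codon(x) && GENETIC_CODE_PLASTID[[x]] == aa
  }, logical(1))) / 3
}

# Synonymous/nonsynonymous substitution counts between two codons, averaged
# over minimal mutational pathways.
ng86_path_counts <- function(ca, cb) {
  va <- chars(ca); vb <- chars(cb)
  diff_pos <- which(va != vb)
  k <- length(diff_pos)
  if (k == 0) return(c(sd = 0, nd = 0))
  perms <- if (k == 1) list(diff_pos) else {
    idx <- seq_len(k)
    p <- list()
    permute <- function(prefix, rest) {
      if (!length(rest)) { p[[length(p) + 1]] <<- diff_pos[prefix]; return() }
      for (r in seq_along(rest)) permute(c(prefix, rest[r]), rest[-r])
    }
    permute(integer(0), idx)
    p
  }
  score_path <- function(order_pos, allow_stops) {
    cur <- va
    sd <- 0; nd <- 0
    for (pos in order_pos) {
      nxt <- cur
      nxt[pos] <- vb[pos]
      c1 <- collapse0(cur); c2 <- collapse0(nxt)
      if (!allow_stops && is_stop_codon(c2)) return(NULL)
      if (GENETIC_CODE_PLASTID[[c1]] == GENETIC_CODE_PLASTID[[c2]]) {
        sd <- sd + 1
      } else {
        nd <- nd + 1
      }
      cur <- nxt
    }
    c(sd = sd, nd = nd)
  }
  res <- Filter(Negate(is.null), lapply(perms, score_path, allow_stops = FALSE))
  if (!length(res)) res <- lapply(perms, score_path, allow_stops = TRUE)
  m <- do.call(rbind, res)
  c(sd = mean(m[, "sd"]), nd = mean(m[, "nd"]))
}

#' Nei-Gojobori (1986) Ka/Ks for a codon-aligned pair
#'
#' @param seq_a,seq_b gapless codon-aligned CDS strings of equal length
#'   divisible by 3 (plastid/bacterial genetic code). Codon pairs where
#'   either codon contains an ambiguous base or is a stop are excluded.
#' @return list with `Ka`, `Ks`, `ratio`, `N_sites`, `S_sites`, `Nd`, `Sd`,
#'   `codons_compared`, `defined` (FALSE when either proportion saturates
#'   the Jukes-Cantor correction); `ratio` is NA when Ks is 0 or undefined
#' @export
ng86 <- function(seq_a, seq_b) {
  seq_a <- toupper(seq_a); seq_b <- toupper(seq_b)
  if (nchar(seq_a) != nchar(seq_b)) stop("sequences must be equal length")
  if (nchar(seq_a) %% 3 != 0) stop("length not divisible by 3")
  ca <- split_codons(seq_a)
  cb <- split_codons(seq_b)
  bad <- function(x) grepl("[^ACGT]", x) || is_stop_codon(x)
  usable <- !vapply(ca, bad, logical(1)) & !vapply(cb, bad, logical(1))
  ca <- ca[usable]; cb <- cb[usable]
  S <- 0; N <- 0; Sd <- 0; Nd <- 0
  for (i in seq_along(ca)) {
    s_i <- (ng86_syn_sites(ca[i]) + ng86_syn_sites(cb[i])) / 2
    S <- S + s_i
    N <- N + (3 - s_i)
    cnt <- ng86_path_counts(ca[i], cb[i])
    Sd <- Sd + cnt[["sd"]]
    Nd <- Nd + cnt[["nd"]]
  }
  jc <- function(p) {
    if (is.nan(p)) return(NA_real_)
    x <- 1 - 4 * p / 3
    if (x <= 0) return(NA_real_)
    -0.75 * log(x)
  }
  pS <- if (S > 0) Sd / S else NaN
  pN <- if (N > 0) Nd / N else NaN
  Ks <- jc(pS)
  Ka <- jc(pN)
  defined <- !is.na(Ka) && !is.na(Ks)
  ratio <- if (defined && Ks > 0) Ka / Ks else NA_real_
  list(Ka = Ka, Ks = Ks, ratio = ratio,
       N_sites = N, S_sites = S, Nd = Nd, Sd = Sd,
       codons_compared = length(ca), defined = defined)
}

#' Pairwise Ka/Ks screen over shared genes
#'
#' Extracts the spliced CDS of each requested gene from every record and
#' computes NG86 Ka/Ks for every species pair, ranking genes by ratio. Genes
#' missing from a record, or with mismatched CDS lengths between a pair
#' (no indel handling), are skipped for that pair.
#'
#' @param records list of [plastome_record()]s
#' @param gene_names genes to screen (default: all genes shared by at least
#'   two records)
#' @return data frame: gene, species_a, species_b, Ka, Ks, ratio, Nd, Sd,
#'   N_sites, S_sites, ordered by ratio descending (NA last)
#' @export
gene_screen <- function(records, gene_names = NULL) {
  coding <- lapply(records, extract_coding)
  ids <- vapply(records, `[[`, character(1), "id")
  names(coding) <- ids
  if (is.null(gene_names)) {
    tab <- table(unlist(lapply(coding, function(df) unique(df$name))))
    gene_names <- names(tab[tab >= 2])
  }
  rows <- list()
  for (g in gene_names) {
    have <- ids[vapply(coding, function(df) g %in% df$name, logical(1))]
    if (length(have) < 2) next
    for (i in seq_len(length(have) - 1)) {
      for (j in (i + 1):length(have)) {
        sa <- coding[[have[i]]]
        sb <- coding[[have[j]]]
        a <- sa$sequence[sa$name == g][1]
        b <- sb$sequence[sb$name == g][1]
        if (nchar(a) != nchar(b)) next
        res <- ng86(a, b)
        rows[[length(rows) + 1]] <- data.frame(
          gene = g, species_a = have[i], species_b = have[j],
          Ka = res$Ka, Ks = res$Ks, ratio = res$ratio,
          Nd = res$Nd, Sd = res$Sd,
          N_sites = res$N_sites, S_sites = res$S_sites,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(gene = character(), species_a = character(),
                      species_b = character(), Ka = numeric(), Ks = numeric(),
                      ratio = numeric(), Nd = numeric(), Sd = numeric(),
                      N_sites = numeric(), S_sites = numeric(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(-out$ratio, out$gene, na.last = TRUE), , drop = FALSE]
  rownames(out) <- NULL
  out
}
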