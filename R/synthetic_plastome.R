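# Synthetic annotated plastome sets with known ground truth for every
# pipeline stage: a circular single-copy (IR-lacking) genome assembled
# gene-by-gene with intergenic spacers, planted SSRs and dispersed repeats,
# region-specific substitution rates with designated hotspot spacers,
# planted gene losses, and evolution of the root genome along a tree under
# a two-class (transition/transversion) substitution model without indels,
# so that truth alignments are positional identities.

#' Simulation configuration for synthetic plastome sets
#'
#' Defaults mirror a four-species comparative design at desk scale: 30 genes
#' (24 CDS, 4 tRNA, 2 rRNA), three intron-containing genes (the first with
#' two introns), two hotspot spacers evolving 10x faster, ten planted SSRs,
#' three planted dispersed repeats and two planted gene losses.
#'
#' @param seed integer seed driving every random choice
#' @param tree Newick string with branch lengths in expected substitutions
#'   per site (tip labels name the taxa)
#' @param n_genes total gene count
#' @param gene_length c(mean, sd) of CDS lengths in bp (rounded to codons)
#' @param igs_length c(mean, sd) of spacer lengths in bp (min 60)
#' @param intron_genes how many CDS genes carry introns (first one gets two)
#' @param base_rate global substitution-rate multiplier (branch lengths are
#'   expected substitutions/site at multiplier 1)
#' @param kappa transition/transversion rate ratio
#' @param hotspot_igs genome-order indices of the spacers evolving faster
#' @param hotspot_multiplier rate multiplier for hotspot spacers
#' @param planted_ssrs data frame (motif, n_units, igs) or NULL for the
#'   default panel of ten
#' @param planted_repeats data frame (kind, length, igs1, igs2) or NULL for
#'   the default panel of three
#' @param gene_losses data frame (taxon, gene) or NULL for the default two
#' @param omega_genes named numeric: per-gene dN/dS targets for codon-aware
#'   evolution (those genes are generated intronless on the + strand)
#' @return a `sim_config` list
#' @export
sim_config <- function(seed = 1,
                       tree = "((T1:0.005,T2:0.005):0.01,(T3:0.01,T4:0.015):0.005);",
                       n_genes = 30,
                       gene_length = c(mean = 900, sd = 300),
                       igs_length = c(mean = 300, sd = 100),
                       intron_genes = 3,
                       base_rate = 1,
                       kappa = 2,
                       hotspot_igs = c(5, 12),
                       hotspot_multiplier = 10,
                       planted_ssrs = NULL,
                       planted_repeats = NULL,
                       gene_losses = NULL,
                       omega_genes = NULL) {
  if (is.null(planted_ssrs)) {
    planted_ssrs <- data.frame(
      motif = c("A", "T", "AT", "TA", "AG", "AAT", "ACG", "AATC", "AGATC", "ACGTAC"),
      n_units = c(10, 9, 6, 5, 5, 5, 4, 4, 3, 3),
      igs = c(1, 2, 3, 4, 6, 7, 8, 9, 10, 11),
      stringsAsFactors = FALSE
    )
    planted_ssrs <- planted_ssrs[planted_ssrs$igs <= n_genes, , drop = FALSE]
  }
  if (is.null(planted_repeats)) {
    planted_repeats <- data.frame(
      kind = c("forward", "palindromic", "forward"),
      length = c(40, 35, 60),
      igs1 = c(13, 15, 17), igs2 = c(14, 16, 18),
      stringsAsFactors = FALSE
    )
    planted_repeats <- planted_repeats[planted_repeats$igs2 <= n_genes, , drop = FALSE]
  }
  hotspot_igs <- hotspot_igs[hotspot_igs <= n_genes]
  if (is.null(gene_losses)) {
    gene_losses <- data.frame(taxon = c("T2", "T4"), gene = c("g05", "g12"),
                              stringsAsFactors = FALSE)
    roster <- sim_gene_roster(n_genes)
    gene_losses <- gene_losses[gene_losses$gene %in% roster$name, , drop = FALSE]
  }
  stopifnot(base_rate >= 0, kappa > 0, n_genes >= 2)
  structure(list(
    seed = seed, tree = tree, n_genes = n_genes,
    gene_length = gene_length, igs_length = igs_length,
    intron_genes = intron_genes, base_rate = base_rate, kappa = kappa,
    hotspot_igs = hotspot_igs, hotspot_multiplier = hotspot_multiplier,
    planted_ssrs = planted_ssrs, planted_repeats = planted_repeats,
    gene_losses = gene_losses, omega_genes = omega_genes
  ), class = "sim_config")
}

random_dna <- function(n) collapse0(sample(DNA_BASES, n, replace = TRUE))

random_cds <- function(n_codons) {
  body <- sample(setdiff(SENSE_CODONS, "ATG"), n_codons - 2, replace = TRUE)
  paste0("ATG", collapse0(body), "TAA")
}

# Gene roster: names and kinds in genome order.
sim_gene_roster <- function(n_genes) {
  trna_names <- c("trnA-UGC", "trnE-UUC", "trnfM-CAU", "trnN-GUU")
  rrna_names <- c("rrn16", "rrn23")
  if (n_genes >= 12) {
    n_trna <- 4; n_rrna <- 2
  } else {
    n_trna <- 0; n_rrna <- 0
  }
  n_cds <- n_genes - n_trna - n_rrna
  names <- sprintf("g%02d", seq_len(n_cds))
  kinds <- rep("CDS", n_cds)
  if (n_trna > 0) {
    # interleave tRNA/rRNA at fixed slots
    names <- append(names, trna_names[1:2], after = min(4, length(names)))
    kinds <- append(kinds, rep("tRNA", 2), after = min(4, length(kinds)))
    names <- append(names, rrna_names, after = min(9, length(names)))
    kinds <- append(kinds, rep("rRNA", 2), after = min(9, length(kinds)))
    names <- append(names, trna_names[3:4], after = min(14, length(names)))
    kinds <- append(kinds, rep("tRNA", 2), after = min(14, length(kinds)))
  }
  data.frame(name = names, kind = kinds, stringsAsFactors = FALSE)
}

plant_ssr_in_igs <- function(igs_seq, motif, n_units) {
  u <- nchar(motif)
  tract <- strrep(motif, n_units)
  lt <- nchar(tract)
  L <- nchar(igs_seq)
  if (lt + 4 > L) stop("planted SSR does not fit in its target spacer")
  off <- (L - lt) %/% 2                       # 0-based offset of tract
  v <- chars(igs_seq)
  v[(off + 1):(off + lt)] <- chars(tract)
  # break tract-extending flanks: left flank must differ from the base one
  # period into the tract; right flank from the base one period back
  if (off >= 1 && v[off] == v[off + u]) {
    v[off] <- setdiff(DNA_BASES, v[off + u])[1]
  }
  rp <- off + lt + 1
  if (rp <= L && v[rp] == v[rp - u]) {
    v[rp] <- setdiff(DNA_BASES, v[rp - u])[1]
  }
  list(seq = collapse0(v), offset = off, tract_len = lt)
}

#' Generate the root synthetic plastome
#'
#' Assembles a circular annotated genome gene-by-gene with random intergenic
#' spacers, plants the configured SSRs and dispersed repeats at recorded
#' coordinates (with flanking bases adjusted so each planted tract/copy is
#' maximal), and returns the record together with the ground truth.
#'
#' @param config a [sim_config()]
#' @return list with `record` ([plastome_record()]) and `truth` (planted
#'   element coordinates, hotspot region names, rate mask intervals)
#' @export
generate_root <- function(config) {
  set.seed(config$seed)
  roster <- sim_gene_roster(config$n_genes)
  n_genes <- nrow(roster)
  omega_genes <- names(config$omega_genes)

  # intron carriers: CDS genes at deterministic slots (skip omega genes)
  cds_idx <- which(roster$kind == "CDS" & !(roster$name %in% omega_genes))
  intron_carriers <- head(cds_idx[seq(2, length(cds_idx), by = 4)],
                          config$intron_genes)

  gene_seqs <- vector("list", n_genes)
  strands <- character(n_genes)
  intron_plan <- vector("list", n_genes)
  for (i in seq_len(n_genes)) {
    kind <- roster$kind[i]
    if (kind == "CDS") {
      n_codons <- max(100, round(rnorm(1, config$gene_length[["mean"]],
                                       config$gene_length[["sd"]]) / 3))
      gene_seqs[[i]] <- random_cds(n_codons)
      strands[i] <- if (roster$name[i] %in% omega_genes) "+"
                    else sample(c("+", "-"), 1)
      if (i %in% intron_carriers) {
        k_introns <- if (i == intron_carriers[1]) 2 else 1
        intron_plan[[i]] <- vapply(seq_len(k_introns), function(z) {
          round(runif(1, 150, 400))
        }, numeric(1))
      }
    } else if (kind == "tRNA") {
      gene_seqs[[i]] <- random_dna(round(runif(1, 72, 90)))
      strands[i] <- sample(c("+", "-"), 1)
    } else {
      gene_seqs[[i]] <- random_dna(round(runif(1, 1490, 2810)))
      strands[i] <- "+"
    }
  }

  igs_seqs <- vapply(seq_len(n_genes), function(i) {
    random_dna(max(60, round(rnorm(1, config$igs_length[["mean"]],
                                   config$igs_length[["sd"]]))))
  }, character(1))

  # plant SSRs into spacers (offsets recorded relative to each spacer)
  ssr_truth <- list()
  for (r in seq_len(nrow(config$planted_ssrs))) {
    p <- config$planted_ssrs[r, ]
    if (p$igs > n_genes) stop("planted SSR targets a nonexistent spacer")
    res <- plant_ssr_in_igs(igs_seqs[p$igs], p$motif, p$n_units)
    igs_seqs[p$igs] <- res$seq
    ssr_truth[[r]] <- list(motif = p$motif, n_units = p$n_units,
                           igs = p$igs, offset = res$offset,
                           tract_len = res$tract_len)
  }

  # plant dispersed repeat copies (flank fixes applied post-assembly)
  rep_blocks <- list()
  for (r in seq_len(nrow(config$planted_repeats))) {
    p <- config$planted_repeats[r, ]
    block <- random_dna(p$length)
    copy2 <- if (p$kind == "palindromic") revcomp(block) else block
    for (side in 1:2) {
      igs_i <- if (side == 1) p$igs1 else p$igs2
      s <- if (side == 1) block else copy2
      L <- nchar(igs_seqs[igs_i])
      if (nchar(s) + 8 > L) stop("planted repeat does not fit in its spacer")
      off <- (L - nchar(s)) %/% 2
      v <- chars(igs_seqs[igs_i])
      v[(off + 1):(off + nchar(s))] <- chars(s)
      igs_seqs[igs_i] <- collapse0(v)
      rep_blocks[[length(rep_blocks) + 1]] <-
        list(repeat_id = r, side = side, igs = igs_i, offset = off,
             len = p$length, kind = p$kind)
    }
  }

  # assemble: gene_1 igs_1 gene_2 igs_2 ... gene_n igs_n (circular; the
  # wrap-around spacer is igs_n, between gene_n and gene_1)
  pieces <- character(0)
  features <- list()
  igs_start0 <- integer(n_genes)
  pos <- 0L
  for (i in seq_len(n_genes)) {
    tx <- gene_seqs[[i]]
    introns <- intron_plan[[i]]
    if (is.null(introns)) {
      block <- tx
      exon_lens <- nchar(tx)
      piece_is_exon <- TRUE
    } else {
      # split the transcript at interior codon boundaries
      k <- length(introns)
      n_cod <- nchar(tx) / 3
      cuts <- sort(sample(seq(30, n_cod - 30), k)) * 3
      bounds <- c(0, cuts, nchar(tx))
      exons_tx <- substring(tx, bounds[-length(bounds)] + 1, bounds[-1])
      parts <- character(0)
      piece_is_exon <- logical(0)
      for (z in seq_along(exons_tx)) {
        parts <- c(parts, exons_tx[z])
        piece_is_exon <- c(piece_is_exon, TRUE)
        if (z <= k) {
          parts <- c(parts, random_dna(introns[z]))
          piece_is_exon <- c(piece_is_exon, FALSE)
        }
      }
      block <- collapse0(parts)
      exon_lens <- nchar(parts)
    }
    if (strands[i] == "-") {
      block <- revcomp(block)
      exon_lens <- rev(if (is.null(intron_plan[[i]])) nchar(tx) else exon_lens)
      piece_is_exon <- rev(piece_is_exon)
    } else if (is.null(intron_plan[[i]])) {
      exon_lens <- nchar(tx)
    }
    # exon intervals in genome (ascending) order
    offs <- cumsum(c(0, exon_lens))
    exons <- cbind(pos + offs[-length(offs)], pos + offs[-1])
    exons <- exons[piece_is_exon, , drop = FALSE]
    features[[i]] <- gene_feature(roster$name[i], kind = roster$kind[i],
                                  exons = exons, strand = strands[i])
    pieces <- c(pieces, block)
    pos <- pos + nchar(block)
    igs_start0[i] <- pos
    pieces <- c(pieces, igs_seqs[i])
    pos <- pos + nchar(igs_seqs[i])
  }
  genome <- collapse0(pieces)
  v <- chars(genome)
  n <- length(v)

  # resolve planted coordinates to genome positions (1-based inclusive)
  empty_ssr_truth <- data.frame(motif = character(), unit_len = integer(),
                                n_units = integer(), start = integer(),
                                end = integer(), stringsAsFactors = FALSE)
  empty_rep_truth <- data.frame(kind = character(), length = integer(),
                                start1 = integer(), end1 = integer(),
                                start2 = integer(), end2 = integer(),
                                stringsAsFactors = FALSE)
  ssr_df <- do.call(rbind, lapply(ssr_truth, function(x) {
    s <- igs_start0[x$igs] + x$offset + 1L
    data.frame(motif = x$motif, unit_len = nchar(x$motif),
               n_units = x$n_units, start = s,
               end = s + x$tract_len - 1L, stringsAsFactors = FALSE)
  }))
  rep_pos <- lapply(rep_blocks, function(b) {
    s <- igs_start0[b$igs] + b$offset + 1L
    c(start = s, end = s + b$len - 1L)
  })
  reps_df <- do.call(rbind, lapply(seq_len(nrow(config$planted_repeats)), function(r) {
    sides <- which(vapply(rep_blocks, function(b) b$repeat_id == r, logical(1)))
    p1 <- rep_pos[[sides[1]]]; p2 <- rep_pos[[sides[2]]]
    if (p1["start"] > p2["start"]) { tmp <- p1; p1 <- p2; p2 <- tmp }
    data.frame(kind = config$planted_repeats$kind[r],
               length = config$planted_repeats$length[r],
               start1 = unname(p1["start"]), end1 = unname(p1["end"]),
               start2 = unname(p2["start"]), end2 = unname(p2["end"]),
               stringsAsFactors = FALSE)
  }))
  if (is.null(ssr_df)) ssr_df <- empty_ssr_truth
  if (is.null(reps_df)) reps_df <- empty_rep_truth

  # force each planted copy pair to be a maximal 0-mismatch repeat: the
  # diagonal partners of the bases flanking the copies must mismatch
  for (r in seq_len(nrow(reps_df))) {
    a1 <- reps_df$start1[r]; a2 <- reps_df$end1[r]
    b1 <- reps_df$start2[r]; b2 <- reps_df$end2[r]
    if (reps_df$kind[r] == "forward") {
      if (a1 > 1 && b1 > 1 && v[a1 - 1] == v[b1 - 1]) {
        v[b1 - 1] <- setdiff(DNA_BASES, v[a1 - 1])[1]
      }
      if (a2 < n && b2 < n && v[a2 + 1] == v[b2 + 1]) {
        v[b2 + 1] <- setdiff(DNA_BASES, v[a2 + 1])[1]
      }
    } else {
      comp <- c(A = "T", C = "G", G = "C", T = "A")
      # extending left pairs position a1-1 with the complement of b2+1
      if (a1 > 1 && b2 < n && v[a1 - 1] == comp[[v[b2 + 1]]]) {
        v[b2 + 1] <- setdiff(DNA_BASES, comp[[v[a1 - 1]]])[1]
      }
      # extending right pairs position a2+1 with the complement of b1-1
      if (a2 < n && b1 > 1 && v[a2 + 1] == comp[[v[b1 - 1]]]) {
        v[b1 - 1] <- setdiff(DNA_BASES, comp[[v[a2 + 1]]])[1]
      }
    }
  }
  genome <- collapse0(v)

  record <- plastome_record("ROOT", genome, features, organism = "synthetic",
                            circular = TRUE)

  # hotspot region names follow the IGS naming convention (genome order)
  hot_names <- vapply(config$hotspot_igs, function(i) {
    j <- if (i == n_genes) 1 else i + 1
    sprintf("%s-%s", roster$name[i], roster$name[j])
  }, character(1))

  # sites exempt from substitution: planted elements (so truth coordinates
  # survive evolution exactly)
  mask <- rep(FALSE, n)
  clamp_span <- function(s, e) max(1, s):min(n, e)
  if (!is.null(ssr_df)) {
    for (r in seq_len(nrow(ssr_df))) {
      mask[clamp_span(ssr_df$start[r] - 1, ssr_df$end[r] + 1)] <- TRUE
    }
  }
  if (!is.null(reps_df)) {
    for (r in seq_len(nrow(reps_df))) {
      mask[clamp_span(reps_df$start1[r] - 1, reps_df$end1[r] + 1)] <- TRUE
      mask[clamp_span(reps_df$start2[r] - 1, reps_df$end2[r] + 1)] <- TRUE
    }
  }

  truth <- list(
    roster = roster,
    planted_ssrs = ssr_df,
    planted_repeats = reps_df,
    hotspot_regions = hot_names,
    hotspot_igs = config$hotspot_igs,
    mask = mask
  )
  list(record = record, truth = truth)
}

# Per-site rate multiplier vector for a root record under a config.
site_rate_multipliers <- function(record, truth, config) {
  n <- nchar(record$sequence)
  rate <- rep(1, n)
  igs <- extract_igs(record)
  for (nm in truth$hotspot_regions) {
    row <- igs[igs$name == nm, ]
    if (!nrow(row)) stop("unknown hotspot region name: ", nm)
    e <- row$end[1]
    idx <- if (e >= row$start[1]) row$start[1]:e else c(row$start[1]:n, 1:e)
    rate[idx] <- config$hotspot_multiplier
  }
  rate[truth$mask] <- 0
  rate
}

mutate_branch <- function(seq_chars, p_site, kappa, omega_sites = NULL) {
  n <- length(seq_chars)
  hits <- which(runif(n) < p_site)
  if (!length(hits)) return(list(seq = seq_chars, ts = integer(0), tv = integer(0)))
  ts_pick <- runif(length(hits)) < kappa / (kappa + 2)
  out <- seq_chars
  transition_of <- c(A = "G", G = "A", C = "T", T = "C")
  for (z in seq_along(hits)) {
    i <- hits[z]
    old <- out[i]
    if (!(old %in% DNA_BASES)) next
    if (ts_pick[z]) {
      new <- transition_of[[old]]
    } else {
      tvs <- if (old %in% PURINES) PYRIMIDINES else PURINES
      new <- tvs[1 + (runif(1) < 0.5)]
    }
    if (!is.null(omega_sites) && !is.na(omega_sites$gene_of[i])) {
      # codon-aware acceptance for omega genes (+ strand, intronless)
      g0 <- omega_sites$gene_start0[i]
      cod_i <- (i - 1 - g0) %/% 3
      cs <- g0 + cod_i * 3 + 1
      cod <- out[cs:(cs + 2)]
      newcod <- cod
      newcod[i - cs + 1] <- new
      old_aa <- GENETIC_CODE_PLASTID[[collapse0(cod)]]
      new_aa <- GENETIC_CODE_PLASTID[[collapse0(newcod)]]
      omega <- omega_sites$omega_of[i]
      if (new_aa == "*") next                     # never create stops
      acc <- if (new_aa == old_aa) 1 / max(1, omega) else omega / max(1, omega)
      if (runif(1) > acc) next
    }
    out[i] <- new
  }
  list(seq = out)
}

#' Evolve a root plastome along a tree
#'
#' Independent per-site substitutions along each branch under the two-class
#' (transition/transversion) model with per-region rate multipliers; no
#' indels, so the leaf genomes stay positionally aligned to the root. Genes
#' with a configured dN/dS target evolve codon-aware. Planted elements are
#' exempt from substitution so that every planted truth survives in every
#' taxon. Configured gene losses are then applied per taxon (feature and
#' sequence removed, downstream coordinates shifted, creating a fused
#' spacer).
#'
#' @param root output of [generate_root()] (list with `record` and `truth`)
#' @param config the [sim_config()] used for generation
#' @return list with `records` (one [plastome_record()] per taxon), `truth`
#'   (augmented with the presence matrix, the generating tree and per-pair
#'   per-region realized transition/transversion counts)
#' @export
evolve_on_tree <- function(root, config) {
  set.seed(config$seed + 1)
  record <- root$record
  truth <- root$truth
  tree <- ape::read.tree(text = config$tree)
  taxa <- tree$tip.label
  n <- nchar(record$sequence)
  rate <- site_rate_multipliers(record, truth, config)

  omega_sites <- NULL
  if (!is.null(config$omega_genes)) {
    gene_of <- rep(NA_character_, n)
    gene_start0 <- rep(NA_integer_, n)
    omega_of <- rep(NA_real_, n)
    for (g in names(config$omega_genes)) {
      f <- Filter(function(x) x$name == g, record$features)[[1]]
      stopifnot(f$strand == "+", nrow(f$exons) == 1)
      idx <- (f$exons[1, 1] + 1):f$exons[1, 2]
      gene_of[idx] <- g
      gene_start0[idx] <- f$exons[1, 1]
      omega_of[idx] <- config$omega_genes[[g]]
    }
    omega_sites <- list(gene_of = gene_of, gene_start0 = gene_start0,
                        omega_of = omega_of)
  }

  # preorder walk from the root node
  nt <- length(taxa)
  root_node <- nt + 1
  seqs <- list()
  seqs[[root_node]] <- chars(record$sequence)
  trw <- ape::reorder.phylo(tree, "cladewise")  # parents before children
  for (e in seq_len(nrow(trw$edge))) {
    parent <- trw$edge[e, 1]; child <- trw$edge[e, 2]
    p_site <- pmin(config$base_rate * trw$edge.length[e] * rate, 0.75)
    seqs[[child]] <- mutate_branch(seqs[[parent]], p_site, config$kappa,
                                   omega_sites)$seq
  }

  leaf_seqs <- lapply(seq_len(nt), function(i) seqs[[i]])
  names(leaf_seqs) <- taxa

  # realized pairwise transition/transversion counts per region (positional
  # truth alignments; computed before losses are applied)
  regions <- extract_regions(record)
  # genome-slice regions only (spliced coding extents would double count)
  regions <- regions[regions$category %in% c("IGS", "intron"), , drop = FALSE]
  pair_counts <- list()
  transition_pairs <- c("AG", "GA", "CT", "TC")
  for (i in seq_len(nt - 1)) {
    for (j in (i + 1):nt) {
      a <- leaf_seqs[[i]]; b <- leaf_seqs[[j]]
      for (r in seq_len(nrow(regions))) {
        e <- regions$end[r]
        idx <- if (e >= regions$start[r]) regions$start[r]:e
               else c(regions$start[r]:n, 1:e)
        aa <- a[idx]; bb <- b[idx]
        dif <- aa != bb
        ts <- sum(dif & paste0(aa, bb) %in% transition_pairs)
        pair_counts[[length(pair_counts) + 1]] <- data.frame(
          species_a = taxa[i], species_b = taxa[j],
          region = regions$name[r], category = regions$category[r],
          ts = ts, tv = sum(dif) - ts, sites = length(idx),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  pair_counts <- do.call(rbind, pair_counts)

  # presence matrix truth and loss application
  roster <- truth$roster
  presence <- matrix(TRUE, nrow = nt, ncol = nrow(roster),
                     dimnames = list(taxa, roster$name))
  records <- list()
  for (i in seq_len(nt)) {
    tx <- taxa[i]
    feats <- record$features
    s <- leaf_seqs[[i]]
    losses <- config$gene_losses[config$gene_losses$taxon == tx, , drop = FALSE]
    for (r in seq_len(nrow(losses))) {
      g <- losses$gene[r]
      presence[tx, g] <- FALSE
      fi <- which(vapply(feats, function(f) f$name == g, logical(1)))
      if (!length(fi)) stop("configured loss of unknown gene: ", g)
      ext <- feature_extent(feats[[fi]])
      cut_len <- ext[2] - ext[1]
      s <- s[-((ext[1] + 1):ext[2])]
      feats <- feats[-fi]
      feats <- lapply(feats, function(f) {
        shift <- ifelse(f$exons >= ext[2], -cut_len, 0)
        if (any(f$exons > ext[1] & f$exons < ext[2])) {
          stop("gene loss overlaps another feature")
        }
        gene_feature(f$name, f$kind, f$exons + shift, f$strand, f$pseudo)
      })
    }
    records[[i]] <- plastome_record(tx, collapse0(s), feats,
                                    organism = paste("synthetic", tx),
                                    circular = TRUE)
  }
  names(records) <- taxa

  truth$presence <- presence
  truth$tree <- tree
  truth$pair_region_counts <- pair_counts
  truth$leaf_alignment <- vapply(leaf_seqs, collapse0, character(1))
  list(records = records, truth = truth)
}

#' Write a synthetic data set to disk
#'
#' One GenBank flat file and one FASTA per taxon, plus ground-truth tables
#' (planted SSRs and repeats, presence matrix, per-pair per-region realized
#' substitution counts), the generating tree (Newick) and the configuration
#' (flat key=value). Re-running with the same config reproduces the files.
#'
#' @param sim output of [evolve_on_tree()]
#' @param config the [sim_config()] used
#' @param outdir output directory (created if needed)
#' @return invisibly, the directory
#' @export
emit_synthetic <- function(sim, config, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  for (tx in names(sim$records)) {
    write_genbank(sim$records[[tx]], file.path(outdir, paste0(tx, ".gb")))
    write_fasta(setNames(sim$records[[tx]]$sequence, tx),
                file.path(outdir, paste0(tx, ".fasta")))
  }
  tw <- function(df, f) write.table(df, file.path(outdir, f), sep = "\t",
                                    quote = FALSE, row.names = FALSE)
  tw(sim$truth$planted_ssrs, "truth_planted_ssrs.tsv")
  tw(sim$truth$planted_repeats, "truth_planted_repeats.tsv")
  tw(sim$truth$pair_region_counts, "truth_pair_region_counts.tsv")
  write_presence_matrix(sim$truth$presence, file.path(outdir, "truth_presence.tsv"))
  ape::write.tree(sim$truth$tree, file.path(outdir, "tree.nwk"))
  scalars <- config[c("seed", "n_genes", "intron_genes", "base_rate",
                      "kappa", "hotspot_multiplier", "tree")]
  writeLines(paste0(names(scalars), "=", unlist(scalars)),
             file.path(outdir, "config.txt"))
  invisible(outdir)
}

#' Simulate one aligned site pair set under the K2p model
#'
#' Draws `n` independent sites at true distance `d` (expected substitutions
#' per site) and transition/transversion rate ratio `kappa`, using the exact
#' K80 transition probabilities, and returns the two aligned sequences. Used
#' to validate the K2p estimator.
#'
#' @param n number of sites
#' @param d true distance
#' @param kappa ts/tv rate ratio
#' @return character vector of two aligned sequences
#' @export
simulate_k2p_pair <- function(n, d, kappa = 2) {
  bt <- d / (kappa + 2)                 # beta * t
  at <- kappa * bt                      # alpha * t
  p_ts <- 0.25 + 0.25 * exp(-4 * bt) - 0.5 * exp(-2 * (at + bt))
  p_tv <- 0.5 - 0.5 * exp(-4 * bt)
  a <- sample(DNA_BASES, n, replace = TRUE)
  u <- runif(n)
  transition_of <- c(A = "G", G = "A", C = "T", T = "C")
  b <- a
  is_ts <- u < p_ts
  b[is_ts] <- transition_of[a[is_ts]]
  is_tv <- !is_ts & u < p_ts + p_tv
  if (any(is_tv)) {
    b[is_tv] <- vapply(a[is_tv], function(x) {
      tvs <- if (x %in% PURINES) PYRIMIDINES else PURINES
      sample(tvs, 1)
    }, character(1))
  }
  c(collapse0(a), collapse0(b))
}

#' Simulate a codon-aligned CDS pair with a target dN/dS
#'
#' The ancestor is a random sense-codon sequence; the descendant accumulates
#' proposed single-nucleotide changes (per-site probability `t`), accepting
#' synonymous proposals with probability 1/max(1, omega) and nonsynonymous
#' ones with probability omega/max(1, omega), never creating stop codons.
#' The realized dN/dS approximates `omega`.
#'
#' @param n_codons number of codons
#' @param t per-site proposal probability
#' @param omega target dN/dS ratio
#' @return character vector of two gapless codon-aligned sequences
#' @export
simulate_codon_pair <- function(n_codons, t, omega) {
  anc <- collapse0(sample(setdiff(SENSE_CODONS, c("ATG", "TGG")), n_codons,
                          replace = TRUE))
  v <- chars(anc)
  n <- length(v)
  hits <- which(runif(n) < t)
  for (i in hits) {
    new <- sample(setdiff(DNA_BASES, v[i]), 1)
    cod_i <- (i - 1) %/% 3
    cs <- cod_i * 3 + 1
    cod <- v[cs:(cs + 2)]
    newcod <- cod
    newcod[i - cs + 1] <- new
    old_aa <- GENETIC_CODE_PLASTID[[collapse0(cod)]]
    new_aa <- GENETIC_CODE_PLASTID[[collapse0(newcod)]]
    if (new_aa == "*") next
    acc <- if (new_aa == old_aa) 1 / max(1, omega) else omega / max(1, omega)
    if (runif(1) <= acc) v[i] <- new
  }
  c(anc, collapse0(v))
}
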