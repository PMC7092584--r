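# Independent brute-force oracles. These deliberately share no code with the
# implementation: plain loops, closed forms, exhaustive enumeration.

# -- six-frame ORF scan: naive per-position walk ----------------------------
oracle_orf <- function(seq) {
  seq <- toupper(seq)
  rc <- intToUtf8(rev(utf8ToInt(chartr("ACGTN", "TGCAN", seq))))
  stops <- c("TAA", "TAG", "TGA")
  best <- 0L
  for (s in c(seq, rc)) {
    n <- nchar(s)
    for (off in 0:2) {
      pos <- 1L + off
      while (pos + 2L <= n) {
        if (substr(s, pos, pos + 2L) == "ATG") {
          aa <- 0L
          p <- pos
          found <- FALSE
          while (p + 2L <= n) {
            cod <- substr(s, p, p + 2L)
            if (cod %in% stops && p > pos) { found <- TRUE; break }
            aa <- aa + 1L
            p <- p + 3L
          }
          if (found && aa > best) best <- aa
        }
        pos <- pos + 3L
      }
    }
  }
  best
}

# -- affine-gap local alignment, score only (Gotoh in plain R) --------------
oracle_sw_score <- function(a, b, score_fun, gap_open, gap_extend) {
  n <- nchar(a); m <- nchar(b)
  av <- strsplit(toupper(a), "")[[1]]
  bv <- strsplit(toupper(b), "")[[1]]
  NEG <- -1e18
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(NEG, n + 1, m + 1)
  F <- matrix(NEG, n + 1, m + 1)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(H[i, j - 1] - gap_open, E[i, j - 1] - gap_extend)
      F[i, j] <- max(H[i - 1, j] - gap_open, F[i - 1, j] - gap_extend)
      H[i, j] <- max(0, H[i - 1, j - 1] + score_fun(av[i - 1], bv[j - 1]),
                     E[i, j], F[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}

# duplex pair scoring in original (a, b) space: complementary pairs
oracle_duplex_score <- function(a, b, p = duplex_params()) {
  rc <- intToUtf8(rev(utf8ToInt(chartr("ACGTN", "TGCAN", toupper(b)))))
  pair <- function(x, y) {
    if (x == "G" && y == "G") p$gc else if (x == "C" && y == "C") p$gc
    else if (x == "A" && y == "A") p$at else if (x == "T" && y == "T") p$at
    else if (x == "G" && y == "A") p$gu else if (x == "T" && y == "C") p$gu
    else p$mismatch
  }
  oracle_sw_score(a, rc, pair, p$gap_open, p$gap_extend)
}

# -- exact conditional binomial, from first principles ----------------------
oracle_binom_p <- function(x, y, na, nb) {
  t <- x + y
  if (t == 0) return(1)
  p0 <- na / (na + nb)
  mass <- vapply(0:t, function(k) choose(t, k) * p0^k * (1 - p0)^(t - k),
                 numeric(1))
  sum(mass[mass <= mass[x + 1] * (1 + 1e-9)])
}

# -- BH step-up, literal definition -----------------------------------------
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  # literal: q_(i) = min over j >= i of p_(j) * m / j
  for (i in seq_len(m)) q[i] <- min(1, min(ps[i:m] * m / (i:m)))
  out <- numeric(m)
  out[o] <- q
  out
}

# -- hypergeometric upper tail by enumeration -------------------------------
oracle_hyper_p <- function(N, K, n, k) {
  js <- k:min(K, n)
  sum(vapply(js, function(j) choose(K, j) * choose(N - K, n - j), numeric(1))) /
    choose(N, n)
}

# -- brute-force window query over the gene table ---------------------------
oracle_query_genes <- function(ann, chrom, start, end, strand = NULL) {
  g <- ann$genes
  hit <- g$chrom == chrom & g$start < end & g$end > start
  if (!is.null(strand)) hit <- hit & g$strand == strand
  sort(unique(g$gene_id[hit]))
}

# -- positional classification by exhaustive pairwise checks ----------------
oracle_classify <- function(ann, lnc_id, window = 1000) {
  tx <- ann$transcripts[ann$transcripts$transcript_id == lnc_id, ]
  lex <- ann$exons[ann$exons$transcript_id == lnc_id, ]
  cod <- ann$exons[ann$exons$biotype == "coding", ]
  cod <- cod[cod$chrom == tx$chrom, ]
  same_hit <- opp_hit <- character(0)
  for (i in seq_len(nrow(lex))) for (j in seq_len(nrow(cod))) {
    if (lex$start[i] < cod$end[j] && lex$end[i] > cod$start[j]) {
      if (lex$strand[i] == cod$strand[j]) same_hit <- c(same_hit, cod$gene_id[j])
      else opp_hit <- c(opp_hit, cod$gene_id[j])
    }
  }
  if (length(same_hit)) return(list(class = "sense", gene = min(same_hit)))
  if (length(opp_hit)) return(list(class = "antisense", gene = min(opp_hit)))
  intron_hit <- character(0)
  for (ct in unique(cod$transcript_id)) {
    ce <- cod[cod$transcript_id == ct, ]
    ce <- ce[order(ce$start), ]
    if (nrow(ce) < 2) next
    for (i in seq_len(nrow(ce) - 1)) {
      is_ <- ce$end[i]; ie_ <- ce$start[i + 1]
      if (is_ <= tx$start && tx$end <= ie_)
        intron_hit <- c(intron_hit, ce$gene_id[1])
    }
  }
  if (length(intron_hit)) return(list(class = "intronic",
                                      gene = min(intron_hit)))
  g <- ann$genes[ann$genes$biotype == "coding" & ann$genes$chrom == tx$chrom, ]
  overlap <- any(g$start < tx$end & g$end > tx$start)
  if (!overlap && nrow(g)) {
    lnc_tss <- if (tx$strand == "+") tx$start else tx$end - 1
    cand <- g[g$strand != tx$strand, ]
    if (nrow(cand)) {
      div <- if (tx$strand == "-") cand$tss >= lnc_tss else cand$tss <= lnc_tss
      ok <- div & abs(cand$tss - lnc_tss) < window
      if (any(ok)) {
        cand <- cand[ok, ]
        cand <- cand[order(abs(cand$tss - lnc_tss), cand$gene_id), ]
        return(list(class = "bidirectional", gene = cand$gene_id[1]))
      }
    }
  }
  list(class = "intergenic", gene = NA_character_)
}

# -- apcGene nearest-neighbor scan ------------------------------------------
oracle_apc <- function(ann, lnc_id, window = 10000) {
  tx <- ann$transcripts[ann$transcripts$transcript_id == lnc_id, ]
  g <- ann$genes[ann$genes$biotype == "coding" & ann$genes$chrom == tx$chrom, ]
  out <- list()
  for (pos in c("left", "right")) {
    if (pos == "left") {
      cand <- g[g$end <= tx$start, ]
      if (nrow(cand)) cand$gap <- tx$start - cand$end
    } else {
      cand <- g[g$start >= tx$end, ]
      if (nrow(cand)) cand$gap <- cand$start - tx$end
    }
    if (!nrow(cand)) next
    cand <- cand[cand$gap > 0 & cand$gap <= window, ]
    if (!nrow(cand)) next
    cand <- cand[order(cand$gap, cand$gene_id), ]
    side <- if (tx$strand == "+") {
      if (pos == "left") "upstream" else "downstream"
    } else {
      if (pos == "left") "downstream" else "upstream"
    }
    out[[pos]] <- data.frame(transcript_id = lnc_id,
                             gene_id = cand$gene_id[1], side = side,
                             gap_bp = cand$gap[1],
                             stringsAsFactors = FALSE)
  }
  do.call(rbind, unname(out))
}

# -- ceRNA network admission / join, relational re-derivation ---------------
oracle_cerna <- function(lnc_ids, expr, de, apc_links, duplex_hits,
                         precursors, targets, min_reads = 10) {
  expr <- as.data.frame(expr); de <- as.data.frame(de)
  apc_links <- as.data.frame(apc_links)
  duplex_hits <- as.data.frame(duplex_hits)
  precursors <- as.data.frame(precursors); targets <- as.data.frame(targets)
  mx <- tapply(expr$read_count, expr$transcript_id, max)
  linked <- union(apc_links$transcript_id, duplex_hits$lnc_id)
  lnc_ok <- sort(intersect(lnc_ids,
                           intersect(names(mx)[mx > min_reads], linked)))
  de_genes <- unique(de$transcript_id[de$call != "ns"])
  mir_ok <- sort(unique(c(
    targets$mirna_id[targets$target_id %in% lnc_ok],
    precursors$hairpin_id[precursors$lnc_id %in% lnc_ok])))
  mrna_universe <- unique(c(de$transcript_id, apc_links$gene_id,
                            duplex_hits$mrna_id))
  mrna_linked <- unique(c(
    apc_links$gene_id[apc_links$transcript_id %in% lnc_ok],
    duplex_hits$mrna_id[duplex_hits$lnc_id %in% lnc_ok],
    targets$target_id[targets$mirna_id %in% mir_ok &
                        targets$target_id %in% mrna_universe]))
  mrna_ok <- sort(intersect(de_genes, mrna_linked))
  ed <- function(from, to, type, keep) {
    i <- which(keep)
    data.frame(from = from[i], to = to[i],
               edge_type = rep(type, length(i)), stringsAsFactors = FALSE)
  }
  edges <- rbind(
    ed(targets$mirna_id, targets$target_id, "mirna_targets_lncrna",
       targets$target_id %in% lnc_ok & targets$mirna_id %in% mir_ok),
    ed(targets$mirna_id, targets$target_id, "mirna_targets_mrna",
       targets$target_id %in% mrna_ok & targets$mirna_id %in% mir_ok),
    ed(precursors$lnc_id, precursors$hairpin_id,
       "lncrna_precursor_of_mirna", precursors$lnc_id %in% lnc_ok),
    ed(apc_links$transcript_id, apc_links$gene_id, "apc",
       apc_links$transcript_id %in% lnc_ok &
         apc_links$gene_id %in% mrna_ok),
    ed(duplex_hits$lnc_id, duplex_hits$mrna_id, "antisense",
       duplex_hits$lnc_id %in% lnc_ok & duplex_hits$mrna_id %in% mrna_ok))
  edges <- unique(edges[edges$from != edges$to, ])
  edges <- edges[order(edges$edge_type, edges$from, edges$to), ]
  rownames(edges) <- NULL
  list(lnc = lnc_ok, mir = mir_ok, mrna = mrna_ok, edges = edges)
}

# -- filter cascade re-applied rule by rule (base-R linear scans) -----------
oracle_filter <- function(ann, cand, expr, seqs, evidence_ids = character(),
                          orf_fun = oracle_orf) {
  tx <- as.data.frame(ann$transcripts)
  ex <- as.data.frame(ann$exons)
  rownames(tx) <- tx$transcript_id
  cod <- ex[ex$biotype == "coding", ]
  expr <- as.data.frame(expr)
  mxc <- tapply(expr$coverage, expr$transcript_id, max)
  mxf <- tapply(expr$fpkm, expr$transcript_id, max)
  first <- setNames(rep("retained", length(cand)), cand)
  for (id in cand) {
    t1 <- tx[id, ]
    le <- ex[ex$transcript_id == id, ]
    sense <- FALSE
    if (t1$biotype != "known_lncRNA") {
      for (i in seq_len(nrow(le))) {
        hit <- cod$chrom == le$chrom[i] & cod$strand == le$strand[i] &
          cod$start < le$end[i] & cod$end > le$start[i]
        if (any(hit)) { sense <- TRUE; break }
      }
    }
    slen <- ann$scaffold_lengths[[t1$chrom]]
    rules <- c(
      sense_exon_overlap = sense,
      min_length = t1$length_bp < 200,
      min_exons = t1$n_exons < 2,
      min_coverage = mxc[[id]] < 0.8,
      min_fpkm = mxf[[id]] < 0.1,
      max_orf = orf_fun(seqs[[id]]) > 100,
      evidence = id %in% evidence_ids,
      scaffold_end = t1$start < 2000 || (slen - t1$end) < 2000)
    bad <- names(rules)[rules]
    if (length(bad)) first[[id]] <- bad[1]
  }
  list(first_fail = first,
       removed = table(factor(first[first != "retained"],
                              levels = c("sense_exon_overlap", "min_length",
                                         "min_exons", "min_coverage",
                                         "min_fpkm", "max_orf", "evidence",
                                         "scaffold_end"))),
       retained = names(first)[first == "retained"])
}
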