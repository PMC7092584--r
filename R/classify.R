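#' Positional classification of lncRNAs
#'
#' Assigns each lncRNA exactly one of five positional classes against the
#' coding annotation, by a fixed priority order:
#' \enumerate{
#'   \item \strong{sense} -- any lncRNA exon overlaps a coding exon (>= 1 bp)
#'     on the same strand;
#'   \item \strong{antisense} -- same, on the opposite strand;
#'   \item \strong{intronic} -- the lncRNA span lies fully inside a single
#'     intron of some coding transcript (either strand);
#'   \item \strong{bidirectional} -- no span overlap with any coding gene,
#'     and the lncRNA TSS lies within `bidirectional_window` bp of a coding
#'     TSS on the opposite strand in divergent (head-to-head) orientation;
#'   \item \strong{intergenic} -- everything else.
#' }
#' Ties within a rule are broken by the lexicographically smallest gene id.
#' The classes are "loose" and non-exclusive in the literature; the priority
#' order (exon evidence strongest) makes the assignment a testable partition.
#'
#' @param ann `lnc_annotation` (coding genes are the reference set).
#' @param lnc_ids transcript ids to classify; must exist in `ann`.
#' @param bidirectional_window divergent-promoter distance (bp); the TSS
#'   distance must be strictly less than this.
#' @return data.table: `transcript_id, lnc_class, evidence_gene_id, detail`
#'   (`evidence_gene_id` is `NA` exactly for intergenic).
#' @export
classify_lncrnas <- function(ann, lnc_ids, bidirectional_window = 1000) {
  tx <- ann$transcripts[match(lnc_ids, transcript_id)]
  assert_that(!anyNA(tx$transcript_id), "unknown transcript id(s): %s",
              paste(head(lnc_ids[is.na(tx$transcript_id)], 3), collapse = ", "))
  assert_that(all(tx$chrom %in% names(ann$scaffold_lengths)),
              "lncRNA on scaffold absent from annotation")
  coding_ex <- ann$exons[biotype == "coding"]
  coding_genes <- ann$genes[biotype == "coding"]
  lnc_ex <- ann$exons[transcript_id %in% lnc_ids]

  res <- data.table(transcript_id = lnc_ids, lnc_class = NA_character_,
                    evidence_gene_id = NA_character_, detail = NA_character_)

  pick <- function(cand_dt) cand_dt[order(gene_id)][1L]  # smallest gene id

  # exon-exon overlaps, both strand senses, in one pass
  if (nrow(coding_ex) && nrow(lnc_ex)) {
    lg <- gr_from_dt(lnc_ex, "transcript_id")
    cg <- gr_from_dt(coding_ex, "transcript_id")
    h <- GenomicRanges::findOverlaps(lg, cg, ignore.strand = TRUE)
    ov <- data.table(
      transcript_id = lnc_ex$transcript_id[S4Vectors::queryHits(h)],
      gene_id = coding_ex$gene_id[S4Vectors::subjectHits(h)],
      same = lnc_ex$strand[S4Vectors::queryHits(h)] ==
             coding_ex$strand[S4Vectors::subjectHits(h)],
      ex_start = coding_ex$start[S4Vectors::subjectHits(h)],
      ex_end = coding_ex$end[S4Vectors::subjectHits(h)])
  } else {
    ov <- data.table(transcript_id = character(), gene_id = character(),
                     same = logical(), ex_start = integer(),
                     ex_end = integer())
  }

  # introns of coding transcripts
  introns <- coding_ex[, if (.N > 1L)
    .(chrom = chrom[1L], start = head(end, -1L), end = tail(start, -1L),
      strand = strand[1L], gene_id = gene_id[1L]),
    by = transcript_id]
  if (nrow(introns)) introns <- introns[start < end]

  for (i in seq_along(lnc_ids)) {
    id <- lnc_ids[i]
    o <- ov[transcript_id == id]
    sen <- o[same == TRUE]
    if (nrow(sen)) {
      b <- pick(sen)
      res[i, `:=`(lnc_class = "sense", evidence_gene_id = b$gene_id,
                  detail = sprintf("exon:%d-%d", b$ex_start, b$ex_end))]
      next
    }
    ant <- o[same == FALSE]
    if (nrow(ant)) {
      b <- pick(ant)
      res[i, `:=`(lnc_class = "antisense", evidence_gene_id = b$gene_id,
                  detail = sprintf("exon:%d-%d", b$ex_start, b$ex_end))]
      next
    }
    # intronic: full span containment in one intron, either strand
    if (nrow(introns)) {
      inn <- introns[chrom == tx$chrom[i] & start <= tx$start[i] &
                       end >= tx$end[i]]
      if (nrow(inn)) {
        b <- pick(inn)
        res[i, `:=`(lnc_class = "intronic", evidence_gene_id = b$gene_id,
                    detail = sprintf("intron:%d-%d", b$start, b$end))]
        next
      }
    }
    # bidirectional: no span overlap with any coding gene + divergent TSS
    g <- coding_genes[chrom == tx$chrom[i]]
    span_ov <- g[start < tx$end[i] & end > tx$start[i]]
    if (nrow(span_ov) == 0L && nrow(g)) {
      lnc_tss <- if (tx$strand[i] == "+") tx$start[i] else tx$end[i] - 1L
      opp <- g[strand != tx$strand[i]]
      if (nrow(opp)) {
        dist <- abs(opp$tss - lnc_tss)
        divergent <- if (tx$strand[i] == "-") opp$tss >= lnc_tss
                     else opp$tss <= lnc_tss
        cand <- opp[divergent & dist < bidirectional_window]
        if (nrow(cand)) {
          cand[, d := abs(tss - lnc_tss)]
          b <- cand[order(d, gene_id)][1L]
          res[i, `:=`(lnc_class = "bidirectional",
                      evidence_gene_id = b$gene_id,
                      detail = sprintf("tss_dist:%d", b$d))]
          next
        }
      }
    }
    res[i, lnc_class := "intergenic"]
  }
  res[]
}

#' Adjacent protein-coding genes (apcGenes) of a lncRNA
#'
#' For each lncRNA, finds the nearest non-overlapping coding gene on each
#' side within `window_bp` (inclusive at exactly `window_bp`; a gap of
#' 10,001 bp yields no link). The gap is the unsigned distance between the
#' facing span ends (gene body to transcript span, not TSS-to-TSS); genes
#' overlapping or abutting the lncRNA (gap 0) are never apcGenes -- overlap
#' produces sense/antisense/intronic evidence instead. Sides are reported in
#' the lncRNA's reading orientation: the 5' neighbor is `upstream`.
#'
#' @param ann `lnc_annotation`.
#' @param lnc_ids transcript ids.
#' @param window_bp maximum gap (bp), default 10000.
#' @return data.table: `transcript_id, gene_id, side, gap_bp` (zero rows if
#'   no gene qualifies).
#' @export
find_apc_genes <- function(ann, lnc_ids, window_bp = 10000) {
  tx <- ann$transcripts[match(lnc_ids, transcript_id)]
  assert_that(!anyNA(tx$transcript_id), "unknown transcript id(s)")
  coding_genes <- ann$genes[biotype == "coding"]
  out <- vector("list", length(lnc_ids))
  for (i in seq_along(lnc_ids)) {
    g <- coding_genes[chrom == tx$chrom[i]]
    if (nrow(g) == 0L) next
    left <- g[end <= tx$start[i]][, gap := tx$start[i] - end]
    right <- g[start >= tx$end[i]][, gap := start - tx$end[i]]
    links <- list()
    for (sideof in list(list(d = left, pos = "left"),
                        list(d = right, pos = "right"))) {
      d <- sideof$d[gap > 0 & gap <= window_bp]
      if (nrow(d) == 0L) next
      b <- d[order(gap, gene_id)][1L]
      side_lab <- if (tx$strand[i] == "+") {
        if (sideof$pos == "left") "upstream" else "downstream"
      } else {
        if (sideof$pos == "left") "downstream" else "upstream"
      }
      links[[length(links) + 1L]] <- data.table(
        transcript_id = lnc_ids[i], gene_id = b$gene_id,
        side = side_lab, gap_bp = b$gap)
    }
    if (length(links)) out[[i]] <- rbindlist(links)
  }
  res <- rbindlist(out)
  if (nrow(res) == 0L)
    res <- data.table(transcript_id = character(), gene_id = character(),
                      side = character(), gap_bp = integer())
  res[]
}
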