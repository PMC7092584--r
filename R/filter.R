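#' Filter cascade configuration
#'
#' Thresholds for the seven-step candidate-lncRNA filter. Boundary semantics
#' follow the strict inequalities of the screening rules: transcripts are
#' removed when length `< 200` bp, exon count `< 2`, best read coverage
#' `< 0.8`, best FPKM `< 0.1`, longest ORF `> 100` aa, or the transcript lies
#' `< 2000` bp from a scaffold end -- so a transcript sitting exactly on every
#' boundary is retained. Coverage and FPKM are the maximum over the three
#' stage libraries (adequately expressed in any one stage suffices).
#'
#' @param min_length_bp minimum spliced length (bp).
#' @param min_exons minimum exon count.
#' @param min_coverage minimum per-library-max read-coverage fraction.
#' @param min_fpkm minimum per-library-max FPKM.
#' @param max_orf_aa maximum allowed longest ORF (amino acids).
#' @param scaffold_end_margin_bp margin from scaffold ends (bp).
#' @param drop_sense_exon_overlap apply step (1) sense-exon-overlap removal
#'   (known lncRNAs always bypass this step).
#' @param evidence_ids transcript ids with known-protein / domain evidence
#'   (pluggable stand-in for external coding-potential classifiers).
#' @param polyA_required optional poly(A)-evidence gate; inert by default
#'   (the corresponding published rule is not interpretable as printed).
#' @param polyA_ids ids with poly(A) evidence, used only when
#'   `polyA_required = TRUE`.
#' @return object of class `filter_config`.
#' @export
filter_config <- function(min_length_bp = 200, min_exons = 2,
                          min_coverage = 0.8, min_fpkm = 0.1,
                          max_orf_aa = 100, scaffold_end_margin_bp = 2000,
                          drop_sense_exon_overlap = TRUE,
                          evidence_ids = character(),
                          polyA_required = FALSE,
                          polyA_ids = character()) {
  cfg <- list(min_length_bp = min_length_bp, min_exons = min_exons,
              min_coverage = min_coverage, min_fpkm = min_fpkm,
              max_orf_aa = max_orf_aa,
              scaffold_end_margin_bp = scaffold_end_margin_bp,
              drop_sense_exon_overlap = isTRUE(drop_sense_exon_overlap),
              evidence_ids = as.character(evidence_ids),
              polyA_required = isTRUE(polyA_required),
              polyA_ids = as.character(polyA_ids))
  num <- c("min_length_bp", "min_exons", "min_coverage", "min_fpkm",
           "max_orf_aa", "scaffold_end_margin_bp")
  for (f in num) assert_that(is.numeric(cfg[[f]]) && cfg[[f]] >= 0,
                             "%s must be a non-negative number", f)
  structure(cfg, class = "filter_config")
}

filter_step_names <- function(cfg) {
  steps <- c("sense_exon_overlap", "min_length", "min_exons", "min_coverage",
             "min_fpkm", "max_orf", "evidence", "scaffold_end")
  if (cfg$polyA_required) steps <- c(steps, "polyA")
  steps
}

# per-rule failure predicates, each a pure function of one candidate
filter_fail_matrix <- function(ann, candidate_ids, expr, seqs, cfg) {
  tx <- ann$transcripts[match(candidate_ids, transcript_id)]
  assert_that(!anyNA(tx$transcript_id), "candidate id not in annotation: %s",
              paste(head(candidate_ids[is.na(tx$transcript_id)], 3),
                    collapse = ", "))
  miss_seq <- setdiff(candidate_ids, names(seqs))
  assert_that(length(miss_seq) == 0, "candidate missing sequence: %s",
              paste(head(miss_seq, 3), collapse = ", "))
  e <- as.data.table(expr)[transcript_id %in% candidate_ids,
                           .(max_cov = max(coverage), max_fpkm = max(fpkm)),
                           by = transcript_id]
  miss_expr <- setdiff(candidate_ids, e$transcript_id)
  assert_that(length(miss_expr) == 0, "candidate missing expression: %s",
              paste(head(miss_expr, 3), collapse = ", "))
  e <- e[match(candidate_ids, transcript_id)]

  # step (1): same-strand exon overlap with a coding exon; known lncRNAs bypass
  sense_fail <- rep(FALSE, length(candidate_ids))
  if (cfg$drop_sense_exon_overlap) {
    coding_gr <- ann$exon_gr[S4Vectors::mcols(ann$exon_gr)$biotype == "coding"]
    cand_ex <- ann$exons[transcript_id %in% candidate_ids]
    if (nrow(cand_ex) && length(coding_gr)) {
      hits <- GenomicRanges::findOverlaps(gr_from_dt(cand_ex, "transcript_id"),
                                          coding_gr, ignore.strand = FALSE)
      hit_tx <- unique(cand_ex$transcript_id[S4Vectors::queryHits(hits)])
      sense_fail <- candidate_ids %in% hit_tx & tx$biotype != "known_lncRNA"
    }
  }

  orf_aa <- vapply(seqs[candidate_ids], scan_longest_orf, integer(1))
  slen <- ann$scaffold_lengths[tx$chrom]
  assert_that(!anyNA(slen), "unknown scaffold for candidate")

  cbind(
    sense_exon_overlap = sense_fail,
    min_length = tx$length_bp < cfg$min_length_bp,
    min_exons = tx$n_exons < cfg$min_exons,
    min_coverage = e$max_cov < cfg$min_coverage,
    min_fpkm = e$max_fpkm < cfg$min_fpkm,
    max_orf = orf_aa > cfg$max_orf_aa,
    evidence = candidate_ids %in% cfg$evidence_ids,
    scaffold_end = tx$start < cfg$scaffold_end_margin_bp |
                   (slen - tx$end) < cfg$scaffold_end_margin_bp,
    polyA = if (cfg$polyA_required) !(candidate_ids %in% cfg$polyA_ids)
            else rep(FALSE, length(candidate_ids))
  )
}

#' Apply the seven-step candidate-lncRNA filter
#'
#' Steps, in order: (1) removal of candidates whose exons overlap a coding
#' exon on the same strand (known lncRNAs bypass this step); (2) minimum
#' length, exon count, read coverage and FPKM (four separately attributed
#' sub-steps); (3) longest-ORF screen; (4--5) exclusion list of transcripts
#' with protein evidence; (6) scaffold-end margin; (7) optional poly(A) gate,
#' off by default. Each removed transcript is attributed to its *first*
#' failing step. Because every rule is a pure predicate, the retained set is
#' independent of step order; only the attribution changes.
#'
#' @param ann `lnc_annotation`.
#' @param candidate_ids transcripts to screen (defaults to all non-coding
#'   biotypes in `ann`).
#' @param expr expression table (see [read_expression()]).
#' @param seqs named character vector of transcript sequences.
#' @param cfg a [filter_config()].
#' @return list with `retained` (character vector), `report` (data.table:
#'   step, removed) and `per_transcript` (data.table: transcript_id,
#'   first_fail -- `"retained"` if kept).
#' @export
apply_filter_cascade <- function(ann, candidate_ids = NULL, expr, seqs,
                                 cfg = filter_config()) {
  candidate_ids <- candidate_ids %||%
    ann$transcripts[biotype != "coding", transcript_id]
  steps <- filter_step_names(cfg)
  if (length(candidate_ids) == 0L)
    return(list(retained = character(),
                report = data.table(step = steps,
                                    removed = rep(0L, length(steps))),
                per_transcript = data.table(transcript_id = character(),
                                            first_fail = character())))
  fm <- filter_fail_matrix(ann, candidate_ids, expr, seqs, cfg)[, steps,
                                                               drop = FALSE]
  first <- apply(fm, 1L, function(r) {
    i <- which(r)
    if (length(i)) steps[i[1L]] else "retained"
  })
  per_tx <- data.table(transcript_id = candidate_ids, first_fail = first)
  report <- data.table(step = steps,
                       removed = vapply(steps, function(s) sum(first == s),
                                        integer(1)))
  retained <- candidate_ids[first == "retained"]
  stopifnot(length(candidate_ids) == length(retained) + sum(report$removed))
  list(retained = retained, report = report, per_transcript = per_tx)
}
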