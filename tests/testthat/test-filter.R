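# a small hand-built world: one coding gene, candidates with controlled
# properties placed far from genes and scaffold ends
mk_filter_world <- function() {
  rows <- list(
    tx_exons("c1", "+", "mrna1", "gene1", c(10000, 13000), c(11000, 14000)),
    # 199 bp, 2 exons (length failure)
    tx_exons("c1", "+", "short", "g:short", c(30000, 30200), c(30100, 30299),
             biotype = "candidate_noncoding"),
    # exact boundaries: 200 bp, 2 exons, mid-scaffold
    tx_exons("c1", "+", "bound", "g:bound", c(40000, 40200), c(40100, 40300),
             biotype = "candidate_noncoding"),
    # 400 bp, for the ORF boundary
    tx_exons("c1", "+", "orfb", "g:orfb", c(60000, 60300), c(60200, 60500),
             biotype = "candidate_noncoding"),
    # sense overlap with gene exon, candidate biotype
    tx_exons("c1", "+", "senseov", "g:senseov", c(10500, 12000),
             c(11500, 12400), biotype = "candidate_noncoding"),
    # identical geometry but known lncRNA -> bypasses step 1
    tx_exons("c1", "+", "knownov", "g:knownov", c(10500, 12000),
             c(11500, 12400), biotype = "known_lncRNA"),
    # single exon
    tx_exons("c1", "-", "monoex", "g:monoex", 50000, 50400,
             biotype = "candidate_noncoding"),
    # near scaffold end (start < 2000)
    tx_exons("c1", "+", "nearend", "g:nearend", c(500, 900), c(800, 1200),
             biotype = "candidate_noncoding"))
  annotation_from_exons(data.table::rbindlist(rows), c(c1 = 100000))
}

# ATG-free random sequences (both strands stay ORF-free because an ORF needs
# a forward ATG or a reverse CAT; we exclude both trigrams)
orf_free_seq <- function(len) {
  s <- rand_dna(len)
  repeat {
    s2 <- gsub("CAT", "CCT", gsub("ATG", "ACG", s))
    if (s2 == s) return(s)
    s <- s2
  }
}

filter_seqs <- function(ann, orf_aa = 100) {
  ids <- ann$transcripts$transcript_id
  out <- list()
  for (id in ids) {
    len <- ann$transcripts$length_bp[ann$transcripts$transcript_id == id]
    out[[id]] <- orf_free_seq(len)
  }
  # ATG + orf_aa-1 codons + stop: longest ORF is exactly orf_aa amino acids
  orf <- paste0("ATG", strrep("GCA", orf_aa - 1), "TAA")
  stopifnot(nchar(out[["orfb"]]) >= nchar(orf))
  out[["orfb"]] <- paste0(orf,
                          substr(out[["orfb"]], nchar(orf) + 1,
                                 nchar(out[["orfb"]])))
  unlist(out)
}

test_that("boundary semantics: first-fail attribution per rule", {
  set.seed(99)
  ann <- mk_filter_world()
  cand <- ann$transcripts$transcript_id[ann$transcripts$biotype != "coding"]
  seqs <- filter_seqs(ann)
  expect_equal(scan_longest_orf(seqs[["orfb"]]), 100L)
  # boundary expression: coverage exactly 0.8, fpkm exactly 0.1 in one library
  expr <- data.table::rbindlist(lapply(c("E", "P", "L"), function(l)
    data.table::data.table(transcript_id = cand, library = l,
      read_count = if (l == "P") 50 else 0,
      fpkm = if (l == "P") 0.1 else 0,
      coverage = if (l == "P") 0.8 else 0.1)))
  res <- apply_filter_cascade(ann, cand, expr, seqs, filter_config())
  ft <- setNames(res$per_transcript$first_fail,
                 res$per_transcript$transcript_id)
  expect_equal(ft[["short"]], "min_length")   # 199 bp < 200
  expect_equal(ft[["bound"]], "retained")     # 200 bp / cov .8 / fpkm .1
  expect_equal(ft[["orfb"]], "retained")      # exactly 100 aa is kept
  expect_equal(ft[["senseov"]], "sense_exon_overlap")
  expect_equal(ft[["knownov"]], "retained")   # known lncRNA bypasses step 1
  expect_equal(ft[["monoex"]], "min_exons")
  expect_equal(ft[["nearend"]], "scaffold_end")
  # 101 aa crosses the "> 100 aa" line
  set.seed(99)
  seqs2 <- filter_seqs(ann, orf_aa = 101)
  res2 <- apply_filter_cascade(ann, cand, expr, seqs2, filter_config())
  expect_equal(res2$per_transcript[transcript_id == "orfb", first_fail],
               "max_orf")
})

test_that("strict inequalities: just-below-boundary values are removed", {
  set.seed(98)
  ann <- mk_filter_world()
  seqs <- filter_seqs(ann)["bound"]
  base <- function(cov, fp) data.table::rbindlist(lapply(c("E", "P", "L"),
    function(l) data.table::data.table(transcript_id = "bound", library = l,
      read_count = 10, fpkm = fp, coverage = cov)))
  r1 <- apply_filter_cascade(ann, "bound", base(0.799, 0.1), seqs,
                             filter_config())
  expect_equal(r1$per_transcript$first_fail, "min_coverage")
  r2 <- apply_filter_cascade(ann, "bound", base(0.8, 0.099), seqs,
                             filter_config())
  expect_equal(r2$per_transcript$first_fail, "min_fpkm")
})

test_that("evidence list and poly(A) gate", {
  set.seed(97)
  ann <- mk_filter_world()
  seqs <- filter_seqs(ann)
  expr <- mk_expr(c("bound", "knownov"))
  cfg <- filter_config(evidence_ids = "knownov")
  res <- apply_filter_cascade(ann, c("bound", "knownov"), expr, seqs, cfg)
  expect_equal(res$retained, "bound")
  expect_equal(res$per_transcript[transcript_id == "knownov", first_fail],
               "evidence")
  # poly(A) gate is inert by default but removes unlisted ids when enabled
  cfg2 <- filter_config(polyA_required = TRUE, polyA_ids = "bound")
  res2 <- apply_filter_cascade(ann, c("bound", "knownov"), expr, seqs, cfg2)
  expect_equal(res2$per_transcript[transcript_id == "knownov", first_fail],
               "polyA")
  expect_equal(res2$retained, "bound")
})

test_that("missing expression or sequence is an error naming the transcript", {
  set.seed(96)
  ann <- mk_filter_world()
  seqs <- filter_seqs(ann)
  expect_error(
    apply_filter_cascade(ann, c("bound", "monoex"), mk_expr("bound"), seqs,
                         filter_config()),
    "missing expression.*monoex")
  expect_error(
    apply_filter_cascade(ann, "bound", mk_expr("bound"), seqs[character(0)],
                         filter_config()),
    "missing sequence.*bound")
})

test_that("conservation, rule purity and monotonicity on planted data", {
  sim <- simulate_dataset(sim_config(seed = 21))
  cfg <- filter_config(evidence_ids = sim$evidence$transcript_id)
  res <- apply_filter_cascade(sim$ann, NULL, sim$expr, sim$seqs, cfg)
  n_cand <- nrow(res$per_transcript)
  expect_equal(n_cand, length(res$retained) + sum(res$report$removed))
  expect_equal(sum(res$report$removed),
               sum(res$per_transcript$first_fail != "retained"))

  # planted single-rule failures: removed and attributed to the planted rule
  planted <- sim$truth$filter_fail
  ft <- setNames(res$per_transcript$first_fail,
                 res$per_transcript$transcript_id)
  for (id in names(planted))
    expect_equal(ft[[id]], planted[[id]], info = id)
  expect_setequal(res$retained, sim$truth$retained)

  # rule purity / monotonicity: disabling one rule re-admits exactly that
  # rule's planted failures (each rule is a pure per-transcript predicate)
  relax <- list(
    min_length = filter_config(min_length_bp = 0,
                               evidence_ids = cfg$evidence_ids),
    min_exons = filter_config(min_exons = 0, evidence_ids = cfg$evidence_ids),
    min_coverage = filter_config(min_coverage = 0,
                                 evidence_ids = cfg$evidence_ids),
    min_fpkm = filter_config(min_fpkm = 0, evidence_ids = cfg$evidence_ids),
    max_orf = filter_config(max_orf_aa = 1e6,
                            evidence_ids = cfg$evidence_ids),
    scaffold_end = filter_config(scaffold_end_margin_bp = 0,
                                 evidence_ids = cfg$evidence_ids),
    evidence = filter_config(evidence_ids = character()),
    sense_exon_overlap = filter_config(drop_sense_exon_overlap = FALSE,
                                       evidence_ids = cfg$evidence_ids))
  for (rule in names(relax)) {
    r <- apply_filter_cascade(sim$ann, NULL, sim$expr, sim$seqs,
                              relax[[rule]])
    readmitted <- names(planted)[unlist(planted) == rule]
    expect_setequal(r$retained, union(res$retained, readmitted))
  }
})
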