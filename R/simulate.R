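#' Synthetic dataset configuration
#'
#' Describes the planted world the generator emits: a multi-scaffold
#' annotation with multi-exon coding genes on both strands, lncRNAs of all
#' five positional classes planted with unambiguous decision margins,
#' single-rule filter failures, three pooled stage libraries (E = early,
#' P = high/peak, L = late lactation) with Poisson counts and planted
#' fold-changes, hairpins embedded verbatim (and with controlled mutations)
#' in some lncRNAs, a miRNA-target table wiring planted ceRNA triples plus
#' one high-degree hub miRNA, and a term map with planted enriched terms.
#'
#' Planting margins: genes occupy fixed offsets inside 20-kb slots; sense /
#' antisense lncRNAs overlap the middle coding exon, intronic lncRNAs sit
#' wholly inside the second intron, bidirectional lncRNAs start 401 bp from
#' the gene TSS in divergent orientation (window 1000), and intergenic
#' lncRNAs lie > 10 kb from any gene, so the classifier's ground-truth class
#' is unambiguous.
#'
#' @param seed RNG seed; one seed, one byte stream.
#' @param n_scaffolds number of scaffolds.
#' @param planted_class_counts named counts for the five positional classes.
#' @param n_filter_failures named counts of planted single-rule filter
#'   failures (names are [apply_filter_cascade()] step names).
#' @param n_extra_coding additional coding genes with no planted lncRNA.
#' @param n_de_lncrnas,n_de_mrnas transcripts with a planted fold change in
#'   library P vs E (L mirrors E); directions alternate up/down.
#' @param planted_log2fc absolute planted log2 fold change (>= 1).
#' @param library_depths nominal total reads per stage library.
#' @param n_hairpins_embedded hairpins embedded verbatim in lncRNA hosts.
#' @param n_hairpins_mutated hairpins embedded after evenly spaced
#'   substitutions at `hairpin_mutation_rate` (planted precursor rejections).
#' @param n_hairpins_decoy hairpins embedded nowhere (null model).
#' @param hairpin_length hairpin length (nt).
#' @param hairpin_mutation_rate substitution fraction for mutated hairpins.
#' @param n_cerna_triples planted (lncRNA, miRNA, mRNA) triples.
#' @param n_background_terms,term_size,n_enriched_terms term-map geometry;
#'   enriched terms annotate exactly the planted-DE coding genes.
#' @param bidirectional_window classifier window the planting respects (bp).
#' @param scaffold_end_margin filter margin the planting respects (bp).
#' @return object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_scaffolds = 4L,
                       planted_class_counts = c(sense = 10L, antisense = 10L,
                                                intronic = 10L,
                                                bidirectional = 10L,
                                                intergenic = 10L),
                       n_filter_failures = c(sense_exon_overlap = 3L,
                                             min_length = 3L, min_exons = 3L,
                                             min_coverage = 3L, min_fpkm = 3L,
                                             max_orf = 3L, evidence = 3L,
                                             scaffold_end = 3L),
                       n_extra_coding = 20L,
                       n_de_lncrnas = 6L, n_de_mrnas = 8L,
                       planted_log2fc = 2,
                       library_depths = c(E = 1e6, P = 1e6, L = 1e6),
                       n_hairpins_embedded = 5L, n_hairpins_mutated = 3L,
                       n_hairpins_decoy = 5L, hairpin_length = 80L,
                       hairpin_mutation_rate = 0.15,
                       n_cerna_triples = 4L,
                       n_background_terms = 20L, term_size = 10L,
                       n_enriched_terms = 2L,
                       bidirectional_window = 1000L,
                       scaffold_end_margin = 2000L) {
  classes <- c("sense", "antisense", "intronic", "bidirectional", "intergenic")
  pcc <- setNames(rep(0L, 5), classes)
  pcc[names(planted_class_counts)] <- as.integer(planted_class_counts)
  rules <- c("sense_exon_overlap", "min_length", "min_exons", "min_coverage",
             "min_fpkm", "max_orf", "evidence", "scaffold_end")
  nff <- setNames(rep(0L, length(rules)), rules)
  nff[names(n_filter_failures)] <- as.integer(n_filter_failures)
  cfg <- list(seed = as.integer(seed), n_scaffolds = as.integer(n_scaffolds),
              planted_class_counts = pcc, n_filter_failures = nff,
              n_extra_coding = as.integer(n_extra_coding),
              n_de_lncrnas = as.integer(n_de_lncrnas),
              n_de_mrnas = as.integer(n_de_mrnas),
              planted_log2fc = planted_log2fc,
              library_depths = library_depths,
              n_hairpins_embedded = as.integer(n_hairpins_embedded),
              n_hairpins_mutated = as.integer(n_hairpins_mutated),
              n_hairpins_decoy = as.integer(n_hairpins_decoy),
              hairpin_length = as.integer(hairpin_length),
              hairpin_mutation_rate = hairpin_mutation_rate,
              n_cerna_triples = as.integer(n_cerna_triples),
              n_background_terms = as.integer(n_background_terms),
              term_size = as.integer(term_size),
              n_enriched_terms = as.integer(n_enriched_terms),
              bidirectional_window = as.integer(bidirectional_window),
              scaffold_end_margin = as.integer(scaffold_end_margin),
              slot_bp = 20000L)
  assert_that(all(pcc >= 0) && all(nff >= 0), "counts must be >= 0")
  assert_that(abs(cfg$planted_log2fc) >= 1, "planted |log2fc| must be >= 1")
  assert_that(cfg$n_hairpins_embedded + cfg$n_hairpins_mutated <=
                pcc["intergenic"],
              "hairpin hosts exceed intergenic lncRNA count")
  if (cfg$n_cerna_triples > 0) {
    assert_that(pcc["bidirectional"] >= max(2L, cfg$n_cerna_triples),
                "ceRNA triples need >= max(2, n_triples) bidirectional lncRNAs")
    assert_that(cfg$n_de_mrnas >= max(3L, cfg$n_cerna_triples),
                "ceRNA triples need >= max(3, n_triples) planted-DE mRNAs")
  }
  total_lnc <- sum(pcc)
  assert_that(cfg$n_de_lncrnas <= total_lnc, "too many DE lncRNAs requested")
  structure(cfg, class = "sim_config")
}

random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# replace one in-frame codon of the longest ORF with TAA until no ORF exceeds
# max_aa; positions inside `protected` (1-based inclusive range) are never
# touched. Works in the orientation the ORF was found in and maps back.
break_long_orfs <- function(seq, max_aa = 100L, protected = NULL,
                            max_iter = 200L) {
  n <- nchar(seq)
  for (it in seq_len(max_iter)) {
    b <- .orf_best(seq)
    if (b$aa <= max_aa) return(seq)
    s <- if (b$orient == 1L) seq else revcomp(seq)
    # candidate codons strictly inside the ORF (never the ATG itself)
    cand_nt <- b$nt_start + 3L * seq_len(b$aa - 1L)
    ok <- rep(TRUE, length(cand_nt))
    if (!is.null(protected)) {
      # map protected range into the current orientation
      pr <- if (b$orient == 1L) protected
            else c(n - protected[2] + 1L, n - protected[1] + 1L)
      ok <- cand_nt + 2L < pr[1] | cand_nt > pr[2]
    }
    assert_that(any(ok), "cannot break ORF without touching protected region")
    pos <- cand_nt[ok][ceiling(sum(ok) / 2)]
    substr(s, pos, pos + 2L) <- "TAA"
    seq <- if (b$orient == 1L) s else revcomp(s)
  }
  stop2("failed to reduce ORFs below %d aa", max_aa)
}

# evenly spaced substitutions, each to a different base (controlled mutation)
mutate_evenly <- function(seq, rate) {
  n <- nchar(seq)
  k <- ceiling(rate * n)
  pos <- unique(round(seq(2, n - 1, length.out = k)))
  ch <- strsplit(seq, "")[[1]]
  for (p in pos) {
    alt <- setdiff(c("A", "C", "G", "T"), ch[p])
    ch[p] <- alt[1L + (p %% 3L)]
  }
  paste(ch, collapse = "")
}

# exon layouts inside a slot starting at S (0-based); all offsets chosen so
# planted classes sit well inside the classifier's decision margins
slot_gene_exons <- function(S) {
  data.table(start = S + c(4000L, 7000L, 11000L),
             end = S + c(5000L, 8000L, 12000L))
}

slot_lnc_exons <- function(S, kind, gene_strand = NULL) {
  switch(kind,
    sense = ,
    antisense = ,
    sense_exon_overlap =
      data.table(start = S + c(6500L, 7700L), end = S + c(7500L, 7900L)),
    intronic =
      data.table(start = S + c(8500L, 9500L), end = S + c(9000L, 10000L)),
    bidirectional = if (gene_strand == "+")
      data.table(start = S + c(2600L, 3300L), end = S + c(3200L, 3600L))
    else
      data.table(start = S + c(12400L, 13100L), end = S + c(13000L, 13400L)),
    intergenic = ,
    min_coverage = ,
    min_fpkm = ,
    evidence =
      data.table(start = S + c(8000L, 8700L), end = S + c(8600L, 9200L)),
    min_length =
      data.table(start = S + c(8000L, 8150L), end = S + c(8100L, 8200L)),
    min_exons =
      data.table(start = S + 8000L, end = S + 8400L),
    max_orf =
      data.table(start = S + c(8000L, 8500L), end = S + c(8400L, 8900L)),
    stop2("unknown slot kind %s", kind))
}

#' Generate the synthetic dataset
#'
#' Deterministic given `config$seed`: the same seed yields byte-identical
#' output files. Emits (when `out_dir` is given): `annotation.gtf`,
#' `scaffolds.tsv`, `transcripts.fa`, `hairpins.fa`, `expression.tsv`,
#' `evidence.tsv`, `targets.tsv`, `terms.tsv` and `ground_truth.json`.
#'
#' Counts are Poisson around depth-scaled expected abundances (no
#' overdispersion: the emulated libraries are pooled singletons, which is
#' also what the exact conditional test assumes). FPKM is computed from the
#' realized counts and spliced lengths by the standard definition; coverage
#' is Uniform(0.85, 1) for transcripts meant to survive the filter and
#' Uniform(0.1, 0.75) for planted coverage failures.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory (created); `NULL` for in-memory only.
#' @return invisible list: `ann`, `expr`, `seqs`, `hairpins`, `targets`,
#'   `terms`, `evidence`, `truth`, `files`.
#' @export
simulate_dataset <- function(config = sim_config(), out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  classes <- c("sense", "antisense", "intronic", "bidirectional", "intergenic")

  # ---- slot plan ---------------------------------------------------------
  plan <- list()
  add <- function(kind, id) plan[[length(plan) + 1L]] <<- list(kind = kind,
                                                               id = id)
  for (cl in classes)
    for (i in seq_len(config$planted_class_counts[[cl]]))
      add(cl, sprintf("lnc-%s-%03d", cl, i))
  for (rule in names(config$n_filter_failures))
    if (rule != "scaffold_end")
      for (i in seq_len(config$n_filter_failures[[rule]]))
        add(rule, sprintf("fail-%s-%02d", rule, i))
  for (i in seq_len(config$n_extra_coding)) add("gene_only", NA_character_)

  n_slots <- length(plan)
  slots_per_scaf <- ceiling(n_slots / config$n_scaffolds)
  scaf_len <- 4000L + slots_per_scaf * config$slot_bp + 4000L
  scaffolds <- setNames(rep(scaf_len, config$n_scaffolds),
                        sprintf("scaf_%02d", seq_len(config$n_scaffolds)))

  # genes occupy every slot whose kind needs a host gene
  gene_kinds <- c("sense", "antisense", "intronic", "bidirectional",
                  "sense_exon_overlap", "gene_only")
  exon_rows <- list()
  truth_class <- list()
  gene_ids <- character()
  gi <- 0L
  # shuffle slot order so classes and scaffolds are interleaved
  plan <- plan[sample.int(n_slots)]
  for (si in seq_len(n_slots)) {
    sc <- names(scaffolds)[((si - 1L) %% config$n_scaffolds) + 1L]
    S <- 4000L + ((si - 1L) %/% config$n_scaffolds) * config$slot_bp
    kind <- plan[[si]]$kind
    id <- plan[[si]]$id
    g_strand <- sample(c("+", "-"), 1L)
    if (kind %in% gene_kinds) {
      gi <- gi + 1L
      gid <- sprintf("gene-%04d", gi)
      gene_ids <- c(gene_ids, gid)
      ge <- slot_gene_exons(S)
      exon_rows[[length(exon_rows) + 1L]] <- data.table(
        chrom = sc, start = ge$start, end = ge$end, strand = g_strand,
        transcript_id = sprintf("mrna-%04d", gi), gene_id = gid,
        biotype = "coding")
    }
    if (kind == "gene_only") next
    lnc_strand <- switch(kind,
      sense = g_strand,
      sense_exon_overlap = g_strand,
      antisense = if (g_strand == "+") "-" else "+",
      bidirectional = if (g_strand == "+") "-" else "+",
      sample(c("+", "-"), 1L))
    le <- slot_lnc_exons(S, kind, gene_strand = g_strand)
    exon_rows[[length(exon_rows) + 1L]] <- data.table(
      chrom = sc, start = le$start, end = le$end, strand = lnc_strand,
      transcript_id = id, gene_id = paste0("g:", id),
      biotype = if (kind == "sense") "known_lncRNA" else "candidate_noncoding")
    if (kind %in% classes)
      truth_class[[id]] <- kind
  }
  # scaffold-end failures: short transcripts inside the 2-kb start margin
  n_se <- config$n_filter_failures[["scaffold_end"]]
  for (i in seq_len(n_se)) {
    sc <- names(scaffolds)[((i - 1L) %% config$n_scaffolds) + 1L]
    o <- 100L + 500L * ((i - 1L) %/% config$n_scaffolds)
    assert_that(o < config$scaffold_end_margin,
                "too many scaffold-end failures for the margin region")
    exon_rows[[length(exon_rows) + 1L]] <- data.table(
      chrom = sc, start = c(o, o + 250L), end = c(o + 200L, o + 450L),
      strand = sample(c("+", "-"), 1L),
      transcript_id = sprintf("fail-scaffold_end-%02d", i),
      gene_id = sprintf("g:fail-scaffold_end-%02d", i),
      biotype = "candidate_noncoding")
  }
  exons <- rbindlist(exon_rows)
  ann <- annotation_from_exons(exons, scaffolds)

  tx <- ann$transcripts
  lnc_ids <- tx[biotype != "coding", transcript_id]
  mrna_ids <- tx[biotype == "coding", transcript_id]
  class_lncs <- names(truth_class)
  fail_ids <- grep("^fail-", lnc_ids, value = TRUE)
  fail_rule <- sub("-[0-9]+$", "", sub("^fail-", "", fail_ids))

  # ---- sequences ---------------------------------------------------------
  seqs <- setNames(vapply(tx$length_bp, random_seq, character(1)),
                   tx$transcript_id)

  # hairpins: embedded verbatim, embedded mutated, decoys
  n_hp <- config$n_hairpins_embedded + config$n_hairpins_mutated +
    config$n_hairpins_decoy
  hairpins <- setNames(vapply(rep(config$hairpin_length, n_hp), random_seq,
                              character(1)),
                       sprintf("hp-%03d", seq_len(n_hp)))
  hosts <- grep("^lnc-intergenic-", class_lncs, value = TRUE)
  hosts <- hosts[seq_len(config$n_hairpins_embedded +
                           config$n_hairpins_mutated)]
  embed_offset <- 101L
  hp_truth <- list()
  for (i in seq_len(config$n_hairpins_embedded + config$n_hairpins_mutated)) {
    hp_id <- names(hairpins)[i]
    host <- hosts[i]
    mutated <- i > config$n_hairpins_embedded
    ins <- if (mutated)
      mutate_evenly(hairpins[[hp_id]], config$hairpin_mutation_rate)
    else hairpins[[hp_id]]
    s <- seqs[[host]]
    substr(s, embed_offset, embed_offset + nchar(ins) - 1L) <- ins
    seqs[[host]] <- s
    hp_truth[[hp_id]] <- list(hairpin_id = hp_id, host = host,
                              offset = embed_offset, mutated = mutated)
  }

  # planted long-ORF failures, then break accidental ORFs everywhere else
  protected <- setNames(vector("list", length(lnc_ids)), lnc_ids)
  for (h in hp_truth)
    protected[[h$host]] <- c(h$offset,
                             h$offset + config$hairpin_length - 1L)
  orf_fails <- fail_ids[fail_rule == "max_orf"]
  for (id in orf_fails) {
    s <- seqs[[id]]
    nonstop <- c("GCA", "GGT", "CTG", "ACC", "TTC", "GAT")
    body <- paste(sample(nonstop, 148L, replace = TRUE), collapse = "")
    orf <- paste0("ATG", body, "TAA")            # 149 aa before the stop
    substr(s, 50L, 50L + nchar(orf) - 1L) <- orf
    seqs[[id]] <- s
  }
  for (id in setdiff(lnc_ids, orf_fails))
    seqs[[id]] <- break_long_orfs(seqs[[id]], max_aa = 100L,
                                  protected = protected[[id]])

  # ---- expression --------------------------------------------------------
  all_tx <- tx$transcript_id
  w <- stats::rlnorm(length(all_tx), meanlog = 0, sdlog = 0.7)
  names(w) <- all_tx
  w[fail_ids[fail_rule == "min_fpkm"]] <- 0
  de_lnc <- head(class_lncs, config$n_de_lncrnas)
  de_mrna_genes <- character(0)
  de_mrna_tx <- head(mrna_ids, config$n_de_mrnas)
  de_mrna_genes <- tx[match(de_mrna_tx, transcript_id), gene_id]
  de_tx <- c(de_lnc, de_mrna_tx)
  w[de_tx] <- pmax(w[de_tx], stats::median(w[w > 0]))
  lfc <- setNames(rep(0, length(all_tx)), all_tx)
  lfc[de_tx] <- config$planted_log2fc *
    ifelse(seq_along(de_tx) %% 2L == 1L, 1, -1)
  wsum <- sum(w)
  expr_rows <- list()
  counts_by_lib <- list()
  for (lib in names(config$library_depths)) {
    mult <- if (lib == "P") 2^lfc else rep(1, length(all_tx))
    mu <- config$library_depths[[lib]] * w * mult / wsum
    counts_by_lib[[lib]] <- rpois(length(all_tx), mu)
  }
  cov_lo <- fail_ids[fail_rule == "min_coverage"]
  for (lib in names(config$library_depths)) {
    cnt <- counts_by_lib[[lib]]
    depth <- sum(as.numeric(cnt))
    fpkm <- ifelse(cnt == 0, 0, cnt * 1e9 / (as.numeric(tx$length_bp) * depth))
    coverage <- runif(length(all_tx), 0.85, 1.0)
    coverage[match(cov_lo, all_tx)] <- runif(length(cov_lo), 0.1, 0.75)
    expr_rows[[lib]] <- data.table(transcript_id = all_tx, library = lib,
                                   read_count = cnt, fpkm = fpkm,
                                   coverage = round(coverage, 6))
  }
  expr <- rbindlist(expr_rows)
  setorder(expr, transcript_id, library)

  # ---- evidence, targets, terms -----------------------------------------
  evidence <- data.table(
    transcript_id = fail_ids[fail_rule == "evidence"],
    source = "swissprot")

  bidir <- grep("^lnc-bidirectional-", class_lncs, value = TRUE)
  targets <- list()
  triples <- list()
  for (i in seq_len(config$n_cerna_triples)) {
    mir <- sprintf("mir-cerna-%02d", i)
    targets[[length(targets) + 1L]] <- data.table(
      mirna_id = mir, target_id = c(bidir[i], de_mrna_genes[i]))
    triples[[i]] <- list(mirna = mir, lncrna = bidir[i],
                         mrna = de_mrna_genes[i])
  }
  hub <- NULL
  if (config$n_cerna_triples > 0) {
    hub <- list(mirna = "mir-hub", lncrnas = bidir[1:2],
                mrnas = de_mrna_genes[1:3])
    targets[[length(targets) + 1L]] <- data.table(
      mirna_id = "mir-hub", target_id = c(bidir[1:2], de_mrna_genes[1:3]))
  }
  targets <- if (length(targets)) rbindlist(targets)
             else data.table(mirna_id = character(), target_id = character())

  term_rows <- list()
  enriched_terms <- sprintf("term-enriched-%02d",
                            seq_len(config$n_enriched_terms))
  for (tm in enriched_terms)
    term_rows[[length(term_rows) + 1L]] <- data.table(term_id = tm,
                                                      gene_id = de_mrna_genes)
  for (i in seq_len(config$n_background_terms))
    term_rows[[length(term_rows) + 1L]] <- data.table(
      term_id = sprintf("term-bg-%03d", i),
      gene_id = sample(gene_ids, min(config$term_size, length(gene_ids))))
  terms <- if (length(term_rows)) rbindlist(term_rows)
           else data.table(term_id = character(), gene_id = character())

  # ---- ground truth ------------------------------------------------------
  truth <- list(
    seed = config$seed,
    classes = truth_class,
    filter_fail = setNames(as.list(fail_rule), fail_ids),
    retained = sort(class_lncs),
    de = list(contrast = "E:P",
              up = de_tx[lfc[de_tx] > 0], down = de_tx[lfc[de_tx] < 0],
              log2fc = as.list(lfc[de_tx])),
    hairpins = list(embedded = unname(hp_truth),
                    decoys = names(hairpins)[seq_len(config$n_hairpins_decoy) +
                      config$n_hairpins_embedded + config$n_hairpins_mutated]),
    triples = triples, hub = hub,
    enriched_terms = as.list(enriched_terms),
    counts = list(
      n_candidates = length(lnc_ids),
      n_retained = length(class_lncs),
      class_counts = as.list(config$planted_class_counts),
      n_coding_genes = length(gene_ids)))

  files <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    files <- list(
      gtf = file.path(out_dir, "annotation.gtf"),
      scaffolds = file.path(out_dir, "scaffolds.tsv"),
      transcripts = file.path(out_dir, "transcripts.fa"),
      hairpins = file.path(out_dir, "hairpins.fa"),
      expression = file.path(out_dir, "expression.tsv"),
      evidence = file.path(out_dir, "evidence.tsv"),
      targets = file.path(out_dir, "targets.tsv"),
      terms = file.path(out_dir, "terms.tsv"),
      truth = file.path(out_dir, "ground_truth.json"))
    write_gtf(ann, files$gtf)
    write_tsv(data.table(chrom = names(scaffolds),
                         length = unname(scaffolds)), files$scaffolds)
    write_fasta(seqs, files$transcripts)
    write_fasta(hairpins, files$hairpins)
    write_tsv(expr, files$expression)
    write_tsv(evidence, files$evidence)
    write_tsv(targets, files$targets)
    write_tsv(terms, files$terms)
    jsonlite::write_json(truth, files$truth, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(list(ann = ann, expr = expr, seqs = seqs, hairpins = hairpins,
                 targets = targets, terms = terms, evidence = evidence,
                 truth = truth, config = config, files = files))
}
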