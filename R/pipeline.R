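#' Pipeline configuration
#'
#' Bundles all module thresholds plus input paths and the seed. Every
#' threshold default restates the published screening rule it implements
#' (see the individual module documentation). Unknown arguments are rejected
#' by normal R argument matching.
#'
#' @param gtf,scaffolds,expression,transcripts_fa required input paths.
#' @param hairpins_fa,evidence,targets,terms optional input paths; stages
#'   lacking their input are skipped with an empty output table.
#' @param out_dir result directory.
#' @param seed RNG seed (the analysis stages are deterministic; the seed is
#'   recorded and set for reproducibility of any future stochastic stage).
#' @param filter a [filter_config()]; evidence ids from the `evidence` file
#'   are merged in.
#' @param bidirectional_window,apc_window classifier windows (bp).
#' @param duplex a [duplex_params()].
#' @param contrasts,fdr,min_abs_log2fc,pseudocount DE settings.
#' @param min_identity,min_coverage precursor thresholds.
#' @param min_reads,enrich_alpha network screen and enrichment threshold.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(gtf, scaffolds, expression, transcripts_fa,
                            hairpins_fa = NULL, evidence = NULL,
                            targets = NULL, terms = NULL,
                            out_dir, seed = 1L,
                            filter = filter_config(),
                            bidirectional_window = 1000L,
                            apc_window = 10000L,
                            duplex = duplex_params(),
                            contrasts = list(c("E", "P"), c("E", "L"),
                                             c("P", "L")),
                            fdr = 0.05, min_abs_log2fc = 1,
                            pseudocount = 0.01,
                            min_identity = 0.90, min_coverage = 0.90,
                            min_reads = 10, enrich_alpha = 0.05) {
  cfg <- as.list(environment())
  structure(cfg, class = "pipeline_config")
}

stage_error <- function(stage, e) {
  stop2("pipeline stage '%s' failed: %s", stage, conditionMessage(e))
}

#' Run the full pipeline
#'
#' Stage order: identify (filter) -> classify -> apcGene links -> antisense
#' duplexes -> precursors -> differential expression -> enrichment ->
#' ceRNA network. All stage outputs land under `cfg$out_dir` together with a
#' machine-readable `manifest.json` (per-stage record counts, config echo,
#' md5 of every output file). A rerun with identical inputs and seed is
#' byte-identical.
#'
#' @param cfg a [pipeline_config()].
#' @param quiet suppress per-stage messages.
#' @return invisible list with the in-memory stage results and the manifest.
#' @export
run_all <- function(cfg, quiet = FALSE) {
  stopifnot(inherits(cfg, "pipeline_config"))
  set.seed(cfg$seed)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))
  outfile <- function(name) file.path(cfg$out_dir, name)

  # ---- inputs ------------------------------------------------------------
  scaf <- read_scaffold_lengths(cfg$scaffolds)
  ann <- tryCatch(read_gtf(cfg$gtf, scaf),
                  error = function(e) stage_error("read_gtf", e))
  seqs <- read_fasta(cfg$transcripts_fa)
  expr <- read_expression(cfg$expression,
                          libraries = unique(unlist(cfg$contrasts)))
  fcfg <- cfg$filter
  if (!is.null(cfg$evidence) && file.exists(cfg$evidence)) {
    ev <- read_tsv(cfg$evidence)
    if (nrow(ev)) fcfg$evidence_ids <- union(fcfg$evidence_ids,
                                             ev$transcript_id)
  }

  # ---- filter ------------------------------------------------------------
  candidates <- ann$transcripts[biotype != "coding", transcript_id]
  flt <- tryCatch(apply_filter_cascade(ann, candidates, expr, seqs, fcfg),
                  error = function(e) stage_error("filter", e))
  write_tsv(flt$report, outfile("filter_report.tsv"))
  write_tsv(flt$per_transcript, outfile("filter_per_transcript.tsv"))
  say("filter: %d candidates -> %d retained", length(candidates),
      length(flt$retained))

  # ---- classify + apc ----------------------------------------------------
  cl <- tryCatch(
    classify_lncrnas(ann, flt$retained,
                     bidirectional_window = cfg$bidirectional_window),
    error = function(e) stage_error("classify", e))
  write_tsv(cl, outfile("classified.tsv"))
  write_bed(cl, ann, outfile("classified.bed"))
  apc <- find_apc_genes(ann, flt$retained, window_bp = cfg$apc_window)
  write_tsv(apc, outfile("apc_links.tsv"))
  say("classify: %s",
      paste(sprintf("%s=%d", names(table(cl$lnc_class)),
                    table(cl$lnc_class)), collapse = " "))

  # ---- antisense duplexes ------------------------------------------------
  anti <- cl[lnc_class == "antisense"]
  dup_gene <- data.table(lnc_id = character(), mrna_id = character(),
                         score = numeric())
  if (nrow(anti)) {
    pairs <- merge(anti[, .(lnc_id = transcript_id,
                            gene_id = evidence_gene_id)],
                   ann$transcripts[biotype == "coding",
                                   .(gene_id, mrna_id = transcript_id)],
                   by = "gene_id", allow.cartesian = TRUE)
    hits <- duplex_screen(pairs[, .(lnc_id, mrna_id)], seqs, cfg$duplex)
    if (nrow(hits)) {
      hits <- merge(hits, ann$transcripts[, .(mrna_id = transcript_id,
                                              gene_id)], by = "mrna_id")
      dup_gene <- unique(hits[, .(lnc_id, mrna_id = gene_id, score)])
    }
  }
  write_tsv(dup_gene, outfile("antisense_duplexes.tsv"))

  # ---- precursors --------------------------------------------------------
  prec <- data.table(lnc_id = character(), hairpin_id = character(),
                     identity = numeric(), coverage = numeric())
  if (!is.null(cfg$hairpins_fa) && file.exists(cfg$hairpins_fa)) {
    hp <- read_fasta(cfg$hairpins_fa)
    prec <- match_precursors(seqs[flt$retained], hp,
                             min_identity = cfg$min_identity,
                             min_coverage = cfg$min_coverage)
  }
  write_tsv(prec, outfile("precursor_hits.tsv"))

  # ---- differential expression ------------------------------------------
  de <- tryCatch(
    call_de(expr, contrasts = cfg$contrasts, fdr = cfg$fdr,
            min_abs_log2fc = cfg$min_abs_log2fc,
            pseudocount = cfg$pseudocount),
    error = function(e) stage_error("diff_expression", e))
  write_tsv(de, outfile("de_results.tsv"))
  coding <- ann$transcripts[biotype == "coding"]
  de_gene <- merge(de, coding[, .(transcript_id, gene_id)],
                   by = "transcript_id")
  de_gene <- de_gene[, .(transcript_id = gene_id, contrast, count_a, count_b,
                         log2fc, pvalue, qvalue, call)]
  say("DE: %d calls over %d contrasts", sum(de$call != "ns"),
      length(cfg$contrasts))

  # ---- enrichment --------------------------------------------------------
  enr <- data.table(term_id = character(), k = integer(), K = integer(),
                    n = integer(), N = integer(), pvalue = numeric(),
                    qvalue = numeric(), significant = logical())
  study <- sort(unique(de_gene[call != "ns", transcript_id]))
  if (!is.null(cfg$terms) && file.exists(cfg$terms) && length(study)) {
    terms <- read_term_map(cfg$terms)
    population <- sort(unique(coding$gene_id))
    enr <- enrich(study, population, terms, alpha = cfg$enrich_alpha)
  }
  write_tsv(enr, outfile("enrichment.tsv"))

  # ---- ceRNA network -----------------------------------------------------
  tgt <- data.table(mirna_id = character(), target_id = character())
  if (!is.null(cfg$targets) && file.exists(cfg$targets))
    tgt <- read_tsv(cfg$targets)
  net <- build_cerna(lnc_ids = flt$retained, expr = expr, de = de_gene,
                     apc_links = apc, duplex_hits = dup_gene,
                     precursors = prec, targets = tgt,
                     min_reads = cfg$min_reads)
  write_cerna(net, outfile("network_nodes.tsv"), outfile("network_edges.tsv"))
  hubs <- score_hubs(net)
  write_tsv(hubs, outfile("hub_scores.tsv"))
  say("network: %d nodes, %d edges", nrow(net$nodes), nrow(net$edges))

  # ---- manifest ----------------------------------------------------------
  cfg_echo <- cfg
  cfg_echo$filter <- unclass(cfg_echo$filter)
  cfg_echo$duplex <- unclass(cfg_echo$duplex)
  # paths are echoed as basenames (and the output directory is omitted: the
  # manifest lives inside it) so a rerun into a fresh directory with
  # identically named inputs produces a byte-identical manifest
  cfg_echo$out_dir <- NULL
  for (f in c("gtf", "scaffolds", "expression", "transcripts_fa",
              "hairpins_fa", "evidence", "targets", "terms"))
    if (!is.null(cfg_echo[[f]])) cfg_echo[[f]] <- basename(cfg_echo[[f]])
  cfg_json <- jsonlite::toJSON(unclass(cfg_echo), auto_unbox = TRUE,
                               digits = NA, null = "null")
  outputs <- list.files(cfg$out_dir, pattern = "\\.(tsv|bed)$",
                        full.names = TRUE)
  manifest <- list(
    seed = cfg$seed,
    config = jsonlite::fromJSON(cfg_json),
    config_md5 = unname(tools::md5sum(
      local({ f <- tempfile(); writeLines(cfg_json, f); f }))),
    stages = list(
      filter = list(n_candidates = length(candidates),
                    n_retained = length(flt$retained),
                    removed = as.list(setNames(flt$report$removed,
                                               flt$report$step))),
      classify = as.list(table(cl$lnc_class)),
      apc = list(n_links = nrow(apc)),
      antisense_duplex = list(n_hits = nrow(dup_gene)),
      precursor = list(n_hits = nrow(prec)),
      de = as.list(tapply(de$call != "ns", de$contrast, sum)),
      enrichment = list(n_significant = sum(enr$significant)),
      network = list(n_nodes = nrow(net$nodes), n_edges = nrow(net$edges),
                     n_skipped_targets = net$skipped_targets)),
    outputs = as.list(setNames(unname(tools::md5sum(sort(outputs))),
                               basename(sort(outputs)))))
  jsonlite::write_json(manifest, outfile("manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(filter = flt, classified = cl, apc = apc,
                 duplex = dup_gene, precursors = prec, de = de,
                 enrichment = enr, network = net, hubs = hubs,
                 manifest = manifest))
}
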