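# Small programmatic fixtures shared across test files.

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

# one transcript's exon rows from a compact description
tx_exons <- function(chrom, strand, tx, gene, starts, ends,
                     biotype = "coding") {
  data.table::data.table(chrom = chrom, start = as.integer(starts),
                         end = as.integer(ends), strand = strand,
                         transcript_id = tx, gene_id = gene,
                         biotype = biotype)
}

# a random multi-gene annotation for property tests: genes with 1-4 exons at
# random positions (overlaps between genes allowed), plus candidate lncRNAs
rand_annotation <- function(n_genes, n_lnc, chrom_len = 100000L,
                            n_chrom = 2L) {
  chroms <- sprintf("c%d", seq_len(n_chrom))
  rows <- list()
  mk_tx <- function(tx, gene, biotype) {
    chrom <- sample(chroms, 1)
    strand <- sample(c("+", "-"), 1)
    n_ex <- sample(1:4, 1)
    w <- sample(100:800, n_ex, replace = TRUE)
    gaps <- sample(50:2000, n_ex, replace = TRUE)
    start0 <- sample.int(chrom_len - sum(w) - sum(gaps) - 10L, 1)
    starts <- start0 + cumsum(c(0L, (w + gaps)[-n_ex]))
    tx_exons(chrom, strand, tx, gene, starts, starts + w, biotype)
  }
  for (i in seq_len(n_genes))
    rows[[length(rows) + 1L]] <- mk_tx(sprintf("t%03d", i),
                                       sprintf("g%03d", i), "coding")
  for (i in seq_len(n_lnc))
    rows[[length(rows) + 1L]] <- mk_tx(sprintf("lnc%03d", i),
                                       sprintf("gl%03d", i),
                                       "candidate_noncoding")
  annotation_from_exons(data.table::rbindlist(rows),
                        stats::setNames(rep(chrom_len, n_chrom), chroms))
}

# minimal expression table: same values in all three libraries unless given
mk_expr <- function(ids, count = 100, fpkm = 10, coverage = 0.95,
                    libs = c("E", "P", "L")) {
  data.table::rbindlist(lapply(libs, function(l)
    data.table::data.table(transcript_id = ids, library = l,
                           read_count = count, fpkm = fpkm,
                           coverage = coverage)))
}

# copy of an annotation with every lncRNA (non-coding) transcript strand
# flipped; flipping both sides at once would leave relative orientation --
# and hence sense/antisense -- unchanged
flip_lnc_strands <- function(ann) {
  ex <- data.table::copy(ann$exons)
  ex[biotype != "coding", strand := ifelse(strand == "+", "-", "+")]
  annotation_from_exons(ex, ann$scaffold_lengths)
}

# memoized datasets shared by the acceptance suite (built once per run)
.acc_cache <- new.env(parent = emptyenv())

# ~2,000 candidates: 100 lncRNAs per class (104 intergenic) plus 187 planted
# failures per filter rule
acc_big_sim <- function() {
  if (is.null(.acc_cache$big)) {
    .acc_cache$big <- simulate_dataset(sim_config(
      seed = 101, n_scaffolds = 48,
      planted_class_counts = c(sense = 100, antisense = 100, intronic = 100,
                               bidirectional = 100, intergenic = 104),
      n_filter_failures = c(sense_exon_overlap = 187, min_length = 187,
                            min_exons = 187, min_coverage = 187,
                            min_fpkm = 187, max_orf = 187, evidence = 187,
                            scaffold_end = 187),
      n_extra_coding = 20, n_de_lncrnas = 20, n_de_mrnas = 20,
      n_cerna_triples = 10, n_hairpins_embedded = 10, n_hairpins_mutated = 5,
      n_hairpins_decoy = 10))
  }
  .acc_cache$big
}

acc_default_sim <- function() {
  if (is.null(.acc_cache$default)) {
    d <- file.path(tempdir(), "acc_default_sim")
    unlink(d, recursive = TRUE)
    .acc_cache$default <- simulate_dataset(sim_config(seed = 102),
                                           out_dir = d)
  }
  .acc_cache$default
}

elapsed <- function(expr) {
  t0 <- Sys.time()
  force(expr)
  as.numeric(Sys.time() - t0, units = "secs")
}
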