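# minimal hand-wired inputs for the worked examples
mk_net_inputs <- function(lnc_reads = 50) {
  list(
    lnc_ids = "lnc1",
    expr = mk_expr("lnc1", count = lnc_reads),
    de = data.table::data.table(transcript_id = "geneA", contrast = "E:P",
                                call = "up"),
    apc = data.table::data.table(transcript_id = "lnc1", gene_id = "geneA",
                                 side = "upstream", gap_bp = 500),
    dup = data.table::data.table(lnc_id = character(),
                                 mrna_id = character(), score = numeric()),
    prec = data.table::data.table(lnc_id = character(),
                                  hairpin_id = character(),
                                  identity = numeric(),
                                  coverage = numeric()),
    targets = data.table::data.table(mirna_id = "mir1",
                                     target_id = c("lnc1", "geneA")))
}

test_that("worked example: one miRNA bridging lnc1 and geneA", {
  x <- mk_net_inputs()
  g <- build_cerna(x$lnc_ids, x$expr, x$de, x$apc, x$dup, x$prec, x$targets)
  expect_setequal(g$nodes$node_id, c("lnc1", "mir1", "geneA"))
  expect_equal(sort(g$edges$edge_type),
               sort(c("mirna_targets_lncrna", "mirna_targets_mrna", "apc")))
  hubs <- score_hubs(g)
  expect_equal(hubs$score, 1L)   # one bridged (lnc, mRNA) pair
})

test_that("read-count screen is strict: exactly 10 is excluded, 11 admitted", {
  x <- mk_net_inputs(lnc_reads = 10)
  g <- build_cerna(x$lnc_ids, x$expr, x$de, x$apc, x$dup, x$prec, x$targets)
  expect_false("lnc1" %in% g$nodes$node_id)
  expect_equal(nrow(g$edges), 0L)
  x2 <- mk_net_inputs(lnc_reads = 11)
  g2 <- build_cerna(x2$lnc_ids, x2$expr, x2$de, x2$apc, x2$dup, x2$prec,
                    x2$targets)
  expect_true("lnc1" %in% g2$nodes$node_id)
})

test_that("lncRNAs without any apc/antisense link are not admitted", {
  x <- mk_net_inputs()
  x$apc <- x$apc[0]
  g <- build_cerna(x$lnc_ids, x$expr, x$de, x$apc, x$dup, x$prec, x$targets)
  expect_false("lnc1" %in% g$nodes$node_id)
})

test_that("unresolvable target rows are skipped with a warning", {
  x <- mk_net_inputs()
  x$targets <- rbind(x$targets,
                     data.table::data.table(mirna_id = "mir9",
                                            target_id = "nothing"))
  expect_warning(
    g <- build_cerna(x$lnc_ids, x$expr, x$de, x$apc, x$dup, x$prec,
                     x$targets),
    "skipped 1 target")
  expect_equal(g$skipped_targets, 1L)
  expect_false("mir9" %in% g$nodes$node_id)
})

test_that("hub scoring: 2 lncRNA x 3 mRNA edges give score 6; ranking", {
  lncs <- paste0("l", 1:2); genes <- paste0("m", 1:3)
  x <- list(
    lnc_ids = lncs,
    expr = mk_expr(lncs, count = 100),
    de = data.table::data.table(transcript_id = genes, contrast = "E:P",
                                call = "up"),
    apc = data.table::data.table(transcript_id = lncs, gene_id = "m1",
                                 side = "upstream", gap_bp = 100),
    dup = data.table::data.table(lnc_id = character(),
                                 mrna_id = character(), score = numeric()),
    prec = data.table::data.table(lnc_id = character(),
                                  hairpin_id = character(),
                                  identity = numeric(), coverage = numeric()),
    targets = data.table::rbindlist(list(
      data.table::data.table(mirna_id = "hub", target_id = c(lncs, genes)),
      data.table::data.table(mirna_id = "mirX", target_id = c("l1", "m2")))))
  g <- build_cerna(x$lnc_ids, x$expr, x$de, x$apc, x$dup, x$prec, x$targets)
  hubs <- score_hubs(g)
  expect_equal(hubs$mirna_id[1], "hub")
  expect_equal(hubs$score[1], 6L)        # 2 x 3 bridged pairs
  expect_equal(hubs[mirna_id == "mirX", score], 1L)
  # sum of hub scores = miRNA-bridged pairs counted with multiplicity
  expect_equal(sum(hubs$score), 7L)
  # miRNA with only mRNA edges scores 0 (and is not even admitted)
  expect_false(any(hubs$n_lnc == 0 & hubs$score > 0))
  # degree mode
  expect_equal(score_hubs(g, mode = "degree")[mirna_id == "hub", score], 5L)
})

test_that("network equals the relational-join oracle on synthetic runs", {
  sim <- simulate_dataset(sim_config(seed = 61))
  flt <- apply_filter_cascade(sim$ann, NULL, sim$expr, sim$seqs,
    filter_config(evidence_ids = sim$evidence$transcript_id))
  apc <- find_apc_genes(sim$ann, flt$retained)
  de <- call_de(sim$expr)
  coding <- sim$ann$transcripts[sim$ann$transcripts$biotype == "coding", ]
  de_gene <- merge(de, coding[, c("transcript_id", "gene_id")],
                   by = "transcript_id")
  de_gene$transcript_id <- de_gene$gene_id
  prec <- match_precursors(sim$seqs[flt$retained], sim$hairpins)
  dup <- data.table::data.table(lnc_id = character(), mrna_id = character(),
                                score = numeric())
  tgt <- sim$targets
  g <- build_cerna(flt$retained, sim$expr, de_gene, apc, dup, prec, tgt)
  o <- oracle_cerna(flt$retained, sim$expr, de_gene, apc, dup, prec, tgt)
  expect_identical(g$nodes[g$nodes$node_type == "lncRNA", node_id], o$lnc)
  expect_identical(g$nodes[g$nodes$node_type == "miRNA", node_id], o$mir)
  expect_identical(g$nodes[g$nodes$node_type == "mRNA", node_id], o$mrna)
  expect_equal(as.data.frame(g$edges), o$edges)

  # planted ceRNA triples all appear as bridged pairs; planted hub is first
  hubs <- score_hubs(g)
  bridged <- function(m) {
    e <- g$edges
    nb <- unique(c(e$to[e$from == m], e$from[e$to == m]))
    list(l = intersect(nb, g$nodes[g$nodes$node_type == "lncRNA", node_id]),
         g = intersect(nb, g$nodes[g$nodes$node_type == "mRNA", node_id]))
  }
  for (tr in sim$truth$triples) {
    b <- bridged(tr$mirna)
    expect_true(tr$lncrna %in% b$l && tr$mrna %in% b$g,
                info = tr$mirna)
  }
  expect_equal(hubs$mirna_id[1], sim$truth$hub$mirna)

  # removing a miRNA removes exactly its incident edges
  m <- hubs$mirna_id[1]
  e_before <- nrow(g$edges)
  incident <- sum(g$edges$from == m | g$edges$to == m)
  g2 <- g
  g2$edges <- g$edges[!(g$edges$from == m | g$edges$to == m), ]
  expect_equal(nrow(g2$edges), e_before - incident)
  h2 <- score_hubs(structure(list(
    nodes = g$nodes[g$nodes$node_id != m, ], edges = g2$edges,
    skipped_targets = 0L), class = "cerna_graph"))
  expect_equal(sum(h2$score), sum(hubs$score) - hubs$score[1])
})

test_that("igraph conversion keeps node and edge counts", {
  x <- mk_net_inputs()
  g <- build_cerna(x$lnc_ids, x$expr, x$de, x$apc, x$dup, x$prec, x$targets)
  ig <- as_igraph(g)
  expect_equal(igraph::vcount(ig), nrow(g$nodes))
  expect_equal(igraph::ecount(ig), nrow(g$edges))
})
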