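test_that("worked examples for the five classes", {
  rows <- list(
    # coding gene, 2 exons [100,250) and [300,900), plus strand
    tx_exons("c1", "+", "t1", "gA", c(100, 300), c(250, 900)),
    # sense: lnc exon [150,200) overlaps coding exon on same strand
    tx_exons("c1", "+", "l_sense", "g:ls", c(150, 260), c(200, 290),
             biotype = "candidate_noncoding"),
    # antisense: same interval, opposite strand
    tx_exons("c1", "-", "l_anti", "g:la", c(150, 260), c(200, 290),
             biotype = "candidate_noncoding"),
    # intronic: inside intron [250,300), minus strand, no exon overlap
    tx_exons("c1", "-", "l_intr", "g:li", 255, 295,
             biotype = "candidate_noncoding"),
    # bidirectional: divergent TSS 400 bp from gene gB's TSS
    tx_exons("c2", "+", "t2", "gB", c(5400, 6000), c(5800, 6400)),
    tx_exons("c2", "-", "l_bidi", "g:lb", c(4600, 4900), c(4800, 5001),
             biotype = "candidate_noncoding"),
    # intergenic: chromosome with no genes at all
    tx_exons("c3", "+", "l_inter", "g:lg", c(1000, 1500), c(1200, 1700),
             biotype = "candidate_noncoding"))
  ann <- annotation_from_exons(data.table::rbindlist(rows),
                               c(c1 = 10000, c2 = 10000, c3 = 10000))
  cl <- classify_lncrnas(ann, c("l_sense", "l_anti", "l_intr", "l_bidi",
                                "l_inter"))
  got <- setNames(cl$lnc_class, cl$transcript_id)
  expect_equal(got[["l_sense"]], "sense")
  expect_equal(got[["l_anti"]], "antisense")
  expect_equal(got[["l_intr"]], "intronic")
  expect_equal(got[["l_bidi"]], "bidirectional")  # TSS 5000 vs 5400, 400 bp
  expect_equal(got[["l_inter"]], "intergenic")
  ev <- setNames(cl$evidence_gene_id, cl$transcript_id)
  expect_equal(unname(ev[c("l_sense", "l_anti", "l_intr", "l_bidi")]),
               c("gA", "gA", "gA", "gB"))
  expect_true(is.na(ev[["l_inter"]]))
  # evidence gene present iff class != intergenic
  expect_identical(is.na(cl$evidence_gene_id), cl$lnc_class == "intergenic")
})

test_that("bidirectional window boundary and convergent orientation", {
  mk <- function(lnc_end) {
    rows <- list(
      tx_exons("c1", "+", "t1", "gA", c(5400, 6000), c(5800, 6400)),
      tx_exons("c1", "-", "lnc", "g:l", c(3000, lnc_end - 100),
               c(3200, lnc_end), biotype = "candidate_noncoding"))
    annotation_from_exons(data.table::rbindlist(rows), c(c1 = 20000))
  }
  # TSS distance = 5400 - (lnc_end - 1); window 1000 is strict
  near <- classify_lncrnas(mk(4500), "lnc")   # distance 901
  expect_equal(near$lnc_class, "bidirectional")
  far <- classify_lncrnas(mk(4401), "lnc")    # distance exactly 1000
  expect_equal(far$lnc_class, "intergenic")
  # same geometry but lnc on + strand: convergent, not bidirectional
  rows <- list(
    tx_exons("c1", "+", "t1", "gA", c(5400, 6000), c(5800, 6400)),
    tx_exons("c1", "+", "lnc", "g:l", c(4300, 4400), c(4380, 4500),
             biotype = "candidate_noncoding"))
  ann <- annotation_from_exons(data.table::rbindlist(rows), c(c1 = 20000))
  expect_equal(classify_lncrnas(ann, "lnc")$lnc_class, "intergenic")
})

test_that("every lncRNA gets exactly one class; planted recovery is 100%", {
  sim <- simulate_dataset(sim_config(seed = 31))
  ids <- sim$truth$retained
  cl <- classify_lncrnas(sim$ann, ids)
  expect_equal(nrow(cl), length(ids))
  expect_true(all(cl$lnc_class %in% c("sense", "antisense", "intronic",
                                      "bidirectional", "intergenic")))
  truth <- unlist(sim$truth$classes)
  got <- setNames(cl$lnc_class, cl$transcript_id)
  expect_equal(got[names(truth)], truth)
})

test_that("strand flip swaps sense/antisense, fixes intronic/intergenic", {
  sim <- simulate_dataset(sim_config(seed = 32))
  ids <- sim$truth$retained
  before <- classify_lncrnas(sim$ann, ids)
  after <- classify_lncrnas(flip_lnc_strands(sim$ann), ids)
  b <- setNames(before$lnc_class, before$transcript_id)
  a <- setNames(after$lnc_class, after$transcript_id)
  expect_equal(unname(a[names(b)[b == "sense"]]),
               rep("antisense", sum(b == "sense")))
  expect_equal(unname(a[names(b)[b == "antisense"]]),
               rep("sense", sum(b == "antisense")))
  expect_equal(a[names(b)[b == "intronic"]], b[b == "intronic"])
  expect_equal(a[names(b)[b == "intergenic"]], b[b == "intergenic"])
})

test_that("classification equals the exhaustive oracle on random annotations", {
  set.seed(77)
  for (rep in 1:6) {
    ann <- rand_annotation(n_genes = sample(5:40, 1), n_lnc = 15,
                           chrom_len = 60000L)
    ids <- ann$transcripts$transcript_id[ann$transcripts$biotype != "coding"]
    cl <- classify_lncrnas(ann, ids)
    for (i in seq_along(ids)) {
      o <- oracle_classify(ann, ids[i])
      expect_equal(cl$lnc_class[i], o$class, info = paste(rep, ids[i]))
      if (!is.na(cl$evidence_gene_id[i]) && o$class != "bidirectional")
        expect_equal(cl$evidence_gene_id[i], o$gene,
                     info = paste(rep, ids[i]))
    }
  }
})

test_that("apcGene worked examples and boundaries", {
  mk <- function(gap) {
    rows <- list(
      tx_exons("c1", "+", "t1", "gA", 500, 1000),
      tx_exons("c1", "+", "lnc", "g:l", c(1000 + gap, 1000 + gap + 600),
               c(1000 + gap + 500, 1000 + gap + 1000),
               biotype = "candidate_noncoding"))
    annotation_from_exons(data.table::rbindlist(rows), c(c1 = 50000))
  }
  # gene ends at 1000 (+), lnc (+) starts 4000 later: upstream link, gap 4000
  l <- find_apc_genes(mk(4000), "lnc")
  expect_equal(nrow(l), 1L)
  expect_equal(l$side, "upstream")
  expect_equal(l$gap_bp, 4000)
  # inclusive at exactly 10000, excluded at 10001
  expect_equal(find_apc_genes(mk(10000), "lnc")$gap_bp, 10000)
  expect_equal(nrow(find_apc_genes(mk(10001), "lnc")), 0L)
  # minus-strand lncRNA: the left-hand gene is its downstream neighbor
  rows <- list(
    tx_exons("c1", "+", "t1", "gA", 500, 1000),
    tx_exons("c1", "-", "lnc", "g:l", c(5000, 5600), c(5500, 6000),
             biotype = "candidate_noncoding"))
  ann <- annotation_from_exons(data.table::rbindlist(rows), c(c1 = 50000))
  l2 <- find_apc_genes(ann, "lnc")
  expect_equal(l2$side, "downstream")
  # overlapping gene is never an apcGene
  rows <- list(
    tx_exons("c1", "+", "t1", "gA", 500, 6000),
    tx_exons("c1", "-", "lnc", "g:l", c(5000, 5600), c(5500, 6100),
             biotype = "candidate_noncoding"))
  ann <- annotation_from_exons(data.table::rbindlist(rows), c(c1 = 50000))
  expect_equal(nrow(find_apc_genes(ann, "lnc")), 0L)
})

test_that("apcGene search equals brute-force scan on random layouts", {
  set.seed(88)
  for (rep in 1:40) {
    ann <- rand_annotation(n_genes = sample(3:20, 1), n_lnc = 5,
                           chrom_len = 80000L)
    ids <- ann$transcripts$transcript_id[ann$transcripts$biotype != "coding"]
    links <- find_apc_genes(ann, ids)
    for (id in ids) {
      got <- as.data.frame(links[links$transcript_id == id, ])
      got <- got[order(got$side), ]
      rownames(got) <- NULL
      exp <- oracle_apc(ann, id)
      if (is.null(exp)) {
        expect_equal(nrow(got), 0L, info = paste(rep, id))
      } else {
        exp <- exp[order(exp$side), ]
        rownames(exp) <- NULL
        expect_equal(got, exp, info = paste(rep, id))
      }
    }
  }
})
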