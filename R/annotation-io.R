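#' Genomic annotation container
#'
#' The shared data model for the pipeline. All internal coordinates are
#' 0-based half-open `[start, end)`; GTF (1-based inclusive) and BED (0-based
#' half-open) conventions are converted only at I/O boundaries. Strand is
#' always `+` or `-`: unstranded records never enter the pipeline.
#'
#' An annotation bundles:
#' \describe{
#'   \item{exons}{data.table: `chrom, start, end, strand, transcript_id,
#'     gene_id, biotype`, sorted by transcript then start.}
#'   \item{transcripts}{one row per transcript: span, exon count, spliced
#'     length, biotype (`coding`, `candidate_noncoding` or `known_lncRNA`).}
#'   \item{genes}{one row per gene: span union over its transcripts and the
#'     strand-aware TSS (5' end).}
#'   \item{scaffold_lengths}{named integer vector, chrom -> length (bp).}
#'   \item{gene_gr, exon_gr}{GenomicRanges interval indices used for window /
#'     stabbing queries; results are checked against a brute-force scan in the
#'     test suite.}
#' }
#'
#' @param exons data.table of exon records in internal coordinates.
#' @param scaffold_lengths named vector of scaffold lengths (bp).
#' @param n_rejected_unstranded number of strand-"." records dropped upstream.
#' @return object of class `lnc_annotation`.
#' @export
annotation_from_exons <- function(exons, scaffold_lengths,
                                  n_rejected_unstranded = 0L) {
  exons <- as.data.table(exons)
  need <- c("chrom", "start", "end", "strand", "transcript_id", "gene_id")
  miss <- setdiff(need, names(exons))
  assert_that(length(miss) == 0, "exon table missing columns: %s",
              paste(miss, collapse = ", "))
  if (is.null(exons$biotype)) exons[, biotype := "coding"]
  assert_that(all(exons$strand %in% c("+", "-")),
              "exon strand must be '+' or '-'")
  assert_that(all(exons$start >= 0 & exons$start < exons$end),
              "exon coordinates must satisfy 0 <= start < end")
  assert_that(all(exons$biotype %in%
                  c("coding", "candidate_noncoding", "known_lncRNA")),
              "unknown biotype value")
  scaffold_lengths <- setNames(as.integer(scaffold_lengths),
                               names(scaffold_lengths))
  unknown <- setdiff(unique(exons$chrom), names(scaffold_lengths))
  assert_that(length(unknown) == 0, "exon on unknown scaffold: %s",
              paste(unknown, collapse = ", "))
  setorder(exons, transcript_id, start)

  # per-transcript consistency: one chrom/strand/gene, disjoint sorted exons
  tx <- exons[, {
    assert_that(data.table::uniqueN(chrom) == 1L &&
                data.table::uniqueN(strand) == 1L &&
                data.table::uniqueN(gene_id) == 1L,
                "transcript %s spans multiple chrom/strand/gene", .BY[[1]])
    if (.N > 1L) assert_that(all(start[-1L] >= end[-.N]),
                             "transcript %s has overlapping exons", .BY[[1]])
    .(gene_id = gene_id[1L], chrom = chrom[1L], strand = strand[1L],
      start = min(start), end = max(end), n_exons = .N,
      length_bp = sum(end - start), biotype = biotype[1L])
  }, by = transcript_id]
  over <- tx[end > scaffold_lengths[chrom]]
  assert_that(nrow(over) == 0, "transcript %s exceeds scaffold length",
              paste(head(over$transcript_id, 3), collapse = ", "))

  genes <- tx[, .(chrom = chrom[1L], strand = strand[1L],
                  start = min(start), end = max(end),
                  biotype = if (any(biotype == "coding")) "coding"
                            else biotype[1L]),
              by = gene_id]
  genes[, tss := ifelse(strand == "+", start, end - 1L)]

  ann <- structure(list(
    exons = exons, transcripts = tx, genes = genes,
    scaffold_lengths = scaffold_lengths,
    n_rejected_unstranded = as.integer(n_rejected_unstranded),
    gene_gr = gr_from_dt(genes, id_col = "gene_id"),
    exon_gr = gr_from_dt(exons, id_col = "transcript_id")
  ), class = "lnc_annotation")
  ann
}

# internal 0-based half-open -> GRanges (1-based inclusive)
gr_from_dt <- function(dt, id_col) {
  gr <- GenomicRanges::GRanges(
    seqnames = dt$chrom,
    ranges = IRanges::IRanges(start = dt$start + 1L, end = dt$end),
    strand = dt$strand)
  S4Vectors::mcols(gr)$id <- dt[[id_col]]
  if (!is.null(dt$gene_id)) S4Vectors::mcols(gr)$gene_id <- dt$gene_id
  if (!is.null(dt$biotype)) S4Vectors::mcols(gr)$biotype <- dt$biotype
  gr
}

#' @export
print.lnc_annotation <- function(x, ...) {
  cat(sprintf(
    "lnc_annotation: %d scaffolds, %d genes, %d transcripts (%d coding / %d candidate / %d known lncRNA)\n",
    length(x$scaffold_lengths), nrow(x$genes), nrow(x$transcripts),
    sum(x$transcripts$biotype == "coding"),
    sum(x$transcripts$biotype == "candidate_noncoding"),
    sum(x$transcripts$biotype == "known_lncRNA")))
  invisible(x)
}

#' Read scaffold lengths
#'
#' Accepts a two-column TSV (`chrom`, `length`) with or without header, or a
#' FASTA index (`.fai`) whose first two columns carry the same information.
#'
#' @param path file path.
#' @return named integer vector.
#' @export
read_scaffold_lengths <- function(path) {
  dt <- fread(path, sep = "\t", header = FALSE)
  if (identical(tolower(as.character(dt[1, 2][[1]])), "length")) dt <- dt[-1]
  setNames(as.integer(dt[[2]]), as.character(dt[[1]]))
}

#' Parse a GTF file into an annotation
#'
#' Reads exon features only. Required attributes: `transcript_id` and
#' `gene_id`; the optional `transcript_biotype` attribute (one of `coding`,
#' `candidate_noncoding`, `known_lncRNA`) defaults to `coding`. GTF 1-based
#' inclusive coordinates become internal 0-based half-open. Records with
#' strand `"."` are rejected with a warning and counted in
#' `$n_rejected_unstranded`; a missing required attribute or an unknown
#' scaffold is an error naming the offending line.
#'
#' @param path GTF file.
#' @param scaffold_lengths named vector (see [read_scaffold_lengths()]).
#' @return an `lnc_annotation`.
#' @export
read_gtf <- function(path, scaffold_lengths) {
  assert_that(file.exists(path), "GTF not found: %s", path)
  raw <- readLines(path)
  keep <- !startsWith(raw, "#") & nzchar(raw)
  lineno <- which(keep)
  raw <- raw[keep]
  if (length(raw) == 0)
    return(annotation_from_exons(
      data.table(chrom = character(), start = integer(), end = integer(),
                 strand = character(), transcript_id = character(),
                 gene_id = character(), biotype = character()),
      scaffold_lengths))
  f <- data.table::tstrsplit(raw, "\t", fixed = TRUE)
  assert_that(length(f) >= 9, "GTF has fewer than 9 tab-separated fields")
  feat <- f[[3]]
  sel <- feat == "exon"
  if (!any(sel))
    stop2("GTF contains no exon features")
  attr_field <- f[[9]][sel]
  get_attr <- function(name) {
    m <- regmatches(attr_field,
                    regexpr(sprintf('%s "[^"]*"', name), attr_field))
    out <- rep(NA_character_, length(attr_field))
    hit <- grepl(sprintf('%s "', name), attr_field, fixed = TRUE)
    out[hit] <- sub(sprintf('^%s "([^"]*)"$', name), "\\1", m)
    out
  }
  tx_id <- get_attr("transcript_id")
  g_id <- get_attr("gene_id")
  bt <- get_attr("transcript_biotype")
  ln <- lineno[sel]
  bad <- which(is.na(tx_id) | is.na(g_id))
  assert_that(length(bad) == 0,
              "GTF line %d: missing required attribute transcript_id/gene_id",
              if (length(bad)) ln[bad[1]] else 0L)
  strand <- f[[7]][sel]
  unstranded <- strand == "."
  if (any(unstranded))
    warning(sprintf("rejected %d unstranded exon record(s) (strand '.')",
                    sum(unstranded)), call. = FALSE)
  dropped_tx <- unique(tx_id[unstranded])
  keep2 <- !(tx_id %in% dropped_tx)  # drop whole transcript, not single exon
  exons <- data.table(
    chrom = f[[1]][sel][keep2],
    start = as.integer(f[[4]][sel][keep2]) - 1L,   # GTF 1-based -> internal
    end = as.integer(f[[5]][sel][keep2]),
    strand = strand[keep2],
    transcript_id = tx_id[keep2],
    gene_id = g_id[keep2],
    biotype = data.table::fifelse(is.na(bt[keep2]), "coding", bt[keep2]))
  unknown <- setdiff(unique(exons$chrom), names(scaffold_lengths))
  if (length(unknown))
    stop2("GTF line %d: exon on unknown scaffold '%s'",
          ln[keep2][match(unknown[1], exons$chrom)], unknown[1])
  annotation_from_exons(exons, scaffold_lengths,
                        n_rejected_unstranded = length(dropped_tx))
}

#' Write an annotation (or exon table) as GTF
#'
#' Internal 0-based half-open exons are emitted as GTF 1-based inclusive
#' `exon` features with `transcript_id`, `gene_id` and `transcript_biotype`
#' attributes. Round-trips through [read_gtf()] losslessly.
#'
#' @param ann `lnc_annotation` or an exon data.table.
#' @param path output path.
#' @param source value for the GTF source column.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(ann, path, source = "lncflow") {
  exons <- if (inherits(ann, "lnc_annotation")) ann$exons else as.data.table(ann)
  lines <- sprintf(
    '%s\t%s\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s"; transcript_biotype "%s";',
    exons$chrom, source, exons$start + 1L, exons$end, exons$strand,
    exons$gene_id, exons$transcript_id, exons$biotype)
  writeLines(lines, path)
  invisible(path)
}

#' Write classified lncRNAs as BED6
#'
#' One line per transcript span; name field is `transcript_id|class`,
#' score 0, strand preserved. BED is 0-based half-open, matching the internal
#' convention, so coordinates pass through unchanged.
#'
#' @param classified data.table from [classify_lncrnas()].
#' @param ann `lnc_annotation` supplying transcript spans.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(classified, ann, path) {
  cl <- as.data.table(classified)
  if (nrow(cl) == 0) { writeLines(character(), path); return(invisible(path)) }
  tx <- ann$transcripts[match(cl$transcript_id, transcript_id)]
  lines <- sprintf("%s\t%d\t%d\t%s|%s\t0\t%s",
                   tx$chrom, tx$start, tx$end,
                   cl$transcript_id, cl$lnc_class, tx$strand)
  writeLines(lines, path)
  invisible(path)
}

#' Read an expression table
#'
#' TSV with header `transcript_id, library, read_count, fpkm, coverage`; one
#' row per transcript per library. Invariants checked: read counts are
#' non-negative integers, FPKM non-negative, coverage in `[0, 1]`, and
#' `fpkm == 0` implies `read_count == 0`.
#'
#' @param path TSV path.
#' @param libraries required library set (default `E`, `P`, `L`).
#' @return data.table.
#' @export
read_expression <- function(path, libraries = c("E", "P", "L")) {
  expr <- read_tsv(path)
  validate_expression(expr, libraries = libraries)
}

#' @rdname read_expression
#' @param expr in-memory expression table.
#' @export
validate_expression <- function(expr, libraries = c("E", "P", "L")) {
  expr <- as.data.table(expr)
  need <- c("transcript_id", "library", "read_count", "fpkm", "coverage")
  miss <- setdiff(need, names(expr))
  assert_that(length(miss) == 0, "expression table missing columns: %s",
              paste(miss, collapse = ", "))
  assert_that(all(expr$library %in% libraries), "unknown library label")
  cnt <- expr[, .N, by = transcript_id]
  assert_that(all(cnt$N == length(libraries)),
              "every transcript needs one row per library")
  assert_that(all(expr$read_count >= 0 & expr$read_count == round(expr$read_count)),
              "read_count must be a non-negative integer")
  assert_that(all(expr$fpkm >= 0), "fpkm must be non-negative")
  assert_that(all(expr$coverage >= 0 & expr$coverage <= 1),
              "coverage must lie in [0, 1]")
  assert_that(all(expr$read_count[expr$fpkm == 0] == 0),
              "fpkm == 0 requires read_count == 0")
  expr
}

#' Read / write FASTA sequence sets
#'
#' A sequence set is a named uppercase character vector over `{A,C,G,T,N}`
#' with unique ids; the id is the first whitespace-delimited header token
#' (miRBase-style headers accepted). Backed by Biostrings.
#'
#' @param path FASTA path.
#' @return named character vector.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  assert_that(!anyDuplicated(ids), "duplicate FASTA ids in %s", path)
  setNames(toupper(as.character(ss)), ids)
}

#' @rdname read_fasta
#' @param seqs named character vector.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  ss <- Biostrings::DNAStringSet(unname(seqs))
  names(ss) <- names(seqs)
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

#' Window query against the gene interval index
#'
#' Returns ids of genes whose span overlaps `[start, end)` on `chrom` by at
#' least 1 bp, optionally restricted to one strand. Equivalent (and tested
#' equal) to a brute-force linear scan of the gene table.
#'
#' @param ann `lnc_annotation`.
#' @param chrom scaffold id.
#' @param start,end window, 0-based half-open.
#' @param strand optional `"+"` or `"-"`.
#' @return character vector of gene ids, sorted.
#' @export
query_genes <- function(ann, chrom, start, end, strand = NULL) {
  q <- GenomicRanges::GRanges(chrom,
         IRanges::IRanges(start + 1L, end),
         strand = strand %||% "*")
  hits <- GenomicRanges::findOverlaps(q, ann$gene_gr,
            ignore.strand = is.null(strand))
  sort(unique(S4Vectors::mcols(ann$gene_gr)$id[S4Vectors::subjectHits(hits)]))
}

#' Spliced transcript sequences from a genome
#'
#' Derives each transcript's sequence by concatenating exon slices of the
#' scaffold sequence (reverse-complemented for minus-strand transcripts).
#' Sequence length equals the summed exon length.
#'
#' @param ann `lnc_annotation`.
#' @param genome named character vector of scaffold sequences.
#' @param ids transcripts to extract (default all).
#' @return named character vector.
#' @export
transcript_sequences <- function(ann, genome, ids = NULL) {
  ids <- ids %||% ann$transcripts$transcript_id
  ex <- ann$exons[transcript_id %in% ids]
  out <- ex[, {
    s <- paste0(substring(genome[[chrom[1L]]], start + 1L, end), collapse = "")
    if (strand[1L] == "-") s <- revcomp(s)
    .(seq = s)
  }, by = transcript_id]
  setNames(out$seq, out$transcript_id)[ids]
}

#' Reverse complement of a DNA string
#' @param s nucleotide string over `{A,C,G,T,N}`.
#' @return reverse complement.
#' @export
revcomp <- function(s) {
  # byte-level reverse + complement; much faster than round-tripping through
  # a DNAString for the short sequences this pipeline handles
  intToUtf8(rev(utf8ToInt(chartr("ACGTNacgtn", "TGCANtgcan", s))))
}
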