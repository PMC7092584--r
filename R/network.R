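#' Assemble the lncRNA--miRNA--mRNA (ceRNA) network
#'
#' Builds the typed tri-partite graph from the pipeline's evidence layers:
#' \itemize{
#'   \item \strong{lncRNA nodes}: maximum read count over libraries strictly
#'     greater than `min_reads` (the published screen "read number greater
#'     than 10") \emph{and} at least one apcGene or antisense (duplex) link;
#'   \item \strong{miRNA nodes}: miRNAs from the target table or precursor
#'     hits that have a lncRNA-side connection to an admitted lncRNA (sponge
#'     targeting or hosted precursor);
#'   \item \strong{mRNA nodes}: differentially expressed in at least one
#'     contrast \emph{and} linked -- apc/antisense to an admitted lncRNA or
#'     targeted by an admitted miRNA.
#' }
#' Edge types: `mirna_targets_lncrna`, `mirna_targets_mrna`,
#' `lncrna_precursor_of_mirna`, `apc`, `antisense`. Target rows referencing
#' an id that resolves to neither an mRNA gene nor a lncRNA are skipped with
#' a warning and counted in the `skipped_targets` attribute.
#'
#' @param lnc_ids candidate lncRNA ids (typically the retained set).
#' @param expr expression table (read counts per library).
#' @param de [call_de()] result for the mRNA/gene side; `transcript_id` here
#'   is matched against gene ids.
#' @param apc_links [find_apc_genes()] result (`transcript_id`, `gene_id`).
#' @param duplex_hits antisense links (`lnc_id`, `mrna_id`), e.g. from
#'   [duplex_screen()] with transcript ids mapped to gene ids.
#' @param precursors [match_precursors()] result; hairpin ids are used as the
#'   miRNA node ids.
#' @param targets miRNA target table (`mirna_id`, `target_id`).
#' @param min_reads strict lower bound on the per-library maximum read count.
#' @return object of class `cerna_graph`: list with `nodes` (data.table
#'   `node_id, node_type, de, max_reads`) and `edges` (data.table
#'   `from, to, edge_type`).
#' @export
build_cerna <- function(lnc_ids, expr, de, apc_links, duplex_hits,
                        precursors, targets, min_reads = 10) {
  expr <- as.data.table(expr)
  de <- as.data.table(de)
  apc_links <- as.data.table(apc_links)
  duplex_hits <- as.data.table(duplex_hits)
  precursors <- as.data.table(precursors)
  targets <- as.data.table(targets)

  de_genes <- unique(de[call != "ns", transcript_id])
  mrna_universe <- unique(c(de$transcript_id, apc_links$gene_id,
                            duplex_hits$mrna_id))

  # (1) admitted lncRNAs: expression screen + >=1 apc or antisense link
  reads <- if (length(lnc_ids))
    expr[transcript_id %in% lnc_ids,
         .(max_reads = max(read_count)), by = transcript_id]
  else data.table(transcript_id = character(), max_reads = numeric())
  linked <- unique(c(apc_links$transcript_id, duplex_hits$lnc_id))
  lnc_ok <- reads[max_reads > min_reads & transcript_id %in% linked,
                  transcript_id]

  # (2) target rows split by what the target id resolves to
  t_lnc <- targets[target_id %in% lnc_ids]
  t_mrna <- targets[target_id %in% mrna_universe]
  unknown <- targets[!target_id %in% c(lnc_ids, mrna_universe)]
  if (nrow(unknown) > 0)
    warning(sprintf("skipped %d target row(s) with unresolvable target id",
                    nrow(unknown)), call. = FALSE)

  # (3) admitted miRNAs: a lncRNA-side edge to an admitted lncRNA
  mir_sponge <- unique(t_lnc[target_id %in% lnc_ok, mirna_id])
  mir_prec <- unique(precursors[lnc_id %in% lnc_ok, hairpin_id])
  mir_ok <- sort(unique(c(mir_sponge, mir_prec)))

  # (4) admitted mRNAs: DE and linked
  mrna_apc <- apc_links[transcript_id %in% lnc_ok, gene_id]
  mrna_anti <- duplex_hits[lnc_id %in% lnc_ok, mrna_id]
  mrna_tgt <- t_mrna[mirna_id %in% mir_ok, target_id]
  mrna_ok <- sort(intersect(de_genes,
                            unique(c(mrna_apc, mrna_anti, mrna_tgt))))

  edges <- rbindlist(list(
    t_lnc[target_id %in% lnc_ok & mirna_id %in% mir_ok,
          .(from = mirna_id, to = target_id,
            edge_type = "mirna_targets_lncrna")],
    t_mrna[target_id %in% mrna_ok & mirna_id %in% mir_ok,
           .(from = mirna_id, to = target_id,
             edge_type = "mirna_targets_mrna")],
    precursors[lnc_id %in% lnc_ok & hairpin_id %in% mir_ok,
               .(from = lnc_id, to = hairpin_id,
                 edge_type = "lncrna_precursor_of_mirna")],
    apc_links[transcript_id %in% lnc_ok & gene_id %in% mrna_ok,
              .(from = transcript_id, to = gene_id, edge_type = "apc")],
    duplex_hits[lnc_id %in% lnc_ok & mrna_id %in% mrna_ok,
                .(from = lnc_id, to = mrna_id, edge_type = "antisense")]))
  edges <- unique(edges)
  edges <- edges[from != to]
  # drop miRNAs left with no edge at all (possible when their only admitted
  # lncRNA link was removed as a duplicate self-loop -- defensive, rare)
  mir_ok <- intersect(mir_ok, unique(c(edges$from, edges$to)))

  nodes <- rbindlist(list(
    data.table(node_id = sort(unique(lnc_ok)), node_type = "lncRNA"),
    data.table(node_id = mir_ok, node_type = "miRNA"),
    data.table(node_id = mrna_ok, node_type = "mRNA")))
  nodes <- merge(nodes, reads, by.x = "node_id", by.y = "transcript_id",
                 all.x = TRUE)
  nodes[, de := node_id %in% de_genes |
          node_id %in% unique(de[call != "ns", transcript_id])]
  setorder(nodes, node_type, node_id)
  setorder(edges, edge_type, from, to)

  structure(list(nodes = nodes[], edges = edges[],
                 skipped_targets = nrow(unknown)),
            class = "cerna_graph")
}

#' @export
print.cerna_graph <- function(x, ...) {
  tv <- table(x$nodes$node_type)
  cat(sprintf("cerna_graph: %d nodes (%s), %d edges\n",
              nrow(x$nodes),
              paste(sprintf("%s=%d", names(tv), tv), collapse = ", "),
              nrow(x$edges)))
  invisible(x)
}

#' Convert a ceRNA graph to igraph
#' @param g a `cerna_graph`.
#' @return an [igraph::graph_from_data_frame()] object (undirected).
#' @export
as_igraph <- function(g) {
  igraph::graph_from_data_frame(
    g$edges, directed = FALSE,
    vertices = as.data.frame(g$nodes))
}

#' Score miRNA hubs by bridged (lncRNA, mRNA) pairs
#'
#' A miRNA's hub score is the number of distinct (lncRNA, mRNA) pairs it
#' bridges: (number of lncRNA neighbors) x (number of mRNA neighbors), any
#' connecting edge type counting as a neighbor link. With `mode =
#' "degree"` the score is instead the miRNA's total degree. The full ranking
#' is returned in descending score order, ties broken by miRNA id.
#'
#' @param g a `cerna_graph`.
#' @param mode `"bridged_pairs"` (default) or `"degree"`.
#' @return data.table: `mirna_id, n_lnc, n_mrna, score`, sorted.
#' @export
score_hubs <- function(g, mode = c("bridged_pairs", "degree")) {
  mode <- match.arg(mode)
  mirs <- g$nodes[node_type == "miRNA", node_id]
  type_of <- setNames(g$nodes$node_type, g$nodes$node_id)
  # neighbor sets irrespective of edge direction as stored
  e <- rbind(g$edges[, .(a = from, b = to)], g$edges[, .(a = to, b = from)])
  out <- rbindlist(lapply(mirs, function(m) {
    nb <- unique(e[a == m, b])
    nl <- sum(type_of[nb] == "lncRNA")
    nm <- sum(type_of[nb] == "mRNA")
    data.table(mirna_id = m, n_lnc = nl, n_mrna = nm,
               score = if (mode == "degree") length(nb) else nl * nm)
  }))
  if (nrow(out) == 0L)
    return(data.table(mirna_id = character(), n_lnc = integer(),
                      n_mrna = integer(), score = integer()))
  setorder(out, -score, mirna_id)
  out[]
}

#' Write a ceRNA graph as node + edge TSV tables
#' @param g a `cerna_graph`.
#' @param node_path,edge_path output paths.
#' @return invisibly, the two paths.
#' @export
write_cerna <- function(g, node_path, edge_path) {
  write_tsv(g$nodes, node_path)
  write_tsv(g$edges, edge_path)
  invisible(c(node_path, edge_path))
}
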