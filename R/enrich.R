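#' Read a term-to-gene map
#'
#' Accepts a two-column TSV (`term_id`, `gene_id`, header optional) or
#' GMT-like lines (`term<TAB>description<TAB>gene1<TAB>gene2...`; detected by
#' rows with more than two fields).
#'
#' @param path file path.
#' @return data.table with columns `term_id`, `gene_id`.
#' @export
read_term_map <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (max(lengths(parts)) > 2L) {            # GMT-like
    out <- rbindlist(lapply(parts, function(p)
      data.table(term_id = p[1], gene_id = p[-(1:2)])))
  } else {
    out <- rbindlist(lapply(parts, function(p)
      data.table(term_id = p[1], gene_id = p[2])))
    if (identical(tolower(out$gene_id[1]), "gene_id")) out <- out[-1]
  }
  unique(out)[]
}

#' Hypergeometric term enrichment
#'
#' One-sided upper-tail hypergeometric test per term:
#' `p = P(X >= k)` for `k` study genes among the term's `K` annotated genes,
#' drawing `n` from a population of `N`. P-values are BH-adjusted across the
#' tested terms; the `significant` flag follows the published criterion of
#' raw `p <= 0.05` (the q-value column is reported alongside). Terms with no
#' annotated population gene are skipped.
#'
#' @param study gene set of interest (must be a subset of `population`).
#' @param population background gene set.
#' @param terms term map (data.table `term_id`, `gene_id`, see
#'   [read_term_map()]).
#' @param alpha significance threshold on the raw p-value.
#' @return data.table: `term_id, k, K, n, N, pvalue, qvalue, significant`,
#'   ordered by p-value.
#' @export
enrich <- function(study, population, terms, alpha = 0.05) {
  study <- unique(as.character(study))
  population <- unique(as.character(population))
  assert_that(length(population) > 0, "empty population")
  off <- setdiff(study, population)
  assert_that(length(off) == 0, "study genes absent from population: %s",
              paste(head(off, 5), collapse = ", "))
  terms <- as.data.table(terms)[gene_id %in% population]
  Nn <- length(population); nn <- length(study)
  res <- terms[, {
    Kk <- data.table::uniqueN(gene_id)
    kk <- sum(unique(gene_id) %in% study)
    .(k = kk, K = Kk, n = nn, N = Nn,
      pvalue = phyper(kk - 1, Kk, Nn - Kk, nn, lower.tail = FALSE))
  }, by = term_id]
  if (nrow(res) == 0L)
    return(data.table(term_id = character(), k = integer(), K = integer(),
                      n = integer(), N = integer(), pvalue = numeric(),
                      qvalue = numeric(), significant = logical()))
  res[, qvalue := bh_adjust(pvalue)]
  res[, significant := pvalue <= alpha]
  setorder(res, pvalue, term_id)
  res[]
}
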