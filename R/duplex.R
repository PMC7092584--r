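#' Duplex scoring parameters
#'
#' Pair scores for the complementarity alignment that stands in for a
#' thermodynamic duplex predictor: a defined, reproducible local alignment of
#' sequence `a` against the reverse complement of `b`, scoring G:C `+3`,
#' A:T `+2`, G:U wobble `+1`, mismatch `-2`, affine gaps `-3` open /
#' `-1` extend. A hit is reported when the best local score reaches
#' `threshold`.
#'
#' @param gc,at,gu,mismatch pair scores.
#' @param gap_open,gap_extend non-negative gap costs.
#' @param threshold minimum reported score (default 40).
#' @return object of class `duplex_params`.
#' @export
duplex_params <- function(gc = 3, at = 2, gu = 1, mismatch = -2,
                          gap_open = 3, gap_extend = 1, threshold = 40) {
  structure(list(gc = gc, at = at, gu = gu, mismatch = mismatch,
                 gap_open = gap_open, gap_extend = gap_extend,
                 threshold = threshold), class = "duplex_params")
}

# pair-score matrix in (a, revcomp(b)) space, rows/cols A,C,G,T,N.
# After reverse-complementing b, a base pairing a_i:b_j appears as the
# column pair (a_i, comp(b_j)): G:C -> (G,G), C:G -> (C,C), A:T -> (A,A),
# T:A -> (T,T), wobble G:T -> (G,A), T:G -> (T,C). Anything with N scores
# as a mismatch.
duplex_score_matrix <- function(p) {
  m <- matrix(p$mismatch, 5, 5,
              dimnames = list(c("A", "C", "G", "T", "N"),
                              c("A", "C", "G", "T", "N")))
  m["G", "G"] <- p$gc; m["C", "C"] <- p$gc
  m["A", "A"] <- p$at; m["T", "T"] <- p$at
  m["G", "A"] <- p$gu; m["T", "C"] <- p$gu
  m
}

#' Score lncRNA--mRNA complementarity
#'
#' Local alignment of `a` against the reverse complement of `b` under
#' [duplex_params()]. Returns the best-scoring duplex segment, with the
#' paired region on each sequence in its own original coordinates (1-based
#' inclusive), or `NULL` when the best score is below the reporting
#' threshold. Ties break to the leftmost segment in `a`, then in `b`.
#' The pairing relation is symmetric, so `duplex_score(a, b)` and
#' `duplex_score(b, a)` agree in score (regions swap).
#'
#' @param a,b nucleotide strings (non-empty).
#' @param params a [duplex_params()].
#' @return list `(a_id-free) score, a_start, a_end, b_start, b_end` or `NULL`.
#' @export
duplex_score <- function(a, b, params = duplex_params()) {
  assert_that(nzchar(a) && nzchar(b), "duplex_score: empty input sequence")
  rcb <- revcomp(b)
  al <- .sw_align(toupper(a), rcb, duplex_score_matrix(params),
                  params$gap_open, params$gap_extend)
  if (al$score < params$threshold) return(NULL)
  nb <- nchar(b)
  list(score = al$score,
       a_start = al$a_start, a_end = al$a_end,
       # map revcomp(b) coordinates back onto b
       b_start = nb - al$b_end + 1L, b_end = nb - al$b_start + 1L)
}

#' Score many lncRNA/mRNA pairs
#'
#' @param pairs data.table/data.frame with columns `lnc_id`, `mrna_id`.
#' @param seqs named character vector covering all referenced ids.
#' @param params a [duplex_params()].
#' @return data.table of hits: `lnc_id, mrna_id, score, lnc_start, lnc_end,
#'   mrna_start, mrna_end` (zero rows when nothing clears the threshold).
#' @export
duplex_screen <- function(pairs, seqs, params = duplex_params()) {
  pairs <- as.data.table(pairs)
  out <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    l <- pairs$lnc_id[i]; m <- pairs$mrna_id[i]
    assert_that(l %in% names(seqs) && m %in% names(seqs),
                "duplex_screen: missing sequence for %s / %s", l, m)
    h <- duplex_score(seqs[[l]], seqs[[m]], params)
    if (!is.null(h))
      out[[i]] <- data.table(lnc_id = l, mrna_id = m, score = h$score,
                             lnc_start = h$a_start, lnc_end = h$a_end,
                             mrna_start = h$b_start, mrna_end = h$b_end)
  }
  res <- rbindlist(out)
  if (nrow(res) == 0L)
    res <- data.table(lnc_id = character(), mrna_id = character(),
                      score = numeric(), lnc_start = integer(),
                      lnc_end = integer(), mrna_start = integer(),
                      mrna_end = integer())
  res[]
}

#' Match lncRNAs to miRNA hairpin precursors
#'
#' Best local alignment (match `+1`, mismatch `-1`, gap `-2`) of each lncRNA
#' against each hairpin, in both the given orientation and the hairpin's
#' reverse complement (best of the two reported, orientation recorded).
#' `identity` is matches / alignment columns (gap columns included);
#' `coverage` is the fraction of hairpin positions inside the aligned
#' segment. A hit requires identity >= `min_identity` (default 0.90) and
#' coverage strictly > `min_coverage` (default 0.90), reading the published
#' screens "identity >= 90%" and "comparison coverage greater than 90%"
#' literally.
#'
#' @param lncs named character vector of lncRNA sequences.
#' @param hairpins named character vector of hairpin sequences (non-empty).
#' @param min_identity,min_coverage reporting thresholds.
#' @return data.table: `lnc_id, hairpin_id, identity, coverage, score,
#'   lnc_start, lnc_end, hairpin_start, hairpin_end, orientation`.
#' @export
match_precursors <- function(lncs, hairpins, min_identity = 0.90,
                             min_coverage = 0.90) {
  assert_that(length(hairpins) > 0, "hairpin set is empty")
  smat <- matrix(-1, 5, 5)
  diag(smat) <- 1
  smat[5, ] <- smat[, 5] <- -1  # N never matches
  out <- list()
  for (l in names(lncs)) {
    for (h in names(hairpins)) {
      hp <- toupper(hairpins[[h]])
      hits <- lapply(c("+", "-"), function(ori) {
        s <- if (ori == "+") hp else revcomp(hp)
        al <- .sw_align(toupper(lncs[[l]]), s, smat, 2, 2)
        al$ori <- ori
        al
      })
      al <- hits[[which.max(vapply(hits, `[[`, numeric(1), "score"))]]
      if (al$aligned_cols == 0) next
      idy <- al$matches / al$aligned_cols
      cov <- al$b_aligned / nchar(hp)
      if (idy >= min_identity && cov > min_coverage) {
        hl <- nchar(hp)
        hs <- if (al$ori == "+") al$b_start else hl - al$b_end + 1L
        he <- if (al$ori == "+") al$b_end else hl - al$b_start + 1L
        out[[length(out) + 1L]] <- data.table(
          lnc_id = l, hairpin_id = h, identity = idy, coverage = cov,
          score = al$score, lnc_start = al$a_start, lnc_end = al$a_end,
          hairpin_start = hs, hairpin_end = he, orientation = al$ori)
      }
    }
  }
  res <- rbindlist(out)
  if (nrow(res) == 0L)
    res <- data.table(lnc_id = character(), hairpin_id = character(),
                      identity = numeric(), coverage = numeric(),
                      score = numeric(), lnc_start = integer(),
                      lnc_end = integer(), hairpin_start = integer(),
                      hairpin_end = integer(), orientation = character())
  res[]
}
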