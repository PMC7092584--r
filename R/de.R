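#' Exact conditional count test for two unreplicated libraries
#'
#' With one pooled library per condition no replicate variance is estimable,
#' so differential expression is tested with the exact conditional binomial
#' construction (the Audic--Claverie test): conditional on the total
#' `t = x + y`, the count `x` is Binomial(`t`, `Na / (Na + Nb)`) under the
#' null of equal relative abundance. The two-sided p-value sums the
#' probability of every outcome no more likely than the observed one.
#' `p(0, 0) = 1` by convention.
#'
#' @param x,y read counts in libraries a and b.
#' @param na,nb library depths (total mapped reads), both > 0.
#' @return p-value in `(0, 1]`.
#' @export
exact_count_test <- function(x, y, na, nb) {
  assert_that(all(c(x, y) >= 0), "counts must be non-negative")
  assert_that(na > 0 && nb > 0, "library depths must be positive")
  t <- x + y
  if (t == 0) return(1)
  p0 <- na / (na + nb)
  d <- dbinom(0:t, t, p0)
  # tolerance guards ties against floating-point noise
  p <- sum(d[d <= d[x + 1L] * (1 + 1e-7)])
  # extreme outcomes can underflow the binomial mass to 0; keep p in (0, 1]
  min(1, max(p, 1e-300))
}

#' Benjamini--Hochberg step-up adjustment
#'
#' `q_(i) = min_{j >= i} p_(j) * m / j` on the sorted p-values, reported in
#' the input order and capped at 1. Inputs outside `(0, 1]` are an error.
#'
#' @param p vector of p-values in `(0, 1]`.
#' @return q-values, same order as `p`.
#' @export
bh_adjust <- function(p) {
  assert_that(length(p) > 0, "empty p-value vector")
  assert_that(all(p > 0 & p <= 1), "p-values must lie in (0, 1]")
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  q <- numeric(m)
  q[o] <- pmin(1, cummin(p[o] * m / m:1))
  q
}

#' Call differential expression between pooled stage libraries
#'
#' For each contrast `(a, b)` runs [exact_count_test()] per transcript with
#' the library totals as depths, adjusts p-values with [bh_adjust()] within
#' the contrast, and computes `log2fc = log2((fpkm_b + c) / (fpkm_a + c))`
#' with pseudocount `c`. A transcript is called `up`/`down` when
#' `qvalue <= fdr` \emph{and} `|log2fc| >= min_abs_log2fc` -- both boundaries
#' inclusive, per the screening conditions "an FDR no more than 0.05 and an
#' absolute fold change no less than two".
#'
#' @param expr expression table (see [read_expression()]).
#' @param contrasts list of ordered library pairs, e.g.
#'   `list(c("E","P"), c("E","L"), c("P","L"))`.
#' @param fdr FDR threshold (default 0.05).
#' @param min_abs_log2fc fold-change gate on the log2 scale (default 1,
#'   i.e. two-fold).
#' @param pseudocount FPKM pseudocount (default 0.01).
#' @return data.table: `transcript_id, contrast, count_a, count_b, depth_a,
#'   depth_b, log2fc, pvalue, qvalue, call`.
#' @export
call_de <- function(expr, contrasts = list(c("E", "P"), c("E", "L"),
                                           c("P", "L")),
                    fdr = 0.05, min_abs_log2fc = 1, pseudocount = 0.01) {
  expr <- as.data.table(expr)
  depths <- expr[, .(depth = sum(read_count)), by = library]
  res <- list()
  for (ct in contrasts) {
    a <- ct[1]; b <- ct[2]
    assert_that(all(c(a, b) %in% depths$library),
                "contrast library missing from expression table: %s:%s", a, b)
    ea <- expr[library == a][order(transcript_id)]
    eb <- expr[library == b][order(transcript_id)]
    stopifnot(identical(ea$transcript_id, eb$transcript_id))
    na <- depths[library == a, depth]; nb <- depths[library == b, depth]
    pv <- mapply(exact_count_test, ea$read_count, eb$read_count,
                 MoreArgs = list(na = na, nb = nb))
    qv <- bh_adjust(pv)
    lfc <- log2((eb$fpkm + pseudocount) / (ea$fpkm + pseudocount))
    call <- data.table::fifelse(
      qv <= fdr & abs(lfc) >= min_abs_log2fc,
      data.table::fifelse(lfc > 0, "up", "down"), "ns")
    res[[paste(ct, collapse = ":")]] <- data.table(
      transcript_id = ea$transcript_id,
      contrast = paste(a, b, sep = ":"),
      count_a = ea$read_count, count_b = eb$read_count,
      depth_a = na, depth_b = nb, log2fc = lfc,
      pvalue = pv, qvalue = qv, call = call)
  }
  rbindlist(res)[]
}
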