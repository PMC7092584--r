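#' Longest open reading frame across six frames
#'
#' Scans the three forward frames of `seq` and the three frames of its
#' reverse complement. An ORF is an in-frame `ATG ... stop` run; the returned
#' length counts codons from the ATG up to but excluding the stop (so
#' `ATGAAATAG` scores 2 aa). ORFs running off the sequence end without a stop
#' are not counted. A codon containing `N` matches neither `ATG` nor a stop:
#' it extends an open frame but can never open or close one.
#'
#' @param seq nucleotide string over `{A,C,G,T,N}` (case-insensitive).
#' @return longest ORF length in amino acids (0 if none).
#' @export
scan_longest_orf <- function(seq) {
  .orf_best(seq)$aa
}

# longest ORF with its location: orientation (1 = forward, 2 = reverse
# complement), frame offset 0..2, and the 1-based nt start of the ATG in the
# oriented string. Used by the synthetic-data generator to break accidental
# long ORFs.
.orf_best <- function(seq) {
  assert_that(is.character(seq) && length(seq) == 1L, "seq must be one string")
  seq <- toupper(seq)
  best <- list(aa = 0L, orient = NA_integer_, frame = NA_integer_,
               nt_start = NA_integer_)
  if (nchar(seq) < 6L) return(best)
  oriented <- c(seq, revcomp(seq))
  for (oi in 1:2) {
    s <- oriented[oi]
    n <- nchar(s)
    for (frame in 0:2) {
      starts <- seq.int(1L + frame, n - 2L, by = 3L)
      if (length(starts) < 2L) next
      codons <- substring(s, starts, starts + 2L)
      atg <- which(codons == "ATG")
      stp <- which(codons %in% c("TAA", "TAG", "TGA"))
      if (!length(atg) || !length(stp)) next
      # next stop strictly after each ATG (ATG is never a stop, so
      # findInterval counts stops before it)
      nxt <- stp[findInterval(atg, stp) + 1L]
      len <- nxt - atg
      ok <- !is.na(len)
      if (any(ok) && max(len[ok]) > best$aa) {
        i <- which(ok)[which.max(len[ok])]
        best <- list(aa = as.integer(len[i]), orient = oi, frame = frame,
                     nt_start = starts[atg[i]])
      }
    }
  }
  best
}
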