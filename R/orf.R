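#' Find the longest complete open reading frame
#'
#' Scans the three forward frames of each RNA-sense sequence for
#' `ATG ... stop` spans. Only stop-terminated ORFs count: an ATG without an
#' in-frame stop codon before the end of the sequence yields no ORF. The
#' reported length in amino acids excludes the stop codon; ties are broken
#' by the leftmost start position.
#'
#' @param seqs Character vector of DNA sequences over `A/C/G/T/N`
#'   (case-insensitive). Codons containing `N` match neither `ATG` nor a
#'   stop.
#' @return A tibble with one row per sequence: `max_orf_aa` (0 when no
#'   complete ORF), `orf_start` (0-based offset of the ATG, `NA` if none),
#'   `frame` (0/1/2, `NA` if none) and `orf_nt` (ORF length in nucleotides
#'   including the stop codon).
#' @export
#' @examples
#' find_max_orf(c("ATGAAATAA", "ATGAAAAAA", "CCATGAAATAACC"))
find_max_orf <- function(seqs) {
  stops <- c("TAA", "TAG", "TGA")
  one <- function(s) {
    s <- toupper(s)
    L <- nchar(s)
    best_aa <- 0L
    best_start <- NA_integer_
    best_frame <- NA_integer_
    for (f in 0:2) {
      if (L - f < 6) next
      starts <- seq.int(f + 1L, L - 2L, by = 3L)
      codons <- substring(s, starts, starts + 2L)
      atg <- which(codons == "ATG")
      stp <- which(codons %in% stops)
      if (length(atg) == 0 || length(stp) == 0) next
      nxt <- stp[findInterval(atg, stp) + 1L]
      ok <- !is.na(nxt)
      if (!any(ok)) next
      aa <- nxt[ok] - atg[ok]
      off <- f + (atg[ok] - 1L) * 3L
      i <- which(aa == max(aa))
      i <- i[which.min(off[i])]
      if (aa[i] > best_aa ||
          (aa[i] == best_aa && !is.na(best_start) && off[i] < best_start)) {
        best_aa <- aa[i]
        best_start <- off[i]
        best_frame <- f
      }
    }
    c(best_aa, best_start, best_frame)
  }
  res <- vapply(seqs, one, numeric(3), USE.NAMES = FALSE)
  tibble::tibble(
    max_orf_aa = as.integer(res[1, ]),
    orf_start = as.integer(res[2, ]),
    frame = as.integer(res[3, ]),
    orf_nt = ifelse(res[1, ] > 0, as.integer(3 * (res[1, ] + 1)), 0L)
  )
}
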