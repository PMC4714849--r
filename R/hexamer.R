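ALL_HEXAMERS <- do.call(paste0, expand.grid(rep(list(c("A", "C", "G", "T")), 6),
                                            stringsAsFactors = FALSE)[, 6:1])

## Count hexamers of `seqs` at the given step (3 = in-frame, 1 = all
## frames), skipping hexamers containing characters outside ACGT. Internal.
count_hexamers <- function(seqs, step) {
  counts <- stats::setNames(numeric(4096), ALL_HEXAMERS)
  for (s in seqs) {
    s <- toupper(s)
    L <- nchar(s)
    if (L < 6) next
    starts <- seq.int(1L, L - 5L, by = step)
    hex <- substring(s, starts, starts + 5L)
    hex <- hex[hex %in% ALL_HEXAMERS]
    if (length(hex) > 0) {
      tab <- table(hex)
      counts[names(tab)] <- counts[names(tab)] + as.numeric(tab)
    }
  }
  counts
}

#' Build a coding/noncoding hexamer frequency table
#'
#' Coding frequencies are estimated from in-frame hexamers (reading frame
#' of the supplied ORF/CDS sequences, step 3); noncoding frequencies from
#' hexamers in all frames (step 1). Counts are Laplace-smoothed and
#' normalised so each class sums to one.
#'
#' @param coding_seqs Character vector of coding sequences given in their
#'   reading frame (frame 0).
#' @param noncoding_seqs Character vector of noncoding sequences.
#' @param pseudocount Smoothing constant added to every hexamer count.
#' @return A `hexamer_table` object: named frequency vectors `f_coding`
#'   and `f_noncoding` over the 4096 hexamers, plus training metadata.
#' @export
build_hexamer_table <- function(coding_seqs, noncoding_seqs, pseudocount = 1) {
  if (length(coding_seqs) == 0 || length(noncoding_seqs) == 0) {
    rlang::abort("both sequence classes must be non-empty")
  }
  coding <- count_hexamers(coding_seqs, step = 3L) + pseudocount
  noncoding <- count_hexamers(noncoding_seqs, step = 1L) + pseudocount
  structure(
    list(f_coding = coding / sum(coding),
         f_noncoding = noncoding / sum(noncoding),
         pseudocount = pseudocount,
         n_coding = length(coding_seqs),
         n_noncoding = length(noncoding_seqs)),
    class = "hexamer_table"
  )
}

#' @export
print.hexamer_table <- function(x, ...) {
  cat("<hexamer_table> 4096 hexamers;",
      x$n_coding, "coding /", x$n_noncoding, "noncoding training sequences;",
      "pseudocount", x$pseudocount, "\n")
  invisible(x)
}

#' Hexamer usage log-likelihood ratio
#'
#' Mean, over the in-frame hexamers of each sequence's maximal ORF, of
#' `log(f_coding / f_noncoding)`. Sequences without a complete ORF are
#' scored over the whole sequence in frame 0. Hexamers containing `N` are
#' skipped; a sequence contributing no scorable hexamer gets 0.
#'
#' @param seqs Character vector of DNA sequences (each >= 6 nt).
#' @param table A [build_hexamer_table()] object.
#' @param orf Optional precomputed [find_max_orf()] result for `seqs`.
#' @return Numeric vector of mean log-likelihood ratios (natural log).
#' @export
hexamer_llr <- function(seqs, table, orf = NULL) {
  stopifnot(inherits(table, "hexamer_table"))
  if (is.null(orf)) orf <- find_max_orf(seqs)
  llr <- log(table$f_coding) - log(table$f_noncoding)
  purrr::map2_dbl(seqs, seq_along(seqs), function(s, i) {
    s <- toupper(s)
    if (orf$max_orf_aa[i] > 0) {
      from <- orf$orf_start[i] + 1L
      to <- orf$orf_start[i] + orf$orf_nt[i]
    } else {
      from <- 1L
      to <- nchar(s)
    }
    if (to - from + 1L < 6L) return(0)
    starts <- seq.int(from, to - 5L, by = 3L)
    hex <- substring(s, starts, starts + 5L)
    hex <- hex[hex %in% ALL_HEXAMERS]
    if (length(hex) == 0) return(0)
    mean(llr[hex])
  })
}
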