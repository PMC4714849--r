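#' Transcript tables
#'
#' The package represents transcript models as a tibble with one row per
#' transcript and an `exons` list-column. All internal coordinates are
#' 0-based half-open; conversion to/from the 1-based inclusive GTF/GFF3
#' convention happens only in the I/O functions.
#'
#' Columns:
#' * `transcript_id`, `locus_id`, `scaffold` -- character
#' * `strand` -- `"+"` or `"-"` (unstranded transcripts are rejected)
#' * `exons` -- list of integer matrices with columns `start`, `end`,
#'   sorted, non-overlapping, all on the transcript's scaffold
#'
#' Optional columns used downstream: `cov`, `fpkm` (doubles), `class_code`,
#' `category` (character), `support` (list of character vectors of
#' `"assembler|tissue"` tags).
#'
#' @param transcript_id,locus_id,scaffold,strand Character vectors.
#' @param exons List of two-column integer matrices (start, end).
#' @param ... Further columns recycled by [tibble::tibble()].
#' @return A validated transcript tibble.
#' @export
#' @examples
#' transcript_tbl(
#'   transcript_id = "t1", locus_id = "l1", scaffold = "chr1", strand = "+",
#'   exons = list(cbind(start = c(10L, 30L), end = c(20L, 40L)))
#' )
transcript_tbl <- function(transcript_id, locus_id = transcript_id,
                           scaffold, strand, exons, ...) {
  tx <- tibble::tibble(
    transcript_id = as.character(transcript_id),
    locus_id = as.character(locus_id),
    scaffold = as.character(scaffold),
    strand = as.character(strand),
    exons = exons,
    ...
  )
  validate_transcripts(tx)
}

#' Validate a transcript table
#'
#' Checks the invariants documented in [transcript_tbl()]: unique ids,
#' `+`/`-` strand, sorted non-overlapping exons with positive width.
#'
#' @param tx A transcript tibble.
#' @return `tx`, invisibly unchanged, or an error.
#' @export
validate_transcripts <- function(tx) {
  need <- c("transcript_id", "locus_id", "scaffold", "strand", "exons")
  missing <- setdiff(need, names(tx))
  if (length(missing) > 0) {
    rlang::abort(paste0("transcript table lacks column(s): ",
                        paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(tx$transcript_id)) {
    rlang::abort("duplicated transcript_id in transcript table")
  }
  bad_strand <- !tx$strand %in% c("+", "-")
  if (any(bad_strand)) {
    rlang::abort(paste0("unstranded or invalid strand for transcript(s): ",
                        paste(utils::head(tx$transcript_id[bad_strand], 5),
                              collapse = ", ")))
  }
  ok <- purrr::map_lgl(tx$exons, function(e) {
    is.matrix(e) && ncol(e) == 2 && nrow(e) >= 1 &&
      all(e[, 2] > e[, 1]) &&
      !is.unsorted(e[, 1], strictly = TRUE) &&
      all(diff(as.vector(t(e))) > 0)
  })
  if (!all(ok)) {
    rlang::abort(paste0("invalid exon structure for transcript(s): ",
                        paste(utils::head(tx$transcript_id[!ok], 5),
                              collapse = ", ")))
  }
  invisible(tx)
}

#' Per-transcript summaries of a transcript table
#'
#' @param tx A transcript tibble.
#' @return `tx_spliced_length()`: integer spliced lengths (sum of exon
#'   widths); `tx_n_exons()`: integer exon counts; `tx_span()`: a tibble
#'   with the genomic `start`/`end` span of each transcript.
#' @export
tx_spliced_length <- function(tx) {
  purrr::map_int(tx$exons, ~ sum(.x[, 2L] - .x[, 1L]))
}

#' @rdname tx_spliced_length
#' @export
tx_n_exons <- function(tx) {
  purrr::map_int(tx$exons, nrow)
}

#' @rdname tx_spliced_length
#' @export
tx_span <- function(tx) {
  tibble::tibble(
    start = purrr::map_int(tx$exons, ~ .x[1L, 1L]),
    end = purrr::map_int(tx$exons, ~ .x[nrow(.x), 2L])
  )
}

## Exon-level GRanges (1-based inclusive, as GenomicRanges requires) with a
## tx index back-reference. Internal.
exon_granges <- function(tx, ignore_strand = FALSE) {
  n <- tx_n_exons(tx)
  idx <- rep.int(seq_len(nrow(tx)), n)
  mat <- do.call(rbind, tx$exons)
  gr <- GenomicRanges::GRanges(
    seqnames = rep.int(tx$scaffold, n),
    ranges = IRanges::IRanges(start = mat[, 1L] + 1L, end = mat[, 2L]),
    strand = if (ignore_strand) "*" else rep.int(tx$strand, n)
  )
  S4Vectors::mcols(gr)$tx <- idx
  gr
}

## Whole-span GRanges per transcript. Internal.
span_granges <- function(tx, ignore_strand = FALSE) {
  sp <- tx_span(tx)
  gr <- GenomicRanges::GRanges(
    seqnames = tx$scaffold,
    ranges = IRanges::IRanges(start = sp$start + 1L, end = sp$end),
    strand = if (ignore_strand) "*" else tx$strand
  )
  S4Vectors::mcols(gr)$tx <- seq_len(nrow(tx))
  gr
}

## Introns of a transcript exon matrix (0-based half-open). Internal.
exon_introns <- function(e) {
  if (nrow(e) < 2) {
    return(matrix(integer(0), ncol = 2,
                  dimnames = list(NULL, c("start", "end"))))
  }
  cbind(start = e[-nrow(e), 2L], end = e[-1L, 1L])
}

#' Extract the spliced (mature) sequence of each transcript
#'
#' Concatenates exon sequences 5' to 3' in transcript orientation:
#' minus-strand transcripts are reverse-complemented. `N` bases are
#' preserved.
#'
#' @param tx A transcript tibble.
#' @param genome A named [Biostrings::DNAStringSet] as returned by
#'   [read_genome()].
#' @return A named character vector of RNA-sense DNA sequences, one per
#'   transcript.
#' @export
spliced_sequence <- function(tx, genome) {
  validate_transcripts(tx)
  missing <- setdiff(unique(tx$scaffold), names(genome))
  if (length(missing) > 0) {
    rlang::abort(paste0("scaffold(s) absent from genome: ",
                        paste(missing, collapse = ", ")))
  }
  lens <- Biostrings::width(genome)[match(tx$scaffold, names(genome))]
  out_of_bounds <- purrr::map2_lgl(tx$exons, lens,
                                   ~ any(.x[, 1L] < 0L | .x[, 2L] > .y))
  if (any(out_of_bounds)) {
    rlang::abort(paste0("exon out of scaffold bounds for transcript(s): ",
                        paste(utils::head(tx$transcript_id[out_of_bounds], 5),
                              collapse = ", ")))
  }
  seqs <- purrr::pmap_chr(
    list(tx$exons, tx$scaffold, tx$strand),
    function(e, sc, st) {
      pieces <- Biostrings::extractAt(
        genome[[sc]], IRanges::IRanges(start = e[, 1L] + 1L, end = e[, 2L])
      )
      s <- Biostrings::DNAString(paste(as.character(pieces), collapse = ""))
      if (st == "-") s <- Biostrings::reverseComplement(s)
      as.character(s)
    }
  )
  stats::setNames(seqs, tx$transcript_id)
}
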