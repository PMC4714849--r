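#' lncRNA loci acting as miRNA precursors
#'
#' A (lncRNA locus, miRNA) pair is reported when the mature miRNA
#' interval overlaps the locus span (union of its isoform spans) by at
#' least 1 bp on the same strand. Because genuine pre-miRNA hairpins are
#' exonic, containment of the miRNA within an exon of any isoform is
#' additionally flagged.
#'
#' @param lncrna Transcript tibble of lncRNA isoforms (with `locus_id`).
#' @param mirna_loci Interval tibble (see [read_intervals()]) of mature
#'   miRNAs; every record must carry a strand.
#' @return A tibble with `locus_id`, `mirna`, `scaffold`, `strand` and
#'   logical `exonic`.
#' @export
precursor_overlap <- function(lncrna, mirna_loci) {
  validate_transcripts(lncrna)
  if (any(is.na(mirna_loci$strand))) {
    rlang::abort("strandless miRNA record(s) in annotation")
  }
  if (nrow(lncrna) == 0 || nrow(mirna_loci) == 0) {
    return(tibble::tibble(locus_id = character(0), mirna = character(0),
                          scaffold = character(0), strand = character(0),
                          exonic = logical(0)))
  }
  mir_gr <- intervals_to_granges(mirna_loci)
  spans <- span_granges(lncrna)
  loci <- GenomicRanges::findOverlaps(mir_gr, spans, ignore.strand = FALSE)
  if (length(loci) == 0) {
    return(tibble::tibble(locus_id = character(0), mirna = character(0),
                          scaffold = character(0), strand = character(0),
                          exonic = logical(0)))
  }
  pairs <- tibble::tibble(
    mirna_idx = S4Vectors::queryHits(loci),
    locus_id = lncrna$locus_id[S4Vectors::subjectHits(loci)]
  ) |> dplyr::distinct()

  ex <- exon_granges(lncrna)
  exonic_hits <- GenomicRanges::findOverlaps(mir_gr, ex, type = "within",
                                             ignore.strand = FALSE)
  exonic_pairs <- tibble::tibble(
    mirna_idx = S4Vectors::queryHits(exonic_hits),
    locus_id = lncrna$locus_id[
      S4Vectors::mcols(ex)$tx[S4Vectors::subjectHits(exonic_hits)]]
  ) |> dplyr::distinct() |> dplyr::mutate(exonic = TRUE)

  pairs |>
    dplyr::left_join(exonic_pairs, by = c("mirna_idx", "locus_id")) |>
    dplyr::mutate(
      mirna = mirna_loci$name[.data$mirna_idx],
      scaffold = mirna_loci$scaffold[.data$mirna_idx],
      strand = mirna_loci$strand[.data$mirna_idx],
      exonic = !is.na(.data$exonic)
    ) |>
    dplyr::select("locus_id", "mirna", "scaffold", "strand", "exonic") |>
    dplyr::arrange(.data$locus_id, .data$mirna)
}

## Reverse complement of a DNA string (U converted to T first). Internal.
revcomp_dna <- function(x) {
  as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(gsub("U", "T", toupper(x)))))
}

#' Scan a transcript for canonical miRNA seed sites (MREs)
#'
#' Finds miRNA response elements on the sense (spliced) sequence of each
#' transcript by canonical seed complementarity (T and U equivalent):
#' a 6mer site is the reverse complement of miRNA positions 2-7; 7mer-m8
#' extends the match to position 8; 7mer-A1 adds an `A` on the target
#' opposite miRNA position 1; 8mer has both. Each seed-core occurrence is
#' reported once, at its strongest type (8mer > 7mer-m8 > 7mer-A1 >
#' 6mer); all occurrences along the transcript are returned.
#'
#' @param lnc_seqs Named character vector of spliced transcript
#'   sequences.
#' @param mirna_seqs Named character vector of mature miRNA sequences,
#'   5' to 3', each at least 19 nt (`U` allowed).
#' @return A tibble with `lncrna_id`, `mirna_id`, `start`, `end`
#'   (0-based half-open on the spliced transcript) and `site_type`.
#' @export
scan_mre_sites <- function(lnc_seqs, mirna_seqs) {
  if (any(nchar(mirna_seqs) < 19)) {
    rlang::abort("mature miRNA sequences must be at least 19 nt")
  }
  if (is.null(names(lnc_seqs))) names(lnc_seqs) <- seq_along(lnc_seqs)
  if (is.null(names(mirna_seqs))) names(mirna_seqs) <- seq_along(mirna_seqs)
  res <- purrr::map(names(mirna_seqs), function(mir_id) {
    mir <- gsub("U", "T", toupper(mirna_seqs[[mir_id]]))
    site6 <- revcomp_dna(substr(mir, 2, 7))
    m8_base <- revcomp_dna(substr(mir, 8, 8))
    purrr::map(names(lnc_seqs), function(lnc_id) {
      s <- toupper(lnc_seqs[[lnc_id]])
      m <- Biostrings::matchPattern(site6, Biostrings::DNAString(s))
      if (length(m) == 0) return(NULL)
      core_start <- BiocGenerics::start(m) - 1L  # 0-based
      has_m8 <- core_start >= 1L &
        substring(s, core_start, core_start) == m8_base
      has_a1 <- core_start + 6L < nchar(s) &
        substring(s, core_start + 7L, core_start + 7L) == "A"
      tibble::tibble(
        lncrna_id = lnc_id,
        mirna_id = mir_id,
        start = ifelse(has_m8, core_start - 1L, core_start),
        end = ifelse(has_a1, core_start + 7L, core_start + 6L),
        site_type = dplyr::case_when(
          has_m8 & has_a1 ~ "8mer",
          has_m8 ~ "7mer-m8",
          has_a1 ~ "7mer-A1",
          .default = "6mer"
        )
      )
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()
  if (is.null(res) || nrow(res) == 0) {
    return(tibble::tibble(lncrna_id = character(0), mirna_id = character(0),
                          start = integer(0), end = integer(0),
                          site_type = character(0)))
  }
  dplyr::arrange(res, .data$lncrna_id, .data$mirna_id, .data$start)
}

#' Filter MRE hits to conserved regions and call ceRNA candidates
#'
#' Keeps hits fully contained in a conserved region of their transcript
#' (regions are supplied in spliced-transcript coordinates, e.g. from
#' ingested cross-species homology tables). A transcript is a ceRNA
#' candidate iff its retained hits involve at least `min_distinct_mirnas`
#' distinct miRNAs.
#'
#' @param hits Output of [scan_mre_sites()].
#' @param conserved_regions Tibble with `transcript_id`, `start`, `end`
#'   (0-based half-open, spliced coordinates).
#' @param min_distinct_mirnas Minimum distinct miRNAs with retained hits.
#' @param lnc_lengths Optional named vector of spliced lengths used to
#'   reject regions outside transcript bounds.
#' @return A list: `hits` (retained hits) and `candidates` (per-lncRNA
#'   `n_sites`, `n_mirnas`, logical `cerna_candidate`).
#' @export
cerna_filter <- function(hits, conserved_regions, min_distinct_mirnas = 1,
                         lnc_lengths = NULL) {
  if (!is.null(lnc_lengths)) {
    len <- lnc_lengths[conserved_regions$transcript_id]
    bad <- is.na(len) | conserved_regions$start < 0 | conserved_regions$end > len
    if (any(bad)) {
      rlang::abort(paste0("conserved region outside transcript bounds for: ",
                          paste(utils::head(
                            conserved_regions$transcript_id[bad], 5),
                            collapse = ", ")))
    }
  }
  kept <- dplyr::inner_join(
    hits, conserved_regions,
    by = c(lncrna_id = "transcript_id"), suffix = c("", ".region"),
    relationship = "many-to-many"
  ) |>
    dplyr::filter(.data$start >= .data$start.region,
                  .data$end <= .data$end.region) |>
    dplyr::select(dplyr::all_of(names(hits))) |>
    dplyr::distinct()
  candidates <- kept |>
    dplyr::group_by(lncrna_id = .data$lncrna_id) |>
    dplyr::summarise(n_sites = dplyr::n(),
                     n_mirnas = dplyr::n_distinct(.data$mirna_id),
                     .groups = "drop") |>
    dplyr::mutate(cerna_candidate = .data$n_mirnas >= min_distinct_mirnas)
  list(hits = kept, candidates = candidates)
}
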