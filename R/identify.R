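#' Classify candidate transcripts relative to a coding annotation
#'
#' Assigns one class code per candidate: `sense_exonic` if any exon
#' overlaps a reference exon on the same strand by at least 1 bp; else
#' `x` (natural antisense) if any exon overlaps a reference exon on the
#' opposite strand; else `i` (intronic) if the candidate lies entirely
#' within a single intron of a single reference transcript (either
#' strand); else `u` (intergenic).
#'
#' @param tx Candidate transcript tibble (stranded, multi-exon).
#' @param reference Reference coding-gene transcript tibble.
#' @param intronic_same_strand_only If `TRUE`, class `i` additionally
#'   requires the host intron to be on the candidate's strand.
#' @return Character vector of class codes, one per candidate.
#' @export
assign_class_code <- function(tx, reference, intronic_same_strand_only = FALSE) {
  validate_transcripts(tx)
  validate_transcripts(reference)
  n <- nrow(tx)
  if (n == 0) return(character(0))
  cand_ex <- exon_granges(tx)
  ref_ex <- exon_granges(reference)

  sense <- GenomicRanges::findOverlaps(cand_ex, ref_ex, ignore.strand = FALSE)
  is_sense <- seq_len(n) %in% S4Vectors::mcols(cand_ex)$tx[S4Vectors::queryHits(sense)]

  flipped <- cand_ex
  GenomicRanges::strand(flipped) <- ifelse(
    as.character(GenomicRanges::strand(cand_ex)) == "+", "-", "+")
  anti <- GenomicRanges::findOverlaps(flipped, ref_ex, ignore.strand = FALSE)
  is_anti <- seq_len(n) %in% S4Vectors::mcols(flipped)$tx[S4Vectors::queryHits(anti)]

  ref_introns <- purrr::map(seq_len(nrow(reference)), function(i) {
    introns <- exon_introns(reference$exons[[i]])
    if (nrow(introns) == 0) return(NULL)
    tibble::tibble(scaffold = reference$scaffold[i],
                   start = introns[, 1L], end = introns[, 2L],
                   strand = reference$strand[i])
  }) |> purrr::compact() |> purrr::list_rbind()
  is_intronic <- rep(FALSE, n)
  if (!is.null(ref_introns) && nrow(ref_introns) > 0) {
    intron_gr <- intervals_to_granges(ref_introns,
                                      ignore_strand = !intronic_same_strand_only)
    spans <- span_granges(tx, ignore_strand = !intronic_same_strand_only)
    within <- GenomicRanges::findOverlaps(spans, intron_gr, type = "within",
                                          ignore.strand = !intronic_same_strand_only)
    is_intronic <- seq_len(n) %in%
      S4Vectors::mcols(spans)$tx[S4Vectors::queryHits(within)]
  }

  dplyr::case_when(
    is_sense ~ "sense_exonic",
    is_anti ~ "x",
    is_intronic ~ "i",
    .default = "u"
  )
}

#' Thresholds of the lncRNA identification cascade
#'
#' Defaults are the canonical thresholds: minimum spliced length 200 nt,
#' at least 2 exons, per-base read coverage >= 0.8, FPKM >= 0.1, maximum
#' ORF <= 100 aa, coding probability <= 0.345, homology E-value cutoff
#' 1e-6, and a 2 kb exclusion margin at scaffold ends.
#'
#' @param min_length_nt,min_exons,min_coverage,min_fpkm,max_orf_aa
#'   Basic per-transcript filters (stages 2-3).
#' @param coding_prob_threshold Decision boundary of the coding-potential
#'   scorer (stage 4).
#' @param homology_evalue E-value below which a protein homology hit
#'   removes a transcript (stage 5).
#' @param scaffold_end_margin_nt Transcripts whose genomic span comes
#'   within this many bases of a scaffold end are excluded (stage 6).
#' @return A `filter_config` list.
#' @export
filter_config <- function(min_length_nt = 200, min_exons = 2,
                          min_coverage = 0.8, min_fpkm = 0.1,
                          max_orf_aa = 100, coding_prob_threshold = 0.345,
                          homology_evalue = 1e-6,
                          scaffold_end_margin_nt = 2000) {
  cfg <- list(min_length_nt = min_length_nt, min_exons = min_exons,
              min_coverage = min_coverage, min_fpkm = min_fpkm,
              max_orf_aa = max_orf_aa,
              coding_prob_threshold = coding_prob_threshold,
              homology_evalue = homology_evalue,
              scaffold_end_margin_nt = scaffold_end_margin_nt)
  if (any(unlist(cfg) <= 0)) rlang::abort("all thresholds must be positive")
  structure(cfg, class = "filter_config")
}

CASCADE_STAGES <- c("sense_overlap", "basic_filters", "orf_filter",
                    "coding_potential", "homology", "scaffold_end",
                    "classification")

CATEGORY_OF_CODE <- c(i = "ilncRNA", u = "lincRNA", x = "lncNAT")

#' Apply the seven-stage lncRNA identification cascade
#'
#' Stages, in order: (1) drop candidates overlapping reference exons in the
#' sense orientation; (2) drop short (< 200 nt), single-exon, low-coverage
#' (< 0.8) or low-FPKM (< 0.1) transcripts, coverage and FPKM taken as the
#' maximum across tissues; (3) drop ORFs > 100 aa; (4) drop transcripts the
#' coding-potential scorer calls coding (probability > threshold) or whose
#' optional external scores (`cpc`, `cnci`) exceed 0; (5) drop transcripts
#' with a protein homology hit at E-value < 1e-6; (6) drop transcripts
#' within the scaffold-end margin; (7) retain class codes `i`/`u`/`x` and
#' attach the category (ilncRNA / lincRNA / lncNAT). Every candidate is
#' attributed to the first stage that removes it.
#'
#' @param candidates Merged candidate transcript tibble with `cov` and
#'   `fpkm` columns populated (maximum across tissues).
#' @param reference Reference coding annotation transcript tibble.
#' @param genome Named [Biostrings::DNAStringSet].
#' @param scaffolds Tibble with `name`, `length` (see
#'   [read_scaffold_lengths()]).
#' @param cfg A [filter_config()].
#' @param scorer Optional function mapping a character vector of spliced
#'   sequences to coding probabilities in `[0, 1]` (see
#'   [coding_probability()]). When `NULL`, stage 4 uses only the external
#'   score columns.
#' @param homology_hits Optional tibble of precomputed protein homology
#'   hits with columns `transcript_id` and `evalue`.
#' @param external_scores Optional tibble with `transcript_id` and any of
#'   `cpc`, `cnci`; a positive score marks the transcript coding.
#' @return A list: `records` (surviving transcripts with `class_code`,
#'   `category`, `max_orf_aa`, `coding_probability`) and `report`, a
#'   telescoping tibble (`stage`, `input_n`, `retained_n`) plus a
#'   `casualties` tibble mapping each removed transcript to its stage.
#' @export
apply_filter_cascade <- function(candidates, reference, genome, scaffolds,
                                 cfg = filter_config(), scorer = NULL,
                                 homology_hits = NULL,
                                 external_scores = NULL) {
  validate_transcripts(candidates)
  if (!all(c("cov", "fpkm") %in% names(candidates)) ||
      anyNA(candidates$fpkm)) {
    bad <- if ("fpkm" %in% names(candidates)) {
      candidates$transcript_id[is.na(candidates$fpkm)]
    } else {
      candidates$transcript_id
    }
    rlang::abort(paste0("missing FPKM attribute for transcript(s): ",
                        paste(utils::head(bad, 5), collapse = ", ")))
  }
  missing_scaf <- setdiff(unique(candidates$scaffold), scaffolds$name)
  if (length(missing_scaf) > 0) {
    rlang::abort(paste0("scaffold(s) absent from length table: ",
                        paste(missing_scaf, collapse = ", ")))
  }

  tx <- candidates
  tx$class_code <- assign_class_code(tx, reference)
  seqs <- spliced_sequence(tx, genome)
  orf <- find_max_orf(seqs)
  tx$max_orf_aa <- orf$max_orf_aa
  tx$coding_probability <- NA_real_
  if (!is.null(scorer)) {
    scorable <- nchar(seqs) >= 200      # shorter ones die at stage 2 anyway
    if (any(scorable)) {
      tx$coding_probability[scorable] <- scorer(seqs[scorable])
    }
  }

  external_coding <- rep(FALSE, nrow(tx))
  if (!is.null(external_scores)) {
    m <- match(tx$transcript_id, external_scores$transcript_id)
    for (col in intersect(c("cpc", "cnci"), names(external_scores))) {
      v <- external_scores[[col]][m]
      external_coding <- external_coding | (!is.na(v) & v > 0)
    }
  }
  has_homology <- rep(FALSE, nrow(tx))
  if (!is.null(homology_hits) && nrow(homology_hits) > 0) {
    sig <- homology_hits$evalue < cfg$homology_evalue
    has_homology <- tx$transcript_id %in% homology_hits$transcript_id[sig]
  }
  span <- tx_span(tx)
  scaf_len <- scaffolds$length[match(tx$scaffold, scaffolds$name)]
  near_end <- span$start < cfg$scaffold_end_margin_nt |
    span$end > scaf_len - cfg$scaffold_end_margin_nt

  fails <- list(
    sense_overlap = tx$class_code == "sense_exonic",
    basic_filters = tx_spliced_length(tx) < cfg$min_length_nt |
      tx_n_exons(tx) < cfg$min_exons |
      (!is.na(tx$cov) & tx$cov < cfg$min_coverage) |
      tx$fpkm < cfg$min_fpkm,
    orf_filter = tx$max_orf_aa > cfg$max_orf_aa,
    coding_potential = (!is.na(tx$coding_probability) &
                          tx$coding_probability > cfg$coding_prob_threshold) |
      external_coding,
    homology = has_homology,
    scaffold_end = near_end,
    classification = !tx$class_code %in% names(CATEGORY_OF_CODE)
  )

  casualty_stage <- rep(NA_character_, nrow(tx))
  alive <- rep(TRUE, nrow(tx))
  report <- tibble::tibble(stage = CASCADE_STAGES,
                           input_n = NA_integer_, retained_n = NA_integer_)
  for (k in seq_along(CASCADE_STAGES)) {
    stage <- CASCADE_STAGES[k]
    report$input_n[k] <- sum(alive)
    died <- alive & fails[[stage]]
    casualty_stage[died] <- stage
    alive <- alive & !died
    report$retained_n[k] <- sum(alive)
  }

  records <- tx[alive, , drop = FALSE]
  records$category <- unname(CATEGORY_OF_CODE[records$class_code])
  casualties <- tibble::tibble(
    transcript_id = tx$transcript_id[!alive],
    casualty_stage = casualty_stage[!alive]
  )
  list(records = records,
       report = list(stages = report, casualties = casualties))
}

#' Per-transcript genomic feature statistics
#'
#' Computes the descriptive features used to compare lncRNAs with coding
#' transcripts: spliced length, exon count, exon/intron lengths, isoforms
#' per locus, maximum ORF length (nt), GC fraction of the spliced
#' sequence, the fraction of exonic bases covered by repeat intervals,
#' and the donor/acceptor dinucleotides of each intron in transcript
#' orientation (canonically `GT`/`AG`).
#'
#' @param tx Transcript tibble.
#' @param genome Named [Biostrings::DNAStringSet].
#' @param repeats Optional interval tibble (see [read_intervals()]); when
#'   `NULL` the repeat-overlap fraction is 0.
#' @return A tibble with one row per transcript; `exon_lengths`,
#'   `intron_lengths`, `splice_donors` and `splice_acceptors` are
#'   list-columns.
#' @export
transcript_features <- function(tx, genome, repeats = NULL) {
  validate_transcripts(tx)
  seqs <- spliced_sequence(tx, genome)
  gc <- purrr::map_dbl(seqs, function(s) {
    f <- Biostrings::alphabetFrequency(Biostrings::DNAString(s))
    acgt <- sum(f[c("A", "C", "G", "T")])
    if (acgt == 0) return(NA_real_)
    sum(f[c("G", "C")]) / acgt
  })
  orf <- find_max_orf(seqs)

  repeat_frac <- rep(0, nrow(tx))
  if (!is.null(repeats) && nrow(repeats) > 0) {
    rep_gr <- GenomicRanges::reduce(intervals_to_granges(repeats,
                                                         ignore_strand = TRUE))
    ex <- exon_granges(tx, ignore_strand = TRUE)
    hits <- GenomicRanges::findOverlaps(ex, rep_gr)
    if (length(hits) > 0) {
      ov <- GenomicRanges::pintersect(ex[S4Vectors::queryHits(hits)],
                                      rep_gr[S4Vectors::subjectHits(hits)])
      bp <- tapply(GenomicRanges::width(ov),
                   S4Vectors::mcols(ex)$tx[S4Vectors::queryHits(hits)], sum)
      repeat_frac[as.integer(names(bp))] <- as.numeric(bp)
    }
    repeat_frac <- repeat_frac / tx_spliced_length(tx)
  }

  introns <- purrr::map(tx$exons, exon_introns)
  donors_acceptors <- purrr::pmap(
    list(introns, tx$scaffold, tx$strand),
    function(intr, sc, st) {
      if (nrow(intr) == 0) {
        return(list(donor = character(0), acceptor = character(0)))
      }
      left <- as.character(Biostrings::extractAt(
        genome[[sc]], IRanges::IRanges(intr[, 1L] + 1L, intr[, 1L] + 2L)))
      right <- as.character(Biostrings::extractAt(
        genome[[sc]], IRanges::IRanges(intr[, 2L] - 1L, intr[, 2L])))
      if (st == "+") {
        list(donor = left, acceptor = right)
      } else {
        rc <- function(x) as.character(Biostrings::reverseComplement(
          Biostrings::DNAStringSet(x)))
        list(donor = rev(rc(right)), acceptor = rev(rc(left)))
      }
    }
  )

  tibble::tibble(
    transcript_id = tx$transcript_id,
    locus_id = tx$locus_id,
    spliced_length = tx_spliced_length(tx),
    n_exons = tx_n_exons(tx),
    exon_lengths = purrr::map(tx$exons, ~ as.integer(.x[, 2L] - .x[, 1L])),
    intron_lengths = purrr::map(introns, ~ as.integer(.x[, 2L] - .x[, 1L])),
    isoforms_per_locus = as.integer(table(tx$locus_id)[tx$locus_id]),
    max_orf_nt = orf$orf_nt,
    gc_fraction = unname(gc),
    repeat_overlap_fraction = repeat_frac,
    splice_donors = purrr::map(donors_acceptors, "donor"),
    splice_acceptors = purrr::map(donors_acceptors, "acceptor")
  )
}
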