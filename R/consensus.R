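#' Intron-chain identity key of multi-exon transcripts
#'
#' Two transcripts share a key iff they lie on the same scaffold and strand
#' and have identical ordered intron coordinates; terminal exon ends do not
#' enter the key. This is the merge identity used to collapse assemblies
#' from different programs and tissues into a unique transcript set.
#'
#' @param tx A transcript tibble. Single-exon transcripts are an error:
#'   they carry no intron chain and are excluded from the pipeline upstream.
#' @return A character vector of keys, one per row of `tx`.
#' @export
intron_chain_key <- function(tx) {
  single <- tx_n_exons(tx) < 2L
  if (any(single)) {
    rlang::abort(paste0("single-exon transcript(s) have no intron chain: ",
                        paste(utils::head(tx$transcript_id[single], 5),
                              collapse = ", ")))
  }
  purrr::pmap_chr(list(tx$exons, tx$scaffold, tx$strand),
                  function(e, sc, st) {
                    i <- exon_introns(e)
                    paste0(sc, st, ":",
                           paste(i[, 1L], i[, 2L], sep = "-", collapse = ","))
                  })
}

#' Tabulate (assembler, tissue) support per intron chain
#'
#' @param assemblies A tibble (or data frame) with columns `assembler`,
#'   `tissue` and a `transcripts` list-column of transcript tibbles, one row
#'   per assembled GTF.
#' @return A tibble with one row per witness transcript: original columns
#'   plus `assembler`, `tissue`, `chain_key` and a `support` list-column
#'   giving the distinct `"assembler|tissue"` tags observed for that chain
#'   across all assemblies.
#' @export
build_support <- function(assemblies) {
  if (nrow(assemblies) == 0) rlang::abort("no assemblies supplied")
  witnesses <- purrr::pmap(
    list(assemblies$assembler, assemblies$tissue, assemblies$transcripts),
    function(asm, tis, tx) {
      tx$assembler <- asm
      tx$tissue <- tis
      tx$chain_key <- intron_chain_key(tx)
      tx
    }
  ) |>
    purrr::list_rbind()
  support <- witnesses |>
    dplyr::distinct(.data$chain_key, .data$assembler, .data$tissue) |>
    dplyr::group_by(.data$chain_key) |>
    dplyr::summarise(
      support = list(sort(paste(.data$assembler, .data$tissue, sep = "|"))),
      .groups = "drop"
    )
  dplyr::left_join(witnesses, support, by = "chain_key")
}

#' Select stringent (consensus-supported) intron chains
#'
#' A chain is retained iff it was reported by at least two distinct
#' assembly programs or observed in at least two distinct tissues.
#' Duplicate observations within one (assembler, tissue) GTF count once.
#'
#' @param support Output of [build_support()].
#' @return The witness rows belonging to retained chains (all witnesses are
#'   kept so that [merge_transcripts()] can reconcile terminal exon ends).
#' @export
stringent_select <- function(support) {
  keep <- purrr::map_lgl(support$support, function(tags) {
    parts <- strsplit(tags, "|", fixed = TRUE)
    length(unique(purrr::map_chr(parts, 1))) >= 2 ||
      length(unique(purrr::map_chr(parts, 2))) >= 2
  })
  support[keep, , drop = FALSE]
}

## Union-find over transcripts linked by same-strand exonic overlap. Internal.
locus_components <- function(tx) {
  parent <- seq_len(nrow(tx))
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  eg <- exon_granges(tx)
  hits <- GenomicRanges::findOverlaps(eg, eg, ignore.strand = FALSE)
  a <- S4Vectors::mcols(eg)$tx[S4Vectors::queryHits(hits)]
  b <- S4Vectors::mcols(eg)$tx[S4Vectors::subjectHits(hits)]
  for (k in seq_along(a)) {
    ra <- find(a[k]); rb <- find(b[k])
    if (ra != rb) parent[ra] <- rb
  }
  vapply(seq_len(nrow(tx)), find, integer(1))
}

#' Merge witness transcripts into a unique transcript set
#'
#' Transcripts with identical intron-chain keys are collapsed into one
#' model whose terminal exon boundaries are the union over witnesses
#' (minimum start of the first exon, maximum end of the last). Locus ids
#' are assigned by single-linkage clustering of merged transcripts that
#' share same-strand exonic overlap; antisense overlap never joins loci.
#' Witness expression attributes are dropped: abundances are re-estimated
#' on the merged set from a separate quantification table.
#'
#' @param witnesses A transcript tibble; a `chain_key` column is computed if
#'   absent, a `support` list-column is unioned per chain if present.
#' @param id_prefix Prefix for the merged transcript and locus ids.
#' @return A transcript tibble with new ids `<prefix>_T<k>` /
#'   `<prefix>_L<k>`, `n_support` counts and the witness `support` tags.
#' @export
merge_transcripts <- function(witnesses, id_prefix = "LNCF") {
  if (nrow(witnesses) == 0) {
    return(transcript_tbl(transcript_id = character(0), scaffold = character(0),
                          strand = character(0), exons = list()))
  }
  if (!"chain_key" %in% names(witnesses)) {
    witnesses$chain_key <- intron_chain_key(witnesses)
  }
  if (!"support" %in% names(witnesses)) {
    witnesses$support <- purrr::map(seq_len(nrow(witnesses)), ~ character(0))
  }
  merged <- witnesses |>
    dplyr::group_by(.data$chain_key) |>
    dplyr::summarise(
      scaffold = .data$scaffold[1],
      strand = .data$strand[1],
      exons = {
        e <- .data$exons[[1]]
        e[1L, 1L] <- min(purrr::map_int(.data$exons, ~ .x[1L, 1L]))
        e[nrow(e), 2L] <- max(purrr::map_int(.data$exons, ~ .x[nrow(.x), 2L]))
        list(e)
      },
      support = list(sort(unique(unlist(.data$support)))),
      .groups = "drop"
    )
  ord <- order(merged$scaffold,
               purrr::map_int(merged$exons, ~ .x[1L, 1L]),
               purrr::map_int(merged$exons, ~ .x[nrow(.x), 2L]),
               merged$strand)
  merged <- merged[ord, ]
  merged$transcript_id <- sprintf("%s_T%06d", id_prefix, seq_len(nrow(merged)))
  comp <- locus_components(merged)
  locus_rank <- match(comp, unique(comp))
  merged$locus_id <- sprintf("%s_L%05d", id_prefix, locus_rank)
  merged$n_support <- lengths(merged$support)
  out <- dplyr::select(merged, "transcript_id", "locus_id", "scaffold",
                       "strand", "exons", "support", "n_support", "chain_key")
  validate_transcripts(out)
  out
}

#' Run the consensus step from an assembly manifest
#'
#' Convenience wrapper: read every GTF in the manifest, tabulate support,
#' apply the stringent rule and merge.
#'
#' @param manifest Tibble with columns `assembler`, `tissue`, `gtf_path`.
#' @param id_prefix Passed to [merge_transcripts()].
#' @return A list with the merged transcript tibble (`transcripts`) and a
#'   per-stage count tibble (`stats`).
#' @export
consensus_from_manifest <- function(manifest, id_prefix = "LNCF") {
  assemblies <- manifest |>
    dplyr::mutate(transcripts = purrr::map(.data$gtf_path, read_gtf)) |>
    dplyr::select("assembler", "tissue", "transcripts")
  support <- build_support(assemblies)
  stringent <- stringent_select(support)
  merged <- merge_transcripts(stringent, id_prefix = id_prefix)
  stats <- tibble::tibble(
    stage = c("assembled", "stringent", "merged"),
    n_transcripts = c(dplyr::n_distinct(support$chain_key),
                      dplyr::n_distinct(stringent$chain_key),
                      nrow(merged))
  )
  list(transcripts = merged, stats = stats)
}
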