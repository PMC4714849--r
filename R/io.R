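#' Read a genome FASTA into a sequence store
#'
#' Sequences are uppercased on read; characters outside `A/C/G/T/N` are
#' rejected.
#'
#' @param path Path to a (multi-record, wrapped or unwrapped) FASTA file.
#' @return A named [Biostrings::DNAStringSet].
#' @export
read_genome <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  seqs <- Biostrings::DNAStringSet(toupper(as.character(seqs)))
  freq <- Biostrings::alphabetFrequency(seqs)
  allowed <- c("A", "C", "G", "T", "N")
  extra <- rowSums(freq[, !colnames(freq) %in% allowed, drop = FALSE])
  if (any(extra > 0)) {
    rlang::abort(paste0("non-ACGTN characters in scaffold(s): ",
                        paste(names(seqs)[extra > 0], collapse = ", ")))
  }
  seqs
}

#' Read a scaffold length table
#'
#' @param path Two-column TSV (`name`, `length`), no header required.
#' @return A tibble with columns `name` and `length`.
#' @export
read_scaffold_lengths <- function(path) {
  df <- readr::read_tsv(path, col_names = c("name", "length"),
                        col_types = "ci", progress = FALSE)
  if (nrow(df) > 0 && (df$name[1] == "name" || is.na(df$length[1]))) {
    df <- df[-1, ]
    df$length <- as.integer(df$length)
  }
  if (any(df$length <= 0) || anyDuplicated(df$name)) {
    rlang::abort("scaffold lengths must be positive and names unique")
  }
  df
}

## Cheap structural scan so malformed GTF lines are reported with their line
## number before handing the file to rtracklayer. Internal.
check_gtf_lines <- function(path) {
  lines <- readLines(path)
  body <- !startsWith(lines, "#") & nzchar(lines)
  nf <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (any(nf < 9)) {
    bad <- which(body)[which(nf < 9)[1]]
    rlang::abort(paste0("malformed GTF line ", bad, " in ", path,
                        " (expected 9 tab-separated fields)"))
  }
  invisible(TRUE)
}

#' Read transcript models from a GTF file
#'
#' Only `exon` feature lines are used. GTF 1-based inclusive coordinates are
#' converted to the internal 0-based half-open convention. `cov`, `FPKM`
#' and `class_code` attributes are carried over when present. A missing
#' `gene_id` falls back to the `transcript_id` as locus id.
#'
#' @param path Path to a GTF file.
#' @param on_unstranded `"error"` (default) rejects transcripts with strand
#'   `"."`; `"drop"` removes them with a warning. Unoriented transcripts
#'   cannot be classified relative to a stranded reference.
#' @return A transcript tibble (see [transcript_tbl()]).
#' @export
read_gtf <- function(path, on_unstranded = c("error", "drop")) {
  on_unstranded <- match.arg(on_unstranded)
  if (!file.exists(path)) rlang::abort(paste0("GTF not found: ", path))
  check_gtf_lines(path)
  lines <- readLines(path)
  if (!any(!startsWith(lines, "#") & nzchar(lines))) {
    return(transcript_tbl(transcript_id = character(0), scaffold = character(0),
                          strand = character(0), exons = list()))
  }
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[S4Vectors::mcols(gr)$type == "exon"]
  if (length(gr) == 0) {
    return(transcript_tbl(transcript_id = character(0), scaffold = character(0),
                          strand = character(0), exons = list()))
  }
  mc <- S4Vectors::mcols(gr)
  df <- tibble::tibble(
    transcript_id = as.character(mc$transcript_id),
    gene_id = if ("gene_id" %in% names(mc)) as.character(mc$gene_id) else NA_character_,
    scaffold = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    cov = if ("cov" %in% names(mc)) suppressWarnings(as.numeric(mc$cov)) else NA_real_,
    fpkm = if ("FPKM" %in% names(mc)) suppressWarnings(as.numeric(mc$FPKM)) else NA_real_,
    class_code = if ("class_code" %in% names(mc)) as.character(mc$class_code) else NA_character_,
    category = if ("category" %in% names(mc)) as.character(mc$category) else NA_character_
  )
  if (anyNA(df$transcript_id)) {
    rlang::abort(paste0("exon line without transcript_id in ", path))
  }
  df$strand[df$strand == "*"] <- "."
  unstranded <- unique(df$transcript_id[df$strand == "."])
  if (length(unstranded) > 0) {
    if (on_unstranded == "error") {
      rlang::abort(paste0("unstranded transcript(s) in ", path, ": ",
                          paste(utils::head(unstranded, 5), collapse = ", ")))
    }
    rlang::warn(paste0("dropping ", length(unstranded),
                       " unstranded transcript(s)"))
    df <- df[!df$transcript_id %in% unstranded, ]
  }
  tx <- df |>
    dplyr::group_by(.data$transcript_id) |>
    dplyr::summarise(
      n_scaffold = dplyr::n_distinct(.data$scaffold),
      n_strand = dplyr::n_distinct(.data$strand),
      locus_id = dplyr::coalesce(.data$gene_id[1], .data$transcript_id[1]),
      scaffold = .data$scaffold[1],
      strand = .data$strand[1],
      exons = list(cbind(start = sort(.data$start),
                         end = .data$end[order(.data$start)])),
      cov = .data$cov[1],
      fpkm = .data$fpkm[1],
      class_code = .data$class_code[1],
      category = .data$category[1],
      .groups = "drop"
    )
  if (any(tx$n_scaffold > 1)) {
    rlang::abort(paste0("inconsistent scaffold for transcript(s): ",
                        paste(tx$transcript_id[tx$n_scaffold > 1], collapse = ", ")))
  }
  if (any(tx$n_strand > 1)) {
    rlang::abort(paste0("inconsistent strand for transcript(s): ",
                        paste(tx$transcript_id[tx$n_strand > 1], collapse = ", ")))
  }
  tx <- dplyr::select(tx, -"n_scaffold", -"n_strand")
  tx <- dplyr::relocate(tx, "transcript_id", "locus_id", "scaffold", "strand",
                        "exons")
  validate_transcripts(tx)
  tx
}

#' Write transcript models to a GTF file
#'
#' Emits one `exon` line per exon with 1-based inclusive coordinates.
#' `read_gtf()` of the written file reproduces the input on ids,
#' coordinates, strand and `class_code`.
#'
#' @param tx A transcript tibble.
#' @param path Output path.
#' @param source Value of the GTF source column.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(tx, path, source = "lncforge") {
  validate_transcripts(tx)
  lines <- character(0)
  if (nrow(tx) > 0) {
    n <- tx_n_exons(tx)
    idx <- rep.int(seq_len(nrow(tx)), n)
    mat <- do.call(rbind, tx$exons)
    attrs <- sprintf('gene_id "%s"; transcript_id "%s";',
                     tx$locus_id[idx], tx$transcript_id[idx])
    add_attr <- function(attrs, col, fmt) {
      if (!col %in% names(tx)) return(attrs)
      v <- tx[[col]][idx]
      has <- !is.na(v)
      attrs[has] <- paste0(attrs[has], sprintf(fmt, v[has]))
      attrs
    }
    attrs <- add_attr(attrs, "cov", ' cov "%.6f";')
    attrs <- add_attr(attrs, "fpkm", ' FPKM "%.6f";')
    attrs <- add_attr(attrs, "class_code", ' class_code "%s";')
    attrs <- add_attr(attrs, "category", ' category "%s";')
    lines <- paste(tx$scaffold[idx], source, "exon",
                   mat[, 1L] + 1L, mat[, 2L], ".", tx$strand[idx], ".",
                   attrs, sep = "\t")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read genomic intervals from BED or GFF3
#'
#' BED input (0-based half-open) and GFF3 input (1-based inclusive) are
#' unified into the internal 0-based half-open convention. GFF3 strand and
#' `Name` attributes are retained.
#'
#' @param path Path to the interval file.
#' @param format `"bed"` or `"gff3"`.
#' @return A tibble with columns `scaffold`, `start`, `end`, `strand`
#'   (`"+"`, `"-"` or `NA`) and `name`.
#' @export
read_intervals <- function(path, format = c("bed", "gff3")) {
  format <- match.arg(format)
  gr <- rtracklayer::import(path, format = format)
  strand <- as.character(GenomicRanges::strand(gr))
  strand[strand == "*"] <- NA_character_
  mc <- S4Vectors::mcols(gr)
  name <- if ("Name" %in% names(mc)) {
    as.character(mc$Name)
  } else if ("name" %in% names(mc)) {
    as.character(mc$name)
  } else {
    NA_character_
  }
  out <- tibble::tibble(
    scaffold = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = strand,
    name = name
  )
  if (any(out$end <= out$start)) {
    rlang::abort(paste0("empty interval (end <= start) in ", path))
  }
  out
}

## Interval tibble -> GRanges (1-based inclusive). Internal.
intervals_to_granges <- function(iv, ignore_strand = FALSE) {
  strand <- iv$strand
  if (ignore_strand || is.null(strand)) strand <- rep("*", nrow(iv))
  strand[is.na(strand)] <- "*"
  GenomicRanges::GRanges(
    seqnames = iv$scaffold,
    ranges = IRanges::IRanges(start = iv$start + 1L, end = iv$end),
    strand = strand
  )
}

#' Read an expression matrix with sample metadata
#'
#' @param expr_path TSV whose first column is `transcript_id` and remaining
#'   columns are samples.
#' @param samples_path TSV with columns `sample_id`, `tissue`, `sex`,
#'   `library_size`.
#' @return A list with a numeric `matrix` (transcripts x samples) and a
#'   `samples` tibble; metadata must cover every expression column.
#' @export
read_expression <- function(expr_path, samples_path) {
  expr <- readr::read_tsv(expr_path, col_types = readr::cols(
    transcript_id = readr::col_character(),
    .default = readr::col_double()
  ), progress = FALSE)
  mat <- as.matrix(expr[, -1, drop = FALSE])
  rownames(mat) <- expr$transcript_id
  samples <- readr::read_tsv(samples_path, col_types = readr::cols(
    sample_id = readr::col_character(),
    tissue = readr::col_character(),
    sex = readr::col_character(),
    library_size = readr::col_double()
  ), progress = FALSE)
  missing <- setdiff(colnames(mat), samples$sample_id)
  if (length(missing) > 0) {
    rlang::abort(paste0("samples without metadata: ",
                        paste(missing, collapse = ", ")))
  }
  if (any(mat < 0)) rlang::abort("negative expression values")
  list(matrix = mat,
       samples = samples[match(colnames(mat), samples$sample_id), ])
}
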