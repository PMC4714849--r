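#' Exact binomial test for sex-biased expression
#'
#' Under library-size-proportional sampling with no sex effect, the
#' female count of a transcript, conditional on the total, is binomial
#' with success probability `N_f / (N_f + N_m)`. The returned p-value is
#' the two-sided exact binomial test of that null; the fold change uses a
#' 0.5 pseudocount on the library-size-normalised counts, so
#' `log2FC = log2(((x_f + 0.5)/N_f) / ((x_m + 0.5)/N_m))` (female over
#' male).
#'
#' @param x_f,x_m Nonnegative integer read counts (vectorised).
#' @param n_f,n_m Positive library sizes.
#' @return A tibble with `log2fc` and `p` (`p = 1` when both counts are
#'   zero).
#' @export
sex_bias_test <- function(x_f, x_m, n_f, n_m) {
  if (any(x_f < 0) || any(x_m < 0)) rlang::abort("negative counts")
  if (any(n_f <= 0) || any(n_m <= 0)) rlang::abort("library sizes must be positive")
  k <- max(length(x_f), length(x_m))
  x_f <- rep_len(x_f, k); x_m <- rep_len(x_m, k)
  n_f <- rep_len(n_f, k); n_m <- rep_len(n_m, k)
  log2fc <- log2(((x_f + 0.5) / n_f) / ((x_m + 0.5) / n_m))
  p0 <- n_f / (n_f + n_m)
  p <- purrr::pmap_dbl(list(x_f, x_m, p0), function(f, m, pr) {
    if (f + m == 0) return(1)
    stats::binom.test(f, f + m, p = pr)$p.value
  })
  tibble::tibble(log2fc = log2fc, p = p)
}

#' Benjamini-Hochberg step-up false discovery rates
#'
#' @param pvals Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted q-values (clipped at 1, order-preserving).
#' @export
bh_fdr <- function(pvals) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) {
    rlang::abort("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvals, method = "BH")
}

#' Per-tissue sex-bias calls for a count matrix
#'
#' For every tissue sampled in both sexes, female and male counts (and
#' nominal library sizes) are pooled per sex, tested with
#' [sex_bias_test()], and corrected with [bh_fdr()] across transcripts
#' within the tissue. A transcript is called biased in a tissue iff
#' `|log2FC| > lfc_cutoff` and `q < fdr_cutoff`.
#'
#' @param counts Integer matrix (transcripts x samples) with rownames.
#' @param samples Sample metadata tibble with `sample_id`, `tissue`,
#'   `sex` (`"F"`/`"M"`) and `library_size`, one row per column of
#'   `counts`.
#' @param lfc_cutoff,fdr_cutoff Decision thresholds (defaults
#'   `|log2FC| > 1`, `FDR < 0.05`).
#' @return A tibble with `transcript_id`, `tissue`, `log2fc`, `p`, `q`
#'   and `call` in `female_biased` / `male_biased` / `unbiased`.
#' @export
sex_bias_table <- function(counts, samples, lfc_cutoff = 1,
                           fdr_cutoff = 0.05) {
  stopifnot(ncol(counts) == nrow(samples))
  tissues <- unique(samples$tissue)
  out <- purrr::map(tissues, function(tis) {
    f <- samples$sample_id[samples$tissue == tis & samples$sex == "F"]
    m <- samples$sample_id[samples$tissue == tis & samples$sex == "M"]
    if (length(f) == 0 || length(m) == 0) return(NULL)
    x_f <- rowSums(counts[, f, drop = FALSE])
    x_m <- rowSums(counts[, m, drop = FALSE])
    n_f <- sum(samples$library_size[samples$sample_id %in% f])
    n_m <- sum(samples$library_size[samples$sample_id %in% m])
    res <- sex_bias_test(x_f, x_m, n_f, n_m)
    res$q <- bh_fdr(res$p)
    tibble::tibble(
      transcript_id = rownames(counts), tissue = tis,
      log2fc = res$log2fc, p = res$p, q = res$q,
      call = dplyr::case_when(
        abs(res$log2fc) > lfc_cutoff & res$q < fdr_cutoff & res$log2fc > 0 ~
          "female_biased",
        abs(res$log2fc) > lfc_cutoff & res$q < fdr_cutoff ~ "male_biased",
        .default = "unbiased"
      )
    )
  })
  purrr::list_rbind(purrr::compact(out))
}

#' Locus-level sex-bias ratio
#'
#' Rolls transcript-level calls up to gene loci: an isoform counts as
#' biased if it is biased in any tissue; the locus ratio is the biased
#' fraction of its isoforms. Multi-isoform loci are called sex-biased iff
#' the ratio strictly exceeds `ratio_cutoff`; a single-isoform locus
#' inherits its isoform's call.
#'
#' @param calls Tibble with columns `locus_id`, `transcript_id` and
#'   either a logical `biased` column or the `call` column of
#'   [sex_bias_table()] (possibly with several rows per transcript, one
#'   per tissue).
#' @param ratio_cutoff Strict lower bound for multi-isoform loci
#'   (default 0.75).
#' @return A tibble with `locus_id`, `n_isoforms`, `n_biased`, `ratio`
#'   and logical `locus_biased`.
#' @export
locus_sex_bias_ratio <- function(calls, ratio_cutoff = 0.75) {
  if (nrow(calls) == 0) rlang::abort("empty locus table")
  if (!"biased" %in% names(calls)) {
    calls$biased <- calls$call != "unbiased"
  }
  calls |>
    dplyr::group_by(.data$locus_id, .data$transcript_id) |>
    dplyr::summarise(biased = any(.data$biased), .groups = "drop") |>
    dplyr::group_by(.data$locus_id) |>
    dplyr::summarise(
      n_isoforms = dplyr::n(),
      n_biased = sum(.data$biased),
      ratio = .data$n_biased / .data$n_isoforms,
      locus_biased = ifelse(.data$n_isoforms == 1, .data$n_biased == 1,
                            .data$ratio > ratio_cutoff),
      .groups = "drop"
    )
}
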