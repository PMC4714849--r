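#' Jensen-Shannon tissue-specificity scores
#'
#' For each transcript the expression profile across tissues is
#' normalised to a probability vector `p`; the specificity to tissue `t`
#' is `1 - sqrt(JSD(p, e_t))`, where `e_t` is the unit profile of tissue
#' `t` and the Jensen-Shannon divergence uses log base 2 (so JSD, and
#' hence every score, lies in `[0, 1]`). The transcript's JS score is the
#' maximum over tissues; it is 1 exactly when the transcript is expressed
#' in a single tissue and approaches 0 for a uniform profile.
#'
#' @param profiles Numeric matrix (transcripts x tissues, >= 2 tissues)
#'   with transcript ids as rownames, or a tibble whose first column is
#'   `transcript_id`. Entries must be nonnegative; positive rescaling of a
#'   row does not change its scores.
#' @return A tibble with `transcript_id`, `js_score`, `js_tissue`,
#'   `all_zero` (profiles summing to zero are flagged and get `NA`
#'   scores), and a `specificity` list-column of per-tissue score vectors.
#' @export
js_specificity <- function(profiles) {
  if (is.data.frame(profiles)) {
    mat <- as.matrix(profiles[, -1, drop = FALSE])
    rownames(mat) <- profiles[[1]]
  } else {
    mat <- as.matrix(profiles)
  }
  if (ncol(mat) < 2) rlang::abort("need at least 2 tissues")
  if (any(mat < 0)) rlang::abort("negative expression values")
  tissues <- colnames(mat)
  if (is.null(tissues)) tissues <- paste0("tissue", seq_len(ncol(mat)))
  ids <- rownames(mat)
  if (is.null(ids)) ids <- paste0("t", seq_len(nrow(mat)))

  tot <- rowSums(mat)
  all_zero <- tot == 0
  p <- mat / ifelse(tot == 0, 1, tot)
  xlog2x <- function(v) ifelse(v > 0, v * log2(v), 0)
  h_p <- -rowSums(xlog2x(p))
  scores <- matrix(NA_real_, nrow(mat), ncol(mat),
                   dimnames = list(ids, tissues))
  for (t in seq_len(ncol(mat))) {
    m <- p / 2
    m[, t] <- m[, t] + 0.5
    h_m <- -rowSums(xlog2x(m))
    jsd <- pmax(h_m - h_p / 2, 0)
    scores[, t] <- 1 - sqrt(jsd)
  }
  scores[all_zero, ] <- NA_real_
  best <- apply(scores, 1, function(r) {
    if (anyNA(r)) NA_integer_ else which.max(r)
  })
  tibble::tibble(
    transcript_id = ids,
    js_score = unname(ifelse(all_zero, NA_real_,
                             scores[cbind(seq_along(best),
                                          ifelse(is.na(best), 1L, best))])),
    js_tissue = unname(ifelse(all_zero, NA_character_, tissues[best])),
    all_zero = unname(all_zero),
    specificity = purrr::map(seq_len(nrow(scores)), ~ scores[.x, ])
  )
}

#' Call tissue-specific transcripts from JS scores
#'
#' @param results Output of [js_specificity()].
#' @param cutoff JS score cutoff (default 0.25).
#' @param strict Use a strict `>` comparison at the boundary (default);
#'   `FALSE` uses `>=`.
#' @return `results` with an added logical `tissue_specific` column
#'   (`NA` for all-zero profiles).
#' @export
classify_tissue_specific <- function(results, cutoff = 0.25, strict = TRUE) {
  cmp <- if (strict) `>` else `>=`
  dplyr::mutate(results, tissue_specific = cmp(.data$js_score, cutoff))
}
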