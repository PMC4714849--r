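## Fickett (1982) TESTCODE lookup tables: probability that a window with a
## given position-asymmetry or composition value is coding, and the weight
## (discriminative value) of each of the eight components. Bins are indexed
## from the highest threshold downwards.
FICKETT_POSITION_PARAM <- c(1.9, 1.8, 1.7, 1.6, 1.5, 1.4, 1.3, 1.2, 1.1, 0.0)
FICKETT_CONTENT_PARAM <- c(0.33, 0.31, 0.29, 0.27, 0.25, 0.23, 0.21, 0.19, 0.17, 0.0)

FICKETT_POSITION_PROB <- list(
  A = c(0.94, 0.68, 0.84, 0.93, 0.58, 0.68, 0.45, 0.34, 0.20, 0.22),
  C = c(0.80, 0.70, 0.70, 0.81, 0.66, 0.48, 0.51, 0.33, 0.30, 0.23),
  G = c(0.90, 0.88, 0.74, 0.64, 0.53, 0.48, 0.27, 0.16, 0.08, 0.08),
  T = c(0.97, 0.97, 0.91, 0.68, 0.69, 0.44, 0.54, 0.20, 0.09, 0.09)
)
FICKETT_POSITION_WEIGHT <- c(A = 0.26, C = 0.18, G = 0.31, T = 0.33)

FICKETT_CONTENT_PROB <- list(
  A = c(0.28, 0.49, 0.44, 0.55, 0.62, 0.49, 0.67, 0.65, 0.81, 0.21),
  C = c(0.82, 0.64, 0.51, 0.64, 0.59, 0.59, 0.43, 0.44, 0.39, 0.31),
  G = c(0.40, 0.54, 0.47, 0.64, 0.64, 0.73, 0.41, 0.41, 0.33, 0.29),
  T = c(0.28, 0.24, 0.39, 0.40, 0.55, 0.75, 0.56, 0.69, 0.51, 0.58)
)
FICKETT_CONTENT_WEIGHT <- c(A = 0.11, C = 0.12, G = 0.15, T = 0.14)

#' Fickett TESTCODE statistic
#'
#' Deterministic coding-potential component built from the published
#' TESTCODE position-asymmetry and composition lookup tables. For each
#' base, the position value is the maximum codon-phase count divided by
#' the minimum plus one, and the content value is the base's fraction of
#' counted (`A/C/G/T`) characters; each value is binned against the
#' published thresholds and contributes its table probability times its
#' weight. Case-insensitive; `N` characters are not counted.
#'
#' @param seqs Character vector of DNA sequences, each at least 200 nt
#'   (shorter input is an error, consistent with the upstream length
#'   filter).
#' @return Numeric vector of TESTCODE scores.
#' @export
fickett_score <- function(seqs) {
  if (any(nchar(seqs) < 200)) {
    rlang::abort("fickett_score requires sequences of at least 200 nt")
  }
  vapply(seqs, function(s) {
    chars <- strsplit(toupper(s), "", fixed = TRUE)[[1]]
    score <- 0
    total <- sum(chars %in% c("A", "C", "G", "T"))
    if (total == 0) return(0)
    phase <- (seq_along(chars) - 1L) %% 3L
    for (base in c("A", "C", "G", "T")) {
      at <- chars == base
      phase_counts <- vapply(0:2, function(p) sum(at & phase == p), numeric(1))
      pos_val <- max(phase_counts) / (min(phase_counts) + 1)
      pos_bin <- which(pos_val >= FICKETT_POSITION_PARAM)[1]
      score <- score + FICKETT_POSITION_PROB[[base]][pos_bin] *
        FICKETT_POSITION_WEIGHT[[base]]
      cont_val <- sum(at) / total
      cont_bin <- which(cont_val >= FICKETT_CONTENT_PARAM)[1]
      score <- score + FICKETT_CONTENT_PROB[[base]][cont_bin] *
        FICKETT_CONTENT_WEIGHT[[base]]
    }
    score
  }, numeric(1), USE.NAMES = FALSE)
}
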