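## Rank-based AUC of scores against binary labels. Internal.
rank_auc <- function(scores, labels) {
  n1 <- sum(labels)
  n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Compute coding-potential features for transcript sequences
#'
#' The four features of the in-house scorer: maximal complete ORF length
#' in nucleotides, ORF coverage (ORF length over transcript length),
#' Fickett TESTCODE score of the full sequence, and the mean in-frame
#' hexamer log-likelihood ratio of the maximal ORF.
#'
#' @param seqs Character vector of spliced transcript sequences (>= 200 nt).
#' @param table A [build_hexamer_table()] object.
#' @return A tibble with columns `max_orf_nt`, `orf_coverage`, `fickett`,
#'   `hexamer_llr`.
#' @export
coding_features <- function(seqs, table) {
  orf <- find_max_orf(seqs)
  tibble::tibble(
    max_orf_nt = orf$orf_nt,
    orf_coverage = orf$orf_nt / nchar(seqs),
    fickett = fickett_score(seqs),
    hexamer_llr = hexamer_llr(seqs, table, orf = orf)
  )
}

#' Fit the logistic coding-potential model
#'
#' Standardises the four features and fits a logistic regression of
#' coding status; a held-out split (stratified random by `seed`) is used
#' to report the area under the ROC curve. The default decision boundary
#' (probability 0.345) is kept for comparability with published
#' coding-potential assessment tools; it was calibrated on their original
#' training corpora, so `recalibrate = TRUE` replaces it with the
#' Youden-optimal threshold on the held-out split.
#'
#' @param features Tibble from [coding_features()].
#' @param labels Logical vector, `TRUE` for coding examples.
#' @param seed Integer seed controlling the train/test split.
#' @param holdout Fraction of examples held out for evaluation.
#' @param threshold Decision boundary on the coding probability.
#' @param recalibrate Replace `threshold` with the Youden-optimal point on
#'   the held-out data.
#' @return A `coding_model` object (coefficients, feature means/scales,
#'   threshold, held-out AUC).
#' @export
fit_coding_model <- function(features, labels, seed = 1, holdout = 0.25,
                             threshold = 0.345, recalibrate = FALSE) {
  stopifnot(nrow(features) == length(labels))
  if (length(unique(labels)) < 2) {
    rlang::abort("need both coding and noncoding examples")
  }
  x <- as.matrix(features[, c("max_orf_nt", "orf_coverage", "fickett",
                              "hexamer_llr")])
  center <- colMeans(x)
  scale <- apply(x, 2, stats::sd)
  scale[scale == 0] <- 1
  z <- sweep(sweep(x, 2, center), 2, scale, "/")

  test_idx <- withr::with_seed(seed, {
    idx1 <- which(labels)
    idx0 <- which(!labels)
    c(sample(idx1, max(1, round(length(idx1) * holdout))),
      sample(idx0, max(1, round(length(idx0) * holdout))))
  })
  train <- setdiff(seq_along(labels), test_idx)
  df <- data.frame(y = as.numeric(labels), z)
  fit <- suppressWarnings(
    stats::glm(y ~ ., data = df[train, ], family = stats::binomial())
  )
  prob_test <- stats::predict(fit, newdata = df[test_idx, ],
                              type = "response")
  auc <- rank_auc(prob_test, labels[test_idx])
  if (recalibrate) {
    cand <- sort(unique(prob_test))
    youden <- vapply(cand, function(t) {
      mean(prob_test[labels[test_idx]] > t) -
        mean(prob_test[!labels[test_idx]] > t)
    }, numeric(1))
    threshold <- cand[which.max(youden)]
  }
  structure(
    list(coef = stats::coef(fit), center = center, scale = scale,
         threshold = threshold, auc_holdout = auc, seed = seed,
         n_train = length(train), n_test = length(test_idx)),
    class = "coding_model"
  )
}

#' @export
print.coding_model <- function(x, ...) {
  cat("<coding_model> logistic regression on 4 features; held-out AUC",
      sprintf("%.3f", x$auc_holdout), "; threshold", x$threshold, "\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname fit_coding_model
#' @param x A `coding_model`.
#' @param ... Unused.
#' @method tidy coding_model
#' @export
tidy.coding_model <- function(x, ...) {
  tibble::tibble(term = names(x$coef), estimate = unname(x$coef))
}

#' @rdname fit_coding_model
#' @method glance coding_model
#' @export
glance.coding_model <- function(x, ...) {
  tibble::tibble(auc_holdout = x$auc_holdout, threshold = x$threshold,
                 n_train = x$n_train, n_test = x$n_test)
}

#' Score transcript sequences with a fitted coding-potential model
#'
#' @param seqs Character vector of spliced sequences (>= 200 nt).
#' @param model A [fit_coding_model()] object.
#' @param table The [build_hexamer_table()] used for the features.
#' @return A tibble with the four features, `coding_probability` in
#'   `[0, 1]` and the boolean `coding_call`
#'   (`coding_probability > model$threshold`).
#' @export
coding_probability <- function(seqs, model, table) {
  if (!inherits(model, "coding_model")) {
    rlang::abort("model must be a fitted coding_model")
  }
  feats <- coding_features(seqs, table)
  z <- sweep(sweep(as.matrix(feats), 2, model$center), 2, model$scale, "/")
  eta <- model$coef[1] + as.vector(z %*% model$coef[-1])
  prob <- stats::plogis(eta)
  dplyr::mutate(feats, coding_probability = prob,
                coding_call = prob > model$threshold)
}

#' Serialise / restore a coding model as JSON
#'
#' @param model A `coding_model`.
#' @param path Output (input) path.
#' @return `path` invisibly; `read_coding_model()` returns the model.
#' @export
write_coding_model <- function(model, path) {
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_coding_model
#' @export
read_coding_model <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$coef <- unlist(raw$coef)
  raw$center <- unlist(raw$center)
  raw$scale <- unlist(raw$scale)
  structure(raw, class = "coding_model")
}
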