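# Independent brute-force oracles used to check the package's
# implementations. These deliberately share no code with R/.

## Longest stop-terminated ORF by explicit enumeration of every ATG in
## every forward frame.
orf_oracle <- function(s) {
  s <- toupper(s)
  chars <- strsplit(s, "")[[1]]
  best <- list(aa = 0L, start = NA_integer_, frame = NA_integer_)
  for (start in seq_len(max(length(chars) - 2, 0))) {
    if (paste(chars[start:(start + 2)], collapse = "") != "ATG") next
    pos <- start + 3
    aa <- 1L
    while (pos + 2 <= length(chars)) {
      codon <- paste(chars[pos:(pos + 2)], collapse = "")
      if (codon %in% c("TAA", "TAG", "TGA")) {
        if (aa > best$aa ||
            (aa == best$aa && !is.na(best$start) && start - 1 < best$start)) {
          best <- list(aa = aa, start = start - 1L, frame = (start - 1L) %% 3L)
        }
        aa <- -1L
        break
      }
      aa <- aa + 1L
      pos <- pos + 3
    }
  }
  best
}

## Straight-from-the-tables TESTCODE reimplementation (scalar, loop-based).
fickett_oracle <- function(s) {
  pos_param <- c(1.9, 1.8, 1.7, 1.6, 1.5, 1.4, 1.3, 1.2, 1.1, 0.0)
  con_param <- c(0.33, 0.31, 0.29, 0.27, 0.25, 0.23, 0.21, 0.19, 0.17, 0.0)
  pos_prob <- list(
    A = c(0.94, 0.68, 0.84, 0.93, 0.58, 0.68, 0.45, 0.34, 0.20, 0.22),
    C = c(0.80, 0.70, 0.70, 0.81, 0.66, 0.48, 0.51, 0.33, 0.30, 0.23),
    G = c(0.90, 0.88, 0.74, 0.64, 0.53, 0.48, 0.27, 0.16, 0.08, 0.08),
    T = c(0.97, 0.97, 0.91, 0.68, 0.69, 0.44, 0.54, 0.20, 0.09, 0.09))
  pos_w <- c(A = 0.26, C = 0.18, G = 0.31, T = 0.33)
  con_prob <- list(
    A = c(0.28, 0.49, 0.44, 0.55, 0.62, 0.49, 0.67, 0.65, 0.81, 0.21),
    C = c(0.82, 0.64, 0.51, 0.64, 0.59, 0.59, 0.43, 0.44, 0.39, 0.31),
    G = c(0.40, 0.54, 0.47, 0.64, 0.64, 0.73, 0.41, 0.41, 0.33, 0.29),
    T = c(0.28, 0.24, 0.39, 0.40, 0.55, 0.75, 0.56, 0.69, 0.51, 0.58))
  con_w <- c(A = 0.11, C = 0.12, G = 0.15, T = 0.14)
  chars <- strsplit(toupper(s), "")[[1]]
  total <- sum(chars %in% c("A", "C", "G", "T"))
  out <- 0
  for (b in c("A", "C", "G", "T")) {
    counts <- c(0, 0, 0)
    for (i in seq_along(chars)) {
      if (chars[i] == b) counts[(i - 1) %% 3 + 1] <- counts[(i - 1) %% 3 + 1] + 1
    }
    pv <- max(counts) / (min(counts) + 1)
    for (j in 1:10) if (pv >= pos_param[j]) break
    out <- out + pos_prob[[b]][j] * pos_w[[b]]
    cv <- sum(chars == b) / total
    for (j in 1:10) if (cv >= con_param[j]) break
    out <- out + con_prob[[b]][j] * con_w[[b]]
  }
  out
}

## Direct per-hexamer summation of the in-frame log ratio of the max ORF
## (frame 0 of the whole sequence when there is no complete ORF).
hexamer_llr_oracle <- function(s, table) {
  s <- toupper(s)
  o <- orf_oracle(s)
  if (o$aa > 0) {
    from <- o$start + 1
    to <- o$start + 3 * (o$aa + 1)
  } else {
    from <- 1
    to <- nchar(s)
  }
  tot <- 0
  nh <- 0
  i <- from
  while (i + 5 <= to) {
    h <- substr(s, i, i + 5)
    if (!grepl("[^ACGT]", h)) {
      tot <- tot + log(table$f_coding[[h]] / table$f_noncoding[[h]])
      nh <- nh + 1
    }
    i <- i + 3
  }
  if (nh == 0) 0 else tot / nh
}

rc <- function(x) {
  chartr("ACGTU", "TGCAA",
         paste(rev(strsplit(toupper(x), "")[[1]]), collapse = ""))
}

## Exhaustive seed-site enumeration: slide over every position of the
## target and test each site type by direct string comparison.
mre_oracle <- function(lnc, mir) {
  lnc <- toupper(lnc)
  mir <- chartr("U", "T", toupper(mir))
  core <- rc(substr(mir, 2, 7))
  m8 <- rc(substr(mir, 8, 8))
  hits <- list()
  for (s in 0:(nchar(lnc) - 6)) {
    if (substr(lnc, s + 1, s + 6) != core) next
    has_m8 <- s >= 1 && substr(lnc, s, s) == m8
    has_a1 <- s + 6 < nchar(lnc) && substr(lnc, s + 7, s + 7) == "A"
    type <- if (has_m8 && has_a1) "8mer" else if (has_m8) "7mer-m8" else
      if (has_a1) "7mer-A1" else "6mer"
    hits[[length(hits) + 1]] <- data.frame(
      start = if (has_m8) s - 1L else s,
      end = if (has_a1) s + 7L else s + 6L,
      site_type = type)
  }
  if (length(hits) == 0) {
    data.frame(start = integer(0), end = integer(0),
               site_type = character(0))
  } else {
    do.call(rbind, hits)
  }
}

## Textbook BH step-up: q_i = min over j with p_j >= p_i of m p_j / rank_j.
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    vals <- vapply(seq_len(m), function(j) {
      if (p[ord[j]] >= p[ord[i]]) m * p[ord[j]] / j else Inf
    }, numeric(1))
    q[ord[i]] <- min(1, min(vals))
  }
  q
}

## Upper-tail hypergeometric by full summation of the PMF.
hyper_tail_oracle <- function(k, K, N, n) {
  upper <- min(K, n)
  if (k > upper) return(0)
  sum(vapply(k:upper, function(x) {
    choose(K, x) * choose(N - K, n - x) / choose(N, n)
  }, numeric(1)))
}

random_dna <- function(n, p = c(0.3, 0.2, 0.2, 0.3)) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p),
        collapse = "")
}
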