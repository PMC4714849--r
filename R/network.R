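MODULE_COLORS <- c(
  "turquoise", "blue", "brown", "yellow", "green", "red", "black", "pink",
  "magenta", "purple", "greenyellow", "tan", "salmon", "cyan",
  "midnightblue", "lightcyan", "grey60", "lightgreen", "lightyellow",
  "royalblue", "darkred", "darkgreen", "darkturquoise", "darkgrey",
  "orange", "darkorange", "skyblue", "saddlebrown", "steelblue", "violet"
)

#' Filter an expression matrix for network construction
#'
#' Keeps transcripts expressed (nonzero) in at least `min_samples`
#' samples and with nonzero variance, the entry rule for co-expression
#' analysis.
#'
#' @param expr Numeric matrix, transcripts x samples.
#' @param min_samples Minimum number of samples with nonzero expression.
#' @return The filtered matrix; dropped transcripts are reported in a
#'   message.
#' @export
filter_expressed <- function(expr, min_samples = 2) {
  keep <- rowSums(expr > 0) >= min_samples & apply(expr, 1, stats::sd) > 0
  if (any(!keep)) {
    rlang::inform(paste0("dropping ", sum(!keep),
                         " unexpressed or zero-variance transcript(s)"))
  }
  expr[keep, , drop = FALSE]
}

#' Soft-thresholded co-expression adjacency
#'
#' Unsigned weighted network: `a_ij = |cor(x_i, x_j)|^beta` with Pearson
#' correlation across samples and soft-thresholding power `beta`
#' (default 9). The diagonal is stored as 1 but excluded from
#' connectivity.
#'
#' @param expr Numeric matrix, transcripts x samples (>= 4 samples);
#'   zero-variance transcripts must be removed first (see
#'   [filter_expressed()]).
#' @param beta Soft-thresholding power.
#' @return A symmetric adjacency matrix in `[0, 1]` with attribute
#'   `beta`.
#' @export
adjacency_from_expression <- function(expr, beta = 9) {
  if (ncol(expr) < 4) rlang::abort("need at least 4 samples")
  sds <- apply(expr, 1, stats::sd)
  if (any(sds == 0)) {
    rlang::abort("zero-variance transcript(s) in expression matrix")
  }
  a <- abs(stats::cor(t(expr)))^beta
  diag(a) <- 1
  attr(a, "beta") <- beta
  a
}

#' Topological overlap matrix
#'
#' `TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with shared
#' neighbourhood `l_ij = sum_{u != i,j} a_iu a_uj` and connectivity
#' `k_i = sum_{u != i} a_iu`; `TOM_ii = 1`. Values lie in `[0, 1]` and
#' equal the adjacency when nodes share no neighbours.
#'
#' @param a Adjacency matrix from [adjacency_from_expression()].
#' @return The TOM matrix.
#' @export
tom_matrix <- function(a) {
  k <- rowSums(a) - 1
  l <- a %*% a - 2 * a        # removes the u = i and u = j terms (diag 1)
  kmin <- outer(k, k, pmin)
  tom <- (l + a) / (kmin + 1 - a)
  diag(tom) <- 1
  dimnames(tom) <- dimnames(a)
  tom
}

#' Detect co-expression modules by hierarchical clustering
#'
#' Average-linkage hierarchical clustering of the topological overlap
#' dissimilarity `1 - TOM`, cut statically at `cut_height`; clusters
#' smaller than `min_module_size` fall into the unassigned `"grey"` bin.
#' Deterministic given its input. Modules are labelled by colour in
#' decreasing size order.
#'
#' @param tom TOM matrix with transcript dimnames.
#' @param min_module_size Smallest retained module (default 30).
#' @param cut_height Static tree-cut height on `1 - TOM` (default 0.995).
#' @return A tibble with `transcript_id` and `module`.
#' @export
detect_modules <- function(tom, min_module_size = 30, cut_height = 0.995) {
  ids <- rownames(tom)
  if (is.null(ids)) ids <- paste0("t", seq_len(nrow(tom)))
  hc <- stats::hclust(stats::as.dist(1 - tom), method = "average")
  cl <- stats::cutree(hc, h = cut_height)
  sizes <- table(cl)
  big <- names(sizes)[sizes >= min_module_size]
  ord <- big[order(-sizes[big], as.integer(big))]
  labels <- rep("grey", length(cl))
  for (i in seq_along(ord)) {
    lab <- if (i <= length(MODULE_COLORS)) MODULE_COLORS[i] else paste0("module", i)
    labels[cl == as.integer(ord[i])] <- lab
  }
  tibble::tibble(transcript_id = ids, module = labels)
}

## First-PC eigengene of one module's expression submatrix, sign-oriented
## so the mean member correlation is positive, unit norm. Internal.
module_eigengene <- function(expr_members) {
  z <- t(scale(t(expr_members)))
  if (nrow(expr_members) == 1) {
    me <- as.vector(z)
    me <- me / sqrt(sum(me^2))
    return(me)
  }
  sv <- svd(t(z), nu = 1, nv = 0)
  me <- sv$u[, 1]
  if (sum(stats::cor(me, t(expr_members))) < 0) me <- -me
  me
}

#' Module eigengenes with correlated-module merging
#'
#' Computes each module's eigengene (first principal component of the
#' standardised member expression, sign-oriented so that the mean member
#' correlation is positive) and iteratively merges the most correlated
#' module pair while any eigengene correlation exceeds `merge_cor`,
#' recomputing eigengenes after every merge. The `"grey"` bin never
#' merges.
#'
#' @param expr Numeric matrix, transcripts x samples.
#' @param assignment Tibble from [detect_modules()].
#' @param merge_cor Eigengene correlation above which modules merge
#'   (default 0.70).
#' @return A list: `modules` (possibly relabelled assignment),
#'   `eigengenes` (samples x modules matrix, unit-norm columns) and
#'   `merges` (tibble of performed merges).
#' @export
module_eigengene_and_merge <- function(expr, assignment, merge_cor = 0.70) {
  stopifnot(all(assignment$transcript_id %in% rownames(expr)))
  labels <- stats::setNames(assignment$module, assignment$transcript_id)
  merges <- tibble::tibble(from = character(0), into = character(0),
                           cor = numeric(0))
  repeat {
    mods <- setdiff(unique(labels), "grey")
    if (length(mods) == 0) {
      rlang::abort("no non-grey module to compute eigengenes for")
    }
    mes <- vapply(mods, function(m) {
      module_eigengene(expr[names(labels)[labels == m], , drop = FALSE])
    }, numeric(ncol(expr)))
    colnames(mes) <- mods
    if (length(mods) == 1) break
    cc <- stats::cor(mes)
    diag(cc) <- -Inf
    top <- which(cc == max(cc), arr.ind = TRUE)[1, ]
    if (cc[top[1], top[2]] <= merge_cor) break
    keep <- mods[min(top)]
    gone <- mods[max(top)]
    sizes <- table(labels)
    if (sizes[gone] > sizes[keep]) {
      tmp <- keep; keep <- gone; gone <- tmp
    }
    labels[labels == gone] <- keep
    merges <- dplyr::bind_rows(merges,
                               tibble::tibble(from = gone, into = keep,
                                              cor = cc[top[1], top[2]]))
  }
  rownames(mes) <- colnames(expr)
  list(
    modules = tibble::tibble(transcript_id = names(labels),
                             module = unname(labels)),
    eigengenes = mes,
    merges = merges
  )
}

#' Module membership (kME) and module-trait correlation
#'
#' kME is the Pearson correlation of each transcript's profile with each
#' module eigengene; module-trait association is the Pearson correlation
#' of the eigengene with a per-sample binary trait indicator, with the
#' two-sided p-value from `t = r * sqrt(n - 2) / sqrt(1 - r^2)` on
#' `n - 2` degrees of freedom.
#'
#' @param expr Numeric matrix, transcripts x samples.
#' @param eigengenes Samples x modules matrix from
#'   [module_eigengene_and_merge()].
#' @param traits Data frame or matrix of per-sample numeric (usually 0/1)
#'   trait columns, rows aligned to the columns of `expr`.
#' @return A list: `kme` (tibble `transcript_id`, `module`, `kme`) and
#'   `module_trait` (tibble `module`, `trait`, `r`, `p`).
#' @export
kme_and_trait_correlation <- function(expr, eigengenes, traits = NULL) {
  kme_mat <- stats::cor(t(expr), eigengenes)
  kme <- tibble::as_tibble(kme_mat, rownames = "transcript_id") |>
    tidyr::pivot_longer(-"transcript_id", names_to = "module",
                        values_to = "kme")
  module_trait <- NULL
  if (!is.null(traits)) {
    traits <- as.matrix(traits)
    stopifnot(nrow(traits) == nrow(eigengenes))
    if (any(apply(traits, 2, stats::sd) == 0)) {
      rlang::abort("constant trait column")
    }
    n <- nrow(traits)
    r <- stats::cor(eigengenes, traits)
    tstat <- r * sqrt(n - 2) / sqrt(pmax(1 - r^2, .Machine$double.eps))
    p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
    p[abs(r) >= 1] <- 0
    p[r == 0] <- 1
    module_trait <- tibble::as_tibble(r, rownames = "module") |>
      tidyr::pivot_longer(-"module", names_to = "trait", values_to = "r") |>
      dplyr::left_join(
        tibble::as_tibble(p, rownames = "module") |>
          tidyr::pivot_longer(-"module", names_to = "trait",
                              values_to = "p"),
        by = c("module", "trait")
      )
  }
  list(kme = kme, module_trait = module_trait)
}

#' Hypergeometric term enrichment of module members
#'
#' Upper-tail hypergeometric test `P(X >= k)` for `k` term members in the
#' module, term size `K`, universe size `N` and module size `n`, with
#' Benjamini-Hochberg correction across terms; a term is enriched iff
#' `q < 0.05`.
#'
#' @param members Character vector of module member gene ids.
#' @param term2gene Tibble with columns `term_id`, `gene_id` (optionally
#'   `description`).
#' @param universe Character vector of all analysed gene ids (must
#'   contain every term gene and every member).
#' @return A tibble with `term_id`, `k`, `K`, `n`, `N`, `p`, `q`,
#'   `enriched`.
#' @export
hypergeometric_enrichment <- function(members, term2gene, universe) {
  if (!all(term2gene$gene_id %in% universe)) {
    rlang::abort("term gene(s) absent from universe")
  }
  if (!all(members %in% universe)) {
    rlang::abort("module member(s) absent from universe")
  }
  N <- length(unique(universe))
  n <- length(unique(members))
  res <- term2gene |>
    dplyr::group_by(.data$term_id) |>
    dplyr::summarise(
      K = dplyr::n_distinct(.data$gene_id),
      k = sum(unique(.data$gene_id) %in% members),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      n = n, N = N,
      p = stats::phyper(.data$k - 1, .data$K, N - .data$K, n,
                        lower.tail = FALSE)
    )
  res$q <- bh_fdr(res$p)
  dplyr::mutate(res, enriched = .data$q < 0.05) |>
    dplyr::select("term_id", "k", "K", "n", "N", "p", "q", "enriched") |>
    dplyr::arrange(.data$p)
}

#' Select hub lncRNAs around annotated proteins
#'
#' Thresholds the weighted network into edges (`weight >= edge_threshold`),
#' then, for each functional sub-network of annotated proteins, takes the
#' lncRNAs adjacent to at least one of its proteins, ranks them by degree
#' within the sub-network's induced graph (ties by total degree, then
#' id) and keeps the top `top_k`. A hub selected in two or more
#' sub-networks is classed `inter`, otherwise `intra`.
#'
#' @param weights Symmetric weight matrix (TOM or adjacency) with node
#'   dimnames.
#' @param edge_threshold Minimum weight for an edge.
#' @param lnc_ids Character vector of lncRNA node ids.
#' @param subnetworks Tibble with columns `subnetwork` and `protein_id`
#'   (labels may overlap).
#' @param top_k Hubs kept per sub-network (default 5).
#' @return A tibble with `lncrna_id`, `subnetwork`, `degree`,
#'   `total_degree` and `hub_class`; empty (with a warning) when no
#'   candidate exists.
#' @export
hub_selection <- function(weights, edge_threshold, lnc_ids, subnetworks,
                          top_k = 5) {
  nodes <- rownames(weights)
  adj <- weights >= edge_threshold
  diag(adj) <- FALSE
  total_degree <- rowSums(adj)
  labs <- unique(subnetworks$subnetwork)
  out <- purrr::map(labs, function(lab) {
    prots <- intersect(subnetworks$protein_id[subnetworks$subnetwork == lab],
                       nodes)
    if (length(prots) == 0) {
      rlang::abort(paste0("empty sub-network: ", lab))
    }
    lncs <- intersect(lnc_ids, nodes)
    neighbour <- lncs[colSums(adj[prots, lncs, drop = FALSE]) > 0]
    if (length(neighbour) == 0) return(NULL)
    induced <- c(prots, neighbour)
    deg <- rowSums(adj[neighbour, induced, drop = FALSE])
    ord <- order(-deg, -total_degree[neighbour], neighbour)
    sel <- neighbour[ord][seq_len(min(top_k, length(neighbour)))]
    tibble::tibble(lncrna_id = sel, subnetwork = lab,
                   degree = unname(deg[sel]),
                   total_degree = unname(total_degree[sel]))
  }) |> purrr::compact() |> purrr::list_rbind()
  if (is.null(out) || nrow(out) == 0) {
    rlang::warn("no lncRNA adjacent to any annotated protein at this threshold")
    return(tibble::tibble(lncrna_id = character(0), subnetwork = character(0),
                          degree = numeric(0), total_degree = numeric(0),
                          hub_class = character(0)))
  }
  out |>
    dplyr::add_count(.data$lncrna_id, name = "n_subnetworks") |>
    dplyr::mutate(hub_class = ifelse(.data$n_subnetworks >= 2,
                                     "inter", "intra")) |>
    dplyr::select(-"n_subnetworks")
}
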