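#' Train the default coding-potential scorer
#'
#' Builds the synthetic coding/noncoding corpus (see
#' [simulate_coding_corpus()]), derives the hexamer table from its coding
#' ORFs versus the noncoding sequences, fits the logistic model and
#' returns a closure mapping sequences to coding probabilities.
#'
#' @param seed Seed for corpus generation and the train/test split.
#' @param n_per_class Training sequences per class.
#' @param recalibrate Passed to [fit_coding_model()].
#' @return A list with `model`, `table`, `corpus` and `score`, the
#'   scoring function used as the cascade's stage-4 hook.
#' @export
train_default_scorer <- function(seed = 1, n_per_class = 500,
                                 recalibrate = FALSE) {
  corpus <- simulate_coding_corpus(n_per_class = n_per_class, seed = seed)
  table <- build_hexamer_table(corpus$cds[corpus$coding],
                               corpus$seq[!corpus$coding])
  feats <- coding_features(corpus$seq, table)
  model <- fit_coding_model(feats, corpus$coding, seed = seed,
                            recalibrate = recalibrate)
  list(model = model, table = table, corpus = corpus,
       score = function(seqs) {
         coding_probability(seqs, model, table)$coding_probability
       })
}

## Max-across-samples quantification attached to merged models through the
## intron-chain key map. Internal.
attach_quantification <- function(merged, key_map, fpkm, coverage) {
  merged$source_id <- key_map$transcript_id[match(merged$chain_key,
                                                  key_map$chain_key)]
  if (anyNA(merged$source_id)) {
    rlang::abort(paste0("no quantification key for merged transcript(s): ",
                        paste(utils::head(
                          merged$transcript_id[is.na(merged$source_id)], 5),
                          collapse = ", ")))
  }
  merged$fpkm <- apply(fpkm[merged$source_id, , drop = FALSE], 1, max)
  cov_mat <- as.matrix(coverage[, -1, drop = FALSE])
  rownames(cov_mat) <- coverage$transcript_id
  merged$cov <- apply(cov_mat[merged$source_id, , drop = FALSE], 1, max)
  merged
}

## Flatten list-columns for TSV output. Internal.
flatten_list_cols <- function(df) {
  dplyr::mutate(df, dplyr::across(
    dplyr::where(is.list),
    ~ purrr::map_chr(.x, function(v) paste(unlist(v), collapse = ","))
  ))
}

#' Run the identification half of the pipeline on a study directory
#'
#' Consensus selection and merge of the assembly GTFs, quantification
#' attachment, the seven-stage cascade with the trained coding-potential
#' scorer, and the per-transcript feature table. Outputs
#' `lncrna.gtf` (categories in attributes), `filter_report.tsv`,
#' `casualties.tsv` and `features.tsv` under `output_dir`.
#'
#' @param input_dir Directory written by [write_simulation()] (or laid
#'   out the same way: `manifest.tsv`, `genome.fa`, `scaffolds.tsv`,
#'   `ref.gtf`, `fpkm.tsv`, `coverage.tsv`, `quant_key.tsv`, optional
#'   `hits.tsv` and `repeats.bed`).
#' @param output_dir Output directory (created if needed).
#' @param cfg A [filter_config()].
#' @param scorer Optional scoring function; defaults to
#'   [train_default_scorer()] with `coding_seed`.
#' @param coding_seed Seed for the default scorer.
#' @return Invisibly, a list with `merged`, `records`, `report`,
#'   `features` and the `scorer` used.
#' @export
run_identify <- function(input_dir, output_dir, cfg = filter_config(),
                         scorer = NULL, coding_seed = 1) {
  path <- function(f) file.path(input_dir, f)
  if (!file.exists(path("genome.fa"))) {
    rlang::abort(paste0("genome not found: ", path("genome.fa")))
  }
  genome <- read_genome(path("genome.fa"))
  scaffolds <- read_scaffold_lengths(path("scaffolds.tsv"))
  reference <- read_gtf(path("ref.gtf"))
  manifest <- readr::read_tsv(path("manifest.tsv"), col_types = "ccc",
                              progress = FALSE)
  relative <- !grepl("^(/|[A-Za-z]:)", manifest$gtf_path)
  manifest$gtf_path[relative] <- file.path(input_dir,
                                           manifest$gtf_path[relative])
  cons <- consensus_from_manifest(manifest)
  merged <- cons$transcripts
  if (nrow(merged) == 0) rlang::warn("no candidate transcripts after consensus")

  key_map <- readr::read_tsv(path("quant_key.tsv"), col_types = "cc",
                             progress = FALSE)
  fpkm_tbl <- readr::read_tsv(path("fpkm.tsv"), col_types = readr::cols(
    transcript_id = readr::col_character(), .default = readr::col_double()),
    progress = FALSE)
  fpkm <- as.matrix(fpkm_tbl[, -1]); rownames(fpkm) <- fpkm_tbl$transcript_id
  coverage <- readr::read_tsv(path("coverage.tsv"), col_types = readr::cols(
    transcript_id = readr::col_character(), .default = readr::col_double()),
    progress = FALSE)
  merged <- attach_quantification(merged, key_map, fpkm, coverage)

  homology_hits <- NULL
  if (file.exists(path("hits.tsv"))) {
    hits <- readr::read_tsv(path("hits.tsv"), col_types = readr::cols(
      transcript_id = readr::col_character(), .default = readr::col_guess()),
      progress = FALSE)
    hits$transcript_id <- merged$transcript_id[match(hits$transcript_id,
                                                     merged$source_id)]
    homology_hits <- hits[!is.na(hits$transcript_id), ]
  }
  if (is.null(scorer)) scorer <- train_default_scorer(seed = coding_seed)$score

  cascade <- apply_filter_cascade(merged, reference, genome, scaffolds,
                                  cfg = cfg, scorer = scorer,
                                  homology_hits = homology_hits)
  repeats <- if (file.exists(path("repeats.bed"))) {
    read_intervals(path("repeats.bed"), "bed")
  } else {
    NULL
  }
  features <- transcript_features(cascade$records, genome, repeats)

  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  write_gtf(cascade$records, file.path(output_dir, "lncrna.gtf"))
  readr::write_tsv(cascade$report$stages,
                   file.path(output_dir, "filter_report.tsv"))
  readr::write_tsv(cascade$report$casualties,
                   file.path(output_dir, "casualties.tsv"))
  readr::write_tsv(flatten_list_cols(features),
                   file.path(output_dir, "features.tsv"))
  invisible(list(merged = merged, records = cascade$records,
                 report = cascade$report, features = features,
                 scorer = scorer))
}

#' Run the characterisation half of the pipeline
#'
#' Takes the identified lncRNAs and produces the downstream reports:
#' JS tissue specificity, per-tissue sex-bias calls with locus-level
#' ratios, miRNA precursor pairs, MRE scanning restricted to conserved
#' regions (ceRNA candidates), and the weighted co-expression network
#' (modules, eigengenes, kME, module-trait correlations, optional term
#' enrichment, hub lncRNAs). Writes `specificity.tsv`, `sexbias.tsv`,
#' `locus_sexbias.tsv`, `precursors.tsv`, `mre_hits.tsv`,
#' `cerna_candidates.tsv`, `modules.tsv`, `module_trait.tsv`,
#' `hubs.tsv`, `edges.tsv`, optionally `enrichment.tsv`, and
#' `summary.json`.
#'
#' @param input_dir Study directory (see [run_identify()]).
#' @param identify_dir Output directory of [run_identify()].
#' @param output_dir Output directory (created if needed).
#' @param js_cutoff JS-score cutoff for tissue specificity.
#' @param beta,min_module_size,cut_height,merge_cor,edge_threshold,top_k
#'   Network parameters (see the network functions).
#' @param terms_path Optional term-to-gene TSV (`term_id`, `gene_id`)
#'   for per-module hypergeometric enrichment.
#' @return Invisibly, a list of the computed tables and the summary.
#' @export
run_characterize <- function(input_dir, identify_dir, output_dir,
                             js_cutoff = 0.25, beta = 9,
                             min_module_size = 30, cut_height = 0.995,
                             merge_cor = 0.70, edge_threshold = 0.15,
                             top_k = 5, terms_path = NULL) {
  path <- function(f) file.path(input_dir, f)
  genome <- read_genome(path("genome.fa"))
  reference <- read_gtf(path("ref.gtf"))
  lnc <- read_gtf(file.path(identify_dir, "lncrna.gtf"))
  key_map <- readr::read_tsv(path("quant_key.tsv"), col_types = "cc",
                             progress = FALSE)
  lnc$chain_key <- intron_chain_key(lnc)
  lnc$source_id <- key_map$transcript_id[match(lnc$chain_key,
                                               key_map$chain_key)]
  expr <- read_expression(path("fpkm.tsv"), path("samples.tsv"))
  counts <- read_expression(path("counts.tsv"), path("samples.tsv"))
  samples <- expr$samples
  tissues <- unique(samples$tissue)

  ## tissue profiles (mean FPKM per tissue) for the identified set
  prof <- vapply(tissues, function(tis) {
    rowMeans(expr$matrix[, samples$sample_id[samples$tissue == tis],
                         drop = FALSE])
  }, numeric(nrow(expr$matrix)))
  lnc_prof <- prof[lnc$source_id, , drop = FALSE]
  rownames(lnc_prof) <- lnc$transcript_id
  specificity <- js_specificity(lnc_prof) |>
    classify_tissue_specific(cutoff = js_cutoff)

  ## sex bias and locus ratio
  lnc_counts <- counts$matrix[lnc$source_id, , drop = FALSE]
  rownames(lnc_counts) <- lnc$transcript_id
  sexbias <- sex_bias_table(lnc_counts, samples)
  locus_bias <- locus_sex_bias_ratio(
    dplyr::left_join(sexbias,
                     dplyr::select(lnc, "transcript_id", "locus_id"),
                     by = "transcript_id"))

  ## miRNA precursors and MREs in conserved regions
  mirna_loci <- read_intervals(path("mirna.gff3"), "gff3")
  precursors <- precursor_overlap(lnc, mirna_loci)
  mirna_seqs <- as.character(Biostrings::readRNAStringSet(path("mirna.fa")))
  names(mirna_seqs) <- sub("\\s.*$", "", names(mirna_seqs))
  lnc_seqs <- spliced_sequence(lnc, genome)
  mre_hits <- scan_mre_sites(lnc_seqs, mirna_seqs)
  conserved <- readr::read_tsv(path("conserved.tsv"), col_types = "cii",
                               progress = FALSE)
  conserved$transcript_id <- lnc$transcript_id[match(conserved$transcript_id,
                                                     lnc$source_id)]
  conserved <- conserved[!is.na(conserved$transcript_id), ]
  lens <- stats::setNames(tx_spliced_length(lnc), lnc$transcript_id)
  conserved$end <- pmin(conserved$end, lens[conserved$transcript_id])
  cerna <- cerna_filter(mre_hits, conserved, lnc_lengths = lens)

  ## co-expression network on coding + identified noncoding transcripts
  net_ids <- c(reference$transcript_id, lnc$source_id)
  net_expr <- filter_expressed(log2(expr$matrix[net_ids, , drop = FALSE] + 1))
  adj <- adjacency_from_expression(net_expr, beta = beta)
  tom <- tom_matrix(adj)
  assignment <- detect_modules(tom, min_module_size = min_module_size,
                               cut_height = cut_height)
  memod <- module_eigengene_and_merge(net_expr, assignment,
                                      merge_cor = merge_cor)
  traits <- vapply(tissues, function(tis) as.numeric(samples$tissue == tis),
                   numeric(nrow(samples)))
  rownames(traits) <- samples$sample_id
  ktc <- kme_and_trait_correlation(net_expr, memod$eigengenes, traits)
  modules <- memod$modules |>
    dplyr::left_join(ktc$kme, by = c("transcript_id", "module"))

  enrichment <- NULL
  if (!is.null(terms_path)) {
    term2gene <- readr::read_tsv(terms_path, col_types = readr::cols(),
                                 progress = FALSE)
    enrichment <- memod$modules |>
      dplyr::filter(.data$module != "grey") |>
      dplyr::group_by(.data$module) |>
      dplyr::group_modify(~ hypergeometric_enrichment(
        .x$transcript_id, term2gene, universe = rownames(net_expr))) |>
      dplyr::ungroup()
  }

  ## functional sub-networks: each module's coding members
  subnetworks <- memod$modules |>
    dplyr::filter(.data$module != "grey",
                  .data$transcript_id %in% reference$transcript_id) |>
    dplyr::select(subnetwork = "module", protein_id = "transcript_id")
  hubs <- if (nrow(subnetworks) > 0) {
    hub_selection(tom, edge_threshold, intersect(lnc$source_id,
                                                 rownames(tom)),
                  subnetworks, top_k = top_k)
  } else {
    tibble::tibble(lncrna_id = character(0), subnetwork = character(0),
                   degree = numeric(0), total_degree = numeric(0),
                   hub_class = character(0))
  }
  edge_idx <- which(tom >= edge_threshold & upper.tri(tom), arr.ind = TRUE)
  edges <- tibble::tibble(from = rownames(tom)[edge_idx[, 1]],
                          to = rownames(tom)[edge_idx[, 2]],
                          weight = tom[edge_idx])

  summary <- list(
    n_lncrna = nrow(lnc),
    n_loci = dplyr::n_distinct(lnc$locus_id),
    n_by_category = as.list(table(lnc$category)),
    n_tissue_specific = sum(specificity$tissue_specific, na.rm = TRUE),
    n_sex_biased_loci = sum(locus_bias$locus_biased),
    sex_biased_locus_fraction = mean(locus_bias$locus_biased),
    n_precursor_pairs = nrow(precursors),
    n_cerna_candidates = sum(cerna$candidates$cerna_candidate),
    n_modules = dplyr::n_distinct(setdiff(memod$modules$module, "grey")),
    n_hub_lncrnas = dplyr::n_distinct(hubs$lncrna_id)
  )

  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(output_dir, f)
  readr::write_tsv(flatten_list_cols(
    dplyr::select(specificity, -"specificity")), out("specificity.tsv"))
  readr::write_tsv(sexbias, out("sexbias.tsv"))
  readr::write_tsv(locus_bias, out("locus_sexbias.tsv"))
  readr::write_tsv(precursors, out("precursors.tsv"))
  readr::write_tsv(cerna$hits, out("mre_hits.tsv"))
  readr::write_tsv(cerna$candidates, out("cerna_candidates.tsv"))
  readr::write_tsv(modules, out("modules.tsv"))
  readr::write_tsv(ktc$module_trait, out("module_trait.tsv"))
  readr::write_tsv(hubs, out("hubs.tsv"))
  readr::write_tsv(edges, out("edges.tsv"))
  if (!is.null(enrichment)) readr::write_tsv(enrichment, out("enrichment.tsv"))
  jsonlite::write_json(summary, out("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(lnc = lnc, specificity = specificity, sexbias = sexbias,
                 locus_bias = locus_bias, precursors = precursors,
                 mre = cerna, modules = modules,
                 module_trait = ktc$module_trait, eigengenes = memod$eigengenes,
                 hubs = hubs, enrichment = enrichment, summary = summary))
}

#' Join pipeline transcripts to the simulation truth
#'
#' Matches merged/identified transcripts to planted transcripts through
#' the intron-chain key (terminal-exon jitter does not change the key).
#'
#' @param tx Transcript tibble with a `chain_key` column (computed when
#'   absent).
#' @param truth Truth manifest of [simulate_lnc_study()].
#' @return `tx` with the truth columns joined on.
#' @export
match_truth <- function(tx, truth) {
  if (!"chain_key" %in% names(tx)) tx$chain_key <- intron_chain_key(tx)
  dplyr::left_join(tx,
                   dplyr::select(truth, -dplyr::any_of(c("locus_id",
                                                         "category"))),
                   by = "chain_key", suffix = c("", ".truth"))
}
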