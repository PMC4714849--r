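# Shared fixtures, built in code. The full default study (simulation +
# identification) is expensive, so it is built lazily once per test run.

the_cache <- new.env(parent = emptyenv())

## Default-condition study (seed 1), written to a temp dir, identified.
get_full_study <- function() {
  if (is.null(the_cache$study)) {
    sim <- simulate_lnc_study(sim_config(seed = 1))
    dir <- file.path(tempdir(), "lncforge_full_study")
    unlink(dir, recursive = TRUE)
    write_simulation(sim, dir)
    out <- file.path(dir, "identify")
    res <- run_identify(dir, out)
    the_cache$study <- list(sim = sim, dir = dir, identify_dir = out,
                            res = res)
  }
  the_cache$study
}

get_default_scorer <- function() {
  if (is.null(the_cache$scorer)) {
    the_cache$scorer <- train_default_scorer(seed = 1, n_per_class = 500)
  }
  the_cache$scorer
}

get_small_sim <- function() {
  if (is.null(the_cache$small_sim)) {
    the_cache$small_sim <- simulate_lnc_study(small_config(seed = 7))
  }
  the_cache$small_sim
}

## A reduced study for fast end-to-end tests.
small_config <- function(seed = 7) {
  sim_config(seed = seed, n_scaffolds = 4, scaffold_length = 60000,
             n_mrna = 40, n_linc = 8, n_ilnc = 3, n_nat = 4,
             n_decoys_per_stage = 2, n_once_only = 2, n_isoform_loci = 2,
             modules = tibble::tibble(tissue = c("msg", "testis"),
                                      n_members = c(15, 15),
                                      strength = c(3, 3)),
             n_mirna = 2, n_mirna_antisense = 1, n_mre = 2)
}

## Tiny hand-built genome and transcripts for geometric tests.
toy_genome <- function() {
  Biostrings::DNAStringSet(c(
    chrA = paste(rep("ACGT", 2500), collapse = ""),  # 10 kb
    chrB = paste(rep("TTGCA", 2000), collapse = "")  # 10 kb
  ))
}

tx_row <- function(id, scaffold, strand, starts, ends, locus = id, ...) {
  transcript_tbl(transcript_id = id, locus_id = locus, scaffold = scaffold,
                 strand = strand,
                 exons = list(cbind(start = as.integer(starts),
                                    end = as.integer(ends))), ...)
}
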