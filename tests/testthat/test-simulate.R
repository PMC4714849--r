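test_that("the generator is deterministic and enforces its geometry by
           construction", {
  cfg <- small_config(seed = 7)
  s1 <- get_small_sim()
  s2 <- simulate_lnc_study(cfg)
  expect_identical(as.character(s1$genome), as.character(s2$genome))
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$counts, s2$counts)
  s3 <- simulate_lnc_study(small_config(seed = 8))
  expect_false(identical(as.character(s1$genome), as.character(s3$genome)))

  ## clean lncRNAs never carry an ORF above 100 aa
  clean <- s1$transcripts[s1$transcripts$role %in%
                            c("lincRNA", "ilncRNA", "lncNAT"), ]
  orf <- find_max_orf(spliced_sequence(clean, s1$genome))
  expect_true(all(orf$max_orf_aa <= 100))

  ## scaffold-end decoys sit inside the 2 kb margin, everything else outside
  sp <- tx_span(s1$transcripts)
  near <- sp$end > cfg$scaffold_length - 2000 | sp$start < 2000
  expect_identical(near, s1$transcripts$decoy_stage %in% "scaffold_end")

  ## ORF decoys fall in the planted 101-300 aa window
  d3 <- s1$transcripts[s1$transcripts$decoy_stage %in% "orf_filter", ]
  orf3 <- find_max_orf(spliced_sequence(d3, s1$genome))
  expect_true(all(orf3$max_orf_aa >= 101 & orf3$max_orf_aa <= 300))
})

test_that("assembly replicates jitter terminals only and respect support
           design", {
  s <- get_small_sim()
  witnesses <- build_support(s$assemblies)
  planted_keys <- intron_chain_key(s$transcripts)
  ## jitter never alters the intron chain
  expect_true(all(witnesses$chain_key %in% planted_keys))
  ## every non-once-only transcript survives the stringent rule
  kept <- unique(stringent_select(witnesses)$chain_key)
  truth_keys <- stats::setNames(planted_keys, s$transcripts$transcript_id)
  regular <- s$transcripts$role != "once_only"
  expect_true(all(truth_keys[regular] %in% kept))
  expect_false(any(truth_keys[!regular] %in% kept))

  ## terminal jitter is bounded
  cmp <- dplyr::left_join(
    witnesses,
    tibble::tibble(chain_key = planted_keys,
                   p_start = tx_span(s$transcripts)$start,
                   p_end = tx_span(s$transcripts)$end),
    by = "chain_key")
  w_sp <- tx_span(cmp)
  expect_true(all(abs(w_sp$start - cmp$p_start) <= 50))
  expect_true(all(abs(w_sp$end - cmp$p_end) <= 50))
})

test_that("simulated counts follow the FPKM identity and planted expression
           structure", {
  s <- get_small_sim()
  lens <- tx_spliced_length(s$transcripts)
  expect_equal(s$fpkm,
               s$counts * 1e9 / (lens * s$config$library_size),
               tolerance = 1e-12)
  ## the closed-form check: 1,000 reads on a 1,000-nt transcript in a
  ## 1e6-read library is FPKM 1,000
  expect_equal(1000 * 1e9 / (1000 * 1e6), 1000)

  ## pure single-tissue transcripts have JS score exactly 1
  pure <- s$truth$transcript_id[s$truth$pure_specific]
  tissues <- unique(s$samples$tissue)
  prof <- vapply(tissues, function(tis) {
    rowSums(s$fpkm[pure, s$samples$tissue == tis, drop = FALSE])
  }, numeric(length(pure)))
  expressed <- rowSums(prof) > 0
  js <- js_specificity(prof[expressed, , drop = FALSE])
  expect_true(all(js$js_score == 1))
  expect_equal(js$js_tissue,
               s$truth$specificity_tissue[s$truth$pure_specific][expressed])

  ## low-FPKM decoys are silent everywhere
  silent <- s$truth$transcript_id[s$truth$low_kind %in% "low_fpkm"]
  expect_true(all(s$counts[silent, ] == 0))
})

test_that("planted interactions are recoverable exactly", {
  s <- get_small_sim()
  seqs <- spliced_sequence(s$transcripts, s$genome)
  mir <- chartr("U", "T", s$mirna_seqs)
  for (i in seq_len(nrow(s$mre_truth))) {
    row <- s$mre_truth[i, ]
    hits <- scan_mre_sites(seqs[row$transcript_id], mir[row$mirna])
    match <- hits[hits$start == row$start & hits$site_type == row$site_type, ]
    expect_equal(nrow(match), 1)
  }
  pre <- precursor_overlap(s$transcripts, s$mirna_loci)
  planted <- s$mirna_loci[!s$mirna_loci$antisense, ]
  got <- dplyr::semi_join(planted,
                          dplyr::rename(pre, host = "locus_id"),
                          by = c(host = "host", name = "mirna"))
  expect_equal(nrow(got), nrow(planted))
  anti <- s$mirna_loci$name[s$mirna_loci$antisense]
  expect_false(any(anti %in% pre$mirna))
})

test_that("writing the study round-trips the truth manifest", {
  s <- get_small_sim()
  dir <- withr::local_tempdir()
  write_simulation(s, dir)
  truth_back <- readr::read_tsv(file.path(dir, "truth.tsv"),
                                show_col_types = FALSE)
  expect_equal(nrow(truth_back), nrow(s$truth))
  expect_identical(truth_back$transcript_id, s$truth$transcript_id)
  expect_identical(truth_back$chain_key, s$truth$chain_key)
  g <- read_genome(file.path(dir, "genome.fa"))
  expect_identical(as.character(g), as.character(s$genome))
})
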