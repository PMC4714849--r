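ref_two_gene <- function() {
  dplyr::bind_rows(
    ## gene on +: exons (100,200) and (900,1100), intron (200,900)
    tx_row("g1", "chrA", "+", c(100, 900), c(200, 1100)),
    ## gene on -: exons (3000,3300) and (4000,4200)
    tx_row("g2", "chrA", "-", c(3000, 4000), c(3300, 4200))
  )
}

test_that("class codes follow the sense/antisense/intronic/intergenic rules", {
  ref <- ref_two_gene()
  cand <- dplyr::bind_rows(
    tx_row("sense", "chrA", "+", c(150, 260), c(210, 320)),
    tx_row("anti", "chrA", "-", c(150, 260), c(210, 320)),
    tx_row("intr", "chrA", "+", c(300, 500), c(400, 700)),
    tx_row("inter", "chrA", "+", c(6000, 6500), c(6200, 6800))
  )
  expect_equal(assign_class_code(cand, ref), c("sense_exonic", "x", "i", "u"))
})

test_that("the cascade removes each failure mode at its stage and telescopes", {
  g <- toy_genome()
  scaffolds <- tibble::tibble(name = c("chrA", "chrB"),
                              length = c(10000L, 10000L))
  ref <- ref_two_gene()
  cand <- dplyr::bind_rows(
    tx_row("ok", "chrA", "+", c(5000, 5400), c(5200, 5600)),
    tx_row("short", "chrA", "+", c(6000, 6200), c(6090, 6260)),
    tx_row("lowfpkm", "chrA", "+", c(7000, 7400), c(7200, 7600)),
    tx_row("nearend", "chrA", "+", c(9000, 9400), c(9200, 9600)),
    tx_row("senseov", "chrA", "+", c(150, 900), c(250, 1200)),
    tx_row("homhit", "chrB", "+", c(5000, 5400), c(5200, 5600))
  )
  cand$cov <- c(5, 5, 5, 5, 5, 5)
  cand$fpkm <- c(2, 2, 0.01, 2, 2, 2)
  out <- apply_filter_cascade(
    cand, ref, g, scaffolds,
    homology_hits = tibble::tibble(transcript_id = "homhit", evalue = 1e-10))
  cas <- out$report$casualties
  stage_of <- function(id) cas$casualty_stage[cas$transcript_id == id]
  expect_equal(stage_of("senseov"), "sense_overlap")
  expect_equal(stage_of("short"), "basic_filters")
  expect_equal(stage_of("lowfpkm"), "basic_filters")
  expect_equal(stage_of("homhit"), "homology")
  expect_equal(stage_of("nearend"), "scaffold_end")
  expect_equal(out$records$transcript_id, "ok")
  expect_equal(out$records$category, "lincRNA")

  st <- out$report$stages
  expect_equal(st$retained_n[-nrow(st)], st$input_n[-1])  # telescoping
  expect_equal(nrow(cas) + nrow(out$records), nrow(cand))
})

test_that("an ORF above 100 aa is a stage-3 casualty", {
  ## plant a 120-aa ORF into the genome under a clean intergenic transcript
  g <- toy_genome()
  chars <- as.character(g[["chrA"]])
  orf <- paste0("ATG", paste(rep("GCT", 120), collapse = ""), "TAA")
  substr(chars, 5001, 5000 + nchar(orf)) <- orf
  g2 <- Biostrings::DNAStringSet(c(chrA = chars,
                                   chrB = as.character(g[["chrB"]])))
  cand <- tx_row("bigorf", "chrA", "+", c(4950, 5500), c(5420, 5700))
  cand$cov <- 5; cand$fpkm <- 2
  out <- apply_filter_cascade(cand, ref_two_gene(), g2,
                              tibble::tibble(name = c("chrA", "chrB"),
                                             length = c(10000L, 10000L)))
  expect_equal(out$report$casualties$casualty_stage, "orf_filter")
})

test_that("cascade input contracts are enforced", {
  g <- toy_genome()
  cand <- tx_row("t", "chrA", "+", c(5000, 5400), c(5200, 5600))
  cand$cov <- 5
  expect_error(
    apply_filter_cascade(cand, ref_two_gene(), g,
                         tibble::tibble(name = "chrA", length = 10000L)),
    "missing FPKM.*t")
  cand$fpkm <- 1
  expect_error(
    apply_filter_cascade(cand, ref_two_gene(), g,
                         tibble::tibble(name = "chrZ", length = 10000L)),
    "absent from length table")
  expect_error(filter_config(min_fpkm = -1), "positive")
})

test_that("feature statistics: GC, repeat fraction and splice dinucleotides", {
  seq <- paste0(strrep("T", 100), "GT", strrep("A", 16), "AG", strrep("C", 80))
  g <- Biostrings::DNAStringSet(c(chrC = seq))
  ## exons (0,100) and (120,200): intron (100,120) carries GT..AG
  tx <- tx_row("f1", "chrC", "+", c(0, 120), c(100, 200))
  feats <- transcript_features(
    tx, g, repeats = tibble::tibble(scaffold = "chrC", start = 50L,
                                    end = 130L, strand = NA, name = NA))
  expect_equal(feats$spliced_length, 180L)
  expect_equal(feats$gc_fraction, 80 / 180)
  ## repeat (50,130) covers exonic bases 50-100 and 120-130 = 60 of 180
  expect_equal(feats$repeat_overlap_fraction, 60 / 180)
  expect_equal(feats$splice_donors[[1]], "GT")
  expect_equal(feats$splice_acceptors[[1]], "AG")

  ## on the minus strand the same genomic intron reads CT..AC sense-wise,
  ## so donor/acceptor are the reverse complements of the plus-strand pair
  tx_m <- tx_row("f2", "chrC", "-", c(0, 120), c(100, 200))
  feats_m <- transcript_features(tx_m, g)
  expect_equal(feats_m$splice_donors[[1]], "CT")
  expect_equal(feats_m$splice_acceptors[[1]], "AC")
  expect_equal(feats_m$repeat_overlap_fraction, 0)

  toy <- transcript_features(
    tx_row("g1", "chrC", "+", 0, 4), g)
  expect_equal(toy$gc_fraction, 0)     # "TTTT"
})
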