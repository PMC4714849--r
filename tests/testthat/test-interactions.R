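test_that("precursor pairing requires same-strand locus overlap and flags
           exonic containment", {
  lnc <- dplyr::bind_rows(
    tx_row("t1", "chrA", "+", c(50, 700), c(500, 900), locus = "L1"),
    tx_row("t2", "chrA", "-", c(2000, 2700), c(2500, 2900), locus = "L2")
  )
  mir <- tibble::tibble(
    scaffold = "chrA",
    start = c(100L, 100L, 550L, 2100L),
    end = c(122L, 122L, 572L, 2122L),
    strand = c("+", "-", "+", "+"),
    name = c("mir-a", "mir-b", "mir-c", "mir-d"))
  out <- precursor_overlap(lnc, mir)
  expect_equal(out$mirna[out$locus_id == "L1"], c("mir-a", "mir-c"))
  ## inside an exon vs inside the intron (locus-span semantics)
  expect_true(out$exonic[out$mirna == "mir-a"])
  expect_false(out$exonic[out$mirna == "mir-c"])
  ## antisense to both loci: never reported
  expect_false("mir-b" %in% out$mirna)
  expect_false("mir-d" %in% out$mirna)

  mir$strand[1] <- NA
  expect_error(precursor_overlap(lnc, mir), "strandless")
})

test_that("seed-site scanning finds the canonical site types at hand positions", {
  mir <- "UGAGGUAGUAGGUUGUAUAGUU"   # seed (2-8) GAGGUAG
  expect_equal(nrow(scan_mre_sites(c(l = "GGGGGGGGGGGG"), c(m = mir))), 0)

  ## "GGGG" then the site: the 6mer core starts at offset 5 when the m8
  ## match base precedes it
  hit <- scan_mre_sites(c(l = paste0("GGGG", "CTACCTC", "CGGG")), c(m = mir))
  expect_equal(hit$site_type, "7mer-m8")
  expect_equal(hit$start, 4L)
  expect_equal(hit$end, 11L)

  hit8 <- scan_mre_sites(c(l = paste0("GGGG", "CTACCTCA", "GGG")), c(m = mir))
  expect_equal(hit8$site_type, "8mer")
  expect_equal(hit8$start, 4L)
  expect_equal(hit8$end, 12L)

  hit6 <- scan_mre_sites(c(l = paste0("GGGG", "TACCTC", "CGG")), c(m = mir))
  expect_equal(hit6$site_type, "6mer")
  hit7a1 <- scan_mre_sites(c(l = paste0("GGGG", "TACCTCA", "GG")), c(m = mir))
  expect_equal(hit7a1$site_type, "7mer-A1")

  expect_error(scan_mre_sites(c(l = "ACGT"), c(m = "UGAGGUAG")), "19")
})

test_that("seed-site scanning equals exhaustive enumeration on random pairs", {
  withr::with_seed(14, {
    for (i in 1:30) {
      lnc <- random_dna(sample(100:600, 1), p = rep(0.25, 4))
      mir <- random_dna(22, p = rep(0.25, 4))
      got <- scan_mre_sites(c(l = lnc), c(m = mir))
      want <- mre_oracle(lnc, mir)
      expect_equal(nrow(got), nrow(want))
      if (nrow(want) > 0) {
        expect_equal(got$start, want$start)
        expect_equal(got$end, want$end)
        expect_equal(got$site_type, want$site_type)
      }
    }
  })
})

test_that("ceRNA filtering keeps fully contained hits and counts distinct
           miRNAs", {
  hits <- tibble::tibble(
    lncrna_id = c("t1", "t1", "t1", "t2"),
    mirna_id = c("m1", "m2", "m3", "m1"),
    start = c(10L, 45L, 20L, 5L),
    end = c(17L, 52L, 27L, 12L),
    site_type = "7mer-m8")
  regions <- tibble::tibble(transcript_id = c("t1", "t2"),
                            start = c(0L, 40L), end = c(50L, 90L))
  out <- cerna_filter(hits, regions, min_distinct_mirnas = 2)
  expect_equal(nrow(out$hits), 2)               # (45,52) straddles region end
  expect_false("t2" %in% out$hits$lncrna_id)    # outside its region
  expect_true(out$candidates$cerna_candidate[out$candidates$lncrna_id == "t1"])

  expect_error(
    cerna_filter(hits, regions, lnc_lengths = c(t1 = 60, t2 = 80)),
    "outside transcript bounds")
})
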