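test_that("the exact binomial sex-bias test matches hand and oracle values", {
  sym <- sex_bias_test(50, 50, 1e6, 1e6)
  expect_equal(sym$log2fc, 0)
  expect_equal(sym$p, 1)

  res <- sex_bias_test(40, 10, 1e6, 1e6)
  expect_equal(res$log2fc, log2(40.5 / 10.5), tolerance = 1e-12)
  ## two-sided exact tail by full PMF summation
  probs <- stats::dbinom(0:50, 50, 0.5)
  expect_equal(res$p, sum(probs[probs <= stats::dbinom(40, 50, 0.5)]),
               tolerance = 1e-9)

  expect_equal(sex_bias_test(0, 0, 1e6, 1e6)$p, 1)
  expect_error(sex_bias_test(-1, 2, 1e6, 1e6), "negative")

  ## unequal library sizes shift the null success probability
  uneq <- sex_bias_test(30, 30, 2e6, 1e6)
  expect_equal(uneq$log2fc, log2((30.5 / 2e6) / (30.5 / 1e6)))
  expect_lt(uneq$p, 1)
})

test_that("BH correction matches the step-up definition", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  withr::with_seed(13, {
    for (i in 1:10) {
      p <- stats::runif(sample(3:40, 1))
      expect_equal(bh_fdr(p), bh_oracle(p), tolerance = 1e-12)
    }
  })
})

test_that("locus-level roll-up applies the strict 0.75 ratio rule", {
  calls <- tibble::tibble(
    locus_id = c(rep("L1", 14), rep("L2", 4), "L3", "L4"),
    transcript_id = paste0("t", 1:20),
    biased = c(rep(TRUE, 11), rep(FALSE, 3),   # 11/14 = 0.786 -> biased
               rep(TRUE, 3), FALSE,            # 3/4 = 0.75 -> NOT biased
               TRUE,                           # single isoform, biased
               FALSE)                          # single isoform, unbiased
  )
  out <- locus_sex_bias_ratio(calls)
  expect_equal(out$ratio[out$locus_id == "L1"], 11 / 14, tolerance = 1e-12)
  expect_true(out$locus_biased[out$locus_id == "L1"])
  expect_false(out$locus_biased[out$locus_id == "L2"])
  expect_true(out$locus_biased[out$locus_id == "L3"])
  expect_false(out$locus_biased[out$locus_id == "L4"])
  expect_error(locus_sex_bias_ratio(calls[0, ]), "empty")
})

test_that("per-tissue tables call bias only at |log2FC| > 1 and q < 0.05,
           biased in any tissue counts at the locus", {
  counts <- rbind(up = c(400, 50, 10, 12), flat = c(100, 100, 20, 20))
  colnames(counts) <- c("gonad_F", "gonad_M", "brain_F", "brain_M")
  samples <- tibble::tibble(
    sample_id = colnames(counts),
    tissue = c("gonad", "gonad", "brain", "brain"),
    sex = c("F", "M", "F", "M"),
    library_size = 1e6)
  tab <- sex_bias_table(counts, samples)
  expect_setequal(unique(tab$tissue), c("gonad", "brain"))
  expect_equal(tab$call[tab$transcript_id == "up" & tab$tissue == "gonad"],
               "female_biased")
  expect_equal(tab$call[tab$transcript_id == "flat" & tab$tissue == "gonad"],
               "unbiased")
  loc <- locus_sex_bias_ratio(
    dplyr::mutate(tab, locus_id = ifelse(transcript_id == "up", "LA", "LB")))
  expect_true(loc$locus_biased[loc$locus_id == "LA"])
  expect_false(loc$locus_biased[loc$locus_id == "LB"])
})
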