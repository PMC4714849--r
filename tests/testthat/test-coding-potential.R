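test_that("TESTCODE is case-invariant, length-guarded and matches the
           table-lookup oracle", {
  s <- paste(rep("ACGT", 100), collapse = "")
  expect_equal(fickett_score(s), fickett_score(tolower(s)))
  expect_error(fickett_score(random_dna(150)), "at least 200")

  withr::with_seed(7, {
    seqs <- vapply(1:50, function(i) random_dna(sample(200:1200, 1)),
                   character(1))
  })
  expect_equal(fickett_score(seqs),
               vapply(seqs, fickett_oracle, numeric(1), USE.NAMES = FALSE),
               tolerance = 1e-12)
})

test_that("hexamer tables are smoothed, normalised and deterministic", {
  withr::with_seed(8, {
    cod <- vapply(1:12, function(i) random_dna(300), character(1))
    non <- vapply(1:12, function(i) random_dna(300), character(1))
  })
  tab <- build_hexamer_table(cod, non)
  expect_equal(sum(tab$f_coding), 1, tolerance = 1e-9)
  expect_equal(sum(tab$f_noncoding), 1, tolerance = 1e-9)
  expect_true(all(tab$f_coding > 0) && all(tab$f_noncoding > 0))
  expect_identical(tab$f_coding, build_hexamer_table(cod, non)$f_coding)

  one <- build_hexamer_table(strrep("ATGGCA", 60), non)
  expect_equal(names(which.max(one$f_coding)), "ATGGCA")
  expect_error(build_hexamer_table(character(0), non), "non-empty")
})

test_that("the hexamer log-likelihood ratio behaves and matches the loop oracle", {
  withr::with_seed(9, {
    cod <- vapply(1:15, function(i) {
      paste0("ATG", paste(sample(c("GCT", "GAA", "AAG", "CTG"), 80,
                                 replace = TRUE, prob = c(4, 3, 2, 1)),
                          collapse = ""), "TAA")
    }, character(1))
    non <- vapply(1:15, function(i) random_dna(500), character(1))
    tab <- build_hexamer_table(cod, non)

    flat <- tab
    flat$f_noncoding <- flat$f_coding
    seqs <- vapply(1:50, function(i) random_dna(sample(60:600, 1)),
                   character(1))
    expect_equal(hexamer_llr(seqs[1:5], flat), rep(0, 5))
    expect_gt(hexamer_llr(cod[1], tab), 0)   # coding-drawn ORF scores coding
    expect_equal(hexamer_llr(seqs, tab),
                 vapply(seqs, hexamer_llr_oracle, numeric(1), table = tab,
                        USE.NAMES = FALSE),
                 tolerance = 1e-12)

    ## antisymmetry under swapping the two classes
    swapped <- tab
    swapped$f_coding <- tab$f_noncoding
    swapped$f_noncoding <- tab$f_coding
    expect_equal(hexamer_llr(seqs, swapped), -hexamer_llr(seqs, tab),
                 tolerance = 1e-12)
  })
})

test_that("the logistic coding model is seed-deterministic and separates a
           separable corpus perfectly", {
  withr::with_seed(10, {
    feats <- tibble::tibble(
      max_orf_nt = c(stats::runif(60, 500, 1500), stats::runif(60, 30, 200)),
      orf_coverage = stats::runif(120),
      fickett = stats::runif(120, 0.7, 1.3),
      hexamer_llr = stats::rnorm(120))
  })
  labels <- rep(c(TRUE, FALSE), each = 60)
  m1 <- fit_coding_model(feats, labels, seed = 4)
  m2 <- fit_coding_model(feats, labels, seed = 4)
  expect_identical(m1$coef, m2$coef)
  expect_equal(m1$auc_holdout, 1)
  expect_error(fit_coding_model(feats, rep(TRUE, 120)), "both")

  expect_equal(tidy(m1)$estimate, unname(m1$coef))
  expect_equal(glance(m1)$auc_holdout, 1)
})

test_that("coding probabilities are in [0, 1] and survive JSON round-trip", {
  scorer <- get_default_scorer()
  withr::with_seed(11, {
    seqs <- vapply(1:10, function(i) random_dna(sample(300:900, 1)),
                   character(1))
  })
  cp <- coding_probability(seqs, scorer$model, scorer$table)
  expect_true(all(cp$coding_probability >= 0 & cp$coding_probability <= 1))
  expect_true(all(cp$orf_coverage >= 0 & cp$orf_coverage <= 1))

  f <- withr::local_tempfile(fileext = ".json")
  write_coding_model(scorer$model, f)
  back <- read_coding_model(f)
  cp2 <- coding_probability(seqs, back, scorer$table)
  expect_equal(cp2$coding_probability, cp$coding_probability,
               tolerance = 1e-12)
  expect_error(coding_probability(seqs, list(), scorer$table), "fitted")
})
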