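test_that("intron-chain keys ignore terminal ends but not strand", {
  a <- tx_row("a", "chr1", "+", c(0, 20), c(10, 30))
  b <- tx_row("b", "chr1", "+", c(2, 20), c(10, 35))
  c_ <- tx_row("c", "chr1", "-", c(0, 20), c(10, 30))
  expect_equal(intron_chain_key(a), intron_chain_key(b))
  expect_false(intron_chain_key(a) == intron_chain_key(c_))
  expect_error(intron_chain_key(tx_row("s", "chr1", "+", 0, 100)),
               "single-exon")
})

test_that("support is tabulated with set semantics over (assembler, tissue)", {
  chain <- function(id) tx_row(id, "chr1", "+", c(0, 20), c(10, 30))
  assemblies <- tibble::tibble(
    assembler = c("cuff", "script", "cuff"),
    tissue = c("brain", "brain", "brain"),
    transcripts = list(chain("w1"),
                       chain("w2"),
                       dplyr::bind_rows(chain("w3"), chain("w4")))
  )
  sup <- build_support(assemblies)
  expect_equal(unique(lengths(sup$support)), 2)  # duplicates count once
  expect_setequal(sup$support[[1]], c("cuff|brain", "script|brain"))
  expect_error(build_support(assemblies[0, ]), "no assemblies")
})

test_that("the stringent rule keeps chains seen twice across programs or tissues", {
  chain <- function(id, start = 0) {
    tx_row(id, "chr1", "+", c(start, 20 + start), c(10 + start, 30 + start))
  }
  asm <- function(assembler, tissue, tx) {
    tibble::tibble(assembler = assembler, tissue = tissue,
                   transcripts = list(tx))
  }
  once <- build_support(asm("cuff", "brain", chain("x")))
  expect_equal(nrow(stringent_select(once)), 0)

  two_tissues <- build_support(dplyr::bind_rows(
    asm("cuff", "brain", chain("x")), asm("cuff", "testis", chain("y"))))
  expect_equal(dplyr::n_distinct(stringent_select(two_tissues)$chain_key), 1)

  two_programs <- build_support(dplyr::bind_rows(
    asm("cuff", "brain", chain("x")), asm("stringtie", "brain", chain("y"))))
  expect_equal(dplyr::n_distinct(stringent_select(two_programs)$chain_key), 1)
})

test_that("stringent selection is monotone in added assemblies", {
  withr::with_seed(3, {
    mk_chain <- function(i) {
      s <- i * 1000
      tx_row(paste0("t", i), "chr1", "+", c(s, s + 200), c(s + 100, s + 300))
    }
    base <- tibble::tibble(
      assembler = c("cuff", "script"), tissue = c("brain", "brain"),
      transcripts = list(dplyr::bind_rows(lapply(1:5, mk_chain)),
                         dplyr::bind_rows(lapply(3:7, mk_chain))))
    kept1 <- unique(stringent_select(build_support(base))$chain_key)
    more <- dplyr::bind_rows(base, tibble::tibble(
      assembler = "stringtie", tissue = "testis",
      transcripts = list(dplyr::bind_rows(lapply(c(1, 6, 8), mk_chain)))))
    kept2 <- unique(stringent_select(build_support(more))$chain_key)
    expect_true(all(kept1 %in% kept2))
  })
})

test_that("merging unions terminal ends and assigns loci by stranded overlap", {
  w <- dplyr::bind_rows(
    tx_row("a", "chr1", "+", c(0, 20), c(10, 30)),
    tx_row("b", "chr1", "+", c(2, 20), c(10, 35))
  )
  m <- merge_transcripts(w)
  expect_equal(nrow(m), 1)
  expect_equal(m$exons[[1]], cbind(start = c(0L, 20L), end = c(10L, 35L)))

  ## disjoint loci vs same-strand overlapping isoforms vs antisense overlap
  w2 <- dplyr::bind_rows(
    tx_row("a", "chr1", "+", c(0, 20), c(10, 30)),
    tx_row("b", "chr1", "+", c(5, 40), c(25, 60)),    # overlaps a, new chain
    tx_row("c", "chr1", "-", c(5, 40), c(25, 60)),    # antisense: own locus
    tx_row("d", "chr1", "+", c(5000, 5200), c(5100, 5300))
  )
  m2 <- merge_transcripts(w2)
  expect_equal(nrow(m2), 4)
  locus_of <- function(old_start) {
    m2$locus_id[purrr::map_int(m2$exons, ~ .x[1, 1]) == old_start]
  }
  expect_equal(locus_of(0), locus_of(5)[1])     # same-strand overlap: one locus
  expect_false(locus_of(5)[2] == locus_of(0))   # antisense overlap: separate
  expect_equal(dplyr::n_distinct(m2$locus_id), 3)
})

test_that("merge is idempotent and counts isoforms per locus correctly", {
  withr::with_seed(5, {
    rows <- lapply(1:12, function(i) {
      s <- sample(0:50, 1) + (i %% 4) * 3000
      tx_row(paste0("t", i), "chr1", sample(c("+", "-"), 1),
             c(s, s + 500), c(s + 200, s + 800))
    })
    m1 <- merge_transcripts(dplyr::bind_rows(rows))
    m2 <- merge_transcripts(m1)
    expect_equal(m2$exons, m1$exons, ignore_attr = TRUE)
    expect_equal(m2$locus_id, m1$locus_id)
    iso <- table(m1$locus_id)
    chains_per_locus <- tapply(m1$chain_key, m1$locus_id,
                               function(k) length(unique(k)))
    expect_equal(as.integer(iso), as.integer(chains_per_locus[names(iso)]))
  })
})
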