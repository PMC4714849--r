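test_that("soft-threshold adjacency is |cor|^beta with guarded input", {
  withr::with_seed(15, {
    x <- stats::rnorm(20)
    expr <- rbind(a = x, b = x, c = -0.8 * x + sqrt(1 - 0.64) * stats::rnorm(20))
  })
  a <- adjacency_from_expression(expr, beta = 9)
  expect_equal(a["a", "b"], 1)
  r <- stats::cor(expr["a", ], expr["c", ])
  expect_equal(a["a", "c"], abs(r)^9, tolerance = 1e-12)
  expect_equal(0.5^9, 0.001953125)  # scale of a moderate correlation at beta 9
  expect_error(adjacency_from_expression(expr[, 1:3]), "at least 4")
  expect_error(adjacency_from_expression(rbind(expr, d = rep(1, 20))),
               "zero-variance")
})

test_that("TOM matches its closed forms and stays in [0, 1]", {
  two <- matrix(c(1, 1, 1, 1), 2, 2)
  expect_equal(tom_matrix(two)[1, 2], 1)
  none <- diag(2)
  expect_equal(tom_matrix(none)[1, 2], 0)
  clique <- matrix(0.5, 3, 3); diag(clique) <- 1
  expect_equal(tom_matrix(clique)[1, 2], (0.25 + 0.5) / (1 + 1 - 0.5),
               tolerance = 1e-12)

  withr::with_seed(16, {
    for (i in 1:5) {
      n <- sample(5:25, 1)
      a <- matrix(stats::runif(n * n), n, n)
      a <- (a + t(a)) / 2
      diag(a) <- 1
      tom <- tom_matrix(a)
      expect_true(all(tom >= -1e-12 & tom <= 1 + 1e-12))
      expect_equal(tom, t(tom), tolerance = 1e-12)
    }
  })

  ## with no shared neighbours TOM reduces to the adjacency
  pair <- diag(2); pair[1, 2] <- pair[2, 1] <- 0.3
  expect_equal(tom_matrix(pair)[1, 2], 0.3, tolerance = 1e-12)
})

test_that("module detection separates planted blocks and greys out noise", {
  withr::with_seed(17, {
    f1 <- stats::rnorm(30); f2 <- stats::rnorm(30)
    expr <- rbind(
      t(replicate(35, f1)) + matrix(stats::rnorm(35 * 30, 0, 1e-3), 35),
      t(replicate(35, f2)) + matrix(stats::rnorm(35 * 30, 0, 1e-3), 35))
    rownames(expr) <- paste0("t", 1:70)
    tom <- tom_matrix(adjacency_from_expression(expr))
    mods <- detect_modules(tom)
    expect_equal(dplyr::n_distinct(mods$module), 2)
    expect_equal(dplyr::n_distinct(mods$module[1:35]), 1)
    expect_equal(dplyr::n_distinct(mods$module[36:70]), 1)
    expect_identical(mods, detect_modules(tom))   # deterministic

    noise <- matrix(stats::rnorm(200 * 40), 200, 40,
                    dimnames = list(paste0("n", 1:200), NULL))
    tom_n <- tom_matrix(adjacency_from_expression(noise))
    expect_true(all(detect_modules(tom_n)$module == "grey"))
  })
})

test_that("eigengenes summarise their module and merging follows the
           correlation rule", {
  withr::with_seed(18, {
    f <- stats::rnorm(24)
    g <- stats::rnorm(24)                     # orthogonal factor
    expr <- rbind(
      t(replicate(10, f)) * stats::runif(10, 0.5, 2) +
        matrix(stats::rnorm(240, 0, 0.05), 10),
      t(replicate(10, 0.97 * f + 0.1 * stats::rnorm(24))) +
        matrix(stats::rnorm(240, 0, 0.05), 10),
      t(replicate(10, g)) + matrix(stats::rnorm(240, 0, 0.05), 10))
    rownames(expr) <- paste0("t", 1:30)
    assignment <- tibble::tibble(transcript_id = rownames(expr),
                                 module = rep(c("m1", "m2", "m3"), each = 10))
    out <- module_eigengene_and_merge(expr, assignment)
    ## the two factor-f modules merge; the orthogonal one stays
    expect_equal(dplyr::n_distinct(out$modules$module), 2)
    expect_equal(dplyr::n_distinct(out$modules$module[1:20]), 1)
    expect_equal(nrow(out$merges), 1)

    ## eigengene of a module of identical profiles correlates 1 with members
    same <- t(replicate(5, f)) + 0
    rownames(same) <- paste0("s", 1:5)
    me <- module_eigengene_and_merge(
      same, tibble::tibble(transcript_id = rownames(same), module = "m"))
    expect_equal(abs(stats::cor(me$eigengenes[, "m"], f)), 1,
                 tolerance = 1e-9)
    expect_equal(sum(me$eigengenes[, "m"]^2), 1, tolerance = 1e-9)
  })
})

test_that("kME and module-trait statistics follow the t-distribution form", {
  withr::with_seed(19, {
    f <- stats::rnorm(20)
    expr <- t(replicate(8, f)) + matrix(stats::rnorm(160, 0, 0.02), 8)
    rownames(expr) <- paste0("t", 1:8)
    me <- module_eigengene_and_merge(
      expr, tibble::tibble(transcript_id = rownames(expr), module = "m"))
    trait_perfect <- me$eigengenes[, "m"]
    traits <- cbind(perfect = trait_perfect, junk = stats::rnorm(20))
    out <- kme_and_trait_correlation(expr, me$eigengenes, traits)
    expect_true(all(out$kme$kme > 0.99))
    r <- out$module_trait$r[out$module_trait$trait == "perfect"]
    p <- out$module_trait$p[out$module_trait$trait == "perfect"]
    expect_equal(r, 1, tolerance = 1e-9)
    expect_lt(p, 1e-12)
    rj <- out$module_trait$r[out$module_trait$trait == "junk"]
    pj <- out$module_trait$p[out$module_trait$trait == "junk"]
    tj <- rj * sqrt(18) / sqrt(1 - rj^2)
    expect_equal(pj, 2 * stats::pt(abs(tj), 18, lower.tail = FALSE),
                 tolerance = 1e-12)
    expect_error(
      kme_and_trait_correlation(expr, me$eigengenes,
                                cbind(const = rep(1, 20))),
      "constant")
  })
})

test_that("hypergeometric enrichment equals direct tail summation", {
  universe <- paste0("g", 1:30)
  term2gene <- tibble::tibble(term_id = rep(c("T1", "T2"), c(10, 4)),
                              gene_id = c(paste0("g", 1:10),
                                          paste0("g", 25:28)))
  members <- paste0("g", 1:8)
  out <- hypergeometric_enrichment(members, term2gene, universe)
  expect_equal(out$p[out$term_id == "T1"],
               hyper_tail_oracle(8, 10, 30, 8), tolerance = 1e-12)
  expect_equal(out$p[out$term_id == "T2"], 1)  # k = 0 -> upper tail is 1
  expect_error(
    hypergeometric_enrichment(members,
                              tibble::tibble(term_id = "T", gene_id = "zzz"),
                              universe),
    "absent from universe")
})

test_that("hub selection ranks by sub-network degree and classes hubs", {
  nodes <- c(paste0("p", 1:10), paste0("q", 1:3), paste0("lnc", 1:4))
  w <- matrix(0, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  w[paste0("p", 1:10), "lnc1"] <- w["lnc1", paste0("p", 1:10)] <- 0.9
  w["p1", "lnc2"] <- w["lnc2", "p1"] <- 0.9
  w[paste0("q", 1:3), "lnc1"] <- w["lnc1", paste0("q", 1:3)] <- 0.9
  w["q1", "lnc3"] <- w["lnc3", "q1"] <- 0.9
  subnet <- tibble::tibble(
    subnetwork = c(rep("A", 10), rep("B", 3)),
    protein_id = c(paste0("p", 1:10), paste0("q", 1:3)))
  hubs <- hub_selection(w, 0.5, paste0("lnc", 1:4), subnet, top_k = 2)
  a <- hubs[hubs$subnetwork == "A", ]
  expect_equal(a$lncrna_id[1], "lnc1")        # star centre ranks first
  expect_equal(a$degree[1], 10)
  expect_equal(hubs$hub_class[hubs$lncrna_id == "lnc1"],
               c("inter", "inter"))           # selected in A and B
  expect_equal(unique(hubs$hub_class[hubs$lncrna_id == "lnc2"]), "intra")

  expect_warning(none <- hub_selection(w, 0.99, paste0("lnc", 1:4), subnet),
                 "no lncRNA")
  expect_equal(nrow(none), 0)
  expect_error(hub_selection(w, 0.5, "lnc1",
                             tibble::tibble(subnetwork = "Z",
                                            protein_id = "missing")),
               "empty sub-network")
})
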