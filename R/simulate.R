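## ---- sequence generators ---------------------------------------------------

## Background (noncoding) base composition: mildly AT-rich, i.i.d.
BG_PROBS <- c(A = 0.30, C = 0.20, G = 0.20, T = 0.30)

## Fixed position-specific codon bias used by the coding-sequence model.
## Any fixed non-uniform table creates a learnable in-frame hexamer signal;
## this one prefers A/G starts and C/G-ending (GC3-rich) codons.
codon_probs <- local({
  bases <- c("A", "C", "G", "T")
  p1 <- c(A = 0.35, C = 0.20, G = 0.30, T = 0.15)
  p2 <- c(A = 0.30, C = 0.30, G = 0.15, T = 0.25)
  p3 <- c(A = 0.20, C = 0.35, G = 0.30, T = 0.15)
  grid <- expand.grid(b3 = bases, b2 = bases, b1 = bases,
                      stringsAsFactors = FALSE)
  codon <- paste0(grid$b1, grid$b2, grid$b3)
  w <- p1[grid$b1] * p2[grid$b2] * p3[grid$b3]
  stops <- codon %in% c("TAA", "TAG", "TGA")
  w[stops] <- 0
  stats::setNames(w / sum(w), codon)
})

rand_seq <- function(n, probs = BG_PROBS) {
  paste(sample(names(probs), n, replace = TRUE, prob = probs), collapse = "")
}

## CDS of `aa` amino acids (incl. the initial Met) plus a stop codon.
gen_cds <- function(aa) {
  body <- sample(names(codon_probs), aa - 1, replace = TRUE,
                 prob = codon_probs)
  paste0("ATG", paste(body, collapse = ""),
         sample(c("TAA", "TAG", "TGA"), 1))
}

## Mean in-frame log-ratio of the maximal ORF's hexamers under the codon
## model versus the background model; windows containing a stop codon are
## skipped. Analytic (no trained table); used to verify planted coding-like
## content. Internal.
codon_model_llr <- function(s) {
  orf <- find_max_orf(s)
  if (orf$max_orf_aa == 0) return(-Inf)
  from <- orf$orf_start + 1L
  to <- orf$orf_start + orf$orf_nt
  st <- seq.int(from, to - 5L, by = 3L)
  hex <- substring(s, st, st + 5L)
  lp <- log(codon_probs[substr(hex, 1, 3)]) +
    log(codon_probs[substr(hex, 4, 6)])
  lbg <- vapply(base::strsplit(hex, "", fixed = TRUE),
                function(b) sum(log(BG_PROBS[b])), numeric(1))
  v <- lp - lbg
  mean(v[is.finite(v)])
}

## Coding-style sequence with no complete ORF longer than `max_aa`:
## codon-model blocks, each opened by ATG and closed by an in-frame stop.
## Rejection-sampled until the in-frame codon bias of the maximal ORF is
## at least as strong as that of genuine coding sequence (min_llr), so a
## planted "coding-like" decoy really carries the signal it is defined by.
gen_coding_like <- function(n_blocks = 3, block_aa = c(60, 96),
                            max_aa = 100, min_llr = 0.45) {
  for (attempt in 1:1000) {
    blocks <- vapply(seq_len(n_blocks), function(i) {
      gen_cds(sample(seq(block_aa[1], block_aa[2]), 1))
    }, character(1))
    s <- paste(blocks, collapse = "")
    if (find_max_orf(s)$max_orf_aa <= max_aa &&
        codon_model_llr(s) >= min_llr) {
      return(s)
    }
  }
  rlang::abort("could not generate a coding-like sequence without long ORFs")
}

## Background sequence rejected until its longest ORF is <= max_aa.
gen_noncoding_seq <- function(len, max_aa = 100) {
  for (attempt in 1:1000) {
    s <- rand_seq(len)
    if (find_max_orf(s)$max_orf_aa <= max_aa) return(s)
  }
  rlang::abort("could not generate a noncoding sequence without long ORFs")
}

## Split `total` into k parts, each >= min_len. Deterministic given RNG.
split_lengths <- function(total, k, min_len) {
  if (total < k * min_len) rlang::abort("length too short to split")
  extra <- total - k * min_len
  if (k == 1) return(total)
  cuts <- sort(sample.int(extra + 1, k - 1, replace = TRUE) - 1L)
  parts <- diff(c(0L, cuts, extra))
  as.integer(min_len + parts)
}

## Exon matrix from a genomic start, exon lengths and intron lengths.
make_exons <- function(start, exon_lens, intron_lens) {
  k <- length(exon_lens)
  starts <- integer(k)
  ends <- integer(k)
  pos <- start
  for (i in seq_len(k)) {
    starts[i] <- pos
    ends[i] <- pos + exon_lens[i]
    pos <- ends[i] + if (i < k) intron_lens[i] else 0L
  }
  cbind(start = starts, end = ends)
}

## ---- configuration ---------------------------------------------------------

#' Configuration of the synthetic transcriptome study
#'
#' Defaults emulate the structure of a multi-tissue, sexed insect RNA-seq
#' study: 10 scaffolds of 200 kb, 300 protein-coding mRNAs, 50 lincRNAs,
#' 20 intronic and 30 antisense lncRNAs, 10 planted decoys per cascade
#' failure stage, 8 tissues sampled in both sexes, negative-binomial
#' counts (dispersion 0.1) at nominal library size 1e6, three
#' tissue-associated co-expression modules and a 4-fold (log2FC = 2) sex
#' effect on a 15% subset of transcripts.
#'
#' @param seed Mandatory integer seed; the whole dataset is a
#'   deterministic function of it.
#' @param n_scaffolds,scaffold_length Genome geometry.
#' @param n_mrna,n_linc,n_ilnc,n_nat Numbers of coding genes and clean
#'   lncRNAs per class.
#' @param n_decoys_per_stage Planted decoys failing at each cascade stage
#'   1-6.
#' @param n_once_only Extra transcripts seen in a single
#'   (assembler, tissue) pair, removed by the stringent filter.
#' @param n_isoform_loci lincRNA loci given a second (exon-skip) isoform.
#' @param tissues Tissue names (>= 2).
#' @param modules Tibble with `tissue`, `n_members`, `strength` (log2
#'   scale of the shared tissue factor).
#' @param frac_sex_biased,sex_log2fc Fraction of transcripts with a
#'   planted sex effect and its magnitude (log2).
#' @param frac_specific Named fractions of tissue-specific transcripts
#'   per role.
#' @param dispersion,library_size Negative-binomial dispersion and
#'   nominal per-sample library size.
#' @param n_mirna,n_mirna_antisense,n_mre Planted precursor miRNAs,
#'   antisense (non-precursor) controls, and MRE-carrying lncRNAs.
#' @param jitter_bp Maximal terminal-exon jitter applied by the
#'   pseudo-assemblers.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed,
                       n_scaffolds = 10, scaffold_length = 200000,
                       n_mrna = 300, n_linc = 50, n_ilnc = 20, n_nat = 30,
                       n_decoys_per_stage = 10, n_once_only = 10,
                       n_isoform_loci = 10,
                       tissues = c("brain", "testis", "ovary", "fat_body",
                                   "malpighian", "integument", "msg", "psg"),
                       modules = tibble::tibble(
                         tissue = c("msg", "testis", "brain"),
                         n_members = c(50, 50, 50),
                         strength = c(3, 3, 3)),
                       frac_sex_biased = 0.15, sex_log2fc = 2,
                       frac_specific = c(mRNA = 0.3, lincRNA = 0.6,
                                         ilncRNA = 0.5, lncNAT = 0.4),
                       dispersion = 0.1, library_size = 1e6,
                       n_mirna = 8, n_mirna_antisense = 2, n_mre = 10,
                       jitter_bp = 50) {
  if (missing(seed)) rlang::abort("seed is mandatory")
  structure(as.list(environment()), class = "sim_config")
}

## ---- geometry --------------------------------------------------------------

## Sequential non-overlapping placement with a protected scaffold-end
## margin. Returns a closure allocating spans.
make_placer <- function(n_scaffolds, scaffold_length, margin = 2150) {
  cursors <- rep(margin, n_scaffolds)
  function(span, gap_range = c(200, 600)) {
    ord <- order(cursors)                     # fill evenly
    for (sc in ord) {
      gap <- sample(seq(gap_range[1], gap_range[2]), 1)
      start <- cursors[sc] + gap
      if (start + span <= scaffold_length - margin) {
        cursors[sc] <<- start + span
        return(list(scaffold = sc, start = as.integer(start)))
      }
    }
    rlang::abort("scaffolds exhausted; increase scaffold_length or n_scaffolds")
  }
}

#' Generate the synthetic genome, annotation and ground truth
#'
#' Builds the full toy dataset: genome FASTA, reference coding
#' annotation, candidate transcript geometry (clean lncRNAs of all three
#' classes, per-stage decoys, once-only transcripts, multi-isoform
#' loci), planted miRNAs and MRE sites, tissue/sex/module-structured
#' expression, pseudo-assembler GTF replicates and the machine-readable
#' truth manifest. Deterministic given `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @return A list with elements `genome` (DNAStringSet), `scaffolds`,
#'   `reference`, `transcripts` (planted candidate models), `assemblies`
#'   (tibble `assembler`, `tissue`, `transcripts`), `counts`, `fpkm`
#'   (matrices), `samples`, `coverage`, `mirna_loci`, `mirna_seqs`,
#'   `conserved`, `homology_hits`, `truth` and `config`.
#' @export
simulate_lnc_study <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(cfg$seed, simulate_lnc_study_impl(cfg))
}

simulate_lnc_study_impl <- function(cfg) {
  scaffold_names <- sprintf("scaffold%02d", seq_len(cfg$n_scaffolds))
  genome <- vapply(seq_len(cfg$n_scaffolds),
                   function(i) rand_seq(cfg$scaffold_length), character(1))
  names(genome) <- scaffold_names
  place <- make_placer(cfg$n_scaffolds, cfg$scaffold_length)

  write_seq <- function(sc, exons, strand, spliced) {
    g <- if (strand == "+") spliced else revcomp_dna(spliced)
    offs <- cumsum(c(0L, exons[, 2L] - exons[, 1L]))
    for (i in seq_len(nrow(exons))) {
      substr(genome[sc], exons[i, 1L] + 1L, exons[i, 2L]) <<-
        substring(g, offs[i] + 1L, offs[i + 1L])
    }
  }
  read_spliced <- function(sc, exons, strand) {
    s <- paste(substring(genome[sc], exons[, 1L] + 1L, exons[, 2L]),
               collapse = "")
    if (strand == "-") revcomp_dna(s) else s
  }

  tx_rows <- list()
  add_tx <- function(id, sc, strand, exons, role, stage = NA_character_,
                     category = NA_character_, host = NA_character_) {
    tx_rows[[length(tx_rows) + 1L]] <<- tibble::tibble(
      transcript_id = id, locus_id = id, scaffold = scaffold_names[sc],
      strand = strand, exons = list(exons), role = role,
      decoy_stage = stage, category = category, host = host
    )
  }

  ## -- mRNAs ------------------------------------------------------------
  n_hosts_ilnc <- cfg$n_ilnc
  for (i in seq_len(cfg$n_mrna)) {
    n_ex <- sample(3:8, 1)
    aa <- sample(150:400, 1)
    utr5 <- sample(100:250, 1)
    utr3 <- sample(100:400, 1)
    spliced_len <- utr5 + 3L * (aa + 1L) + utr3
    exon_lens <- split_lengths(spliced_len, n_ex, 80L)
    intron_lens <- sample(400:700, n_ex - 1, replace = TRUE)
    if (i <= n_hosts_ilnc) {           # reserve one wide intron for an ilncRNA
      intron_lens[sample(n_ex - 1, 1)] <- sample(1600:2400, 1)
    }
    strand <- sample(c("+", "-"), 1)
    span <- sum(exon_lens) + sum(intron_lens)
    at <- place(span)
    exons <- make_exons(at$start, exon_lens, intron_lens)
    spliced <- paste0(rand_seq(utr5), gen_cds(aa), rand_seq(utr3))
    write_seq(at$scaffold, exons, strand, spliced)
    add_tx(sprintf("mrna%03d", i), at$scaffold, strand, exons, "mRNA")
  }
  tx <- purrr::list_rbind(tx_rows)
  mrna <- tx[tx$role == "mRNA", ]

  gen_linc_like <- function(id, role, stage = NA, category = "lincRNA",
                            exon_range = 2:4, place_fun = place) {
    n_ex <- sample(exon_range, 1)
    exon_lens <- sample(150:400, n_ex, replace = TRUE)
    intron_lens <- sample(200:800, n_ex - 1, replace = TRUE)
    strand <- sample(c("+", "-"), 1)
    at <- place_fun(sum(exon_lens) + sum(intron_lens))
    exons <- make_exons(at$start, exon_lens, intron_lens)
    spliced <- gen_noncoding_seq(sum(exon_lens))
    write_seq(at$scaffold, exons, strand, spliced)
    add_tx(id, at$scaffold, strand, exons, role, stage, category)
  }

  ## -- clean lincRNAs ---------------------------------------------------
  for (i in seq_len(cfg$n_linc)) {
    gen_linc_like(sprintf("linc%03d", i), "lincRNA")
  }

  ## -- ilncRNAs inside reserved host introns ----------------------------
  for (i in seq_len(cfg$n_ilnc)) {
    host <- mrna[i, ]
    introns <- exon_introns(host$exons[[1]])
    wide <- which.max(introns[, 2L] - introns[, 1L])
    i0 <- introns[wide, 1L]
    exon_lens <- sample(120:200, 2, replace = TRUE)
    intron_len <- sample(200:400, 1)
    start <- i0 + 100L
    exons <- make_exons(start, exon_lens, intron_len)
    stopifnot(exons[2, 2] + 100 <= introns[wide, 2L])
    strand <- sample(c("+", "-"), 1)
    spliced <- gen_noncoding_seq(sum(exon_lens))
    sc <- match(host$scaffold, scaffold_names)
    write_seq(sc, exons, strand, spliced)
    add_tx(sprintf("ilnc%03d", i), sc, strand, exons, "ilncRNA",
           category = "ilncRNA", host = host$transcript_id)
  }

  ## -- lncNATs antisense to host first exons ----------------------------
  make_antisense <- function(id, host, same_strand = FALSE, role, stage = NA,
                             category = NA) {
    he <- host$exons[[1]]
    a <- he[1L, 1L]; b <- he[1L, 2L]
    intron1 <- c(b, he[2L, 1L])
    overlap <- min(150L, b - a)
    strand <- if (same_strand) host$strand else setdiff(c("+", "-"), host$strand)
    sc <- match(host$scaffold, scaffold_names)
    for (attempt in 1:20) {
      off2 <- 60L + 7L * (attempt - 1L)
      e2_len <- sample(180:260, 1)
      exons <- cbind(start = c(a - 150L, intron1[1] + off2),
                     end = c(a + overlap, intron1[1] + off2 + e2_len))
      if (exons[2, 2] + 20 > intron1[2]) next
      s <- read_spliced(sc, exons, strand)
      if (find_max_orf(s)$max_orf_aa <= 100) {
        add_tx(id, sc, strand, exons, role, stage, category,
               host = host$transcript_id)
        return(invisible(TRUE))
      }
    }
    rlang::abort(paste0("could not place antisense transcript near ",
                        host$transcript_id))
  }
  nat_hosts <- mrna[seq(n_hosts_ilnc + 1, n_hosts_ilnc + cfg$n_nat), ]
  for (i in seq_len(cfg$n_nat)) {
    make_antisense(sprintf("nat%03d", i), nat_hosts[i, ],
                   same_strand = FALSE, role = "lncNAT", category = "lncNAT")
  }

  ## -- decoys -----------------------------------------------------------
  nd <- cfg$n_decoys_per_stage
  s1_hosts <- mrna[seq(n_hosts_ilnc + cfg$n_nat + 1,
                       n_hosts_ilnc + cfg$n_nat + nd), ]
  for (i in seq_len(nd)) {              # stage 1: sense-exonic overlap
    make_antisense(sprintf("dec1_%02d", i), s1_hosts[i, ], same_strand = TRUE,
                   role = "decoy", stage = "sense_overlap")
  }
  s2_kind <- rep(c("short", "low_cov", "low_fpkm"), length.out = nd)
  for (i in seq_len(nd)) {              # stage 2: short / low-cov / low-FPKM
    if (s2_kind[i] == "short") {
      exon_lens <- c(42L, sample(40:45, 1))
      intron_len <- sample(200:400, 1)
      strand <- sample(c("+", "-"), 1)
      at <- place(sum(exon_lens) + intron_len)
      exons <- make_exons(at$start, exon_lens, intron_len)
      write_seq(at$scaffold, exons, strand,
                gen_noncoding_seq(sum(exon_lens)))
      add_tx(sprintf("dec2_%02d", i), at$scaffold, strand, exons,
             "decoy", "basic_filters")
    } else {
      gen_linc_like(sprintf("dec2_%02d", i), "decoy", "basic_filters",
                    category = NA)
    }
  }
  for (i in seq_len(nd)) {              # stage 3: ORF of 101-300 aa
    aa <- sample(101:300, 1)
    spliced <- paste0(rand_seq(80), gen_cds(aa), rand_seq(80))
    n_ex <- sample(2:3, 1)
    exon_lens <- split_lengths(nchar(spliced), n_ex, 80L)
    intron_lens <- sample(200:600, n_ex - 1, replace = TRUE)
    strand <- sample(c("+", "-"), 1)
    at <- place(sum(exon_lens) + sum(intron_lens))
    exons <- make_exons(at$start, exon_lens, intron_lens)
    write_seq(at$scaffold, exons, strand, spliced)
    add_tx(sprintf("dec3_%02d", i), at$scaffold, strand, exons,
           "decoy", "orf_filter")
  }
  for (i in seq_len(nd)) {              # stage 4: coding-like, short ORFs
    spliced <- gen_coding_like(n_blocks = 2, block_aa = c(80, 96))
    exon_lens <- split_lengths(nchar(spliced), 2L, 80L)
    intron_len <- sample(200:600, 1)
    strand <- sample(c("+", "-"), 1)
    at <- place(sum(exon_lens) + intron_len)
    exons <- make_exons(at$start, exon_lens, intron_len)
    write_seq(at$scaffold, exons, strand, spliced)
    add_tx(sprintf("dec4_%02d", i), at$scaffold, strand, exons,
           "decoy", "coding_potential")
  }
  for (i in seq_len(nd)) {              # stage 5: homology-hit-listed
    gen_linc_like(sprintf("dec5_%02d", i), "decoy", "homology",
                  category = NA)
  }
  for (i in seq_len(nd)) {              # stage 6: near a scaffold end
    exon_lens <- sample(130:180, 2, replace = TRUE)
    intron_len <- sample(200:300, 1)
    span <- sum(exon_lens) + intron_len
    sc <- ((i - 1L) %% cfg$n_scaffolds) + 1L
    start <- as.integer(cfg$scaffold_length - 1500L)
    exons <- make_exons(start, exon_lens, intron_len)
    strand <- sample(c("+", "-"), 1)
    write_seq(sc, exons, strand, gen_noncoding_seq(sum(exon_lens)))
    add_tx(sprintf("dec6_%02d", i), sc, strand, exons,
           "decoy", "scaffold_end")
  }

  ## -- once-only transcripts (fail the stringent filter) ----------------
  for (i in seq_len(cfg$n_once_only)) {
    gen_linc_like(sprintf("once%02d", i), "once_only", category = NA)
  }

  tx <- purrr::list_rbind(tx_rows)

  ## -- second isoforms for some multi-exon lincRNA loci -----------------
  linc_multi <- tx[tx$role == "lincRNA" & tx_n_exons(tx) >= 3, ]
  iso_added <- 0L
  for (j in seq_len(nrow(linc_multi))) {
    if (iso_added >= cfg$n_isoform_loci) break
    parent <- linc_multi[j, ]
    e <- parent$exons[[1]]
    e2 <- e[-2L, , drop = FALSE]
    sc <- match(parent$scaffold, scaffold_names)
    s <- read_spliced(sc, e2, parent$strand)
    if (find_max_orf(s)$max_orf_aa > 100) next
    iso_added <- iso_added + 1L
    tx_rows[[length(tx_rows) + 1L]] <- tibble::tibble(
      transcript_id = paste0(parent$transcript_id, "b"),
      locus_id = parent$transcript_id, scaffold = parent$scaffold,
      strand = parent$strand, exons = list(e2), role = "lincRNA",
      decoy_stage = NA_character_, category = "lincRNA",
      host = NA_character_
    )
  }
  tx <- purrr::list_rbind(tx_rows)
  tx$locus_id <- ifelse(is.na(tx$locus_id), tx$transcript_id, tx$locus_id)

  ## -- miRNAs: precursors, antisense controls, MRE donors ---------------
  linc_plus <- tx[tx$role == "lincRNA" & tx$strand == "+" &
                    !grepl("b$", tx$transcript_id), ]
  linc_any <- tx[tx$role == "lincRNA" & !grepl("b$", tx$transcript_id), ]
  n_mir_total <- cfg$n_mirna + cfg$n_mirna_antisense
  mir_rows <- list()
  mir_seqs <- character(0)
  mir_hosts <- linc_any$transcript_id[seq_len(n_mir_total)]
  for (i in seq_len(n_mir_total)) {
    host <- tx[tx$transcript_id == mir_hosts[i], ]
    e <- host$exons[[1]]
    wide <- which.max(e[, 2L] - e[, 1L])
    pos <- e[wide, 1L] + sample(10:(e[wide, 2L] - e[wide, 1L] - 32), 1)
    antisense <- i > cfg$n_mirna
    strand <- if (antisense) setdiff(c("+", "-"), host$strand) else host$strand
    sc <- match(host$scaffold, scaffold_names)
    gseq <- substring(genome[sc], pos + 1L, pos + 22L)
    mature <- if (strand == "-") revcomp_dna(gseq) else gseq
    name <- sprintf("bmo-miR-sim%d", i)
    mir_rows[[i]] <- tibble::tibble(
      scaffold = host$scaffold, start = pos, end = pos + 22L,
      strand = strand, name = name, host = host$transcript_id,
      antisense = antisense
    )
    mir_seqs[name] <- mature
  }
  mirna_loci <- purrr::list_rbind(mir_rows)

  ## -- MRE sites in conserved windows of + strand lincRNAs --------------
  mre_hosts <- setdiff(linc_plus$transcript_id, mir_hosts)
  mre_hosts <- mre_hosts[seq_len(min(cfg$n_mre, length(mre_hosts)))]
  site_types <- rep(c("8mer", "7mer-m8", "7mer-A1", "6mer"),
                    length.out = length(mre_hosts))
  mre_rows <- list()
  conserved_rows <- list()
  for (i in seq_along(mre_hosts)) {
    host <- tx[tx$transcript_id == mre_hosts[i], ]
    mir_name <- names(mir_seqs)[((i - 1L) %% cfg$n_mirna) + 1L]
    mir <- gsub("U", "T", mir_seqs[[mir_name]])
    core <- revcomp_dna(substr(mir, 2, 7))
    m8 <- revcomp_dna(substr(mir, 8, 8))
    type <- site_types[i]
    not_m8 <- setdiff(c("C", "G"), m8)[1]
    site <- switch(type,
      "8mer" = paste0(m8, core, "A"),
      "7mer-m8" = paste0(m8, core, "C"),
      "7mer-A1" = paste0(not_m8, core, "A"),
      "6mer" = paste0(not_m8, core, "C")
    )
    e <- host$exons[[1]]
    wide <- which.max(e[, 2L] - e[, 1L])
    sc <- match(host$scaffold, scaffold_names)
    placed <- FALSE
    for (attempt in 1:20) {
      off <- sample(12:(e[wide, 2L] - e[wide, 1L] - nchar(site) - 12), 1)
      gpos <- e[wide, 1L] + off
      old <- substring(genome[sc], gpos + 1L, gpos + nchar(site))
      substr(genome[sc], gpos + 1L, gpos + nchar(site)) <- site
      s <- read_spliced(sc, e, "+")
      if (find_max_orf(s)$max_orf_aa <= 100) { placed <- TRUE; break }
      substr(genome[sc], gpos + 1L, gpos + nchar(site)) <- old
    }
    if (!placed) next
    offs <- cumsum(c(0L, e[, 2L] - e[, 1L]))
    spliced_site <- offs[wide] + off
    hit_start <- if (type %in% c("8mer", "7mer-m8")) spliced_site else spliced_site + 1L
    hit_end <- hit_start +
      switch(type, "8mer" = 8L, "7mer-m8" = 7L, "7mer-A1" = 7L, "6mer" = 6L)
    mre_rows[[length(mre_rows) + 1L]] <- tibble::tibble(
      transcript_id = host$transcript_id, mirna = mir_name,
      site_type = type, start = hit_start, end = hit_end
    )
    total_len <- sum(e[, 2L] - e[, 1L])
    conserved_rows[[length(conserved_rows) + 1L]] <- tibble::tibble(
      transcript_id = host$transcript_id,
      start = max(0L, hit_start - 80L),
      end = min(total_len, hit_end + 80L)
    )
  }
  empty_mre <- tibble::tibble(transcript_id = character(0),
                              mirna = character(0), site_type = character(0),
                              start = integer(0), end = integer(0))
  mre_truth <- if (length(mre_rows) > 0) purrr::list_rbind(mre_rows) else empty_mre
  conserved <- if (length(conserved_rows) > 0) {
    purrr::list_rbind(conserved_rows)
  } else {
    tibble::tibble(transcript_id = character(0), start = integer(0),
                   end = integer(0))
  }

  ## -- homology hits for stage-5 decoys ---------------------------------
  homology_hits <- tibble::tibble(
    transcript_id = tx$transcript_id[tx$decoy_stage %in% "homology"],
    subject = sprintf("sp|P%05d|SIMPROT", seq_len(nd)),
    evalue = 1e-10
  )

  ## -- expression -------------------------------------------------------
  expr <- simulate_expression_impl(tx, cfg)

  ## -- assemblies -------------------------------------------------------
  assemblies <- simulate_assembly_impl(tx, expr$tissue_weights, cfg)

  ## -- truth manifest ---------------------------------------------------
  truth <- tx |>
    dplyr::mutate(chain_key = intron_chain_key(tx)) |>
    dplyr::select("transcript_id", "locus_id", "role", "decoy_stage",
                  "category", "chain_key") |>
    dplyr::left_join(expr$truth_expr, by = "transcript_id") |>
    dplyr::left_join(
      dplyr::select(dplyr::filter(mirna_loci, !.data$antisense),
                    host = "host", precursor_mirna = "name"),
      by = c(transcript_id = "host")
    ) |>
    dplyr::left_join(
      dplyr::select(mre_truth, "transcript_id", mre_mirna = "mirna",
                    mre_type = "site_type", mre_start = "start"),
      by = "transcript_id"
    )

  genome_set <- Biostrings::DNAStringSet(genome)
  scaffolds <- tibble::tibble(name = scaffold_names,
                              length = cfg$scaffold_length)

  ## geometry invariants, asserted post-generation
  clean <- tx$role %in% c("lincRNA", "ilncRNA", "lncNAT")
  seqs <- spliced_sequence(tx[clean, ], genome_set)
  stopifnot(all(find_max_orf(seqs)$max_orf_aa <= 100))
  d6 <- tx_span(tx[tx$decoy_stage %in% "scaffold_end", ])
  stopifnot(all(d6$end > cfg$scaffold_length - 2000))

  list(genome = genome_set, scaffolds = scaffolds,
       reference = validate_transcripts(
         dplyr::select(mrna, "transcript_id", "locus_id", "scaffold",
                       "strand", "exons")),
       transcripts = tx, assemblies = assemblies,
       counts = expr$counts, fpkm = expr$fpkm, samples = expr$samples,
       coverage = expr$coverage, tissue_weights = expr$tissue_weights,
       mirna_loci = mirna_loci, mirna_seqs = gsub("T", "U", mir_seqs),
       mre_truth = mre_truth, conserved = conserved,
       homology_hits = homology_hits, truth = truth, config = cfg)
}

## ---- expression ------------------------------------------------------------

## Tissue weights, module/sex assignments, NB counts and FPKM. Internal;
## runs inside the seeded block of simulate_lnc_study_impl().
simulate_expression_impl <- function(tx, cfg) {
  n <- nrow(tx)
  tissues <- cfg$tissues
  nt <- length(tissues)
  samples <- tibble::tibble(
    sample_id = paste0(rep(tissues, each = 2), "_", c("F", "M")),
    tissue = rep(tissues, each = 2),
    sex = rep(c("F", "M"), nt),
    library_size = cfg$library_size
  )

  role <- tx$role
  base_log2 <- ifelse(role == "mRNA", stats::rnorm(n, 6, 1.2),
                      stats::rnorm(n, 4.5, 1.2))

  ## tissue specificity
  frac <- cfg$frac_specific
  spec_prob <- dplyr::case_when(
    role == "mRNA" ~ frac[["mRNA"]], role == "lincRNA" ~ frac[["lincRNA"]],
    role == "ilncRNA" ~ frac[["ilncRNA"]], role == "lncNAT" ~ frac[["lncNAT"]],
    .default = 0.2
  )
  is_specific <- stats::runif(n) < spec_prob
  tissue_pref <- rep(1, nt)                     # brain/testis-heavy if present
  tissue_pref[tissues == "brain"] <- 2
  tissue_pref[tissues == "testis"] <- 3
  spec_tissue <- sample(tissues, n, replace = TRUE, prob = tissue_pref)
  pure <- is_specific & stats::runif(n) < 0.5
  w <- matrix(NA_real_, n, nt, dimnames = list(tx$transcript_id, tissues))
  for (i in seq_len(n)) {
    if (pure[i]) {
      w[i, ] <- 0
      w[i, spec_tissue[i]] <- 1
    } else if (is_specific[i]) {
      alpha <- rep(0.1, nt)
      alpha[match(spec_tissue[i], tissues)] <- 8
      g <- stats::rgamma(nt, alpha)
      w[i, ] <- g / sum(g)
    } else {
      g <- stats::rgamma(nt, 5)
      w[i, ] <- g / sum(g)
    }
  }

  ## co-expression modules among non-specific clean transcripts
  module_id <- rep(NA_character_, n)
  eligible <- which(!is_specific & role %in% c("mRNA", "lincRNA", "ilncRNA",
                                               "lncNAT"))
  mods <- cfg$modules
  pool <- eligible
  factor_mat <- matrix(0, n, nrow(samples))
  for (m in seq_len(nrow(mods))) {
    take <- min(mods$n_members[m], length(pool))
    if (take == 0) next
    members <- sample(pool, take)
    pool <- setdiff(pool, members)
    module_id[members] <- paste0("M", m, "_", mods$tissue[m])
    ind <- as.numeric(samples$tissue == mods$tissue[m])
    f <- mods$strength[m] * (ind - mean(ind)) +
      stats::rnorm(nrow(samples), 0, 0.3)
    factor_mat[members, ] <- matrix(f, length(members), nrow(samples),
                                    byrow = TRUE)
  }

  ## sex bias
  sexable <- role %in% c("mRNA", "lincRNA", "ilncRNA", "lncNAT")
  sex_biased <- sexable & stats::runif(n) < cfg$frac_sex_biased
  sex_dir <- ifelse(sex_biased, sample(c("F", "M"), n, replace = TRUE),
                    "none")
  sex_mat <- matrix(0, n, nrow(samples))
  f_cols <- samples$sex == "F"
  sex_mat[sex_dir == "F", f_cols] <- cfg$sex_log2fc
  sex_mat[sex_dir == "M", !f_cols] <- cfg$sex_log2fc

  ## means and counts; low-FPKM decoys are silent in every sample (any
  ## single read at this library size already exceeds FPKM 0.1)
  zero_expr <- rep(FALSE, n)
  low_kind <- rep(NA_character_, n)
  d2 <- which(!is.na(tx$decoy_stage) & tx$decoy_stage == "basic_filters")
  if (length(d2) > 0) {
    kinds <- rep(c("short", "low_cov", "low_fpkm"), length.out = length(d2))
    low_kind[d2] <- kinds
    zero_expr[d2[kinds == "low_fpkm"]] <- TRUE
  }

  tissue_of_sample <- match(samples$tissue, tissues)
  mu <- (2^base_log2 * nt) * w[, tissue_of_sample] *
    2^(factor_mat + sex_mat)
  mu[zero_expr, ] <- 0
  counts <- matrix(stats::rnbinom(length(mu), mu = mu,
                                  size = 1 / cfg$dispersion),
                   n, nrow(samples),
                   dimnames = list(tx$transcript_id, samples$sample_id))
  counts[is.na(counts)] <- 0L
  lens <- tx_spliced_length(tx)
  fpkm <- counts * 1e9 / (lens * cfg$library_size)

  ## per-tissue read coverage; max across tissues is the attribute the
  ## cascade filters on
  cov_base <- stats::runif(n, 5, 50)
  cov_base[low_kind %in% "low_cov"] <- stats::runif(sum(low_kind %in% "low_cov"),
                                                    0.2, 0.7)
  wmax <- apply(w, 1, max)
  coverage <- tibble::as_tibble(
    sweep(w, 1, ifelse(wmax == 0, 1, wmax), "/") * cov_base,
    .name_repair = "minimal"
  )
  names(coverage) <- tissues
  coverage <- dplyr::bind_cols(
    tibble::tibble(transcript_id = tx$transcript_id), coverage)

  truth_expr <- tibble::tibble(
    transcript_id = tx$transcript_id,
    specificity_tissue = ifelse(is_specific, spec_tissue, "ubiquitous"),
    pure_specific = pure,
    sex_bias = sex_dir,
    module = module_id,
    low_kind = low_kind
  )
  list(counts = counts, fpkm = fpkm, samples = samples,
       coverage = coverage, tissue_weights = w, truth_expr = truth_expr)
}

## ---- pseudo-assembler replicates -------------------------------------------

## Each transcript is observed in >= 2 (assembler, tissue) pairs chosen
## among its most expressed tissues (once-only transcripts in exactly
## one); terminal exon ends are jittered, introns untouched. Internal;
## runs inside the seeded block.
simulate_assembly_impl <- function(tx, tissue_weights, cfg) {
  assemblers <- c("cufflinks", "scripture", "stringtie")
  tissues <- cfg$tissues
  slots <- expand.grid(assembler = assemblers, tissue = tissues,
                       stringsAsFactors = FALSE)
  obs <- vector("list", nrow(slots))

  top_tissues <- apply(tissue_weights, 1, function(v) {
    tissues[order(-v, stats::runif(length(v)))]
  })
  for (i in seq_len(nrow(tx))) {
    tt <- top_tissues[, i]
    if (tx$role[i] == "once_only") {
      picks <- tibble::tibble(assembler = sample(assemblers, 1),
                              tissue = tt[1])
    } else {
      mode <- sample(c("assemblers", "tissues", "both"), 1)
      picks <- switch(mode,
        assemblers = tibble::tibble(assembler = sample(assemblers, 2),
                                    tissue = tt[1]),
        tissues = tibble::tibble(assembler = sample(assemblers, 1),
                                 tissue = tt[1:2]),
        both = tidyr::crossing(assembler = sample(assemblers, 2),
                               tissue = tt[1:2])
      )
    }
    for (j in seq_len(nrow(picks))) {
      slot <- which(slots$assembler == picks$assembler[j] &
                      slots$tissue == picks$tissue[j])
      e <- tx$exons[[i]]
      w1 <- e[1L, 2L] - e[1L, 1L]
      wk <- e[nrow(e), 2L] - e[nrow(e), 1L]
      e[1L, 1L] <- e[1L, 1L] - sample(seq(-min(cfg$jitter_bp, w1 - 10L),
                                          cfg$jitter_bp), 1)
      e[nrow(e), 2L] <- e[nrow(e), 2L] + sample(seq(-min(cfg$jitter_bp, wk - 10L),
                                                    cfg$jitter_bp), 1)
      obs[[slot]][[length(obs[[slot]]) + 1L]] <- tibble::tibble(
        transcript_id = tx$transcript_id[i], locus_id = tx$locus_id[i],
        scaffold = tx$scaffold[i], strand = tx$strand[i], exons = list(e)
      )
    }
  }
  slots$transcripts <- purrr::map(obs, function(x) {
    if (is.null(x)) {
      transcript_tbl(transcript_id = character(0), scaffold = character(0),
                     strand = character(0), exons = list())
    } else {
      purrr::list_rbind(x)
    }
  })
  tibble::as_tibble(slots[lengths(obs) > 0, ])
}

#' Standalone access to the expression and assembly sub-generators
#'
#' [simulate_lnc_study()] runs both inside one seeded block; these
#' wrappers expose them separately for testing, each seeded on its own.
#'
#' @param tx Planted transcript tibble (with `role`, `decoy_stage`).
#' @param cfg A [sim_config()].
#' @param tissue_weights Transcripts x tissues weight matrix as produced
#'   by `simulate_expression()`.
#' @param seed Integer seed.
#' @return `simulate_expression()`: list with `counts`, `fpkm`,
#'   `samples`, `coverage`, `tissue_weights`, `truth_expr`;
#'   `simulate_assembly_replicates()`: tibble of
#'   (`assembler`, `tissue`, `transcripts`) observations.
#' @export
simulate_expression <- function(tx, cfg, seed = cfg$seed) {
  withr::with_seed(seed, simulate_expression_impl(tx, cfg))
}

#' @rdname simulate_expression
#' @export
simulate_assembly_replicates <- function(tx, tissue_weights, cfg,
                                         seed = cfg$seed) {
  withr::with_seed(seed, simulate_assembly_impl(tx, tissue_weights, cfg))
}

## ---- corpus for the coding-potential model ---------------------------------

#' Simulate a coding/noncoding training corpus
#'
#' Coding transcripts carry a codon-model CDS of 150-450 aa between
#' short UTRs; noncoding transcripts are background sequence
#' rejection-sampled to have no ORF above 100 aa. Used to train and
#' evaluate the coding-potential scorer.
#'
#' @param n_per_class Sequences per class.
#' @param seed Integer seed.
#' @return A tibble with `seq`, `cds` (NA for noncoding), and logical
#'   `coding`.
#' @export
simulate_coding_corpus <- function(n_per_class = 500, seed = 1) {
  withr::with_seed(seed, {
    coding <- purrr::map(seq_len(n_per_class), function(i) {
      cds <- gen_cds(sample(150:450, 1))
      tibble::tibble(
        seq = paste0(rand_seq(sample(50:150, 1)), cds,
                     rand_seq(sample(100:300, 1))),
        cds = cds, coding = TRUE)
    })
    noncoding <- purrr::map(seq_len(n_per_class), function(i) {
      tibble::tibble(seq = gen_noncoding_seq(sample(300:2000, 1)),
                     cds = NA_character_, coding = FALSE)
    })
    purrr::list_rbind(c(coding, noncoding))
  })
}

## ---- serialisation ---------------------------------------------------------

#' Write a simulated study to disk
#'
#' Emits the plain-text files a real study would provide: `genome.fa`,
#' `ref.gtf`, per-(assembler, tissue) GTFs with `manifest.tsv`,
#' `counts.tsv`, `fpkm.tsv`, `coverage.tsv`, `samples.tsv`,
#' `quant_key.tsv` (transcript to intron-chain key, the join used to
#' attach quantification to merged models), `mirna.gff3`, `mirna.fa`,
#' `conserved.tsv`, `hits.tsv` and `truth.tsv`.
#'
#' @param sim Output of [simulate_lnc_study()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(file.path(dir, "assemblies"), recursive = TRUE,
             showWarnings = FALSE)
  Biostrings::writeXStringSet(sim$genome, file.path(dir, "genome.fa"))
  readr::write_tsv(sim$scaffolds, file.path(dir, "scaffolds.tsv"),
                   col_names = FALSE)
  write_gtf(sim$reference, file.path(dir, "ref.gtf"))
  manifest <- sim$assemblies |>
    dplyr::mutate(gtf_path = file.path("assemblies",
                                       paste0(.data$assembler, "_",
                                              .data$tissue, ".gtf")))
  purrr::pwalk(list(manifest$transcripts, manifest$gtf_path),
               function(t, p) write_gtf(t, file.path(dir, p)))
  readr::write_tsv(dplyr::select(manifest, -"transcripts"),
                   file.path(dir, "manifest.tsv"))
  mat_tsv <- function(m, path) {
    readr::write_tsv(tibble::as_tibble(m, rownames = "transcript_id"), path)
  }
  mat_tsv(sim$counts, file.path(dir, "counts.tsv"))
  mat_tsv(sim$fpkm, file.path(dir, "fpkm.tsv"))
  readr::write_tsv(sim$coverage, file.path(dir, "coverage.tsv"))
  readr::write_tsv(sim$samples, file.path(dir, "samples.tsv"))
  readr::write_tsv(
    dplyr::select(sim$truth, "transcript_id", "chain_key"),
    file.path(dir, "quant_key.tsv"))
  gff <- sprintf("%s\tsim\tmiRNA\t%d\t%d\t.\t%s\t.\tID=%s;Name=%s",
                 sim$mirna_loci$scaffold, sim$mirna_loci$start + 1L,
                 sim$mirna_loci$end, sim$mirna_loci$strand,
                 sim$mirna_loci$name, sim$mirna_loci$name)
  writeLines(c("##gff-version 3", gff), file.path(dir, "mirna.gff3"))
  writeLines(paste0(">", names(sim$mirna_seqs), "\n",
                    unname(sim$mirna_seqs)),
             file.path(dir, "mirna.fa"))
  readr::write_tsv(sim$conserved, file.path(dir, "conserved.tsv"))
  readr::write_tsv(sim$homology_hits, file.path(dir, "hits.tsv"))
  readr::write_tsv(dplyr::select(sim$truth, -dplyr::any_of("exons")),
                   file.path(dir, "truth.tsv"))
  invisible(dir)
}
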