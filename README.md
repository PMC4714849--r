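# lncforge

Genome-wide identification and characterisation of long non-coding RNAs
(lncRNAs) from multi-assembler transcriptome assemblies, as a tested,
deterministic R pipeline.

Transcript assemblers run on deep RNA-seq emit millions of fragments;
only a small fraction are credible lncRNAs. `lncforge` is for
transcriptomics researchers who need that filtering to be reproducible
and auditable. It implements:

* **Consensus selection and merge** — transcripts are identified by
  their intron chain (scaffold + strand + ordered intron coordinates);
  a chain is kept iff seen by ≥ 2 assembly programs or in ≥ 2 tissues
  ("stringent" transcripts), then chains are merged into a unique set
  with terminal exon ends taken as the union over witnesses.
* **A seven-stage identification cascade** with per-stage accounting:
  (1) drop sense overlap with coding exons; (2) drop length < 200 nt,
  single-exon, read coverage < 0.8 or FPKM < 0.1; (3) drop maximal ORF
  > 100 aa; (4) drop predicted coding potential (internal scorer
  probability > 0.345, or external `cpc`/`cnci` scores > 0); (5) drop
  protein homology hits at E < 1e-6; (6) drop transcripts within 2 kb of
  scaffold ends; (7) keep class codes `i`/`u`/`x` as intronic
  (ilncRNA), intergenic (lincRNA) and natural-antisense (lncNAT)
  transcripts.
* **Coding-potential scoring** — logistic regression on maximal ORF
  length, ORF coverage, the Fickett TESTCODE statistic and an in-frame
  hexamer log-likelihood ratio, trained on a synthetic corpus, with
  broom-style `tidy()`/`glance()` accessors.
* **Tissue specificity** — the Jensen–Shannon score
  `max_t (1 − sqrt(JSD(p, e_t)))` with log base 2, called specific at
  `> 0.25`.
* **Sex bias** — exact binomial test of female vs male pooled counts
  under library-size-proportional sampling, called at `|log2FC| > 1`
  and BH FDR < 0.05 per tissue; locus-level calls at a biased-isoform
  ratio `> 0.75`.
* **miRNA interactions** — precursor detection by same-strand locus
  overlap with mature miRNAs, and canonical seed-site (MRE) scanning
  (6mer / 7mer-A1 / 7mer-m8 / 8mer) restricted to conserved regions for
  ceRNA candidates.
* **Co-expression networks** — unsigned adjacency `|cor|^9`, the
  topological overlap matrix
  `TOM_ij = (l_ij + a_ij)/(min(k_i,k_j) + 1 − a_ij)`, average-linkage
  modules on `1 − TOM`, eigengene merging at correlation > 0.70, kME,
  module–trait correlation, hypergeometric enrichment and top-5-degree
  hub lncRNAs per functional sub-network.
* **A ground-truth simulator** — genome, annotation, pseudo-assembler
  GTFs with terminal jitter, planted lncRNA classes and per-stage
  decoys, tissue/sex/module-structured negative-binomial expression,
  planted miRNA precursors and seed sites, and a machine-readable truth
  manifest, all a deterministic function of one seed.

Everything is tibble-in/tibble-out and pipe-friendly; standard formats
(GTF, GFF3, BED, FASTA) are read through rtracklayer and Biostrings.

## Worked example

Simulate the default study (480 planted transcripts on a 2 Mb genome,
8 tissues × 2 sexes), run both pipeline halves, and inspect the
results:

```r
library(lncforge)

sim <- simulate_lnc_study(sim_config(seed = 1))
write_simulation(sim, "study")

ident <- run_identify("study", "study/ident")
ident$report$stages
#>   stage            input_n retained_n
#> 1 sense_overlap        470        160
#> 2 basic_filters        160        150
#> 3 orf_filter           150        140
#> 4 coding_potential     140        130
#> 5 homology             130        120
#> 6 scaffold_end         120        110
#> 7 classification       110        110
```

The cascade starts from 470 merged consensus transcripts (the ten
"once-only" plants never survive the stringent filter): 310 are removed
as sense overlaps of coding genes (300 mRNAs plus 10 planted decoys),
and each later stage removes exactly its ten planted decoys, leaving the
110 planted clean lncRNAs. Categories and downstream biology:

```r
char <- run_characterize("study", "study/ident", "study/char")
char$summary
#> $n_lncrna             110
#> $n_loci               100
#> $n_by_category        ilncRNA 20, lincRNA 60, lncNAT 30
#> $n_tissue_specific    102
#> $n_sex_biased_loci    46
#> $n_precursor_pairs    8
#> $n_cerna_candidates   10
#> $n_modules            4
#> $n_hub_lncrnas        20

dplyr::arrange(char$module_trait, dplyr::desc(abs(r)))
#>   module    trait      r        p
#> 1 blue      testis 0.997 1.15e-16
#> 2 brown     msg    0.978 5.46e-11
#> 3 turquoise brain  0.976 1.10e-10
#> 4 yellow    psg    0.938 7.62e- 8
```

All three planted tissue-associated modules are recovered with
eigengene–trait correlations above 0.97 (the fourth module is an
emergent cluster of co-specific transcripts); all 8 planted miRNA
precursors and all 10 planted MRE carriers are found. Comparing against
the truth manifest is one join:

```r
match_truth(ident$records, sim$truth) |>
  dplyr::count(category, role)
#> 110 of 110 planted clean lncRNAs recovered, each in its planted class
```

Plot helpers (`plot_filter_cascade()`, `plot_specificity()`,
`plot_module_trait()`) give ggplot2 views of the cascade, the JS-score
distributions and the module–trait heatmap.

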