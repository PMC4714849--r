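---
title: "Methods: lncRNA identification and characterisation with lncforge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lncRNA identification and characterisation with lncforge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Long non-coding RNAs (lncRNAs) are transcripts longer than 200 nt with no
open reading frame above 100 amino acids. Discovering them genome-wide
from short-read RNA-seq is a filtering problem: transcript assemblers
emit millions of fragments, most of which are mis-assemblies, coding
transcripts, or truncation artefacts. `lncforge` implements the full
desk half of such a study as a reusable, deterministic pipeline:
consensus transcript selection across assemblers and tissues, a
seven-stage identification cascade with class-based categorisation,
coding-potential scoring, tissue-specificity and sex-bias statistics,
miRNA precursor and response-element detection, and weighted
co-expression modules with hub selection. A ground-truth simulator makes
every stage testable without any external download.

# Consensus ("stringent") transcripts and merging

Each assembled GTF is reduced to intron chains: two transcripts are the
same isoform iff they share scaffold, strand and the exact ordered list
of intron coordinates; terminal exon ends do not enter the identity.
A chain is *stringent* when it is reported by at least two assembly
programs or observed in at least two tissues; duplicates within one
(assembler, tissue) GTF count once. Stringent chains are merged into a
unique transcript set: one model per chain, with terminal exon
boundaries taken as the union over witnesses (minimum start, maximum
end). The union is our choice — the tools this emulates do not document
how they reconcile witness ends — and it is the conservative option for
the downstream length filter. Locus ids come from single-linkage
clustering of same-strand exonic overlap; antisense overlap never joins
loci, which is what makes the natural-antisense class meaningful.
Witness expression attributes are discarded: abundance is re-estimated
on the merged set, matching workflows that re-quantify abundance after merging.

Single-exon transcripts carry no intron chain and are excluded up front;
with non-strand-specific libraries their orientation is unknowable, so
this exclusion is also the scientifically safe choice.

# The identification cascade

Stages run in a fixed order; each candidate is attributed to the first
stage that removes it. Stages 2–6 are pure per-transcript predicates, so
the surviving set does not depend on the order — only the attribution
does.

1. **Sense overlap** — any exon overlapping a reference coding exon on
   the same strand by ≥ 1 bp.
2. **Basic filters** — spliced length < 200 nt, < 2 exons, per-base read
   coverage < 0.8, or FPKM < 0.1. Coverage and FPKM are the maximum
   across tissues: a transcript credibly expressed anywhere is kept,
   matching a single filter applied to the merged set rather than
   per-tissue filtering (a choice the config makes explicit).
3. **ORF filter** — maximal ORF > 100 aa. The ORF caller scans the three
   forward frames of the oriented transcript for `ATG…stop` spans;
   ORFs without an in-frame stop before the transcript end do not
   count, the start codon is strictly ATG, and ties break to the
   leftmost start. This is deterministic and conservative.
4. **Coding potential** — internal scorer probability > 0.345, or any
   supplied external score column (`cpc`, `cnci`) > 0; the calls are
   OR-combined, mirroring "any scorer says coding → drop".
5. **Homology** — any hit at E-value < 1e-6 in a supplied tabular
   protein-homology table. The package consumes precomputed tables
   rather than running a search, which keeps it download-free; the
   underlying operation is a thresholding step either way.
6. **Scaffold end** — genomic span within 2 kb of either scaffold end
   (incomplete assemblies at contig boundaries).
7. **Classification** — class codes `i`/`u`/`x` are retained and mapped
   to categories: intronic (ilncRNA), intergenic (lincRNA), antisense
   (lncNAT).

Class `i` requires containment within a single intron of a single
reference transcript and accepts either strand (sense-exonic overlap has
already been removed by stage 1); a same-strand-only variant is a flag.
Class `x` requires exonic antisense overlap, not merely locus overlap —
our reading of common class-code practice.

# The coding-potential scorer

The internal scorer follows the classic alignment-free design: four
features — maximal ORF length (nt), ORF coverage, the Fickett TESTCODE
statistic, and an in-frame hexamer usage log-likelihood ratio — combined
by logistic regression on standardised features.

* **Fickett TESTCODE** is computed from the published position-asymmetry
  and composition lookup tables, embedded as constants; it is a pure
  function of the sequence (case-insensitive, `N` not counted) and is
  only defined here for sequences ≥ 200 nt, consistent with the
  upstream length filter.
* **Hexamer ratio**: the mean over in-frame hexamers of the maximal ORF
  (whole sequence in frame 0 when there is no complete ORF) of
  `log(f_coding/f_noncoding)`. The table is trained from in-frame
  hexamers of coding ORFs versus all-frame hexamers of noncoding
  sequences, Laplace-smoothed.
* The default decision boundary, probability **0.345**, is kept for
  comparability with the published coding-potential tool it stands in
  for; that number was calibrated on that tool's original training
  corpus, not ours, so `fit_coding_model(..., recalibrate = TRUE)`
  replaces it with the Youden-optimal threshold on held-out data.
* The model trains on the package's own synthetic corpus (500 sequences
  per class by default): no external training data exist for this
  scorer by design. Training is seed-deterministic; the held-out AUC is
  reported in `glance()`.

Comparable pipelines consult up to three external scorers; two of the
usual ones depend
on external databases and pretrained models, so they are accepted as
optional score columns rather than reimplemented.

# Tissue specificity and sex bias

The tissue-specificity score of a transcript is
`max_t (1 − sqrt(JSD(p, e_t)))`, where `p` is the expression profile
normalised to sum 1, `e_t` the unit profile of tissue `t`, and JSD the
Jensen–Shannon divergence with log base 2 (`0·log 0 = 0`). The score
lies in [0, 1], is invariant to positive rescaling, and equals 1 exactly
for single-tissue expression. The specificity call uses a strict
`> 0.25` comparison; conventions differ on the boundary side, so it is configurable.

Sex bias per tissue is tested on pooled counts with an exact binomial
test: under library-size-proportional sampling with no sex effect, the
female count conditional on the total is binomial with success
probability `N_F/(N_F+N_M)`. This replaces the normal-approximate random-sampling model of the
differential-expression tools commonly used for pooled libraries — same null, exact tail — and preserves the decision rule
(`|log2FC| > 1` and BH FDR < 0.05, corrected per tissue across
transcripts). The fold change uses a 0.5 pseudocount. Two caveats are
deliberate and documented: (i) the test, like the tool it replaces, is
calibrated under its sampling null; with biological replicate
overdispersion it is anti-conservative, which is why the package's
calibration checks draw Poisson counts; (ii) with one library per
(tissue, sex), "biased" means biased at the sampling level, as in the
pooled-library design this emulates.

A transcript counts as sex-biased at the locus level if it is biased in
at least one tissue (the roll-up rule is not documented in the source
convention; "any tissue" is the inclusive choice). A multi-isoform locus
is sex-biased iff its biased-isoform ratio strictly exceeds 0.75; a
single-isoform locus inherits its isoform's call.

# miRNA precursors and response elements

A lncRNA locus is a candidate miRNA precursor when a mature miRNA
interval overlaps the locus span on the same strand by ≥ 1 bp; because
genuine pre-miRNA hairpins are exonic, exonic containment is flagged
separately rather than required. Response elements (MREs) are found by
canonical seed matching on the spliced sense sequence: 6mer (reverse
complement of miRNA positions 2–7), 7mer-m8 (2–8), 7mer-A1 (2–7 plus
`A` opposite position 1) and 8mer; each seed-core occurrence is reported
once at its strongest type. Seed matching is the shared core of the standard site predictors
(miRanda, PITA, RNAhybrid);
thermodynamic scoring would import a folding engine and is out of
scope. Hits are kept only when fully inside supplied conserved regions
(spliced coordinates), and a transcript becomes a ceRNA candidate with
hits from at least `min_distinct_mirnas` distinct miRNAs — a knob; how multiple external predictors should be combined has no
single convention.

# Co-expression network

Transcripts expressed in at least two samples enter the network. The
adjacency is unsigned, `|cor|^9` (Pearson): the soft power 9 is this workflow's standard choice, and unsigned was the prevailing default of the
era; both are configurable. The topological overlap matrix is

```
TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 − a_ij),
l_ij = Σ_{u≠i,j} a_iu a_uj,  k_i = Σ_{u≠i} a_iu
```

Modules come from average-linkage clustering of `1 − TOM` with a
*static* cut at height 0.995 — fully specified and deterministic, where dynamic tree cutting has tunable internals. Minimum module size defaults to 30; real transcriptome modules can be far smaller (down to ~17 members), so
reproducing that granularity requires lowering the knob. Module eigengenes are first principal components of
standardised member expression, sign-oriented so the mean member
correlation is positive (removing PC sign ambiguity); modules whose
eigengenes correlate above 0.70 merge iteratively, highest pair first,
to a fixed point. kME is the correlation of a transcript with an
eigengene; module–trait association is the eigengene–trait Pearson
correlation with the usual t-based two-sided p-value. Enrichment is a
plain upper-tail hypergeometric test with BH correction (no length-bias
correction — a noted deviation from GOseq). Hub lncRNAs are, per
functional sub-network of annotated proteins, the top 5 by degree among
lncRNAs adjacent to at least one of its proteins, with ties broken by
total degree then id; a hub in two or more sub-networks is
"inter-network". The edge threshold (default TOM ≥ 0.15) stands in for
an undocumented graph-export cutoff and is exposed as configuration.

# The synthetic study

`simulate_lnc_study()` generates, deterministically from one seed: a
10-scaffold × 200 kb genome; 300 coding genes with codon-model CDSs of
150–400 aa; 50 intergenic, 20 intronic and 30 antisense clean lncRNAs
(rejection-sampled to carry no ORF above 100 aa); ten decoys per cascade
failure stage; ten transcripts seen only once (to exercise the stringent
filter); second isoforms for ten lincRNA loci; planted miRNAs inside
lncRNA exons (plus antisense controls) and seed sites of declared types
written into conserved windows; three pseudo-assemblers per tissue with
±50 bp terminal jitter (introns untouched, so the intron-chain identity
is invariant); and negative-binomial counts (dispersion 0.1, library
size 1e6) with Dirichlet tissue profiles, three tissue-associated
latent-factor modules (factor scale 3 on log2, giving within-module
correlation near 0.8 at this noise level) and 4-fold sex effects on 15%
of transcripts. FPKM is derived from counts by the standard formula so
the two matrices are mutually consistent. Stage-4 decoys are
rejection-sampled until their in-frame codon bias is at least as strong
as genuine CDS draws (analytic log-ratio ≥ 0.45 against the generator's
own fixed codon table), because "coding-like content" is the ground
truth they are defined by.

What the simulator does **not** emulate: read-level noise and mapping
ambiguity, fragment-length effects on FPKM, assembler-specific
systematic errors, polyadenylation status, single-exon transcripts,
biological replicate variation within a (tissue, sex) library, and real
codon usage or repeat landscapes. Passing tests on this data therefore
demonstrate correctness of the pipeline's logic and statistics under
its stated model, not performance on real silkworm libraries.

Two simulator conveniences are worth noting. Low-FPKM decoys are
zero-count: with a 1e6 library and kilobase transcripts a single read
already exceeds FPKM 0.1, so "expressed below 0.1" is not representable
with integer counts. And quantification tables are joined to merged
models through the intron-chain key (`quant_key.tsv`), the same identity
the merge itself uses.

# Numerical and boundary choices

* Internal coordinates are 0-based half-open everywhere; GTF/GFF3/BED
  conventions are converted only at I/O.
* Strict comparators at published thresholds: JS `> 0.25`, locus ratio
  `> 0.75`, coding probability `> 0.345`, FPKM/coverage/length/ORF use
  the inequalities as printed (`< 200 nt`, `< 0.8`, `< 0.1`,
  `> 100 aa`).
* `N` bases: preserved in sequence, skipped in hexamer counting, not
  counted by TESTCODE, and never part of a start/stop codon.
* Unstranded input transcripts are rejected by default (droppable with a
  warning): an unoriented model cannot be classified against a stranded
  reference.
* All-zero expression profiles are flagged and excluded from
  specificity rather than scored.
* Both-zero sex-bias counts give p = 1 and the pseudocount fold change.
* Eigengene sign: oriented so the summed member correlation is
  positive.
* RNG discipline: every stochastic step runs inside `withr::with_seed`;
  two runs with one seed are byte-identical end to end.

# Problem sizes

The shipped defaults — 480 planted transcripts on a 2 Mb genome, 16
samples, a 1,000-sequence training corpus, a 200 × 40 module-recovery
design and a 10,000-transcript null calibration — were chosen so the
full test suite and the acceptance script each run comfortably on a
single CPU while leaving every statistical check well-powered; all of
them scale up through `sim_config()` if heavier validation is wanted.

# Known limitations

* The coding scorer is synthetic-corpus-trained; its absolute
  probabilities are not transferable to real transcriptomes without
  retraining, and the 0.345 default boundary is a comparability
  convention, not a calibration.
* The exact binomial sex-bias test is anti-conservative under
  biological replication; with replicated designs a count model with a
  dispersion parameter should replace it.
* Static tree cutting can split very tight nested modules that dynamic
  cutting would separate adaptively; the merge step recovers most of
  this at the default 0.70 correlation.
* Hypergeometric enrichment ignores transcript-length selection bias.
* The MRE scanner reports canonical seed sites only; no pairing
  energetics, no 3' compensatory sites.
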