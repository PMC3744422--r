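---
title: "Reference-centric comparative genomics and geno-phenotype typing with panpheno"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-centric comparative genomics and geno-phenotype typing with panpheno}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panpheno)
```

## The analysis

panpheno re-creates, at desk scale, the reference-centric study design used
for large bacterial strain collections such as the *Lactobacillus
rhamnosus* species: each strain's genome is compared against one fully
annotated reference chromosome, every reference gene is called *present*
or *divergent/missing* per strain, and the resulting binary
presence/absence matrix — together with CRISPR spacer oligotypes and
phenotype assays — drives all downstream inference:

1. shared-content and core-genome statistics, with a core accumulation
   curve over random strain orderings;
2. gene-content clustering (Jaccard distance, UPGMA) compared against a
   neighbor-joining substitution-distance tree built over the core genes;
3. detection of hyper-variable chromosomal regions ("lifestyle islands")
   from per-gene loss frequencies;
4. CRISPR spacer oligotyping against the reference Type II-A locus, with a
   protospacer search against a phage/plasmid database;
5. phenotype statistics (bile categories, mucus binding, pilosotype
   contingency, the growth-curve area reduction percentage) and an
   integrated geno-phenotype classification of every strain into
   dairy-adapted (A) and intestinal-adapted (B, B_dspaCBA) types.

Because raw strain genomes for such collections are rarely deposited, the
package ships a first-class synthetic cohort generator whose outputs carry
full ground truth; every stage of the pipeline is tested for parameter
recovery against that truth.

## Presence/absence calling

A reference gene is searched in a strain genome (all contigs, both
strands) by k-mer anchored local alignment: exact k-mers of the gene
(default `k = 11`, one probe every 7 bp) are matched against the subject,
anchors are clustered by alignment diagonal, and the best-supported
windows are aligned by local dynamic programming. Subjects below 10 kb
skip the anchoring and are aligned exactly, so small test instances are
directly comparable to a full Smith–Waterman oracle. Windows supported by
fewer than a quarter of the best window's anchors are not aligned.

The call rule follows the annotation-transfer criterion of the study
design: *present* requires nucleotide identity **≥ 0.40** (inclusive — a
gene at exactly 40% identity is present) of the best local alignment. The
source criterion is identity-only, defined on whole synteny blocks; at
gene level a coverage criterion is additionally required to reject
spurious short matches, and the default **coverage ≥ 0.80** of the gene
length is chosen so that a half-deleted gene scores absent. "Divergent"
and "missing" genes are deliberately collapsed into a single 0 call, as in
the matrix format this reproduces; the best identity and coverage per gene
are retained as matrix attributes for diagnostics.

### Alignment scoring

Scores are +2 match, −3 mismatch, affine gaps (open 5, extend 2). This
scheme is *subcritical* on random DNA — chance local alignments stay short
— while genes diverged by point mutations up to ~25% still extend over
their full length (expected score per column at 20% divergence is +1).
Earlier experimentation with milder mismatch/gap costs showed why this
matters: a supercritical scheme lets random sequence accrete long,
gap-riddled "alignments" at 50–60% identity, which silently satisfies a
40%-identity threshold. With the subcritical scheme, a deleted gene's best
chance alignment covers a few percent of the gene and is called absent.

The identity reported is matches over alignment columns; coverage is the
aligned fraction of the gene. Both equal an independent pure-R
Smith–Waterman (Gotoh) oracle on all test instances.

## Pan/core statistics

* **Truncated percentages.** All printed percentages use
  `truncate_percent()`: `floor(1000·n/d)/10`. Truncation (not rounding) is
  the convention reverse-engineered from the study's printed ratios — 31/77
  printed as 40.2 and 2918/3016 as 96.7, both of which round-half-up would
  print differently.
* **Median.** The cohort median shared count uses the *lower* median for
  even cohort sizes, so the reported value is always an attainable row
  sum.
* **Core accumulation.** For each of `n_permutations` random strain
  orderings the prefix intersections are computed (`exact = TRUE`
  enumerates all orderings for ≤ 8 strains). The curve is monotone
  non-increasing and its k = n point equals the core size identically.
* **Clustering.** The study design specifies hierarchical clustering on
  relative shared gene content but neither distance nor linkage; Jaccard
  distance on binary rows with average linkage (UPGMA) is the standard
  pairing for binary gene-content data and both are configurable.
  Tie-breaking on equal merge heights follows `stats::hclust`, which is
  deterministic.
* **Group comparison.** The dairy-vs-human shared-content comparison
  (clinical isolates excluded) reports full-precision arithmetic means and
  a two-sided Mann–Whitney U test — percentage data with no normality
  claim. When every observation is tied the p-value is defined as 1.
* **SNP tree.** Strain sequences are projected onto reference gene
  coordinates through their best local alignments; pairwise distances are
  raw substitution proportions with pairwise gap deletion, and the tree is
  neighbor-joining (`ape::nj`; the 3-leaf case is solved in closed form).
  Tree concordance is the Pearson correlation of cophenetic distances over
  shared leaves, clamped to [0, 1].

## Variable-region detection

Loss frequency per gene is 1 minus the column mean of the matrix. Regions
are maximal runs, in gene-index space, of genes with loss frequency
≥ `freq_threshold` (default 0.10), tolerating up to `max_gap` (default 1)
consecutive below-threshold genes inside a run, with a minimum span of
`min_genes` (default 5). Runs start and end on above-threshold genes. The
source study states the outcome (17 regions on its cohort) but not the
segmentation rule; these defaults are the package's own and are exposed as
parameters. IS-element genes count toward run length, since the regions
this emulates include their IS elements. Lowering `freq_threshold` can
only grow the set of genes covered by regions (tested as a property).

## CRISPR oligotyping

Spacers are typed by the same seed-and-extend machinery with word size 7
(the word size the study's protospacer BLAST used). Three classes:

* **conserved** — at least 90% of the spacer's bases are matched in the
  best local alignment. The criterion is on the matched fraction of the
  whole spacer, not on identity × coverage separately, because local
  alignment trims terminal mismatches: a spacer with one substitution two
  bases from its end would otherwise drop below a 95% coverage cut while a
  central substitution would not. A single-SNP spacer is always conserved.
* **partial** — identity ≥ 80% over ≥ 50% of the spacer length (a
  half-deleted spacer scores partial, at 100% identity over half its
  length).
* **absent** — anything else.

At genome scale a candidate spacer locus must be supported by at least
three exact word-7 seeds on one diagonal; with hundreds of kilobases of
subject sequence, two-seed diagonals arise by chance and produce spurious
short "partial" matches. The class thresholds themselves are calibration
knobs of this package (the emulated analysis names only three colour
classes), chosen so single-SNP spacers stay conserved and half spacers
score partial. E-value machinery is intentionally not implemented;
identity/coverage cutoffs with seed support substitute for it,
deterministically. Cas genes use the ortholog presence rule (0.40/0.80).

The protospacer search reports hits ≥ 85% identity over ≥ 80% of the
spacer, possibly in several targets; the shipped analysis plants
protospacers in synthetic phage sequences, and completeness is tested
against an exhaustive-scan oracle.

Profile distance treats partial conservation as half a match: statuses are
scored conserved = 1, partial = 0.5, absent = 0 (cas: 1/0) and the
distance is the mean absolute score difference.

## Phenotypes and the geno-phenotype classifier

The area reduction percentage of a pathogen growth curve is
`ARP = 100 · (AUC_control − AUC_sample) / AUC_control`, with trapezoidal
AUC on the native 30-minute grid (no resampling); negative values flag
growth enhancement and are reported as-is. Mucus binding is the bound/total
signal percentage. A strain is pilosotype-positive when all pilus-cluster
genes are called present *and* any supplied assay evidence is positive — a
highly conserved but non-expressed cluster scores negative, as observed in
real collections. Group contingency tables use truncated percentages and a
two-sided Fisher exact test.

The A/B classification integrates seven axes, each in [0, 1] with 1
B-like (intestinal-adapted):

| axis | score |
|---|---|
| gene content | shared fraction rescaled over configurable bounds (default 0.85–1.0) |
| CRISPR oligotype | fraction of reference spacers conserved |
| bile | resistant 1, moderately 0.67, poorly 0.33, sensitive 0 |
| pilosotype | positive 1, negative 0 |
| sugar group I | fraction fermented (partial = 0.5) |
| sugar groups II, III | 1 − fraction fermented |

The class rule: mean axis score ≥ 0.6 → B family (B if the spaCBA-like
pilus island is fully present, B_dspaCBA otherwise); ≤ 0.4 → A; otherwise
unassigned. The emulated study names the classes and the axes but no
numeric scoring formula, weights or cut-offs; those are this package's
construction, uniform weights and 0.4/0.6 cuts, all exposed in
`genopheno_config()`. Sugar axes score fractions rather than all-or-none
(the alternative reading), with partially positive calls at 0.5 — the
midpoint, absent any guidance. TLR2 fold-induction is carried as data but
excluded from scoring, since the emulated analysis found no link between
TLR2 response and niche or clustering.

## The synthetic cohort generator

`simulate_reference()` builds a chromosome of ORF-like random genes with
contiguous island runs (pilus cluster, fucose utilization, lactose/maltose
PTS, taurine transport, EPS, phage remnant — each with themed products, a
COG category and two flagged IS elements) and a repeat-spacer CRISPR array
with cas genes. `simulate_strain()` applies, per niche profile: all-or-none
island deletion (variable regions are lost as blocks), independent
background gene deletion, genome-wide random substitutions, and truncation
of the CRISPR array to the retained (trailer-proximal, i.e. oldest)
spacers. Phenotypes are deterministic functions of the island retention
pattern — pili require the pilus island, bile resistance the taurine
island, group I sugars the fucose island, groups II/III its absence (the
dairy trade-off), antagonistic activity tracks intestinal adaptation —
flipped or jittered with the profile's `phenotype_noise`. Each strain
records its full ground truth, including the intended class (the
classifier applied to the true genotype and noiseless phenotypes).

Default profiles encode the qualitative niche contrasts of the emulated
system: dairy strains lose the pilus/fucose/taurine islands with high
probability (0.7–0.9), keep 6 of 24 spacers and carry ~2% substitutions;
intestinal strains stay close to the reference with the full spacer set;
oral and vaginal strains are A-like (vaginal keeping bile resistance); the
clinical pool mixes an A-like and a B-like profile, the latter with an
elevated chance of losing just the pilus island (yielding B_dspaCBA
strains); the default 100-strain mix is 23 dairy / 16 intestinal / 3 oral /
8 vaginal / 31 clinical / 19 other. The source reports no quantitative
loss rates; these values are calibrated once so the simulated cohort
reproduces the qualitative structure — a coherent dairy gene-content
cluster, dairy-specific island losses, spacer sharing of 6–7 — and are not
meant as estimates of real rates. Within-niche loss probabilities near 0.5
would make dairy strains as distant from each other as from intestinal
ones and destroy the reported cluster structure, which is why the defaults
sit near 0 or near 1.

What the generator does **not** emulate: insertions/deletions within genes
(substitutions only — presence calling is identity/coverage based, and
indels would add no tested behaviour), strain-specific genes absent from
the reference (the emulated study defers pan-genome discovery), plasmids,
sequencing error or read-level artefacts, and recombination. Passing
recovery tests on this generator therefore demonstrates correctness of the
pipeline's inference under its stated model, not robustness to assembly
artefacts or novel gene content in real data.

## Numerical and degenerate-input choices

* All randomness flows from one integer seed per entry point; seeded
  functions restore the caller's RNG state. Fixed-seed runs produce
  byte-identical outputs (tested).
* Equal-start gene coordinates order by locus tag; coordinates are 1-based
  inclusive in memory, converted at format boundaries.
* Empty cohorts, non-binary matrix cells, ragged tables, unbalanced
  Newick strings, zero-length groups and zero control AUCs raise errors
  rather than propagating.
* The presence-table import shim auto-detects orientation by taking the
  longer axis as the gene axis (reference genes always outnumber strains
  in the cohorts this serves); an explicit `orientation` argument
  overrides.
* Problem sizes in the test suite: the standard test reference has 300
  genes and 6 islands on 300 kb (full pipeline on a 40-strain cohort in
  about two minutes), the quick fixture 40 genes and 2 islands; recovery
  properties run at seeds 1–5 with 40-strain cohorts.

## Known limitations

* Gene-level alignment replaces whole-genome synteny: translocated or
  heavily rearranged copies are found (best hit over all contigs and both
  strands) but synteny context is not verified.
* Nucleotide identity below ~60% is not meaningfully alignable with any
  scoring; the inclusive 0.40 threshold is honoured at the call-rule level,
  but genuinely 40%-divergent genes will typically fail coverage and score
  absent — consistent with their "divergent" (0) status in the emulated
  matrix.
* The spacer class thresholds and the geno-phenotype cut-offs are
  package calibrations; cohort class counts from other rule choices will
  differ, and the unassigned band (0.4–0.6) is sensitive to them.
* The XLSX import shim reads one sheet with an id column; multi-sheet or
  annotated workbooks need manual cleaning first.
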