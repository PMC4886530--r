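---
title: "Profiling fermentation microbiomes and predicting wine quality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling fermentation microbiomes and predicting wine quality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fermeta)
```

## The problem

Open cereal-wine fermentations are driven by a succession of moulds,
yeasts and bacteria. A batch spoils when heterofermentative lactic acid
bacteria — chiefly *Lactobacillus* — come to dominate the community early:
their lactic and acetic acid sours the wine and suppresses the fungi that
carry saccharification and alcoholic fermentation. Because the community
divergence between good and failing batches is already visible around day
7 of a roughly 70-day process, the day-7 genus profile can serve as an
early predictor of final quality.

`fermeta` implements the full analysis chain for this problem: amplicon
community profiling, diversity and group-separation statistics, the day-7
quality predictor, and the shotgun-metagenomic stages (read QC, cereal
decontamination, species abundance, contig handling, gene catalogues,
functional profiles). This vignette documents the models, the parameters
that matter, and the design decisions taken where the procedures were
genuinely open.

## Amplicon profiling

**Tag QC** (`qc_filter_tags`). Merged amplicon tags are kept when their
length falls in the marker window — 350–500 bp for 16S V3–V4, 300–420 bp
for ITS2 — their mean Phred score is at least 20, and they carry at most 3
ambiguous N bases. The mean quality is computed on the tag as read; no
trimming is applied to tags.

**Dereplication and clustering** (`dereplicate_tags`, `cluster_otus`).
Exact duplicates are collapsed, and only sequences observed more than once
seed OTUs: singletons are disproportionately error reads, but they remain
available for the later mapping step. Clustering is greedy centroid
clustering at 97% identity in descending abundance order, ties broken by
lexicographic sequence so the partition is deterministic and input-order
invariant. A sequence joins the earliest-founded centroid reaching the
threshold, else founds a new OTU.

*Pairwise identity* is matches divided by full alignment length of a
global alignment under unit scoring (match +1, mismatch −1, −1 per gapped
column), computed with `Biostrings::pairwiseAlignment`. Clustering tools
differ in their identity definitions; this one is declared explicitly and
is cross-checked in the test suite against an independent
dynamic-programming implementation.

**Chimera screen** (`flag_chimeras`). Full chimera detection is out of
scope here; the package ships a deliberately simple two-parent splice
test. A representative is flagged when splitting it at its midpoint yields
halves whose best-matching parents (among more abundant OTUs, compared
half against half) are distinct, each half matching at >= 99% identity,
while the full-length identity to both parents stays below the clustering
threshold. A flagged OTU is dropped entirely. This catches exactly the
class of chimeras the tag simulator plants (single-breakpoint splices of
two templates); real chimeras with uneven breakpoints or more parents will
escape it, which is the main reason this screen should be considered a
placeholder interface rather than a finished detector.

**Mapping and rarefaction** (`map_tags_to_otus`, `rarefy`). All QC-passed
tags, singletons included, are mapped to the best non-chimeric
representative at >= 97% identity (ties to the more abundant OTU).
Counts are then rarefied — subsampled without replacement — to a common
depth per sample to remove sequencing-depth differences. Samples below the
target depth are dropped with a warning rather than failing the table;
losing a shallow sample is the analyst's signal to pick a smaller depth.

**Genus tables** (`genus_profile`). OTU counts are summed per lowest
assigned taxonomy label (`g__` genus names stripped of their prefix,
above-genus labels like `f__Lactobacillaceae` kept prefixed) and rows are
normalised to relative abundance. Taxonomic assignment itself (naive-Bayes
classification against a reference) is out of scope; the package consumes
a taxonomy map and, for synthetic data, carries truth labels.

## Diversity and separation statistics

* `shannon_wiener` uses the natural logarithm (the base is a convention
  choice; ln makes H = ln k for k equal taxa).
* `bray_curtis_pcoa` computes Bray–Curtis dissimilarity on relative
  abundances and classical PCoA (double centering + eigendecomposition via
  `stats::cmdscale`). Bray–Curtis is the field default for compositional
  community data; the distance is not Euclidean, so negative eigenvalues
  can occur — they are reported but carry no coordinate axes, and no
  Cailliez correction is applied. Rarefied or unrarefied input is the
  caller's choice; the workflows here ordinate relative abundances.
* `spearman_antagonism` restricts to the 30 most abundant genera (mean
  relative abundance) and reports Spearman rho with average ranks;
  strongly negative pairs flag candidate antagonisms. Constant genera have
  undefined rank correlation and are reported `NA`, never coerced to 0.
* `wilcoxon_rank_sum` enumerates all group assignments exactly when the
  combined sample size is at most 12 (ties handled by average ranks, so
  identical groups give p = 1), and otherwise uses the normal
  approximation with tie and continuity correction.
* `permutation_separation_test` uses the absolute difference of class
  means of an ordination coordinate as statistic and
  p = (1 + exceedances)/(n + 1), so p can never fall below 1/(n + 1): with
  the conventional 999 permutations a complete separation reports
  p = 0.001. The statistic is a design choice — the mean difference on
  axis 1 is the simplest statistic consistent with "separation along the
  first axis"; between-group sums of squares would behave equivalently on
  one axis.

Quality-association analyses exclude samples fermented fewer than 7 days
(`exclude_early_samples`): before day 7 the classes have not diverged and
would only dilute group contrasts.

## The day-7 quality model

`fit_decision_stump` considers midpoints between adjacent distinct values
of one genus as candidate thresholds and picks the split minimising
weighted Gini impurity, ties to the smaller threshold. `fit_quality_tree`
applies stumps recursively, restricted by default to *Lactobacillus* and
*Thermoactinomyces* — the two genera whose day-7 abundances distinguish
good from failed fermentations — to depth 2. Three conventions matter:

* **Boundary inclusivity**: a value equal to the threshold descends left,
  so "Lactobacillus <= threshold" predicts *good* inclusively.
* **Tie labels**: a leaf with equally many good and poor samples is
  labelled *poor* — prediction errs toward flagging spoilage, the cheaper
  mistake in production.
* **Induction algorithm**: nothing fancier than Gini stumps with midpoint
  candidates is used. The minimal model is auditable — the fitted
  threshold is always the midpoint of two observed day-7 abundances — and
  is sufficient to recover planted class boundaries exactly. One
  consequence worth knowing: on data where one class spans a wide interior
  range, Gini may prefer peeling a pure run off one end over splitting a
  between-class gap; with the two-genus feature set and day-7 cohorts this
  does not change predictions, only which equivalent rule is printed.

The *Thermoactinomyces* threshold is always recovered from data, never
hard-coded; only the feature list is a default.

Models serialise to JSON (`write_quality_tree`/`read_quality_tree`) so a
fitted rule can be shipped and applied to new day-7 genus tables.

## Shotgun reads and species abundance

`qc_filter_pairs` applies three rules per mate in order: drop mates with
more than 3 Ns; drop mates with fewer than 60% of bases at Phred >= 20;
trim the 3' end back to the last base at or above Q20. A pair is discarded
whole if either mate is dropped or trims below 30 bp (the 30 bp floor is a
package addition — untrimmed-length rules alone would let near-empty mates
through).

`remove_cereal_pairs` drops a pair when either mate hits any cereal
genome: cereal DNA co-extracts with fungal DNA and can contribute
~40% of reads, and a mate anchored in cereal condemns its partner too.

`assign_species` counts a *valid hit* for genome G when both mates of a
pair align to the same contig of G. Orientation and insert-size
consistency are deliberately not enforced — the rule is a containment
test, not a proper-pair test. Pairs valid for several genomes are
ambiguous; the default discards them (fractional assignment is available
via `ambiguous = "fractional"`). The same-contig rule is applied
identically to bacterial and fungal genomes.

`species_abundance` divides valid-hit counts by *gap-adjusted* genome
lengths — the contig-length sum minus gap count x 350 bp mean insert,
since reads cannot be sampled from unsequenced gap spans — and
renormalises per sample. The estimator is scale-free in the counts, and
on simulated mixtures with no decoy hits it recovers the planted genome
mixture to within sampling error (max absolute error below 0.02 at 50,000
pairs in the test suite).

## Contigs, catalogues, functional profiles

**Contig handling.** Scaffolds are cut at every N run and only pieces
strictly longer than 500 bp are kept. Per sample, several k-mer assemblies
(39–59 step 4 in the protocol this mirrors) are compared by N50 — the
smallest length whose at-least-as-long contigs cover half the assembly —
and the largest-N50 assembly wins; ties go to the larger total assembly,
then the smaller k-mer. Contigs with >= 90% coverage (merged interval
union of hit spans) and >= 95% identity (alignment-length-weighted mean)
against a cereal genome are removed.

**Domain classification** proceeds in three steps: (1) contigs
gene-predictable by only one of the two gene predictors take that domain;
(2) otherwise a qualifying genome alignment — coverage >= 90% with
identity >= 95%, or aligned overlap strictly over 100 bp with identity
>= 95% — assigns the domain of the best (bit-score) hit; (3) otherwise
NR protein labels at E < 1e-10 vote: a domain wins if it is the unique
maximum and reaches 40% of the vote base, a tie or shortfall falls back to
the higher mean m8 bit score, and no evidence leaves the contig
unclassified. The 40% vote base is the *labelled* genes by default
(`vote_base = "all"` counts unlabelled genes in the denominator); voting
among assignable genes is the natural reading and the difference only
matters for sparsely annotated contigs.

**Gene catalogues.** Dereplication is greedy longest-first: a gene is
redundant when it aligns to a retained gene at >= 95% identity with
>= 90% coverage *of the shorter sequence* (CD-HIT-style; coverage of the
longer is configurable by threshold choice). Redundancy is computed on
nucleotide sequences; bacterial and fungal catalogues dereplicate
separately before merging, mirroring how the two CDS catalogues are built.
Gene abundance mirrors the species valid-hit rule at gene level with the
same length-normalised estimator.

**Functional annotation.** Quorum-sensing hits are effective at score
>= 60 and E < 1e-5, and each gene takes its best surviving hit's group
(one of 8: Autoinducer, Autoinducer_producer, Autoinducer_receptor,
Decomposer, Effector, Regulator, Transporter, unclear). Ties break by
lower E-value, then lexicographic label — arbitrary but deterministic.
Antibiotic-resistance hits are valid at >= 80% identity, best identity
wins. The tenfold marker rule flags a gene as significantly more abundant
in one sample when its relative abundance there is at least 10x the
other's; a gene absent from one sample counts as enriched when it reaches
a floor of 10x the smallest nonzero abundance in the table (a zero
denominator must be handled somehow; the floor keeps barely-detected genes
from becoming markers). The rule operates on relative abundances, not raw
counts. A real curated QS reference cannot be redistributed; the package
ships a small synthetic labelled stand-in (`qs_reference()`) for
exercising the rules and accepts any user-supplied table of the same
shape.

## The synthetic-data module

The generators produce every input the pipeline consumes, with truth
attached, under the conditions the analyses assume:

* `simulate_cohort` draws per-(batch, day) genus compositions; from day 7
  the *Lactobacillus* abundance comes from class-specific ranges (defaults:
  good 0.05–0.60, poor 0.88–0.99 — poor batches dominated, good batches
  not, with the ranges configurable since per-batch trajectories are not
  published numerically) and the rest of the mass is a symmetric Dirichlet
  split (concentration 5, mildly even communities) over a default
  ten-genus vocabulary typical of these fermentations.
* `simulate_tags` copies per-genus random template sequences (420 bp for
  16S, 350 bp for ITS — typical merged-tag lengths), applies per-base
  substitution errors, plants midpoint splices of two distinct templates
  at the chimera rate, and draws Phred+33 qualities so a chosen fraction
  fails QC. Templates are random sequences, not real rRNA/ITS: taxonomy
  travels as truth labels because classifier training is out of scope.
* `simulate_shotgun` draws pairs genome-proportional to mixture x genome
  length (read yield scales with both abundance and genome size), inserts
  normal around 350 bp (sd 35, floored at the 125 bp read length), and
  emits m8 records placing both mates on the true source contig, plus
  optional single-mate decoy hits to exercise the valid-hit filter. Reads
  are random sequence: alignments are emitted from truth rather than
  recomputed, so tests control the filter's inputs exactly.
* `simulate_gene_table` plants a chosen fraction of genes whose abundance
  differs >= 10-fold between two designated samples (boosted 50x before
  column normalisation, leaving a wide margin on both sides of the
  threshold) and labels every gene with QS group, AR type and KEGG
  identifiers.

Everything is bit-for-bit reproducible under a seed, and planted structure
is recoverable by the corresponding downstream stage when noise is off.

What the generators do **not** emulate: realistic sequence evolution or
platform-specific error profiles, chimera breakpoint diversity, assembly
artefacts, strain-level variation, or compositional correlations between
genera beyond the Dirichlet split. Passing tests therefore demonstrate
that the *rules and estimators* are implemented correctly and recover
planted truth — not that they are robust to every artefact of real
sequencing data.

## Numerical choices and problem sizes

Identity is a fraction in [0, 1] everywhere in memory; m8 files use the
blast percent convention, converted at the I/O boundary. m8 coordinates
are 1-based inclusive; reverse-strand hits carry descending subject
coordinates. Compositional rows sum to 1 within 1e-9. Degenerate inputs
error early and loudly: all-zero abundance rows, single-class training
data, empty contig sets, adjusted genome lengths <= 0.

The validation suite exercises the stages at sizes chosen to make
statistical checks sharp while staying quick on a laptop: 1,000-tag QC
oracles, 20-sequence clustering oracles, 50-pair valid-hit enumerations,
50,000-pair mixture recovery, 100-seed threshold-recovery sweeps, 200-seed
type-I-error calibration of the permutation test, and 999-permutation
separation tests throughout.
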