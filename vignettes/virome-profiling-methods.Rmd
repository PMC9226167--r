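---
title: "Profiling gut viromes from metagenomic contigs: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling gut viromes from metagenomic contigs: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(viromeprofiler)
library(dplyr)
```

# The problem

Human gut phages outnumber and shape gut bacteria, but most gut phage
lineages have no cultured representatives and no universal marker gene, so
case/control virome studies work entirely from assembled metagenomic
contigs. `viromeprofiler` implements that desk pipeline end to end: deciding
which contigs are phage versus bacterial, collapsing redundant assemblies,
grouping phage contigs into approximately genus-level **viral clusters
(VCs)** by shared protein content, turning read alignments into a
coverage-filtered abundance table, linking VCs to bacterial hosts, carving
out marker-gene-defined phage lineages with subfamily structure, and
running the two-group ecology and prevalence statistics used to compare a
disease group against controls.

Because the cohort data this kind of study runs on are typically under
restricted access, the package ships a deterministic synthetic-community
generator that reproduces the *statistical structure* the analysis assumes
-- planted relatedness groups, a marker-gene family, prophages, CRISPR
arrays, two-group abundance and prevalence effects -- so every stage is
exercised and scored against known ground truth.

# Stage by stage

## Sequence triage

Upstream virus-prediction tools are not rerun; their per-contig outputs
(a sorter category 1-6, a finder score and p-value, a superkingdom
annotation) are consumed as a feature table. The decision rule in
`classify_viral()` is:

* phage if the sorter category is 1, 2, 4 or 5; **or** the finder score
  exceeds 0.9 at p < 0.05; **or** the category is 3 or 6, the finder score
  exceeds 0.7 at p < 0.05, and the annotation is "Viruses" or
  "unclassified" at superkingdom rank;
* contigs annotated as eukaryotic viruses are then removed;
* bacterial if annotated "Bacteria", unless already called phage --
  except for prophage categories (4, 5, 6), which stay in **both**
  datasets so that integrated phages can anchor host predictions.

Absent evidence fails its clause rather than raising an error, because
real upstream feature tables are sparse. Each call carries a rule trace.

`detect_circular()` flags short contigs (1,500-5,000 bp by default) whose
first and last bases form an exact terminal direct repeat; contigs above
the window are retained by the >5,000 bp length rule regardless, so they
are not flagged. The minimum repeat length is not fixed by any published
convention; we use 20 bp, long enough that a chance hit is vanishingly
unlikely (4^20 >> genome sizes) and short enough to catch assembler-style
overlaps. It is exposed as an argument.

`deduplicate()` reproduces duplicate-plus-containment removal: a contig is
dropped when it aligns to a strictly longer retained contig (ties broken
toward the lexicographically earlier id) at >= 90% identity over >= 95% of
the shorter contig's length. The 95% span requirement is this package's
choice -- the upstream tool's exact containment span is undocumented --
and is exposed as a flag. Candidate pairs are pre-screened by shared
14-mers before alignment.

## Protein clusters and viral clusters

All-versus-all protein homology is scored by Smith-Waterman local
alignment (BLOSUM62, gap open 11 / extend 1) with raw scores converted to
bits through the ungapped Karlin-Altschul constants lambda = 0.267,
K = 0.041:

$$\mathrm{bits} = \frac{\lambda \cdot s - \ln K}{\ln 2}$$

A pair is a hit at >= 50 bits. We do not promise to match a heuristic
search engine's exact bit scores -- only the >= 50-bit decision on clearly
homologous versus unrelated pairs, which is what the method consumes.
An amino-acid 5-mer prefilter skips pairs that share no 5-mer; such pairs
essentially cannot reach 50 bits, and the tests verify the filtered search
equals the exhaustive one.

**Protein clusters (PCs)** are the connected components of the 50-bit hit
graph. (The upstream clustering tool uses Markov clustering for PCs as
well; components at the same threshold are simpler and deterministic, and
we reserve Markov clustering for the VC step, where the network topology
matters most. This divergence is deliberate.)

**Viral clusters** are formed on the contig-by-PC incidence: each contig
pair sharing PCs gets a similarity
$-\log_{10}\!\big(P_{\text{hyper}}(X \ge \text{shared}) \cdot n(n-1)/2\big)$
under a hypergeometric null on the PC universe; pairs at similarity >= 1
become edges, and the weighted network is partitioned by Markov clustering
(inflation 1.5, convergence 1e-6, at most 200 iterations), with edgeless
contigs becoming singleton VCs. The Markov-cluster iteration adds
self-loops at each node's maximum incident edge weight; with unit
self-loops a two-node clique with a strong edge oscillates toward its
diagonal and splits, which is an artifact, not a cluster structure.
All tie-breaks (PC ids, VC ids) are lexicographic, so the partition is
invariant to input order.

`shared_pc_fraction()` is the Jaccard percentage of two contigs' PC sets.
Because divergence can split one core gene into several PCs, genuinely
related genomes can share a small percentage -- which is why the family
gate below is marker-based, not PC-fraction-based.

## Coverage-filtered abundance

The pipeline order is fixed and tested against brute-force recomputation:

1. **Identity filter**: alignment records below 0.90 identity are removed
   (the boundary is inclusive -- "less than 90%" is removed).
2. **Horizontal-coverage zeroing**: per contig and sample, the fraction of
   positions covered by at least one record; counts with coverage below
   0.75 are set to zero (exactly 0.75 is kept). The coverage of every
   contig-sample pair is retained as a provenance mask.
3. **RPKM**: `count / ((len/1000) * (library_size/1e6))`. Library size
   defaults to the identity-filtered mapped reads per sample; counting all
   quality-controlled reads instead is defensible, so it is a flag.
4. **VC aggregation**: values summed over member contigs (totals conserve).
5. **Relative abundance**: per-sample closure to 1; all-zero samples stay
   zero with a warning.

Coordinates are 0-based half-open everywhere; `from_one_based()` /
`to_one_based()` convert. The coverage filter is applied uniformly --
including for richness and evenness, where the source protocol is
ambiguous about whether evenness also used it; uniformity is the simpler
contract and is stated here so it can be revisited.

## Ecology

Richness counts units with non-zero filtered abundance; Shannon H' uses
natural logarithms (the convention of the ecology stack this field uses;
the base is an argument); Pielou evenness is H/ln(S); Chao1 uses the
classic estimator S + F1^2/(2 F2) (or S + F1(F1-1)/2 without doubletons)
on integer counts. Bray-Curtis dissimilarity and PCoA are classical:
double-center -D^2/2, eigendecompose, keep positive eigenvalues (negative
ones are dropped with a warning; no Cailliez correction). PERMANOVA uses
sequential (Type I) partitioning with covariates entered before the group
term and raw-label permutation, `p = (1 + #{F* >= F}) / (1 + n_perm)`;
this matches the cited ordination tool's default scheme. Spearman
correlations are BH-adjusted across all tested pairs.

## Host linkage

Three evidence routes, merged with provenance:

* **CRISPR protospacers.** A simplified array detector finds >= 3
  near-identical direct repeats (23-55 bp, <= 1 mismatch against the
  consensus) separated by distinct 18-50 bp spacers, seeded on exact
  repeated 23-mers. Array quality scoring is out of scope: downstream
  computation consumes spacers, not scores. Spacers are then matched
  against phage contigs on both strands by Hamming distance --
  substitutions only, no indels, matching short protospacer practice --
  with at most 1 mismatch by default ("less than 2 mismatches" read
  literally; a flag allows 2 for sensitivity analyses).
* **Prophages.** Every VC containing a prophage-flagged bacterial contig
  inherits that contig's taxon.
* **Reference co-clustering.** A VC containing characterized reference
  phages is linked to a host family only when *all* its references infect
  the same family; this route emits family-rank links only, since
  unanimity below family rank is not established practice.

Merged predictions are deduplicated by (VC, taxon, rank); VCs whose
predictions span more than one bacterial phylum are flagged, as candidate
broad-host-range phages or chimeric clusters.

## Marker-gene lineages

A lineage is defined by a `marker_gene_set()`: marker proteins, the subset
that must all hit, a 50-bit threshold, and a minimum contig length.
The nine-gene family gate requires contigs >= 30,000 bp carrying all nine
markers (four structural: terminase large subunit, portal, Clp protease,
major capsid; three transcription-related: DNA polymerase I, SNF2-like
helicase, VRR-NUC nuclease; two of unknown function). The relaxed
validation mode requires only the four structural genes, tolerating
incomplete assemblies. The shipped marker fixtures are synthetic random
proteins (the genuine genes derive from restricted-access data); only the
homology structure matters to the method, and real sequences can be
dropped in via `marker_gene_set()`.

Subfamilies are delineated by average-linkage hierarchical clustering of
Euclidean distances between rows of the pairwise shared-PC-fraction
matrix, cut at k clusters. k = 3 reflects the structure of the motivating
data; no automatic k selection is attempted -- for other data, k is the
user's call. Labels are assigned in decreasing cluster size, so they are
deterministic.

The Crassvirales classifier flags contigs >= 70 kb whose proteins hit both
the terminase and polymerase queries at >= 50 bits with a query alignment
of >= 350 columns. The published threshold is stated in bp although the
search is protein-space; we interpret it as alignment columns in the
search's native unit (residues) by default, with a `unit = "nt"` flag that
scales by codon length, and record the ambiguity here.

Prophage boundaries are extracted from per-base read-depth profiles in
samples where the bacterial flanks are covered (mean flank depth >= 5) but
the integrated phage is absent (candidate-region mean <= 0.1 x flank):
depth is smoothed with a 21-bp running median and the boundaries are the
outermost positions where the smoothed depth crosses half the flank mean,
with the interval taken as the per-sample median. The smoothing window
and half-height crossing are this package's choices; the source protocol
describes only visual coverage-based extraction. On noise-free step
profiles the extraction is exact, and under Poisson depth noise it stays
within +/-50 bp of the planted insertion points (both tested).

## Group comparison

`fisher_exact()` is an exact enumeration: with margins fixed, the
two-sided p-value sums hypergeometric probabilities of all tables no more
probable than the observed one (probability-mass method, with 1e-7
relative slack against floating-point ties) -- the convention of the
statistical stack this field uses; sidedness is a flag since protocols
rarely state it. Degenerate tables in which a *column* margin is zero
(a unit present or absent in every sample) admit a single table and return
p = 1; zero *row* margins (an empty group) are errors.
`wilcoxon_rank_sum()` switches from exact enumeration to the
tie-corrected, continuity-corrected normal approximation above
min(n, m) = 25 -- the boundary is placed so balanced 24-per-group designs
take the exact path. BH adjustment is standard; note that the BH map is
monotone in p-rank but *not* idempotent (re-adjusting q-values changes
them), so q-values are computed once from raw p-values.
`prevalence_compare()` builds per-unit 2x2 presence tables, tests each
with `fisher_exact()`, and BH-adjusts across units.

Covariate-adjusted compositional differential abundance is a published
external method's contribution; `ancombc_adapter()` only validates and
ingests its result table (unit, log-fold-change, standard error, q).

# The synthetic-community generator

`community_spec()` fixes the study conditions; `generate_community()` is
deterministic given the spec (same seed, byte-identical bundle; every
draw flows through a named substream of one master seed).

What it emulates:

* **Two balanced groups**, "control" and "case", 24 samples each by
  default -- the balanced sub-cohort design used where the full cohort
  was near-balanced (99 vs 97).
* **Relatedness groups**: background phage genomes in groups of 4 sharing
  80% of a 16-protein pool at 2% divergence (plus singletons), so VC
  formation has a planted partition to recover.
* **A marker family**: 3 subfamilies x 5 genomes; subfamily ancestors
  diverge from the marker seeds at 0.35 substitutions/site and members at
  0.05 within subfamilies -- values at which all homologs still clear 50
  bits against the seeds, while subfamily-private accessory pools make
  within-subfamily shared-PC fractions strictly exceed between-subfamily
  ones.
* **Prophages**: a fraction (default 0.2) of phages also inserted into
  host contigs with recorded intervals; carrier contigs get prophage
  triage categories.
* **CRISPR arrays**: 30-bp repeats interleaved with 32-bp spacers lifted
  from target phages, with a planned per-spacer mismatch count (0-3).
  Array boundary bases are rejection-sampled so that no three consecutive
  repeat copies share their flanking base -- otherwise the (simplified)
  array detector could legitimately extend the repeat consensus into the
  spacers and report a shifted sub-array.
* **Abundance**: log-normal per-genome abundance (meanlog 0, sdlog 1.5)
  for genomes present in a sample; presence is Bernoulli with per-group
  inclusion probabilities (default 0.9 control / 0.7 case, a modest
  case-group richness deficit mirroring the motivating cohort's
  direction), except planted-effect lineages, which are present as a
  lineage with the planted per-group prevalences (default 0.9 vs 0.1 --
  the differential used for the power checks).
* **Alignments, not reads.** All in-scope computation consumes alignment
  records, so reads are never simulated: `generate_alignments()` emits
  PAF-like records whose per-contig read sums are proportional to planted
  abundance x length with Poisson noise, tiled in 2-kb chunks (so present
  contigs have near-complete horizontal coverage), with a configurable
  fraction (default 5%) of records below 0.90 identity to exercise the
  filter. Depth vectors derive deterministically from records and
  conserve aligned bases.

What it does **not** emulate: sequencing error and read-level noise,
assembly fragmentation and chimerism, strain-level micro-diversity,
compositional coupling between phage and bacterial fractions, and real
taxonomies (host taxa are synthetic labels). Passing tests therefore
demonstrate that the *computational procedure* recovers what it is defined
to recover under its own assumptions -- not that those assumptions hold in
any particular real cohort.

# Numerical choices and problem sizes

* Thresholds at stated boundaries are inclusive on the "keep" side
  (identity >= 0.90, coverage >= 0.75, bits >= 50).
* The hypergeometric edge score, Fisher enumeration and BH adjustment are
  exact; Markov clustering prunes entries below 1e-12 and stops at a
  max-change of 1e-6.
* Degenerate inputs: empty alignment sets give zero coverage; all-zero
  samples stay zero with a warning; contigs without PCs are singleton VCs
  but are errors for shared-PC fractions; profiles with no discriminating
  sample are an error for boundary extraction.
* The test suite and the acceptance script run on deliberately small
  problem sizes -- communities of 8-24 phage genomes, 15-genome marker
  families, 200-600 aa proteins, 48 samples -- chosen so the planted
  effects are comfortably detectable at the study's per-group sample
  sizes while the full suite completes in minutes on one CPU. Power-style
  checks (Fisher at 24 per group, Wilcoxon richness at 24 per group,
  PERMANOVA type-I calibration) use the group sizes stated with each
  check. The Fisher null-calibration band is evaluated at the full
  bulk-cohort size (99 vs 97), where the test's discreteness is mild; at
  24 per group Fisher is conservative (type-I ~0.03 at nominal 0.05),
  which the suite asserts as an upper bound instead.

# Known limitations

* PC formation by connected components can chain distantly related
  proteins through intermediates; Markov clustering of the protein graph
  would split such chains at the cost of determinism simplicity.
* The array detector is deliberately minimal (no degenerate-repeat
  models, no orientation calling, no quality score) and will miss
  low-copy or highly degenerate arrays.
* Bit scores are raw Smith-Waterman conversions without composition-based
  statistics, so absolute values differ from heuristic search engines
  near the threshold.
* `deduplicate()` aligns candidate pairs exhaustively after a k-mer
  screen; it is meant for contig sets in the thousands, not millions.
* PERMANOVA permutes raw labels; restricted permutation schemes
  (strata, repeated measures) are not implemented.
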