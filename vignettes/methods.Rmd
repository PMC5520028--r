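---
title: "Methods: genome-interpretation models and their assumptions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genome-interpretation models and their assumptions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genopotential)
```

`genopotential` turns the standard downstream artifacts of a
genome-resolved metagenomics project — per-bin protein FASTA, GFF3 gene
calls, profile-search hit tables, per-scaffold depth tables and a
bin-membership table — into metabolic and ecological calls. This vignette
records the models behind each call, the tunable parameters and why their
defaults are what they are, the numerical conventions, and what the
synthetic fixtures do and do not demonstrate.

## Multiheme cytochromes and iron reduction

c-type cytochromes attach heme covalently at the motif CXXCH (cysteine,
two arbitrary residues, cysteine, histidine). Proteins with many such
sites — multiheme cytochromes, MHCs — are the hallmark of dissimilatory
metal reducers such as *Geobacter* and *Shewanella*, and their abundance
in a genome is a usable predictor of iron-reduction capacity.

`count_cxxch()` counts **every qualifying window**, overlapping windows
included. The motif definition itself does not say whether overlaps
count; we count them because heme-binding sites tile closely in real
cytochrome sequences and because the overlapping-count is a deterministic,
order-free statistic. This is flagged here as an interpretation. The two
wildcard positions accept any residue (including C and H); the constrained
positions accept only the exact letter, so the ambiguity code `X` never
creates a motif. Sequences are uppercased at ingest and a terminal stop
`*` is stripped.

Two thresholds drive the calls (`gp_thresholds()`):

* `mhc_min_motifs = 10` — a protein is an MHC at 10 or more motifs;
* `iron_min_mhcs = 4` — a genome is a candidate iron reducer at 4 or more
  MHC proteins.

Both are inclusive ("or more"), and the per-protein maximum motif count is
reported alongside, because single exceptionally heme-rich proteins (50+
motifs) are biologically interesting on their own.

`evaluate_predictor()` summarises a screen of the predictor against
labelled reference genomes as *prevalence* (flagged / screened) and
*precision* (flagged-and-known / flagged-and-labelled). Flagged genomes
without a label are excluded from the precision denominator with a
warning; zero flagged genomes give a missing precision, not zero. The
package validates this only on synthetic labels: a historical reference
database snapshot cannot be reconstructed reproducibly.

## Hydrogenase typing by operon context

Hydrogenases are classified first by cofactor and group from the best
profile hit (`NiFe_G1..G4`, `FeFe_GA/GB/GC`, `Fe_hmd`); the best bit score
wins, exact ties are broken by lexicographic profile name and flagged
ambiguous, so the call set is independent of input order.

Sequence alone cannot separate [FeFe] Group A subgroups; genomic context
can. Electron-bifurcating Group A3 enzymes are hetero-oligomeric: the
catalytic subunit is encoded in an operon with a diaphorase subunit
(*hydB*, multiple [4Fe-4S] clusters) and a small [2Fe-2S] protein
(*hydC*). Monomeric Group A1 enzymes lack both. `resolve_groupA()` walks
up to `operon_window = 3` genes downstream of the catalytic gene in its
strand's reading direction (+ strand: increasing gene ordinal; − strand:
decreasing), requiring neighbors to share the catalytic gene's strand.
Finding both roles gives A3. If the window runs into the scaffold end
before filling and the evidence is incomplete, the call is `A_unresolved`
— the operon may continue on an unassembled fragment — otherwise A1.

Three choices here were genuinely open and are package decisions:

* **window of 3 genes** — covers hydABC(D) arrangements while limiting
  false joins across operon boundaries; configurable;
* **co-orientation required** — operons are co-transcribed, so a
  neighbor on the opposite strand is not evidence; an opposite-strand
  *hydB* still occupies a window slot;
* **partial evidence at an edge** (for example *hydB* found, then the
  scaffold ends) maps to `A_unresolved`, not A1 — the conservative
  reading.

Ordinals are assigned by ascending start coordinate irrespective of
strand (GFF3 convention), which is what makes "downstream" well defined
per strand; coordinates are 1-based inclusive.

Co-occurrence statistics are bin-level fractions
|bins with both| / |bins with the first|, reported as missing when the
denominator is zero: A1-with-A3 (do H2-evolvers also carry uptake-capable
bifurcating enzymes?), bifurcating-with-Rnf (can ferredoxin reduced by H2
be cashed into a membrane gradient?), and B-with-A3.

## Pathway rules

A pathway rule is a conjunction of clauses, each a disjunction of
alternative marker genes — denitrification to N2, for example, is
{narG|napA} AND {nirK|nirS} AND {norB} AND {nosZ}. Status is `complete`
when every clause holds, `absent` when no positive clause holds,
`partial` otherwise. A clause may be negated; negated clauses encode
calls that are *defined by an absence* (partial nitrification:
hydroxylamine dehydrogenase present AND ammonia monooxygenase absent).
With negated clauses the monotonicity guarantee (adding genes can only
move absent → partial → complete) holds for positive-only rules, which is
how the property is tested.

The shipped rulebook (`inst/extdata/pathway_rules.tsv`) is data, not
code, and covers nitrogen fixation, denitrification, DNRA, partial
nitrification, anammox, sulfate reduction, sulfur oxidation,
Wood–Ljungdahl, the Calvin cycle (RuBisCO forms including II/III and
III-like), hydrogenotrophic methanogenesis (with a NOT-clause excluding
acetoclastic/methylotrophic genes), the Rnf complex and formate
dehydrogenase. It is a reconstruction from first principles of the
capacities a subsurface survey reports on, not a transcription of any
specific supplementary table; users mirroring a particular study should
edit the TSV. Fermentation and complex-carbon degradation involve large
redundant gene families, so they are scored as gene counts bucketed into
none/low/high tiers (tercile break over all bins; zero is always "none")
rather than as completeness.

The bin-by-feature matrix keeps genomes with mean relative abundance
above `rare_abundance_frac = 0.001` (0.1%), ordered by descending
abundance — the community-level summary a survey figure would show.

## Bin QC, dereplication, community accounting

**Completeness/contamination.** With an expected single-copy marker set
(default: 51 ribosomal-protein-style markers), completeness is
100 × |markers seen ≥ 1×| / |set| and contamination
100 × |markers seen ≥ 2×| / |set| (distinct genes per marker). High
quality means completeness **strictly above 70** and contamination
**strictly below 10** — at a 51-marker set no bin can sit exactly on the
boundary, but the strictness matters for custom sets (7/10 markers is
70% and is *not* high quality).

**Dereplication.** Bins re-assembled from multiple samples are collapsed
by single-linkage clustering over edges with nucleotide identity
≥ `derep_identity = 0.98` and aligned fraction
≥ `derep_aligned_frac = 0.5` of the shorter genome. Neither threshold is
universal in the literature; 98% is the common strain boundary, and both
are configurable. The identity estimator is deliberately self-contained
and fixture-scale: scaffolds are matched by shared 16-mers (pairs sharing
fewer than 5 are skipped, so unrelated bins cost nothing and score zero
aligned fraction) and matched pairs are globally aligned
(match +1, mismatch −1, gap open 5, extend 2 — penalties under which a
substitution-only divergence aligns gap-free); identity is pooled matches
over pooled aligned positions. This is not a whole-genome aligner and is
not meant to scale to real assemblies. Representatives are the most
complete bin, ties broken by lower contamination then lexicographic id.

**rpS3 accounting.** Ribosomal protein S3 assembles reliably and is
single copy, so clustering all rpS3 sequences enumerates organisms,
binned or not. Greedy centroid clustering at
`rps3_cluster_identity = 0.99` global amino-acid identity, longest
sequence seeding (ties by name, for determinism). Organism abundance is
its rpS3-scaffold depth as a fraction of all rpS3-scaffold depth; the
ranking summary reports how many of the top-k organisms fall inside a
bin and, among unbinned organisms, the fraction below the 0.1% rarity
cutoff — the accounting that says how much of a community a genome
catalogue captures.

**Relative abundance.** A bin's per-sample coverage is the
length-weighted mean of its scaffolds' depths (equal to mapped bases per
genome base; the mean-vs-median choice is a package decision),
normalised to sum to one per sample. Scale invariance (doubling a
sample's depths changes nothing) follows by construction.

**Alignment preparation.** `trim_concatenated_alignment()` applies, in
one non-iterated pass: per-block removal of columns with gap fraction
strictly above `gap_col_max_frac = 0.90`; concatenation over the taxon
union (taxa absent from a block filled with gaps); removal of taxa with
non-gap fraction strictly below `seq_min_aligned_frac = 0.50`; and a
tree-eligibility flag at `tree_min_positions = 450` non-gap columns
(449 positions: retained in the alignment, excluded from the tree). The
column filter precedes taxon dropping and is not re-run afterwards, so a
retained column's gap fraction is guaranteed only relative to the pass-1
taxon set; re-running the trimmer on its own output is a no-op. Tree
inference itself is out of scope.

**Correlation screen.** `abundance_correlation()` is an optional
exploratory utility: Spearman correlation of per-sample abundances,
restricted to genome pairs within `cooccur_ratio = 10`-fold in mean
abundance. The restriction-by-ratio design is an interpretation of a
loosely specified screen and is labelled as such.

## The synthetic community and what it shows

`generate_community()` is first-class, tested code, and its defaults are
the package's study conditions: 12 source bins (5 scaffolds of 2,500 bp
each), 8 replicate bins at 0.5% divergence, 4 decoy bins at 10%, 6
unbinned organisms, 4 samples, organism abundances log-normal
(sdlog 2.2, a long-tailed rank-abundance curve with per-sample log-normal
variation at sdlog 0.5), depth = abundance × 1000 identical for every
scaffold of a bin. Marker complements are drawn per bin (28–51 of 51
markers present, 0–6 duplicated), so completeness spans the high-quality
boundary. Hydrogenase content is planted so that every A1 and every
Group B genome also carries A3, and Rnf is planted in five of the six
bifurcating source bins — the co-occurrence structure the co-occurrence
statistics must recover exactly.

Three constructions make planted truth *exact* rather than statistical:

* **Guarded alphabet.** Background residues come from 18 letters
  excluding C and H, so the only CXXCH motifs are the planted ones — an
  accidental motif would need a background C at two constrained
  positions and an H at a third. Motif recovery is therefore tested at
  equality, not approximately. A full-alphabet mode exists solely for
  oracle-versus-implementation testing.
* **Exactly realised mutation counts.** A replicate at rate r mutates
  exactly round(r × length) positions per sequence, so a 0.5% replicate
  is at identity 0.995 and a 10% decoy at 0.900 deterministically —
  comfortably either side of the 0.98 dereplication and 0.99 rpS3
  thresholds. Behaviour *at* the thresholds is documented, not asserted.
* **Uniform within-bin depth.** Depth identical across a bin's scaffolds
  makes length-weighted and unweighted abundance coincide, isolating the
  estimator under test.

What the fixtures do **not** show: real proteomes have C/H-rich
backgrounds (motif counts there are only lower-bounded by planting); real
genome pairs diverge by indels and rearrangement, not pure substitution,
so the identity estimator's fixture accuracy does not transfer to real
assemblies; depth in real data varies within genomes; and profile-search
scores here are planted labels, not HMM alignments, so nothing is learned
about HMM sensitivity. Passing the suite demonstrates the
interpretation-layer logic, not the upstream sequence analysis.

Problem sizes were chosen so that the full demo (generation plus the
complete pipeline, including all-pairs dereplication) runs in well under
two minutes on one CPU: 24 bins, ~200 scaffolds, ~1,700 genes, 10,000
random proteins in the scanner oracle, 72 operon layouts, and exhaustive
truth tables (~1,300 cases) for the rule engine.

## Numerical conventions and degenerate inputs

* Fractions with zero denominators (precision with nothing flagged,
  co-occurrence with no qualifying bins) are reported missing (`NA`),
  never 0.
* An empty protein or one shorter than 5 residues has motif count 0;
  an empty rpS3 input yields zero clusters; an all-zero abundance table
  yields an empty profile matrix with a warning; all-zero rpS3 depths
  are an error.
* Abundance columns sum to 1 within 1e-9 (in practice to machine
  precision); coverage tables are written with 17 significant digits so
  the double → text → double round trip is exact.
* Ties: profile-score ties break lexicographically and are flagged;
  cluster representatives tie-break by contamination then id; rpS3
  centroid seeding ties break by name. Every output is invariant under
  permutation of input rows.
* The demo's `expected_summary.json` is computed from the planted truth
  alone (never by running the pipeline at generation time); integer
  counts and small-integer ratios are used in the summary precisely so
  that the truth-side and measured-side computations agree bitwise.

## Known limitations

* [NiFe] subgroup localisation beyond the profile label, and
  phylogenetic placement of hydrogenases, are out of scope; group
  identity comes from profile labels alone.
* The pairwise identity estimator is for fixture-scale genomes
  (≤ ~1 Mb); use a genome aligner for real dereplication.
* Profile-search score cutoffs default to a uniform bit score of 50 and
  are configuration, not inference.
* The taxonomy consensus takes the longest shared lineage prefix across
  up to three methods; with evidence missing it degrades to the methods
  available (warning) — it does not attempt to arbitrate conflicts below
  the first disagreement.
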