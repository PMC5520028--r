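# genopotential

Genome-resolved metabolic potential profiling for metagenome-assembled
genomes (MAGs) from anoxic subsurface communities.

Deep sedimentary aquifers host microbial communities that cycle hydrogen,
iron, sulfur, nitrogen and carbon, with direct consequences for engineered
systems such as geological radioactive-waste repositories (H2 consumption,
sulfide-driven corrosion, reductive immobilisation of radionuclides). Once
such a community has been assembled and binned into draft genomes, a
recurring set of interpretation steps turns gene calls and profile-search
hits into ecology: who can respire iron, who cycles H2 and in which
direction, which pathways are complete, which bins are redundant
assemblies of the same organism, and how much of the community the genome
catalogue actually captures. `genopotential` implements that
interpretation layer as tested, reusable R functions, together with a
seeded synthetic-community generator that plants ground truth for every
stage.

## What it computes

* **Multiheme cytochromes and iron reduction** — every protein is scanned
  for the c-type cytochrome heme-attachment motif CXXCH (all overlapping
  occurrences counted). A protein with ≥ 10 motifs is a multiheme
  cytochrome (MHC); a genome with ≥ 4 MHCs is flagged as a candidate
  dissimilatory iron reducer. `evaluate_predictor()` summarises a
  labelled reference screen as prevalence and precision.
* **Hydrogenase typing** — cofactor class ([NiFe], [FeFe], [Fe]) and group
  from best profile hits; [FeFe] Group A is resolved by operon context:
  a catalytic subunit with co-oriented *hydB* (diaphorase, [4Fe-4S]) and
  *hydC* ([2Fe-2S]) genes within 3 genes downstream is an
  electron-bifurcating Group A3 enzyme; without them it is monomeric
  Group A1; a window truncated by the scaffold edge with incomplete
  evidence is `A_unresolved`. Co-occurrence statistics (A1-with-A3,
  bifurcating-with-Rnf, B-with-A3) follow.
* **Pathway profiling** — a rulebook of marker-gene clauses (conjunctions
  of disjunctions, with NOT-clauses for absence-defined calls such as
  partial nitrification) yields complete / partial / absent status per
  bin and pathway, and a bin-by-feature matrix restricted to genomes above
  a 0.1% mean-abundance cutoff.
* **Bin QC and dereplication** — completeness and contamination as the
  percentage of a single-copy marker set present once / more than once;
  high-quality drafts at > 70% complete and < 10% contamination;
  single-linkage dereplication of bins at ≥ 98% pairwise nucleotide
  identity over ≥ 50% aligned fraction.
* **Community accounting** — organisms enumerated by clustering ribosomal
  protein S3 (rpS3) sequences at 99% identity; rank abundance from
  scaffold depth; per-bin relative abundance as length-weighted mean
  depth normalised per sample; and the trimming contract for concatenated
  ribosomal-protein alignments (drop columns > 90% gaps, drop sequences
  < 50% aligned positions, tree eligibility at ≥ 450 positions).

## Worked example

```r
library(genopotential)

count_cxxch("CAACHACHMKCAYCH")
#> $count
#> [1] 3
#> $starts
#> [1]  1  4 11

gen <- generate_proteome(5, motif_counts = c(0, 3, 9, 10, 14), seed = 11)
call_mhcs(gen$proteome)[, c("gene_id", "motif_count", "is_mhc")]
#>     gene_id motif_count is_mhc
#> 1 prot_0001           0  FALSE
#> 2 prot_0002           3  FALSE
#> 3 prot_0003           9  FALSE
#> 4 prot_0004          10   TRUE
#> 5 prot_0005          14   TRUE

fx <- generate_operon_fixture(list(
  operon_layout("FeFe_GA", "+", c("hydB", "hydC", "other")),
  operon_layout("FeFe_GA", "-", rep("other", 3)),
  operon_layout("FeFe_GA", "+", character(0))), seed = 2)
call_hydrogenases(fx$genes, fx$hits)[, c("gene_id", "cofactor", "group",
                                         "subgroup")]
#>      gene_id cofactor group     subgroup
#> 1 op_001_g02     FeFe     A           A3
#> 2 op_002_g04     FeFe     A           A1
#> 3 op_003_g02     FeFe     A A_unresolved
```

The 9-motif protein is not an MHC (the threshold is "10 or more"); the
catalytic gene followed by co-oriented *hydB* and *hydC* is bifurcating
(A3), the one followed by three unrelated genes is monomeric (A1), and the
one at the scaffold edge cannot be resolved.

End to end, on a seeded synthetic community (12 source bins, 8 close
replicate bins at 0.5% divergence, 4 decoys at 10%, 6 unbinned
organisms):

```r
td <- tempfile(); make_demo(seed = 1, outdir = td)
res <- run_pipeline(list(input_dir = td, out_dir = file.path(td, "out"),
                         seed = 1))
#> bins: 24   high-quality: 15   after dereplication: 16
#> MHC proteins: 41   predicted iron reducers: 6
#> hydrogenases: 56 in 22 bins; 67% of Group A are A3
#> Rnf in 88% of bifurcating-hydrogenase genomes
```

(the counts above are read from `res$summary`). Dereplication recovers
exactly the planted structure: the 8 close replicates merge into their
sources, the 4 decoys do not. The same summary is written as
`summary.json`, and matches the generator's truth-derived
`expected_summary.json` byte for byte.

A thin command-line front-end is included:

```sh
exec/genopotential demo --seed 1 --out demo/
exec/genopotential run --in demo/ --out demo/out --seed 1
```

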