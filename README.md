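# drbstr

Characterising the MHC-DRB intron-2 microsatellite for allele typing in
owl monkeys (*Aotus*), as a reusable, tested R pipeline.

MHC-DRB alleles in New World monkeys are conventionally typed by
sequencing exon 2. Directly downstream, at the start of intron 2, sits a
short tandem repeat (STR) — a (GA)<sub>y</sub> tract interrupted by CT
motifs, homologous to the human D6S2878 marker — whose length and
structure track allelic lineages. `drbstr` provides the computational
toolkit for studying that marker on exon 2 + partial intron 2 amplicons:
sector partitioning and conservation statistics, imperfect-microsatellite
detection, an alignment-free compression distance, and concordance
analysis between the groupings each gene sector induces. A seeded
synthetic-panel generator emulating the published 34-allele *A.
vociferans* / *A. nancymaae* dataset makes every stage testable end to
end.

## The core method

The STR sector cannot be aligned unambiguously, so sequences are compared
by compressibility. For an STR sector *s* of length *L*:

* **tandem amplification:** `s^100` (the sequence repeated 100 times in
  tandem, no separators), so the adaptive dictionary saturates on the
  sequence's own repeat structure;
* **compression:** `B = |LZW(s^100)|` in bytes, with a faithful
  implementation of the Unix `compress` `.Z` coder (block mode, 9-16 bit
  codes; streams are accepted by `uncompress`/`gzip -d`);
* **distance:** `d(i,j) = |B_i − B_j|` (scalar size mode, under which the
  Euclidean, Maximum and Manhattan metrics coincide exactly);
* **grouping:** complete- or single-linkage hierarchical clustering of
  `d`, compared against neighbour-joining bootstrap trees built from the
  alignable exon-2 and intron-2A/2B sectors via shared bipartitions and
  adjusted Rand indices.

Repeat runs are detected in imperfect mode: perfect tracts of one
canonical motif family merged across interruptions of at most 4 nt, valid
from 12 mononucleotide or 4 multinucleotide copies, purity ≥ 0.85.

## Worked example

```r
library(drbstr)

panel <- generate_panel(panel_config(seed = 1))
panel
#> drb_panel: 34 records, 11 lineages, seed 1
#>   STR sector lengths 66-754 nt

part <- partition_alignment(panel$alignment, default_sector_scheme())
part
#> sector_partition: intron1[15] + exon2[270] + intron2A[40] + intron2R[785] + intron2B[268]

pairwise_identity(part$sectors$exon2)
#> mean pairwise identity 90.5% (se 0.15, sd 3.47, 561 pairs)
pairwise_identity(concat_sectors(part, c("intron2A", "intron2B")))
#> mean pairwise identity 95.8% (se 0.07, sd 1.55, 561 pairs)

prof <- profile_panel(panel, tandem_factor = 100)
range(prof$B)
#> [1]  769 4117
length_correlation(prof)          # R^2 of compressed bytes on length
#> [1] 0.9834482

hc <- str_hclust(distance_matrix(prof, "manhattan"), linkage = "complete")
exon_tree <- bootstrap_support(part$sectors$exon2, n = 1000, seed = 1)
compare_groupings(hc, exon_tree,
                  truth = setNames(panel$truth$lineage, panel$truth$id))
#> grouping comparison (k = 11): ARI 0.418, 4 shared bipartitions (of 31 / 9)
#>   ARI against truth lineages: a 0.418, b 1.000
```

The numbers illustrate the marker's character: intron 2's alignable
sectors are more conserved (95.8%) than exon 2 (90.5%); compressed size
is nearly collinear with STR length (R² ≈ 0.98) because the repeats share
one motif family and vary chiefly in number; and the STR grouping
recovers lineage structure only partially (ARI 0.42 against truth, versus
1.0 for the exon-2 tree) — it separates the major lineage groups but
merges lineages of similar repeat count, which is exactly the
screening-not-typing behaviour of interest.

A step-by-step version of this analysis lives in `analysis/01...06`
(simulate → partition/identity → STR scan → compression distance → trees
→ concordance); each script is a thin driver over the package functions
and writes its tables under `results/`.

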