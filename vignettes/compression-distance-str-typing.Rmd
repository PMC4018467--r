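---
title: "Methods: compression-distance analysis of the DRB intron-2 microsatellite"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: compression-distance analysis of the DRB intron-2 microsatellite}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drbstr)
```

## The problem

MHC-DRB genotyping in New World monkeys usually means amplifying, cloning
and sequencing exon 2, which carries most allelic polymorphism. A short
tandem repeat (STR) at the start of intron 2 — a (GA)~y~ tract interrupted
by CT motifs, homologous to the human D6S2878 marker — varies in length and
structure between allelic lineages, so it is a candidate for cheaper
screening-level typing. `drbstr` implements the computational side of
characterising that marker on exon 2 + partial intron 2 amplicons:

1. **Sector partition.** The amplicon alignment is split by fixed column
   coordinates into intron 1 (15 sites), exon 2 (270), alignable intron
   sector 2A (40), the STR sector 2R (785) and alignable sector 2B (268);
   per-sector conservation is summarised as mean pairwise percent identity.
2. **Imperfect repeat scan.** Tandem repeat runs are detected under
   explicit validity thresholds and the STR is decomposed into initial,
   central and final sectors.
3. **Compression distance.** Because the repeat tract cannot be aligned
   unambiguously, sequences are compared alignment-free: each STR sector is
   repeated 100 times in tandem, compressed with an adaptive Lempel-Ziv
   coder, and the compressed sizes are turned into a distance matrix.
4. **Groupings and concordance.** Hierarchical clustering (single/complete
   linkage) over the compression distances; neighbour-joining trees with
   column-resampling bootstrap for the alignable sectors; shared
   bipartitions and adjusted Rand indices between the sector-wise
   groupings.

## The compression distance

For an STR sector $s$ of length $L$ nt, define

$$B(s) \;=\; \bigl|\,\mathrm{LZW}(s^{100})\,\bigr| \quad\text{bytes},$$

where $s^{100}$ is the 100-fold tandem concatenation and LZW is the
classic Unix `compress` coder. Tandem amplification lets the adaptive
dictionary saturate on the sequence's own repeat structure: after the
first copy, subsequent copies cost only as much as the sequence's
effective complexity, so $B$ resolves both length and internal repeat
structure at much finer granularity than $B(s)$ alone. The default
distance is the scalar collapse

$$d(i, j) \;=\; \lvert B_i - B_j \rvert ,$$

under which the Euclidean, maximum and Manhattan metrics coincide exactly
(asserted in the test suite). A `byte_vector` mode — metrics over the
zero-padded compressed payload bytes — is provided for sensitivity
analysis; it is *not* the default because the byte stream of an adaptive
coder has no positional alignment between sequences, making the scalar
size the better-behaved summary.

### The coder dialect

`compress_lzw()` implements the `.Z` container precisely: magic bytes
`1F 9D`, flags `0x90` (block mode, 16-bit maximum code), code widths
growing from 9 to 16 bits, and a CLEAR code that resets the dictionary
when the running compression ratio degrades (checked every 10,000 input
bytes once the dictionary is full). Two quirks of the historical coder
are reproduced because the reference decoder depends on them:

* the code stream is padded to an `n_bits`-byte group boundary *relative
  to the start of the current width segment* whenever the width changes or
  a CLEAR is emitted (the historical coder flushed its 8-code buffer);
  padding bytes are zeros here — the reference left stale buffer content,
  which decoders ignore;
* the width check runs after packing each code and before that step's
  dictionary insertion, which fixes on which code the width grows.

Streams are validated in the test suite by round-trip through (a) the
package decoder, (b) an independently written pure-R decoder, and (c)
the system's reference decoder (`gzip -d`, which shares the historical
`uncompress` code path). A byte-for-byte comparison against a `compress`
*encoder* binary is not part of the suite; the three-decoder agreement,
including inputs that exercise the dictionary-reset path, pins the
dialect.

Sequences are encoded as uppercase ASCII bytes with no newlines before
compression, i.e. exactly the bytes of the sequence written to its own
file.

## Imperfect repeat detection

No installed package scans for *imperfect* microsatellites under the
validity rules this analysis needs, so the scanner is implemented here:

* perfect tandem tracts of unit length 1-6 are found for primitive motifs
  (a motif that is itself a repeat, e.g. `GAGA`, is attributed to its
  shorter unit);
* tracts of the same canonical motif rotation (`GA` and `AG` report as
  one family) separated by interruptions of at most `max_gap` nt
  (default 4 = two dinucleotide units) are merged into one imperfect run;
  gaps containing `N` are never bridged;
* a run is valid with at least 12 mononucleotide copies, or at least 4
  copies for di- to hexanucleotide units (thresholds applied to the floor
  of the real-valued copy number, so partial trailing units count toward
  length but not validity), and purity — matched bases over spanned
  bases — at least `min_purity` (default 0.85);
* overlapping candidates are resolved deterministically: longest first,
  ties by smaller start, then lexicographically smaller motif.

The scanner is checked against an exhaustive window-enumeration oracle on
random 200-nt sequences. `decompose_str()` takes the longest merged
GA-family run as the STR's **central** sector and the flanking
subsequences as **initial** and **final** sectors; this is a
motif-structure definition of the three sectors (an alignment-anchor
definition would need the cross-sequence alignment that the repeat tract
does not support).

## The synthetic panel

All validation runs on seeded synthetic panels, because the original
amplicon set is not redistributable. The default configuration emulates
the published study conditions: 34 alleles in 11 lineages across two
species tags, a conserved 15-nt intron-1 stub, a 270-nt exon 2 whose
lineage prototypes diverge at 4.5% per site (within-lineage 0.8%), 40-nt
and 268-nt alignable intron sectors at 2.2%/0.4% divergence, and an STR
sector built as conserved 20-nt flanks around a (GA)~y~ core with
isolated CT interruptions. Per-lineage central repeat counts follow the
published per-lineage sector-length ranges (66 nt for the W93-like
singleton with its 26-nt central region, 144-160 nt for W18-like
alleles, 68-156 for the short-STR lineage group, roughly 290-460 for the
DRB3\*06 / DRB1\*03GA groups, and a long lineage approaching the 761-nt
extreme). The divergence rates were calibrated once so that the panel's
mean pairwise identities land at the published sector contrast (about
91% for exon 2 vs 95% for intron 2A+2B) and were not revisited.

Two structural choices matter downstream:

* **Interruption counts are deterministic** — `round(copies × rate / 10)`
  with per-lineage rates between 0.6 and 1.4 per 10 units — while
  interruption *positions* are random but isolated (never adjacent, never
  in the terminal unit pairs). Alleles of a lineage therefore share
  complexity and differ chiefly in repeat number, which is what makes
  compressed size nearly collinear with length; a Poisson count draw
  instead injects complexity noise that swamps the length signal and
  breaks lineage recovery.
* **The length window [66, 761] is enforced** by redrawing the repeat
  count (then clamping, without interruptions, as a last resort), so the
  generator cannot emit sectors outside the observed extremes or wider
  than the 785-column STR sector.

What the generator does *not* emulate: PCR/cloning artefacts and
sequencing error, recombination between lineages, indels in the
alignable sectors (alignment columns are exact by construction), and
central-motif diversity beyond the GA/CT families. The last limitation
is visible in the compressed sizes: the synthetic panel's largest
100-fold-amplified sector compresses to roughly 4.1 kB, while values
above 7 kB would require more motif diversity than a two-family model
can produce. Passing tests therefore demonstrate the pipeline's
behaviour under the stated generative model, not performance on raw
trace data.

## Trees, supports and concordance

Hierarchical clustering is delegated to `stats::hclust` (single and
complete linkage), as `stats::dist`/`hclust` are the canonical tools for
this step; merge-height monotonicity is property-tested. Distance trees
for the alignable sectors use neighbour joining (`ape::nj`) on the
uncorrected p-distance with pairwise deletion — model-based distances
and likelihood/parsimony estimation are deliberately out of scope, and
the p-distance choice is a documented limitation, not an oversight.
Bootstrap support resamples alignment columns with replacement,
rebuilds the tree per replicate, and counts unrooted bipartitions
(`ape::prop.clades`); supports attach to internal edges of the point
estimate, whose zero-length internal edges are first collapsed so that
unresolved structure is never assigned support. The root entry of the
clade list, which is no bipartition, is reported as `NA`. The supported-
group threshold defaults to 70%.

`compare_groupings()` quantifies concordance as (a) the number of shared
internal bipartitions, filtered to supported ones where bootstrap values
exist, and (b) the adjusted Rand index between k-group cuts, with k
defaulting to the number of truth lineages. Cutting an unrooted tree
into k groups uses average-linkage clustering of its cophenetic
distances — a convention, stated here because several inequivalent
conventions exist.

## Numerical and degenerate-case decisions

* Pairwise identity excludes columns where either sequence has `-` or
  `N` from numerator and denominator; a pair with no comparable columns
  scores 0 with a warning. The published "±1%" dispersion is read as a
  standard error over pairs; both SE and SD are reported.
* A single-pair alignment has SE and SD 0 (not `NA`).
* Sector coordinates are 1-based inclusive at every interface.
* `find_repeats("")` returns an empty table, not an error; invalid
  alphabets error.
* Tie-breaking inside `hclust` and `nj` follows those implementations,
  which are deterministic for fixed input order; panel record order is
  itself deterministic under a seed, so pipeline reruns are
  checksum-identical.
* Non-positive repeat-count draws are redrawn (up to 100 times) rather
  than truncated, keeping the count distribution shape; the fallback
  clamp never fires under the default configuration.

## Problem sizes

The test suite and the acceptance script run at desk scale by design:
34-allele panels, twenty seeds for panel-level marginals and recovery
rates, 100-1,000 bootstrap replicates, 50-input coder corpora with
inputs up to ~10 kB plus one 400 kB reset-path input, and exhaustive
repeat-scan oracles on 200-nt sequences. These sizes were chosen so the
whole validation cycle completes in a few minutes on one core while
still exercising every code path, including the 9-to-16-bit width
ladder of the coder.

## Known limitations

* The compressed-size ceiling of the GA/CT generative model discussed
  above: synthetic maxima reach ~4-5.5 kB, not the >7 kB attainable with
  richer central-motif alphabets.
* The coder is pinned to one dialect (16-bit, block mode); other
  `compress` variants (e.g. `-b12`) decode but are not emitted.
* `byte_vector` mode pads after the 3-byte header with zeros; distances
  in that mode depend on this stated convention.
* Bootstrap supports are the only group-support measure implemented;
  interior-branch tests are out of scope.
* Species tags are decorative: the generator encodes no species-level
  signal, consistent with lineages that cross the species boundary.
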