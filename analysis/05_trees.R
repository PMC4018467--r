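#!/usr/bin/env Rscript
# Stage 5: groupings per sector. The STR grouping is a complete-linkage
# dendrogram over the compression distances; exon 2 and the concatenated
# alignable intron sectors get neighbour-joining trees on p-distance
# with 1,000 column-resampling bootstrap replicates (support threshold
# 70%).

library(drbstr)

seed <- 1L
records <- read_fasta("results/panel_aligned.fasta")
aln <- setNames(records$sequence, records$id)
part <- partition_alignment(aln, default_sector_scheme())

d <- distance_matrix(profile_panel(
  apply(part$sectors$intron2R, 1, function(r) paste(r[r != "-"], collapse = "")),
  tandem_factor = 100L
), metric = "manhattan")
hc <- str_hclust(d, linkage = "complete")
to_newick(hc, "results/str_hclust.nwk")

exon_bt <- bootstrap_support(part$sectors$exon2, n = 1000L, seed = seed)
intron_bt <- bootstrap_support(concat_sectors(part, c("intron2A", "intron2B")),
                               n = 1000L, seed = seed)
to_newick(exon_bt, "results/exon2_nj.nwk")
to_newick(intron_bt, "results/intron2AB_nj.nwk")

print(exon_bt)
print(intron_bt)
cat("wrote results/str_hclust.nwk, exon2_nj.nwk, intron2AB_nj.nwk\n")
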