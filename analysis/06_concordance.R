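#!/usr/bin/env Rscript
# Stage 6: concordance between the sector-wise groupings. For each pair
# of groupings: shared (support-filtered) bipartitions, adjusted Rand
# index of the k-cut clusterings (k = number of truth lineages), and the
# agreement of each grouping with the truth lineage labels.

library(drbstr)

seed <- 1L
records <- read_fasta("results/panel_aligned.fasta")
truth <- setNames(records$lineage, records$id)
aln <- setNames(records$sequence, records$id)
part <- partition_alignment(aln, default_sector_scheme())

d <- distance_matrix(profile_panel(
  apply(part$sectors$intron2R, 1, function(r) paste(r[r != "-"], collapse = "")),
  tandem_factor = 100L
), metric = "manhattan")
hc <- str_hclust(d, linkage = "complete")
exon_bt <- bootstrap_support(part$sectors$exon2, n = 1000L, seed = seed)
intron_bt <- bootstrap_support(concat_sectors(part, c("intron2A", "intron2B")),
                               n = 1000L, seed = seed)

pairs <- list(str_vs_exon = list(hc, exon_bt),
              str_vs_intron = list(hc, intron_bt),
              exon_vs_intron = list(exon_bt, intron_bt))
rows <- lapply(names(pairs), function(nm) {
  cmp <- compare_groupings(pairs[[nm]][[1]], pairs[[nm]][[2]], truth = truth)
  print(cmp)
  data.frame(pair = nm, k = cmp$k, ari = cmp$ari,
             shared_bipartitions = cmp$shared_bipartitions,
             ari_truth_a = unname(cmp$ari_truth["a"]),
             ari_truth_b = unname(cmp$ari_truth["b"]))
})
tab <- do.call(rbind, rows)
write.table(tab, "results/comparison.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
print(tab, digits = 3)
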