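#!/usr/bin/env Rscript
# Step 3: whole-genome comparison of the confirmed circular genome
# scaffolds. Sums cross-hit bitscores per genome pair, computes Dice
# similarity and its dissimilarity transform, builds the neighbor-joining
# tree, and cuts single-linkage groups. To show the comparison resolving
# relatedness, the planted redundant contigs (near-identical copies) are
# included here alongside their parents.

suppressPackageStartupMessages(library(virosieve))
cm <- readRDS("results/community.rds")
cur <- readRDS("results/curation.rds")

viral <- cur$triage$results$scaffold_id[cur$triage$results$label == "viral"]
circ <- cur$calls$scaffold_id[cur$calls$is_circular]
ids <- intersect(viral, circ)
# Add the planted redundant copies of viral genomes for the relatedness
# demonstration.
red <- cm$truth[!is.na(cm$truth$redundant_of) &
                  cm$truth$class_label == "viral", ]
ids <- sort(Reduce(union, list(ids, red$scaffold_id, red$redundant_of)))
cat(sprintf("comparing %d genomes (%d confirmed circular, %d planted copy pairs)\n",
            length(ids), length(intersect(viral, circ)), nrow(red)))

hits <- emit_cross_hits(cm)
hits <- hits[hits$qseqid %in% ids & hits$sseqid %in% ids, ]
S <- summed_scores(filter_hits(hits), ids)
dm <- dice_matrix(S)
write.table(round(dm$D, 4), "results/dice_matrix.tsv", sep = "\t",
            quote = FALSE, col.names = NA)

tree <- nj_tree(dm$dissim)
writeLines(attr(tree, "newick"), "results/nj_tree.nwk")

groups <- cluster_groups(dm$D, threshold = 0.05)
cat(sprintf("groups at D >= 0.05: %d multi-member, %d unique genomes\n",
            length(groups$groups), length(groups$singletons)))
for (g in seq_along(groups$groups)) {
  cat(sprintf("  G%d: %s\n", g, paste(groups$groups[[g]], collapse = ", ")))
}
write.table(groups$membership, "results/genome_groups.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
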