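#!/usr/bin/env Rscript
# Step 1: draw the synthetic virome community used throughout the
# analysis: 60 genomes (30 viral, 15 cellular, 8 plasmid-like,
# 7 mitochondrion-like), half of each class circular, with 4 planted attP
# sites, 2 planted CRISPR spacer links and 4 planted redundant contigs.
# Writes the genome FASTA, the ground-truth tables, and an example
# read-pair simulation for one circular scaffold.

suppressPackageStartupMessages(library(virosieve))
dir.create("results", showWarnings = FALSE)

spec <- community_spec(n_viral = 30, n_cellular = 15, n_plasmidlike = 8,
                       n_mitolike = 7, n_attp = 4, n_crispr = 2,
                       n_redundant = 4, seed = 20260924L)
cm <- generate_community(spec)
print(cm)

write_community_fasta(cm, "results/community.fasta")
write.table(cm$truth, "results/truth.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(cm$trna_db, "results/trna_db.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(cm$arrays, "results/crispr_arrays.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
saveRDS(cm, "results/community.rds")

# Example read simulation: the first circular scaffold at nominal coverage.
i <- which(cm$truth$is_circular)[1]
id <- cm$truth$scaffold_id[i]
n_pairs <- round(spec$coverage * cm$truth$length[i] / (2 * spec$read_length))
sim <- simulate_paired_reads(cm$genomes[[id]], TRUE, n_pairs, spec, id,
                             seed = 1L)
write_sam(sim$sam, stats::setNames(cm$truth$length[i], id),
          "results/example_mapping.sam")
write_fastq_pair(sim$reads, "results/example_R1.fastq",
                 "results/example_R2.fastq")
cat(sprintf("simulated %d pairs for %s (%d wrap the origin)\n",
            n_pairs, id, sum(sim$wrapped)))
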