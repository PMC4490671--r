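#!/usr/bin/env Rscript
# Step 2: curate the pooled synthetic assembly. Removes planted redundant
# contigs with the descending-length sweep, calls circularity for every
# retained scaffold from simulated read mappings, applies the length and
# coverage gates, and triages the candidates into viral vs contamination
# queues.

suppressPackageStartupMessages(library(virosieve))
cm <- readRDS("results/community.rds")
spec <- cm$spec

# Redundancy sweep over the pooled contigs.
pooled <- data.frame(id = cm$truth$scaffold_id, length = cm$truth$length,
                     coverage = cm$truth$coverage, stringsAsFactors = FALSE)
dedup <- remove_redundancy(pooled, emit_self_hits(cm))
cat(sprintf("dedup: %d pooled -> %d retained (%d redundant removed)\n",
            nrow(pooled), nrow(dedup$retained), nrow(dedup$removal_log)))
write.table(dedup$removal_log, "results/removal_log.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

# Circularity calls from simulated read mappings at nominal coverage.
calls <- do.call(rbind, lapply(seq_len(nrow(dedup$retained)), function(i) {
  id <- dedup$retained$id[i]
  ti <- match(id, cm$truth$scaffold_id)
  L <- cm$truth$length[ti]
  n_pairs <- round(spec$coverage * L / (2 * spec$read_length))
  sim <- simulate_paired_reads(cm$genomes[[id]], cm$truth$is_circular[ti],
                               n_pairs, spec, id,
                               seed = child_seed(spec$seed, ti, 30L))
  call_circularity(id, L, pair_alignments(sim$sam), cm$genomes[[id]])
}))
write.table(calls, "results/circularity_calls.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
truth_flags <- cm$truth$is_circular[match(calls$scaffold_id,
                                          cm$truth$scaffold_id)]
cat(sprintf("circularity: %d/%d calls agree with planted truth\n",
            sum(calls$is_circular == truth_flags), nrow(calls)))

# Gate and triage.
gated <- length_gate(dedup$retained,
                     circular = calls$scaffold_id[calls$is_circular])
candidates <- gated[gated$status == "candidate", ]
ht <- emit_hit_tables(cm$truth, seed = child_seed(spec$seed, 0L, 40L))
prof <- build_profiles(ht$genes, ht$hits,
                       stats::setNames(cm$truth$coverage,
                                       cm$truth$scaffold_id))
tri <- triage_batch(prof[prof$scaffold_id %in% candidates$id, ])
write.table(tri$results, "results/triage.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
saveRDS(list(dedup = dedup, calls = calls, gated = gated, genes = ht$genes,
             profiles = prof, triage = tri), "results/curation.rds")

cat("triage labels:\n")
print(tri$summary$label_counts)
cat(sprintf("viral fraction of candidates: %.1f%%\n",
            tri$summary$viral_fraction_pct))
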