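#!/usr/bin/env Rscript
# Step 4: host links. Searches every scaffold against the tRNA database
# for 100%-identity attP matches, assigns putative hosts (class level) to
# integrase-bearing scaffolds, and cross-matches the planted CRISPR
# spacers against the whole assembly.

suppressPackageStartupMessages(library(virosieve))
cm <- readRDS("results/community.rds")
cur <- readRDS("results/curation.rds")

# Search the curated assembly (redundant copies removed in step 2).
curated <- cm$genomes[cur$dedup$retained$id]
attp <- find_attp(curated, cm$trna_db, min_len = 25)
cat(sprintf("attP search: %d exact matches of %s bp\n", nrow(attp),
            if (nrow(attp)) paste(range(attp$match_len), collapse = "-")
            else "0"))
write.table(attp, "results/attp_matches.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

hosts <- assign_hosts(attp, cur$genes, cm$trna_db, rank_cap = "class")
cat(sprintf("host assignments (integrase-gated): %d scaffolds\n",
            nrow(hosts$assignments)))
print(hosts$assignments[, c("scaffold_id", "host_taxon", "trna_id",
                            "match_len")])
write.table(hosts$assignments, "results/host_assignments.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

spacers <- match_spacers(cm$arrays, curated, both_strands = TRUE)
cat(sprintf("CRISPR spacer links: %d exact matches outside their own array\n",
            nrow(spacers)))
print(spacers[, c("array_id", "spacer_index", "target_id", "match_len")])
write.table(spacers, "results/spacer_matches.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

# Cross-check against the generator's planted truth.
ok_attp <- all(cm$attp_truth$scaffold_id %in% hosts$assignments$scaffold_id)
ok_sp <- all(mapply(function(a, i, t) {
  any(spacers$array_id == a & spacers$spacer_index == i &
        spacers$target_id == t)
}, cm$spacer_truth$array_id, cm$spacer_truth$spacer_index,
   cm$spacer_truth$target_scaffold))
cat(sprintf("planted truth recovered: attP %s, spacers %s\n",
            ok_attp, ok_sp))
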