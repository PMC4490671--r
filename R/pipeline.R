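#' Whole-genome comparison hit rows for a synthetic community
#'
#' Emits an all-vs-all cross-hit table (tblastx-style bitscores) consistent
#' with the community's ground truth: every genome gets self-comparison
#' rows with summed bitscore proportional to its length, and each planted
#' redundant pair gets cross rows proportional to the shared (child)
#' length, split over both query directions. Unrelated genomes share no
#' sequence, so they get no rows. This is fixture machinery standing in
#' for an external all-vs-all translated search; the score model is
#' deliberately minimal (score ~ alignable length).
#'
#' @param community A `synthetic_community`.
#' @param score_per_bp Bitscore contributed per alignable bp (default 0.2).
#' @return A 12-column BLAST tabular data frame.
#' @export
emit_cross_hits <- function(community, score_per_bp = 0.2) {
  tr <- community$truth
  rows <- lapply(seq_len(nrow(tr)), function(i) {
    id <- tr$scaffold_id[i]
    len <- tr$length[i]
    blast_row(id, id, 100, len, 1L, len, 1L, len, evalue = 0,
              bitscore = score_per_bp * len)
  })
  red <- tr[!is.na(tr$redundant_of), , drop = FALSE]
  for (k in seq_len(nrow(red))) {
    child <- red$scaffold_id[k]
    parent <- red$redundant_of[k]
    clen <- red$length[k]
    half <- score_per_bp * clen / 2
    rows[[length(rows) + 1L]] <-
      blast_row(child, parent, 100, clen, 1L, clen, 1L, clen,
                evalue = 0, bitscore = half)
    rows[[length(rows) + 1L]] <-
      blast_row(parent, child, 100, clen, 1L, clen, 1L, clen,
                evalue = 0, bitscore = half)
  }
  do.call(rbind, rows)
}

#' Run the full curation pipeline on a synthetic community
#'
#' End-to-end exercise of every stage against planted ground truth:
#'
#' 1. generate the community and its planted features;
#' 2. redundancy sweep over the pooled contigs using the community's
#'    self-hit table ([emit_self_hits()]);
#' 3. per-scaffold paired-read simulation at the community's nominal
#'    coverage (`n = coverage * length / (2 * read_length)` pairs) and
#'    circularity calls from the resulting alignments;
#' 4. length/coverage gating of the retained scaffolds;
#' 5. hit-table emission, profile assembly and triage of the candidates;
#' 6. Dice/neighbor-joining comparison of the confirmed circular genomes
#'    (cross hits from [emit_cross_hits()]), with single-linkage groups;
#' 7. attP/tRNA host assignment and CRISPR spacer matching.
#'
#' @param spec A [community_spec()].
#' @param read_seed_salt Salt for the per-scaffold read streams.
#' @return A list with the community, every intermediate table, and
#'   `metrics`: named numeric vector of recovery statistics (percentages
#'   of planted truth recovered at each stage).
#' @export
run_virome_pipeline <- function(spec, read_seed_salt = 30L) {
  cm <- generate_community(spec)
  tr <- cm$truth

  # Redundancy sweep over the pooled contig set.
  pooled <- data.frame(id = tr$scaffold_id, length = tr$length,
                       coverage = tr$coverage, stringsAsFactors = FALSE)
  dedup <- remove_redundancy(pooled, emit_self_hits(cm))
  retained <- dedup$retained

  # Circularity from simulated read mappings, per retained scaffold.
  calls <- vector("list", nrow(retained))
  for (i in seq_len(nrow(retained))) {
    id <- retained$id[i]
    L <- retained$length[i]
    ti <- match(id, tr$scaffold_id)
    n_pairs <- max(1L, as.integer(round(spec$coverage * L /
                                          (2 * spec$read_length))))
    sim <- simulate_paired_reads(cm$genomes[[id]], tr$is_circular[ti],
                                 n_pairs, spec, id,
                                 seed = child_seed(spec$seed, ti,
                                                   read_seed_salt))
    calls[[i]] <- call_circularity(id, L, pair_alignments(sim$sam))
  }
  calls <- do.call(rbind, calls)

  gated <- length_gate(retained, circular = calls$scaffold_id[calls$is_circular])
  candidates <- gated[gated$status == "candidate", , drop = FALSE]

  # Triage of the candidates.
  ht <- emit_hit_tables(tr, seed = child_seed(spec$seed, 0L, 40L))
  prof <- build_profiles(ht$genes, ht$hits,
                         stats::setNames(tr$coverage, tr$scaffold_id))
  prof_cand <- prof[prof$scaffold_id %in% candidates$id, , drop = FALSE]
  triage <- triage_batch(prof_cand)

  # Whole-genome comparison over confirmed circular genomes.
  viral_ids <- triage$results$scaffold_id[triage$results$label == "viral"]
  circ_ids <- intersect(viral_ids,
                        calls$scaffold_id[calls$is_circular])
  distance <- NULL
  if (length(circ_ids) >= 3) {
    ch <- emit_cross_hits(cm)
    ch <- ch[ch$qseqid %in% circ_ids & ch$sseqid %in% circ_ids, ,
             drop = FALSE]
    S <- summed_scores(filter_hits(ch), sort(circ_ids))
    dm <- dice_matrix(S)
    distance <- list(S = S, dice = dm, tree = nj_tree(dm$dissim),
                     groups = cluster_groups(dm$D, threshold = 0.05))
  }

  # Host links over the curated (post-dedup) assembly; searching the
  # redundant copies too would re-find every planted motif inside them.
  curated <- cm$genomes[retained$id]
  attp <- find_attp(curated, cm$trna_db)
  hosts <- assign_hosts(attp, ht$genes, cm$trna_db)
  spacers <- match_spacers(cm$arrays, curated)

  # Recovery metrics against planted truth.
  ti <- match(calls$scaffold_id, tr$scaffold_id)
  circ_ok <- calls$is_circular == tr$is_circular[ti]
  expected_label <- c(viral = "viral", cellular = "cellular_review",
                      plasmid = "plasmid_review",
                      mitochondrial = "mito_review")
  tri_truth <- expected_label[tr$class_label[match(
    triage$results$scaffold_id, tr$scaffold_id)]]
  red_ids <- tr$scaffold_id[!is.na(tr$redundant_of)]
  attp_hit <- vapply(seq_len(nrow(cm$attp_truth)), function(k) {
    a <- cm$attp_truth[k, ]
    any(attp$scaffold_id == a$scaffold_id & attp$trna_id == a$trna_id &
          attp$scaf_start <= a$scaf_start &
          attp$scaf_end >= a$scaf_start + a$match_len - 1)
  }, logical(1))
  spacer_hit <- vapply(seq_len(nrow(cm$spacer_truth)), function(k) {
    s <- cm$spacer_truth[k, ]
    any(spacers$array_id == s$array_id &
          spacers$spacer_index == s$spacer_index &
          spacers$target_id == s$target_scaffold)
  }, logical(1))

  metrics <- c(
    n_scaffolds = nrow(tr),
    circular_recovery_pct = 100 * mean(circ_ok),
    redundant_removed_pct =
      if (length(red_ids) > 0)
        100 * mean(red_ids %in% dedup$removal_log$removed) else NA_real_,
    triage_recovery_pct = 100 * mean(triage$results$label ==
                                       unname(tri_truth)),
    attp_recovery_pct =
      if (length(attp_hit) > 0) 100 * mean(attp_hit) else NA_real_,
    spacer_recovery_pct =
      if (length(spacer_hit) > 0) 100 * mean(spacer_hit) else NA_real_,
    false_attp_links = sum(!attp$scaffold_id %in% cm$attp_truth$scaffold_id),
    false_spacer_links = nrow(spacers) - sum(spacer_hit)
  )

  list(community = cm, dedup = dedup, circularity = calls, gated = gated,
       profiles = prof, triage = triage, distance = distance,
       attp = attp, hosts = hosts, spacers = spacers, metrics = metrics)
}
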