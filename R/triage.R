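#' Classify one scaffold from its gene-hit profile
#'
#' Applies the virus-confirmation decision rules to a per-scaffold hit
#' profile. Because most predicted genes in a virome have no database
#' match, all ratio rules are normalized to the number of Pfam-A hits
#' (`n_pfam`), not to the total gene count. Rules fire in a fixed
#' precedence, contamination flags before the automatic viral call:
#'
#' 1. coverage below `min_cov` -> `low_coverage_reject` (chimera risk);
#' 2. any Silva SSU/LSU hit -> `cellular_review`;
#' 3. mitochondrion hits > `mito_frac` of Pfam hits -> `mito_review`;
#' 4. ACLAME plasmid hits > `plasmid_frac` of Pfam hits -> `plasmid_review`;
#' 5. any POGs-7 (phage-exclusive families) hit -> `viral`;
#' 6. RefSeq-virus hits >= `virus_refseq_frac` AND POGs-10 hits >=
#'    `virus_pogs_frac` of Pfam hits -> `viral`;
#' 7. otherwise `ambiguous`.
#'
#' With `n_pfam = 0` the ratio rules (3, 4, 6) evaluate false rather than
#' dividing by zero; the rationale notes it. Review labels are not final
#' verdicts: they are queues for manual inspection downstream.
#'
#' @param p One-row profile (data frame or list) with fields `scaffold_id`,
#'   `n_genes`, `n_pfam`, `n_refseq_virus`, `n_pogs10`, `n_pogs7`,
#'   `n_aclame`, `n_mito`, `n_silva`, `coverage`.
#' @param min_cov Minimum fold-coverage (default 10).
#' @param virus_refseq_frac RefSeq-virus fraction of Pfam hits required for
#'   the automatic viral call (default 0.5, inclusive).
#' @param virus_pogs_frac POGs-10 fraction of Pfam hits required (default
#'   0.1, inclusive).
#' @param plasmid_frac ACLAME fraction above which a scaffold is queued for
#'   plasmid review (default 0.5, exclusive).
#' @param mito_frac Mitochondrion fraction above which a scaffold is queued
#'   for mitochondrial review (default 0.5, exclusive).
#' @return One-row data frame: `scaffold_id`, `label`, `flags`
#'   (comma-separated rule names that fired), `rationale`.
#' @export
triage_scaffold <- function(p, min_cov = 10, virus_refseq_frac = 0.5,
                            virus_pogs_frac = 0.1, plasmid_frac = 0.5,
                            mito_frac = 0.5) {
  p <- as.list(p)
  for (f in c("n_pfam", "n_refseq_virus", "n_pogs10", "n_pogs7", "n_aclame",
              "n_mito", "n_silva", "coverage")) {
    if (is.null(p[[f]]) || is.na(p[[f]]) || p[[f]] < 0) {
      stop("invalid profile field: ", f)
    }
  }
  no_pfam <- p$n_pfam == 0
  ratio <- function(x) if (no_pfam) 0 else x / p$n_pfam
  fired <- character(0)
  note <- character(0)
  if (no_pfam) note <- "no Pfam hits: ratio rules evaluate false"

  if (p$coverage < min_cov) {
    label <- "low_coverage_reject"
    fired <- "low_coverage"
    note <- c(note, sprintf("coverage %.1f < %g", p$coverage, min_cov))
  } else if (p$n_silva >= 1) {
    label <- "cellular_review"
    fired <- "silva"
    note <- c(note, sprintf("%d Silva SSU/LSU hit(s)", p$n_silva))
  } else if (!no_pfam && ratio(p$n_mito) > mito_frac) {
    label <- "mito_review"
    fired <- "mito"
    note <- c(note, sprintf("mito hits %.0f%% of Pfam hits",
                            100 * ratio(p$n_mito)))
  } else if (!no_pfam && ratio(p$n_aclame) > plasmid_frac) {
    label <- "plasmid_review"
    fired <- "aclame"
    note <- c(note, sprintf("plasmid hits %.0f%% of Pfam hits",
                            100 * ratio(p$n_aclame)))
  } else if (p$n_pogs7 >= 1) {
    label <- "viral"
    fired <- "pogs7"
    note <- c(note, "hit to phage-exclusive POGs-7 families")
  } else if (!no_pfam && ratio(p$n_refseq_virus) >= virus_refseq_frac &&
             ratio(p$n_pogs10) >= virus_pogs_frac) {
    label <- "viral"
    fired <- c("refseq_virus", "pogs10")
    note <- c(note, sprintf("RefSeq virus %.0f%%, POGs-10 %.0f%% of Pfam hits",
                            100 * ratio(p$n_refseq_virus),
                            100 * ratio(p$n_pogs10)))
  } else {
    label <- "ambiguous"
    note <- c(note, "no rule fired")
  }
  data.frame(scaffold_id = p$scaffold_id %||% NA_character_, label = label,
             flags = paste(fired, collapse = ","),
             rationale = paste(note, collapse = "; "),
             stringsAsFactors = FALSE)
}

#' Triage a batch of scaffold profiles and summarize the virome
#'
#' Applies [triage_scaffold()] to every row and assembles the virome-level
#' summary: per-label scaffold counts, each database's gene-hit total as a
#' percentage of all gene predictions (one decimal place, the convention of
#' assembly summary tables), and the confirmed-viral fraction of the
#' candidate scaffolds.
#'
#' @param profiles Profile data frame, one row per scaffold (see
#'   [build_profiles()]); duplicate scaffold ids are an error.
#' @param ... Thresholds forwarded to [triage_scaffold()].
#' @return List with `results` (one row per scaffold) and `summary` (list
#'   of `label_counts`, `db_gene_pct`, `viral_fraction_pct`, `n_candidates`).
#' @export
triage_batch <- function(profiles, ...) {
  if (nrow(profiles) == 0) stop("profile table is empty")
  if (anyDuplicated(profiles$scaffold_id)) {
    stop("duplicate scaffold_id in profile table")
  }
  results <- do.call(rbind, lapply(seq_len(nrow(profiles)), function(i) {
    triage_scaffold(profiles[i, , drop = FALSE], ...)
  }))
  labels <- c("viral", "cellular_review", "plasmid_review", "mito_review",
              "low_coverage_reject", "ambiguous")
  label_counts <- table(factor(results$label, levels = labels))
  total_genes <- sum(profiles$n_genes)
  db_cols <- c(pfam = "n_pfam", refseq_virus = "n_refseq_virus",
               pogs10 = "n_pogs10", pogs7 = "n_pogs7")
  db_gene_pct <- data.frame(
    database = names(db_cols),
    gene_hits = vapply(db_cols, function(cl) sum(profiles[[cl]]), 0),
    pct_of_genes = vapply(db_cols, function(cl) {
      gene_hit_pct(sum(profiles[[cl]]), total_genes)
    }, 0),
    row.names = NULL, stringsAsFactors = FALSE
  )
  n_viral <- sum(results$label == "viral")
  list(
    results = results,
    summary = list(
      label_counts = label_counts,
      db_gene_pct = db_gene_pct,
      total_genes = total_genes,
      n_candidates = nrow(profiles),
      n_viral = n_viral,
      viral_fraction_pct = gene_hit_pct(n_viral, nrow(profiles))
    )
  )
}

#' Percentage at table precision (one decimal place)
#'
#' @param num,den Numerator and denominator counts (vectorized).
#' @return `100 * num / den` rounded to one decimal place; `NA` where the
#'   denominator is zero.
#' @export
gene_hit_pct <- function(num, den) {
  ifelse(den == 0, NA_real_, round(100 * num / den, 1))
}
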