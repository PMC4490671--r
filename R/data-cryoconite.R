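#' Example dataset: cryoconite-hole virome curation counts
#'
#' Published summary counts from the curation of three dsDNA viromes
#' sequenced from glacier-surface cryoconite holes (one from the Greenland
#' Ice Sheet margin, CY1, and two from Svalbard glaciers, ML and AB):
#' Illumina read totals before and after quality control, per-virome gene
#' prediction and database gene-hit counts over the pooled multi-k-mer
#' assemblies, scaffold candidate/confirmation counts, read-mapping counts
#' onto candidate and confirmed-viral scaffolds, and the two
#' exceptional-coverage scaffolds reported individually. These counts are
#' the *inputs* of the percentage arithmetic in [read_fraction_report()],
#' [triage_batch()]-style summaries and [gene_hit_pct()]; all percentages
#' are recomputed, never stored.
#'
#' @return A list of data frames:
#' \describe{
#'   \item{reads}{per-virome read totals: `virome`, `read_pairs`, `reads`,
#'     `passed_qc`.}
#'   \item{genes}{per-virome gene predictions and database gene hits:
#'     `virome`, `gene_predictions`, `pfam`, `refseq_virus`, `pogs10`,
#'     `pogs7`, `silva`.}
#'   \item{scaffolds}{per-virome candidate scaffolds >= 15 kb, confirmed
#'     virus scaffolds among them, and mapped-read counts: `virome`,
#'     `candidates_15kb`, `virus_confirmed`, `reads_mapped_candidates`,
#'     `reads_mapped_viral`, `reads_mapped_other`.}
#'   \item{circular}{per-virome circular scaffolds >= 10 kb and their
#'     resolution: `virome`, `circular_10kb`, `phage_confirmed`,
#'     `mitochondrial`, `other_cellular`.}
#'   \item{highlights}{the two exceptional-coverage scaffolds: `scaffold_id`,
#'     `virome`, `reads`, `coverage`, `length`, `circular`.}
#' }
#' @export
cryoconite_counts <- function() {
  list(
    reads = data.frame(
      virome = c("CY1", "ML", "AB"),
      read_pairs = c(41205412, 47705988, 34093025),
      reads = c(82410824, 95411976, 68186050),
      passed_qc = c(71444796, 78956224, 58304468),
      stringsAsFactors = FALSE
    ),
    genes = data.frame(
      virome = c("CY1", "ML", "AB"),
      gene_predictions = c(59739, 114914, 55209),
      pfam = c(29228, 72103, 31721),
      refseq_virus = c(10520, 17609, 8899),
      pogs10 = c(4402, 5632, 2909),
      pogs7 = c(135, 98, 82),
      silva = c(244, 385, 274),
      stringsAsFactors = FALSE
    ),
    scaffolds = data.frame(
      virome = c("CY1", "ML", "AB"),
      candidates_15kb = c(865, 1855, 659),
      virus_confirmed = c(262, 152, 128),
      reads_mapped_candidates = c(8363805, 20979299, 4834392),
      reads_mapped_viral = c(4019865, 1677841, 1077717),
      reads_mapped_other = c(4343940, 19301458, 3756675),
      stringsAsFactors = FALSE
    ),
    circular = data.frame(
      virome = c("CY1", "ML", "AB"),
      circular_10kb = c(53, 25, 16),
      phage_confirmed = c(35, 12, 10),
      mitochondrial = c(5, 1, 0),
      other_cellular = c(13, 12, 6),
      stringsAsFactors = FALSE
    ),
    highlights = data.frame(
      scaffold_id = c("CY1_33_46", "CY1_53_205"),
      virome = c("CY1", "CY1"),
      reads = c(819974, 113372),
      coverage = c(2500, 713),
      length = c(37632, 15474),
      circular = c(TRUE, FALSE),
      stringsAsFactors = FALSE
    )
  )
}
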