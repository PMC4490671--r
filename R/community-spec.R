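#' Specify a synthetic virome community
#'
#' A `community_spec` fixes every parameter of the synthetic virome
#' generator: how many genomes of each contamination class to draw, their
#' length range, the fraction flagged circular, the sequencing geometry used
#' by [simulate_paired_reads()] (100 bp paired-end reads with a 400 bp
#' insert, concordant range 60-650 bp), and how many ground-truth features
#' (redundant copies, attP sites, CRISPR arrays) to plant.
#'
#' Genomes carry abstract "genes": fixed-length windows of `gene_len` bp laid
#' head-to-tail from position 1. Downstream triage consumes per-gene hit
#' counts, not sequence content, so the windows are content-free except for
#' planted motifs (attP segments, CRISPR loci).
#'
#' @param n_viral,n_cellular,n_plasmidlike,n_mitolike Number of genomes per
#'   class. All must be >= 0.
#' @param length_range Genome length interval in bp (min >= 1000). The
#'   default 15-60 kb brackets the typical assembled phage scaffold range.
#' @param fraction_circular Fraction of genomes per class flagged circular
#'   (deterministic count `round(fraction * n)`, applied to the first genomes
#'   of each class).
#' @param gene_len Length in bp of the abstract gene windows (default 900,
#'   about 1.1 genes per kb, a typical phage coding density).
#' @param coverage Mean fold-coverage recorded for every scaffold
#'   (default 40x, in the range observed for confidently assembled virome
#'   scaffolds).
#' @param read_length Read length in bp (default 100).
#' @param insert_mean,insert_sd Fragment (insert) size distribution in bp
#'   (default 400 +/- 80).
#' @param concordant_range Paired-distance interval in bp considered
#'   concordant by the mapper emulation (default 60-650).
#' @param n_redundant Number of planted redundant contigs: exact substrings
#'   of a longer genome, emitted as additional contigs with
#'   `truth$redundant_of` set.
#' @param n_attp Number of viral genomes that receive a planted attP: an
#'   exact copy of a 28-60 bp segment of a tRNA database entry, plus an
#'   annotated integrase gene.
#' @param n_crispr Number of viral genomes that receive a planted CRISPR
#'   array whose penultimate spacer exactly matches another genome.
#' @param n_trna Size of the synthetic tRNA database drawn alongside the
#'   community.
#' @param seed Root integer seed; all randomness derives from it through
#'   per-scaffold child streams.
#' @return An object of class `community_spec` (a validated list).
#' @seealso [generate_community()]
#' @export
community_spec <- function(n_viral = 10, n_cellular = 0, n_plasmidlike = 0,
                           n_mitolike = 0,
                           length_range = c(15000, 60000),
                           fraction_circular = 0.5,
                           gene_len = 900,
                           coverage = 40,
                           read_length = 100,
                           insert_mean = 400, insert_sd = 80,
                           concordant_range = c(60, 650),
                           n_redundant = 0, n_attp = 0, n_crispr = 0,
                           n_trna = 20,
                           seed = 1L) {
  counts <- c(n_viral = n_viral, n_cellular = n_cellular,
              n_plasmidlike = n_plasmidlike, n_mitolike = n_mitolike)
  if (any(counts < 0)) stop("class counts must be >= 0")
  if (length(length_range) != 2 || length_range[1] < 1000 ||
      length_range[2] < length_range[1]) {
    stop("length_range must be an interval with min >= 1000 bp")
  }
  if (fraction_circular < 0 || fraction_circular > 1) {
    stop("fraction_circular must lie in [0, 1]")
  }
  if (gene_len < 100) stop("gene_len must be >= 100 bp")
  if (read_length < 20) stop("read_length must be >= 20 bp")
  if (insert_mean <= 2 * read_length) {
    stop("insert_mean must exceed twice the read length")
  }
  if (n_attp > n_viral) stop("n_attp cannot exceed n_viral")
  if (n_crispr > 0 && n_viral + n_cellular + n_plasmidlike + n_mitolike < 2) {
    stop("planting spacer links requires at least two genomes")
  }
  spec <- list(
    n_viral = as.integer(n_viral), n_cellular = as.integer(n_cellular),
    n_plasmidlike = as.integer(n_plasmidlike),
    n_mitolike = as.integer(n_mitolike),
    length_range = as.integer(length_range),
    fraction_circular = fraction_circular,
    gene_len = as.integer(gene_len),
    coverage = coverage,
    read_length = as.integer(read_length),
    insert_mean = insert_mean, insert_sd = insert_sd,
    concordant_range = as.integer(concordant_range),
    n_redundant = as.integer(n_redundant),
    n_attp = as.integer(n_attp),
    n_crispr = as.integer(n_crispr),
    n_trna = as.integer(n_trna),
    seed = as.integer(seed)
  )
  class(spec) <- "community_spec"
  spec
}

#' @export
print.community_spec <- function(x, ...) {
  cat("Synthetic virome community spec\n")
  cat(sprintf("  genomes: %d viral, %d cellular, %d plasmid-like, %d mito-like\n",
              x$n_viral, x$n_cellular, x$n_plasmidlike, x$n_mitolike))
  cat(sprintf("  lengths: %d-%d bp, %.0f%% circular, %dx coverage\n",
              x$length_range[1], x$length_range[2],
              100 * x$fraction_circular, x$coverage))
  cat(sprintf("  reads: %d bp paired, insert %.0f +/- %.0f bp\n",
              x$read_length, x$insert_mean, x$insert_sd))
  cat(sprintf("  planted: %d redundant, %d attP, %d CRISPR; seed %d\n",
              x$n_redundant, x$n_attp, x$n_crispr, x$seed))
  invisible(x)
}
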