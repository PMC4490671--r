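#' Randomly subsample reads
#'
#' Two modes: `"exact"` keeps exactly `round(fraction * n)` reads chosen
#' uniformly without replacement; `"bernoulli"` keeps each read
#' independently with probability `fraction`. In paired data the unit is
#' the pair, so mates are kept or dropped together. Deterministic per
#' seed; kept elements preserve input order.
#'
#' `subsample_indices()` is the core used by the FASTQ-level wrapper and
#' is exported for subsampling any parallel structure.
#'
#' @param n Number of reads (or pairs).
#' @param fraction Sampling fraction in (0, 1].
#' @param seed Integer seed.
#' @param mode `"exact"` or `"bernoulli"`.
#' @return Sorted integer vector of kept indices.
#' @export
subsample_indices <- function(n, fraction, seed,
                              mode = c("exact", "bernoulli")) {
  mode <- match.arg(mode)
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1) {
    stop("fraction must lie in (0, 1]")
  }
  if (n == 0) return(integer(0))
  with_seed(seed, {
    if (mode == "exact") {
      sort(sample.int(n, round(fraction * n)))
    } else {
      which(stats::runif(n) < fraction)
    }
  })
}

#' @rdname subsample_indices
#' @param reads Paired-read data frame (as from [simulate_paired_reads()]);
#'   each row is one pair.
#' @export
subsample_reads <- function(reads, fraction, seed,
                            mode = c("exact", "bernoulli")) {
  idx <- subsample_indices(nrow(reads), fraction, seed, mode)
  reads[idx, , drop = FALSE]
}

#' Genome-length-normalized taxonomic composition
#'
#' Raw hit counts per virotype over-represent long genomes (more sequence,
#' more hits), so abundances are taken proportional to
#' `hit_count / genome_length` and renormalized to sum to one.
#'
#' @param composition Data frame with `virotype`, `hit_count`,
#'   `genome_length` columns.
#' @return The input with a `normalized_abundance` column summing to 1.
#' @export
normalize_composition <- function(composition) {
  if (any(composition$genome_length <= 0)) {
    stop("genome_length must be positive for every virotype")
  }
  w <- composition$hit_count / composition$genome_length
  tot <- sum(w)
  if (tot == 0) stop("no hits: composition undefined")
  composition$normalized_abundance <- w / tot
  composition
}

#' Read-mapping fraction report for a virome
#'
#' Emits the headline percentages of a virome curation: the fraction of
#' all reads mapping to candidate scaffolds, to confirmed virus scaffolds,
#' and to the remaining (non-viral) scaffolds, plus the viral share of
#' candidate-mapped reads; optionally per-scaffold shares of the total and
#' of the viral-mapped reads for highlighted scaffolds.
#'
#' Percentages use mixed precision matching reporting practice: values of
#' at least 1% are rounded to one decimal place, values below 1% to two
#' (see [format_percent()]); `style = "integer"` is available for headline
#' figures.
#'
#' @param stats One-row (or per-virome) data frame: `virome`,
#'   `total_reads`, `reads_mapped_candidates`, `reads_mapped_viral`,
#'   `reads_mapped_other`. `viral + other` must equal `candidates`.
#' @param highlights Optional data frame of per-scaffold mapped-read
#'   counts: `scaffold_id`, `virome`, `reads`.
#' @return List with `virome` (data frame of the four percentages per
#'   virome) and `scaffolds` (per-highlight percentages, `NULL` if no
#'   highlights).
#' @export
read_fraction_report <- function(stats, highlights = NULL) {
  bad <- stats$reads_mapped_viral + stats$reads_mapped_other !=
    stats$reads_mapped_candidates
  if (any(bad)) {
    stop("inconsistent counts: viral + other must equal candidates")
  }
  if (any(stats$reads_mapped_candidates > stats$total_reads)) {
    stop("mapped counts exceed total reads")
  }
  virome <- data.frame(
    virome = stats$virome,
    pct_candidates_of_total = format_percent(
      stats$reads_mapped_candidates / stats$total_reads),
    pct_viral_of_total = format_percent(
      stats$reads_mapped_viral / stats$total_reads),
    pct_other_of_total = format_percent(
      stats$reads_mapped_other / stats$total_reads),
    pct_viral_of_candidates = format_percent(
      stats$reads_mapped_viral / stats$reads_mapped_candidates),
    stringsAsFactors = FALSE
  )
  scaffolds <- NULL
  if (!is.null(highlights) && nrow(highlights) > 0) {
    i <- match(highlights$virome, stats$virome)
    if (anyNA(i)) stop("highlight rows reference unknown viromes")
    scaffolds <- data.frame(
      scaffold_id = highlights$scaffold_id,
      virome = highlights$virome,
      pct_of_total = format_percent(highlights$reads / stats$total_reads[i]),
      pct_of_viral = format_percent(
        highlights$reads / stats$reads_mapped_viral[i]),
      pct_of_viral_integer = format_percent(
        highlights$reads / stats$reads_mapped_viral[i], style = "integer"),
      stringsAsFactors = FALSE
    )
  }
  list(virome = virome, scaffolds = scaffolds)
}

#' Format a proportion as a percentage at mixed precision
#'
#' `style = "auto"` (default) rounds percentages of at least 1% to one
#' decimal place and smaller ones to two decimal places;
#' `style = "integer"` rounds to whole percent (headline figures);
#' `style = "one"` always uses one decimal place.
#'
#' @param x Proportion(s) in \[0, 1\].
#' @param style `"auto"`, `"integer"`, or `"one"`.
#' @return Numeric percentage(s), rounded.
#' @export
format_percent <- function(x, style = c("auto", "integer", "one")) {
  style <- match.arg(style)
  pct <- 100 * x
  switch(style,
         auto = ifelse(pct >= 1, round(pct, 1), round(pct, 2)),
         integer = round(pct),
         one = round(pct, 1))
}
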