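#' Partition paired alignments into concordant and discordant pairs
#'
#' A pair is discordant when its apparent span on the linearized scaffold
#' exceeds `max_concordant` bp (the mapper's paired-distance ceiling).
#' Pairs whose mates aligned to different scaffolds cannot be given a span
#' and are excluded; their count is attached as the `n_cross_scaffold`
#' attribute and reported with a warning.
#'
#' @param pairs Paired-alignment data frame from [pair_alignments()].
#' @param max_concordant Maximum concordant span in bp (default 900).
#' @return List with `concordant` and `discordant` data frames;
#'   attribute `n_cross_scaffold` carries the excluded-pair count.
#' @export
classify_pairs <- function(pairs, max_concordant = 900) {
  cross <- !pairs$same_scaffold
  n_cross <- sum(cross)
  if (n_cross > 0) {
    warning(n_cross, " pair(s) with mates on different scaffolds excluded")
    pairs <- pairs[!cross, , drop = FALSE]
  }
  disc <- pairs$apparent_span > max_concordant
  out <- list(concordant = pairs[!disc, , drop = FALSE],
              discordant = pairs[disc, , drop = FALSE])
  attr(out, "n_cross_scaffold") <- n_cross
  out
}

#' Call scaffold circularity from end-spanning discordant pairs
#'
#' A discordant pair counts as circularly mapped when one mate's alignment
#' lies entirely within the first `end_window` bp of the scaffold and the
#' other's entirely within the last `end_window` bp — i.e. the pair maps to
#' the start and the end of the scaffold, which on a linearized circular
#' genome is where fragments wrapping the origin land. The scaffold is
#' called circular when at least `min_pairs` such pairs are found.
#'
#' For scaffolds shorter than twice the window the two windows are
#' truncated at the midpoint and the call is flagged `short`.
#'
#' @param scaffold_len Scaffold length in bp.
#' @param discordant Discordant paired-alignment data frame (the
#'   `discordant` element of [classify_pairs()]).
#' @param end_window Terminal window size in bp (default 1000).
#' @param min_pairs Minimum circularly mapped pairs for a circular call
#'   (default 3).
#' @param scaffold_id Optional id recorded in the call.
#' @return One-row data frame: `scaffold_id`, `n_circular_pairs`,
#'   `is_circular`, `method` (`"spanning-pairs"`), `short`.
#' @export
detect_circular <- function(scaffold_len, discordant, end_window = 1000,
                            min_pairs = 3, scaffold_id = NA_character_) {
  w <- min(end_window, floor(scaffold_len / 2))
  short <- scaffold_len <= 2 * end_window
  start_hi <- w
  end_lo <- scaffold_len - w + 1L
  n <- 0L
  if (nrow(discordant) > 0) {
    m1_in_start <- discordant$m1_start >= 1 & discordant$m1_end <= start_hi
    m2_in_start <- discordant$m2_start >= 1 & discordant$m2_end <= start_hi
    m1_in_end <- discordant$m1_start >= end_lo &
      discordant$m1_end <= scaffold_len
    m2_in_end <- discordant$m2_start >= end_lo &
      discordant$m2_end <= scaffold_len
    n <- sum((m1_in_start & m2_in_end) | (m2_in_start & m1_in_end))
  }
  data.frame(scaffold_id = scaffold_id, n_circular_pairs = n,
             is_circular = n >= min_pairs, method = "spanning-pairs",
             short = short, stringsAsFactors = FALSE)
}

#' Detect a terminal overlap (overlapping ends) in a scaffold sequence
#'
#' Finds the longest exact direct repeat shared by the start and the end of
#' the sequence — the signature of a completely assembled circular genome
#' whose assembler ran past the origin. Only overlaps of at least
#' `min_overlap` bp are reported.
#'
#' Candidate overlap lengths are located by matching the first
#' `min_overlap` bp of the sequence near its end, so only positions that
#' can start a qualifying suffix are verified in full.
#'
#' @param sequence Scaffold sequence (character string or `DNAString`).
#' @param min_overlap Minimum overlap length in bp (default 20).
#' @return Integer overlap length, or `NA_integer_` when none is found.
#' @export
detect_terminal_overlap <- function(sequence, min_overlap = 20) {
  sequence <- as.character(sequence)
  L <- nchar(sequence)
  if (L <= 2 * min_overlap) return(NA_integer_)
  seed <- substr(sequence, 1L, min_overlap)
  # Occurrences of the prefix seed; a full prefix/suffix repeat of length k
  # requires the seed to occur at position L - k + 1.
  m <- Biostrings::matchPattern(Biostrings::DNAString(seed),
                                Biostrings::DNAString(sequence))
  starts <- IRanges::start(m)
  ks <- L - starts + 1L
  keep <- ks >= min_overlap & ks <= floor(L / 2)
  for (k in sort(ks[keep], decreasing = TRUE)) {
    if (substr(sequence, 1L, k) == substr(sequence, L - k + 1L, L)) {
      return(as.integer(k))
    }
  }
  NA_integer_
}

#' Full circularity call combining read pairs and terminal overlaps
#'
#' Runs [classify_pairs()] + [detect_circular()] on the scaffold's paired
#' alignments and, when the sequence is supplied, [detect_terminal_overlap()];
#' a scaffold is circular when either line of evidence fires.
#'
#' @param scaffold_id Scaffold id.
#' @param scaffold_len Scaffold length in bp.
#' @param pairs Paired-alignment data frame for this scaffold.
#' @param sequence Optional scaffold sequence for terminal-overlap
#'   detection.
#' @param max_concordant,end_window,min_pairs,min_overlap Stage thresholds;
#'   see the component functions.
#' @return One-row data frame: `scaffold_id`, `n_circular_pairs`,
#'   `overlap_len`, `is_circular`, `method` (`spanning-pairs`,
#'   `terminal-overlap`, `both`, or `none`).
#' @export
call_circularity <- function(scaffold_id, scaffold_len, pairs,
                             sequence = NULL, max_concordant = 900,
                             end_window = 1000, min_pairs = 3,
                             min_overlap = 20) {
  parts <- classify_pairs(pairs, max_concordant)
  call <- detect_circular(scaffold_len, parts$discordant, end_window,
                          min_pairs, scaffold_id)
  ov <- NA_integer_
  if (!is.null(sequence)) {
    ov <- detect_terminal_overlap(sequence, min_overlap)
  }
  by_pairs <- call$is_circular
  by_overlap <- !is.na(ov)
  method <- if (by_pairs && by_overlap) "both"
    else if (by_pairs) "spanning-pairs"
    else if (by_overlap) "terminal-overlap"
    else "none"
  data.frame(scaffold_id = scaffold_id,
             n_circular_pairs = call$n_circular_pairs,
             overlap_len = ov, is_circular = by_pairs | by_overlap,
             method = method, short = call$short, stringsAsFactors = FALSE)
}
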