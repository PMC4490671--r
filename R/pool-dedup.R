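#' Pool contigs from multiple k-mer assemblies
#'
#' Concatenates the contig tables of several assemblies of the same virome
#' (one per k-mer length), keeps contigs of at least `min_len` bp, and
#' sorts by descending length (ties broken by id, ascending) — the order
#' the redundancy sweep requires.
#'
#' @param assemblies A list of contig data frames, each with at least `id`
#'   and `length` columns (optionally `sequence`, `virome`, `kmer`,
#'   `coverage`). Ids must be unique across assemblies (namespace them by
#'   k-mer).
#' @param min_len Minimum contig length retained (default 5000 bp, the
#'   export cutoff applied to each assembly).
#' @return One pooled contig data frame, sorted.
#' @export
pool_assemblies <- function(assemblies, min_len = 5000) {
  if (length(assemblies) == 0) return(empty_contig_table())
  pooled <- do.call(rbind, lapply(assemblies, as.data.frame))
  if (nrow(pooled) == 0) return(pooled)
  if (anyDuplicated(pooled$id)) {
    stop("duplicate contig ids across assemblies: ",
         paste(utils::head(unique(pooled$id[duplicated(pooled$id)]), 3),
               collapse = ", "),
         " (namespace ids by k-mer)")
  }
  if (!is.null(pooled$sequence)) {
    if (!all(is.na(pooled$sequence) |
             nchar(pooled$sequence) == pooled$length)) {
      stop("contig length column disagrees with sequence length")
    }
  }
  pooled <- pooled[pooled$length >= min_len, , drop = FALSE]
  pooled <- pooled[order(-pooled$length, pooled$id), , drop = FALSE]
  rownames(pooled) <- NULL
  pooled
}

empty_contig_table <- function() {
  data.frame(id = character(), length = integer(), stringsAsFactors = FALSE)
}

#' Remove redundant smaller contigs from a pooled assembly
#'
#' Implements the pooled-assembly redundancy sweep: contigs are visited in
#' descending length order and a contig is removed iff it has a qualifying
#' self-search hit (alignment length > `min_aln` bp, identity >=
#' `min_ident` %, E-value <= `max_e`, thresholds applied per hit row, not
#' summed across HSPs) to a strictly longer contig that is *still retained*
#' at the moment it is considered. Resolving matches against the currently
#' retained set (rather than all longer contigs) prevents cascade removal
#' through an already-removed intermediary; set `against = "all-larger"`
#' for the alternative reading. Equal-length pairs with mutual qualifying
#' hits lose their lexicographically later member.
#'
#' @param pooled Pooled contig data frame (from [pool_assemblies()]); any
#'   order is accepted, the sweep re-sorts internally.
#' @param hits Self-comparison hit table (BLAST tabular columns `qseqid`,
#'   `sseqid`, `pident`, `length`, `evalue`); self-vs-self rows are
#'   ignored. Hits referencing unknown contig ids are an error.
#' @param min_aln Qualifying hits must be strictly longer than this
#'   (default 1000 bp).
#' @param min_ident Minimum percent identity (default 97).
#' @param max_e Maximum E-value (default 1e-5).
#' @param against `"retained"` (default) or `"all-larger"`.
#' @return A list with `retained` (contig data frame, descending length)
#'   and `removal_log` (data frame: `removed`, `kept`, `identity`,
#'   `aln_length`).
#' @export
remove_redundancy <- function(pooled, hits, min_aln = 1000, min_ident = 97,
                              max_e = 1e-5,
                              against = c("retained", "all-larger")) {
  against <- match.arg(against)
  pooled <- pooled[order(-pooled$length, pooled$id), , drop = FALSE]
  rownames(pooled) <- NULL
  log_empty <- data.frame(removed = character(), kept = character(),
                          identity = numeric(), aln_length = integer(),
                          stringsAsFactors = FALSE)
  if (nrow(pooled) == 0) {
    return(list(retained = pooled, removal_log = log_empty))
  }
  if (nrow(hits) > 0) {
    unknown <- setdiff(unique(c(hits$qseqid, hits$sseqid)), pooled$id)
    if (length(unknown) > 0) {
      stop("hit table references unknown contig ids: ",
           paste(utils::head(unknown, 3), collapse = ", "))
    }
    hits <- hits[hits$qseqid != hits$sseqid &
                   hits$length > min_aln &
                   hits$pident >= min_ident &
                   hits$evalue <= max_e, , drop = FALSE]
  } else {
    hits <- hits[0, , drop = FALSE]
  }

  len <- stats::setNames(pooled$length, pooled$id)
  # Undirected qualifying partner lists per contig.
  partner <- list()
  if (nrow(hits) > 0) {
    both <- data.frame(a = c(hits$qseqid, hits$sseqid),
                       b = c(hits$sseqid, hits$qseqid),
                       identity = c(hits$pident, hits$pident),
                       aln_length = c(hits$length, hits$length),
                       stringsAsFactors = FALSE)
    partner <- split(both[c("b", "identity", "aln_length")], both$a)
  }

  retained <- character(0)
  log_rows <- list()
  for (i in seq_len(nrow(pooled))) {
    id <- pooled$id[i]
    p <- partner[[id]]
    removed <- FALSE
    if (!is.null(p) && nrow(p) > 0) {
      # Partner counts as "larger" if strictly longer, or equal length with
      # lexicographically earlier id (deterministic tie-break).
      larger <- len[p$b] > len[id] | (len[p$b] == len[id] & p$b < id)
      pool_ok <- if (against == "retained") p$b %in% retained else TRUE
      q <- p[larger & pool_ok, , drop = FALSE]
      if (nrow(q) > 0) {
        q <- q[order(-len[q$b], q$b), , drop = FALSE]
        log_rows[[length(log_rows) + 1L]] <- data.frame(
          removed = id, kept = q$b[1], identity = q$identity[1],
          aln_length = q$aln_length[1], stringsAsFactors = FALSE)
        removed <- TRUE
      }
    }
    if (!removed) retained <- c(retained, id)
  }
  list(
    retained = pooled[pooled$id %in% retained, , drop = FALSE],
    removal_log = if (length(log_rows) == 0) log_empty else
      do.call(rbind, log_rows)
  )
}

#' Apply length and coverage gates to curated contigs
#'
#' Keeps circular contigs of at least `circular_min` bp and linear contigs
#' of at least `linear_min` bp as candidates for viral-origin testing;
#' length-passing contigs below `min_coverage` fold-coverage are rejected
#' (chimera risk) with the reason recorded.
#'
#' @param contigs Contig data frame with `id`, `length` and `coverage`
#'   columns.
#' @param circular Logical vector (parallel to `contigs`) or character
#'   vector of circular contig ids.
#' @param linear_min,circular_min Length gates in bp (defaults 15000 and
#'   10000).
#' @param min_coverage Minimum mean fold-coverage (default 10).
#' @return The contig data frame with `is_circular` and `status` columns
#'   (`candidate`, `too_short`, or `low_coverage`).
#' @export
length_gate <- function(contigs, circular, linear_min = 15000,
                        circular_min = 10000, min_coverage = 10) {
  if (nrow(contigs) == 0) {
    contigs$is_circular <- logical(0)
    contigs$status <- character(0)
    return(contigs)
  }
  if (is.character(circular)) circular <- contigs$id %in% circular
  stopifnot(length(circular) == nrow(contigs))
  min_len <- ifelse(circular, circular_min, linear_min)
  status <- ifelse(contigs$length < min_len, "too_short",
                   ifelse(contigs$coverage < min_coverage, "low_coverage",
                          "candidate"))
  contigs$is_circular <- circular
  contigs$status <- status
  contigs
}
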