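#' Simulate paired-end reads from a (possibly circular) genome
#'
#' Draws sequencing fragments uniformly along a genome and reports both
#' mates at their linearized coordinates, emulating what a short-read
#' mapper would produce when the reads are mapped back to the assembled
#' scaffold. For a circular genome a fragment may wrap the origin: its two
#' mates then map near opposite ends of the linearized scaffold, producing
#' the end-spanning "discordant" pairs that the circularity detector keys
#' on. Fragment starts that would make a single read itself cross the
#' origin are redrawn, since such a read could not align contiguously.
#'
#' Fragment lengths are Normal(`insert_mean`, `insert_sd`), truncated to
#' `[2 * read_length, insert_mean + 4 * insert_sd]`.
#'
#' @param genome Genome sequence (character string or `DNAString`).
#' @param is_circular Whether the underlying genome is circular.
#' @param n_pairs Number of read pairs to draw. `n_pairs <= 0` yields empty
#'   outputs without error.
#' @param spec A [community_spec()] supplying read length and insert size.
#' @param scaffold_id Scaffold name used in read ids and SAM records.
#' @param seed Integer seed for this scaffold's read stream.
#' @return A list with `reads` (data frame: `id`, `seq1`, `seq2`, constant
#'   Phred+33 qualities) and `sam` (data frame of SAM records, two rows per
#'   pair, with FLAG/POS/PNEXT/TLEN at linearized coordinates).
#' @export
simulate_paired_reads <- function(genome, is_circular, n_pairs, spec,
                                  scaffold_id = "scaffold", seed = 1L) {
  genome <- as.character(genome)
  L <- nchar(genome)
  rl <- spec$read_length
  if (L <= spec$insert_mean + 4 * spec$insert_sd) {
    stop("genome shorter than insert_mean + 4*insert_sd")
  }
  if (n_pairs <= 0) {
    return(list(reads = empty_reads_table(), sam = empty_sam_table(),
                wrapped = logical(0)))
  }

  sim <- with_seed(seed, {
    frag <- round(stats::rnorm(n_pairs, spec$insert_mean, spec$insert_sd))
    frag <- pmin(pmax(frag, 2 * rl), spec$insert_mean + 4 * spec$insert_sd)
    frag <- pmin(frag, L)
    if (is_circular) {
      start <- 1L + floor(stats::runif(n_pairs) * L)
      # Redraw starts whose individual mates would cross the origin.
      repeat {
        m1_cross <- ((start - 1L) %% L) + rl > L
        m2_off <- (start + frag - rl - 1L) %% L
        m2_cross <- m2_off + rl > L
        bad <- m1_cross | m2_cross
        if (!any(bad)) break
        start[bad] <- 1L + floor(stats::runif(sum(bad)) * L)
      }
    } else {
      start <- 1L + floor(stats::runif(n_pairs) * (L - frag + 1))
    }
    list(frag = as.integer(frag), start = as.integer(start))
  })
  frag <- sim$frag
  start <- sim$start

  pos1 <- ((start - 1L) %% L) + 1L
  pos2 <- ((start + frag - rl - 1L) %% L) + 1L
  wrapped <- is_circular & (start + frag - 1L > L)

  seq1 <- substring(genome, pos1, pos1 + rl - 1L)
  seq2 <- revcomp(substring(genome, pos2, pos2 + rl - 1L))

  # Apparent span on the linearized scaffold (outermost distance).
  end1 <- pos1 + rl - 1L
  end2 <- pos2 + rl - 1L
  span <- pmax(end1, end2) - pmin(pos1, pos2) + 1L

  qname <- sprintf("%s_p%06d", scaffold_id, seq_len(n_pairs))
  qual <- strrep("I", rl)
  proper <- span <= 900L  # mapper emulation: paired distance range 0-900 bp
  # FLAG bits: 1 paired, 2 proper, 16 reverse, 32 mate reverse,
  # 64 first in pair, 128 second in pair.
  flag1 <- 1L + 32L + 64L + ifelse(proper, 2L, 0L)
  flag2 <- 1L + 16L + 128L + ifelse(proper, 2L, 0L)
  tlen1 <- ifelse(pos1 <= pos2, span, -span)

  sam <- data.frame(
    qname = rep(qname, each = 2L),
    flag = as.integer(rbind(flag1, flag2)),
    rname = scaffold_id,
    pos = as.integer(rbind(pos1, pos2)),
    mapq = 42L,
    cigar = paste0(rl, "M"),
    rnext = "=",
    pnext = as.integer(rbind(pos2, pos1)),
    tlen = as.integer(rbind(tlen1, -tlen1)),
    seq = as.character(rbind(seq1, seq2)),
    qual = qual,
    stringsAsFactors = FALSE
  )
  reads <- data.frame(id = qname, seq1 = seq1, qual1 = qual,
                      seq2 = seq2, qual2 = qual, stringsAsFactors = FALSE)
  list(reads = reads, sam = sam, wrapped = wrapped)
}

empty_reads_table <- function() {
  data.frame(id = character(), seq1 = character(), qual1 = character(),
             seq2 = character(), qual2 = character(), stringsAsFactors = FALSE)
}

empty_sam_table <- function() {
  data.frame(qname = character(), flag = integer(), rname = character(),
             pos = integer(), mapq = integer(), cigar = character(),
             rnext = character(), pnext = integer(), tlen = integer(),
             seq = character(), qual = character(), stringsAsFactors = FALSE)
}

#' Collapse SAM records into paired alignments
#'
#' Joins the two mate records of each read pair into one row carrying both
#' alignment intervals and the apparent span (outermost distance on the
#' linearized scaffold), the quantity the concordance filter and the
#' circularity detector operate on. Pairs whose mates aligned to different
#' scaffolds are retained but flagged, so callers can exclude and count
#' them.
#'
#' @param sam SAM records as a data frame (from [simulate_paired_reads()] or
#'   [read_sam()]); alignment length is taken from the matched bases of the
#'   CIGAR string.
#' @return Data frame with one row per pair: `pair_id`, `scaffold_id`,
#'   `m1_start`, `m1_end`, `m2_start`, `m2_end`, `apparent_span`,
#'   `same_scaffold`.
#' @export
pair_alignments <- function(sam) {
  if (nrow(sam) == 0) {
    return(data.frame(pair_id = character(), scaffold_id = character(),
                      m1_start = integer(), m1_end = integer(),
                      m2_start = integer(), m2_end = integer(),
                      apparent_span = integer(), same_scaffold = logical(),
                      stringsAsFactors = FALSE))
  }
  aln_len <- cigar_ref_span(sam$cigar)
  first <- bitwAnd(sam$flag, 64L) > 0L
  f <- sam[first, , drop = FALSE]
  s <- sam[!first, , drop = FALSE]
  flen <- aln_len[first]
  slen <- aln_len[!first]
  j <- match(f$qname, s$qname)
  if (anyNA(j)) stop("unpaired SAM records: ",
                     paste(utils::head(f$qname[is.na(j)], 3), collapse = ", "))
  s <- s[j, , drop = FALSE]
  slen <- slen[j]
  m1_end <- f$pos + flen - 1L
  m2_end <- s$pos + slen - 1L
  rn2 <- ifelse(s$rname == "=", f$rname, s$rname)
  same <- f$rname == rn2
  span <- pmax(m1_end, m2_end) - pmin(f$pos, s$pos) + 1L
  data.frame(pair_id = f$qname, scaffold_id = f$rname,
             m1_start = f$pos, m1_end = m1_end,
             m2_start = s$pos, m2_end = m2_end,
             apparent_span = as.integer(ifelse(same, span, NA_integer_)),
             same_scaffold = same, stringsAsFactors = FALSE)
}

# Reference-consuming span of CIGAR strings (M/D/N/=/X operations).
cigar_ref_span <- function(cigar) {
  vapply(cigar, function(cg) {
    if (cg == "*") return(0L)
    parts <- regmatches(cg, gregexpr("\\d+[MIDNSHP=X]", cg))[[1]]
    op <- substring(parts, nchar(parts))
    n <- as.integer(substring(parts, 1L, nchar(parts) - 1L))
    sum(n[op %in% c("M", "D", "N", "=", "X")])
  }, integer(1), USE.NAMES = FALSE)
}

#' Write SAM records to a headerful SAM file
#'
#' @param sam SAM records data frame.
#' @param seqlens Named integer vector of scaffold lengths (one `@SQ` line
#'   each).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(sam, seqlens, path) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(seqlens), as.integer(seqlens)))
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t%d\t%s\t%s",
                  sam$qname, sam$flag, sam$rname, sam$pos, sam$mapq,
                  sam$cigar, sam$rnext, sam$pnext, sam$tlen, sam$seq,
                  sam$qual)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read alignment records from a SAM file
#'
#' Parses the eleven mandatory columns of a SAM file (header lines are
#' skipped) into the data frame layout used throughout the package.
#'
#' @param path SAM file path.
#' @return SAM records data frame.
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (length(lines) == 0) return(empty_sam_table())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  get <- function(i) vapply(parts, `[[`, "", i)
  data.frame(qname = get(1), flag = as.integer(get(2)), rname = get(3),
             pos = as.integer(get(4)), mapq = as.integer(get(5)),
             cigar = get(6), rnext = get(7), pnext = as.integer(get(8)),
             tlen = as.integer(get(9)), seq = get(10), qual = get(11),
             stringsAsFactors = FALSE)
}

#' Write paired reads to FASTQ files (Phred+33)
#'
#' @param reads Reads data frame from [simulate_paired_reads()].
#' @param path1,path2 Output paths for mate 1 and mate 2.
#' @return `c(path1, path2)`, invisibly.
#' @export
write_fastq_pair <- function(reads, path1, path2) {
  rec <- function(id, seq, qual, mate) {
    as.vector(rbind(paste0("@", id, "/", mate), seq, "+", qual))
  }
  writeLines(rec(reads$id, reads$seq1, reads$qual1, 1L), path1)
  writeLines(rec(reads$id, reads$seq2, reads$qual2, 2L), path2)
  invisible(c(path1, path2))
}
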