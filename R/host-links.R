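#' Find exact attP/tRNA matches between scaffolds and a tRNA database
#'
#' Integrating phages carry an attachment site (attP) that is an exact copy
#' of part of a host tRNA gene (attB), so a 100%-identity match between a
#' scaffold and a tRNA database entry is evidence of the phage's host.
#' This reports all maximal exact shared substrings of length at least
#' `min_len` between any scaffold (either strand) and any tRNA sequence:
#' no mismatches, no gaps.
#'
#' Matching is seed-and-extend: every `min_len`-mer of each tRNA is located
#' on the scaffolds with an indexed exact search, then extended maximally
#' in both directions; duplicate seeds of one maximal match collapse to a
#' single row.
#'
#' @param scaffolds Named character vector or `DNAStringSet` of scaffold
#'   sequences.
#' @param trna_db Data frame with `id` and `sequence` columns (taxonomy
#'   columns are carried along by [assign_hosts()]), or a `DNAStringSet`
#'   whose names follow `id|phylum|class`.
#' @param min_len Minimum match length in bp (default 25; exact matches
#'   much below ~20 bp arise by chance in large databases).
#' @return Data frame: `scaffold_id`, `trna_id`, `match_len`, `scaf_start`,
#'   `scaf_end`, `trna_start`, `trna_end`, `strand` (`+` when the scaffold
#'   carries the tRNA-strand sequence). tRNA coordinates are always on the
#'   tRNA's own strand.
#' @export
find_attp <- function(scaffolds, trna_db, min_len = 25) {
  scaffolds <- as_seq_vector(scaffolds)
  trna_db <- as_trna_db(trna_db)
  out <- empty_attp_table()
  if (nrow(trna_db) == 0 || length(scaffolds) == 0) return(out)

  # Seed dictionaries are built once per (tRNA, strand), then matched
  # against every scaffold.
  queries <- list()
  for (ti in seq_len(nrow(trna_db))) {
    tseq <- trna_db$sequence[ti]
    if (nchar(tseq) < min_len) next
    for (strand in c("+", "-")) {
      qseq <- if (strand == "+") tseq else revcomp(tseq)
      n_seed <- nchar(qseq) - min_len + 1L
      seeds <- substring(qseq, seq_len(n_seed), seq_len(n_seed) + min_len - 1L)
      queries[[length(queries) + 1L]] <- list(
        ti = ti, strand = strand, qseq = qseq,
        pdict = Biostrings::PDict(Biostrings::DNAStringSet(seeds)))
    }
  }

  rows <- list()
  for (sid in names(scaffolds)) {
    sseq <- scaffolds[[sid]]
    subject <- Biostrings::DNAString(sseq)
    for (qr in queries) {
      ti <- qr$ti
      tseq <- trna_db$sequence[ti]
      strand <- qr$strand
      hits <- exact_shared_substrings(sseq, subject, qr$qseq, min_len,
                                      pdict = qr$pdict)
      if (nrow(hits) == 0) next
      if (strand == "-") {
        # Map query coordinates back to the tRNA's own strand.
        tlen <- nchar(tseq)
        tstart <- tlen - hits$q_end + 1L
        tend <- tlen - hits$q_start + 1L
        hits$q_start <- tstart
        hits$q_end <- tend
      }
      rows[[length(rows) + 1L]] <- data.frame(
        scaffold_id = sid, trna_id = trna_db$id[ti],
        match_len = hits$len, scaf_start = hits$s_start,
        scaf_end = hits$s_end, trna_start = hits$q_start,
        trna_end = hits$q_end, strand = strand, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) return(out)
  out <- do.call(rbind, rows)
  out[order(out$scaffold_id, out$trna_id, out$scaf_start), , drop = FALSE]
}

empty_attp_table <- function() {
  data.frame(scaffold_id = character(), trna_id = character(),
             match_len = integer(), scaf_start = integer(),
             scaf_end = integer(), trna_start = integer(),
             trna_end = integer(), strand = character(),
             stringsAsFactors = FALSE)
}

as_trna_db <- function(trna_db) {
  if (is.data.frame(trna_db)) return(trna_db)
  seqs <- as_seq_vector(trna_db)
  parts <- strsplit(names(seqs), "|", fixed = TRUE)
  data.frame(
    id = vapply(parts, `[[`, "", 1),
    phylum = vapply(parts, function(x) if (length(x) > 1) x[[2]] else NA_character_, ""),
    class = vapply(parts, function(x) if (length(x) > 2) x[[3]] else NA_character_, ""),
    sequence = unname(seqs), stringsAsFactors = FALSE
  )
}

# All maximal exact shared substrings of length >= min_len between a query
# sequence (plain string) and a subject (string + DNAString for matching).
# Returns q_start/q_end on the query as given, s_start/s_end on the subject.
exact_shared_substrings <- function(s_chr, s_dna, q_chr, min_len,
                                    pdict = NULL) {
  empty <- data.frame(q_start = integer(), q_end = integer(),
                      s_start = integer(), s_end = integer(),
                      len = integer(), stringsAsFactors = FALSE)
  qlen <- nchar(q_chr)
  if (qlen < min_len) return(empty)
  n_seed <- qlen - min_len + 1L
  pd <- pdict
  if (is.null(pd)) {
    seeds <- substring(q_chr, seq_len(n_seed), seq_len(n_seed) + min_len - 1L)
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(seeds))
  }
  m <- Biostrings::matchPDict(pd, s_dna)
  starts <- IRanges::start(m)
  hit_rows <- list()
  seen <- character(0)
  for (qi in seq_len(n_seed)) {
    sp <- starts[[qi]]
    for (p in sp) {
      # Extend the seed maximally in both directions.
      qs <- qi; ss <- p
      while (qs > 1 && ss > 1 &&
             substr(q_chr, qs - 1L, qs - 1L) == substr(s_chr, ss - 1L, ss - 1L)) {
        qs <- qs - 1L; ss <- ss - 1L
      }
      qe <- qi + min_len - 1L; se <- p + min_len - 1L
      slen <- nchar(s_chr)
      while (qe < qlen && se < slen &&
             substr(q_chr, qe + 1L, qe + 1L) == substr(s_chr, se + 1L, se + 1L)) {
        qe <- qe + 1L; se <- se + 1L
      }
      key <- paste(qs, ss, qe, sep = ":")
      if (!(key %in% seen)) {
        seen <- c(seen, key)
        hit_rows[[length(hit_rows) + 1L]] <- data.frame(
          q_start = qs, q_end = qe, s_start = ss, s_end = se,
          len = qe - qs + 1L, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(hit_rows) == 0) return(empty)
  do.call(rbind, hit_rows)
}

#' Assign putative hosts from attP matches gated on integrase presence
#'
#' attP/attB matching only makes biological sense for phages that can
#' integrate, so assignments are restricted to scaffolds carrying an
#' annotated integrase gene; scaffolds with tRNA matches but no integrase
#' are returned in a side table, not assigned. Because tRNA genes are
#' conserved across species, the assignment is capped at a broad rank
#' (class by default, phylum optionally). A scaffold matched to tRNAs of
#' conflicting phyla keeps all assignments, flagged ambiguous.
#'
#' @param matches attP match table from [find_attp()].
#' @param genes Gene-annotation table with `scaffold_id` and `product`
#'   columns; integrase genes are recognized by keyword.
#' @param trna_db tRNA database (data frame with `id`, `phylum`, `class`).
#' @param rank_cap `"class"` (default) or `"phylum"`.
#' @param integrase_keywords Regular expressions matched (case-insensitive)
#'   against gene products (default `"integrase"`).
#' @return List with `assignments` (data frame: `scaffold_id`,
#'   `host_taxon`, `phylum`, `trna_id`, `match_len`, `integrase_gene`,
#'   `ambiguous`) and `no_integrase` (match rows dropped for lack of an
#'   integrase).
#' @export
assign_hosts <- function(matches, genes, trna_db,
                         rank_cap = c("class", "phylum"),
                         integrase_keywords = "integrase") {
  rank_cap <- match.arg(rank_cap)
  trna_db <- as_trna_db(trna_db)
  empty <- data.frame(scaffold_id = character(), host_taxon = character(),
                      phylum = character(), trna_id = character(),
                      match_len = integer(), integrase_gene = character(),
                      ambiguous = logical(), stringsAsFactors = FALSE)
  if (nrow(matches) == 0) {
    return(list(assignments = empty, no_integrase = matches))
  }
  pat <- paste(integrase_keywords, collapse = "|")
  int_genes <- genes[grepl(pat, genes$product, ignore.case = TRUE), ,
                     drop = FALSE]
  int_by_scaffold <- split(int_genes$gene_id, int_genes$scaffold_id)
  has_int <- matches$scaffold_id %in% names(int_by_scaffold)
  no_integrase <- matches[!has_int, , drop = FALSE]
  matches <- matches[has_int, , drop = FALSE]
  if (nrow(matches) == 0) {
    return(list(assignments = empty, no_integrase = no_integrase))
  }
  ti <- match(matches$trna_id, trna_db$id)
  if (anyNA(ti)) stop("match table references unknown tRNA ids")
  host <- if (rank_cap == "class") trna_db$class[ti] else trna_db$phylum[ti]
  host <- ifelse(is.na(host), trna_db$phylum[ti], host)
  ass <- data.frame(
    scaffold_id = matches$scaffold_id, host_taxon = host,
    phylum = trna_db$phylum[ti], trna_id = matches$trna_id,
    match_len = matches$match_len,
    integrase_gene = vapply(matches$scaffold_id,
                            function(s) int_by_scaffold[[s]][1], ""),
    ambiguous = FALSE, stringsAsFactors = FALSE
  )
  # One row per (scaffold, taxon); conflicting phyla flag the scaffold.
  ass <- ass[order(ass$scaffold_id, ass$host_taxon, -ass$match_len), ,
             drop = FALSE]
  ass <- ass[!duplicated(ass[c("scaffold_id", "host_taxon")]), , drop = FALSE]
  n_phyla <- tapply(ass$phylum, ass$scaffold_id,
                    function(x) length(unique(x)))
  ass$ambiguous <- n_phyla[ass$scaffold_id] > 1
  rownames(ass) <- NULL
  list(assignments = ass, no_integrase = no_integrase)
}

#' Match CRISPR spacers against assembled contigs
#'
#' Searches every spacer for exact, full-length occurrences in the
#' assembled virome (both strands by default). A hit links the array's
#' carrier to the targeted element. Matches falling inside the source
#' array's own locus (same scaffold, overlapping the array coordinates,
#' when `array_start`/`array_end` are provided) are excluded, since every
#' spacer trivially matches itself.
#'
#' @param arrays CRISPR array table, one row per spacer: `array_id`,
#'   `scaffold_id`, `spacer_index`, `spacer`, and optionally
#'   `array_start`, `array_end` for self-locus exclusion. Array detection
#'   itself is an external input.
#' @param contigs Named character vector or `DNAStringSet` of contig
#'   sequences.
#' @param both_strands Search the reverse strand too (default `TRUE`).
#' @return Data frame: `array_id`, `source_scaffold`, `spacer_index`,
#'   `target_id`, `t_start`, `t_end`, `strand`, `match_len`. Spacers
#'   shorter than 15 bp are still searched but trigger a warning (high
#'   chance-match risk).
#' @export
match_spacers <- function(arrays, contigs, both_strands = TRUE) {
  empty <- data.frame(array_id = character(), source_scaffold = character(),
                      spacer_index = integer(), target_id = character(),
                      t_start = integer(), t_end = integer(),
                      strand = character(), match_len = integer(),
                      stringsAsFactors = FALSE)
  if (is.null(arrays) || nrow(arrays) == 0) return(empty)
  contigs <- as_seq_vector(contigs)
  if (any(nchar(arrays$spacer) < 15)) {
    warning(sum(nchar(arrays$spacer) < 15),
            " spacer(s) shorter than 15 bp: exact matches may occur by chance")
  }
  dna <- Biostrings::DNAStringSet(contigs)
  rows <- list()
  strands <- if (both_strands) c("+", "-") else "+"
  for (k in seq_len(nrow(arrays))) {
    sp <- arrays$spacer[k]
    for (strand in strands) {
      pat <- if (strand == "+") sp else revcomp(sp)
      m <- Biostrings::vmatchPattern(pat, dna)
      for (ci in seq_along(m)) {
        st <- IRanges::start(m[[ci]])
        if (length(st) == 0) next
        for (p in st) {
          t_end <- p + nchar(sp) - 1L
          # Exclude hits inside the source array's own locus.
          if (names(contigs)[ci] == arrays$scaffold_id[k] &&
              !is.null(arrays$array_start) &&
              !is.na(arrays$array_start[k]) &&
              p <= arrays$array_end[k] && t_end >= arrays$array_start[k]) {
            next
          }
          rows[[length(rows) + 1L]] <- data.frame(
            array_id = arrays$array_id[k],
            source_scaffold = arrays$scaffold_id[k],
            spacer_index = arrays$spacer_index[k],
            target_id = names(contigs)[ci], t_start = p, t_end = t_end,
            strand = strand, match_len = nchar(sp),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(rows) == 0) return(empty)
  do.call(rbind, rows)
}
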