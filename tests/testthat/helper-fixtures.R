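# Shared fixture builders for the test suite.

# Read pairs at the community's nominal coverage (cov * L / (2 * read_len)).
pairs_for <- function(spec, genome_len) {
  max(1L, as.integer(round(spec$coverage * genome_len /
                             (2 * spec$read_length))))
}

# A small contig table.
contig_table <- function(ids, lengths, coverage = 40, kmer = 33,
                         virome = "V1") {
  data.frame(id = ids, length = as.integer(lengths), virome = virome,
             kmer = kmer, coverage = coverage, stringsAsFactors = FALSE)
}

# One self-hit row in the minimal column set remove_redundancy() needs.
self_hit <- function(q, s, pident = 99, len = 2000, evalue = 1e-20) {
  data.frame(qseqid = q, sseqid = s, pident = pident, length = len,
             evalue = evalue, stringsAsFactors = FALSE)
}

# Hand-built paired alignment rows.
pair_row <- function(m1_start, m2_start, len1 = 100, len2 = 100,
                     scaffold = "S", id = "p") {
  m1_end <- m1_start + len1 - 1L
  m2_end <- m2_start + len2 - 1L
  data.frame(pair_id = id, scaffold_id = scaffold,
             m1_start = m1_start, m1_end = m1_end,
             m2_start = m2_start, m2_end = m2_end,
             apparent_span = max(m1_end, m2_end) - min(m1_start, m2_start) + 1L,
             same_scaffold = TRUE, stringsAsFactors = FALSE)
}

# Random DNA string with a local seed.
rand_seq <- function(len, seed) {
  withr::with_seed(seed, {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  })
}
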