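# Independent brute-force oracles. Each re-derives a result by the most
# direct method available so the production code is checked against a
# second, unrelated computation.

# All maximal exact shared substrings of length >= min_len between two
# sequences, by scanning every diagonal of the character-match matrix.
brute_shared_substrings <- function(a, b, min_len) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av)
  m <- length(bv)
  out <- list()
  for (off in (-(m - 1)):(n - 1)) {
    i0 <- max(1, 1 + off)
    j0 <- i0 - off
    len <- min(n - i0, m - j0) + 1
    if (len < min_len) next
    eq <- av[i0:(i0 + len - 1)] == bv[j0:(j0 + len - 1)]
    r <- rle(eq)
    pos <- cumsum(c(1, r$lengths))
    for (k in seq_along(r$lengths)) {
      if (r$values[k] && r$lengths[k] >= min_len) {
        s <- pos[k]
        out[[length(out) + 1]] <- data.frame(
          a_start = i0 + s - 1, b_start = j0 + s - 1,
          len = r$lengths[k])
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(a_start = integer(), b_start = integer(),
                      len = integer()))
  }
  do.call(rbind, out)
}

# Longest exact prefix-suffix repeat by direct comparison of every length.
brute_terminal_overlap <- function(seq, min_overlap) {
  L <- nchar(seq)
  for (k in seq(floor(L / 2), min_overlap)) {
    if (substr(seq, 1, k) == substr(seq, L - k + 1, L)) return(k)
  }
  NA_integer_
}

# Circular-pair count by an explicit double check over all coordinates.
brute_circular_count <- function(scaffold_len, pairs, end_window) {
  w <- min(end_window, floor(scaffold_len / 2))
  n <- 0L
  for (i in seq_len(nrow(pairs))) {
    p <- pairs[i, ]
    in_start <- function(s, e) s >= 1 && e <= w
    in_end <- function(s, e) s >= scaffold_len - w + 1 && e <= scaffold_len
    if ((in_start(p$m1_start, p$m1_end) && in_end(p$m2_start, p$m2_end)) ||
        (in_start(p$m2_start, p$m2_end) && in_end(p$m1_start, p$m1_end))) {
      n <- n + 1L
    }
  }
  n
}

# Independent straight-line re-encoding of the triage rule list.
triage_oracle <- function(p, min_cov = 10, virus_refseq_frac = 0.5,
                          virus_pogs_frac = 0.1, plasmid_frac = 0.5,
                          mito_frac = 0.5) {
  if (p$coverage < min_cov) return("low_coverage_reject")
  if (p$n_silva >= 1) return("cellular_review")
  if (p$n_pfam > 0 && p$n_mito / p$n_pfam > mito_frac) return("mito_review")
  if (p$n_pfam > 0 && p$n_aclame / p$n_pfam > plasmid_frac) {
    return("plasmid_review")
  }
  if (p$n_pogs7 >= 1) return("viral")
  if (p$n_pfam > 0 && p$n_refseq_virus / p$n_pfam >= virus_refseq_frac &&
      p$n_pogs10 / p$n_pfam >= virus_pogs_frac) {
    return("viral")
  }
  "ambiguous"
}

# Summed-score matrix by a naive accumulation loop.
brute_summed_scores <- function(hits, genomes) {
  S <- matrix(0, length(genomes), length(genomes),
              dimnames = list(genomes, genomes))
  for (k in seq_len(nrow(hits))) {
    a <- hits$qseqid[k]
    b <- hits$sseqid[k]
    S[a, b] <- S[a, b] + hits$bitscore[k]
    if (a != b) S[b, a] <- S[b, a] + hits$bitscore[k]
  }
  S
}

# Expected triage label for a planted community class.
class_to_label <- function(class_label) {
  c(viral = "viral", cellular = "cellular_review",
    plasmid = "plasmid_review", mitochondrial = "mito_review")[class_label]
}

# Random triage profile generator for the equivalence sweeps.
random_profiles <- function(n, seed) {
  withr::with_seed(seed, {
    n_genes <- sample(1:60, n, replace = TRUE)
    n_pfam <- vapply(n_genes, function(g) sample(0:g, 1), 0L)
    pick <- function(top) vapply(top, function(t) sample(0:t, 1), 0L)
    data.frame(
      scaffold_id = sprintf("S%05d", seq_len(n)),
      n_genes = n_genes,
      n_pfam = n_pfam,
      n_refseq_virus = pick(n_pfam),
      n_pogs10 = pick(n_pfam),
      n_pogs7 = vapply(n_pfam, function(t) sample(0:min(t, 2), 1), 0L),
      n_aclame = pick(n_pfam),
      n_mito = sample(0:12, n, replace = TRUE),
      n_silva = sample(0:2, n, replace = TRUE, prob = c(0.7, 0.2, 0.1)),
      coverage = round(stats::runif(n, 5, 60), 1),
      stringsAsFactors = FALSE
    )
  })
}
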