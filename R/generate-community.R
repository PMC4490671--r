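#' Generate a synthetic virome community with planted ground truth
#'
#' Draws a set of genomes according to a [community_spec()] and plants every
#' feature the downstream curation stages are meant to recover: circular
#' genomes (flagged; circularity manifests through wrap-around read pairs in
#' [simulate_paired_reads()]), redundant contigs that are exact substrings of
#' a longer genome, attP sites copied verbatim from a synthetic tRNA
#' database onto integrase-bearing scaffolds, and CRISPR arrays whose
#' penultimate spacer exactly matches another genome in the community.
#'
#' All randomness derives from `spec$seed` through per-scaffold child
#' streams, so the same spec always yields byte-identical output and adding
#' a scaffold does not perturb the sequences of the others.
#'
#' @param spec A [community_spec()].
#' @return An object of class `synthetic_community`: a list with elements
#'   * `genomes`: named character vector of genome sequences;
#'   * `truth`: data frame with one row per scaffold (`scaffold_id`,
#'     `class_label` in viral/cellular/plasmid/mitochondrial, `length`,
#'     `is_circular`, `coverage`, `redundant_of`, `attp_donor`,
#'     `integrase_gene`);
#'   * `trna_db`: synthetic tRNA database (`id`, `phylum`, `class`,
#'     `sequence`);
#'   * `attp_truth`: planted attP segments (scaffold, donor tRNA,
#'     coordinates on both);
#'   * `arrays`: planted CRISPR spacers, one row per spacer with array
#'     locus coordinates;
#'   * `spacer_truth`: planted spacer-to-genome links;
#'   * `spec`: the input spec.
#' @examples
#' cm <- generate_community(community_spec(n_viral = 3, seed = 42))
#' cm$truth[, c("scaffold_id", "class_label", "is_circular")]
#' @export
generate_community <- function(spec) {
  stopifnot(inherits(spec, "community_spec"))
  counts <- c(viral = spec$n_viral, cellular = spec$n_cellular,
              plasmid = spec$n_plasmidlike, mitochondrial = spec$n_mitolike)
  n_total <- sum(counts)
  if (n_total == 0) stop("community spec requests zero genomes")

  prefix <- c(viral = "VIR", cellular = "CEL", plasmid = "PLA",
              mitochondrial = "MIT")
  class_label <- rep(names(counts), counts)
  ids <- unlist(lapply(names(counts), function(cl) {
    if (counts[[cl]] == 0) return(character())
    sprintf("%s_%03d", prefix[[cl]], seq_len(counts[[cl]]))
  }), use.names = FALSE)

  # Genome lengths and sequences, one child stream per scaffold.
  lens <- integer(n_total)
  seqs <- character(n_total)
  for (i in seq_len(n_total)) {
    lens[i] <- with_seed(child_seed(spec$seed, i, 1L), {
      sample(spec$length_range[1]:spec$length_range[2], 1L)
    })
    seqs[i] <- with_seed(child_seed(spec$seed, i, 2L), random_dna(lens[i]))
  }
  names(seqs) <- ids

  # Circular flags: deterministic count per class, assigned to the first
  # genomes of each class.
  is_circular <- logical(n_total)
  for (cl in names(counts)) {
    idx <- which(class_label == cl)
    n_circ <- round(spec$fraction_circular * length(idx))
    if (n_circ > 0) is_circular[idx[seq_len(n_circ)]] <- TRUE
  }

  truth <- data.frame(
    scaffold_id = ids, class_label = class_label, length = lens,
    is_circular = is_circular, coverage = spec$coverage,
    redundant_of = NA_character_, attp_donor = NA_character_,
    integrase_gene = NA_character_, stringsAsFactors = FALSE
  )

  # Intervals already claimed by planted motifs, per scaffold.
  used <- list()
  claim <- function(id, start, len) {
    used[[id]] <<- rbind(used[[id]], c(start, start + len - 1L))
  }
  pick_free_pos <- function(id, motif_len) {
    L <- nchar(seqs[[id]])
    lo <- 1001L
    hi <- L - motif_len - 1000L
    if (hi < lo) stop("genome too short to plant a ", motif_len, " bp motif")
    for (try in 1:200) {
      p <- sample(lo:hi, 1L)
      iv <- used[[id]]
      if (is.null(iv) ||
          all(p > iv[, 2] | (p + motif_len - 1L) < iv[, 1])) {
        return(p)
      }
    }
    stop("could not find a free position on ", id)
  }

  # Synthetic tRNA database with phylum/class lineages.
  taxa <- data.frame(
    phylum = c("Actinobacteria", "Proteobacteria", "Proteobacteria",
               "Firmicutes", "Cyanobacteria", "Bacteroidetes", "Haptophyta"),
    class = c("Actinomycetia", "Alphaproteobacteria", "Gammaproteobacteria",
              "Bacilli", "Cyanophyceae", "Flavobacteriia", "Haptophyceae"),
    stringsAsFactors = FALSE
  )
  trna_db <- NULL
  if (spec$n_trna > 0) {
    trna_db <- do.call(rbind, lapply(seq_len(spec$n_trna), function(j) {
      with_seed(child_seed(spec$seed, j, 4L), {
        tx <- taxa[sample(nrow(taxa), 1L), ]
        data.frame(id = sprintf("tRNA_%03d", j), phylum = tx$phylum,
                   class = tx$class, sequence = random_dna(sample(72:90, 1L)),
                   stringsAsFactors = FALSE)
      })
    }))
  }

  # Plant attP sites: exact copy of a 28-60 bp tRNA segment, plus an
  # integrase gene annotation on the same scaffold.
  attp_truth <- data.frame(
    scaffold_id = character(), trna_id = character(), match_len = integer(),
    scaf_start = integer(), trna_start = integer(), stringsAsFactors = FALSE
  )
  viral_idx <- which(class_label == "viral")
  if (spec$n_attp > 0) {
    if (is.null(trna_db)) stop("attP planting requires n_trna > 0")
    hosts <- with_seed(child_seed(spec$seed, 0L, 6L),
                       sample(viral_idx, spec$n_attp))
    for (k in seq_along(hosts)) {
      i <- hosts[k]
      id <- ids[i]
      rec <- with_seed(child_seed(spec$seed, k, 7L), {
        donor <- trna_db[sample(nrow(trna_db), 1L), ]
        seg_len <- sample(28:60, 1L)
        seg_len <- min(seg_len, nchar(donor$sequence))
        t_start <- sample(seq_len(nchar(donor$sequence) - seg_len + 1L), 1L)
        pos <- pick_free_pos(id, seg_len)
        gene_idx <- sample(floor(lens[i] / spec$gene_len), 1L)
        list(donor = donor, seg_len = seg_len, t_start = t_start,
             pos = pos, gene_idx = gene_idx)
      })
      seg <- substr(rec$donor$sequence, rec$t_start,
                    rec$t_start + rec$seg_len - 1L)
      seqs[[id]] <- splice_substr(seqs[[id]], rec$pos, seg)
      claim(id, rec$pos, rec$seg_len)
      truth$attp_donor[i] <- rec$donor$id
      truth$integrase_gene[i] <- sprintf("%s_g%04d", id, rec$gene_idx)
      attp_truth <- rbind(attp_truth, data.frame(
        scaffold_id = id, trna_id = rec$donor$id, match_len = rec$seg_len,
        scaf_start = rec$pos, trna_start = rec$t_start,
        stringsAsFactors = FALSE
      ))
    }
  }

  # Plant CRISPR arrays: repeat-spacer-...-repeat locus; the penultimate
  # spacer is copied verbatim into another viral genome.
  arrays <- data.frame(
    array_id = character(), scaffold_id = character(),
    repeat_consensus = character(), spacer_index = integer(),
    spacer = character(), start = integer(), end = integer(),
    array_start = integer(), array_end = integer(), stringsAsFactors = FALSE
  )
  spacer_truth <- data.frame(
    array_id = character(), spacer_index = integer(),
    source_scaffold = character(), target_scaffold = character(),
    spacer = character(), stringsAsFactors = FALSE
  )
  if (spec$n_crispr > 0) {
    if (length(viral_idx) < 2) {
      stop("spacer planting requires at least two viral genomes")
    }
    hosts <- with_seed(child_seed(spec$seed, 0L, 8L),
                       sample(viral_idx, spec$n_crispr))
    for (k in seq_along(hosts)) {
      i <- hosts[k]
      id <- ids[i]
      rec <- with_seed(child_seed(spec$seed, k, 9L), {
        rep_seq <- random_dna(29L)
        n_sp <- sample(8:15, 1L)
        spacers <- vapply(seq_len(n_sp), function(s) random_dna(32L), "")
        target <- ids[sample(setdiff(viral_idx, i), 1L)]
        list(rep_seq = rep_seq, spacers = spacers, target = target)
      })
      n_sp <- length(rec$spacers)
      locus <- paste0(rec$rep_seq,
                      paste0(rec$spacers, rec$rep_seq, collapse = ""))
      pos <- with_seed(child_seed(spec$seed, k, 10L), {
        pick_free_pos(id, nchar(locus))
      })
      seqs[[id]] <- splice_substr(seqs[[id]], pos, locus)
      claim(id, pos, nchar(locus))
      array_id <- sprintf("%s_crispr%d", id, k)
      sp_start <- pos + 29L + (seq_len(n_sp) - 1L) * (29L + 32L)
      arrays <- rbind(arrays, data.frame(
        array_id = array_id, scaffold_id = id,
        repeat_consensus = rec$rep_seq, spacer_index = seq_len(n_sp),
        spacer = rec$spacers, start = sp_start, end = sp_start + 31L,
        array_start = pos, array_end = pos + nchar(locus) - 1L,
        stringsAsFactors = FALSE
      ))
      # Copy the penultimate spacer into the target genome.
      link_idx <- n_sp - 1L
      tpos <- with_seed(child_seed(spec$seed, k, 11L), {
        pick_free_pos(rec$target, 32L)
      })
      seqs[[rec$target]] <- splice_substr(seqs[[rec$target]], tpos,
                                          rec$spacers[link_idx])
      claim(rec$target, tpos, 32L)
      spacer_truth <- rbind(spacer_truth, data.frame(
        array_id = array_id, spacer_index = link_idx,
        source_scaffold = id, target_scaffold = rec$target,
        spacer = rec$spacers[link_idx], stringsAsFactors = FALSE
      ))
    }
  }

  # Planted redundancy: exact substrings of a longer genome, emitted as
  # extra contigs (last, so they inherit any planted motifs verbatim).
  if (spec$n_redundant > 0) {
    parents <- with_seed(child_seed(spec$seed, 0L, 12L),
                         sample(n_total, spec$n_redundant, replace = TRUE))
    for (k in seq_along(parents)) {
      i <- parents[k]
      pid <- ids[i]
      rec <- with_seed(child_seed(spec$seed, k, 13L), {
        clen <- as.integer(round(0.6 * lens[i]))
        start <- sample(seq_len(lens[i] - clen + 1L), 1L)
        list(clen = clen, start = start)
      })
      cid <- sprintf("%s_r%d", pid, k)
      cseq <- substr(seqs[[pid]], rec$start, rec$start + rec$clen - 1L)
      seqs[[cid]] <- cseq
      truth <- rbind(truth, data.frame(
        scaffold_id = cid, class_label = truth$class_label[i],
        length = rec$clen, is_circular = FALSE, coverage = spec$coverage,
        redundant_of = pid, attp_donor = NA_character_,
        integrase_gene = NA_character_, stringsAsFactors = FALSE
      ))
    }
  }

  structure(
    list(genomes = seqs, truth = truth, trna_db = trna_db,
         attp_truth = attp_truth, arrays = arrays,
         spacer_truth = spacer_truth, spec = spec),
    class = "synthetic_community"
  )
}

#' @export
print.synthetic_community <- function(x, ...) {
  cat(sprintf("Synthetic virome community: %d scaffolds (%s)\n",
              nrow(x$truth),
              paste(names(table(x$truth$class_label)),
                    table(x$truth$class_label), collapse = ", ")))
  cat(sprintf("  %d circular, %d planted attP, %d planted spacer links, %d redundant\n",
              sum(x$truth$is_circular), nrow(x$attp_truth),
              nrow(x$spacer_truth), sum(!is.na(x$truth$redundant_of))))
  invisible(x)
}

#' Write community genomes to a FASTA file
#'
#' @param community A `synthetic_community`.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_community_fasta <- function(community, path) {
  dna <- Biostrings::DNAStringSet(community$genomes)
  Biostrings::writeXStringSet(dna, filepath = path, width = 70L)
  invisible(path)
}

#' Self-comparison hit rows for planted redundancy
#'
#' Emits a BLAST-tabular style self-hit table for a community: one
#' 100%-identity full-length hit per planted redundant contig against its
#' parent (both directions), the rows a nucleotide self-search at a 97%
#' identity / 1e-5 E-value cutoff would report for exact substring copies.
#' Non-planted scaffold pairs share no long exact repeats, so they produce
#' no rows.
#'
#' @param community A `synthetic_community`.
#' @return A 12-column BLAST tabular data frame (possibly empty).
#' @export
emit_self_hits <- function(community) {
  tr <- community$truth
  red <- tr[!is.na(tr$redundant_of), , drop = FALSE]
  if (nrow(red) == 0) return(empty_blast_table())
  rows <- lapply(seq_len(nrow(red)), function(k) {
    child <- red$scaffold_id[k]
    parent <- red$redundant_of[k]
    clen <- red$length[k]
    pstart <- as.integer(regexpr(community$genomes[[child]],
                                 community$genomes[[parent]],
                                 fixed = TRUE))
    rbind(
      blast_row(child, parent, 100, clen, 1L, clen, pstart,
                pstart + clen - 1L),
      blast_row(parent, child, 100, clen, pstart, pstart + clen - 1L,
                1L, clen)
    )
  })
  do.call(rbind, rows)
}

# One BLAST outfmt-6 row.
blast_row <- function(q, s, pident, len, qstart, qend, sstart, send,
                      evalue = 0, bitscore = 2 * len) {
  data.frame(qseqid = q, sseqid = s, pident = pident, length = len,
             mismatch = 0L, gapopen = 0L, qstart = qstart, qend = qend,
             sstart = sstart, send = send, evalue = evalue,
             bitscore = bitscore, stringsAsFactors = FALSE)
}

empty_blast_table <- function() {
  data.frame(qseqid = character(), sseqid = character(), pident = numeric(),
             length = integer(), mismatch = integer(), gapopen = integer(),
             qstart = integer(), qend = integer(), sstart = integer(),
             send = integer(), evalue = numeric(), bitscore = numeric(),
             stringsAsFactors = FALSE)
}
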