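test_that("generator honours counts, circular flags, and determinism", {
  sp <- community_spec(n_viral = 5, fraction_circular = 1.0, seed = 7)
  cm <- generate_community(sp)
  expect_equal(nrow(cm$truth), 5)
  expect_true(all(cm$truth$is_circular))

  # Byte-identical regeneration from the same spec.
  cm2 <- generate_community(sp)
  expect_identical(cm$genomes, cm2$genomes)
  expect_identical(cm$truth, cm2$truth)

  # Exact class counts, not sampled.
  sp2 <- community_spec(n_viral = 50, n_cellular = 50, seed = 1,
                        length_range = c(15000, 20000))
  cm3 <- generate_community(sp2)
  expect_equal(as.vector(table(cm3$truth$class_label)[c("viral", "cellular")]),
               c(50, 50))

  expect_error(generate_community(community_spec(n_viral = 0)),
               "zero genomes")
  expect_error(community_spec(n_viral = -1), ">= 0")
  expect_error(community_spec(length_range = c(500, 2000)), "1000")
  expect_error(community_spec(fraction_circular = 1.2), "\\[0, 1\\]")
})

test_that("planted truth re-verifies by direct string search", {
  sp <- community_spec(n_viral = 8, n_cellular = 2, n_attp = 3, n_crispr = 2,
                       n_redundant = 2, seed = 19)
  cm <- generate_community(sp)

  # Every planted attP is an exact substring of its donor tRNA.
  expect_equal(nrow(cm$attp_truth), 3)
  for (k in seq_len(nrow(cm$attp_truth))) {
    a <- cm$attp_truth[k, ]
    donor <- cm$trna_db$sequence[cm$trna_db$id == a$trna_id]
    seg <- substr(donor, a$trna_start, a$trna_start + a$match_len - 1)
    expect_gte(a$match_len, 28)
    expect_lte(a$match_len, 60)
    expect_identical(substr(cm$genomes[[a$scaffold_id]], a$scaf_start,
                            a$scaf_start + a$match_len - 1), seg)
  }
  # attP scaffolds carry an integrase gene in the truth table.
  attp_rows <- cm$truth[!is.na(cm$truth$attp_donor), ]
  expect_true(all(!is.na(attp_rows$integrase_gene)))

  # Every planted spacer link is found verbatim in its target.
  expect_equal(nrow(cm$spacer_truth), 2)
  for (k in seq_len(nrow(cm$spacer_truth))) {
    s <- cm$spacer_truth[k, ]
    expect_true(grepl(s$spacer, cm$genomes[[s$target_scaffold]],
                      fixed = TRUE))
    expect_true(s$target_scaffold != s$source_scaffold)
  }
  # Array coordinates address the spacers on the source scaffold.
  for (k in seq_len(nrow(cm$arrays))) {
    r <- cm$arrays[k, ]
    expect_identical(substr(cm$genomes[[r$scaffold_id]], r$start, r$end),
                     r$spacer)
  }

  # Redundant contigs are exact substrings of a strictly longer parent.
  red <- cm$truth[!is.na(cm$truth$redundant_of), ]
  expect_equal(nrow(red), 2)
  for (k in seq_len(nrow(red))) {
    parent_len <- cm$truth$length[cm$truth$scaffold_id == red$redundant_of[k]]
    expect_lt(red$length[k], parent_len)
    expect_true(grepl(cm$genomes[[red$scaffold_id[k]]],
                      cm$genomes[[red$redundant_of[k]]], fixed = TRUE))
  }
})

test_that("paired-read simulation wraps only circular genomes", {
  sp <- community_spec(n_viral = 1, length_range = c(20000, 20000), seed = 3)
  g <- rand_seq(20000, 11)

  lin <- simulate_paired_reads(g, FALSE, 1000, sp, "lin", seed = 5)
  pa <- pair_alignments(lin$sam)
  # Linear genomes cannot produce end-spanning pairs: no mate pair with one
  # mate within 1 kb of each end and a span beyond the insert range.
  near_both_ends <- (pa$m1_end <= 1000 & pa$m2_start >= 19001) |
    (pa$m2_end <= 1000 & pa$m1_start >= 19001)
  expect_equal(sum(near_both_ends & pa$apparent_span > 900), 0)
  expect_equal(sum(lin$wrapped), 0)
  # All alignments inside the scaffold.
  expect_true(all(pa$m1_start >= 1 & pa$m2_start >= 1))
  expect_true(all(pmax(pa$m1_end, pa$m2_end) <= 20000))

  circ <- simulate_paired_reads(g, TRUE, 1000, sp, "circ", seed = 5)
  # Observed wrap count within 3 sigma of the simulator's binomial model:
  # a fragment wraps when the origin falls between the mates, probability
  # about (insert - 2*(read_len - 1)) / L.
  p_wrap <- (sp$insert_mean - 2 * (sp$read_length - 1)) / 20000
  expected <- 1000 * p_wrap
  sigma <- sqrt(1000 * p_wrap * (1 - p_wrap))
  expect_gte(sum(circ$wrapped), expected - 3 * sigma)
  expect_lte(sum(circ$wrapped), expected + 3 * sigma)
  # Oracle: a wrapped fragment is exactly one whose mates land at opposite
  # scaffold ends (mate2 left of mate1 on the linearized coordinates).
  pc <- pair_alignments(circ$sam)
  expect_equal(sum(circ$wrapped), sum(pc$m2_start < pc$m1_start))

  # n_pairs = 0 yields empty outputs without error.
  z <- simulate_paired_reads(g, TRUE, 0, sp)
  expect_equal(nrow(z$reads), 0)
  expect_equal(nrow(z$sam), 0)
})

test_that("SAM round-trip preserves records and FASTQ is well-formed", {
  sp <- community_spec(n_viral = 1, length_range = c(16000, 16000), seed = 2)
  g <- rand_seq(16000, 21)
  sim <- simulate_paired_reads(g, TRUE, 50, sp, "scafA", seed = 9)

  tmp <- withr::local_tempfile(fileext = ".sam")
  write_sam(sim$sam, c(scafA = 16000L), tmp)
  lines <- readLines(tmp)
  expect_true(any(startsWith(lines, "@SQ")))
  back <- read_sam(tmp)
  expect_equal(back, sim$sam)

  fq1 <- withr::local_tempfile(fileext = ".fastq")
  fq2 <- withr::local_tempfile(fileext = ".fastq")
  write_fastq_pair(sim$reads, fq1, fq2)
  r1 <- Biostrings::readDNAStringSet(fq1, format = "fastq")
  expect_equal(length(r1), 50)
  expect_equal(unique(Biostrings::width(r1)), sp$read_length)
  expect_identical(unname(as.character(r1)), sim$reads$seq1)
})

test_that("emitted hit tables satisfy the class regimes exactly", {
  sp <- community_spec(n_viral = 6, n_cellular = 4, n_plasmidlike = 3,
                       n_mitolike = 3, seed = 23)
  cm <- generate_community(sp)
  ht <- emit_hit_tables(cm$truth, seed = 31)
  prof <- build_profiles(ht$genes, ht$hits,
                         stats::setNames(cm$truth$coverage,
                                         cm$truth$scaffold_id))
  prof <- prof[match(cm$truth$scaffold_id, prof$scaffold_id), ]
  cls <- cm$truth$class_label

  viral <- prof[cls == "viral", ]
  expect_true(all(viral$n_refseq_virus / viral$n_pfam >= 0.5))
  expect_true(all(viral$n_pogs10 / viral$n_pfam >= 0.1))
  expect_true(all(viral$n_silva == 0))
  cellular <- prof[cls == "cellular", ]
  expect_true(all(cellular$n_silva >= 1))
  plasmid <- prof[cls == "plasmid", ]
  expect_true(all(plasmid$n_aclame / plasmid$n_pfam > 0.5))
  mito <- prof[cls == "mitochondrial", ]
  expect_true(all(mito$n_mito / mito$n_pfam > 0.5))
  # Gene-level counts never exceed the gene total.
  for (cl in c("n_pfam", "n_refseq_virus", "n_pogs10", "n_pogs7",
               "n_aclame")) {
    expect_true(all(prof[[cl]] <= prof$n_genes))
  }

  # Planted integrase genes surface in the gene calls.
  sp2 <- community_spec(n_viral = 4, n_attp = 2, seed = 29)
  cm2 <- generate_community(sp2)
  ht2 <- emit_hit_tables(cm2$truth, seed = 5)
  integrase <- ht2$genes$gene_id[grepl("integrase", ht2$genes$product)]
  expect_setequal(integrase,
                  cm2$truth$integrase_gene[!is.na(cm2$truth$integrase_gene)])

  expect_error(emit_hit_tables(cm$truth[0, ], 1), "empty")
  bad <- cm$truth
  bad$class_label[1] <- "archaeal"
  expect_error(emit_hit_tables(bad, 1), "unknown class")
})
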