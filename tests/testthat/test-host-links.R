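make_trna_db <- function() {
  data.frame(
    id = c("tA", "tB"),
    phylum = c("Actinobacteria", "Proteobacteria"),
    class = c("Actinomycetia", "Gammaproteobacteria"),
    sequence = c(rand_seq(80, 101), rand_seq(76, 102)),
    stringsAsFactors = FALSE
  )
}

test_that("planted attP segments are found at 100% identity only", {
  db <- make_trna_db()
  seg <- substr(db$sequence[1], 11, 50) # 40 bp
  scaf <- rand_seq(3000, 7)
  scaf_planted <- paste0(substr(scaf, 1, 1200), seg, substr(scaf, 1241, 3000))
  m <- find_attp(c(S1 = scaf_planted), db)
  expect_equal(nrow(m), 1)
  expect_equal(m$trna_id, "tA")
  expect_equal(m$match_len, 40)
  expect_equal(m$scaf_start, 1201)
  expect_equal(m$trna_start, 11)
  expect_equal(m$strand, "+")
  # Reported match re-verifies by direct string comparison.
  expect_identical(substr(scaf_planted, m$scaf_start, m$scaf_end),
                   substr(db$sequence[1], m$trna_start, m$trna_end))

  # One mismatch in the planted copy: no match at all (no 25-mer survives).
  seg_mm <- seg
  substr(seg_mm, 20, 20) <- chartr("ACGT", "TGCA", substr(seg_mm, 20, 20))
  scaf_mm <- paste0(substr(scaf, 1, 1200), seg_mm, substr(scaf, 1241, 3000))
  m_mm <- find_attp(c(S1 = scaf_mm), db, min_len = 25)
  expect_equal(nrow(m_mm), 0)

  # Reverse-strand copy is reported with tRNA coordinates on its own strand.
  scaf_rc <- paste0(substr(scaf, 1, 1200),
                    as.character(Biostrings::reverseComplement(
                      Biostrings::DNAString(seg))),
                    substr(scaf, 1241, 3000))
  m_rc <- find_attp(c(S1 = scaf_rc), db)
  expect_equal(nrow(m_rc), 1)
  expect_equal(m_rc$strand, "-")
  expect_equal(m_rc$trna_start, 11)

  # Random scaffolds vs the database: no chance 25-mer matches, and empty
  # databases give empty tables.
  expect_equal(nrow(find_attp(c(R = rand_seq(5000, 77)), db)), 0)
  expect_equal(nrow(find_attp(c(R = rand_seq(5000, 77)), db[0, ])), 0)
})

test_that("attP search is complete against brute-force substring enumeration", {
  db <- make_trna_db()
  withr::with_seed(31, {
    for (rep in 1:6) {
      scaf <- rand_seq(2000, 300 + rep)
      # Plant 1-2 segments of varying length, some below the floor.
      seg_len <- sample(c(18, 25, 33, 52), 1)
      t_start <- sample(20, 1)
      seg <- substr(db$sequence[2], t_start, t_start + seg_len - 1)
      pos <- sample(1500, 1) + 100
      scaf <- paste0(substr(scaf, 1, pos - 1), seg,
                     substr(scaf, pos + seg_len, 2000))
      got <- find_attp(c(S = scaf), db, min_len = 25)
      got_fwd <- got[got$strand == "+", , drop = FALSE]
      for (ti in 1:2) {
        oracle <- brute_shared_substrings(scaf, db$sequence[ti], 25)
        mine <- got_fwd[got_fwd$trna_id == db$id[ti], , drop = FALSE]
        expect_equal(nrow(mine), nrow(oracle))
        if (nrow(oracle) > 0) {
          o <- oracle[order(oracle$a_start), ]
          g <- mine[order(mine$scaf_start), ]
          expect_equal(g$scaf_start, o$a_start)
          expect_equal(g$trna_start, o$b_start)
          expect_equal(g$match_len, o$len)
        }
      }
    }
  })
})

test_that("host assignment requires an integrase and caps the rank", {
  db <- make_trna_db()
  matches <- data.frame(
    scaffold_id = c("withInt", "noInt"), trna_id = c("tA", "tB"),
    match_len = c(40L, 33L), scaf_start = c(100L, 200L),
    scaf_end = c(139L, 232L), trna_start = c(1L, 1L),
    trna_end = c(40L, 33L), strand = "+", stringsAsFactors = FALSE)
  genes <- data.frame(
    scaffold_id = c("withInt", "withInt", "noInt"),
    gene_id = c("withInt_g1", "withInt_g2", "noInt_g1"),
    product = c("hypothetical protein", "phage integrase",
                "hypothetical protein"),
    stringsAsFactors = FALSE)
  res <- assign_hosts(matches, genes, db)
  expect_equal(res$assignments$scaffold_id, "withInt")
  expect_equal(res$assignments$host_taxon, "Actinomycetia")
  expect_equal(res$assignments$integrase_gene, "withInt_g2")
  expect_equal(res$no_integrase$scaffold_id, "noInt")
  # Phylum cap.
  res_p <- assign_hosts(matches, genes, db, rank_cap = "phylum")
  expect_equal(res_p$assignments$host_taxon, "Actinobacteria")

  # Conflicting phyla on one scaffold: both reported, flagged ambiguous.
  m2 <- matches
  m2$scaffold_id <- "withInt"
  res2 <- assign_hosts(m2, genes, db)
  expect_equal(nrow(res2$assignments), 2)
  expect_true(all(res2$assignments$ambiguous))

  # No matches: empty output.
  res0 <- assign_hosts(matches[0, ], genes, db)
  expect_equal(nrow(res0$assignments), 0)
})

test_that("spacer matching is exact, strand-aware, and skips the source locus", {
  spacer <- rand_seq(32, 401)
  target <- paste0(rand_seq(900, 402), spacer, rand_seq(568, 403))
  source_seq <- paste0(rand_seq(500, 404), spacer, rand_seq(468, 405))
  arrays <- data.frame(array_id = "arr1", scaffold_id = "src",
                       spacer_index = 12L, spacer = spacer,
                       array_start = 490L, array_end = 560L,
                       stringsAsFactors = FALSE)
  contigs <- c(src = source_seq, tgt = target, other = rand_seq(1500, 406))

  hits <- match_spacers(arrays, contigs)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$target_id, "tgt")
  expect_equal(hits$t_start, 901)
  expect_equal(hits$match_len, 32)
  expect_identical(substr(target, hits$t_start, hits$t_end), spacer)

  # Reverse-complement copy found only when both strands are searched.
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(spacer)))
  contigs_rc <- c(src = source_seq,
                  tgt = paste0(rand_seq(700, 407), rc, rand_seq(300, 408)))
  hits_rc <- match_spacers(arrays, contigs_rc, both_strands = TRUE)
  expect_equal(nrow(hits_rc), 1)
  expect_equal(hits_rc$strand, "-")
  expect_equal(nrow(match_spacers(arrays, contigs_rc, both_strands = FALSE)),
               0)

  # Short spacers warn but are still searched.
  short_arr <- arrays
  short_arr$spacer <- substr(spacer, 1, 12)
  short_arr$array_end <- 510L
  expect_warning(match_spacers(short_arr, contigs), "15 bp")

  expect_equal(nrow(match_spacers(arrays[0, ], contigs)), 0)
})

test_that("generator-planted host links are recovered with zero extras", {
  sp <- community_spec(n_viral = 10, n_cellular = 3, n_attp = 3, n_crispr = 2,
                       seed = 83)
  cm <- generate_community(sp)
  ht <- emit_hit_tables(cm$truth, seed = 7)

  m <- find_attp(cm$genomes, cm$trna_db)
  # Every planted attP recovered at its planted coordinates.
  for (k in seq_len(nrow(cm$attp_truth))) {
    a <- cm$attp_truth[k, ]
    # The reported maximal match must cover the planted interval (chance
    # one-base extensions past the planted boundary are possible).
    hit <- m[m$scaffold_id == a$scaffold_id & m$trna_id == a$trna_id &
               m$scaf_start <= a$scaf_start &
               m$scaf_end >= a$scaf_start + a$match_len - 1, , drop = FALSE]
    expect_equal(nrow(hit), 1)
    expect_gte(hit$match_len, a$match_len)
  }
  # No matches on scaffolds without a planted attP.
  planted_scafs <- cm$attp_truth$scaffold_id
  expect_equal(nrow(m[!m$scaffold_id %in% planted_scafs, ]), 0)

  # Host assignment lands on the donor's class for every planted scaffold.
  res <- assign_hosts(m, ht$genes, cm$trna_db)
  expect_setequal(res$assignments$scaffold_id, planted_scafs)
  for (k in seq_len(nrow(cm$attp_truth))) {
    a <- cm$attp_truth[k, ]
    want <- cm$trna_db$class[cm$trna_db$id == a$trna_id]
    got <- res$assignments$host_taxon[
      res$assignments$scaffold_id == a$scaffold_id]
    expect_true(want %in% got)
  }

  # Every planted spacer link recovered; no links besides the planted ones.
  sm <- match_spacers(cm$arrays, cm$genomes)
  for (k in seq_len(nrow(cm$spacer_truth))) {
    s <- cm$spacer_truth[k, ]
    hit <- sm[sm$array_id == s$array_id & sm$spacer_index == s$spacer_index &
                sm$target_id == s$target_scaffold, , drop = FALSE]
    expect_equal(nrow(hit), 1)
  }
  expect_equal(nrow(sm), nrow(cm$spacer_truth))
})
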