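#' Emit per-database hit tables and gene calls for a synthetic community
#'
#' Produces, for every scaffold in the community, a gene-call table and one
#' BLAST-tabular hit table per reference database (Pfam-A, RefSeq virus,
#' POGs-10, POGs-7, ACLAME plasmids, RefSeq mitochondrion, Silva SSU/LSU),
#' drawn from class-conditional regimes chosen so the triage decision rules
#' recover the planted class exactly:
#'
#' * viral: RefSeq-virus hits on >= 50% and POGs-10 on >= 10% of Pfam-hit
#'   genes; no Silva or mitochondrion hits.
#' * cellular: at least one Silva SSU/LSU hit (scaffold-level rows).
#' * plasmid: ACLAME hits on > 50% of Pfam-hit genes.
#' * mitochondrial: mitochondrion hits (scaffold-level tblastx rows)
#'   outnumbering 50% of Pfam-hit genes.
#'
#' Genes are the fixed-length windows of the community spec; planted
#' integrase genes are annotated with product "phage integrase" so host
#' assignment can gate on them.
#'
#' @param truth Community truth table (from [generate_community()]); the
#'   `class_label`, `length` and `integrase_gene` columns are used.
#' @param seed Integer seed for the hit-count streams.
#' @param gene_len Gene window length in bp (default 900, matching
#'   [community_spec()]).
#' @return A list with `genes` (GFF3-like data frame: `scaffold_id`,
#'   `gene_id`, `start`, `end`, `strand`, `product`) and `hits`, a named
#'   list of 12-column BLAST tabular data frames keyed by database
#'   (`pfam`, `refseq_virus`, `pogs10`, `pogs7`, `aclame`, `mito`,
#'   `silva`). `mito` and `silva` rows are scaffold-level (qseqid is the
#'   scaffold); the rest are gene-level (qseqid is the gene).
#' @export
emit_hit_tables <- function(truth, seed = 1L, gene_len = 900L) {
  if (nrow(truth) == 0) stop("truth table is empty")
  known <- c("viral", "cellular", "plasmid", "mitochondrial")
  bad <- setdiff(unique(truth$class_label), known)
  if (length(bad) > 0) stop("unknown class label: ", paste(bad, collapse = ", "))

  genes_list <- vector("list", nrow(truth))
  hit_rows <- list(pfam = list(), refseq_virus = list(), pogs10 = list(),
                   pogs7 = list(), aclame = list(), mito = list(),
                   silva = list())

  for (i in seq_len(nrow(truth))) {
    id <- truth$scaffold_id[i]
    cls <- truth$class_label[i]
    n_genes <- max(1L, floor(truth$length[i] / gene_len))
    gene_ids <- sprintf("%s_g%04d", id, seq_len(n_genes))
    product <- rep("hypothetical protein", n_genes)
    if (!is.na(truth$integrase_gene[i])) {
      gi <- match(truth$integrase_gene[i], gene_ids)
      if (!is.na(gi)) product[gi] <- "phage integrase"
    }
    genes_list[[i]] <- data.frame(
      scaffold_id = id, gene_id = gene_ids,
      start = (seq_len(n_genes) - 1L) * gene_len + 1L,
      end = seq_len(n_genes) * gene_len,
      strand = "+", product = product, stringsAsFactors = FALSE
    )

    prof <- with_seed(child_seed(seed, i, 20L), {
      n_pfam <- max(1L, round(stats::runif(1, 0.45, 0.65) * n_genes))
      pfam_genes <- sort(sample.int(n_genes, n_pfam))
      p <- list(pfam = pfam_genes)
      if (cls == "viral") {
        p$refseq_virus <- sort(sample_vec(pfam_genes,
                                      ceiling(stats::runif(1, 0.6, 0.8) * n_pfam)))
        p$pogs10 <- sort(sample_vec(pfam_genes,
                                max(1L, ceiling(stats::runif(1, 0.15, 0.3) * n_pfam))))
        p$pogs7 <- sample_vec(pfam_genes, stats::rbinom(1, 1, 0.3))
        p$aclame <- sample_vec(pfam_genes,
                           floor(stats::runif(1, 0, 0.2) * n_pfam))
        p$n_mito <- 0L
        p$n_silva <- 0L
      } else if (cls == "cellular") {
        p$refseq_virus <- sample_vec(pfam_genes,
                                 floor(stats::runif(1, 0, 0.3) * n_pfam))
        p$pogs10 <- integer(0)
        p$pogs7 <- integer(0)
        p$aclame <- sample_vec(pfam_genes,
                           floor(stats::runif(1, 0, 0.3) * n_pfam))
        p$n_mito <- 0L
        p$n_silva <- 1L + stats::rpois(1, 1)
      } else if (cls == "plasmid") {
        p$refseq_virus <- sample_vec(pfam_genes,
                                 floor(stats::runif(1, 0, 0.3) * n_pfam))
        p$pogs10 <- integer(0)
        p$pogs7 <- integer(0)
        p$aclame <- sort(sample_vec(pfam_genes,
                                ceiling(stats::runif(1, 0.6, 0.85) * n_pfam)))
        p$n_mito <- 0L
        p$n_silva <- 0L
      } else { # mitochondrial
        p$refseq_virus <- sample_vec(pfam_genes,
                                 floor(stats::runif(1, 0, 0.3) * n_pfam))
        p$pogs10 <- integer(0)
        p$pogs7 <- integer(0)
        p$aclame <- sample_vec(pfam_genes,
                           floor(stats::runif(1, 0, 0.2) * n_pfam))
        p$n_mito <- as.integer(ceiling(0.7 * n_pfam))
        p$n_silva <- 0L
      }
      p
    })

    gene_hits <- function(idx, db) {
      if (length(idx) == 0) return(NULL)
      blast_row(gene_ids[idx], sprintf("%s_%05d", db, idx),
                pident = 45, len = 120L,
                qstart = 1L, qend = 120L, sstart = 1L, send = 120L,
                evalue = 1e-10, bitscore = 150)
    }
    hit_rows$pfam[[i]] <- gene_hits(prof$pfam, "PF")
    hit_rows$refseq_virus[[i]] <- gene_hits(prof$refseq_virus, "RSV")
    hit_rows$pogs10[[i]] <- gene_hits(prof$pogs10, "POG10")
    hit_rows$pogs7[[i]] <- gene_hits(prof$pogs7, "POG7")
    hit_rows$aclame[[i]] <- gene_hits(prof$aclame, "ACL")
    if (prof$n_mito > 0) {
      hit_rows$mito[[i]] <- blast_row(
        rep(id, prof$n_mito), sprintf("MITO_%05d", seq_len(prof$n_mito)),
        pident = 60, len = 200L, qstart = 1L, qend = 200L,
        sstart = 1L, send = 200L, evalue = 1e-8, bitscore = 180)
    }
    if (prof$n_silva > 0) {
      hit_rows$silva[[i]] <- blast_row(
        rep(id, prof$n_silva), sprintf("SILVA_%05d", seq_len(prof$n_silva)),
        pident = 80, len = 300L, qstart = 1L, qend = 300L,
        sstart = 1L, send = 300L, evalue = 1e-20, bitscore = 400)
    }
  }

  hits <- lapply(hit_rows, function(rows) {
    rows <- Filter(Negate(is.null), rows)
    if (length(rows) == 0) empty_blast_table() else do.call(rbind, rows)
  })
  list(genes = do.call(rbind, genes_list), hits = hits)
}

#' Assemble per-scaffold gene-hit profiles from gene calls and hit tables
#'
#' Counts, for every scaffold, the predicted genes and the genes with a hit
#' in each gene-level database (a gene is counted once per database no
#' matter how many hit rows it has), plus scaffold-level tblastx hit rows
#' for the mitochondrion and Silva rRNA searches. The result is the
#' sufficient statistic the triage rules operate on.
#'
#' @param genes Gene-call table (`scaffold_id`, `gene_id` columns).
#' @param hits Named list of BLAST tabular data frames as produced by
#'   [emit_hit_tables()] (or parsed from real search output); gene-level
#'   tables keyed `pfam`, `refseq_virus`, `pogs10`, `pogs7`, `aclame`;
#'   scaffold-level tables keyed `mito`, `silva`.
#' @param coverage Named numeric vector (or data frame with `scaffold_id`,
#'   `coverage`) of mean fold-coverage per scaffold.
#' @param max_e E-value cutoff applied to every hit row (default 1e-5).
#' @return Data frame with one row per scaffold: `scaffold_id`, `n_genes`,
#'   `n_pfam`, `n_refseq_virus`, `n_pogs10`, `n_pogs7`, `n_aclame`,
#'   `n_mito`, `n_silva`, `coverage`.
#' @export
build_profiles <- function(genes, hits, coverage, max_e = 1e-5) {
  if (is.data.frame(coverage)) {
    cov <- stats::setNames(coverage$coverage, coverage$scaffold_id)
  } else {
    cov <- coverage
  }
  scaffolds <- unique(genes$scaffold_id)
  gene2scaf <- stats::setNames(genes$scaffold_id, genes$gene_id)

  count_gene_level <- function(tab) {
    if (nrow(tab) == 0) return(stats::setNames(integer(length(scaffolds)), scaffolds))
    tab <- tab[tab$evalue <= max_e, , drop = FALSE]
    hit_genes <- unique(tab$qseqid)
    sc <- gene2scaf[hit_genes]
    if (anyNA(sc)) stop("hit table references unknown gene ids")
    t <- table(factor(sc, levels = scaffolds))
    stats::setNames(as.integer(t), scaffolds)
  }
  count_scaffold_level <- function(tab) {
    if (nrow(tab) == 0) return(stats::setNames(integer(length(scaffolds)), scaffolds))
    tab <- tab[tab$evalue <= max_e, , drop = FALSE]
    t <- table(factor(tab$qseqid, levels = scaffolds))
    stats::setNames(as.integer(t), scaffolds)
  }

  n_genes <- table(factor(genes$scaffold_id, levels = scaffolds))
  out <- data.frame(
    scaffold_id = scaffolds,
    n_genes = as.integer(n_genes),
    n_pfam = count_gene_level(hits$pfam),
    n_refseq_virus = count_gene_level(hits$refseq_virus),
    n_pogs10 = count_gene_level(hits$pogs10),
    n_pogs7 = count_gene_level(hits$pogs7),
    n_aclame = count_gene_level(hits$aclame),
    n_mito = count_scaffold_level(hits$mito),
    n_silva = count_scaffold_level(hits$silva),
    coverage = as.numeric(cov[scaffolds]),
    stringsAsFactors = FALSE, row.names = NULL
  )
  if (anyNA(out$coverage)) stop("missing coverage for some scaffolds")
  out
}
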