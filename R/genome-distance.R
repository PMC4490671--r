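#' Filter all-vs-all genome comparison hits
#'
#' Retains hit rows meeting the whole-genome comparison thresholds: percent
#' identity strictly above `min_ident`, aligned length of at least
#' `min_len` residues, and E-value strictly below `max_e`.
#'
#' @param hits Cross-hit data frame with `pident`, `length`, `evalue`
#'   columns (BLAST tabular naming).
#' @param min_ident Identity threshold in percent, exclusive (default 30).
#' @param min_len Minimum aligned length, inclusive (default 30 amino
#'   acids).
#' @param max_e E-value ceiling, exclusive (default 0.01).
#' @return The filtered data frame.
#' @export
filter_hits <- function(hits, min_ident = 30, min_len = 30, max_e = 0.01) {
  hits[hits$pident > min_ident & hits$length >= min_len &
         hits$evalue < max_e, , drop = FALSE]
}

#' Sum hit bitscores into a genome-pair score matrix
#'
#' `S[a, b]` is the sum of bitscores over all (filtered) hits between
#' genomes `a` and `b`, both query directions pooled so the matrix is
#' symmetric by construction (set `directional = TRUE` to keep
#' query->subject direction separate). Self-comparison hits fill the
#' diagonal, which the Dice denominator requires; genomes with a zero
#' self-score are flagged via the `zero_self` attribute.
#'
#' @param hits Filtered cross-hit data frame with `qseqid`, `sseqid`,
#'   `bitscore`.
#' @param genomes Character vector of genome ids fixing matrix order.
#' @param directional If `TRUE`, `S[a, b]` sums only hits with query `a`
#'   and subject `b`.
#' @return Numeric matrix with `genomes` as dimnames.
#' @export
summed_scores <- function(hits, genomes, directional = FALSE) {
  S <- matrix(0, length(genomes), length(genomes),
              dimnames = list(genomes, genomes))
  if (nrow(hits) > 0) {
    unknown <- setdiff(unique(c(hits$qseqid, hits$sseqid)), genomes)
    if (length(unknown) > 0) {
      stop("hits reference genomes outside the given set: ",
           paste(utils::head(unknown, 3), collapse = ", "))
    }
    qi <- match(hits$qseqid, genomes)
    si <- match(hits$sseqid, genomes)
    for (k in seq_along(qi)) {
      S[qi[k], si[k]] <- S[qi[k], si[k]] + hits$bitscore[k]
      if (!directional && qi[k] != si[k]) {
        S[si[k], qi[k]] <- S[si[k], qi[k]] + hits$bitscore[k]
      }
    }
  }
  zero_self <- genomes[diag(S) == 0]
  if (length(zero_self) > 0) {
    warning("zero self-score for: ", paste(zero_self, collapse = ", "))
  }
  attr(S, "zero_self") <- zero_self
  S
}

#' Dice similarity and dissimilarity matrices from summed scores
#'
#' Computes the Dice coefficient for each genome pair,
#' `D[a, b] = 2 S[a, b] / (S[a, a] + S[b, b])`, and the dissimilarity
#' `1 - D` used for tree building. Pairs with a zero denominator get
#' `D = 0` and both genomes are flagged.
#'
#' @param S Summed-score matrix from [summed_scores()].
#' @return List of class `dice_matrix` with elements `S`, `D`, `dissim`,
#'   `flagged` (ids involved in zero denominators).
#' @export
dice_matrix <- function(S) {
  stopifnot(is.matrix(S), nrow(S) == ncol(S))
  self <- diag(S)
  denom <- outer(self, self, `+`)
  D <- ifelse(denom > 0, 2 * S / denom, 0)
  flagged <- rownames(S)[self == 0]
  dimnames(D) <- dimnames(S)
  structure(list(S = S, D = D, dissim = 1 - D, flagged = flagged),
            class = "dice_matrix")
}

#' @export
print.dice_matrix <- function(x, ...) {
  cat(sprintf("Dice matrix over %d genomes (mean off-diagonal D = %.3f)\n",
              nrow(x$D),
              mean(x$D[upper.tri(x$D)])))
  if (length(x$flagged) > 0) {
    cat("  flagged (zero self-score):", paste(x$flagged, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Neighbor-joining tree from a dissimilarity matrix
#'
#' Textbook neighbor joining (Saitou-Nei, with the Studier-Keppler
#' Q-criterion): at each step the pair minimizing
#' `Q(i, j) = (n - 2) d(i, j) - r(i) - r(j)` is joined, branch lengths
#' follow the standard three-point formulas, and the joined nodes are
#' replaced by their ancestor with `d(u, k) = (d(i, k) + d(j, k) -
#' d(i, j)) / 2`. Ties on Q are broken by the lexicographically smallest
#' pair of clade labels (a clade is labelled by its smallest leaf id), so
#' the output is deterministic and independent of input row order.
#'
#' Negative branch lengths (possible on non-additive input) are clamped to
#' zero with the deficit transferred to the sibling branch of the same
#' join; the unclamped tree is kept in the `raw_newick` attribute.
#'
#' @param dissim Square symmetric dissimilarity matrix with zero diagonal
#'   and genome ids as dimnames.
#' @return An [ape::read.tree()] `phylo` object (unrooted, basal
#'   trichotomy) with attributes `newick` and `raw_newick`. With fewer
#'   than 3 taxa a trivial tree is returned with a warning.
#' @export
nj_tree <- function(dissim) {
  stopifnot(is.matrix(dissim), nrow(dissim) == ncol(dissim))
  ids <- rownames(dissim)
  if (is.null(ids)) stop("dissimilarity matrix must have genome ids as dimnames")
  n <- length(ids)
  if (n < 3) {
    warning("fewer than 3 taxa: returning trivial tree")
    nwk <- if (n == 1) paste0(ids, ";") else
      sprintf("(%s:%.10g,%s:%.10g);", ids[1], dissim[1, 2] / 2,
              ids[2], dissim[1, 2] / 2)
    tr <- ape::read.tree(text = nwk)
    attr(tr, "newick") <- nwk
    attr(tr, "raw_newick") <- nwk
    return(tr)
  }
  if (max(abs(dissim - t(dissim))) > 1e-8) stop("matrix is not symmetric")
  if (any(abs(diag(dissim)) > 1e-12)) stop("diagonal must be zero")

  d <- dissim
  # Per-node state: newick fragments (clamped and raw) and clade label.
  nwk <- stats::setNames(ids, ids)
  raw <- stats::setNames(ids, ids)
  lab <- stats::setNames(ids, ids)
  active <- ids

  fmt <- function(x) sprintf("%.10g", x)
  join_str <- function(frag, v) sprintf("%s:%s", frag, fmt(v))

  while (length(active) > 3) {
    m <- length(active)
    dm <- d[active, active]
    r <- rowSums(dm)
    Q <- (m - 2) * dm - outer(r, r, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q <= qmin + 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    # Deterministic tie-break: smallest (sorted) pair of clade labels.
    pl <- cbind(pmin(lab[active[cand[, 1]]], lab[active[cand[, 2]]]),
                pmax(lab[active[cand[, 1]]], lab[active[cand[, 2]]]))
    pick <- order(pl[, 1], pl[, 2])[1]
    i <- active[cand[pick, 1]]
    j <- active[cand[pick, 2]]

    dij <- d[i, j]
    vi <- dij / 2 + (r[i] - r[j]) / (2 * (m - 2))
    vj <- dij - vi
    # Clamp negatives, transferring the deficit to the sibling branch.
    ci <- vi; cj <- vj
    if (ci < 0) { cj <- cj + ci; ci <- 0 }
    if (cj < 0) { ci <- ci + cj; cj <- 0 }
    ci <- max(ci, 0); cj <- max(cj, 0)

    u <- paste0("u", length(nwk) + 1L)
    others <- setdiff(active, c(i, j))
    du <- (d[i, others] + d[j, others] - dij) / 2
    d <- rbind(cbind(d, rep(0, nrow(d))), rep(0, ncol(d) + 1))
    rownames(d)[nrow(d)] <- u
    colnames(d)[ncol(d)] <- u
    d[u, others] <- du
    d[others, u] <- du

    nwk[u] <- sprintf("(%s,%s)", join_str(nwk[i], ci), join_str(nwk[j], cj))
    raw[u] <- sprintf("(%s,%s)", join_str(raw[i], vi), join_str(raw[j], vj))
    lab[u] <- min(lab[i], lab[j])
    active <- c(others, u)
  }

  # Final three nodes: closed-form three-point branch lengths.
  a <- active[order(lab[active])]
  va <- (d[a[1], a[2]] + d[a[1], a[3]] - d[a[2], a[3]]) / 2
  vb <- (d[a[1], a[2]] + d[a[2], a[3]] - d[a[1], a[3]]) / 2
  vc <- (d[a[1], a[3]] + d[a[2], a[3]] - d[a[1], a[2]]) / 2
  clamp <- function(x) max(x, 0)
  newick <- sprintf("(%s,%s,%s);",
                    join_str(nwk[a[1]], clamp(va)),
                    join_str(nwk[a[2]], clamp(vb)),
                    join_str(nwk[a[3]], clamp(vc)))
  raw_newick <- sprintf("(%s,%s,%s);",
                        join_str(raw[a[1]], va),
                        join_str(raw[a[2]], vb),
                        join_str(raw[a[3]], vc))
  tr <- ape::read.tree(text = newick)
  attr(tr, "newick") <- newick
  attr(tr, "raw_newick") <- raw_newick
  tr
}

#' Group genomes by single-linkage on Dice similarity
#'
#' Connected components of the graph whose edges join genome pairs with
#' `D[a, b] >= threshold`. Components of two or more genomes are the
#' groups; the rest are reported as singletons ("unique" genomes).
#'
#' @param D Dice similarity matrix (the `D` element of [dice_matrix()]).
#' @param threshold Minimum Dice similarity for an edge (default 0.05; the
#'   grouping threshold is a free parameter of the analysis).
#' @return List with `membership` (data frame `genome`, `group`; group 0 =
#'   singleton), `groups` (list of character vectors, size >= 2) and
#'   `singletons` (character vector).
#' @export
cluster_groups <- function(D, threshold = 0.05) {
  ids <- rownames(D)
  n <- length(ids)
  adj <- D >= threshold
  diag(adj) <- FALSE
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] > 0) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue) > 0) {
      v <- queue[[1]]
      queue <- queue[-1]
      nb <- which(adj[v, ] & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  sizes <- table(comp)
  group_comps <- as.integer(names(sizes)[sizes >= 2])
  groups <- lapply(group_comps, function(g) sort(ids[comp == g]))
  groups <- groups[order(vapply(groups, `[[`, "", 1))]
  singles <- sort(ids[comp %in% as.integer(names(sizes)[sizes == 1])])
  membership <- data.frame(genome = ids, group = 0L,
                           stringsAsFactors = FALSE)
  for (g in seq_along(groups)) {
    membership$group[membership$genome %in% groups[[g]]] <- g
  }
  list(membership = membership, groups = groups, singletons = singles)
}
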