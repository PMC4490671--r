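cross_hit <- function(q, s, bitscore, pident = 50, len = 100, evalue = 1e-6) {
  data.frame(qseqid = q, sseqid = s, pident = pident, length = len,
             evalue = evalue, bitscore = bitscore, stringsAsFactors = FALSE)
}

test_that("hit filter applies the whole-genome comparison thresholds", {
  hits <- rbind(cross_hit("a", "b", 50, pident = 30.0),   # identity not > 30
                cross_hit("a", "b", 50, pident = 30.1),
                cross_hit("a", "b", 50, len = 29),        # too short
                cross_hit("a", "b", 50, len = 30),
                cross_hit("a", "b", 50, evalue = 0.01),   # E not < 0.01
                cross_hit("a", "b", 50, evalue = 0.009))
  kept <- filter_hits(hits)
  expect_equal(nrow(kept), 3)
  expect_true(all(kept$pident > 30 & kept$length >= 30 & kept$evalue < 0.01))
  expect_equal(nrow(filter_hits(hits[0, ])), 0)
})

test_that("summed scores pool both directions and match a naive loop", {
  genomes <- c("a", "b", "c")
  hits <- rbind(cross_hit("a", "a", 100), cross_hit("b", "b", 300),
                cross_hit("c", "c", 200),
                cross_hit("a", "b", 50), cross_hit("b", "a", 30))
  S <- summed_scores(hits, genomes)
  expect_equal(S["a", "b"], 80)
  expect_equal(S["b", "a"], 80)
  expect_equal(S["a", "c"], 0)
  expect_true(isSymmetric(unname(S)))

  # Random tables agree with brute-force accumulation.
  withr::with_seed(3, {
    for (rep in 1:10) {
      g <- letters[1:sample(3:8, 1)]
      n <- sample(5:40, 1)
      h <- cross_hit(sample(g, n, replace = TRUE),
                     sample(g, n, replace = TRUE),
                     bitscore = round(stats::runif(n, 20, 500), 1))
      expect_equal(suppressWarnings(summed_scores(h, g)),
                   brute_summed_scores(h, g),
                   ignore_attr = TRUE)
    }
  })

  expect_error(summed_scores(cross_hit("a", "zz", 10), genomes),
               "outside the given set")
  expect_warning(summed_scores(cross_hit("a", "b", 10), c("a", "b")),
                 "zero self-score")
})

test_that("Dice matrix follows the summed-score formula and its bounds", {
  S <- matrix(c(100, 50, 50, 300), 2, 2, dimnames = list(c("a", "b"),
                                                         c("a", "b")))
  dm <- dice_matrix(S)
  expect_equal(dm$D["a", "b"], 2 * 50 / (100 + 300))
  expect_equal(dm$dissim["a", "b"], 0.75)
  expect_equal(diag(dm$D), c(a = 1, b = 1))
  expect_equal(diag(dm$dissim), c(a = 0, b = 0))

  # Duplicated genome: D = 1.
  S2 <- matrix(200, 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(dice_matrix(S2)$D["a", "b"], 1)

  # Zero self-score: D defined as 0 and the genome flagged.
  S3 <- S
  S3["b", "b"] <- 0
  S3["a", "b"] <- S3["b", "a"] <- 0
  dm3 <- dice_matrix(S3)
  expect_equal(dm3$flagged, "b")
  expect_equal(dm3$D["b", "b"], 0)

  # Random S with cross-scores bounded by self-scores keeps D in [0, 1].
  withr::with_seed(9, {
    for (rep in 1:10) {
      n <- sample(3:7, 1)
      self <- stats::runif(n, 50, 500)
      S4 <- diag(self)
      for (i in seq_len(n - 1)) for (j in (i + 1):n) {
        S4[i, j] <- S4[j, i] <- stats::runif(1, 0, min(self[i], self[j]))
      }
      dimnames(S4) <- list(letters[1:n], letters[1:n])
      D <- dice_matrix(S4)$D
      expect_true(all(D >= 0 & D <= 1))
      expect_true(isSymmetric(unname(D)))
    }
  })
})

test_that("neighbor joining recovers additive trees exactly", {
  # Additive matrices from hand-built trees, 4 to 8 taxa: NJ must recover
  # topology and branch lengths (cophenetic distances reproduce the input).
  newicks <- c(
    "((a:2,b:3):1,(c:4,d:5):2);",
    "(((a:1,b:1.5):0.7,c:2.2):0.4,(d:0.9,e:1.1):0.6);",
    "((a:2,(b:1,c:1.2):0.8):0.5,((d:0.7,e:0.9):1.1,(f:1.3,g:0.4):0.2):0.9);",
    "(((a:1,b:2):1,(c:1,d:2):2):1,((e:2,f:1):1.5,(g:1,h:1):0.5):1);"
  )
  for (nwk in newicks) {
    ref <- ape::read.tree(text = nwk)
    dm <- ape::cophenetic.phylo(ref)
    ids <- sort(rownames(dm))
    tr <- nj_tree(dm[ids, ids])
    expect_true(ape::all.equal.phylo(ape::unroot(ref), tr,
                                     use.edge.length = FALSE))
    expect_equal(ape::cophenetic.phylo(tr)[rownames(dm), colnames(dm)], dm,
                 tolerance = 1e-8)
    # Independent implementation agrees on the topology.
    cross <- ape::nj(stats::as.dist(dm))
    expect_true(ape::all.equal.phylo(cross, tr, use.edge.length = FALSE))
    # Taxon-order invariance: permuting the matrix gives an isomorphic tree.
    perm <- sample(ids)
    tr2 <- nj_tree(dm[perm, perm])
    expect_true(ape::all.equal.phylo(tr, tr2, use.edge.length = FALSE))
  }

  # Three taxa: closed-form three-point branch lengths.
  d3 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  t3 <- nj_tree(d3)
  el <- stats::setNames(t3$edge.length,
                        t3$tip.label[t3$edge[, 2]])
  expect_equal(el[c("a", "b", "c")], c(a = 1, b = 2, c = 3))

  expect_warning(nj_tree(d3[1:2, 1:2]), "fewer than 3 taxa")
  expect_error(nj_tree(unname(d3)), "dimnames")
})

test_that("Newick serialization round-trips through ape", {
  dm <- ape::cophenetic.phylo(ape::read.tree(
    text = "((a:2,b:3):1,(c:4,d:5):2);"))
  tr <- nj_tree(dm)
  nwk <- attr(tr, "newick")
  expect_true(endsWith(nwk, ";"))
  back <- ape::read.tree(text = nwk)
  expect_true(ape::all.equal.phylo(back, tr))
})

test_that("Dice-threshold grouping equals graph connected components", {
  # Chain a-b, b-c at threshold 0+ forms one group.
  D <- diag(3)
  dimnames(D) <- list(c("a", "b", "c"), c("a", "b", "c"))
  D["a", "b"] <- D["b", "a"] <- 0.4
  D["b", "c"] <- D["c", "b"] <- 0.2
  g <- cluster_groups(D, threshold = 0.05)
  expect_equal(g$groups, list(c("a", "b", "c")))
  expect_equal(g$singletons, character(0))
  # Threshold above the largest off-diagonal similarity: all singletons.
  g2 <- cluster_groups(D, threshold = 0.5)
  expect_equal(length(g2$groups), 0)
  expect_setequal(g2$singletons, c("a", "b", "c"))

  # Random similarity graphs vs igraph components.
  skip_if_not_installed("igraph")
  withr::with_seed(23, {
    for (rep in 1:15) {
      n <- sample(4:12, 1)
      ids <- sprintf("g%02d", 1:n)
      D <- matrix(0, n, n, dimnames = list(ids, ids))
      pairs <- which(upper.tri(D), arr.ind = TRUE)
      vals <- stats::runif(nrow(pairs))
      D[pairs] <- vals
      D[cbind(pairs[, 2], pairs[, 1])] <- vals
      diag(D) <- 1
      thr <- stats::runif(1, 0.2, 0.9)
      mine <- cluster_groups(D, thr)
      adj <- (D >= thr)
      diag(adj) <- FALSE
      ig <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
      comp <- igraph::components(ig)$membership
      # Same partition: identical co-membership for every pair, with
      # singletons (group 0) as their own components.
      m <- mine$membership$group
      m[m == 0] <- -seq_len(sum(m == 0))
      expect_equal(unname(outer(m, m, `==`)),
                   unname(outer(comp, comp, `==`)))
    }
  })
})

test_that("near-identical genome pair is isolated by the Dice pipeline", {
  # Two copies of one genome among unrelated ones: D ~ 1 for the pair,
  # ~ 0 elsewhere, and grouping isolates the pair.
  genomes <- c("dup1", "dup2", "x", "y")
  hits <- rbind(
    cross_hit("dup1", "dup1", 1000), cross_hit("dup2", "dup2", 1000),
    cross_hit("x", "x", 800), cross_hit("y", "y", 1200),
    cross_hit("dup1", "dup2", 990), cross_hit("dup2", "dup1", 985),
    cross_hit("dup1", "x", 5), cross_hit("y", "dup2", 3))
  S <- summed_scores(filter_hits(hits), genomes)
  dm <- dice_matrix(S)
  expect_gt(dm$D["dup1", "dup2"], 0.95)
  expect_lt(max(dm$D["x", "y"], dm$D["dup1", "x"], dm$D["dup2", "y"]), 0.01)
  g <- cluster_groups(dm$D, threshold = 0.05)
  expect_equal(g$groups, list(c("dup1", "dup2")))
  expect_setequal(g$singletons, c("x", "y"))
})
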