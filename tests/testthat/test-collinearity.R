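test_that("anchor pairs resolve homology records against the genomes", {
  a <- tinyGenome("ga", starts = seq(100L, 1000L, by = 100L))
  b <- tinyGenome("gb", starts = seq(100L, 1000L, by = 100L))
  ga <- geneTable(a)$gene_id
  gb <- geneTable(b)$gene_id
  hom <- homologyTable(ga[1:6], gb[1:6])
  anchors <- findAnchorPairs(a, b, hom)
  expect_equal(nrow(anchors), 6L)
  expect_equal(anchors$ord_a, anchors$ord_b)

  # unresolvable records are skipped with a warning
  hom2 <- rbind(hom, data.frame(gene_a = "missing", gene_b = gb[1],
                                score = 1, e_value = 0))
  expect_warning(anchors2 <- findAnchorPairs(a, b, hom2), "skipped")
  expect_equal(nrow(anchors2), 6L)

  # self-comparison drops the trivial (g, g) pair; all-singleton
  # families give an empty anchor set
  self <- findAnchorPairs(a, a, homologyTable(ga, ga))
  expect_equal(nrow(self), 0L)
})

test_that("chaining recovers diagonals and respects the gap limit", {
  mkAnchors <- function(oa, ob, score = 1) {
    data.frame(gene_a = sprintf("a%d", seq_along(oa)),
               gene_b = sprintf("b%d", seq_along(oa)),
               chr_a = rep("c1", length(oa)),
               chr_b = rep("c2", length(oa)),
               ord_a = oa, ord_b = ob,
               score = rep_len(score, length(oa)),
               stringsAsFactors = FALSE)
  }
  # exact diagonal -> one parallel block
  one <- chainAnchors(mkAnchors(0:9, 10:19))
  expect_equal(length(one), 1L)
  expect_equal(blockTable(one)$orientation, "parallel")
  expect_equal(blockTable(one)$n_anchors, 10L)

  # antiparallel diagonal
  anti <- chainAnchors(mkAnchors(0:9, 19:10))
  expect_equal(blockTable(anti)$orientation, "antiparallel")

  # two 6-anchor runs separated by 51 intervening genes on genome A
  # exceed the 50-gene gap and stay separate blocks
  split <- chainAnchors(mkAnchors(c(0:5, 57:62), c(0:5, 57:62)),
                        maxGap = 50L)
  expect_equal(length(split), 2L)
  # ...but a 50-gene separation is still one block
  joined <- chainAnchors(mkAnchors(c(0:5, 56:61), c(0:5, 56:61)),
                         maxGap = 50L)
  expect_equal(length(joined), 1L)

  expect_equal(length(chainAnchors(mkAnchors(integer(), integer()))), 0L)
})

test_that("chained score equals the exhaustive maximal-chain oracle", {
  set.seed(31)
  for (i in 1:40) {
    n <- sample(4:12, 1)
    anchors <- data.frame(
      gene_a = sprintf("a%d", 1:n), gene_b = sprintf("b%d", 1:n),
      chr_a = "c1", chr_b = "c2",
      ord_a = sample.int(40L, n), ord_b = sample.int(40L, n),
      score = round(runif(n, 0.5, 2), 3), stringsAsFactors = FALSE)
    anchors <- anchors[!duplicated(anchors$ord_a), ]
    blocks <- chainAnchors(anchors, maxGap = 50L, minAnchors = 1L)
    a <- anchorTable(blocks)
    b <- blockTable(blocks)
    first <- a[a$block_id == b$block_id[which.max(b$n_anchors)[1]], ]
    # the best extracted chain must carry the oracle-optimal score;
    # compare the maximum block score against exhaustive search
    scores <- vapply(split(a$score, a$block_id), sum, numeric(1))
    expect_equal(max(scores), oracleBestChainScore(anchors),
                 tolerance = 1e-9)
  }
})

test_that("shrinking the gap never increases chained anchors", {
  set.seed(13)
  for (i in 1:10) {
    n <- 30L
    anchors <- data.frame(
      gene_a = sprintf("a%d", 1:n), gene_b = sprintf("b%d", 1:n),
      chr_a = "c1", chr_b = "c2",
      ord_a = sample.int(120L, n), ord_b = sample.int(120L, n),
      score = 1, stringsAsFactors = FALSE)
    anchors <- anchors[!duplicated(anchors$ord_a) &
                         !duplicated(anchors$ord_b), ]
    total <- vapply(c(50L, 25L, 10L, 5L), function(gp) {
      sum(blockTable(chainAnchors(anchors, maxGap = gp,
                                  minAnchors = 2L))$n_anchors)
    }, numeric(1))
    expect_true(all(diff(total) <= 0))
  }
})

test_that("chaining is symmetric up to coordinate transposition", {
  set.seed(17)
  n <- 25L
  anchors <- data.frame(
    gene_a = sprintf("a%d", 1:n), gene_b = sprintf("b%d", 1:n),
    chr_a = "c1", chr_b = "c2",
    ord_a = sample.int(80L, n), ord_b = sample.int(80L, n),
    score = round(runif(n, 0.5, 3), 3), stringsAsFactors = FALSE)
  fwd <- chainAnchors(anchors, minAnchors = 3L)
  flipped <- anchors
  names(flipped)[match(c("gene_a", "gene_b", "chr_a", "chr_b",
                         "ord_a", "ord_b"), names(flipped))] <-
    c("gene_b", "gene_a", "chr_b", "chr_a", "ord_b", "ord_a")
  rev_ <- chainAnchors(flipped, minAnchors = 3L)
  keyF <- sort(vapply(split(anchorTable(fwd)$gene_a,
                            anchorTable(fwd)$block_id),
                      function(x) paste(sort(x), collapse = ","),
                      character(1)))
  keyR <- sort(vapply(split(anchorTable(rev_)$gene_b,
                            anchorTable(rev_)$block_id),
                      function(x) paste(sort(x), collapse = ","),
                      character(1)))
  expect_equal(unname(keyF), unname(keyR))
})

test_that("block medians follow the stated median rules", {
  mk <- data.frame(gene_a = sprintf("a%d", 1:5),
                   gene_b = sprintf("b%d", 1:5), chr_a = "c1",
                   chr_b = "c2", ord_a = 0:4, ord_b = 0:4, score = 1,
                   stringsAsFactors = FALSE)
  blocks <- chainAnchors(mk, minAnchors = 5L)
  ks3 <- data.frame(gene_a = mk$gene_a[1:3], gene_b = mk$gene_b[1:3],
                    ks = c(0.1, 0.2, 0.9))
  expect_equal(blockTable(attachBlockKs(blocks, ks3))$median_ks, 0.2)
  # fewer than three defined values -> undefined median
  ks2 <- ks3[1:2, ]
  ks2$ks <- c(0.1, 0.3)
  expect_true(is.na(blockTable(attachBlockKs(blocks, ks2))$median_ks))
  # saturated anchors are excluded from the median
  ks4 <- data.frame(gene_a = mk$gene_a[1:4], gene_b = mk$gene_b[1:4],
                    ks = c(0.1, 0.2, 0.3, 2.9),
                    saturated = c(FALSE, FALSE, FALSE, TRUE))
  expect_equal(blockTable(attachBlockKs(blocks, ks4))$median_ks, 0.2)
})

test_that("depth profiles count covering block spans", {
  g <- tinyGenome("tg", starts = seq(100L, 3000L, by = 100L))
  empty <- chainAnchors(data.frame(gene_a = character(),
                                   gene_b = character(),
                                   chr_a = character(),
                                   chr_b = character(),
                                   ord_a = integer(), ord_b = integer(),
                                   score = numeric()))
  expect_true(all(depthProfile(empty, g)$depth == 0L))

  ids <- geneTable(g)$gene_id
  mk <- data.frame(gene_a = ids[11:21], gene_b = sprintf("x%d", 1:11),
                   chr_a = "chr1", chr_b = "cX", ord_a = 10:20,
                   ord_b = 0:10, score = 1, stringsAsFactors = FALSE)
  blocks <- chainAnchors(mk, genomeAName = "tg", genomeBName = "other")
  d <- depthProfile(blocks, g)
  expect_equal(d$depth[d$ordinal >= 10 & d$ordinal <= 20], rep(1L, 11))
  expect_equal(sum(d$depth), 11L)
})

test_that("depth ratio reflects ploidy since divergence on simulation", {
  # lineage X underwent one extra WGD relative to lineage Y after their
  # split: the best-matched region ratio is 2:1
  fx <- list(
    name = "mini", root_node = "R",
    root = list(n_chromosomes = 3L, genes_per_chromosome = 40L),
    ages = list(R = 40, Xm = 25, X = 0, Y = 0),
    lineages = c("X", "Y"),
    branches = list(
      list(from = "R", to = "Xm", rate = 0.004, dnds = 0.2,
           events = list()),
      list(from = "Xm", to = "X", rate = 0.004, dnds = 0.2,
           events = list(list(kind = "WGD", tag = "w"),
                         list(kind = "FRACTIONATION", prob = 0.15))),
      list(from = "R", to = "Y", rate = 0.004, dnds = 0.2,
           events = list())))
  sim <- simulateTrajectory(fx, seed = 8L)
  X <- sim$genomes$X
  Y <- sim$genomes$Y
  mkBlocks <- function(a, b) {
    anchors <- findAnchorPairs(a, b, familyHomology(a, b))
    blk <- chainAnchors(anchors, genomeAName = genomeName(a),
                        genomeBName = genomeName(b))
    attachBlockKs(blk, computeAnchorKs(blk, a, b))
  }
  ratio <- bestMatchRatio(mkBlocks(X, Y), mkBlocks(X, X), mkBlocks(Y, Y),
                          X, Y)
  expect_equal(as.integer(ratio[c("a", "b")]), c(2L, 1L))
})
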