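mkBlockSet <- function(df) {
  # df: chr_a, chr_b, lo_a, hi_a, lo_b, hi_b, median (one row per block)
  anchors <- do.call(rbind, lapply(seq_len(nrow(df)), function(i) {
    n <- 6L
    data.frame(block_id = sprintf("b%02d", i),
               gene_a = sprintf("b%02d_a%d", i, 1:n),
               gene_b = sprintf("b%02d_b%d", i, 1:n),
               chr_a = df$chr_a[i], chr_b = df$chr_b[i],
               ord_a = round(seq(df$lo_a[i], df$hi_a[i], length.out = n)),
               ord_b = round(seq(df$lo_b[i], df$hi_b[i], length.out = n)),
               score = 1, ks = df$median[i], stringsAsFactors = FALSE)
  }))
  blocks <- data.frame(block_id = sprintf("b%02d", seq_len(nrow(df))),
                       genome_a = "T", genome_b = "R",
                       chr_a = df$chr_a, chr_b = df$chr_b,
                       orientation = "parallel", n_anchors = 6L,
                       median_ks = df$median,
                       event_layer = NA_character_,
                       stringsAsFactors = FALSE)
  new("CollinearBlockSet", blocks = blocks, anchors = anchors)
}

test_that("event layers follow the posterior with a 3-sigma guard", {
  peaks <- new("KsPeakSet",
               components = data.frame(mean = c(0.3, 0.9),
                                       sd = c(0.05, 0.1),
                                       weight = c(0.4, 0.6)),
               k = 2L, residual = 0, bandwidth = 0.025)
  bs <- mkBlockSet(data.frame(chr_a = "t1", chr_b = "r1",
                              lo_a = c(0, 40, 80), hi_a = c(30, 70, 110),
                              lo_b = c(0, 40, 80), hi_b = c(30, 70, 110),
                              median = c(0.31, 0.88, 2.5)))
  out <- blockTable(assignEventLayers(bs, peaks))
  expect_equal(out$event_layer, c("P1", "P2", "unassigned"))
  expect_error(assignEventLayers(bs, new("KsPeakSet",
                                         components = data.frame(
                                           mean = numeric(),
                                           sd = numeric(),
                                           weight = numeric()),
                                         k = 0L, residual = 0,
                                         bandwidth = 0.025)),
               "empty")
})

test_that("painting partitions chromosomes and respects merge/min rules", {
  target <- tinyGenome("T", starts = seq(100L, 12000L, by = 100L))
  ref <- tinyGenome("R", starts = seq(100L, 12000L, by = 100L))
  # two blocks to the same reference chromosome within the merge gap,
  # then a different reference, then back (nested-insertion pattern)
  bs <- mkBlockSet(data.frame(
    chr_a = "chr1", chr_b = c("r1", "r1", "r2", "r1"),
    lo_a = c(0, 25, 45, 80), hi_a = c(20, 40, 75, 110),
    lo_b = c(0, 25, 0, 50), hi_b = c(20, 40, 30, 80),
    median = NA_real_))
  segs <- paintGenome(target, ref, bs, mergeGap = 10L, minSegment = 5L)
  expect_equal(nrow(segs), 3L)
  expect_equal(segs$proto_label, c("r1", "r2", "r1"))
  # outer two segments share the label of the interrupted chromosome
  expect_equal(segs$proto_label[1], segs$proto_label[3])

  # gene-level labels: segment fill plus exact anchor overrides
  labs <- paintingLabels(target, segs, blocks = bs)
  expect_equal(unname(labs[geneTable(target)$gene_id[10]]), "r1")
  expect_equal(unname(labs[geneTable(target)$gene_id[60]]), "r2")

  expect_warning(paintGenome(target, ref, chainAnchors(NULL)),
                 "no blocks")
})

test_that("proto-karyotype inference uses multiplicity-bounded components", {
  # a single unrearranged genome painted against itself gives back its
  # own karyotype
  g <- buildProtoKaryotype(4L, 20L, seed = 12L)
  hom <- familyHomology(g, g)
  selfPaint <- data.frame(genome = "root", chromosome = chromosomeNames(g),
                          start_ord = 0L, end_ord = 19L,
                          proto_label = chromosomeNames(g),
                          orientation = "parallel", n_genes = 20L,
                          reference = "root", stringsAsFactors = FALSE)
  proto <- inferProtoKaryotype(list(selfPaint), g,
                               multiplicities = c(root = 1L))
  expect_equal(chromosomeCount(proto$karyotype), 4L)
  expect_equal(length(proto$conflicts), 0L)
})

test_that("branch event classification matches the designed patterns", {
  A <- NodeKaryotype("A", as.list(paste0("A", 1:4)))
  # EEJ
  evE <- classifyBranchEvents(A, NodeKaryotype("c", list(
    c("A1", "A2"), "A3", "A4")))
  expect_equal(sort(evE$kind), c("EEJ"))
  # nested fusion: child = A1 prefix + whole A2 + A1 suffix
  evN <- classifyBranchEvents(A, NodeKaryotype("c", list(
    c("A1", "A2", "A1"), "A3", "A4")))
  expect_equal(evN$kind, "NESTED_FUSION")
  # reciprocal arm exchange, mid-label breakpoints
  evA <- classifyBranchEvents(A, NodeKaryotype("c", list(
    c("A1", "A2"), c("A2", "A1"), "A3", "A4")))
  expect_equal(evA$kind, "ARM_EXCHANGE")
  # identical karyotypes need no events
  expect_equal(nrow(classifyBranchEvents(A, A)), 0L)
})

test_that("classification is event-count-minimal on solvable instances", {
  set.seed(23)
  labels <- paste0("L", 1:5)
  for (i in 1:12) {
    nChrom <- sample(3:5, 1)
    parents <- lapply(sample(labels, nChrom), identity)
    state <- parents
    nEvents <- sample(1:2, 1)
    for (e in seq_len(nEvents)) {
      moves <- oracleMoves(state)
      state <- moves[[sample.int(length(moves), 1)]]
    }
    got <- classifyBranchEvents(NodeKaryotype("p", parents),
                                NodeKaryotype("c", state))
    expect_false(any(got$kind == "unresolved"))
    opt <- oracleMinEvents(parents, state, maxDepth = 3L)
    expect_equal(nrow(got), opt)
  }
})

test_that("bookkeeping validation flags inconsistent trajectories", {
  kar <- list(NodeKaryotype("p", list("A1", "A2")),
              NodeKaryotype("c", list(c("A1", "A2"))))
  names(kar) <- c("p", "c")
  ev <- list(`p->c` = data.frame(kind = "EEJ", detail = "A1 + A2",
                                 stringsAsFactors = FALSE))
  traj <- new("Trajectory", karyotypes = kar, events = ev,
              multiplicities = c(`p->c` = 1))
  expect_true(all(validateBookkeeping(traj)$ok))

  evBad <- list(`p->c` = data.frame(kind = character(),
                                    detail = character()))
  trajBad <- new("Trajectory", karyotypes = kar, events = evBad,
                 multiplicities = c(`p->c` = 1))
  expect_false(all(validateBookkeeping(trajBad)$ok))
})

test_that("bookkeeping holds over random simulated trajectories", {
  root <- buildProtoKaryotype(5L, 12L, seed = 77L)
  set.seed(77)
  for (rep_ in 1:25) {
    g <- root
    nExp <- 5L
    for (k in 1:3) {
      chrs <- chromosomeNames(g)
      kind <- sample(c("EEJ", "NESTED_FUSION", "ARM_EXCHANGE", "WGD"), 1,
                     prob = c(0.35, 0.2, 0.35, 0.1))
      sizes <- table(geneTable(g)$chromosome_id)[chrs]
      big <- chrs[sizes >= 4]
      if (kind == "EEJ" && length(chrs) >= 2) {
        pick <- sample(chrs, 2)
        g <- applyEvent(g, evolutionEvent("EEJ", chr1 = pick[1],
                                          chr2 = pick[2]))
        nExp <- nExp - 1L
      } else if (kind == "NESTED_FUSION" && length(big) >= 1 &&
                 length(chrs) >= 2) {
        host <- sample(big, 1)
        ins <- sample(setdiff(chrs, host), 1)
        g <- applyEvent(g, evolutionEvent("NESTED_FUSION", host = host,
                                          insert = ins, atFrac = 0.5))
        nExp <- nExp - 1L
      } else if (kind == "ARM_EXCHANGE" && length(big) >= 2) {
        pick <- sample(big, 2)
        g <- applyEvent(g, evolutionEvent("ARM_EXCHANGE",
                                          chr1 = pick[1],
                                          chr2 = pick[2],
                                          at1Frac = 0.5, at2Frac = 0.5))
      } else if (kind == "WGD") {
        g <- applyEvent(g, evolutionEvent("WGD",
                                          tag = sprintf("w%d%d", rep_, k)))
        nExp <- nExp * 2L
      }
    }
    expect_equal(length(chromosomeNames(g)), nExp)
  }
})
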