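test_that("candidate segments are the complement of block coverage", {
  lens <- list(a = c(chrA = 100000L), b = c(chrB = 100000L))
  tiling <- data.frame(chr_a = "chrA", start_a = 0L, end_a = 100000L,
                       chr_b = "chrB", start_b = 0L, end_b = 100000L,
                       identity = 1, one_to_one = TRUE)
  expect_equal(nrow(pavCandidates(tiling, lens)), 0L)

  gap <- data.frame(chr_a = "chrA", start_a = c(0L, 60000L),
                    end_a = c(50000L, 100000L), chr_b = "chrB",
                    start_b = c(0L, 50000L), end_b = c(50000L, 90000L),
                    identity = 1, one_to_one = TRUE)
  cand <- pavCandidates(gap, lens)
  onA <- cand[cand$genome == "a", ]
  expect_equal(nrow(onA), 1L)
  expect_equal(c(onA$start, onA$end), c(50000L, 60000L))
  onB <- cand[cand$genome == "b", ]
  expect_equal(c(onB$start, onB$end), c(90000L, 100000L))

  bad <- gap
  bad$end_a[2] <- 100001L
  expect_error(pavCandidates(bad, lens), "out of genome bounds")
})

test_that("candidates match a per-bp coverage oracle on random blocks", {
  set.seed(41)
  len <- 20000L
  for (i in 1:5) {
    n <- sample(3:7, 1)
    st <- sort(sample.int(len - 1000L, n))
    en <- pmin(st + sample(300:2500, n, replace = TRUE), len)
    blocks <- data.frame(chr_a = "c", start_a = st, end_a = en,
                         chr_b = "c", start_b = st, end_b = en,
                         identity = 1, one_to_one = TRUE)
    cand <- pavCandidates(blocks, list(a = c(c = len), b = c(c = len)),
                          minLength = 1L)
    onA <- cand[cand$genome == "a", ]
    cov <- logical(len)
    for (j in seq_len(n)) cov[(st[j] + 1L):en[j]] <- TRUE
    r <- rle(cov)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    oracle <- data.frame(start = starts[!r$values] - 1L,
                         end = ends[!r$values])
    expect_equal(onA$start, oracle$start)
    expect_equal(onA$end, oracle$end)
  }
})

test_that("validation applies the strict 80 percent coverage rule", {
  set.seed(43)
  seqFrom <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                      replace = TRUE), collapse = "")
  candSeq <- seqFrom(1000L)
  filler <- seqFrom(5000L)
  mkGenome <- function(name, chrom, s) {
    AnnotatedGenome(name,
                    data.frame(gene_id = paste0(name, "_g1"),
                               chromosome_id = chrom, start = 1L,
                               end = 10L, strand = "+",
                               stringsAsFactors = FALSE),
                    chromosomeLengths = stats::setNames(nchar(s), chrom),
                    sequence = stats::setNames(s, chrom))
  }
  gA <- mkGenome("A", "cA", paste0(filler, candSeq, seqFrom(3000L)))
  cand <- data.frame(genome = "a", chrom = "cA", start = 5000L,
                     end = 6000L, status = "candidate",
                     residual_coverage = NA_real_,
                     stringsAsFactors = FALSE)

  # fully present verbatim in the other genome -> rejected
  gFull <- mkGenome("B", "cB", paste0(seqFrom(2000L), candSeq))
  full <- validatePavs(cand, gA, gFull)
  expect_equal(full$residual_coverage, 1)
  expect_equal(full$status, "rejected")

  # completely novel -> retained with zero coverage
  gNone <- mkGenome("B", "cB", seqFrom(8000L))
  none <- validatePavs(cand, gA, gNone)
  expect_equal(none$residual_coverage, 0)
  expect_equal(none$status, "retained")

  # exactly 80% present -> retained (strict > rule)
  g80 <- mkGenome("B", "cB", paste0(seqFrom(2000L),
                                    substr(candSeq, 1, 800)))
  at80 <- validatePavs(cand, gA, g80)
  expect_equal(at80$residual_coverage, 0.8)
  expect_equal(at80$status, "retained")
  # just past the threshold -> rejected
  g81 <- mkGenome("B", "cB", paste0(seqFrom(2000L),
                                    substr(candSeq, 1, 810)))
  at81 <- validatePavs(cand, gA, g81)
  expect_equal(at81$residual_coverage, 0.81)
  expect_equal(at81$status, "rejected")
})

test_that("PAV genes require strictly more than 80 percent overlap", {
  g <- tinyGenome("pg", starts = c(1000L, 5000L, 9000L))
  segs <- data.frame(
    genome = "a", chrom = "chr1",
    start = c(900L, 5000L), end = c(1500L, 5150L),   # 100% and 50%
    status = "retained", residual_coverage = 0,
    stringsAsFactors = FALSE)
  pg <- pavGenes(segs, g)
  expect_equal(pg$gene_id, "pg_g1")
  expect_equal(pg$overlap_fraction, 1)

  # exactly 80% overlap is excluded by the strict rule
  segs80 <- data.frame(genome = "a", chrom = "chr1", start = 1000L,
                       end = 1240L, status = "retained",
                       residual_coverage = 0, stringsAsFactors = FALSE)
  expect_equal(nrow(pavGenes(segs80, g)), 0L)
  segs81 <- segs80
  segs81$end <- 1241L
  expect_equal(pavGenes(segs81, g)$gene_id, "pg_g1")
})

test_that("simulated indels are recovered with high precision and recall", {
  pair <- simulatePavPair(seed = 4L)
  res <- runPav(pair)
  ret <- res$segments[res$segments$status == "retained", ]
  truth <- pair$truth
  tNovel <- truth[truth$novel, ]
  sideOf <- function(g) ifelse(g == "accA", "a", "b")
  matched <- logical(nrow(tNovel))
  falsePos <- 0L
  for (i in seq_len(nrow(ret))) {
    hit <- which(sideOf(tNovel$genome) == ret$genome[i] &
                   pmin(tNovel$end, ret$end[i]) -
                     pmax(tNovel$start, ret$start[i]) >
                   0.5 * (tNovel$end - tNovel$start))
    if (length(hit)) matched[hit] <- TRUE else falsePos <- falsePos + 1L
  }
  precision <- 1 - falsePos / max(nrow(ret), 1L)
  recall <- mean(matched)
  expect_gte(precision, 0.95)
  expect_gte(recall, 0.95)

  # copied (non-novel) insertions are rejected by the coverage filter
  tCopied <- truth[truth$kind == "insertion" & !truth$novel, ]
  rej <- res$segments[res$segments$status == "rejected", ]
  for (i in seq_len(nrow(tCopied))) {
    expect_true(any(rej$genome == "b" &
                      pmin(tCopied$end[i], rej$end) -
                        pmax(tCopied$start[i], rej$start) > 0))
  }

  # deleted genes are reported exactly
  pgA <- res$pavGenes$a
  expect_setequal(pgA$gene_id, pair$deletedGenes)
})

test_that("raising the coverage threshold never shrinks the retained set", {
  pair <- simulatePavPair(seed = 6L, nInsertions = 5L, nDeletions = 4L,
                          copiedFraction = 0.5)
  lens <- list(a = chromosomeLengths(pair$genomeA),
               b = chromosomeLengths(pair$genomeB))
  cand <- pavCandidates(pair$blocks, lens)
  counts <- vapply(c(0.2, 0.5, 0.8, 0.95), function(th) {
    v <- validatePavs(cand, pair$genomeA, pair$genomeB,
                      coverageThreshold = th)
    sum(v$status == "retained")
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("identical accessions give an empty PAV report", {
  g <- simulatePavPair(seed = 5L)$genomeA
  blocks <- data.frame(chr_a = "chrA", start_a = 0L,
                       end_a = unname(chromosomeLengths(g)),
                       chr_b = "chrA", start_b = 0L,
                       end_b = unname(chromosomeLengths(g)),
                       identity = 1, one_to_one = TRUE)
  g2 <- g
  g2@name <- "accB"
  res <- runPav(list(genomeA = g, genomeB = g2, blocks = blocks))
  expect_equal(res$summary$n_segments, 0L)
  expect_equal(nrow(res$pavGenes$a), 0L)
})
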