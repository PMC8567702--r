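test_that("annotated genome round-trips through GFF3 and FASTA", {
  cds <- c(toy_g1 = "ATGGCTGCTTAA", toy_g2 = "ATGAAGGGG",
           toy_g3 = "ATGTTTGGGCCC")
  g <- tinyGenome(cds = cds)
  gff <- tempfile(fileext = ".gff3")
  fa <- tempfile(fileext = ".fa")
  writeAnnotatedGenome(g, gff, fa)
  g2 <- readAnnotatedGenome(gff, fa, name = "toy")
  expect_equal(geneTable(g2), geneTable(g))
  expect_equal(sort(names(cdsSequences(g2))), sort(names(cds)))
  expect_equal(cdsSequences(g2)[names(cds)], cds)
  expect_equal(chromosomeLengths(g2), chromosomeLengths(g))
  expect_equal(g2@telomeres$left, g@telomeres$left)
})

test_that("gene ordering assigns ordinals by start with id tie-break", {
  g <- tinyGenome(starts = c(900L, 100L, 500L))  # listed out of order
  gt <- geneTable(g)
  expect_equal(gt$ordinal, 0:2)
  # ordinals must match an independent sort by start
  expect_equal(gt$start, sort(c(900L, 100L, 500L)))
  idx <- geneOrderIndex(g)
  expect_equal(idx[gt$gene_id, "ordinal"], gt$ordinal)
  expect_true(all(!duplicated(idx$gene_id)))
})

test_that("GFF3 reader rejects empty and malformed input", {
  empty <- tempfile(fileext = ".gff3")
  writeLines("##gff-version 3", empty)
  expect_error(readAnnotatedGenome(empty), "no gene features")

  bad <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3", "chr1\tsrc\tgene\t1\t10"), bad)
  expect_error(readAnnotatedGenome(bad), "line 2")
})

test_that("genome validity catches broken invariants", {
  genes <- data.frame(gene_id = c("a", "a"), chromosome_id = "chr1",
                      start = c(1L, 50L), end = c(10L, 60L),
                      strand = "+", stringsAsFactors = FALSE)
  expect_error(AnnotatedGenome("dup", genes), "duplicate gene_id")
  genes2 <- data.frame(gene_id = c("a", "b"), chromosome_id = "chr1",
                       start = c(20L, 50L), end = c(10L, 60L),
                       strand = "+", stringsAsFactors = FALSE)
  expect_error(AnnotatedGenome("rev", genes2), "start must be < end")
})

test_that("homology table applies the e-value cutoff and deduplicates", {
  path <- tempfile()
  writeLines(c("g1\tg2\t90\t1e-30",
               "g2\tg1\t85\t1e-20",    # same pair, other orientation
               "g1\tg3\t50\t1e-3",     # above the cutoff
               "g4\tg5\t70\t1e-10",
               "g6\tg7\t60\tnot_a_number"), path)
  expect_warning(h <- readHomologyTable(path), "non-numeric")
  expect_equal(nrow(h), 2L)
  # canonical pair kept once, with the better e-value
  row <- h[paste(pmin(h$gene_a, h$gene_b),
                 pmax(h$gene_a, h$gene_b)) == "g1 g2", ]
  expect_equal(row$e_value, 1e-30)
  # infinite cutoff retains every numeric row
  suppressWarnings(hAll <- readHomologyTable(path, eValueCutoff = Inf))
  expect_equal(nrow(hAll), 3L)
})

test_that("block tables round-trip losslessly", {
  g <- tinyGenome(starts = seq(100L, 2000L, by = 100L))
  hom <- homologyTable(gene_a = geneTable(g)$gene_id[1:10],
                       gene_b = geneTable(g)$gene_id[11:20])
  anchors <- findAnchorPairs(g, g, hom)
  blocks <- chainAnchors(anchors, minAnchors = 5L,
                         genomeAName = "toy", genomeBName = "toy")
  ks <- data.frame(gene_a = anchors$gene_a, gene_b = anchors$gene_b,
                   ks = seq(0.44080001, by = 0.001,
                            length.out = nrow(anchors)))
  blocks <- attachBlockKs(blocks, ks)
  path <- tempfile()
  writeBlockTable(blocks, path)
  back <- readBlockTable(path)
  expect_equal(blockTable(back), blockTable(blocks), tolerance = 1e-9)
  expect_equal(anchorTable(back), anchorTable(blocks), tolerance = 1e-9)
  # a median survives to at least 6 decimals
  expect_lt(max(abs(blockTable(back)$median_ks -
                      blockTable(blocks)$median_ks), na.rm = TRUE), 1e-6)

  # empty set round trip
  empty <- chainAnchors(anchors[0, ])
  writeBlockTable(empty, path)
  expect_equal(length(readBlockTable(path)), 0L)
})
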