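test_that("proto-karyotype construction honours sizes and determinism", {
  g <- buildProtoKaryotype(10L, 100L, seed = 1L)
  expect_equal(length(chromosomeNames(g)), 10L)
  expect_equal(geneCount(g), 1000L)
  expect_true(all(g@telomeres$left & g@telomeres$right))

  g1 <- buildProtoKaryotype(3L, 20L, seed = 5L)
  g2 <- buildProtoKaryotype(3L, 20L, seed = 5L)
  g3 <- buildProtoKaryotype(3L, 20L, seed = 6L)
  expect_identical(cdsSequences(g1), cdsSequences(g2))
  expect_false(identical(cdsSequences(g1), cdsSequences(g3)))

  cds <- cdsSequences(g1)
  expect_true(all(nchar(cds) %% 3 == 0))
  expect_true(all(nchar(cds) >= 300 & nchar(cds) <= 900))
  # no internal stop codons in frame 1
  hasStop <- vapply(cds, function(s) {
    cods <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
    any(Biostrings::GENETIC_CODE[cods] == "*")
  }, logical(1))
  expect_false(any(hasStop))

  expect_error(buildProtoKaryotype(0L, 100L), "nChromosomes")
  expect_error(buildProtoKaryotype(2L, 5L), "genesPerChromosome")
})

test_that("karyotype events obey chromosome-count bookkeeping", {
  set.seed(2)
  g <- buildProtoKaryotype(8L, 12L, seed = 2L)
  wgd <- applyEvent(g, evolutionEvent("WGD", tag = "x"))
  expect_equal(length(chromosomeNames(wgd)), 16L)
  wgt <- applyEvent(g, evolutionEvent("WGT", tag = "y"))
  expect_equal(length(chromosomeNames(wgt)), 24L)

  eej <- applyEvent(g, evolutionEvent("EEJ", chr1 = "A1", chr2 = "A2"))
  expect_equal(length(chromosomeNames(eej)), 7L)
  joined <- geneTable(eej)
  jc <- joined[joined$chromosome_id == "A1--A2", ]
  expect_equal(nrow(jc), 24L)
  # order: all of A1 then all of A2
  g0 <- geneTable(g)
  expect_equal(jc$gene_id[order(jc$ordinal)],
               c(g0$gene_id[g0$chromosome_id == "A1"][order(
                   g0$ordinal[g0$chromosome_id == "A1"])],
                 g0$gene_id[g0$chromosome_id == "A2"][order(
                   g0$ordinal[g0$chromosome_id == "A2"])]))
  # junction telomeres removed, outer ones kept
  tl <- eej@telomeres[eej@telomeres$chromosome_id == "A1--A2", ]
  expect_true(tl$left && tl$right)
  expect_error(applyEvent(g, evolutionEvent("EEJ", chr1 = "A1",
                                            chr2 = "A1")),
               "itself")

  nf <- applyEvent(g, evolutionEvent("NESTED_FUSION", host = "A1",
                                     insert = "A2", at = 5L))
  expect_equal(length(chromosomeNames(nf)), 7L)
  expect_error(applyEvent(g, evolutionEvent("NESTED_FUSION", host = "A1",
                                            insert = "A2", at = 0L)),
               "EEJ")
  expect_error(applyEvent(g, evolutionEvent("NESTED_FUSION", host = "A1",
                                            insert = "A2", at = 12L)),
               "EEJ")

  ae <- applyEvent(g, evolutionEvent("ARM_EXCHANGE", chr1 = "A1",
                                     chr2 = "A2", at1 = 4L, at2 = 8L))
  expect_equal(length(chromosomeNames(ae)), 8L)
  a1 <- geneTable(ae)
  expect_equal(sum(a1$chromosome_id == "A1"), 4L + 4L)
  expect_equal(sum(a1$chromosome_id == "A2"), 8L + 8L)

  inv <- applyEvent(g, evolutionEvent("INVERSION", chr = "A1", from = 3L,
                                      to = 8L))
  gi <- geneTable(inv)
  gi <- gi[gi$chromosome_id == "A1", ][order(
    gi$ordinal[gi$chromosome_id == "A1"]), ]
  g0a <- g0[g0$chromosome_id == "A1", ][order(
    g0$ordinal[g0$chromosome_id == "A1"]), ]
  expect_equal(gi$gene_id, g0a$gene_id[c(1:2, 8:3, 9:12)])
})

test_that("all events except fractionation preserve gene content", {
  g <- buildProtoKaryotype(4L, 15L, seed = 3L)
  before <- sort(geneTable(g)$family_id)
  for (ev in list(evolutionEvent("EEJ", chr1 = "A1", chr2 = "A3"),
                  evolutionEvent("NESTED_FUSION", host = "A2",
                                 insert = "A4", at = 7L),
                  evolutionEvent("ARM_EXCHANGE", chr1 = "A1",
                                 chr2 = "A2", at1 = 5L, at2 = 9L),
                  evolutionEvent("INVERSION", chr = "A3", from = 2L,
                                 to = 12L))) {
    expect_equal(sort(geneTable(applyEvent(g, ev))$family_id), before)
  }
})

test_that("fractionation respects its probability limits", {
  g <- buildProtoKaryotype(3L, 15L, seed = 4L)
  d <- applyEvent(g, evolutionEvent("WGD", tag = "w"))
  set.seed(10)
  same <- applyEvent(d, evolutionEvent("FRACTIONATION", prob = 0))
  expect_equal(geneCount(same), geneCount(d))
  set.seed(10)
  one <- applyEvent(d, evolutionEvent("FRACTIONATION", prob = 1))
  # exactly one surviving copy per family (count oracle over families)
  expect_equal(unname(table(geneTable(one)$family_id)),
               rep(1L, 45L), ignore_attr = TRUE)
  expect_equal(geneCount(one), 45L)
})

test_that("evolveCds hits the requested synonymous distance", {
  cds <- randomCdsOracle(200)
  expect_identical(evolveCds(cds, 0), cds)
  out <- evolveCds(cds, 0.3, dnds = 0, seed = 1)
  e <- neiGojobori(cds, out)
  expect_equal(e$nd, 0)  # dnds = 0: strictly synonymous changes
  set.seed(21)
  ks <- vapply(1:120, function(i) {
    s <- randomCdsOracle(300)
    neiGojobori(s, evolveCds(s, 0.2, dnds = 0))$Ks
  }, numeric(1))
  expect_gt(mean(ks), 0.185)
  expect_lt(mean(ks), 0.215)
  # saturation warning flag for extreme distances
  expect_true(isTRUE(attr(evolveCds(cds, 3, seed = 1), "saturated")))
})

test_that("the packaged trajectory reproduces its chromosome counts", {
  fx <- coconutFixture(genesPerChromosome = 30L)
  sim <- simulateTrajectory(fx, seed = 42L)
  k <- sim$truth@extra$karyotypes
  counts <- vapply(k[c("A", "B", "C", "D", "E", "Cn")], length,
                   integer(1))
  expect_equal(unname(counts), c(10L, 8L, 16L, 9L, 18L, 16L))
  expect_equal(length(chromosomeNames(sim$genomes$Cn)), 16L)
  expect_equal(length(chromosomeNames(sim$genomes$Sp)), 10L)

  # bookkeeping oracle n' = m * n - EEJ - NESTED_FUSION along each branch
  ev <- sim$truth@events
  nodeOf <- function(x) vapply(strsplit(x, "->"), `[`, character(1), 2)
  path <- c("A", "B", "C", "D", "E", "Cn")
  n <- length(k$A)
  for (i in seq_len(length(path) - 1L)) {
    br <- paste0(path[i], "->", path[i + 1L])
    kinds <- ev$kind[ev$branch == br]
    m <- if ("WGD" %in% kinds) 2L else if ("WGT" %in% kinds) 3L else 1L
    n <- m * n - sum(kinds == "EEJ") - sum(kinds == "NESTED_FUSION")
    expect_equal(length(k[[path[i + 1L]]]), n, label = br)
  }
  # the pre-tau reduction uses exactly two end-to-end joins
  expect_equal(sum(ev$kind == "EEJ" & ev$branch == "A->B"), 2L)
})

test_that("trajectory simulation is deterministic given the seed", {
  fx <- coconutFixture(genesPerChromosome = 20L)
  s1 <- simulateTrajectory(fx, seed = 9L)
  s2 <- simulateTrajectory(fx, seed = 9L)
  expect_identical(lapply(s1$genomes, geneTable),
                   lapply(s2$genomes, geneTable))
  expect_identical(lapply(s1$genomes, cdsSequences),
                   lapply(s2$genomes, cdsSequences))
  # every extant gene traces to exactly one root gene
  gen <- s1$truth@genealogy
  expect_true(all(gen$root_gene %in%
                    geneTable(buildProtoKaryotype(10L, 20L,
                                                  seed = 9L + 7L))$gene_id))
})

test_that("emitted GFF3/FASTA reproduce the simulated genome exactly", {
  fx <- coconutFixture(genesPerChromosome = 20L)
  sim <- simulateTrajectory(fx, seed = 3L)
  sp <- sim$genomes$Sp
  gff <- tempfile(fileext = ".gff3")
  fa <- tempfile(fileext = ".fa")
  writeAnnotatedGenome(sp, gff, fa)
  back <- readAnnotatedGenome(gff, fa, name = "Sp")
  expect_equal(geneTable(back), geneTable(sp))
  expect_equal(cdsSequences(back)[names(cdsSequences(sp))],
               cdsSequences(sp))
})
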