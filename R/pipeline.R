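#' Build a homology table from shared gene families
#'
#' Enumerates all between-genome (or, for a self-comparison, all
#' within-genome) gene pairs sharing a `family_id` — the stand-in for a
#' BLASTP all-against-all when working with simulated genomes whose
#' family labels are known.
#'
#' @param genomeA,genomeB [AnnotatedGenome-class] objects (the same
#'   object for a self-comparison).
#' @return data.frame with `gene_a`, `gene_b`, `score`, `e_value`.
#' @export
familyHomology <- function(genomeA, genomeB = genomeA) {
  selfCmp <- identical(genomeA, genomeB)
  ga <- genomeA@genes
  gb <- genomeB@genes
  fams <- intersect(ga$family_id, gb$family_id)
  out <- list()
  byA <- split(ga$gene_id, ga$family_id)
  byB <- split(gb$gene_id, gb$family_id)
  for (f in fams) {
    a <- byA[[f]]
    b <- byB[[f]]
    pairs <- expand.grid(gene_a = a, gene_b = b,
                         stringsAsFactors = FALSE)
    if (selfCmp) {
      pairs <- pairs[pairs$gene_a < pairs$gene_b, , drop = FALSE]
    }
    if (nrow(pairs)) out[[length(out) + 1L]] <- pairs
  }
  if (!length(out)) {
    return(data.frame(gene_a = character(), gene_b = character(),
                      score = numeric(), e_value = numeric()))
  }
  res <- do.call(rbind, out)
  res$score <- 100
  res$e_value <- 1e-50
  rownames(res) <- NULL
  res
}

# blocks + Ks medians for one genome pair
.blocksWithKs <- function(genomeA, genomeB, maxGap = 50L,
                          minAnchors = 5L) {
  hom <- familyHomology(genomeA, genomeB)
  anchors <- findAnchorPairs(genomeA, genomeB, hom)
  blocks <- chainAnchors(anchors, maxGap = maxGap,
                         minAnchors = minAnchors,
                         genomeAName = genomeName(genomeA),
                         genomeBName = genomeName(genomeB))
  if (length(blocks)) {
    ks <- computeAnchorKs(blocks, genomeA, genomeB)
    blocks <- attachBlockKs(blocks, ks)
  }
  blocks
}

.peakOf <- function(medians, ksMax = 3) {
  v <- medians[is.finite(medians)]
  curve <- kdeDensity(v, ksMax = ksMax)
  fit <- fitKsMixture(curve)
  comp <- peakComponents(fit)
  comp$mean[which.max(comp$weight)]
}

#' Run the packaged coconut-descent demonstration
#'
#' Simulates the packaged trajectory fixture (coconut-like lineage with
#' tau and omega WGDs, basal outgroup, sigma-WGT lineage, eudicot-like
#' calibrator), then runs the full inference pipeline on the simulated
#' genomes: collinearity detection, per-anchor Nei-Gojobori Ks, event
#' layer assignment, proto-karyotype inference by cross-genome painting,
#' node-by-node karyotype reconstruction with branch-event
#' classification, bookkeeping validation, best-matched depth ratios and
#' (unless `skipDating`) rate-corrected WGD dating against the
#' 163-184 Mya calibration.
#'
#' @param seed RNG seed for the simulation.
#' @param genesPerChromosome Proto-chromosome size (default 100).
#' @param skipDating Omit the dating stage (default FALSE).
#' @param outputDir Optional directory: when given, block tables, the
#'   painting, the trajectory report and the summary are written there.
#' @param verbose Print progress (default FALSE).
#' @return List with the simulation, block sets, peaks, painting, proto
#'   inference, trajectory, bookkeeping report, depth ratio and dated
#'   events.
#' @export
runDemo <- function(seed = 1L, genesPerChromosome = 100L,
                    skipDating = FALSE, outputDir = NULL,
                    verbose = FALSE) {
  say <- function(...) if (verbose) message(...)
  say("simulating fixture trajectory (seed ", seed, ")")
  fixture <- coconutFixture(genesPerChromosome)
  sim <- simulateTrajectory(fixture, seed = seed)
  Cn <- sim$genomes$Cn
  Sp <- sim$genomes$Sp
  Ac <- sim$genomes$Ac
  Vv <- sim$genomes$Vv

  say("collinearity and Ks")
  selfCn <- .blocksWithKs(Cn, Cn)
  cnSp <- .blocksWithKs(Cn, Sp)
  cnAc <- .blocksWithKs(Cn, Ac)
  selfAc <- .blocksWithKs(Ac, Ac)

  say("event layers")
  med <- blockTable(selfCn)$median_ks
  curve <- kdeDensity(med[is.finite(med)], ksMax = 3)
  # the 4:1 depth against the unduplicated outgroup indicates two
  # polyploidies, so two components are fitted for layer assignment
  peaks <- fitKsMixture(curve, kMax = 2L)
  selfCn <- assignEventLayers(selfCn, peaks)

  say("painting and proto-karyotype")
  paintCn <- paintGenome(Cn, Sp, cnSp)
  acSp <- .blocksWithKs(Ac, Sp)
  paintAc <- paintGenome(Ac, Sp, acSp)
  proto <- inferProtoKaryotype(list(paintCn, paintAc), Sp,
                               multiplicities = c(Cn = 4L, Ac = 6L))
  # express the painting in final proto labels
  paintFinal <- paintCn
  paintFinal$proto_label <- proto$labels[paintFinal$proto_label]
  geneLabels <- paintingLabels(Cn, paintFinal, blocks = cnSp,
                               refLabels = proto$labels)

  say("node karyotypes and branch events")
  traj <- reconstructNodeKaryotypes(
    Cn, proto$karyotype, geneLabels, selfCn, peaks)
  bookkeeping <- validateBookkeeping(traj)

  say("depth ratio Cn vs Ac")
  ratio <- tryCatch(
    bestMatchRatio(cnAc, selfCn, selfAc, Cn, Ac),
    error = function(e) {
      warning("depth ratio unavailable: ", conditionMessage(e))
      NULL
    })

  dated <- NULL
  if (!skipDating) {
    say("rate correction and dating")
    cnVv <- .blocksWithKs(Cn, Vv)
    spVv <- .blocksWithKs(Sp, Vv)
    acVv <- .blocksWithKs(Ac, Vv)
    orthoPeaks <- c(
      Cn = .peakOf(blockTable(cnVv)$median_ks),
      Sp = .peakOf(blockTable(spVv)$median_ks),
      Ac = .peakOf(blockTable(acVv)$median_ks))
    model <- computeCorrection(orthoPeaks, calibration = c(163, 184))
    bt <- blockTable(selfCn)
    omegaRaw <- .peakOf(bt$median_ks[bt$event_layer %in% "P1"])
    tauRaw <- .peakOf(bt$median_ks[bt$event_layer %in% "P2"])
    corrected <- c(
      omega_wgd = applyCorrection(omegaRaw, model, "Cn"),
      tau_wgd = applyCorrection(tauRaw, model, "Cn"))
    dated <- dateEvents(corrected, model)
    dated$raw_peak <- c(omegaRaw, tauRaw)
  }

  result <- list(seed = seed, sim = sim, blocks = list(
    selfCn = selfCn, cnSp = cnSp, cnAc = cnAc, selfAc = selfAc),
    peaks = peaks, painting = paintFinal, proto = proto,
    trajectory = traj, bookkeeping = bookkeeping, ratio = ratio,
    dated = dated)

  if (!is.null(outputDir)) {
    dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
    writeBlockTable(selfCn, file.path(outputDir, "blocks_Cn_self.tsv"))
    writeBlockTable(cnSp, file.path(outputDir, "blocks_Cn_Sp.tsv"))
    utils::write.table(paintFinal,
                       file.path(outputDir, "painting_Cn.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(.demoReport(result), file.path(outputDir, "summary.txt"))
  }
  result
}

.demoReport <- function(res) {
  counts <- nodeCounts(res$trajectory)
  lines <- c(
    sprintf("seed: %d", res$seed),
    sprintf("proto-chromosomes: %d",
            chromosomeCount(res$proto$karyotype)),
    sprintf("node counts: %s",
            paste(sprintf("%s=%d", names(counts), counts),
                  collapse = " ")),
    "branch events:")
  for (br in names(branchEvents(res$trajectory))) {
    ev <- branchEvents(res$trajectory)[[br]]
    if (!nrow(ev)) next
    tl <- table(ev$kind)
    lines <- c(lines, sprintf("  %s: %s", br,
                              paste(sprintf("%dx %s", as.integer(tl),
                                            names(tl)),
                                    collapse = ", ")))
  }
  if (!is.null(res$ratio)) {
    lines <- c(lines, sprintf("depth ratio Cn:Ac = %d:%d",
                              res$ratio[["a"]], res$ratio[["b"]]))
  }
  if (!is.null(res$dated)) {
    for (i in seq_len(nrow(res$dated))) {
      lines <- c(lines, sprintf("dated %s: %.1f-%.1f Mya",
                                res$dated$event[i], res$dated$age_lo[i],
                                res$dated$age_hi[i]))
    }
  }
  lines
}

#' Run the rate-asymmetric WGD dating experiment
#'
#' Simulates block-median Ks data for two lineages with a 1.5x rate
#' asymmetry and a shared WGD of known age ([simulateKsDating()]), then
#' recovers the age: KDE (bandwidth 0.025) and Gaussian multipeak fitting
#' per distribution, rate correction from the ortholog-vs-outgroup
#' peaks, and calibration to 163-184 Mya.
#'
#' @param seed RNG seed.
#' @param n Block medians per distribution.
#' @param trueAge Simulated WGD age (My).
#' @return List with the simulated data, fitted peaks, correction model
#'   and the dated event table.
#' @export
runDating <- function(seed = 1L, n = 1500L, trueAge = 50) {
  sim <- simulateKsDating(seed = seed, n = n, trueAge = trueAge)
  orthoPeaks <- vapply(sim$ortholog, .peakOf, numeric(1))
  paraPeaks <- vapply(sim$paralog, .peakOf, numeric(1))
  model <- computeCorrection(orthoPeaks, calibration = c(163, 184))
  corrected <- mean(vapply(names(paraPeaks), function(sp) {
    applyCorrection(paraPeaks[[sp]], model, sp)
  }, numeric(1)))
  dated <- dateEvents(c(wgd = corrected), model)
  list(sim = sim, orthologPeaks = orthoPeaks, paralogPeaks = paraPeaks,
       model = model, dated = dated)
}

#' Run the karyotype stage on a completed demo result
#'
#' Re-derives the trajectory report (node karyotypes, branch events,
#' bookkeeping) from a [runDemo()] result; exposed as the stage interface
#' of the karyotype module.
#'
#' @param demo A [runDemo()] result.
#' @return List with the trajectory, bookkeeping report and a printable
#'   report.
#' @export
runKaryotype <- function(demo) {
  list(trajectory = demo$trajectory,
       bookkeeping = demo$bookkeeping,
       report = .demoReport(demo))
}

#' Run the PAV stage on a simulated accession pair
#'
#' Candidate calling from the one-to-one alignment blocks, k-mer
#' validation against the other accession, PAV gene calling and a
#' summary.
#'
#' @param pair A [simulatePavPair()] result (or a list with the same
#'   elements from real aligner output).
#' @param minLength Minimum candidate length (bp).
#' @param coverageThreshold Validation coverage threshold (strict `>`).
#' @param overlapThreshold PAV-gene overlap threshold (strict `>`).
#' @return List with candidates, validated segments, PAV genes per
#'   genome and the summary.
#' @export
runPav <- function(pair, minLength = 100L, coverageThreshold = 0.8,
                   overlapThreshold = 0.8) {
  lens <- list(a = chromosomeLengths(pair$genomeA),
               b = chromosomeLengths(pair$genomeB))
  cand <- pavCandidates(pair$blocks, lens, minLength = minLength)
  val <- validatePavs(cand, pair$genomeA, pair$genomeB,
                      coverageThreshold = coverageThreshold)
  genesA <- pavGenes(val[val$genome == "a", ], pair$genomeA,
                     overlapThreshold)
  genesB <- pavGenes(val[val$genome == "b", ], pair$genomeB,
                     overlapThreshold)
  list(candidates = cand, segments = val,
       pavGenes = list(a = genesA, b = genesB),
       summary = pavSummary(val, rbind(genesA, genesB)))
}
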